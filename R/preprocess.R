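#' Sum XICs across fractions
#'
#' Peptides from fractionated samples are measured in several high-pH
#' fractions; their extracted-ion-chromatogram areas are summed across the
#' fractions of each (peptide, condition, biological replicate, injection)
#' cell before any statistics. The sum ignores missing fractions; a cell is
#' missing only if every fraction is missing.
#'
#' @param table A `quant_tbl` at stage `"raw"`.
#' @return A `quant_tbl` at stage `"fractions_summed"` with `fraction = 1`
#'   everywhere.
#' @export
sum_fractions <- function(table) {
  require_stage(table, "raw", "sum_fractions")
  design <- table_design(table)
  out <- as_tibble(table) |>
    group_by(.data$protein_id, .data$gene_symbol, .data$peptide_key,
             .data$is_proteotypic, .data$gg_positions, .data$condition,
             .data$bio_rep, .data$tech_rep) |>
    summarise(
      xic = if (all(is.na(.data$xic))) NA_real_ else
        sum(.data$xic, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(fraction = 1L)
  # fraction bound 1 after summing regardless of the design's n_fractions
  new_quant_tbl(out[quant_table_cols], design, "fractions_summed")
}

#' Merge technical replicates
#'
#' Repeated MS injections of the same sample are merged by averaging the
#' non-missing XICs on the linear intensity scale (XICs are areas, so the
#' merge happens before any log transform); a value measured once is
#' carried through unchanged.
#'
#' @param table A `quant_tbl` at stage `"fractions_summed"`.
#' @return A `quant_tbl` at stage `"tech_merged"` with `tech_rep = 1`
#'   everywhere.
#' @export
merge_technical_replicates <- function(table) {
  require_stage(table, "fractions_summed", "merge_technical_replicates")
  design <- table_design(table)
  out <- as_tibble(table) |>
    group_by(.data$protein_id, .data$gene_symbol, .data$peptide_key,
             .data$is_proteotypic, .data$gg_positions, .data$condition,
             .data$bio_rep) |>
    summarise(
      xic = if (all(is.na(.data$xic))) NA_real_ else
        mean(.data$xic, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(tech_rep = 1L, fraction = 1L)
  new_quant_tbl(out[quant_table_cols], design, "tech_merged")
}

#' Group peptide observations into quantifiable features
#'
#' Maps merged peptide observations onto the features that will be tested:
#' one group per protein accession (protein-level designs) or one per
#' (protein, GG position) ubiquitylation site (site-level designs; a
#' peptide carrying several GG remnants contributes one observation per
#' site, so multiply-modified evidence is never silently dropped).
#'
#' Non-proteotypic peptides are discarded. Within each group a peptide is
#' retained for model fitting only if it is *shared* between the compared
#' conditions, i.e. has at least one non-missing observation in each.
#' Groups with no shared peptide but observations in exactly one condition
#' are kept and tagged as condition-specific candidates; groups with no
#' observations at all are dropped. Per-feature detection counts (number of
#' biological replicates of each condition with at least one observed
#' peptide) are recorded *before* the shared-peptide filter, so
#' condition-specific features have honest counts.
#'
#' @param table A `quant_tbl` at stage `"tech_merged"`.
#' @param top_n Optional cap on the number of shared peptides used per
#'   feature (highest total intensity first); default `Inf` uses all shared
#'   proteotypic peptides.
#' @return A `feature_groups` object: a tibble of non-missing model-ready
#'   observations (`feature_id`, `level`, `protein_id`, `peptide_key`,
#'   `condition`, `bio_rep`, `value` on the linear scale, `is_shared`) with
#'   a per-feature metadata tibble in `attr(, "features")` (`feature_id`,
#'   `protein_id`, `level`, `specific_flag`, `detect_reps_a`,
#'   `detect_reps_b`, `n_peptides_total`, `n_peptides_shared`).
#' @export
build_feature_groups <- function(table, top_n = Inf) {
  require_stage(table, "tech_merged", "build_feature_groups")
  design <- table_design(table)
  level <- design$feature_level
  df <- as_tibble(table) |>
    filter(.data$is_proteotypic, !is.na(.data$xic))

  if (level == "site") {
    gg <- parse_gg_positions(df$gg_positions)
    n_sites <- vapply(gg, length, integer(1))
    if (any(n_sites == 0L)) {
      abort("Site-level design requires gg_positions on every proteotypic peptide observation.",
            class = "ubiquant_validation_error")
    }
    df <- df[rep(seq_len(nrow(df)), n_sites), ]
    df$site_position <- unlist(gg)
    df$feature_id <- site_key(df$protein_id, df$site_position)
  } else {
    df$feature_id <- df$protein_id
  }

  if (nrow(df) == 0L) {
    abort("No quantifiable observations (after discarding non-proteotypic and missing rows).",
          class = "ubiquant_validation_error")
  }

  cond_a <- design$condition_a
  cond_b <- design$condition_b

  # detection counts per feature, before any peptide filtering
  det <- df |>
    group_by(.data$feature_id) |>
    summarise(
      detect_reps_a = n_distinct(.data$bio_rep[.data$condition == cond_a]),
      detect_reps_b = n_distinct(.data$bio_rep[.data$condition == cond_b]),
      n_peptides_total = n_distinct(.data$peptide_key),
      protein_id = .data$protein_id[1],
      .groups = "drop"
    )

  # shared = observed at least once in EACH condition
  pep_share <- df |>
    group_by(.data$feature_id, .data$peptide_key) |>
    summarise(
      in_a = any(.data$condition == cond_a),
      in_b = any(.data$condition == cond_b),
      total_xic = sum(.data$xic),
      .groups = "drop"
    ) |>
    mutate(is_shared = .data$in_a & .data$in_b)

  if (is.finite(top_n)) {
    pep_share <- pep_share |>
      group_by(.data$feature_id) |>
      arrange(desc(.data$is_shared), desc(.data$total_xic),
              .data$peptide_key, .by_group = TRUE) |>
      mutate(is_shared = .data$is_shared &
               cumsum(.data$is_shared) <= top_n) |>
      ungroup()
  }

  df <- df |>
    left_join(pep_share[c("feature_id", "peptide_key", "is_shared")],
              by = c("feature_id", "peptide_key"))

  feat_flag <- pep_share |>
    group_by(.data$feature_id) |>
    summarise(
      n_peptides_shared = sum(.data$is_shared),
      any_a = any(.data$in_a),
      any_b = any(.data$in_b),
      .groups = "drop"
    ) |>
    mutate(specific_flag = case_when(
      .data$n_peptides_shared > 0L ~ "none",
      .data$any_a & !.data$any_b ~ "a_only",
      .data$any_b & !.data$any_a ~ "b_only",
      TRUE ~ "none" # observed in both conditions but no shared peptide
    ))

  features <- det |>
    left_join(feat_flag[c("feature_id", "n_peptides_shared", "specific_flag")],
              by = "feature_id") |>
    mutate(level = level) |>
    arrange(.data$feature_id)

  obs <- df |>
    transmute(
      feature_id = .data$feature_id,
      level = level,
      protein_id = .data$protein_id,
      peptide_key = .data$peptide_key,
      condition = .data$condition,
      bio_rep = .data$bio_rep,
      value = .data$xic,
      is_shared = .data$is_shared
    ) |>
    arrange(.data$feature_id, .data$peptide_key, .data$condition,
            .data$bio_rep)

  structure(
    obs,
    features = features,
    design = design,
    scale = "linear",
    class = c("feature_groups", class(tibble()))
  )
}

#' @export
print.feature_groups <- function(x, ...) {
  feats <- attr(x, "features")
  cat(sprintf("<feature_groups> %d observations, %d features (%s scale)\n",
              nrow(x), nrow(feats), attr(x, "scale")))
  NextMethod()
}

feature_meta <- function(groups) attr(groups, "features")

restore_groups <- function(df, template, scale = NULL) {
  structure(
    as_tibble(df),
    features = attr(template, "features"),
    design = attr(template, "design"),
    scale = scale %||% attr(template, "scale"),
    normalization_report = attr(template, "normalization_report"),
    class = c("feature_groups", class(tibble()))
  )
}

#' Log2-transform feature-group observations
#'
#' The differential model operates on the log2 intensity scale. Zero
#' intensities are illegal by contract: a zero is an unobserved XIC and
#' must be encoded as missing upstream, since log2(0) would corrupt the
#' statistics.
#'
#' @param groups A `feature_groups` object on the linear scale.
#' @return The same object with `value` replaced by `log2(value)` and the
#'   scale attribute set to `"log2"`.
#' @export
log2_transform <- function(groups) {
  stopifnot(inherits(groups, "feature_groups"))
  if (identical(attr(groups, "scale"), "log2")) {
    abort("Observations are already on the log2 scale.",
          class = "ubiquant_stage_error")
  }
  if (any(groups$value == 0, na.rm = TRUE)) {
    abort("Zero intensities found: encode unobserved XICs as missing (NA), not 0.",
          class = "ubiquant_validation_error")
  }
  if (any(groups$value < 0, na.rm = TRUE)) {
    abort("Negative intensities are invalid.",
          class = "ubiquant_validation_error")
  }
  out <- groups
  out$value <- log2(out$value)
  restore_groups(out, groups, scale = "log2")
}
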