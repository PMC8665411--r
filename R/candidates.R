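#' Select substrate candidates from differential results
#'
#' Applies the screen's selection criteria to a [run_differential()] table:
#' a minimum fold change in the stated direction (boundary included — a
#' fold of exactly 2 passes), an adjusted p-value of at most `alpha`
#' (boundary included), and detection of at least one peptide in
#' `min_detect_reps` biological replicates of *either* condition.
#' Condition-specific features carry no p-value; they are included on the
#' detection filter alone when their presence pattern matches the
#' direction: a feature observed only in condition b behaves as an
#' increase in b, one observed only in condition a as a decrease.
#'
#' @param results A `diff_results` table.
#' @param config A [quant_config()]; `direction`, `fold_threshold`, `alpha`
#'   and `min_detect_reps` are used.
#' @param experiment Label for the experiment (used in integration).
#' @return A `candidate_set`: the selected rows of `results` plus an
#'   `is_specific` column, with the experiment label, direction, feature
#'   level and thresholds attached as attributes.
#' @export
select_candidates <- function(results, config = quant_config(),
                              experiment = "experiment") {
  stopifnot(inherits(results, "diff_results") || is.data.frame(results))
  if (is.null(config$direction)) {
    abort("`direction` must be set in the config.",
          class = "ubiquant_config_error")
  }
  lfc_cut <- log2(config$fold_threshold)
  sign_ok <- if (config$direction == "increase") {
    !is.na(results$log2_fc) & results$log2_fc >= lfc_cut
  } else {
    !is.na(results$log2_fc) & results$log2_fc <= -lfc_cut
  }
  detect_ok <- pmax(results$detect_reps_a, results$detect_reps_b) >=
    config$min_detect_reps
  tested <- sign_ok & !is.na(results$adj_p) &
    results$adj_p <= config$alpha & detect_ok

  specific_dir <- if (config$direction == "increase") "b_only" else "a_only"
  specific_detect <- if (config$direction == "increase") {
    results$detect_reps_b
  } else {
    results$detect_reps_a
  }
  specific <- results$specific_flag == specific_dir &
    specific_detect >= config$min_detect_reps

  out <- as_tibble(results)[tested | specific, ]
  out$is_specific <- specific[tested | specific]
  out <- arrange(out, .data$feature_id)
  level <- if (nrow(out)) out$level[1] else
    (attr(results, "design")$feature_level %||% "protein")
  structure(
    out,
    experiment = experiment,
    direction = config$direction,
    level = level,
    thresholds = list(fold_threshold = config$fold_threshold,
                      alpha = config$alpha,
                      min_detect_reps = config$min_detect_reps),
    class = c("candidate_set", class(tibble()))
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  th <- attr(x, "thresholds")
  if (is.null(th) || !"is_specific" %in% names(x)) return(NextMethod())
  cat(sprintf(
    "<candidate_set '%s'> %d members (%d condition-specific), direction %s, fold >= %g, adj p <= %g\n",
    attr(x, "experiment"), nrow(x), sum(x$is_specific),
    attr(x, "direction"), th$fold_threshold, th$alpha))
  NextMethod()
}

#' Collapse a site-level candidate set to proteins
#'
#' Cross-experiment comparisons are made at the protein level: a site-level
#' (diGly) candidate set is projected to its distinct protein accessions
#' before intersection, keeping the site-to-protein mapping for provenance
#' (protein values may correspond to several sites).
#'
#' @param set A site-level `candidate_set`.
#' @return A protein-level `candidate_set` with one row per distinct
#'   protein; the mapping tibble (`protein_id`, `feature_id`) is attached
#'   as attribute `"site_mapping"`.
#' @export
collapse_sites_to_proteins <- function(set) {
  stopifnot(inherits(set, "candidate_set"))
  if (attr(set, "level") != "site") {
    abort("collapse_sites_to_proteins expects a site-level candidate set.",
          class = "ubiquant_validation_error")
  }
  mapping <- as_tibble(set)[, c("protein_id", "feature_id")]
  proteins <- as_tibble(set) |>
    group_by(.data$protein_id) |>
    arrange(.data$adj_p, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    mutate(feature_id = .data$protein_id, level = "protein") |>
    arrange(.data$feature_id)
  structure(
    proteins,
    experiment = attr(set, "experiment"),
    direction = attr(set, "direction"),
    level = "protein",
    thresholds = attr(set, "thresholds"),
    site_mapping = mapping,
    class = c("candidate_set", class(tibble()))
  )
}

#' Intersect candidate sets across experiments
#'
#' Computes the pairwise and full overlaps (Venn structure) of two or more
#' protein-level candidate sets — site-level sets must be collapsed with
#' [collapse_sites_to_proteins()] first. Membership lists are ordered
#' lexicographically so output is deterministic.
#'
#' @param sets A named list of protein-level `candidate_set` objects;
#'   names are the experiment labels and must be unique.
#' @return An `integration_report`: list with `counts` (tibble: experiment,
#'   n_candidates), `pairwise` (tibble: experiment pair, overlap size,
#'   members as a semicolon-joined string), `common` (character vector,
#'   the full intersection) and `members` (named list of candidate id
#'   vectors).
#' @export
intersect_candidates <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  labels <- names(sets) %||% vapply(sets, attr, "", "experiment")
  if (is.null(names(sets))) names(sets) <- labels
  if (anyDuplicated(labels)) {
    abort("Duplicate experiment labels in candidate sets.",
          class = "ubiquant_validation_error")
  }
  for (lab in labels) {
    if (attr(sets[[lab]], "level") != "protein") {
      abort(sprintf(
        "Candidate set '%s' is site-level: collapse_sites_to_proteins() first.",
        lab), class = "ubiquant_validation_error")
    }
  }
  members <- lapply(sets, function(s) sort(unique(s$feature_id)))
  counts <- tibble(experiment = labels,
                   n_candidates = vapply(members, length, integer(1)))
  pairs <- utils::combn(labels, 2L, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    ov <- sort(intersect(members[[pr[1]]], members[[pr[2]]]))
    tibble(experiment_1 = pr[1], experiment_2 = pr[2],
           n_overlap = length(ov),
           members = paste(ov, collapse = ";"))
  })
  common <- sort(Reduce(intersect, members))
  structure(
    list(counts = counts, pairwise = pairwise, common = common,
         members = members),
    class = "integration_report"
  )
}

#' @export
print.integration_report <- function(x, ...) {
  cat("<integration_report>\n")
  print(x$counts)
  print(x$pairwise[, c("experiment_1", "experiment_2", "n_overlap")])
  cat(sprintf("common to all: %s\n",
              if (length(x$common)) paste(x$common, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Significance stars
#'
#' Figure-legend annotation: `"***"` for p <= 0.001, `"**"` for p <= 0.01,
#' `"*"` for p <= 0.05, empty otherwise; missing p (e.g.
#' condition-specific features) renders empty.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Character vector of star strings.
#' @examples
#' format_significance_stars(c(0.0005, 0.03, 0.2, NA))
#' @export
format_significance_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].", class = "ubiquant_validation_error")
  }
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Cross-experiment heatmap table
#'
#' Long, TSV-serializable table behind the integration heatmaps: rows are
#' candidate features, columns experiments, cells the linear fold change
#' (`2^|log2_fc|`) with its direction and significance stars. Site-level
#' rows repeat the protein-level values of the other experiments for each
#' site of the protein. Stars are computed from the adjusted p-value (the
#' quantity the candidate criterion thresholds); condition-specific members
#' render as `"specific"` with no stars; a feature absent from an
#' experiment yields an empty cell (row omitted from the long table).
#'
#' @param results_list Named list of `diff_results`, one per experiment.
#' @param candidates Named list of `candidate_set` objects (same names)
#'   whose union of members defines the rows.
#' @return A `heatmap_tbl` tibble: `row_id` (site key or protein id),
#'   `protein_id`, `experiment`, `fold`, `direction`, `stars`,
#'   `is_specific`.
#' @export
build_heatmap_table <- function(results_list, candidates) {
  stopifnot(is.list(results_list), is.list(candidates),
            !is.null(names(results_list)),
            all(names(candidates) %in% names(results_list)))
  # row universe: site-level candidates contribute site rows, protein-level
  # candidates protein rows
  rows <- purrr::map_dfr(names(candidates), function(lab) {
    s <- candidates[[lab]]
    tibble(row_id = s$feature_id, protein_id = s$protein_id)
  }) |>
    distinct() |>
    arrange(.data$row_id)

  cells <- purrr::map_dfr(names(results_list), function(lab) {
    r <- as_tibble(results_list[[lab]])
    lvl <- if (nrow(r)) r$level[1] else "protein"
    joined <- if (lvl == "site") {
      inner_join(rows, r, by = c("row_id" = "feature_id",
                                 "protein_id" = "protein_id"))
    } else {
      inner_join(rows, r[, setdiff(names(r), "feature_id")],
                 by = "protein_id")
    }
    joined |>
      transmute(
        row_id = .data$row_id,
        protein_id = .data$protein_id,
        experiment = lab,
        fold = ifelse(is.na(.data$log2_fc), NA_real_,
                      2^abs(.data$log2_fc)),
        direction = case_when(
          .data$specific_flag != "none" ~ "specific",
          .data$log2_fc >= 0 ~ "increase",
          TRUE ~ "decrease"
        ),
        stars = ifelse(.data$specific_flag != "none", "",
                       format_significance_stars(.data$adj_p)),
        is_specific = .data$specific_flag != "none"
      )
  }) |>
    arrange(.data$row_id, .data$experiment)

  structure(cells, class = c("heatmap_tbl", class(tibble())))
}
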