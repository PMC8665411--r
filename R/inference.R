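#' Tukey's-fences outlier mask
#'
#' Classical interquartile-range fences: a value is retained iff it lies
#' within `[Q1 - k * IQR, Q3 + k * IQR]`. Quartiles use linear
#' interpolation (R's default type 7, under which Q1 of `{1, 2, 3, 4}` is
#' 1.75) — stated explicitly because fence membership depends on the
#' convention. Cells with fewer than 4 values are returned unfiltered: the
#' quartiles of 2–3 points carry no outlier information. In the pipeline
#' the values are peptide-centred residuals of one feature within one
#' condition, so that genuine ionization differences between peptides are
#' not mistaken for outliers.
#'
#' @param values Numeric vector (missing values are retained untouched).
#' @param fence_k Non-negative fence multiplier; 1.5 is the conventional
#'   choice.
#' @return A logical vector, `TRUE` where the value is retained.
#' @examples
#' tukey_fences_filter(c(1, 2, 3, 4, 100)) # the 100 is removed
#' @export
tukey_fences_filter <- function(values, fence_k = 1.5) {
  if (fence_k < 0) {
    abort("`fence_k` must be >= 0.", class = "ubiquant_config_error")
  }
  ok <- !is.na(values)
  keep <- rep(TRUE, length(values))
  v <- values[ok]
  if (length(v) < 4L) return(keep)
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - fence_k * iqr
  hi <- q[2] + fence_k * iqr
  keep[ok] <- v >= lo & v <= hi
  keep
}

# Peptide-centred Tukey filtering within each (feature, condition) cell.
# Residual = observation minus its peptide's mean across all replicates of
# both conditions.
apply_outlier_filter <- function(groups, fence_k) {
  obs <- as_tibble(groups) |> filter(.data$is_shared)
  if (nrow(obs) == 0L) {
    return(list(obs = obs,
                removed = tibble(feature_id = character(0),
                                 n_removed = integer(0))))
  }
  obs <- obs |>
    group_by(.data$feature_id, .data$peptide_key) |>
    mutate(resid = .data$value - mean(.data$value)) |>
    group_by(.data$feature_id, .data$condition) |>
    mutate(keep = tukey_fences_filter(.data$resid, fence_k)) |>
    ungroup()
  removed <- obs |>
    group_by(.data$feature_id) |>
    summarise(n_removed = sum(!.data$keep), .groups = "drop")
  list(obs = obs |> filter(.data$keep) |> select(-"resid", -"keep"),
       removed = removed)
}

#' Fit the peptide- and replicate-adjusted linear model for one feature
#'
#' Least-squares fit of the fixed-effects model
#' `log2(x) = mu + beta_peptide + delta * 1[condition = b] + epsilon`:
#' peptide main effects absorb between-peptide ionization differences
#' ("adjusted on peptides") and biological replicates enter as independent
#' observations, i.e. the residual term ("adjusted on biological
#' replicates"). `delta-hat` is the log2 fold change of condition b over
#' condition a; its two-sided p-value comes from the t-distribution with
#' the residual degrees of freedom. A single-peptide feature reduces
#' exactly to a two-sample equal-variance t-test on that peptide's
#' replicate values.
#'
#' @param obs Tibble of one feature's model-ready observations: columns
#'   `peptide_key`, `condition`, `value` (log2 scale, no missing values).
#' @param condition_a,condition_b The reference and test condition labels.
#' @return A one-row tibble: `log2_fc`, `se`, `df`, `raw_p`,
#'   `n_peptides_used`, `n_obs_used`, `note`. When the fit is degenerate
#'   the p-value (and possibly the estimate) is `NA` and `note` says why:
#'   `"insufficient data"` (fewer than 2 observations in a condition),
#'   `"no residual df"`, or `"zero residual variance"`.
#' @export
fit_feature_model <- function(obs, condition_a, condition_b) {
  empty <- tibble(log2_fc = NA_real_, se = NA_real_, df = NA_real_,
                  raw_p = NA_real_,
                  n_peptides_used = n_distinct(obs$peptide_key),
                  n_obs_used = nrow(obs), note = "insufficient data")
  n_a <- sum(obs$condition == condition_a)
  n_b <- sum(obs$condition == condition_b)
  if (n_a < 2L || n_b < 2L) return(empty)

  d <- obs
  d$condition <- factor(d$condition, levels = c(condition_a, condition_b))
  n_pep <- n_distinct(d$peptide_key)
  fit <- if (n_pep > 1L) {
    lm(value ~ peptide_key + condition, data = d)
  } else {
    lm(value ~ condition, data = d)
  }
  cf <- coef(fit)
  term <- paste0("condition", condition_b)
  delta <- unname(cf[term])
  if (is.na(delta)) {
    empty$note <- "condition effect not estimable"
    return(empty)
  }
  rdf <- fit$df.residual
  if (rdf <= 0) {
    return(tibble(log2_fc = delta, se = NA_real_, df = 0, raw_p = NA_real_,
                  n_peptides_used = n_pep, n_obs_used = nrow(d),
                  note = "no residual df"))
  }
  # summary.lm warns on (near-)perfect fits; that is the expected noiseless
  # limit here and is handled via the zero-variance branch below
  se <- unname(suppressWarnings(
    summary(fit)$coefficients[term, "Std. Error"]))
  if (!is.finite(se) || se == 0) {
    return(tibble(log2_fc = delta, se = 0, df = rdf, raw_p = NA_real_,
                  n_peptides_used = n_pep, n_obs_used = nrow(d),
                  note = "zero residual variance"))
  }
  tval <- delta / se
  p <- 2 * pt(-abs(tval), df = rdf)
  tibble(log2_fc = delta, se = se, df = rdf, raw_p = p,
         n_peptides_used = n_pep, n_obs_used = nrow(d), note = "ok")
}

#' Flag a condition-specific feature
#'
#' Features quantified in only one condition bypass the linear model (no
#' fold change or p-value can be computed) and are carried to candidate
#' selection on the detection filter alone.
#'
#' @param obs One feature's observations (columns `condition`, `value`).
#' @param condition_a,condition_b Condition labels.
#' @return `"a_only"` if every observation lies in condition a, `"b_only"`
#'   if in condition b; an error if the feature has observations in both
#'   conditions (it should not have been tagged specific).
#' @export
flag_condition_specific <- function(obs, condition_a, condition_b) {
  in_a <- any(obs$condition == condition_a)
  in_b <- any(obs$condition == condition_b)
  if (in_a && in_b) {
    abort("Feature has observations in both conditions: not condition-specific.",
          class = "ubiquant_contract_error")
  }
  if (in_a) "a_only" else "b_only"
}

#' Benjamini–Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment over the family of *tested*
#' features: missing p-values (condition-specific or degenerate features)
#' are excluded from the family — the BH `m` counts only tested hypotheses
#' — and returned as missing.
#'
#' @param raw_p Numeric vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, same length and order; `NA` where input was
#'   `NA`. Satisfies `adj_p >= raw_p` and monotonicity in the raw ranks.
#' @examples
#' adjust_bh(c(0.01, 0.03, 0.04))
#' @export
adjust_bh <- function(raw_p) {
  ok <- !is.na(raw_p)
  if (any(raw_p[ok] < 0 | raw_p[ok] > 1)) {
    abort("p-values must lie in [0, 1].", class = "ubiquant_validation_error")
  }
  out <- rep(NA_real_, length(raw_p))
  out[ok] <- p.adjust(raw_p[ok], method = "BH")
  out
}

#' Differential-abundance analysis of a quantification table
#'
#' Runs the full statistical stage on a technical-replicate-merged table:
#' feature-group construction (proteotypic, shared-peptide rule, site
#' mapping), log2 transform, per-replicate median-and-scale normalization
#' of the total signal, peptide-centred Tukey's-fences outlier removal
#' within each (feature, condition) cell, the peptide/replicate-adjusted
#' linear model per testable feature (condition-specific features are
#' flagged instead), and Benjamini–Hochberg adjustment across the tested
#' family. Deterministic given its input.
#'
#' @param table A `quant_tbl` at stage `"tech_merged"` (run
#'   [sum_fractions()] and [merge_technical_replicates()] first).
#' @param config A [quant_config()]; `fence_k`, `normalization`,
#'   `scale_estimator` and `top_n` are used here.
#' @return A `diff_results` tibble, one row per feature: `feature_id`,
#'   `protein_id`, `level`, `log2_fc` (condition b over a; `NA` for
#'   condition-specific features), `se`, `df`, `raw_p`, `adj_p`,
#'   `n_peptides_used`, `n_obs_removed_outlier`, `detect_reps_a`,
#'   `detect_reps_b`, `specific_flag`, `note`. The design, config and
#'   normalization report are attached as attributes (see
#'   [normalization_report()]).
#' @examples
#' fx <- fixture_toy_table()
#' res <- fx$table |> sum_fractions() |> merge_technical_replicates() |>
#'   run_differential()
#' res[, c("feature_id", "log2_fc", "adj_p", "specific_flag")]
#' @export
run_differential <- function(table, config = quant_config()) {
  stopifnot(inherits(config, "quant_config"))
  stage <- table_stage(table)
  if (match(stage, quant_stages) < match("tech_merged", quant_stages)) {
    abort(sprintf(
      "run_differential expects a table at stage 'tech_merged' or later, got '%s'; run sum_fractions() and merge_technical_replicates() first.",
      stage), class = "ubiquant_stage_error")
  }
  design <- table_design(table)
  groups <- build_feature_groups(table, top_n = config$top_n)
  groups <- log2_transform(groups)
  groups <- normalize_median_scale(groups, method = config$normalization,
                                   scale_estimator = config$scale_estimator)
  features <- feature_meta(groups)

  filtered <- apply_outlier_filter(groups, config$fence_k)
  model_obs <- filtered$obs

  fits <- model_obs |>
    group_by(.data$feature_id) |>
    reframe(fit_feature_model(pick(everything()),
                              design$condition_a, design$condition_b))

  res <- features |>
    left_join(fits, by = "feature_id") |>
    left_join(filtered$removed, by = "feature_id") |>
    mutate(
      n_obs_removed_outlier = coalesce(.data$n_removed, 0L),
      n_peptides_used = coalesce(.data$n_peptides_used, 0L),
      log2_fc = ifelse(.data$specific_flag == "none", .data$log2_fc, NA_real_),
      raw_p = ifelse(.data$specific_flag == "none", .data$raw_p, NA_real_),
      note = case_when(
        .data$specific_flag != "none" ~ "condition specific",
        is.na(.data$note) ~ "no shared peptide",
        TRUE ~ .data$note
      )
    ) |>
    select(-"n_removed")
  res$adj_p <- adjust_bh(res$raw_p)

  out <- res |>
    transmute(
      feature_id = .data$feature_id,
      protein_id = .data$protein_id,
      level = .data$level,
      log2_fc = .data$log2_fc,
      se = .data$se,
      df = .data$df,
      raw_p = .data$raw_p,
      adj_p = .data$adj_p,
      n_peptides_used = as.integer(.data$n_peptides_used),
      n_obs_removed_outlier = as.integer(.data$n_obs_removed_outlier),
      detect_reps_a = as.integer(.data$detect_reps_a),
      detect_reps_b = as.integer(.data$detect_reps_b),
      specific_flag = .data$specific_flag,
      note = .data$note
    ) |>
    arrange(.data$feature_id)

  structure(
    out,
    design = design,
    config = config,
    normalization_report = attr(groups, "normalization_report"),
    class = c("diff_results", class(tibble()))
  )
}

#' @export
print.diff_results <- function(x, ...) {
  if (all(c("raw_p", "specific_flag") %in% names(x))) {
    cat(sprintf("<diff_results> %d features (%d tested, %d condition-specific)\n",
                nrow(x), sum(!is.na(x$raw_p)),
                sum(x$specific_flag != "none")))
  }
  NextMethod()
}
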