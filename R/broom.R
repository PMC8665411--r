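#' Tidy and summarise differential results
#'
#' `tidy()` returns the per-feature result table as a plain tibble;
#' `glance()` returns a one-row summary of the analysis (feature, tested
#' and candidate-relevant counts).
#'
#' @param x A `diff_results` table.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.diff_results <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.diff_results
#' @exportS3Method generics::glance
glance.diff_results <- function(x, ...) {
  cfg <- attr(x, "config") %||% quant_config()
  design <- attr(x, "design")
  tibble(
    n_features = nrow(x),
    n_tested = sum(!is.na(x$raw_p)),
    n_specific_a = sum(x$specific_flag == "a_only"),
    n_specific_b = sum(x$specific_flag == "b_only"),
    n_sig = sum(x$adj_p <= cfg$alpha, na.rm = TRUE),
    median_se = median(x$se, na.rm = TRUE),
    design = design$name %||% NA_character_
  )
}

#' Tidy and summarise a candidate set
#'
#' @param x A `candidate_set`.
#' @param ... Unused.
#' @return `tidy()`: the member rows as a tibble. `glance()`: one row with
#'   the experiment label, direction, thresholds and member counts.
#' @exportS3Method generics::tidy
tidy.candidate_set <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.candidate_set
#' @exportS3Method generics::glance
glance.candidate_set <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    experiment = attr(x, "experiment"),
    direction = attr(x, "direction"),
    level = attr(x, "level"),
    fold_threshold = th$fold_threshold,
    alpha = th$alpha,
    min_detect_reps = th$min_detect_reps,
    n_members = nrow(x),
    n_specific = sum(x$is_specific)
  )
}
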