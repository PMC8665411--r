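#' Advisory normality check for one replicate's log2 intensities
#'
#' Anderson–Darling goodness-of-fit test of the log2 intensities of one
#' biological replicate against a normal distribution. The check is purely
#' advisory: it is logged in the normalization report and never gates the
#' pipeline — LFQ log-intensity distributions are expected to be roughly
#' normal, and the report lets the analyst spot replicates that are not.
#'
#' @param values Numeric log2 intensities of one replicate (missing values
#'   are dropped). At least 8 non-missing values are required for the test.
#' @return A one-row tibble with `statistic`, `p_value`, `n` and `note`
#'   (`"ok"`, or `"insufficient data"` when `n < 8`, in which case the
#'   statistic and p-value are `NA` and no error is raised).
#' @export
check_normality <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 8L) {
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  n = length(v), note = "insufficient data"))
  }
  t <- nortest::ad.test(v)
  tibble(statistic = unname(t$statistic), p_value = unname(t$p.value),
         n = length(v), note = "ok")
}

robust_scale <- function(x, estimator) {
  switch(estimator,
         mad = mad(x, constant = 1.4826),
         iqr = IQR(x, type = 7) / 1.349)
}

#' Median-and-scale normalization across biological replicates
#'
#' Corrects each biological replicate's log2 intensities for global
#' location and spread differences, using the replicate's *total signal*
#' (all quantified peptide observations of that replicate, not per
#' feature). For replicate column j with median `m_j` and robust scale
#' `s_j`, values are mapped as
#'
#' \deqn{x' = (x - m_j)/s_j \cdot \bar s + \bar m}
#'
#' where `m-bar` and `s-bar` are the across-replicate means of the medians
#' and scales, so intensities stay in their familiar range while all
#' replicates end up with identical medians and scales. The scale
#' estimator is the MAD (scaled by 1.4826) by default, with the IQR
#' available; `method = "median"` centres without rescaling and
#' `method = "none"` is the identity (useful when isolating the behaviour
#' of the downstream estimator).
#'
#' @param groups A `feature_groups` object on the log2 scale.
#' @param method `"median_scale"` (default), `"median"`, or `"none"`.
#' @param scale_estimator `"mad"` or `"iqr"`.
#' @return The normalized `feature_groups`, with a [normalization_report()]
#'   attached: one row per replicate with pre/post medians and scales plus
#'   the advisory [check_normality()] result.
#' @export
normalize_median_scale <- function(groups,
                                   method = c("median_scale", "median", "none"),
                                   scale_estimator = c("mad", "iqr")) {
  stopifnot(inherits(groups, "feature_groups"))
  method <- match.arg(method)
  scale_estimator <- match.arg(scale_estimator)
  if (!identical(attr(groups, "scale"), "log2")) {
    abort("normalize_median_scale expects log2-scale observations.",
          class = "ubiquant_stage_error")
  }
  design <- attr(groups, "design")
  cols <- groups |>
    group_by(.data$condition, .data$bio_rep) |>
    summarise(
      n = sum(!is.na(.data$value)),
      pre_median = median(.data$value, na.rm = TRUE),
      pre_scale = robust_scale(.data$value[!is.na(.data$value)],
                               scale_estimator),
      .groups = "drop"
    )
  if (any(cols$n < 2L)) {
    abort("Replicate with fewer than 2 observations: cannot normalize.",
          class = "ubiquant_normalization_error")
  }
  if (method == "median_scale" && any(cols$pre_scale == 0)) {
    abort("Degenerate scale (robust scale estimate 0) in at least one replicate.",
          class = "ubiquant_normalization_error")
  }
  m_bar <- mean(cols$pre_median)
  s_bar <- mean(cols$pre_scale)

  out <- groups |>
    left_join(cols, by = c("condition", "bio_rep"))
  out$value <- switch(
    method,
    median_scale = (out$value - out$pre_median) / out$pre_scale * s_bar + m_bar,
    median = out$value - out$pre_median + m_bar,
    none = out$value
  )
  out <- out[, names(groups)]

  post <- out |>
    group_by(.data$condition, .data$bio_rep) |>
    summarise(
      post_median = median(.data$value, na.rm = TRUE),
      post_scale = robust_scale(.data$value[!is.na(.data$value)],
                                scale_estimator),
      .groups = "drop"
    )
  norm_check <- out |>
    group_by(.data$condition, .data$bio_rep) |>
    reframe(check_normality(.data$value))
  report <- cols |>
    left_join(post, by = c("condition", "bio_rep")) |>
    left_join(norm_check, by = c("condition", "bio_rep"),
              suffix = c("", "_normality")) |>
    rename(normality_stat = "statistic", normality_p = "p_value",
           normality_note = "note", n_normality = "n_normality") |>
    mutate(method = method, scale_estimator = scale_estimator)

  res <- restore_groups(out, groups)
  attr(res, "normalization_report") <- report
  res
}

#' Retrieve the normalization report
#'
#' @param x A `feature_groups` returned by [normalize_median_scale()] or a
#'   `diff_results` table from [run_differential()].
#' @return A tibble with one row per biological replicate: observation
#'   count, pre/post median and scale, and the advisory normality check.
#' @export
normalization_report <- function(x) {
  attr(x, "normalization_report")
}
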