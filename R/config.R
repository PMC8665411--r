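#' Analysis configuration
#'
#' Bundles the tunable thresholds of the differential-abundance analysis.
#' The defaults reproduce the substrate-screen selection criteria exactly:
#' a minimum 2-fold change, an adjusted p-value of at most 0.05, Tukey's
#' fences with k = 1.5 for outlier removal, and detection in at least three
#' biological replicates of either condition.
#'
#' @param fold_threshold Minimum linear fold change for candidate selection
#'   (> 1; the cut is `|log2 FC| >= log2(fold_threshold)`, boundary
#'   included). Default 2.
#' @param alpha Adjusted p-value cut-off in (0, 1), boundary included.
#'   Default 0.05.
#' @param fence_k Tukey's-fences multiplier (>= 0) for outlier removal.
#'   Default 1.5.
#' @param min_detect_reps Minimum number of biological replicates (in either
#'   condition) in which at least one peptide of a feature must be observed.
#'   Default 3.
#' @param direction Direction of change that defines a candidate:
#'   `"increase"` (proteome screens, substrate accumulates when the ligase
#'   is inactivated) or `"decrease"` (ubiquitylome screens, ubiquitylation
#'   is lost).
#' @param normalization Per-replicate normalization applied to log2
#'   intensities: `"median_scale"` (median centring plus robust scale
#'   matching, the default), `"median"` (centring only), or `"none"`.
#' @param scale_estimator Robust scale estimator for `"median_scale"`:
#'   `"mad"` (median absolute deviation, scaled by 1.4826) or `"iqr"`
#'   (interquartile range, scaled by 1.349).
#' @param top_n Maximum number of shared proteotypic peptides used per
#'   feature, highest total intensity first. Default `Inf` (all shared
#'   peptides are used).
#' @param seed Integer seed recorded in run manifests and used by any stage
#'   that draws random numbers.
#' @return An object of class `quant_config` (a named list).
#' @seealso [load_config()] to read a configuration from JSON or YAML.
#' @export
quant_config <- function(fold_threshold = 2,
                         alpha = 0.05,
                         fence_k = 1.5,
                         min_detect_reps = 3L,
                         direction = c("increase", "decrease"),
                         normalization = c("median_scale", "median", "none"),
                         scale_estimator = c("mad", "iqr"),
                         top_n = Inf,
                         seed = 1L) {
  direction <- match.arg(direction)
  normalization <- match.arg(normalization)
  scale_estimator <- match.arg(scale_estimator)
  cfg_err <- function(msg) abort(msg, class = "ubiquant_config_error")
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1L ||
      is.na(fold_threshold) || fold_threshold <= 1) {
    cfg_err("`fold_threshold` must be a single number > 1.")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    cfg_err("`alpha` must lie strictly inside (0, 1).")
  }
  if (!is.numeric(fence_k) || length(fence_k) != 1L || is.na(fence_k) ||
      fence_k < 0) {
    cfg_err("`fence_k` must be a single number >= 0.")
  }
  if (!is.numeric(min_detect_reps) || length(min_detect_reps) != 1L ||
      is.na(min_detect_reps) || min_detect_reps < 1) {
    cfg_err("`min_detect_reps` must be a positive integer.")
  }
  if (!is.numeric(top_n) || length(top_n) != 1L || is.na(top_n) ||
      top_n < 1) {
    cfg_err("`top_n` must be a positive number (Inf for unlimited).")
  }
  structure(
    list(
      fold_threshold = as.numeric(fold_threshold),
      alpha = as.numeric(alpha),
      fence_k = as.numeric(fence_k),
      min_detect_reps = as.integer(min_detect_reps),
      direction = direction,
      normalization = normalization,
      scale_estimator = scale_estimator,
      top_n = as.numeric(top_n),
      seed = as.integer(seed)
    ),
    class = "quant_config"
  )
}

#' @export
print.quant_config <- function(x, ...) {
  cat(sprintf(
    paste0("<quant_config> fold >= %g, adj p <= %g, fence k = %g, ",
           "detect >= %d reps, direction = %s, normalization = %s\n"),
    x$fold_threshold, x$alpha, x$fence_k, x$min_detect_reps,
    x$direction, x$normalization
  ))
  invisible(x)
}

#' Load an analysis configuration from JSON or YAML
#'
#' Reads a flat mapping whose keys are the arguments of [quant_config()].
#' All keys are optional: unspecified fields take the screen defaults
#' (fold threshold 2, alpha 0.05, fence k 1.5, detection in 3 replicates).
#' Unknown keys raise a configuration error, as do out-of-range values.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `quant_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "ubiquant_io_error")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) {
    abort("Config must be a mapping of option names to values.",
          class = "ubiquant_config_error")
  }
  known <- names(formals(quant_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "ubiquant_config_error")
  }
  do.call(quant_config, raw)
}
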