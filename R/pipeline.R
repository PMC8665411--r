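format_results_tsv <- function(df, path, digits = 6, full_precision = FALSE) {
  out <- as_tibble(df)
  if (!full_precision) {
    num <- vapply(out, is.double, logical(1))
    out[num] <- lapply(out[num], signif, digits = digits)
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Run the full screen pipeline
#'
#' Orchestrates simulate (or read) -> preprocess -> differential analysis ->
#' candidate selection for one or more experiments, then (when at least two
#' experiments are given) the protein-level integration, writing all result
#' tables and a reproducibility manifest under `out_dir`. Given identical
#' inputs and seed, the result TSVs are byte-identical across runs; result
#' floats are written with 6 significant digits for golden-file stability
#' (`full_precision = TRUE` writes round-trip precision).
#'
#' @param experiments A named list describing each experiment. Every entry
#'   is a list with either `input` (path to a raw quantification TSV) or
#'   `params` (a [truth_params()]; the experiment is then simulated), plus
#'   `design` (an [lfq_design()]) and `direction` (`"increase"` or
#'   `"decrease"`).
#' @param config A [quant_config()] shared by all experiments (direction is
#'   overridden per experiment).
#' @param out_dir Output directory, created if needed. Inputs are never
#'   modified; all outputs land here.
#' @param seed Integer seed applied to simulated experiments (experiment i
#'   uses `seed + i - 1`).
#' @param full_precision Write result floats at full precision.
#' @return The run manifest (also written as `manifest.json`): package
#'   version, seed, config, per-stage observation/feature counts, input
#'   checksums and output files with MD5 checksums.
#' @examples
#' \donttest{
#' out <- tempfile("run")
#' mf <- run_pipeline(
#'   list(panub = list(design = screen_designs()$panub,
#'                     params = truth_params(n_features = 30, seed = 3),
#'                     direction = "decrease")),
#'   out_dir = out, seed = 3
#' )
#' mf$stages
#' }
#' @export
run_pipeline <- function(experiments, config = quant_config(),
                         out_dir, seed = config$seed,
                         full_precision = FALSE) {
  stopifnot(is.list(experiments), length(experiments) >= 1L,
            !is.null(names(experiments)))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  outputs <- character(0)
  input_checksums <- list()
  results_list <- list()
  candidate_list <- list()
  truths <- list()

  for (i in seq_along(experiments)) {
    lab <- names(experiments)[i]
    ex <- experiments[[i]]
    if (is.null(ex$design) || !is_lfq_design(ex$design)) {
      abort(sprintf("Experiment '%s' lacks a valid design.", lab),
            class = "ubiquant_config_error")
    }
    if (!is.null(ex$input)) {
      if (!file.exists(ex$input)) {
        abort(sprintf("Experiment '%s': input path not found: %s",
                      lab, ex$input), class = "ubiquant_io_error")
      }
      input_checksums[[lab]] <- unname(tools::md5sum(ex$input))
      table <- read_quant_table(ex$input, ex$design)
    } else if (!is.null(ex$params)) {
      params <- ex$params
      params$seed <- as.integer(seed + i - 1L)
      sim <- simulate_experiment(ex$design, params)
      table <- sim$table
      truths[[lab]] <- sim$truth
      truth_path <- file.path(out_dir, paste0(lab, "_truth.tsv"))
      format_results_tsv(sim$truth, truth_path,
                         full_precision = full_precision)
      table_path <- file.path(out_dir, paste0(lab, "_table.tsv"))
      write_quant_table(table, table_path)
      outputs <- c(outputs, truth_path, table_path)
    } else {
      abort(sprintf("Experiment '%s' needs either `input` or `params`.", lab),
            class = "ubiquant_config_error")
    }

    n_raw <- nrow(table)
    table <- sum_fractions(table)
    table <- merge_technical_replicates(table)
    cfg <- config
    cfg$direction <- ex$direction %||% config$direction
    res <- run_differential(table, cfg)
    cand <- select_candidates(res, cfg, experiment = lab)
    stages[[lab]] <- list(
      n_obs_raw = n_raw,
      n_obs_merged = nrow(table),
      n_features = nrow(res),
      n_tested = sum(!is.na(res$raw_p)),
      n_specific = sum(res$specific_flag != "none"),
      n_candidates = nrow(cand),
      direction = cfg$direction
    )
    inform(sprintf(
      "[%s] %d raw obs -> %d merged obs -> %d features (%d tested, %d specific) -> %d candidates (%s)",
      lab, n_raw, nrow(table), nrow(res), stages[[lab]]$n_tested,
      stages[[lab]]$n_specific, nrow(cand), cfg$direction))

    res_path <- file.path(out_dir, paste0(lab, "_results.tsv"))
    format_results_tsv(res, res_path, full_precision = full_precision)
    cand_path <- file.path(out_dir, paste0(lab, "_candidates.tsv"))
    format_results_tsv(as_tibble(cand), cand_path,
                       full_precision = full_precision)
    volcano_path <- file.path(out_dir, paste0(lab, "_volcano.tsv"))
    format_results_tsv(
      tibble(feature_id = res$feature_id, log2_fc = res$log2_fc,
             minus_log10_raw_p = -log10(res$raw_p)),
      volcano_path, full_precision = full_precision)
    outputs <- c(outputs, res_path, cand_path, volcano_path)
    results_list[[lab]] <- res
    candidate_list[[lab]] <- cand
  }

  if (length(experiments) >= 2L) {
    protein_sets <- lapply(candidate_list, function(s) {
      if (attr(s, "level") == "site") collapse_sites_to_proteins(s) else s
    })
    report <- intersect_candidates(protein_sets)
    overlap_path <- file.path(out_dir, "integration_overlaps.tsv")
    format_results_tsv(report$pairwise, overlap_path)
    counts_path <- file.path(out_dir, "integration_counts.json")
    jsonlite::write_json(
      list(counts = report$counts, common = report$common),
      counts_path, auto_unbox = TRUE, digits = NA)
    heat <- build_heatmap_table(results_list, candidate_list)
    heat_path <- file.path(out_dir, "integration_heatmap.tsv")
    format_results_tsv(heat, heat_path)
    outputs <- c(outputs, overlap_path, counts_path, heat_path)
  }

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  outputs <- c(outputs, cfg_path)

  manifest <- list(
    tool = "ubiquant",
    version = as.character(utils::packageVersion("ubiquant")),
    seed = as.integer(seed),
    config_hash = unname(tools::md5sum(cfg_path)),
    input_checksums = input_checksums,
    stages = stages,
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs)),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 3)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
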