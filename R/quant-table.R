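quant_table_cols <- c(
  "protein_id", "gene_symbol", "peptide_key", "is_proteotypic",
  "gg_positions", "condition", "bio_rep", "tech_rep", "fraction", "xic"
)

quant_stages <- c("raw", "fractions_summed", "tech_merged", "filtered",
                  "normalized")

new_quant_tbl <- function(df, design, stage = "raw") {
  stopifnot(is_lfq_design(design), stage %in% quant_stages)
  out <- as_tibble(df)
  attr(out, "design") <- design
  attr(out, "stage") <- stage
  class(out) <- c("quant_tbl", class(tibble()))
  out
}

#' Access a table's design and processing stage
#'
#' Quantification tables carry their [lfq_design()] and a processing-stage
#' marker (`raw` -> `fractions_summed` -> `tech_merged` -> ...), so that each
#' pipeline step can verify it receives input in the state it expects.
#'
#' @param table A `quant_tbl`.
#' @return `table_design()`: the `lfq_design`. `table_stage()`: a string.
#' @export
table_design <- function(table) {
  d <- attr(table, "design")
  if (!is_lfq_design(d)) {
    abort("Not a quant_tbl: missing design attribute.",
          class = "ubiquant_validation_error")
  }
  d
}

#' @rdname table_design
#' @export
table_stage <- function(table) {
  attr(table, "stage") %||% "raw"
}

set_stage <- function(table, stage) {
  attr(table, "stage") <- match.arg(stage, quant_stages)
  table
}

require_stage <- function(table, stage, caller) {
  have <- table_stage(table)
  ok <- match(have, quant_stages) >= match(stage, quant_stages)
  if (have != stage && !identical(caller, "any")) {
    abort(sprintf("`%s` expects a table at stage '%s', got '%s'.",
                  caller, stage, have),
          class = "ubiquant_stage_error")
  }
  invisible(ok)
}

#' Assemble a peptide quantification table
#'
#' Builds a validated `quant_tbl` from a data frame of peptide extracted-ion
#' chromatogram (XIC) observations: one row per peptide per (condition,
#' biological replicate, technical replicate, fraction) cell. Missing
#' intensities are encoded as `NA`, never zero — the pipeline quantifies only
#' observed XICs, and zeros would corrupt log-scale statistics.
#'
#' @param df Data frame with columns `protein_id`, `gene_symbol`,
#'   `peptide_key`, `is_proteotypic`, `gg_positions` (semicolon-joined
#'   1-based positions, `""` for none), `condition`, `bio_rep`, `tech_rep`,
#'   `fraction`, `xic`. `gene_symbol` and `gg_positions` may be omitted and
#'   default to empty.
#' @param design The [lfq_design()] the observations belong to.
#' @param stage Processing stage of the rows (default `"raw"`).
#' @return A validated `quant_tbl` (a tibble carrying the design and stage
#'   as attributes).
#' @seealso [read_quant_table()], [write_quant_table()]
#' @export
quant_table <- function(df, design, stage = "raw") {
  df <- as_tibble(df)
  if (!"gene_symbol" %in% names(df)) df$gene_symbol <- NA_character_
  if (!"gg_positions" %in% names(df)) df$gg_positions <- ""
  missing_cols <- setdiff(quant_table_cols, names(df))
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")),
          class = "ubiquant_schema_error")
  }
  df <- df[quant_table_cols]
  df$protein_id <- as.character(df$protein_id)
  df$gene_symbol <- as.character(df$gene_symbol)
  df$peptide_key <- as.character(df$peptide_key)
  df$is_proteotypic <- as.logical(df$is_proteotypic)
  df$gg_positions <- as.character(df$gg_positions)
  df$gg_positions[is.na(df$gg_positions)] <- ""
  df$condition <- as.character(df$condition)
  df$bio_rep <- as.integer(df$bio_rep)
  df$tech_rep <- as.integer(df$tech_rep)
  df$fraction <- as.integer(df$fraction)
  df$xic <- as.numeric(df$xic)
  out <- new_quant_tbl(df, design, stage)
  validate_quant_table(out)
}

#' Validate a quantification table against its design
#'
#' Checks the schema and row-level invariants: non-negative (or missing)
#' intensities, labels restricted to the design's two conditions, replicate
#' / injection / fraction indices within the design bounds, uniqueness of
#' the observation key `(peptide_key, condition, bio_rep, tech_rep,
#' fraction)`, and well-formed GG positions. Every violation is reported
#' with its row number.
#'
#' @param table A `quant_tbl`.
#' @return The table, invisibly unchanged, if valid; otherwise an error of
#'   class `ubiquant_validation_error` naming the offending rows.
#' @export
validate_quant_table <- function(table) {
  design <- table_design(table)
  fail <- function(msg) abort(msg, class = "ubiquant_validation_error")
  row_msg <- function(rows, what) {
    sprintf("%s at row(s) %s.", what,
            paste(head(rows, 5L), collapse = ", "))
  }
  neg <- which(!is.na(table$xic) & table$xic < 0)
  if (length(neg)) fail(row_msg(neg, "Negative xic"))
  bad_cond <- which(!table$condition %in% c(design$condition_a,
                                            design$condition_b))
  if (length(bad_cond)) {
    fail(row_msg(bad_cond, sprintf(
      "Condition label outside design {%s, %s}",
      design$condition_a, design$condition_b)))
  }
  n_reps <- ifelse(table$condition == design$condition_a,
                   design$n_reps_a, design$n_reps_b)
  bad_rep <- which(is.na(table$bio_rep) | table$bio_rep < 1L |
                     table$bio_rep > n_reps)
  if (length(bad_rep)) fail(row_msg(bad_rep, "bio_rep outside design bounds"))
  bad_tech <- which(is.na(table$tech_rep) | table$tech_rep < 1L |
                      table$tech_rep > design$n_tech_reps)
  if (length(bad_tech)) {
    fail(row_msg(bad_tech, "tech_rep outside design bounds"))
  }
  bad_frac <- which(is.na(table$fraction) | table$fraction < 1L |
                      table$fraction > design$n_fractions)
  if (length(bad_frac)) {
    fail(row_msg(bad_frac, "fraction outside design bounds"))
  }
  key <- paste(table$peptide_key, table$condition, table$bio_rep,
               table$tech_rep, table$fraction, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    fail(row_msg(dup, "Duplicate observation key (peptide_key, condition, bio_rep, tech_rep, fraction)"))
  }
  gg <- parse_gg_positions(table$gg_positions)
  bad_gg <- which(vapply(gg, function(p) any(is.na(p) | p < 1L), logical(1)))
  if (length(bad_gg)) fail(row_msg(bad_gg, "Malformed gg_positions"))
  has_gg <- vapply(gg, length, integer(1)) > 0L
  if (design$feature_level == "protein" && any(has_gg)) {
    fail(row_msg(which(has_gg),
                 "gg_positions present in a protein-level design"))
  }
  invisible(table)
}

parse_gg_positions <- function(x) {
  if (length(x) == 0L) return(list())
  lapply(strsplit(ifelse(is.na(x) | x == "", NA_character_, x), ";",
                  fixed = TRUE),
         function(p) if (length(p) == 1L && is.na(p)) integer(0)
         else suppressWarnings(as.integer(p)))
}

#' Read and write peptide quantification tables
#'
#' The canonical exchange format is a flat tab-separated table, one row per
#' XIC observation, with the header
#' `protein_id gene_symbol peptide_key is_proteotypic gg_positions condition
#' bio_rep tech_rep fraction xic`. Missing intensities are written/read as
#' `NA` (an empty cell also reads as missing); `gg_positions` is a
#' semicolon-joined list of 1-based residue positions, empty for none.
#' Intensities are written with full (round-trip) precision, so
#' write-then-read reproduces the table exactly.
#'
#' @param path File path of the TSV.
#' @param design The [lfq_design()] the table belongs to.
#' @return `read_quant_table()`: a validated `quant_tbl` at stage `"raw"`
#'   with row order preserved. `write_quant_table()`: `path`, invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' sim <- simulate_experiment(screen_designs()$panub,
#'                            truth_params(n_features = 5, seed = 1))
#' write_quant_table(sim$table, tf)
#' tbl <- read_quant_table(tf, screen_designs()$panub)
#' @export
read_quant_table <- function(path, design) {
  if (!file.exists(path)) {
    abort(sprintf("Input file not found: %s", path),
          class = "ubiquant_io_error")
  }
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      gene_symbol = readr::col_character(),
      peptide_key = readr::col_character(),
      is_proteotypic = readr::col_logical(),
      gg_positions = readr::col_character(),
      condition = readr::col_character(),
      bio_rep = readr::col_integer(),
      tech_rep = readr::col_integer(),
      fraction = readr::col_integer(),
      # parsed as text then converted with strtod: bit-exact round trip
      xic = readr::col_character()
    ),
    na = c("", "NA"),
    progress = FALSE
  )
  df$xic <- as.numeric(df$xic)
  missing_cols <- setdiff(quant_table_cols, names(df))
  if (length(missing_cols)) {
    abort(sprintf("File %s lacks required column(s): %s.", path,
                  paste(missing_cols, collapse = ", ")),
          class = "ubiquant_schema_error")
  }
  quant_table(df, design, stage = "raw")
}

#' @rdname read_quant_table
#' @param table A validated `quant_tbl`.
#' @export
write_quant_table <- function(table, path) {
  validate_quant_table(table)
  out <- as_tibble(table)[quant_table_cols]
  # 17 significant digits guarantee an exact double round-trip
  out$xic <- ifelse(is.na(out$xic), NA_character_,
                    sprintf("%.17g", out$xic))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}
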