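#' Describe an experimental design
#'
#' A design records the comparison layout of one label-free quantification
#' experiment: the two conditions being compared, how many biological
#' replicates each has, how many chromatographic fractions and repeated MS
#' injections (technical replicates) were acquired per replicate, and whether
#' the quantified feature is a whole protein or a ubiquitylation site.
#'
#' @param name Design label. One of `"proteome"`, `"digly"`, `"panub"` or
#'   `"custom"`.
#' @param condition_a Label of the reference condition (e.g. parental cells).
#' @param condition_b Label of the test condition (e.g. a knockout clone).
#'   Fold changes are always reported as `condition_b / condition_a`.
#' @param n_reps_a,n_reps_b Number of biological replicates per condition
#'   (positive integers).
#' @param n_fractions Number of high-pH fractions per biological replicate
#'   (1 for unfractionated runs).
#' @param n_tech_reps Number of repeated MS injections per sample.
#' @param feature_level `"protein"` for whole-protein quantification or
#'   `"site"` for diGly ubiquitylation-site quantification. Site-level
#'   designs require GG-position annotations on the peptide observations.
#'
#' @return An object of class `lfq_design` (a named list).
#' @seealso [screen_designs()] for the three ready-made substrate-screen
#'   designs.
#' @examples
#' lfq_design("custom", "wt", "mut", n_reps_a = 3, n_reps_b = 3)
#' @export
lfq_design <- function(name = c("custom", "proteome", "digly", "panub"),
                       condition_a, condition_b,
                       n_reps_a, n_reps_b,
                       n_fractions = 1L, n_tech_reps = 1L,
                       feature_level = c("protein", "site")) {
  name <- match.arg(name)
  feature_level <- match.arg(feature_level)
  check_count <- function(x, what, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
      abort(sprintf("`%s` must be a single integer >= %d.", what, min),
            class = "ubiquant_design_error")
    }
    as.integer(x)
  }
  if (!is.character(condition_a) || !is.character(condition_b) ||
      identical(condition_a, condition_b)) {
    abort("`condition_a` and `condition_b` must be distinct labels.",
          class = "ubiquant_design_error")
  }
  structure(
    list(
      name = name,
      condition_a = condition_a,
      condition_b = condition_b,
      n_reps_a = check_count(n_reps_a, "n_reps_a"),
      n_reps_b = check_count(n_reps_b, "n_reps_b"),
      n_fractions = check_count(n_fractions, "n_fractions"),
      n_tech_reps = check_count(n_tech_reps, "n_tech_reps"),
      feature_level = feature_level
    ),
    class = "lfq_design"
  )
}

#' The three designs of the RNF111 substrate screen
#'
#' Returns the comparison layouts used when screening for E3-ligase
#' substrates by comparing parental U2OS cells against RNF111-RING-KO
#' clones:
#'
#' * `proteome` — whole-proteome LFQ, 3 parental vs 6 KO biological
#'   replicates, each separated into 6 high-pH fractions;
#' * `digly` — diGly-remnant (K-epsilon-GG) site-level ubiquitylome,
#'   3 vs 3 biological replicates, each injected twice;
#' * `panub` — pan-ubiquitin nanobody protein-level ubiquitylome,
#'   4 vs 8 biological replicates.
#'
#' @return A named list of three [lfq_design()] objects.
#' @examples
#' screen_designs()$proteome
#' @export
screen_designs <- function() {
  list(
    proteome = lfq_design("proteome", "U2OS", "KO", 3L, 6L,
                          n_fractions = 6L, feature_level = "protein"),
    digly = lfq_design("digly", "U2OS", "KO", 3L, 3L,
                       n_tech_reps = 2L, feature_level = "site"),
    panub = lfq_design("panub", "U2OS", "KO", 4L, 8L,
                       feature_level = "protein")
  )
}

#' @export
print.lfq_design <- function(x, ...) {
  cat(sprintf(
    "<lfq_design: %s>  %s (n=%d) vs %s (n=%d), %d fraction(s), %d injection(s), %s-level\n",
    x$name, x$condition_a, x$n_reps_a, x$condition_b, x$n_reps_b,
    x$n_fractions, x$n_tech_reps, x$feature_level
  ))
  invisible(x)
}

is_lfq_design <- function(x) inherits(x, "lfq_design")

#' Ubiquitylation-site keys
#'
#' A ubiquitylation site is a protein accession plus a 1-based lysine
#' position in protein coordinates; its canonical string form is
#' `"<protein_id>_K<position>"` (e.g. `"SKIL_K343"`). `site_key()` formats
#' and `parse_site_key()` inverts it.
#'
#' @param protein_id Character vector of protein accessions.
#' @param position Integer vector of 1-based residue positions.
#' @return `site_key()`: a character vector. `parse_site_key()`: a tibble
#'   with columns `protein_id` and `position`.
#' @examples
#' site_key("SKIL", 343)
#' parse_site_key("SKIL_K343")
#' @export
site_key <- function(protein_id, position) {
  if (any(position < 1 | position != as.integer(position), na.rm = TRUE)) {
    abort("Site positions must be positive integers.",
          class = "ubiquant_validation_error")
  }
  sprintf("%s_K%d", protein_id, as.integer(position))
}

#' @rdname site_key
#' @param key Character vector of site keys.
#' @export
parse_site_key <- function(key) {
  m <- regmatches(key, regexec("^(.*)_K([0-9]+)$", key))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(sprintf("Malformed site key(s): %s",
                  paste(key[bad], collapse = ", ")),
          class = "ubiquant_validation_error")
  }
  tibble(
    protein_id = vapply(m, `[`, character(1), 2L),
    position = as.integer(vapply(m, `[`, character(1), 3L))
  )
}
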