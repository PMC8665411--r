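#' Ground-truth parameters for the synthetic-data generator
#'
#' Describes the generative model behind [simulate_experiment()]. For
#' feature f, peptide p, biological replicate r of condition c, and
#' injection t, the log2 intensity is
#'
#' \deqn{B_f + P_p + R_{c,r} + \Delta_f \, 1[c = b] + \epsilon + \tau_t}
#'
#' with feature baseline `B ~ N(baseline_log2_mean, baseline_log2_sd)`,
#' peptide ionization offset `P ~ N(0, sigma_peptide)`, replicate effect
#' `R ~ N(0, sigma_rep)` (shared by all peptides measured in that
#' replicate), residual `epsilon ~ N(0, sigma_noise)` and per-injection
#' noise `tau ~ N(0, sigma_tech)`. `Delta_f` equals `log2fc_changed` for
#' the changed features and 0 otherwise. Condition-specific features have
#' all observations of the other condition removed. Each observation is
#' shifted by `outlier_shift` with probability `outlier_rate`, and dropped
#' with probability `missing_rate_base` (optionally intensity-dependent).
#'
#' Defaults emulate a realistic E3-ligase substrate screen: about 1% of
#' features truly changed (screens of this kind report hit rates of
#' 0.6–1.3%), a 1.5 log2-unit injected effect (comfortably past the 2-fold
#' candidate cut), replicate SD 0.3 and residual SD 0.5 log2 units
#' (equivalent to 20–40% CVs), 1% outlier observations shifted by 4 log2
#' units, and 5% missing observations.
#'
#' @param n_features Number of quantified features (proteins or sites).
#' @param peptides_per_feature Integer range `c(min, max)` of peptides per
#'   feature, drawn uniformly.
#' @param frac_changed Fraction of features with an injected fold change;
#'   exactly `round(frac_changed * n_features)` features are changed.
#' @param log2fc_changed Injected log2 fold change (condition b over a).
#' @param frac_specific_a,frac_specific_b Fractions of features observed
#'   only in condition a (resp. b).
#' @param sigma_rep Biological-replicate SD (log2 units).
#' @param sigma_noise Residual SD (log2 units).
#' @param sigma_tech Technical-replicate (injection) SD (log2 units).
#' @param sigma_peptide SD of per-peptide ionization offsets (log2 units);
#'   peptide ionization efficiency dominates between-peptide variance in
#'   real LFQ data, hence the default of 1.
#' @param outlier_rate Probability that an observation is an outlier.
#' @param outlier_shift Log2 shift applied to outlier observations.
#' @param missing_rate_base Marginal missingness rate.
#' @param missing_mode `"mcar"` (missing completely at random, default) or
#'   `"intensity"` (logistic in log2 intensity: low-abundance observations
#'   are more likely to be missing).
#' @param baseline_log2_mean,baseline_log2_sd Mean and SD of feature
#'   baseline log2 intensities.
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical output.
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(n_features = 200L,
                         peptides_per_feature = c(2L, 6L),
                         frac_changed = 0.01,
                         log2fc_changed = 1.5,
                         frac_specific_a = 0.005,
                         frac_specific_b = 0.005,
                         sigma_rep = 0.3,
                         sigma_noise = 0.5,
                         sigma_tech = 0.2,
                         sigma_peptide = 1,
                         outlier_rate = 0.01,
                         outlier_shift = 4,
                         missing_rate_base = 0.05,
                         missing_mode = c("mcar", "intensity"),
                         baseline_log2_mean = 20,
                         baseline_log2_sd = 2,
                         seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  cfg_err <- function(msg) abort(msg, class = "ubiquant_config_error")
  chk_rate <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      cfg_err(sprintf("`%s` must be a rate in [0, 1].", what))
    }
  }
  chk_sd <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
      cfg_err(sprintf("`%s` must be a non-negative SD.", what))
    }
  }
  if (n_features < 1 || n_features != as.integer(n_features)) {
    cfg_err("`n_features` must be a positive integer.")
  }
  ppf <- as.integer(peptides_per_feature)
  if (length(ppf) != 2L || any(is.na(ppf)) || ppf[1] < 1L || ppf[2] < ppf[1]) {
    cfg_err("`peptides_per_feature` must be an increasing positive range c(min, max).")
  }
  for (r in c("frac_changed", "frac_specific_a", "frac_specific_b",
              "outlier_rate", "missing_rate_base")) {
    chk_rate(get(r), r)
  }
  for (s in c("sigma_rep", "sigma_noise", "sigma_tech", "sigma_peptide",
              "baseline_log2_sd")) {
    chk_sd(get(s), s)
  }
  if (frac_changed + frac_specific_a + frac_specific_b > 1) {
    cfg_err("frac_changed + frac_specific_a + frac_specific_b must not exceed 1.")
  }
  structure(
    list(
      n_features = as.integer(n_features),
      peptides_per_feature = ppf,
      frac_changed = frac_changed,
      log2fc_changed = log2fc_changed,
      frac_specific_a = frac_specific_a,
      frac_specific_b = frac_specific_b,
      sigma_rep = sigma_rep,
      sigma_noise = sigma_noise,
      sigma_tech = sigma_tech,
      sigma_peptide = sigma_peptide,
      outlier_rate = outlier_rate,
      outlier_shift = outlier_shift,
      missing_rate_base = missing_rate_base,
      missing_mode = missing_mode,
      baseline_log2_mean = baseline_log2_mean,
      baseline_log2_sd = baseline_log2_sd,
      seed = as.integer(seed)
    ),
    class = "truth_params"
  )
}

# Uniform integer draw in [lo, hi], one runif() consumed per element so the
# RNG stream length never depends on the drawn values.
runif_int <- function(n, lo, hi) {
  pmin(lo + as.integer(floor(runif(n) * (hi - lo + 1L))), hi)
}

#' Simulate a label-free quantification experiment with known truth
#'
#' Generates a raw peptide XIC table under the generative model documented
#' in [truth_params()], together with the ground truth needed for
#' parameter-recovery and FDR-control tests. All randomness flows from a
#' single RNG stream keyed by `params$seed` and consumed in a fixed,
#' documented order (feature flags, baselines, peptide counts, site
#' positions, peptide offsets, replicate effects, residuals, injection
#' noise, outliers, fraction splitting, missingness), so identical inputs
#' give bit-identical output.
#'
#' Fractionated designs split each injection-level intensity across one or
#' two randomly chosen fractions with random proportions summing to 1 on
#' the linear scale, mirroring a peptide eluting in few adjacent high-pH
#' fractions; summing fractions recovers the pre-split intensity exactly.
#' Missingness is applied to the emitted rows (i.e. after fraction
#' splitting). Site-level designs attach one GG position per feature, with
#' neighbouring features sharing a protein part of the time so that the
#' site-within-protein hierarchy is represented.
#'
#' @param design An [lfq_design()].
#' @param params A [truth_params()].
#' @return An object of class `lfq_simulation`: a list with elements
#'   `table` (a raw-stage `quant_tbl`), `truth` (tibble: `feature_id`,
#'   `protein_id`, `true_log2fc` — `NA` for condition-specific features —,
#'   `specific_flag`, `n_peptides`), `outliers` (tibble of shifted
#'   observation keys), `presplit` (pre-fractionation injection-level
#'   intensities, `NULL` for unfractionated designs) and `params`.
#' @examples
#' sim <- simulate_experiment(screen_designs()$panub,
#'                            truth_params(n_features = 20, seed = 7))
#' dplyr::count(sim$truth, specific_flag)
#' @export
simulate_experiment <- function(design, params = truth_params()) {
  stopifnot(is_lfq_design(design), inherits(params, "truth_params"))
  p <- params
  n <- p$n_features
  set.seed(p$seed)

  # 1. feature flags (exact counts by construction)
  n_changed <- round(p$frac_changed * n)
  n_spec_a <- round(p$frac_specific_a * n)
  n_spec_b <- round(p$frac_specific_b * n)
  ord <- sample.int(n)
  flag <- rep("none", n)
  delta <- rep(0, n)
  if (n_changed > 0) delta[ord[seq_len(n_changed)]] <- p$log2fc_changed
  if (n_spec_a > 0) flag[ord[n_changed + seq_len(n_spec_a)]] <- "a_only"
  if (n_spec_b > 0) flag[ord[n_changed + n_spec_a + seq_len(n_spec_b)]] <- "b_only"

  # 2. baselines
  baseline <- rnorm(n, p$baseline_log2_mean, p$baseline_log2_sd)

  # 3. peptide counts
  n_pep <- runif_int(n, p$peptides_per_feature[1], p$peptides_per_feature[2])

  # 4. protein / site bookkeeping
  if (design$feature_level == "site") {
    share <- c(FALSE, runif(n - 1L) < 0.3)
    protein_idx <- cumsum(!share)
    protein_id <- sprintf("PROT%05d", protein_idx)
    position <- runif_int(n, 50L, 950L)
    # de-duplicate positions within a protein deterministically
    repeat {
      key <- paste(protein_id, position)
      dup <- duplicated(key)
      if (!any(dup)) break
      position[dup] <- position[dup] + 1L
    }
    feature_id <- site_key(protein_id, position)
    gg <- as.character(position)
  } else {
    protein_id <- sprintf("PROT%05d", seq_len(n))
    feature_id <- protein_id
    gg <- rep("", n)
  }

  # 5. peptide offsets
  pep_feature <- rep(seq_len(n), n_pep)
  pep_within <- sequence(n_pep)
  pep_key <- sprintf("%s_pep%02d", feature_id[pep_feature], pep_within)
  pep_offset <- rnorm(length(pep_key), 0, p$sigma_peptide)

  # 6. replicate effects, indexed (condition a reps, then condition b reps)
  reps_a <- seq_len(design$n_reps_a)
  reps_b <- seq_len(design$n_reps_b)
  rep_eff <- rnorm(design$n_reps_a + design$n_reps_b, 0, p$sigma_rep)

  # 7. replicate-level residuals: peptide x (condition, rep) grid
  rep_grid <- tibble(
    condition = c(rep(design$condition_a, design$n_reps_a),
                  rep(design$condition_b, design$n_reps_b)),
    bio_rep = c(reps_a, reps_b),
    rep_index = seq_along(rep_eff)
  )
  n_rep_cols <- nrow(rep_grid)
  obs <- tibble(
    pep_row = rep(seq_along(pep_key), each = n_rep_cols),
    rep_index = rep(rep_grid$rep_index, times = length(pep_key))
  )
  obs$feature_row <- pep_feature[obs$pep_row]
  obs$condition <- rep_grid$condition[obs$rep_index]
  obs$bio_rep <- rep_grid$bio_rep[obs$rep_index]
  eps <- rnorm(nrow(obs), 0, p$sigma_noise)
  is_b <- obs$condition == design$condition_b
  obs$log2_base <- baseline[obs$feature_row] + pep_offset[obs$pep_row] +
    rep_eff[obs$rep_index] + delta[obs$feature_row] * is_b + eps

  # 8. injection (technical replicate) noise
  n_tech <- design$n_tech_reps
  inj <- obs[rep(seq_len(nrow(obs)), each = n_tech), ]
  inj$tech_rep <- rep(seq_len(n_tech), times = nrow(obs))
  inj$log2 <- inj$log2_base + rnorm(nrow(inj), 0, p$sigma_tech)

  # 9. outliers
  is_outlier <- runif(nrow(inj)) < p$outlier_rate
  inj$log2 <- inj$log2 + p$outlier_shift * is_outlier
  outliers <- tibble(
    peptide_key = pep_key[inj$pep_row[is_outlier]],
    condition = inj$condition[is_outlier],
    bio_rep = inj$bio_rep[is_outlier],
    tech_rep = inj$tech_rep[is_outlier]
  )

  inj$xic <- 2^inj$log2
  presplit <- NULL

  # 10. fraction splitting (linear scale, 1 or 2 fractions per injection)
  if (design$n_fractions > 1L) {
    presplit <- tibble(
      peptide_key = pep_key[inj$pep_row],
      condition = inj$condition,
      bio_rep = inj$bio_rep,
      tech_rep = inj$tech_rep,
      xic = inj$xic
    )
    m <- nrow(inj)
    two <- runif(m) < 0.5
    frac1 <- runif_int(m, 1L, design$n_fractions)
    frac2 <- runif_int(m, 1L, design$n_fractions - 1L)
    frac2 <- frac2 + (frac2 >= frac1)
    w <- runif(m)
    first <- inj
    first$fraction <- frac1
    first$xic <- inj$xic * ifelse(two, w, 1)
    second <- inj[two, ]
    second$fraction <- frac2[two]
    second$xic <- inj$xic[two] * (1 - w[two])
    rows <- bind_rows(first, second)
  } else {
    rows <- inj
    rows$fraction <- 1L
  }

  # 11. missingness (per emitted row)
  u <- runif(nrow(rows))
  if (p$missing_mode == "mcar") {
    p_miss <- rep(p$missing_rate_base, nrow(rows))
  } else {
    l2 <- log2(rows$xic)
    mid <- quantile(l2, 0.25, names = FALSE)
    p_miss <- pmin(1, 2 * p$missing_rate_base * stats::plogis(-(l2 - mid)))
  }
  rows <- rows[u >= p_miss, ]

  # condition-specific features: drop the other condition entirely
  f_flag <- flag[rows$feature_row]
  keep <- !(f_flag == "a_only" & rows$condition == design$condition_b) &
    !(f_flag == "b_only" & rows$condition == design$condition_a)
  rows <- rows[keep, ]

  table <- quant_table(
    tibble(
      protein_id = protein_id[rows$feature_row],
      gene_symbol = NA_character_,
      peptide_key = pep_key[rows$pep_row],
      is_proteotypic = TRUE,
      gg_positions = gg[rows$feature_row],
      condition = rows$condition,
      bio_rep = rows$bio_rep,
      tech_rep = rows$tech_rep,
      fraction = rows$fraction,
      xic = rows$xic
    ),
    design = design, stage = "raw"
  )

  truth <- tibble(
    feature_id = feature_id,
    protein_id = protein_id,
    true_log2fc = ifelse(flag == "none", delta, NA_real_),
    specific_flag = flag,
    n_peptides = n_pep
  )

  structure(
    list(table = table, truth = truth, outliers = outliers,
         presplit = presplit, params = p, design = design),
    class = "lfq_simulation"
  )
}

#' @export
print.lfq_simulation <- function(x, ...) {
  cat(sprintf(
    "<lfq_simulation> %d features, %d observations (design %s, seed %d)\n",
    nrow(x$truth), nrow(x$table), x$design$name, x$params$seed
  ))
  invisible(x)
}

#' A small deterministic end-to-end fixture
#'
#' Hand-constructed table under the pan-UB design (4 vs 8 biological
#' replicates, protein level) with six features covering the pipeline's
#' branches: a 4-fold increased protein, a 4-fold decreased protein, one
#' protein observed only in the reference condition, one only in the test
#' condition, a multi-peptide null and a single-peptide null. One
#' non-proteotypic peptide (discarded by preprocessing), one missing
#' intensity and one gross outlier observation are planted. Residual noise
#' is generated from a fixed internal seed, so repeated calls are
#' bit-identical; this is the deterministic surface for end-to-end and
#' golden-file tests.
#'
#' @return An `lfq_simulation` (see [simulate_experiment()]; `presplit` is
#'   `NULL` and `outliers` lists the single planted outlier).
#' @examples
#' fx <- fixture_toy_table()
#' dplyr::count(fx$table, condition)
#' @export
fixture_toy_table <- function() {
  design <- screen_designs()$panub
  # peptide ionization offsets are chosen so that, by construction, every
  # replicate column's median falls inside a run of null-feature values and
  # the MAD is identical across conditions: normalization is then close to
  # the identity and the planted effects survive it undistorted
  offsets <- list(
    FEAT_UP = c(-1, 0, 1), FEAT_DOWN = c(-1, 0, 1),
    FEAT_AONLY = c(-1, 1), FEAT_BONLY = c(-1, 1),
    FEAT_NULL = c(-1, 0, 0, 1), FEAT_SINGLE = 0
  )
  feats <- tibble(
    feature_id = names(offsets),
    delta = c(2, -2, NA, NA, 0, 0),
    specific_flag = c("none", "none", "a_only", "b_only", "none", "none"),
    n_pep = lengths(offsets)
  )
  pep <- tibble(
    feature_id = rep(feats$feature_id, feats$n_pep),
    delta = rep(feats$delta, feats$n_pep),
    flag = rep(feats$specific_flag, feats$n_pep),
    pep_i = sequence(feats$n_pep),
    offset = unlist(offsets, use.names = FALSE)
  )
  pep$peptide_key <- sprintf("%s_pep%d", pep$feature_id, pep$pep_i)

  reps <- tibble(
    condition = c(rep("U2OS", 4), rep("KO", 8)),
    bio_rep = c(1:4, 1:8)
  )
  grid <- tidyr::crossing(pep, reps)
  grid <- grid[!(grid$flag == "a_only" & grid$condition == "KO") &
                 !(grid$flag == "b_only" & grid$condition == "U2OS"), ]
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(20211L)
  noise <- rnorm(nrow(grid), 0, 0.15)
  log2_val <- 20 + grid$offset + noise +
    ifelse(grid$condition == "KO" & !is.na(grid$delta), grid$delta, 0)

  tbl <- tibble(
    protein_id = grid$feature_id,
    gene_symbol = NA_character_,
    peptide_key = grid$peptide_key,
    is_proteotypic = TRUE,
    gg_positions = "",
    condition = grid$condition,
    bio_rep = grid$bio_rep,
    tech_rep = 1L,
    fraction = 1L,
    xic = 2^log2_val
  )
  # planted outlier: FEAT_NULL_pep2 in KO replicate 3
  out_row <- which(tbl$peptide_key == "FEAT_NULL_pep2" &
                     tbl$condition == "KO" & tbl$bio_rep == 3L)
  tbl$xic[out_row] <- tbl$xic[out_row] * 2^5
  # planted missing value: FEAT_UP_pep1 in U2OS replicate 2
  na_row <- which(tbl$peptide_key == "FEAT_UP_pep1" &
                    tbl$condition == "U2OS" & tbl$bio_rep == 2L)
  tbl$xic[na_row] <- NA_real_
  # non-proteotypic peptide on FEAT_NULL, present everywhere, discarded later
  npp <- tbl[tbl$peptide_key == "FEAT_NULL_pep1", ]
  npp$peptide_key <- "FEAT_NULL_shared"
  npp$is_proteotypic <- FALSE
  tbl <- bind_rows(tbl, npp)

  table <- quant_table(tbl, design = design, stage = "raw")
  truth <- tibble(
    feature_id = feats$feature_id,
    protein_id = feats$feature_id,
    true_log2fc = ifelse(feats$specific_flag == "none", feats$delta, NA_real_),
    specific_flag = feats$specific_flag,
    n_peptides = feats$n_pep
  )
  structure(
    list(table = table, truth = truth,
         outliers = tibble(peptide_key = "FEAT_NULL_pep2", condition = "KO",
                           bio_rep = 3L, tech_rep = 1L),
         presplit = NULL, params = NULL, design = design),
    class = "lfq_simulation"
  )
}
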