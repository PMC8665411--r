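# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Literal Benjamini-Hochberg step-up definition:
# adj(i) = min over j with p_j >= p_i of min(1, m * p_j / rank_j).
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  ratio <- pmin(1, m * p / r)
  vapply(seq_len(m), function(i) min(ratio[p >= p[i]]), numeric(1))
}

# Brute-force least squares for the peptide + condition model via the
# normal equations, with the equal-variance t-test on the condition term.
ls_oracle <- function(obs, cond_a, cond_b) {
  peps <- sort(unique(obs$peptide_key))
  X <- cbind(1, sapply(peps[-1], function(pk) as.numeric(obs$peptide_key == pk)),
             as.numeric(obs$condition == cond_b))
  X <- matrix(as.numeric(X), nrow = nrow(obs))
  y <- obs$value
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  k <- ncol(X)
  res <- y - X %*% beta
  rdf <- nrow(X) - k
  sigma2 <- sum(res^2) / rdf
  se <- sqrt(sigma2 * xtx_inv[k, k])
  tval <- beta[k] / se
  list(log2_fc = beta[k], se = se, df = rdf,
       raw_p = 2 * pt(-abs(tval), rdf))
}

# Tiny well-formed raw table (panub design) for IO tests.
make_tiny_table <- function(design = screen_designs()$panub) {
  quant_table(
    tibble::tibble(
      protein_id = c("P1", "P1", "P2"),
      gene_symbol = c("G1", "G1", NA),
      peptide_key = c("P1_a", "P1_a", "P2_a"),
      is_proteotypic = TRUE,
      gg_positions = "",
      condition = c("U2OS", "KO", "KO"),
      bio_rep = c(1L, 1L, 2L),
      tech_rep = 1L,
      fraction = 1L,
      xic = c(100, 250, NA)
    ),
    design = design
  )
}

# Swap the two conditions of a design (and replicate counts with them).
swap_design <- function(design) {
  lfq_design("custom",
             condition_a = design$condition_b,
             condition_b = design$condition_a,
             n_reps_a = design$n_reps_b,
             n_reps_b = design$n_reps_a,
             n_fractions = design$n_fractions,
             n_tech_reps = design$n_tech_reps,
             feature_level = design$feature_level)
}

# Hand-built diff_results table for candidate-selection tests.
make_results <- function(x, design = screen_designs()$panub,
                         config = quant_config()) {
  col <- function(name, default) x[[name]] %||% default
  out <- tibble::tibble(
    feature_id = x$feature_id,
    protein_id = col("protein_id", x$feature_id),
    level = col("level", "protein"),
    log2_fc = col("log2_fc", NA_real_),
    se = col("se", 0.1),
    df = col("df", 10),
    raw_p = col("raw_p", col("adj_p", NA_real_)),
    adj_p = col("adj_p", NA_real_),
    n_peptides_used = col("n_peptides_used", 3L),
    n_obs_removed_outlier = 0L,
    detect_reps_a = col("detect_reps_a", design$n_reps_a),
    detect_reps_b = col("detect_reps_b", design$n_reps_b),
    specific_flag = col("specific_flag", "none"),
    note = "ok"
  )
  structure(out, design = design, config = config,
            class = c("diff_results", class(tibble::tibble())))
}

`%||%` <- rlang::`%||%`
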