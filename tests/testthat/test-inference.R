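test_that("Tukey's fences match hand-computed quartiles", {
  # {1,2,3,4,100}: type-7 quartiles Q1 = 2, Q3 = 4, upper fence = 7
  keep <- tukey_fences_filter(c(1, 2, 3, 4, 100), fence_k = 1.5)
  expect_identical(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # the stated quartile convention: Q1 of {1,2,3,4} is 1.75
  expect_equal(quantile(1:4, 0.25, type = 7, names = FALSE), 1.75)
  # zero IQR keeps everything (values sit exactly at the fences)
  expect_true(all(tukey_fences_filter(rep(5, 4), 1.5)))
  # huge k keeps everything
  expect_true(all(tukey_fences_filter(c(-1e6, 0, 3, 8, 1e6), 1e6)))
  # fewer than 4 values pass unfiltered
  expect_true(all(tukey_fences_filter(c(0, 1000, -1000))))
  # NA values pass through untouched
  expect_identical(tukey_fences_filter(c(1, 2, NA, 3, 4, 100))[3], TRUE)
})

test_that("retained values all lie within the original fences", {
  set.seed(7)
  for (i in 1:20) {
    v <- rnorm(30) + sample(c(0, 10), 30, replace = TRUE, prob = c(0.9, 0.1))
    keep <- tukey_fences_filter(v, 1.5)
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    lo <- q[1] - 1.5 * (q[2] - q[1])
    hi <- q[2] + 1.5 * (q[2] - q[1])
    expect_true(all(v[keep] >= lo & v[keep] <= hi))
    expect_true(all(v[!keep] < lo | v[!keep] > hi))
  }
})

test_that("the linear model recovers noiseless effects exactly", {
  obs <- tibble::tibble(
    peptide_key = rep(c("p1", "p2", "p3"), each = 6),
    condition = rep(rep(c("a", "b"), each = 3), 3),
    value = rep(c(18, 21, 24), each = 6) +
      rep(rep(c(0, 1), each = 3), 3)
  )
  fit <- fit_feature_model(obs, "a", "b")
  expect_equal(fit$log2_fc, 1, tolerance = 1e-12)
  # residuals vanish up to floating-point noise
  expect_lt(fit$se, 1e-8)
})

test_that("a single-peptide feature reduces to the equal-variance t-test", {
  obs <- tibble::tibble(
    peptide_key = "p1",
    condition = rep(c("a", "b"), each = 3),
    value = c(10, 11, 12, 10, 11, 12)
  )
  fit <- fit_feature_model(obs, "a", "b")
  expect_equal(fit$log2_fc, 0)
  expect_equal(fit$raw_p, 1)

  set.seed(8)
  y_a <- rnorm(5, 20, 1); y_b <- rnorm(7, 21, 1)
  obs2 <- tibble::tibble(
    peptide_key = "p1",
    condition = rep(c("a", "b"), c(5, 7)),
    value = c(y_a, y_b)
  )
  fit2 <- fit_feature_model(obs2, "a", "b")
  tt <- t.test(y_b, y_a, var.equal = TRUE)
  expect_equal(fit2$raw_p, tt$p.value, tolerance = 1e-12)
  expect_equal(fit2$log2_fc, mean(y_b) - mean(y_a), tolerance = 1e-12)
})

test_that("multi-peptide fits match the normal-equations oracle", {
  set.seed(9)
  for (i in 1:10) {
    n_pep <- sample(2:4, 1)
    obs <- tidyr::crossing(
      peptide_key = sprintf("p%d", seq_len(n_pep)),
      condition = c("a", "b"),
      rep = 1:4
    )
    obs$value <- 20 + rnorm(n_pep)[match(obs$peptide_key, sprintf("p%d", seq_len(n_pep)))] +
      0.8 * (obs$condition == "b") + rnorm(nrow(obs), 0, 0.5)
    fit <- fit_feature_model(obs, "a", "b")
    oracle <- ls_oracle(obs, "a", "b")
    expect_equal(fit$log2_fc, oracle$log2_fc, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se, tolerance = 1e-10)
    expect_equal(fit$raw_p, oracle$raw_p, tolerance = 1e-10)
    expect_equal(fit$df, oracle$df)
  }
})

test_that("insufficient observations are flagged instead of fitted", {
  obs <- tibble::tibble(peptide_key = "p1",
                        condition = c("a", "b", "b"),
                        value = c(10, 11, 12))
  fit <- fit_feature_model(obs, "a", "b")
  expect_identical(fit$note, "insufficient data")
  expect_true(is.na(fit$raw_p))
})

test_that("condition-specific flags are assigned and contract-checked", {
  obs_b <- tibble::tibble(condition = rep("KO", 4), value = 1:4)
  expect_identical(flag_condition_specific(obs_b, "U2OS", "KO"), "b_only")
  obs_a <- tibble::tibble(condition = rep("U2OS", 2), value = 1:2)
  expect_identical(flag_condition_specific(obs_a, "U2OS", "KO"), "a_only")
  both <- tibble::tibble(condition = c("U2OS", "KO"), value = 1:2)
  expect_error(flag_condition_specific(both, "U2OS", "KO"),
               class = "ubiquant_contract_error")
})

test_that("BH adjustment matches hand and brute-force computations", {
  expect_equal(adjust_bh(c(0.01, 0.03, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(adjust_bh(0.5), 0.5)
  # missing p-values are excluded from the family and stay missing
  mixed <- adjust_bh(c(0.01, NA, 0.03, 0.04, NA))
  expect_equal(mixed, c(0.03, NA, 0.04, 0.04, NA))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "ubiquant_validation_error")

  set.seed(10)
  for (i in 1:20) {
    p <- round(runif(200), 3) # rounding forces ties
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("adjusted p-values dominate raw ones and are monotone", {
  set.seed(11)
  p <- runif(100)
  adj <- adjust_bh(p)
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
})

test_that("run_differential requires a merged table", {
  sim <- simulate_experiment(screen_designs()$proteome,
                             truth_params(n_features = 5, seed = 1))
  expect_error(run_differential(sim$table), class = "ubiquant_stage_error")
})

test_that("swapping condition labels negates fold changes and keeps p-values", {
  sim <- simulate_experiment(
    screen_designs()$panub,
    truth_params(n_features = 40, frac_changed = 0.2, frac_specific_a = 0.05,
                 frac_specific_b = 0.05, seed = 12))
  tab <- merge_technical_replicates(sum_fractions(sim$table))
  res <- run_differential(tab)
  swapped_tab <- quant_table(as_tibble(tab), swap_design(table_design(tab)),
                             stage = "tech_merged")
  res_sw <- run_differential(swapped_tab)
  expect_identical(res$feature_id, res_sw$feature_id)
  tested <- !is.na(res$log2_fc)
  expect_equal(res_sw$log2_fc[tested], -res$log2_fc[tested],
               tolerance = 1e-12)
  expect_equal(res_sw$raw_p[tested], res$raw_p[tested], tolerance = 1e-12)
  expect_equal(res_sw$adj_p[tested], res$adj_p[tested], tolerance = 1e-12)
  # specific flags mirror
  expect_identical(res_sw$specific_flag[res$specific_flag == "a_only"],
                   rep("b_only", sum(res$specific_flag == "a_only")))
  expect_identical(res_sw$detect_reps_a, res$detect_reps_b)
})

test_that("outliers planted by the simulator are removed by the fences", {
  p <- truth_params(n_features = 30, peptides_per_feature = c(4L, 6L),
                    frac_changed = 0, frac_specific_a = 0,
                    frac_specific_b = 0, outlier_rate = 0.02,
                    outlier_shift = 6, missing_rate_base = 0, seed = 13)
  sim <- simulate_experiment(screen_designs()$panub, p)
  tab <- merge_technical_replicates(sum_fractions(sim$table))
  res <- run_differential(tab)
  expect_gt(sum(res$n_obs_removed_outlier), 0)
  # with gross outliers fenced out, no feature should show a large shift
  expect_lt(max(abs(res$log2_fc), na.rm = TRUE), 1)
})
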