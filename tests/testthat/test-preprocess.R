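make_frac_table <- function(xics, fractions = seq_along(xics)) {
  design <- lfq_design("custom", "a", "b", 1L, 1L, n_fractions = 6L)
  quant_table(
    tibble::tibble(
      protein_id = "P1", peptide_key = "P1_x", is_proteotypic = TRUE,
      condition = "a", bio_rep = 1L, tech_rep = 1L,
      fraction = as.integer(fractions), xic = xics
    ),
    design = design
  )
}

test_that("fraction XICs are summed, ignoring missing fractions", {
  out <- sum_fractions(make_frac_table(c(100, NA, 50), c(1, 2, 3)))
  expect_equal(out$xic, 150)
  expect_equal(out$fraction, 1L)
  expect_identical(table_stage(out), "fractions_summed")

  all_na <- sum_fractions(make_frac_table(rep(NA_real_, 6)))
  expect_equal(nrow(all_na), 1L)
  expect_true(is.na(all_na$xic))
})

test_that("technical replicates average on the linear scale; singles pass through", {
  design <- lfq_design("custom", "a", "b", 1L, 2L, n_tech_reps = 2L)
  tab <- quant_table(
    tibble::tibble(
      protein_id = "P1", peptide_key = c("P1_x", "P1_x", "P1_y", "P1_y"),
      is_proteotypic = TRUE, condition = c("a", "a", "b", "b"),
      bio_rep = c(1L, 1L, 2L, 2L), tech_rep = c(1L, 2L, 1L, 2L),
      fraction = 1L, xic = c(100, 120, 80, NA)
    ),
    design = design, stage = "fractions_summed"
  )
  out <- merge_technical_replicates(tab)
  expect_equal(sort(out$xic), c(80, 110))
  expect_identical(table_stage(out), "tech_merged")

  # a 1-injection design is unchanged
  sim <- simulate_experiment(screen_designs()$panub,
                             truth_params(n_features = 5, seed = 1))
  merged <- merge_technical_replicates(sum_fractions(sim$table))
  expect_equal(sort(merged$xic), sort(sim$table$xic))
})

test_that("preprocessing commutes with relabelling of replicate indices", {
  sim <- simulate_experiment(screen_designs()$digly,
                             truth_params(n_features = 10, seed = 3))
  tab <- sim$table
  relab <- as_tibble(tab)
  # swap technical replicates 1 and 2, and reverse bio_rep labels within KO
  relab$tech_rep <- 3L - relab$tech_rep
  ko <- relab$condition == "KO"
  relab$bio_rep[ko] <- 4L - relab$bio_rep[ko]
  relab_tab <- quant_table(relab, table_design(tab))
  a <- merge_technical_replicates(sum_fractions(tab))
  b <- merge_technical_replicates(sum_fractions(relab_tab))
  b_restored <- as_tibble(b)
  b_restored$bio_rep[b_restored$condition == "KO"] <-
    4L - b_restored$bio_rep[b_restored$condition == "KO"]
  key <- function(d) d[order(d$peptide_key, d$condition, d$bio_rep), ]
  expect_equal(key(as_tibble(a))$xic, key(b_restored)$xic)
})

test_that("only shared proteotypic peptides feed the model", {
  design <- screen_designs()$panub
  tab <- quant_table(
    tibble::tibble(
      protein_id = "P1",
      peptide_key = c("shared", "shared", "aonly", "npp", "npp"),
      is_proteotypic = c(TRUE, TRUE, TRUE, FALSE, FALSE),
      condition = c("U2OS", "KO", "U2OS", "U2OS", "KO"),
      bio_rep = c(1L, 1L, 2L, 1L, 1L),
      tech_rep = 1L, fraction = 1L,
      xic = c(10, 20, 30, 40, 50)
    ),
    design = design, stage = "tech_merged"
  )
  g <- build_feature_groups(tab)
  expect_equal(sort(unique(g$peptide_key)), c("aonly", "shared"))
  expect_equal(g$is_shared[g$peptide_key == "shared"], c(TRUE, TRUE))
  expect_false(any(g$is_shared[g$peptide_key == "aonly"]))
  meta <- attr(g, "features")
  expect_equal(meta$specific_flag, "none")
  expect_equal(meta$n_peptides_shared, 1L)
  # detection counts include the non-shared peptide (counted pre-filter)
  expect_equal(meta$detect_reps_a, 2L)
  expect_equal(meta$detect_reps_b, 1L)
})

test_that("single-condition groups are tagged condition-specific", {
  design <- screen_designs()$panub
  tab <- quant_table(
    tibble::tibble(
      protein_id = c("PA", "PA", "PB"),
      peptide_key = c("PA_x", "PA_y", "PB_x"),
      is_proteotypic = TRUE,
      condition = c("U2OS", "U2OS", "KO"),
      bio_rep = c(1L, 2L, 5L),
      tech_rep = 1L, fraction = 1L, xic = c(10, 11, 12)
    ),
    design = design, stage = "tech_merged"
  )
  meta <- attr(build_feature_groups(tab), "features")
  expect_equal(meta$specific_flag[meta$feature_id == "PA"], "a_only")
  expect_equal(meta$specific_flag[meta$feature_id == "PB"], "b_only")
})

test_that("multiply GG-modified peptides contribute one observation per site", {
  design <- screen_designs()$digly
  tab <- quant_table(
    tibble::tibble(
      protein_id = "SKIL",
      peptide_key = c("double", "single"),
      is_proteotypic = TRUE,
      gg_positions = c("343;432", "343"),
      condition = c("U2OS", "KO"),
      bio_rep = 1L, tech_rep = 1L, fraction = 1L,
      xic = c(100, 60)
    ),
    design = design, stage = "tech_merged"
  )
  g <- build_feature_groups(tab)
  expect_setequal(unique(g$feature_id), c("SKIL_K343", "SKIL_K432"))
  expect_equal(sum(g$feature_id == "SKIL_K343"), 2L)
  expect_equal(sum(g$feature_id == "SKIL_K432"), 1L)
  # total site-level observations = sum over rows of (#gg positions)
  expect_equal(nrow(g), 3L)
})

test_that("site-level tables never have fewer sites than proteins", {
  sim <- simulate_experiment(screen_designs()$digly,
                             truth_params(n_features = 60, seed = 8))
  tab <- merge_technical_replicates(sum_fractions(sim$table))
  meta <- attr(build_feature_groups(tab), "features")
  expect_gte(length(unique(meta$feature_id)),
             length(unique(meta$protein_id)))
})

test_that("log2 transform rejects zeros and preserves missingness semantics", {
  design <- screen_designs()$panub
  tab <- quant_table(
    tibble::tibble(
      protein_id = "P1", peptide_key = "P1_x", is_proteotypic = TRUE,
      condition = c("U2OS", "KO"), bio_rep = 1L, tech_rep = 1L,
      fraction = 1L, xic = c(8, 1)
    ),
    design = design, stage = "tech_merged"
  )
  g <- log2_transform(build_feature_groups(tab))
  expect_equal(sort(g$value), c(0, 3))
  expect_error(log2_transform(g), class = "ubiquant_stage_error")

  zero <- as_tibble(tab)
  zero$xic[1] <- 0
  ztab <- quant_table(zero, design, stage = "tech_merged")
  expect_error(log2_transform(build_feature_groups(ztab)),
               "missing", class = "ubiquant_validation_error")
})

test_that("the top_n cap keeps the highest-intensity shared peptides", {
  design <- screen_designs()$panub
  tab <- quant_table(
    tibble::tibble(
      protein_id = "P1",
      peptide_key = rep(c("low", "mid", "high"), each = 2),
      is_proteotypic = TRUE,
      condition = rep(c("U2OS", "KO"), 3),
      bio_rep = 1L, tech_rep = 1L, fraction = 1L,
      xic = c(1, 2, 10, 20, 100, 200)
    ),
    design = design, stage = "tech_merged"
  )
  g <- build_feature_groups(tab, top_n = 2)
  shared <- unique(g$peptide_key[g$is_shared])
  expect_setequal(shared, c("high", "mid"))
  g_all <- build_feature_groups(tab)
  expect_setequal(unique(g_all$peptide_key[g_all$is_shared]),
                  c("low", "mid", "high"))
})
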