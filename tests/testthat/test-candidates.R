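test_that("selection applies the fold, significance and detection criteria", {
  res <- make_results(tibble::tibble(
    feature_id = c("pass_dec", "weak_p", "weak_fold", "few_reps",
                   "pass_inc", "spec_a", "spec_b"),
    log2_fc = c(-1.2, -1.2, -0.9, -2, 1.5, NA, NA),
    adj_p = c(0.01, 0.2, 0.001, 0.001, 0.02, NA, NA),
    detect_reps_a = c(3L, 4L, 4L, 2L, 4L, 4L, 0L),
    detect_reps_b = c(2L, 8L, 8L, 2L, 8L, 0L, 8L),
    specific_flag = c("none", "none", "none", "none", "none",
                      "a_only", "b_only")
  ))
  dec <- select_candidates(res, quant_config(direction = "decrease"), "ubi")
  expect_setequal(dec$feature_id, c("pass_dec", "spec_a"))
  expect_true(dec$is_specific[dec$feature_id == "spec_a"])
  inc <- select_candidates(res, quant_config(direction = "increase"), "prot")
  expect_setequal(inc$feature_id, c("pass_inc", "spec_b"))
})

test_that("threshold boundaries are inclusive", {
  res <- make_results(tibble::tibble(
    feature_id = c("fold_exact", "alpha_exact", "both_under"),
    log2_fc = c(1, 2, 0.99),
    adj_p = c(0.01, 0.05, 0.06)
  ))
  sel <- select_candidates(res, quant_config(direction = "increase"), "x")
  expect_setequal(sel$feature_id, c("fold_exact", "alpha_exact"))
})

test_that("candidate sets are monotone in the thresholds", {
  set.seed(14)
  res <- make_results(tibble::tibble(
    feature_id = sprintf("F%03d", 1:80),
    log2_fc = rnorm(80, 0, 1.5),
    adj_p = runif(80)^2,
    detect_reps_a = sample(0:4, 80, replace = TRUE),
    detect_reps_b = sample(0:8, 80, replace = TRUE)
  ))
  strict <- select_candidates(res, quant_config(direction = "increase"), "x")
  relaxed <- select_candidates(
    res, quant_config(direction = "increase", fold_threshold = 1.5,
                      alpha = 0.2, min_detect_reps = 2L), "x")
  expect_true(all(strict$feature_id %in% relaxed$feature_id))
})

test_that("site candidate sets collapse to distinct proteins with provenance", {
  res <- make_results(
    tibble::tibble(
      feature_id = c("SKIL_K343", "P1_K10", "P1_K99"),
      protein_id = c("SKIL", "P1", "P1"),
      level = "site",
      log2_fc = c(-2, -1.8, -1.4),
      adj_p = c(0.001, 0.01, 0.04)
    ),
    design = screen_designs()$digly
  )
  set <- select_candidates(res, quant_config(direction = "decrease"), "digly")
  expect_equal(attr(set, "level"), "site")
  prot <- collapse_sites_to_proteins(set)
  expect_setequal(prot$feature_id, c("SKIL", "P1"))
  expect_lte(nrow(prot), nrow(set))
  mapping <- attr(prot, "site_mapping")
  expect_equal(sort(mapping$feature_id[mapping$protein_id == "P1"]),
               c("P1_K10", "P1_K99"))
  # empty site set collapses to an empty protein set
  empty <- select_candidates(res, quant_config(direction = "increase"),
                             "digly")
  expect_equal(nrow(collapse_sites_to_proteins(empty)), 0L)
})

test_that("intersections equal brute-force set algebra", {
  mk <- function(ids, exp) {
    s <- make_results(tibble::tibble(feature_id = ids, log2_fc = 2,
                                     adj_p = 0.001))
    select_candidates(s, quant_config(direction = "increase"), exp)
  }
  rpt <- intersect_candidates(list(one = mk(c("A", "B", "C", "D"), "one"),
                                   two = mk(c("C", "D", "E"), "two")))
  expect_equal(rpt$pairwise$n_overlap, 2L)
  expect_equal(rpt$common, c("C", "D"))

  disjoint <- intersect_candidates(list(one = mk(c("A", "B"), "one"),
                                        two = mk(c("C"), "two")))
  expect_equal(disjoint$pairwise$n_overlap, 0L)
  expect_length(disjoint$common, 0L)

  set.seed(15)
  ids <- sprintf("P%03d", 1:60)
  sets <- list(x = mk(sample(ids, 30), "x"), y = mk(sample(ids, 25), "y"),
               z = mk(sample(ids, 20), "z"))
  rpt3 <- intersect_candidates(sets)
  expect_equal(rpt3$common,
               sort(Reduce(intersect, lapply(sets, function(s) s$feature_id))))
  for (k in seq_len(nrow(rpt3$pairwise))) {
    pr <- rpt3$pairwise[k, ]
    expect_equal(pr$n_overlap,
                 length(intersect(sets[[pr$experiment_1]]$feature_id,
                                  sets[[pr$experiment_2]]$feature_id)))
  }
  expect_error(intersect_candidates(list(x = sets$x, x = sets$y)),
               class = "ubiquant_validation_error")
})

test_that("significance stars follow the figure-legend thresholds", {
  expect_identical(
    format_significance_stars(c(0.0005, 0.001, 0.005, 0.01, 0.03, 0.05,
                                0.2, NA)),
    c("***", "***", "**", "**", "*", "*", "", ""))
  expect_error(format_significance_stars(-0.1),
               class = "ubiquant_validation_error")
})

test_that("the heatmap table renders folds, stars and specific cells", {
  prot_res <- make_results(tibble::tibble(
    feature_id = c("SKIL", "SKI", "OTHER"),
    log2_fc = c(1, 2.3, NA),
    adj_p = c(0.03, 0.0005, NA),
    specific_flag = c("none", "none", "b_only")
  ))
  site_res <- make_results(
    tibble::tibble(
      feature_id = c("SKIL_K343", "SKIL_K432"),
      protein_id = "SKIL",
      level = "site",
      log2_fc = c(-2, -0.3),
      adj_p = c(0.004, 0.6)
    ),
    design = screen_designs()$digly
  )
  prot_cand <- select_candidates(prot_res, quant_config(direction = "increase"),
                                 "proteome")
  site_cand <- select_candidates(site_res, quant_config(direction = "decrease"),
                                 "digly")
  heat <- build_heatmap_table(
    list(proteome = prot_res, digly = site_res),
    list(proteome = prot_cand, digly = site_cand))

  skil_prot <- heat[heat$row_id == "SKIL" & heat$experiment == "proteome", ]
  expect_equal(skil_prot$fold, 2)
  expect_identical(skil_prot$direction, "increase")
  expect_identical(skil_prot$stars, "*")
  # the proteome value repeats on the site row of the same protein
  skil_site_row <- heat[heat$row_id == "SKIL_K343" &
                          heat$experiment == "proteome", ]
  expect_equal(skil_site_row$fold, 2)
  # condition-specific member renders as specific with no stars
  spec <- heat[heat$row_id == "OTHER" & heat$experiment == "proteome", ]
  expect_identical(spec$direction, "specific")
  expect_identical(spec$stars, "")
  # features absent from an experiment yield no cell
  expect_equal(nrow(heat[heat$row_id == "OTHER" &
                           heat$experiment == "digly", ]), 0L)
})
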