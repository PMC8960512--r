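null_cohort <- function(n_per_group = 12, p = 8, seed = 1) {
  cfg <- cohort_config(n_regions = p,
                       group_sizes = c(A = n_per_group, B = n_per_group),
                       lesion_load_mean_sd = list(A = c(10, 8), B = c(10, 8)),
                       seed = seed)
  generate_cohort(cfg)$original
}

test_that("identical group data gives zero observed differences and no detections", {
  set.seed(6)
  X <- matrix(runif(10 * 6, 0.3, 0.7), 10, 6)
  coh <- scn_cohort(rbind(X, X), rep(c("A", "B"), each = 10))
  pt <- permutation_compare(coh, "A", "B",
                            parameters = c("average_degree",
                                           "average_strength", "clustering",
                                           "transitivity"),
                            n_perm = 100, seed = 1)
  expect_equal(pt$global$observed_diff, rep(0, 4), tolerance = 1e-12)
  expect_false(any(pt$global$significant_unadjusted))
  expect_true(all(pt$global$p_two_sided > 0.9))
})

test_that("results are bit-identical under a fixed seed", {
  coh <- null_cohort(seed = 2)
  args <- list(coh, "A", "B",
               parameters = c("average_strength", "clustering", "modularity"),
               nodal_parameters = c("degree", "strength"),
               n_perm = 120, seed = 33)
  p1 <- do.call(permutation_compare, args)
  p2 <- do.call(permutation_compare, args)
  expect_identical(p1$global, p2$global)
  expect_identical(p1$nodal, p2$nodal)
  expect_identical(p1$null_global, p2$null_global)
  p3 <- do.call(permutation_compare, c(args[-7], list(seed = 34)))
  expect_false(identical(p1$null_global, p3$null_global))
})

test_that("the CI decision rule and the two-sided p-value agree on most null cases", {
  agree <- 0; total <- 0
  for (r in 1:30) {
    coh <- null_cohort(seed = 100 + r)
    pt <- permutation_compare(coh, "A", "B",
                              parameters = c("average_strength",
                                             "clustering",
                                             "global_efficiency"),
                              n_perm = 200, seed = 200 + r)
    ci_rule <- pt$global$significant_unadjusted
    p_rule <- pt$global$p_two_sided <= 0.05
    agree <- agree + sum(ci_rule == p_rule)
    total <- total + length(ci_rule)
  }
  expect_gt(agree / total, 0.95)
})

test_that("invariants of the outcome object hold", {
  coh <- null_cohort(seed = 3)
  pt <- permutation_compare(coh, "A", "B",
                            parameters = c("average_degree", "modularity",
                                           "assortativity"),
                            nodal_parameters = "strength",
                            n_perm = 150, seed = 5)
  g <- pt$global
  expect_true(all(g$ci_low <= g$ci_high, na.rm = TRUE))
  expect_true(all(g$p_two_sided > 0 & g$p_two_sided <= 1, na.rm = TRUE))
  expect_identical(g$significant_unadjusted,
                   g$observed_diff < g$ci_low | g$observed_diff > g$ci_high)
  expect_equal(nrow(pt$nodal), 8)
  expect_true(all(pt$nodal$level == "nodal"))
  # excluded permutations are counted, never silently dropped
  expect_true(all(g$n_excluded + colSums(!is.na(pt$null_global)) == pt$n_perm))
})

test_that("groups below 3 subjects or unknown labels are rejected", {
  coh <- null_cohort(seed = 4)
  expect_error(permutation_compare(coh, "A", "Z", n_perm = 100), "subjects")
  small <- scn_cohort(coh$values[1:14, ], c(rep("A", 2), rep("B", 12)))
  expect_error(permutation_compare(small, "A", "B", n_perm = 100), ">= 3")
  expect_error(permutation_compare(coh, "A", "B", n_perm = 10), "n_perm")
})

test_that("power increases along a planted effect-size ladder", {
  detections <- vapply(c(0, 0.45, 0.9), function(es) {
    hits <- 0
    for (r in 1:6) {
      cfg <- cohort_config(n_regions = 12,
                           group_sizes = c(HC = 15, MS = 15),
                           lesion_load_mean_sd = list(HC = c(0.3, 0.8),
                                                      MS = c(15.3, 18.7)),
                           heterogeneity_gain = 0, artefact_rate = 0,
                           affected_regions = 1:12, effect_size = es,
                           effect_groups = "MS", seed = 3000 + r)
      coh <- generate_cohort(cfg)$original
      pt <- permutation_compare(coh, "HC", "MS",
                                parameters = "average_strength",
                                n_perm = 200, seed = 4000 + r)
      hits <- hits + sum(pt$global$significant_unadjusted)
    }
    hits
  }, 0)
  # monotone non-decreasing within stochastic tolerance of one detection
  expect_gte(detections[2] + 1, detections[1])
  expect_gte(detections[3] + 1, detections[2])
  expect_gt(detections[3], detections[1])
})

test_that("pooled MS-total labels are shuffled as one group", {
  cfg <- cohort_config(n_regions = 8,
                       group_sizes = c(HC = 6, RRMS = 5, PMS = 5), seed = 9)
  coh <- generate_cohort(cfg)$original
  rep1 <- run_comparisons(coh, list(c("HC", "MS")),
                          pool = list(MS = c("RRMS", "PMS")),
                          parameters = c("average_strength", "clustering"),
                          n_perm = 100, seed = 2)
  expect_named(rep1$comparisons, "HC_vs_MS")
  pt <- rep1$comparisons$HC_vs_MS
  expect_equal(pt$n_A, 6)
  expect_equal(pt$n_B, 10)
  expect_error(run_comparisons(coh, list(c("HC", "XX"))), "unknown group")
})

test_that("comparison reports compile nodal findings by lobe", {
  regions <- aal_regions()
  cfg <- cohort_config(group_sizes = c(HC = 8, MS = 8),
                       affected_regions = 1:116, effect_size = 0.8,
                       effect_groups = "MS", heterogeneity_gain = 0,
                       artefact_rate = 0, seed = 11)
  coh <- generate_cohort(cfg)$original
  expect_identical(coh$region_names, regions$region)
  rep1 <- run_comparisons(coh, list(c("HC", "MS")),
                          parameters = "average_strength",
                          nodal_parameters = "strength",
                          n_perm = 100, seed = 3)
  expect_s3_class(rep1, "scn_report")
  expect_equal(nrow(rep1$nodal_table), 116)
  if (!is.null(rep1$lobe_table) && nrow(rep1$lobe_table) > 0)
    expect_true(all(rep1$lobe_table$lobe %in% unique(regions$lobe)))
  dir <- withr::local_tempdir()
  write_report(rep1, dir)
  expect_true(all(file.exists(file.path(dir, c("global.csv", "nodal.csv",
                                               "summary.json")))))
})
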