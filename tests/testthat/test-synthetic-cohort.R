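test_that("degenerate couplings give identical arms and the noise-free limit is exact", {
  cfg <- cohort_config(n_regions = 8, group_sizes = c(HC = 5, MS = 5),
                       heterogeneity_gain = 0, artefact_rate = 0, seed = 4)
  arms <- generate_cohort(cfg)
  expect_identical(arms$original$values, arms$filled$values)
  expect_identical(arms$original$lesion_load, arms$filled$lesion_load)

  # zero covariance and zero noise: every row equals its group's means
  mu <- list(HC = rep(0.4, 8), MS = rep(0.6, 8))
  cfg0 <- cohort_config(n_regions = 8, group_sizes = c(HC = 4, MS = 4),
                        region_means = mu,
                        base_covariance = matrix(0, 8, 8),
                        heterogeneity_gain = 0, artefact_rate = 0, seed = 4)
  arms0 <- generate_cohort(cfg0)
  expect_equal(unname(arms0$original$values[1, ]), mu$HC, tolerance = 1e-14)
  expect_equal(unname(arms0$original$values[8, ]), mu$MS, tolerance = 1e-14)
})

test_that("identical seed and config give bit-identical cohorts", {
  cfg <- cohort_config(n_regions = 12, group_sizes = c(HC = 6, MS = 8),
                       seed = 99)
  a1 <- generate_cohort(cfg)
  a2 <- generate_cohort(cfg)
  expect_identical(a1$original$values, a2$original$values)
  expect_identical(a1$filled$values, a2$filled$values)
  a3 <- generate_cohort(cohort_config(n_regions = 12,
                                      group_sizes = c(HC = 6, MS = 8),
                                      seed = 100))
  expect_false(identical(a1$original$values, a3$original$values))
})

test_that("sample covariance of a large single-group draw matches the generative model", {
  p <- 10
  S <- diag(0.002, p)
  S[1, 2] <- S[2, 1] <- 0.001
  gain <- 1e-4
  cfg <- cohort_config(n_regions = p, group_sizes = c(G = 2000),
                       region_means = rep(0.5, p), base_covariance = S,
                       lesion_load_mean_sd = list(G = c(10, 5)),
                       heterogeneity_gain = gain, artefact_rate = 0, seed = 7)
  arms <- generate_cohort(cfg)
  emp <- cov(arms$original$values)
  # analytic covariance: base + diag(gain * E[load]); loads are known exactly
  expected <- S + diag(gain * mean(arms$original$lesion_load), p)
  expect_lt(max(abs(emp - expected)), 4e-4)
  # filled arm lacks the lesion-noise term
  emp_f <- cov(arms$filled$values)
  expect_lt(max(abs(emp_f - S)), 4e-4)
})

test_that("the filled arm has lower per-region variance in lesion-bearing groups", {
  cfg <- cohort_config(n_regions = 20, group_sizes = c(MS = 400),
                       lesion_load_mean_sd = list(MS = c(15.3, 18.7)),
                       seed = 21)
  arms <- generate_cohort(cfg)
  v_orig <- apply(arms$original$values, 2, var)
  v_fill <- apply(arms$filled$values, 2, var)
  expect_true(all(v_orig > v_fill))
})

test_that("clipping to [0, 1] is rare under default parameters", {
  arms <- generate_cohort(cohort_config(seed = 5))
  at_bound <- mean(arms$original$values %in% c(0, 1))
  expect_lt(at_bound, 0.01)
})

test_that("artefact counts match the planted perturbations and track lesion load", {
  # by construction: plant 3 artefacts in one subject
  cfg <- cohort_config(n_regions = 30, group_sizes = c(MS = 5),
                       artefact_rate = 0, seed = 3)
  arms <- generate_cohort(cfg)
  filled <- arms$filled
  base <- attr(filled, "baseline")
  tweaked <- filled$values
  tweaked[2, c(4, 9, 17)] <- scnet:::clip01(base[2, c(4, 9, 17)] + 0.05)
  filled$values <- tweaked
  counts <- artefact_count_per_subject(filled, arms$original)
  expect_equal(as.integer(counts), c(0L, 3L, 0L, 0L, 0L))

  # artefact_rate = 0: all zero, correlation undefined and flagged NA
  counts0 <- artefact_count_per_subject(arms$filled, arms$original)
  expect_true(all(counts0 == 0))
  expect_true(is.na(attr(counts0, "spearman")))

  # positive rate: counts correlate positively with lesion load
  cfg2 <- cohort_config(n_regions = 30, group_sizes = c(MS = 200),
                        lesion_load_mean_sd = list(MS = c(15.3, 18.7)),
                        seed = 31)
  arms2 <- generate_cohort(cfg2)
  c2 <- artefact_count_per_subject(arms2$filled, arms2$original)
  expect_gt(attr(c2, "spearman"), 0)

  # mismatched subject sets are rejected
  sub <- cohort_subset(arms2$original, "MS")
  sub$subject_id <- rev(sub$subject_id)
  expect_error(artefact_count_per_subject(arms2$filled, sub), "share")
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(cohort_config(group_sizes = c(HC = 2, MS = 10)), ">= 3")
  bad <- matrix(c(1, 2, 2, 1) * 1e-3, 2)  # not PSD (eigenvalue -1e-3)
  expect_error(cohort_config(n_regions = 2, group_sizes = c(A = 5, B = 5),
                             base_covariance = bad),
               "positive semidefinite")
  asym <- matrix(c(1, 0.5, 0.1, 1) * 1e-3, 2)
  expect_error(cohort_config(n_regions = 2, group_sizes = c(A = 5, B = 5),
                             base_covariance = asym),
               "symmetric")
  expect_error(cohort_config(effect_size = 1.5), "effect_size")
})

test_that("shared-factor effect raises covariance in effect groups only", {
  p <- 20
  cfg <- cohort_config(n_regions = p, group_sizes = c(HC = 500, MS = 500),
                       affected_regions = 1:p, effect_size = 0.6,
                       effect_groups = "MS", heterogeneity_gain = 0,
                       artefact_rate = 0, seed = 17)
  arms <- generate_cohort(cfg)
  hc <- arms$original$values[arms$original$group == "HC", ]
  ms <- arms$original$values[arms$original$group == "MS", ]
  off <- function(M) mean(M[upper.tri(M)])
  expect_gt(off(cov(ms)), off(cov(hc)))
})

test_that("cohort CSV round-trips", {
  arms <- generate_cohort(cohort_config(n_regions = 6,
                                        group_sizes = c(HC = 4, MS = 4),
                                        seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(arms$original, path)
  back <- read_cohort_csv(path)
  expect_equal(back$values, arms$original$values, tolerance = 1e-12)
  expect_identical(back$group, arms$original$group)
  expect_equal(back$lesion_load, arms$original$lesion_load, tolerance = 1e-12)
})
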