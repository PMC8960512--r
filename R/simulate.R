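#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model for paired "original" and "lesion-filled"
#' cohorts of regional grey-matter fractions. The model is: a shared
#' multivariate-normal draw per subject (group mean vector, common base
#' covariance), plus lesion-load-driven independent regional noise in the
#' original arm, and sparse artefact perturbations in the filled arm.
#' Lesion loads are log-normal with group-specific mean/SD (ml).
#'
#' A planted group effect, when requested, alters the covariance structure of
#' `affected_regions` in `effect_groups` (a mean shift would leave a
#' correlation network untouched). Two mechanisms are available:
#' `effect_type = "shared_factor"` (default) adds a common disease factor —
#' a rank-one term `s s'` with loadings `effect_size * sd` on the affected
#' regions — emulating coordinated atrophy, the classic source of increased
#' structural covariance in MS; `effect_type = "disconnection"` instead
#' scales the affected regions' off-diagonal covariance by `1 - effect_size`,
#' emulating selective decoupling.
#'
#' @param n_regions number of regions (default 116, the AAL parcellation).
#' @param group_sizes named integer vector of subjects per group; the default
#'   `c(HC = 19, RRMS = 30, PMS = 19)` mirrors a typical single-centre MS
#'   cohort. Each group needs at least 3 subjects.
#' @param region_means per-group list of mean grey-matter-fraction vectors, or
#'   a single vector shared by all groups. Default: a fixed profile spanning
#'   0.35-0.55.
#' @param base_covariance regions x regions positive-semidefinite matrix.
#'   Default: a block (community) structure with 6 blocks, region SD 0.04,
#'   within-block correlation 0.45, between-block 0.15.
#' @param lesion_load_mean_sd per-group list of `c(mean, sd)` of lesion load
#'   in ml; log-normal parameters are derived by moment matching. Defaults:
#'   HC 0.3 +/- 0.8, RRMS 15.3 +/- 18.7, PMS 25.5 +/- 29.9; unnamed extra
#'   groups fall back to the RRMS values.
#' @param heterogeneity_gain added independent noise variance per region per
#'   ml of lesion load (original arm only). Default 2e-4: at a 20 ml load the
#'   lesion noise SD (~0.063) is about 1.5x the base regional SD.
#' @param artefact_rate expected artefacts per ml of lesion load in the
#'   filled arm. Default 0.25 (a few artefacts per typical MS subject).
#' @param artefact_magnitude absolute grey-matter-fraction perturbation per
#'   artefact. Default 0.05.
#' @param affected_regions integer indices of regions carrying a true group
#'   effect; `NULL` for none.
#' @param effect_size effect magnitude in \[0, 1\]: the shared-factor loading
#'   per unit region SD (`"shared_factor"`), or the attenuation of the
#'   affected regions' inter-regional covariance (`"disconnection"`).
#' @param effect_type `"shared_factor"` or `"disconnection"` (see Details).
#' @param effect_groups groups carrying the effect; default all but the first
#'   (reference) group.
#' @param seed master integer seed; all per-arm streams derive from it.
#'
#' @return A list of class `scn_cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_regions = 116,
                          group_sizes = c(HC = 19, RRMS = 30, PMS = 19),
                          region_means = NULL,
                          base_covariance = NULL,
                          lesion_load_mean_sd = NULL,
                          heterogeneity_gain = 2e-4,
                          artefact_rate = 0.25,
                          artefact_magnitude = 0.05,
                          affected_regions = NULL,
                          effect_size = 0,
                          effect_type = c("shared_factor", "disconnection"),
                          effect_groups = NULL,
                          seed = 1L) {
  effect_type <- match.arg(effect_type)
  group_sizes <- unlist(group_sizes)  # tolerate JSON/YAML list configs
  if (length(group_sizes) < 1 || is.null(names(group_sizes)))
    stopf("group_sizes must be a named vector")
  if (any(group_sizes < 3))
    stopf("each group needs >= 3 subjects (correlation networks are undefined below that)")
  groups <- names(group_sizes)
  if (is.null(region_means))
    region_means <- seq(0.35, 0.55, length.out = n_regions)
  if (!is.list(region_means))
    region_means <- stats::setNames(rep(list(region_means), length(groups)), groups)
  for (g in groups) {
    m <- region_means[[g]]
    if (length(m) != n_regions || any(m < 0 | m > 1))
      stopf("region_means for group %s must be %d values in [0, 1]", g, n_regions)
  }
  if (is.null(base_covariance))
    base_covariance <- default_base_covariance(n_regions)
  base_covariance <- as.matrix(base_covariance)
  if (nrow(base_covariance) != n_regions || ncol(base_covariance) != n_regions)
    stopf("base_covariance must be %d x %d", n_regions, n_regions)
  if (max(abs(base_covariance - t(base_covariance))) > 1e-10)
    stopf("base_covariance is not symmetric")
  ev <- eigen(base_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stopf("base_covariance is not positive semidefinite (min eigenvalue %.3g)", min(ev))
  if (is.null(lesion_load_mean_sd)) {
    defaults <- list(HC = c(0.3, 0.8), RRMS = c(15.3, 18.7), PMS = c(25.5, 29.9))
    lesion_load_mean_sd <- lapply(groups, function(g)
      defaults[[g]] %||% defaults[["RRMS"]])
    names(lesion_load_mean_sd) <- groups
  }
  if (effect_size < 0 || effect_size > 1) stopf("effect_size must be in [0, 1]")
  if (!is.null(affected_regions) &&
      (any(affected_regions < 1) || any(affected_regions > n_regions)))
    stopf("affected_regions out of range")
  if (is.null(effect_groups)) effect_groups <- groups[-1]
  structure(
    list(n_regions = n_regions, group_sizes = group_sizes,
         region_means = region_means, base_covariance = base_covariance,
         lesion_load_mean_sd = lesion_load_mean_sd,
         heterogeneity_gain = heterogeneity_gain,
         artefact_rate = artefact_rate,
         artefact_magnitude = artefact_magnitude,
         affected_regions = affected_regions, effect_size = effect_size,
         effect_type = effect_type, effect_groups = effect_groups,
         seed = as.integer(seed)),
    class = "scn_cohort_config")
}

# Block-structured default covariance: 6 equal blocks, sd 0.04,
# within-block correlation 0.45, between-block 0.15.
#' @keywords internal
#' @noRd
default_base_covariance <- function(n_regions, n_blocks = 6, sd = 0.04,
                                    rho_within = 0.45, rho_between = 0.15) {
  block <- rep(seq_len(n_blocks), length.out = n_regions)
  block <- sort(block)
  C <- matrix(rho_between, n_regions, n_regions)
  same <- outer(block, block, "==")
  C[same] <- rho_within
  diag(C) <- 1
  C * sd^2
}

# Symmetric PSD square root via eigendecomposition (tolerates zero matrices,
# unlike chol()).
#' @keywords internal
#' @noRd
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate paired original and lesion-filled synthetic cohorts
#'
#' Draws one shared multivariate-normal grey-matter-fraction matrix per
#' subject, then derives the two arms: the original arm adds per-subject
#' independent regional noise with variance `heterogeneity_gain * lesion_load`
#' (the imprint of unfilled lesions on segmentation), while the filled arm
#' omits that noise but perturbs `Poisson(artefact_rate * lesion_load)`
#' randomly chosen regions per subject by `+/- artefact_magnitude` (filling
#' artefacts). Both arms share subjects, groups, lesion loads and seed
#' lineage; all values are clipped to \[0, 1\].
#'
#' @param config an [cohort_config()] object.
#' @return A list with elements `original` and `filled`, each an
#'   [scn_cohort]. The filled arm carries two attributes: `baseline` (the
#'   artefact-free filled values) and `artefact_regions` (list of perturbed
#'   region indices per subject).
#' @examples
#' cfg <- cohort_config(n_regions = 10, group_sizes = c(HC = 8, MS = 8), seed = 7)
#' arms <- generate_cohort(cfg)
#' arms$original
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scn_cohort_config"))
  p <- config$n_regions
  sizes <- config$group_sizes
  groups <- names(sizes)
  n <- sum(sizes)
  group_of <- rep(groups, sizes)
  region_names <- if (p == 116) aal_regions()$region else sprintf("region_%03d", seq_len(p))

  # per-group covariance square roots (effect attenuation applied here)
  roots <- lapply(groups, function(g) {
    S <- config$base_covariance
    if (!is.null(config$affected_regions) && config$effect_size > 0 &&
        g %in% config$effect_groups) {
      a <- config$affected_regions
      if (config$effect_type == "shared_factor") {
        s <- numeric(config$n_regions)
        s[a] <- config$effect_size * sqrt(diag(S))[a]
        S <- S + tcrossprod(s)
      } else {
        f <- 1 - config$effect_size
        S[a, ] <- S[a, ] * f
        S[, a] <- S[, a] * f
        diag(S)[a] <- diag(config$base_covariance)[a]
      }
    }
    psd_sqrt(S)
  })
  names(roots) <- groups

  # stream 1: shared multivariate base draw
  set.seed(child_seed(config$seed, 1L))
  B <- matrix(0, n, p)
  for (g in groups) {
    idx <- which(group_of == g)
    Z <- matrix(stats::rnorm(length(idx) * p), length(idx), p)
    B[idx, ] <- rep(config$region_means[[g]], each = length(idx)) +
      Z %*% roots[[g]]
  }

  # stream 2: lesion loads (log-normal, moment matched per group)
  set.seed(child_seed(config$seed, 2L))
  load <- numeric(n)
  for (g in groups) {
    ms <- config$lesion_load_mean_sd[[g]]
    m <- ms[1]; s <- ms[2]
    idx <- which(group_of == g)
    if (m <= 0) {
      load[idx] <- 0
    } else {
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      load[idx] <- stats::rlnorm(length(idx), meanlog, sdlog)
    }
  }

  # stream 3: lesion-load-driven heterogeneity noise (original arm)
  set.seed(child_seed(config$seed, 3L))
  noise_sd <- sqrt(config$heterogeneity_gain * load)
  N <- matrix(stats::rnorm(n * p), n, p) * noise_sd
  original <- clip01(B + N)

  # stream 4: filling artefacts (filled arm)
  set.seed(child_seed(config$seed, 4L))
  baseline <- clip01(B)
  filled <- baseline
  artefact_regions <- vector("list", n)
  if (config$artefact_rate > 0 && config$artefact_magnitude > 0) {
    counts <- stats::rpois(n, config$artefact_rate * load)
    for (i in seq_len(n)) {
      k <- min(counts[i], p)
      if (k == 0) next
      r <- sample.int(p, k)
      sgn <- sample(c(-1, 1), k, replace = TRUE)
      filled[i, r] <- clip01(filled[i, r] + sgn * config$artefact_magnitude)
      artefact_regions[[i]] <- r
    }
  }

  ids <- sprintf("S%03d", seq_len(n))
  orig <- scn_cohort(original, group_of, region_names, lesion_load = load,
                     arm = "original", subject_id = ids)
  fill <- scn_cohort(filled, group_of, region_names, lesion_load = load,
                     arm = "filled", subject_id = ids)
  attr(fill, "baseline") <- baseline
  attr(fill, "artefact_regions") <- artefact_regions
  list(original = orig, filled = fill)
}

#' Count filling artefacts per subject and relate them to lesion load
#'
#' Counts, per subject, the regions of the filled arm whose value deviates
#' from the artefact-free filled value by more than `tolerance`, and reports
#' the Spearman correlation of those counts with lesion load — the synthetic
#' analogue of an artefact census on lesion-filled images, where artefact
#' counts rise steeply with total lesion volume.
#'
#' @param filled_arm filled-arm [scn_cohort] from [generate_cohort()] (must
#'   carry the `baseline` attribute).
#' @param original_arm the paired original-arm cohort (subject check only).
#' @param tolerance deviation threshold in grey-matter-fraction units.
#' @return Integer vector of per-subject artefact counts, with attributes
#'   `spearman` (correlation with lesion load; `NA` when undefined, e.g. all
#'   counts zero) and `lesion_load`.
#' @export
artefact_count_per_subject <- function(filled_arm, original_arm,
                                       tolerance = 1e-8) {
  stopifnot(inherits(filled_arm, "scn_cohort"), inherits(original_arm, "scn_cohort"))
  if (!identical(filled_arm$subject_id, original_arm$subject_id) ||
      !identical(filled_arm$region_names, original_arm$region_names))
    stopf("arms do not share subjects/regions")
  baseline <- attr(filled_arm, "baseline")
  if (is.null(baseline))
    stopf("filled arm lacks the artefact-free baseline attribute")
  counts <- as.integer(rowSums(abs(filled_arm$values - baseline) > tolerance))
  load <- filled_arm$lesion_load
  rho <- NA_real_
  if (!is.null(load) && stats::sd(counts) > 0 && stats::sd(load) > 0)
    rho <- stats::cor(load, counts, method = "spearman")
  structure(counts, spearman = rho, lesion_load = load)
}
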