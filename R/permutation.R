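GLOBAL_PARAMETERS <- c("average_degree", "average_strength",
                       "average_path_length", "clustering",
                       "global_efficiency", "local_efficiency",
                       "transitivity", "modularity", "assortativity",
                       "small_worldness")
NODAL_PARAMETERS <- c("degree", "strength", "path_length", "clustering",
                      "global_efficiency", "local_efficiency",
                      "within_module_z", "participation")

# Compute requested parameters for one group's subject x region matrix.
# Only the ingredients a requested parameter needs are computed, because this
# sits inside the permutation loop. Returns list(global = named numeric,
# nodal = regions x parameters matrix).
#' @keywords internal
#' @noRd
compute_group_params <- function(X, global_params, nodal_params,
                                 n_random = 20, region_names = NULL) {
  W <- .cpp_spearman_graph(X)
  attr(W, "n_constant") <- NULL
  p <- ncol(X)
  region_names <- region_names %||% sprintf("region_%03d", seq_len(p))
  g <- new_scn_graph(W, region_names, nrow(X), "tmp")
  need <- function(...) any(c(...) %in% c(global_params, nodal_params))
  glob <- c()
  nod <- NULL
  deg <- as.integer(rowSums(W > 0))
  str <- rowSums(W)
  pe <- NULL
  if (need("path_length", "average_path_length", "global_efficiency",
           "small_worldness"))
    pe <- path_and_efficiency(g)
  cl <- NULL
  if (need("clustering", "transitivity", "local_efficiency", "small_worldness"))
    cl <- clustering_transitivity(g, local = need("local_efficiency"))
  part <- NULL
  if (need("modularity", "within_module_z", "participation"))
    part <- detect_communities(g, seed = sample.int(2147483646L, 1))
  mr <- NULL
  if (need("within_module_z", "participation"))
    mr <- module_roles(g, part)

  if (length(global_params)) {
    vals <- vapply(global_params, function(pm) {
      switch(pm,
        average_degree = mean(deg),
        average_strength = mean(str),
        average_path_length = {
          l <- pe$path_length
          if (any(is.finite(l))) mean(l[is.finite(l)]) else NA_real_
        },
        clustering = mean(cl$clustering),
        global_efficiency = mean(pe$efficiency),
        local_efficiency = mean(cl$local_efficiency),
        transitivity = cl$transitivity,
        modularity = part$Q,
        assortativity = {
          r <- tryCatch(suppressWarnings(assortativity(g)),
                        error = function(e) NaN)
          if (is.nan(r)) NA_real_ else r
        },
        small_worldness = tryCatch(
          as.numeric(small_worldness(g, n_random = n_random,
                                     seed = sample.int(2147483646L, 1))),
          error = function(e) NA_real_),
        stopf("unknown global parameter '%s'", pm))
    }, numeric(1))
    glob <- stats::setNames(vals, global_params)
  }
  if (length(nodal_params)) {
    nod <- vapply(nodal_params, function(pm) {
      switch(pm,
        degree = as.numeric(deg),
        strength = str,
        path_length = as.numeric(pe$path_length),
        clustering = as.numeric(cl$clustering),
        global_efficiency = as.numeric(pe$efficiency),
        local_efficiency = as.numeric(cl$local_efficiency),
        within_module_z = as.numeric(mr$within_module_z),
        participation = as.numeric(mr$participation),
        stopf("unknown nodal parameter '%s'", pm))
    }, numeric(p))
    nod <- matrix(nod, nrow = p,
                  dimnames = list(region_names, nodal_params))
  }
  list(global = glob, nodal = nod)
}

#' Permutation comparison of network parameters between two groups
#'
#' The inferential engine: the observed between-group difference
#' (`groupB - groupA`) of each network parameter is referenced against a
#' label-permutation null. Each permutation reshuffles subjects between the
#' two groups (preserving group sizes), rebuilds both covariance graphs, and
#' recomputes every requested parameter; all parameters share the same
#' permutation sequence (joint resampling). A difference is significant at
#' the global level when it falls outside the 95% confidence interval
#' (2.5/97.5 percentiles) of the permutation null. Nodal maps are
#' additionally corrected across regions per parameter with the
#' Benjamini-Hochberg procedure at `q`, combined with the requirement that
#' the uncorrected p-value is at most 0.05 (see [fdr_bh()]).
#'
#' Permutations on which a parameter is undefined (e.g. assortativity on a
#' degree-regular permuted graph) are recorded as missing and excluded from
#' that parameter's null; a parameter with more than 20% exclusions is
#' flagged unreliable.
#'
#' @param cohort an [scn_cohort] containing both groups.
#' @param groupA reference group label (differences are `groupB - groupA`,
#'   and the null CI plays the role of the reference interval).
#' @param groupB comparison group label.
#' @param parameters global parameters to test: any of `average_degree`,
#'   `average_strength`, `average_path_length`, `clustering`,
#'   `global_efficiency`, `local_efficiency`, `transitivity`, `modularity`,
#'   `assortativity`, `small_worldness`; `character(0)` skips the global
#'   level.
#' @param nodal_parameters nodal parameters to test: any of `degree`,
#'   `strength`, `path_length`, `clustering`, `global_efficiency`,
#'   `local_efficiency`, `within_module_z`, `participation`;
#'   `character(0)` skips the nodal level.
#' @param n_perm number of permutations (>= 100; 1000 is the conventional
#'   choice).
#' @param seed integer seed; fixed seed gives a bit-identical result.
#' @param n_random null graphs per small-worldness evaluation.
#' @param q FDR level for nodal maps.
#' @return An object of class `scn_permtest`: list with data.frames `global`
#'   and `nodal` (one row per outcome: observed difference, CI bounds,
#'   two-sided p, significance flags, exclusion count), matrix `null_global`
#'   (permutation draws), and metadata.
#' @examples
#' x <- matrix(runif(200, 0.3, 0.7), 20, 10)
#' coh <- scn_cohort(x, rep(c("HC", "MS"), each = 10))
#' pt <- permutation_compare(coh, "HC", "MS",
#'                           parameters = c("average_strength", "clustering"),
#'                           nodal_parameters = character(0),
#'                           n_perm = 100, seed = 1)
#' pt
#' @export
permutation_compare <- function(cohort, groupA, groupB,
                                parameters = setdiff(GLOBAL_PARAMETERS,
                                                     "small_worldness"),
                                nodal_parameters = character(0),
                                n_perm = 1000, seed = 1L, n_random = 20,
                                q = 0.05) {
  stopifnot(inherits(cohort, "scn_cohort"))
  if (length(parameters))
    parameters <- match.arg(parameters, GLOBAL_PARAMETERS, several.ok = TRUE)
  if (length(nodal_parameters))
    nodal_parameters <- match.arg(nodal_parameters, NODAL_PARAMETERS,
                                  several.ok = TRUE)
  if (!length(parameters) && !length(nodal_parameters))
    stopf("request at least one parameter")
  if (n_perm < 100) stopf("n_perm must be >= 100")
  ia <- which(cohort$group == groupA)
  ib <- which(cohort$group == groupB)
  if (length(ia) < 3 || length(ib) < 3)
    stopf("both groups need >= 3 subjects (have %d and %d)",
          length(ia), length(ib))
  X <- cohort$values[c(ia, ib), , drop = FALSE]
  na <- length(ia)
  n <- nrow(X)
  p <- ncol(X)
  rn <- cohort$region_names

  set.seed(child_seed(seed, 11L))
  obsA <- compute_group_params(X[seq_len(na), , drop = FALSE], parameters,
                               nodal_parameters, n_random, rn)
  obsB <- compute_group_params(X[-seq_len(na), , drop = FALSE], parameters,
                               nodal_parameters, n_random, rn)
  obs_g <- if (length(parameters)) obsB$global - obsA$global else numeric(0)
  obs_n <- if (length(nodal_parameters)) obsB$nodal - obsA$nodal else NULL

  null_g <- matrix(NA_real_, n_perm, length(parameters),
                   dimnames = list(NULL, parameters))
  null_n <- if (length(nodal_parameters))
    array(NA_real_, c(n_perm, p, length(nodal_parameters)),
          dimnames = list(NULL, rn, nodal_parameters)) else NULL
  set.seed(child_seed(seed, 12L))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    pa <- compute_group_params(X[idx[seq_len(na)], , drop = FALSE],
                               parameters, nodal_parameters, n_random, rn)
    pb <- compute_group_params(X[idx[-seq_len(na)], , drop = FALSE],
                               parameters, nodal_parameters, n_random, rn)
    if (length(parameters)) null_g[b, ] <- pb$global - pa$global
    if (length(nodal_parameters)) null_n[b, , ] <- pb$nodal - pa$nodal
  }

  summarise_one <- function(obs, null) {
    ok <- !is.na(null)
    nv <- null[ok]
    excl <- sum(!ok)
    if (is.na(obs) || length(nv) == 0)
      return(data.frame(observed_diff = obs, ci_low = NA_real_,
                        ci_high = NA_real_, p_two_sided = NA_real_,
                        significant_unadjusted = NA, n_excluded = excl,
                        unreliable = TRUE))
    # type-6 percentiles: for an exchangeable observed value the exceedance
    # probability of each bound is ~2.5% at any permutation count, keeping
    # the CI rule's level at its nominal 5%
    ci <- unname(stats::quantile(nv, c(0.025, 0.975), type = 6))
    pval <- (1 + sum(abs(nv) >= abs(obs))) / (length(nv) + 1)
    data.frame(observed_diff = obs, ci_low = ci[1], ci_high = ci[2],
               p_two_sided = pval,
               significant_unadjusted = obs < ci[1] | obs > ci[2],
               n_excluded = excl,
               unreliable = excl > 0.2 * length(null))
  }

  glob <- if (length(parameters)) {
    out <- do.call(rbind, lapply(seq_along(parameters), function(j) {
      cbind(data.frame(parameter = parameters[j], level = "global",
                       region = NA_character_),
            summarise_one(obs_g[j], null_g[, j]))
    }))
    rownames(out) <- NULL
    out
  } else NULL

  nod <- NULL
  if (length(nodal_parameters)) {
    nod <- do.call(rbind, lapply(seq_along(nodal_parameters), function(k) {
      rows <- do.call(rbind, lapply(seq_len(p), function(r) {
        cbind(data.frame(parameter = nodal_parameters[k], level = "nodal",
                         region = rn[r]),
              summarise_one(obs_n[r, k], null_n[, r, k]))
      }))
      pv <- rows$p_two_sided
      sig <- rep(NA, length(pv))
      usable <- !is.na(pv)
      sig[usable] <- fdr_bh(pv[usable], q = q)
      rows$significant_fdr <- sig
      rows
    }))
    rownames(nod) <- NULL
  }

  structure(
    list(global = glob, nodal = nod, null_global = null_g,
         groupA = groupA, groupB = groupB, n_A = na, n_B = n - na,
         n_perm = n_perm, seed = seed, q = q,
         arm = cohort$arm),
    class = "scn_permtest")
}

#' @export
print.scn_permtest <- function(x, ...) {
  cat(sprintf("Permutation comparison: %s vs %s (%d vs %d subjects, %d permutations)\n",
              x$groupA, x$groupB, x$n_A, x$n_B, x$n_perm))
  g <- x$global
  if (is.null(g)) g <- data.frame()
  else cat(sprintf("  global: %d/%d parameters significant (95%% CI rule)\n",
                   sum(g$significant_unadjusted, na.rm = TRUE), nrow(g)))
  for (i in seq_len(nrow(g)))
    cat(sprintf("    %-22s diff %+8.4f  CI [%8.4f, %8.4f]  p=%.4f%s\n",
                g$parameter[i], g$observed_diff[i], g$ci_low[i], g$ci_high[i],
                g$p_two_sided[i],
                if (isTRUE(g$significant_unadjusted[i])) " *" else ""))
  if (!is.null(x$nodal)) {
    n_sig <- sum(x$nodal$significant_fdr, na.rm = TRUE)
    cat(sprintf("  nodal: %d region-parameter pairs significant after FDR (q = %g)\n",
                n_sig, x$q))
  }
  invisible(x)
}

#' @export
summary.scn_permtest <- function(object, ...) {
  out <- object$global
  if (!is.null(object$nodal)) {
    out <- rbind(cbind(out, significant_fdr = NA), object$nodal)
  }
  out
}

#' Benjamini-Hochberg discovery set with the conjunction rule
#'
#' Standard step-up BH at level `q`: sort p-values ascending, find the
#' largest i with `p_(i) <= (i/m) q`, declare the i smallest significant.
#' With `conjunction = TRUE` (default) the final nodal significance
#' additionally requires the raw p-value to be at most 0.05 — the decision
#' rule used for nodal covariance-network maps (the conjunction is stated as
#' "p both <= 0.05 and <= the FDR-corrected p"; since BH-adjusted p-values
#' are never smaller than raw ones, its effective content is membership in
#' the BH discovery set plus raw p <= 0.05).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param q FDR level in (0, 1).
#' @param conjunction additionally require raw p <= 0.05.
#' @return Logical vector: which hypotheses are declared significant.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)  # all TRUE
#' @export
fdr_bh <- function(p_values, q = 0.05, conjunction = TRUE) {
  if (length(p_values) == 0) return(logical(0))
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stopf("p-values must lie in (0, 1]")
  if (q <= 0 || q >= 1) stopf("q must be in (0, 1)")
  sig <- stats::p.adjust(p_values, method = "BH") <= q
  if (conjunction) sig <- sig & p_values <= 0.05
  sig
}
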