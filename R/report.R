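#' Run the full set of between-group comparisons
#'
#' Applies [permutation_compare()] to an ordered list of group pairs — the
#' conventional design is HC vs MS total, HC vs RRMS, HC vs PMS, and RRMS vs
#' PMS — and compiles the outcomes. Pooled labels (e.g. "MS" as the union of
#' RRMS and PMS) are declared via `pool` and applied before permutation, so
#' the shuffled labels are reference vs pooled group.
#'
#' @param cohort an [scn_cohort].
#' @param design list of length-2 character vectors `c(reference, comparison)`.
#' @param pool named list mapping a pooled label to the member group labels.
#' @param parameters,nodal_parameters,n_perm,seed,n_random,q passed to
#'   [permutation_compare()]; each pair gets a seed derived from `seed`.
#' @param lobe_map optional data.frame with columns `region`, `lobe` used to
#'   compile nodal findings by lobe; defaults to the AAL-116 grouping when
#'   the cohort has 116 regions.
#' @return An object of class `scn_report`: list with `comparisons` (one
#'   `scn_permtest` per pair, named "A_vs_B"), `global_table`, `nodal_table`
#'   and `lobe_table` (NULL without nodal parameters or lobe map).
#' @export
run_comparisons <- function(cohort, design, pool = list(),
                            parameters = setdiff(GLOBAL_PARAMETERS,
                                                 "small_worldness"),
                            nodal_parameters = character(0),
                            n_perm = 1000, seed = 1L, n_random = 20,
                            q = 0.05, lobe_map = NULL) {
  stopifnot(inherits(cohort, "scn_cohort"))
  if (!length(design)) stopf("design must list at least one group pair")
  known <- unique(cohort$group)
  if (is.null(lobe_map) && length(cohort$region_names) == 116 &&
      all(cohort$region_names == aal_regions()$region))
    lobe_map <- aal_regions()
  comparisons <- list()
  for (k in seq_along(design)) {
    pair <- design[[k]]
    if (length(pair) != 2) stopf("each design entry must name two groups")
    members <- lapply(pair, function(g) {
      if (g %in% names(pool)) pool[[g]] else g
    })
    bad <- setdiff(unlist(members), known)
    if (length(bad)) stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
    sub <- cohort_subset(cohort, unlist(members[1]), relabel = pair[1])
    subB <- cohort_subset(cohort, unlist(members[2]), relabel = pair[2])
    paired <- scn_cohort(rbind(sub$values, subB$values),
                         c(sub$group, subB$group),
                         region_names = cohort$region_names,
                         lesion_load = c(sub$lesion_load, subB$lesion_load),
                         arm = cohort$arm,
                         subject_id = c(sub$subject_id, subB$subject_id))
    comparisons[[paste0(pair[1], "_vs_", pair[2])]] <-
      permutation_compare(paired, pair[1], pair[2], parameters = parameters,
                          nodal_parameters = nodal_parameters,
                          n_perm = n_perm, seed = child_seed(seed, k),
                          n_random = n_random, q = q)
  }
  global_table <- do.call(rbind, lapply(names(comparisons), function(nm) {
    g <- comparisons[[nm]]$global
    if (is.null(g)) return(NULL)
    cbind(comparison = nm, g)
  }))
  nodal_table <- do.call(rbind, lapply(names(comparisons), function(nm) {
    nd <- comparisons[[nm]]$nodal
    if (is.null(nd)) return(NULL)
    cbind(comparison = nm, nd)
  }))
  lobe_table <- NULL
  if (!is.null(nodal_table) && !is.null(lobe_map)) {
    nt <- merge(nodal_table, lobe_map, by = "region", all.x = TRUE)
    nt$lobe[is.na(nt$lobe)] <- "unassigned"
    agg <- stats::aggregate(
      cbind(n_regions = significant_fdr) ~ comparison + parameter + lobe,
      data = transform(nt, significant_fdr = as.integer(significant_fdr)),
      FUN = sum, na.rm = TRUE)
    lobe_table <- agg[agg$n_regions > 0, , drop = FALSE]
    rownames(lobe_table) <- NULL
  }
  structure(list(comparisons = comparisons, global_table = global_table,
                 nodal_table = nodal_table, lobe_table = lobe_table,
                 design = design, n_perm = n_perm, seed = seed,
                 arm = cohort$arm),
            class = "scn_report")
}

#' @export
print.scn_report <- function(x, ...) {
  cat(sprintf("Group-comparison report (%s arm, %d permutations per pair)\n",
              x$arm, x$n_perm))
  for (nm in names(x$comparisons)) {
    pt <- x$comparisons[[nm]]
    n_sig <- sum(pt$global$significant_unadjusted, na.rm = TRUE)
    line <- sprintf("  %-18s %d/%d global parameters significant",
                    nm, n_sig, nrow(pt$global))
    if (!is.null(pt$nodal))
      line <- paste0(line, sprintf(", %d nodal findings after FDR",
                                   sum(pt$nodal$significant_fdr, na.rm = TRUE)))
    cat(line, "\n")
  }
  if (!is.null(x$lobe_table) && nrow(x$lobe_table)) {
    cat("  nodal findings by lobe:\n")
    print(x$lobe_table, row.names = FALSE)
  }
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Writes `global.csv`, `nodal.csv`, `lobes.csv` (when present) and a JSON
#' summary with counts of significant findings per comparison.
#'
#' @param report an `scn_report`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(report$global_table))
    utils::write.csv(report$global_table, file.path(dir, "global.csv"),
                     row.names = FALSE)
  if (!is.null(report$nodal_table))
    utils::write.csv(report$nodal_table, file.path(dir, "nodal.csv"),
                     row.names = FALSE)
  if (!is.null(report$lobe_table))
    utils::write.csv(report$lobe_table, file.path(dir, "lobes.csv"),
                     row.names = FALSE)
  summ <- lapply(report$comparisons, function(pt) {
    list(n_global_significant =
           sum(pt$global$significant_unadjusted, na.rm = TRUE),
         n_global_tested = nrow(pt$global),
         n_nodal_significant_fdr =
           if (is.null(pt$nodal)) 0L
           else sum(pt$nodal$significant_fdr, na.rm = TRUE))
  })
  jsonlite::write_json(
    list(arm = report$arm, n_perm = report$n_perm, seed = report$seed,
         comparisons = summ),
    file.path(dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
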