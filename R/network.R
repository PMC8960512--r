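#' Build a group-level structural covariance network
#'
#' Constructs the weighted undirected association graph of one group: edge
#' (i, j) is the Spearman rank correlation of region i versus region j across
#' that group's subjects (average ranks for ties), with negative correlations
#' set to zero and a zero diagonal. One graph per group — covariance networks
#' exist at the group level, not per subject.
#'
#' @param cohort an [scn_cohort].
#' @param group group label to select; `NULL` uses all subjects (useful for a
#'   cohort already subset or relabelled).
#' @return An object of class `scn_graph`: list with `weights` (regions x
#'   regions, in \[0, 1\], symmetric, zero diagonal), `region_names`,
#'   `n_subjects_used` and `group`. Regions with zero variance across
#'   subjects have all their edges set to 0 (with a warning).
#' @examples
#' x <- matrix(runif(60, 0.3, 0.7), 15, 4)
#' g <- build_association_matrix(scn_cohort(x, rep("HC", 15)), "HC")
#' g
#' @export
build_association_matrix <- function(cohort, group = NULL) {
  stopifnot(inherits(cohort, "scn_cohort"))
  if (is.null(group)) {
    X <- cohort$values
    group <- if (length(unique(cohort$group)) == 1) cohort$group[1] else "ALL"
  } else {
    keep <- cohort$group == group
    if (!any(keep)) stopf("no subjects with group label '%s'", group)
    X <- cohort$values[keep, , drop = FALSE]
  }
  if (nrow(X) < 3)
    stopf("group '%s' has %d subjects; >= 3 required for a correlation network",
          group, nrow(X))
  if (ncol(X) < 2) stopf("need >= 2 regions")
  W <- .cpp_spearman_graph(X)
  nc <- attr(W, "n_constant")
  if (!is.null(nc) && nc > 0)
    warning(sprintf("%d region(s) with zero variance in group '%s'; their edges set to 0",
                    nc, group), call. = FALSE)
  attr(W, "n_constant") <- NULL
  dimnames(W) <- list(cohort$region_names, cohort$region_names)
  new_scn_graph(W, cohort$region_names, nrow(X), group)
}

#' @keywords internal
#' @noRd
new_scn_graph <- function(weights, region_names, n_subjects, group) {
  structure(
    list(weights = weights, region_names = region_names,
         n_subjects_used = n_subjects, group = group),
    class = "scn_graph")
}

#' Construct an scn_graph from a weight matrix
#'
#' Validates and wraps a symmetric nonnegative weight matrix (zero diagonal,
#' entries in \[0, 1\]) as a structural covariance graph. Mostly useful for
#' tests and for analysing externally computed association matrices.
#'
#' @param weights square numeric matrix.
#' @param region_names optional names; defaults to matrix dimnames.
#' @param group group label attached to the graph.
#' @return An `scn_graph`.
#' @export
scn_graph <- function(weights, region_names = NULL, group = "graph") {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (ncol(weights) != p) stopf("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-12) stopf("weights must be symmetric")
  if (any(weights < 0) || any(weights > 1)) stopf("weights must lie in [0, 1]")
  if (any(diag(weights) != 0)) stopf("diagonal must be zero")
  region_names <- region_names %||% rownames(weights) %||%
    sprintf("region_%d", seq_len(p))
  dimnames(weights) <- list(region_names, region_names)
  new_scn_graph(weights, region_names, NA_integer_, group)
}

#' @export
print.scn_graph <- function(x, ...) {
  W <- x$weights
  p <- nrow(W)
  ne <- sum(W[upper.tri(W)] > 0)
  cat(sprintf("Structural covariance graph: group '%s'\n", x$group))
  cat(sprintf("  %d regions, %d edges (density %.2f)", p, ne,
              ne / (p * (p - 1) / 2)))
  if (!is.na(x$n_subjects_used))
    cat(sprintf(", from %d subjects", x$n_subjects_used))
  cat("\n")
  if (ne > 0)
    cat(sprintf("  weights: mean %.3f, max %.3f\n",
                mean(W[upper.tri(W)][W[upper.tri(W)] > 0]), max(W)))
  invisible(x)
}

#' Serialise a graph as CSV
#'
#' `write_graph_csv()` writes the full square weight matrix with a region
#' header; `graph_edge_list()` returns the (region_i, region_j, weight)
#' long form for nonzero edges.
#'
#' @param graph an `scn_graph`.
#' @param path output file.
#' @return The path (write) or a data.frame (edge list).
#' @export
write_graph_csv <- function(graph, path) {
  utils::write.csv(as.data.frame(graph$weights), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_graph_csv
#' @export
graph_edge_list <- function(graph) {
  W <- graph$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  data.frame(region_i = graph$region_names[idx[, 1]],
             region_j = graph$region_names[idx[, 2]],
             weight = W[idx], row.names = NULL)
}
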