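#' Nodal degree and strength
#'
#' Degree is the count of nonzero-weight connections at each node; strength
#' is the sum of connection weights. Exact-zero correlations count as absent
#' edges.
#'
#' @param graph an `scn_graph`.
#' @return A list with integer vector `degree` and numeric vector `strength`,
#'   both named by region.
#' @export
degree_strength <- function(graph) {
  W <- graph$weights
  list(degree = stats::setNames(as.integer(rowSums(W > 0)), graph$region_names),
       strength = stats::setNames(rowSums(W), graph$region_names))
}

#' Weighted shortest-path distance matrix
#'
#' Edge length is the reciprocal of the weight (strong associations are
#' short), so path length generalises the binary "lowest number of
#' connections" to weighted graphs. Unreachable pairs are `Inf`.
#'
#' @param graph an `scn_graph`.
#' @return Numeric matrix of pairwise distances with zero diagonal.
#' @export
shortest_paths <- function(graph) {
  D <- .cpp_shortest_paths(graph$weights)
  dimnames(D) <- list(graph$region_names, graph$region_names)
  D
}

#' Nodal characteristic path length and global efficiency
#'
#' `path_length[i]` is the mean finite shortest-path distance from node i to
#' all other nodes (`Inf` for isolated nodes); `efficiency[i]` is the mean of
#' inverse distances with `1/Inf = 0`, so disconnection lowers efficiency
#' rather than destroying the statistic.
#'
#' @param graph an `scn_graph`.
#' @param distances optional precomputed matrix from [shortest_paths()].
#' @return List with numeric vectors `path_length` and `efficiency`.
#' @export
path_and_efficiency <- function(graph, distances = NULL) {
  D <- distances %||% shortest_paths(graph)
  n <- nrow(D)
  fin <- is.finite(D)
  diag(fin) <- FALSE
  Df <- D
  Df[!fin] <- 0
  n_fin <- rowSums(fin)
  l <- ifelse(n_fin > 0, rowSums(Df) / n_fin, Inf)
  Inv <- 1 / D
  Inv[!fin] <- 0
  E <- rowSums(Inv) / (n - 1)
  list(path_length = stats::setNames(l, graph$region_names),
       efficiency = stats::setNames(E, graph$region_names))
}

#' Weighted clustering, transitivity, and local efficiency
#'
#' Clustering uses the Onnela formula: geometric-mean triangle intensity of
#' max-normalised weights, `C_i = sum_(jh) (w'_ij w'_jh w'_hi)^(1/3) /
#' (k_i (k_i - 1))` with `w' = w / max(w)`, and 0 for nodes of degree < 2.
#' Transitivity is the graph-wide ratio of summed triangle intensity to
#' summed `k_i (k_i - 1)`. Local efficiency of node i is the global
#' efficiency of the subgraph induced by i's neighbours (0 for degree < 2).
#'
#' @param graph an `scn_graph`.
#' @param local also compute local efficiency (the expensive part on dense
#'   graphs: one subgraph shortest-path problem per node).
#' @return List with vector `clustering`, scalar `transitivity` and (when
#'   `local = TRUE`) vector `local_efficiency`.
#' @export
clustering_transitivity <- function(graph, local = TRUE) {
  W <- graph$weights
  n <- nrow(W)
  wmax <- max(W)
  k <- rowSums(W > 0)
  if (wmax <= 0) {
    C <- rep(0, n)
    T <- 0
  } else {
    Wh <- (W / wmax)^(1 / 3)
    num <- rowSums((Wh %*% Wh) * Wh)  # diag of Wh^3: triangle intensity
    den <- k * (k - 1)
    C <- ifelse(k >= 2, num / pmax(den, 1), 0)
    T <- if (sum(den) > 0) sum(num) / sum(den) else 0
  }
  out <- list(clustering = stats::setNames(as.numeric(C),
                                           graph$region_names),
              transitivity = T)
  if (local)
    out$local_efficiency <- stats::setNames(
      as.numeric(.cpp_local_efficiency(graph$weights)), graph$region_names)
  out
}

#' Newman weighted modularity of a partition
#'
#' `Q = sum_c (W_c / m - (S_c / 2m)^2)` where `m` is the total edge weight,
#' `W_c` the intra-community edge weight, and `S_c` the summed strength of
#' community `c`.
#'
#' @param graph an `scn_graph`.
#' @param membership integer community label per region.
#' @return Scalar modularity.
#' @export
modularity_q <- function(graph, membership) {
  W <- graph$weights
  if (length(membership) != nrow(W)) stopf("membership must label every region")
  m <- sum(W) / 2
  if (m <= 0) return(0)
  s <- rowSums(W)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    W_c <- sum(W[idx, idx, drop = FALSE]) / 2
    S_c <- sum(s[idx])
    q <- q + W_c / m - (S_c / (2 * m))^2
  }
  q
}

#' Detect communities by Louvain modularity maximisation
#'
#' Runs seeded Louvain optimisation of Newman weighted modularity at
#' resolution 1 and returns the partition used downstream for within-module
#' degree z-scores and participation coefficients.
#'
#' @param graph an `scn_graph` with at least one edge.
#' @param seed integer seed making the (stochastic) optimisation
#'   reproducible.
#' @return An object of class `scn_partition`: list with `membership`
#'   (integer labels `0..M-1` in first-appearance order), `n_modules`, and
#'   the partition's modularity `Q`.
#' @export
detect_communities <- function(graph, seed = 1L) {
  W <- graph$weights
  if (all(W == 0)) stopf("community detection requires at least one edge")
  ig <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  memb <- withr::with_seed(seed,
    igraph::membership(igraph::cluster_louvain(ig, resolution = 1)))
  memb <- as.integer(memb)
  memb <- match(memb, unique(memb)) - 1L  # contiguous 0..M-1
  structure(
    list(membership = stats::setNames(memb, graph$region_names),
         n_modules = length(unique(memb)),
         Q = modularity_q(graph, memb)),
    class = "scn_partition")
}

#' @export
print.scn_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d modules, Q = %.4f\n", x$n_modules, x$Q))
  print(table(module = x$membership))
  invisible(x)
}

#' Within-module degree z-score and participation coefficient
#'
#' `z_i` standardises node i's within-module strength against its module's
#' mean and SD (0 when the SD is 0). `P_i = 1 - sum_m (s_im / s_i)^2`
#' measures how evenly node i's strength is spread over modules (0 for a
#' provincial node, 0 for an isolated node by convention).
#'
#' @param graph an `scn_graph`.
#' @param partition an `scn_partition` covering all regions.
#' @return List with numeric vectors `within_module_z` and `participation`.
#' @export
module_roles <- function(graph, partition) {
  W <- graph$weights
  memb <- partition$membership
  if (length(memb) != nrow(W) || anyNA(memb))
    stopf("partition must label every region")
  n <- nrow(W)
  mods <- sort(unique(memb))
  # strength of each node into each module
  s_im <- vapply(mods, function(m) rowSums(W[, memb == m, drop = FALSE]),
                 numeric(n))
  s_im <- matrix(s_im, nrow = n)
  s <- rowSums(s_im)
  kappa <- s_im[cbind(seq_len(n), match(memb, mods))]  # within-own-module strength
  z <- numeric(n)
  for (m in mods) {
    idx <- memb == m
    mu <- mean(kappa[idx])
    sdv <- stats::sd(kappa[idx])
    z[idx] <- if (is.na(sdv) || sdv == 0) 0 else (kappa[idx] - mu) / sdv
  }
  P <- ifelse(s > 0, 1 - rowSums((s_im / ifelse(s > 0, s, 1))^2), 0)
  list(within_module_z = stats::setNames(z, graph$region_names),
       participation = stats::setNames(as.numeric(P), graph$region_names))
}

#' Degree (or strength) assortativity
#'
#' Newman's assortativity: the Pearson correlation of endpoint degrees over
#' all edges, each undirected edge contributing both orientations. Positive
#' values mean hubs connect to hubs. Undefined (NaN, with a warning) when
#' endpoint degrees have zero variance, e.g. on regular graphs.
#'
#' @param graph an `scn_graph` with at least 2 edges.
#' @param variant `"degree"` (default) or `"strength"`: which endpoint
#'   property is correlated.
#' @return Scalar assortativity coefficient.
#' @export
assortativity <- function(graph, variant = c("degree", "strength")) {
  variant <- match.arg(variant)
  W <- graph$weights
  ds <- degree_strength(graph)
  x <- if (variant == "degree") ds$degree else ds$strength
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(idx) < 2) stopf("assortativity needs >= 2 edges")
  a <- c(x[idx[, 1]], x[idx[, 2]])
  b <- c(x[idx[, 2]], x[idx[, 1]])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("assortativity undefined: zero variance of endpoint degrees",
            call. = FALSE)
    return(NaN)
  }
  stats::cor(a, b)
}

#' Small-worldness sigma
#'
#' `sigma = (C / C_rand) / (L / L_rand)` where C and L are the global
#' (nodal-averaged) clustering coefficient and characteristic path length of
#' the graph, and `C_rand`, `L_rand` their means over `n_random`
#' degree-preserving null graphs: the topology is rewired by degree-sequence
#' preserving edge swaps and the original weight multiset is reassigned at
#' random to the surviving edges. Values above 1 indicate clustering in
#' excess of a matched random graph at comparable path length.
#'
#' @param graph an `scn_graph`.
#' @param n_random number of null graphs (default 20; use more, e.g. 100,
#'   outside permutation loops).
#' @param seed integer seed.
#' @return Scalar sigma, with attributes `C`, `L`, `C_rand`, `L_rand`.
#' @export
small_worldness <- function(graph, n_random = 20, seed = 1L) {
  stopifnot(n_random >= 1)
  cl <- clustering_transitivity(graph, local = FALSE)
  pe <- path_and_efficiency(graph)
  C <- mean(cl$clustering)
  L <- mean(pe$path_length[is.finite(pe$path_length)])
  nulls <- withr::with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      for (attempt in 1:10) {
        gr <- random_reference(graph)
        ncl <- clustering_transitivity(gr, local = FALSE)
        npe <- path_and_efficiency(gr)
        Cr <- mean(ncl$clustering)
        fin <- npe$path_length[is.finite(npe$path_length)]
        if (Cr > 0 && length(fin) > 0) return(c(Cr, mean(fin)))
      }
      stop("null-model resampling failed 10 times (degenerate graph)",
           call. = FALSE)
    }, numeric(2))
  })
  C_rand <- mean(nulls[1, ])
  L_rand <- mean(nulls[2, ])
  sigma <- (C / C_rand) / (L / L_rand)
  structure(sigma, C = C, L = L, C_rand = C_rand, L_rand = L_rand)
}

# Degree-preserving rewired null graph with randomly reassigned weights.
# Uses the current RNG stream (callers seed it).
#' @keywords internal
#' @noRd
random_reference <- function(graph) {
  W <- graph$weights
  ig <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected",
                                            diag = FALSE)
  ne <- igraph::ecount(ig)
  if (ne < 2) stopf("null model needs >= 2 edges")
  ig <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                                  niter = 10 * ne))
  el <- igraph::as_edgelist(ig, names = FALSE)
  w <- sample(W[upper.tri(W)][W[upper.tri(W)] > 0])
  Wr <- matrix(0, nrow(W), ncol(W))
  Wr[el] <- w
  Wr <- Wr + t(Wr)
  dimnames(Wr) <- dimnames(W)
  new_scn_graph(Wr, graph$region_names, graph$n_subjects_used,
                paste0(graph$group, "_null"))
}

#' Compute the full nodal and global parameter set of a graph
#'
#' One call computing every parameter of the standard structural covariance
#' set: nodal degree, strength, characteristic path length, clustering,
#' global efficiency, local efficiency, within-module degree z-score and
#' participation coefficient; global averages of the first six (the global
#' level is defined as the nodal mean over all regions, infinite path
#' lengths excluded), plus transitivity, modularity, assortativity and —
#' optionally — small-worldness.
#'
#' @param graph an `scn_graph`.
#' @param seed seed for community detection and the small-world null.
#' @param n_random null graphs for sigma; `0` skips small-worldness.
#' @return An object of class `scn_metrics`: list with data.frame `nodal`
#'   (region x parameter), named list `global`, and the `scn_partition` used.
#' @examples
#' W <- matrix(0.5, 5, 5); diag(W) <- 0
#' m <- graph_metrics(scn_graph(W), n_random = 0)
#' m$global$average_degree
#' @export
graph_metrics <- function(graph, seed = 1L, n_random = 20) {
  ds <- degree_strength(graph)
  pe <- path_and_efficiency(graph)
  cl <- clustering_transitivity(graph)
  part <- detect_communities(graph, seed = seed)
  mr <- module_roles(graph, part)
  nodal <- data.frame(
    region = graph$region_names,
    degree = as.numeric(ds$degree),
    strength = ds$strength,
    path_length = pe$path_length,
    clustering = cl$clustering,
    global_efficiency = pe$efficiency,
    local_efficiency = cl$local_efficiency,
    within_module_z = mr$within_module_z,
    participation = mr$participation,
    row.names = NULL)
  r <- tryCatch(assortativity(graph), warning = function(w) NaN)
  glob <- global_summary(nodal, transitivity = cl$transitivity,
                         modularity = part$Q, assortativity = r)
  if (n_random > 0)
    glob$small_worldness <-
      as.numeric(small_worldness(graph, n_random = n_random, seed = seed))
  structure(list(nodal = nodal, global = glob, partition = part,
                 group = graph$group),
            class = "scn_metrics")
}

#' Average nodal parameters into the global level
#'
#' The global level of the averaged parameters is the arithmetic mean of the
#' nodal vector over all regions; infinite path lengths are excluded from
#' the mean and their count reported.
#'
#' @param nodal nodal data.frame as produced by [graph_metrics()].
#' @param transitivity,modularity,assortativity,small_worldness optional
#'   graph-level scalars to attach.
#' @return Named list of global parameters.
#' @export
global_summary <- function(nodal, transitivity = NULL, modularity = NULL,
                           assortativity = NULL, small_worldness = NULL) {
  pl <- nodal$path_length
  out <- list(
    average_degree = mean(nodal$degree),
    average_strength = mean(nodal$strength),
    average_path_length = if (any(is.finite(pl))) mean(pl[is.finite(pl)]) else Inf,
    n_infinite_path_length = sum(!is.finite(pl)),
    clustering = mean(nodal$clustering),
    global_efficiency = mean(nodal$global_efficiency),
    local_efficiency = mean(nodal$local_efficiency))
  if (!is.null(transitivity)) out$transitivity <- transitivity
  if (!is.null(modularity)) out$modularity <- modularity
  if (!is.null(assortativity)) out$assortativity <- assortativity
  if (!is.null(small_worldness)) out$small_worldness <- small_worldness
  out
}

#' @export
print.scn_metrics <- function(x, ...) {
  cat(sprintf("Network parameters: group '%s' (%d regions, %d modules)\n",
              x$group, nrow(x$nodal), x$partition$n_modules))
  g <- x$global
  for (nm in setdiff(names(g), "n_infinite_path_length"))
    cat(sprintf("  %-22s %.4f\n", nm, g[[nm]]))
  if (g$n_infinite_path_length > 0)
    cat(sprintf("  (%d region(s) with infinite path length excluded)\n",
                g$n_infinite_path_length))
  invisible(x)
}

#' Write metrics as a tidy CSV
#'
#' Long format: one row per (group, level, region, metric) with
#' `region = "ALL"` at the global level.
#'
#' @param metrics an `scn_metrics`.
#' @param path output file; `NULL` returns the data.frame without writing.
#' @return The tidy data.frame, invisibly when written.
#' @export
write_metrics_csv <- function(metrics, path = NULL) {
  nod <- metrics$nodal
  long <- do.call(rbind, lapply(setdiff(names(nod), "region"), function(m)
    data.frame(group = metrics$group, level = "nodal", region = nod$region,
               metric = m, value = nod[[m]])))
  g <- metrics$global
  glob <- data.frame(group = metrics$group, level = "global", region = "ALL",
                     metric = names(g), value = as.numeric(unlist(g)))
  out <- rbind(long, glob)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
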