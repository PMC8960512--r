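test_that("degree, strength, distances, efficiency and clustering match brute-force oracles", {
  for (nm in names(fixture_graphs())) {
    W <- fixture_graphs()[[nm]]
    g <- scn_graph(W)

    ds <- degree_strength(g)
    ods <- oracle_degree_strength(W)
    expect_equal(unname(ds$degree), ods$degree, info = nm)
    expect_equal(unname(ds$strength), ods$strength, tolerance = 1e-12, info = nm)

    D <- shortest_paths(g)
    OD <- oracle_distances_minplus(W)
    expect_lt(max(abs(unname(D) - OD)[is.finite(OD)]), 1e-10)
    expect_identical(is.finite(unname(D)), is.finite(OD))

    pe <- path_and_efficiency(g)
    ope <- oracle_path_eff(OD)
    fin <- is.finite(ope$path_length)
    expect_lt(max(abs(unname(pe$path_length)[fin] - ope$path_length[fin]), 0),
              1e-10)
    expect_equal(unname(pe$efficiency), ope$efficiency, tolerance = 1e-10)

    cl <- clustering_transitivity(g)
    ocl <- oracle_onnela(W)
    expect_equal(unname(cl$clustering), ocl$C, tolerance = 1e-10, info = nm)
    expect_equal(cl$transitivity, ocl$transitivity, tolerance = 1e-10)
    expect_equal(unname(cl$local_efficiency), oracle_local_eff(W),
                 tolerance = 1e-10, info = nm)
  }
})

test_that("weighted shortest paths agree with exhaustive path enumeration", {
  W <- fx_random(8, 0.5, 77)
  D <- shortest_paths(scn_graph(W))
  expect_equal(unname(D), oracle_distances_enum(W), tolerance = 1e-10)
})

test_that("assortativity matches the edge-list Pearson oracle and flags regular graphs", {
  expect_equal(assortativity(scn_graph(fx_star(4))), -1, tolerance = 1e-12)
  expect_warning(r <- assortativity(scn_graph(fx_cycle(6))), "zero variance")
  expect_true(is.nan(r))
  for (s in 1:5) {
    W <- fx_random(10, 0.4, 500 + s)
    o <- oracle_assortativity(W)
    if (is.nan(o)) next
    expect_equal(assortativity(scn_graph(W)), o, tolerance = 1e-10)
  }
})

test_that("analytic values on canonical graphs", {
  # complete unit-weight graph: all distances 1
  for (n in c(4, 6, 8)) {
    m <- graph_metrics(scn_graph(fx_complete(n)), n_random = 0)
    expect_equal(m$global$average_degree, n - 1)
    expect_equal(m$global$average_path_length, 1)
    expect_equal(m$global$global_efficiency, 1)
    expect_equal(m$global$clustering, 1)
    expect_equal(m$global$transitivity, 1)
  }
  # two-node graph, w = 0.5: distance 1/w
  D <- shortest_paths(scn_graph(matrix(c(0, 0.5, 0.5, 0), 2)))
  expect_equal(D[1, 2], 2)
  # 3-node path, unit weights: end-to-end distance 2
  expect_equal(shortest_paths(scn_graph(fx_path(3)))[1, 3], 2)
  # star: no triangles
  cl <- clustering_transitivity(scn_graph(fx_star(3)))
  expect_equal(unname(cl$clustering), rep(0, 4))
  expect_equal(cl$transitivity, 0)
  # triangle with equal weights: perfect clustering
  cl3 <- clustering_transitivity(scn_graph(fx_complete(3, 0.8)))
  expect_equal(unname(cl3$clustering), rep(1, 3), tolerance = 1e-12)
  # isolated node has zero efficiency and infinite path length
  W <- fx_complete(4); W[4, ] <- W[, 4] <- 0
  pe <- path_and_efficiency(scn_graph(W))
  expect_equal(unname(pe$efficiency[4]), 0)
  expect_equal(unname(pe$path_length[4]), Inf)
  # degree/strength on a single 0.3 edge among 3 nodes
  ds <- degree_strength(scn_graph(matrix(c(0, .3, 0, .3, 0, 0, 0, 0, 0), 3)))
  expect_equal(unname(ds$degree), c(1, 1, 0))
  expect_equal(unname(ds$strength), c(0.3, 0.3, 0))
})

test_that("scaling all weights leaves scale-free metrics unchanged and rescales the rest", {
  W <- fx_random(8, 0.6, 42)
  g1 <- scn_graph(W)
  c_scale <- 0.4
  g2 <- scn_graph(W * c_scale)
  expect_equal(degree_strength(g2)$degree, degree_strength(g1)$degree)
  expect_equal(degree_strength(g2)$strength,
               degree_strength(g1)$strength * c_scale, tolerance = 1e-12)
  expect_equal(unname(shortest_paths(g2)), unname(shortest_paths(g1)) / c_scale,
               tolerance = 1e-10)
  cl1 <- clustering_transitivity(g1, local = FALSE)
  cl2 <- clustering_transitivity(g2, local = FALSE)
  expect_equal(cl2$clustering, cl1$clustering, tolerance = 1e-12)
  p1 <- detect_communities(g1, seed = 5)
  p2 <- detect_communities(g2, seed = 5)
  expect_equal(p2$membership, p1$membership)
  mr1 <- module_roles(g1, p1)
  mr2 <- module_roles(g2, p1)
  expect_equal(mr2$participation, mr1$participation, tolerance = 1e-12)
})

test_that("relabelling nodes permutes nodal vectors and preserves global scalars", {
  W <- fx_random(8, 0.6, 43)
  perm <- c(3, 1, 4, 2, 8, 6, 5, 7)
  Wp <- W[perm, perm]
  g <- scn_graph(W); gp <- scn_graph(Wp)
  expect_equal(unname(degree_strength(gp)$strength),
               unname(degree_strength(g)$strength)[perm], tolerance = 1e-12)
  expect_equal(unname(path_and_efficiency(gp)$efficiency),
               unname(path_and_efficiency(g)$efficiency)[perm],
               tolerance = 1e-10)
  expect_equal(clustering_transitivity(gp)$transitivity,
               clustering_transitivity(g)$transitivity, tolerance = 1e-12)
  expect_equal(assortativity(gp), assortativity(g), tolerance = 1e-10)
})

test_that("global summary averages the nodal vectors, excluding infinite path lengths", {
  W <- fx_random(8, 0.5, 44)
  W[8, ] <- W[, 8] <- 0  # isolate one node
  m <- graph_metrics(scn_graph(W), n_random = 0)
  expect_equal(m$global$average_degree, mean(m$nodal$degree))
  expect_equal(m$global$average_strength, mean(m$nodal$strength))
  pl <- m$nodal$path_length
  expect_equal(m$global$average_path_length, mean(pl[is.finite(pl)]))
  expect_equal(m$global$n_infinite_path_length, sum(!is.finite(pl)))
  expect_equal(m$global$clustering, mean(m$nodal$clustering))
  expect_equal(m$global$global_efficiency, mean(m$nodal$global_efficiency))
})

test_that("graph metrics on a random graph equal the oracle end to end", {
  W <- fx_random(7, 0.6, 45)
  m <- graph_metrics(scn_graph(W), seed = 3, n_random = 0)
  ods <- oracle_degree_strength(W)
  OD <- oracle_distances_minplus(W)
  ope <- oracle_path_eff(OD)
  ocl <- oracle_onnela(W)
  expect_equal(m$nodal$degree, as.numeric(ods$degree))
  expect_equal(m$nodal$strength, ods$strength, tolerance = 1e-10)
  expect_equal(m$nodal$path_length, ope$path_length, tolerance = 1e-10)
  expect_equal(m$nodal$clustering, ocl$C, tolerance = 1e-10)
  expect_equal(m$nodal$global_efficiency, ope$efficiency, tolerance = 1e-10)
  expect_equal(m$nodal$local_efficiency, oracle_local_eff(W), tolerance = 1e-10)
  # module roles recomputed from the same partition by the oracle
  omr <- oracle_module_roles(W, unname(m$partition$membership))
  expect_equal(m$nodal$within_module_z, omr$z, tolerance = 1e-10)
  expect_equal(m$nodal$participation, omr$P, tolerance = 1e-10)
  expect_equal(m$global$modularity,
               oracle_modularity(W, unname(m$partition$membership)),
               tolerance = 1e-10)
})

test_that("small-worldness is reproducible, near 1 under self-comparison, above 1 for clustered graphs", {
  # lattice with shortcuts: high clustering, short paths
  W <- matrix(0, 20, 20)
  for (i in 1:20) for (d in 1:2) {
    j <- ((i + d - 1) %% 20) + 1
    W[i, j] <- W[j, i] <- 1
  }
  W[1, 11] <- W[11, 1] <- 1
  W[5, 15] <- W[15, 5] <- 1
  g <- scn_graph(W)
  s1 <- small_worldness(g, n_random = 20, seed = 9)
  s2 <- small_worldness(g, n_random = 20, seed = 9)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_gt(as.numeric(s1), 1)
  # a graph drawn from the null family scores near 1
  gr <- withr::with_seed(7, scnet:::random_reference(g))
  expect_lt(abs(as.numeric(small_worldness(gr, n_random = 30, seed = 11)) - 1),
            0.25)
})
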