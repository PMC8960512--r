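# Fixture graph set: >= 20 small graphs (<= 8 nodes) spanning the families
# used for oracle-equivalence checks. Weight matrices only.

fx_complete <- function(n, w = 1) {
  W <- matrix(w, n, n); diag(W) <- 0; W
}

fx_star <- function(leaves, w = 1) {
  n <- leaves + 1
  W <- matrix(0, n, n)
  W[1, 2:n] <- W[2:n, 1] <- w
  W
}

fx_cycle <- function(n, w = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    W[i, j] <- W[j, i] <- w
  }
  W
}

fx_path <- function(n, w = 1) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- w
  W
}

fx_two_triangles <- function(w = 1) {
  W <- matrix(0, 6, 6)
  for (tri in list(1:3, 4:6))
    for (i in tri) for (j in tri) if (i != j) W[i, j] <- w
  W
}

fx_barbell <- function(w = 1) {
  W <- matrix(0, 8, 8)
  for (cl in list(1:4, 5:8))
    for (i in cl) for (j in cl) if (i != j) W[i, j] <- w
  W[4, 5] <- W[5, 4] <- w
  W
}

fx_random <- function(n, density, seed, weights = TRUE) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < density) {
      w <- if (weights) round(runif(1, 0.05, 1), 3) else 1
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}

fixture_graphs <- function() {
  g <- list(
    complete4 = fx_complete(4),
    complete6_half = fx_complete(6, 0.5),
    complete8 = fx_complete(8),
    star4 = fx_star(4),
    star6_w = fx_star(6, 0.3),
    cycle5 = fx_cycle(5),
    cycle8_w = fx_cycle(8, 0.7),
    path5 = fx_path(5),
    path8 = fx_path(8),
    two_triangles = fx_two_triangles(),
    two_triangles_w = fx_two_triangles(0.4),
    barbell = fx_barbell(),
    barbell_w = fx_barbell(0.6))
  for (s in 1:7)
    g[[sprintf("rand7_%d", s)]] <- fx_random(7, 0.5, 100 + s)
  for (s in 1:4)
    g[[sprintf("rand8_dense_%d", s)]] <- fx_random(8, 0.8, 200 + s)
  g$rand6_sparse <- fx_random(6, 0.3, 300)
  g$with_isolated <- {
    W <- fx_random(7, 0.6, 400)
    W[7, ] <- W[, 7] <- 0
    W
  }
  g
}
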