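# Independent brute-force oracles. Deliberately naive: explicit loops and
# exhaustive enumeration, sharing no code with the package internals.

oracle_spearman_graph <- function(X) {
  p <- ncol(X)
  R <- apply(X, 2, rank)  # average ties by default
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (sd(R[, i]) == 0 || sd(R[, j]) == 0) next
    r <- cor(R[, i], R[, j])
    W[i, j] <- W[j, i] <- max(0, r)
  }
  W
}

oracle_degree_strength <- function(W) {
  n <- nrow(W)
  k <- integer(n); s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j != i && W[i, j] > 0) {
      k[i] <- k[i] + 1
      s[i] <- s[i] + W[i, j]
    }
  }
  list(degree = k, strength = s)
}

# All-pairs shortest paths by exhaustive simple-path enumeration (n <= 8).
oracle_distances_enum <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n); diag(D) <- 0
  recurse <- function(node, target, visited, len) {
    if (node == target) {
      if (len < D[start, target]) D[start, target] <<- len
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && W[node, nxt] > 0)
        recurse(nxt, target, `[<-`(visited, nxt, TRUE), len + 1 / W[node, nxt])
    }
  }
  for (start in seq_len(n)) for (target in seq_len(n)) {
    if (start != target) recurse(start, target, `[<-`(rep(FALSE, n), start, TRUE), 0)
  }
  D
}

# Faster independent oracle: min-plus matrix closure (repeated relaxation).
oracle_distances_minplus <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf); diag(L) <- 0
  D <- L
  for (rep in seq_len(n)) {
    Dn <- D
    for (i in seq_len(n)) for (j in seq_len(n))
      Dn[i, j] <- min(D[i, j], min(D[i, ] + L[, j]))
    if (identical(Dn, D)) break
    D <- Dn
  }
  D
}

oracle_path_eff <- function(D) {
  n <- nrow(D)
  l <- numeric(n); E <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    fin <- d[is.finite(d)]
    l[i] <- if (length(fin)) mean(fin) else Inf
    E[i] <- sum(ifelse(is.finite(d), 1 / d, 0)) / (n - 1)
  }
  list(path_length = l, efficiency = E)
}

oracle_onnela <- function(W) {
  n <- nrow(W)
  wmax <- max(W)
  k <- oracle_degree_strength(W)$degree
  C <- numeric(n); num <- numeric(n)
  if (wmax > 0) {
    Wh <- (W / wmax)^(1 / 3)
    for (i in seq_len(n)) {
      s <- 0
      for (j in seq_len(n)) for (h in seq_len(n)) {
        if (i == j || i == h || j == h) next
        s <- s + Wh[i, j] * Wh[j, h] * Wh[h, i]
      }
      num[i] <- s
      if (k[i] >= 2) C[i] <- s / (k[i] * (k[i] - 1))
    }
  }
  den <- sum(k * (k - 1))
  list(C = C, transitivity = if (den > 0) sum(num) / den else 0)
}

oracle_local_eff <- function(W) {
  n <- nrow(W)
  E <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    S <- W[nb, nb, drop = FALSE]
    D <- oracle_distances_minplus(S)
    k <- length(nb)
    tot <- 0
    for (a in seq_len(k)) for (b in seq_len(k))
      if (a != b && is.finite(D[a, b])) tot <- tot + 1 / D[a, b]
    E[i] <- tot / (k * (k - 1))
  }
  E
}

oracle_assortativity <- function(W) {
  n <- nrow(W)
  k <- oracle_degree_strength(W)$degree
  a <- c(); b <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (W[i, j] > 0) {
      a <- c(a, k[i], k[j])
      b <- c(b, k[j], k[i])
    }
  }
  if (sd(a) == 0) return(NaN)
  cor(a, b)
}

oracle_modularity <- function(W, memb) {
  m <- sum(W) / 2
  if (m <= 0) return(0)
  s <- rowSums(W)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(W[idx, idx]) / 2 / m - (sum(s[idx]) / (2 * m))^2
  }
  q
}

# Enumerate all set partitions of 1..n (restricted-growth strings).
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    mx <- if (length(labels)) max(labels) else 0
    for (v in seq_len(mx + 1)) grow(c(labels, v))
  }
  grow(integer(0))
  out
}

oracle_best_partition <- function(W) {
  best_q <- -Inf; best <- NULL
  for (memb in all_partitions(nrow(W))) {
    q <- oracle_modularity(W, memb)
    if (q > best_q) {
      best_q <- q
      best <- memb
    }
  }
  list(membership = best, Q = best_q)
}

oracle_module_roles <- function(W, memb) {
  n <- nrow(W)
  z <- numeric(n); P <- numeric(n)
  kappa <- vapply(seq_len(n), function(i) sum(W[i, memb == memb[i]]), 0)
  for (m in unique(memb)) {
    idx <- which(memb == m)
    sdv <- sd(kappa[idx])
    if (length(idx) > 1 && !is.na(sdv) && sdv > 0)
      z[idx] <- (kappa[idx] - mean(kappa[idx])) / sdv
  }
  for (i in seq_len(n)) {
    s <- sum(W[i, ])
    if (s > 0) {
      frac2 <- vapply(unique(memb), function(m) (sum(W[i, memb == m]) / s)^2, 0)
      P[i] <- 1 - sum(frac2)
    }
  }
  list(z = z, P = P)
}

# Pass-by-pass synchronous filling recurrence, explicit loops.
oracle_fill <- function(vol, mask) {
  d <- dim(vol)
  out <- vol
  todo <- mask
  while (any(todo)) {
    upd_idx <- list(); upd_val <- c()
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
      if (!todo[x, y, z]) next
      vals <- c()
      for (del in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                       c(0, 0, -1), c(0, 0, 1))) {
        xx <- x + del[1]; yy <- y + del[2]; zz <- z + del[3]
        if (xx >= 1 && xx <= d[1] && yy >= 1 && yy <= d[2] &&
            zz >= 1 && zz <= d[3] && !todo[xx, yy, zz])
          vals <- c(vals, out[xx, yy, zz])
      }
      if (length(vals)) {
        upd_idx[[length(upd_idx) + 1]] <- c(x, y, z)
        # plain double-precision accumulation in neighbour order
        upd_val <- c(upd_val, Reduce(`+`, as.list(vals)) / length(vals))
      }
    }
    if (!length(upd_idx)) stop("stuck")
    for (k in seq_along(upd_idx)) {
      ii <- upd_idx[[k]]
      out[ii[1], ii[2], ii[3]] <- upd_val[k]
      todo[ii[1], ii[2], ii[3]] <- FALSE
    }
  }
  out
}

# Hand step-up BH discovery set.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  sig <- rep(FALSE, m)
  if (k > 0) sig[o[seq_len(k)]] <- TRUE
  sig
}
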