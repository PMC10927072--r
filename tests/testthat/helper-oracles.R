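# Independent oracle implementations used only by the tests. They share no
# code with the package internals.

# Dense brute-force DPT distance: full affinity matrix (no kNN
# sparsification), symmetric-conjugate eigendecomposition, explicit
# double-sum formula.
oracle_dpt <- function(X, k_bandwidth, m) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  # bandwidth = distance to the k-th neighbor (self excluded)
  sigma <- vapply(seq_len(n), function(i) sort(D[i, -i])[k_bandwidth],
                  numeric(1))
  W <- exp(-D^2 / outer(sigma, sigma))
  # affinities exist between distinct pairs only (with k = n - 1 the kNN
  # graph is complete), so the diagonal carries no edge
  diag(W) <- 0
  W <- (W + t(W)) / 2
  deg <- rowSums(W)
  S <- diag(1 / sqrt(deg)) %*% W %*% diag(1 / sqrt(deg))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  lam <- es$values
  psi <- diag(1 / sqrt(deg)) %*% es$vectors
  keep <- which(lam < 1 - 1e-10)
  use <- keep[seq_len(min(m, length(keep)))]
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      v <- (lam[use] / (1 - lam[use]))^2 * (psi[i, use] - psi[j, use])^2
      out[i, j] <- out[j, i] <- sqrt(sum(v))
    }
  }
  out
}

# Kruskal's minimum spanning tree on a dense distance matrix; returns the
# edge-weight multiset (sorted).
oracle_kruskal_mst <- function(D) {
  n <- nrow(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  weights <- numeric(0)
  for (e in ord) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      parent[ri] <- rj
      weights <- c(weights, D[i, j])
      if (length(weights) == n - 1) break
    }
  }
  sort(weights)
}

# Direct -sum(p log p) over an explicitly built equal-width histogram.
oracle_entropy <- function(values, n_bins = 10) {
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(0)
  edges <- lo + (hi - lo) * (0:n_bins) / n_bins
  counts <- numeric(n_bins)
  for (v in values) {
    b <- n_bins
    for (q in seq_len(n_bins))
      if (v >= edges[q] && (v < edges[q + 1] || q == n_bins)) { b <- q; break }
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Mutual-kNN component membership by explicit neighbor sets + union-find.
oracle_mutual_components <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  knn <- lapply(seq_len(n), function(i) {
    o <- order(D[i, ])
    o <- o[o != i]
    o[seq_len(k)]
  })
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in knn[[i]])
    if (i %in% knn[[j]]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  vapply(seq_len(n), find, integer(1))
}

rand_cloud <- function(n, d = 2, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

# Plain trapezoid rule, spelled out independently of the package helper.
trapezoid_probe <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (y[i] + y[i + 1]) / 2 * (x[i + 1] - x[i])
  s
}

# Replay the greedy nearest-unvisited walk and return the final position.
replay_walk_end <- function(centers, start, stop_percentile) {
  m <- nrow(centers)
  dmat <- as.matrix(dist(centers))
  thr <- quantile(dmat[upper.tri(dmat)], stop_percentile / 100, names = FALSE)
  visited <- start
  cur <- start
  repeat {
    cand <- setdiff(seq_len(m), visited)
    if (length(cand) == 0) break
    nxt <- cand[which.min(dmat[cur, cand])]
    if (dmat[cur, nxt] > thr) break
    visited <- c(visited, nxt)
    cur <- nxt
  }
  centers[cur, ]
}
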