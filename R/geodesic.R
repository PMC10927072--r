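#' Diffusion configuration
#'
#' Parameters for the diffusion-pseudotime (DPT) geodesic distance.
#' `n_graph_neighbors` controls the k-nearest-neighbor graph on which the
#' diffusion operator is built; `n_diffusion_components` is the number m of
#' leading non-stationary eigenpairs entering the distance;
#' `infinity_fill_factor` is the multiplier applied to the maximum finite
#' distance when substituting unreachable (disconnected) pairs.
#'
#' @param n_graph_neighbors Integer >= 2, neighborhood size of the kNN graph.
#' @param n_diffusion_components Integer >= 1, number of eigenpairs m.
#' @param infinity_fill_factor Positive multiplier for [finite_fill()].
#' @return A list of class `diffusion_config`.
#' @export
diffusion_config <- function(n_graph_neighbors = 15L,
                             n_diffusion_components = 10L,
                             infinity_fill_factor = 1.5) {
  assert_count(n_graph_neighbors, "n_graph_neighbors", min = 2L)
  assert_count(n_diffusion_components, "n_diffusion_components", min = 1L)
  if (!is.finite(infinity_fill_factor) || infinity_fill_factor <= 0)
    stop("`infinity_fill_factor` must be positive", call. = FALSE)
  structure(list(n_graph_neighbors = as.integer(n_graph_neighbors),
                 n_diffusion_components = as.integer(n_diffusion_components),
                 infinity_fill_factor = infinity_fill_factor),
            class = "diffusion_config")
}

#' Diffusion-pseudotime geodesic distance matrix
#'
#' Builds a symmetric k-nearest-neighbor graph on the point cloud
#' (Euclidean distances, ties broken by ascending point index), forms a
#' Gaussian-kernel affinity with adaptive bandwidth
#' `W_ij = exp(-d_ij^2 / (sigma_i * sigma_j))` where `sigma_i` is the
#' distance from point i to its `n_graph_neighbors`-th neighbor, symmetrizes
#' `W <- (W + t(W))/2`, row-normalizes to a diffusion transition operator,
#' and eigendecomposes it through its symmetric conjugate
#' `S = D^{-1/2} W D^{-1/2}`. With orthonormal eigenvectors v of S,
#' `psi = D^{-1/2} v` and the DPT distance is
#' \deqn{dpt(i,j) = \sqrt{\sum_{s=1}^{m} \left(\frac{\lambda_s}{1-\lambda_s}\right)^2
#'   (\psi_s(i) - \psi_s(j))^2}}
#' over the m leading non-stationary eigenpairs (eigenvalues below
#' 1 - 1e-10, in decreasing order). Pairs of points in different connected
#' components of the graph are unreachable and marked `NA`; use
#' [finite_fill()] before feeding the matrix to the scoring metrics.
#'
#' @param pc A [point_cloud()] with at least `n_graph_neighbors + 1` points.
#' @param cfg A [diffusion_config()].
#' @return A symmetric n x n matrix with zero diagonal; `NA` marks
#'   cross-component pairs.
#' @export
dpt_distance_matrix <- function(pc, cfg = diffusion_config()) {
  pc <- as_point_cloud(pc)
  n <- nrow(pc)
  if (n < 3L) stop("degenerate input: need at least 3 points", call. = FALSE)
  k <- cfg$n_graph_neighbors
  if (n < k + 1L)
    stop(sprintf("need at least n_graph_neighbors + 1 = %d points, got %d",
                 k + 1L, n), call. = FALSE)
  nn <- knn_index_dist(unclass(pc), k)
  sigma <- nn$dist[, k]
  if (any(sigma == 0)) {
    # coincident points collapse the bandwidth; fall back to the smallest
    # positive neighbor distance to keep the kernel defined
    pos <- nn$dist[nn$dist > 0]
    if (length(pos) == 0L)
      stop("degenerate input: all points coincide", call. = FALSE)
    sigma[sigma == 0] <- min(pos)
  }
  ii <- rep(seq_len(n), k)
  jj <- as.vector(nn$index)
  w <- exp(-as.vector(nn$dist)^2 / (sigma[ii] * sigma[jj]))
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  W <- (W + Matrix::t(W)) / 2

  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    W != 0, mode = "undirected"))$membership
  out <- matrix(NA_real_, n, n)
  for (c_id in unique(comp)) {
    idx <- which(comp == c_id)
    if (length(idx) == 1L) { out[idx, idx] <- 0; next }
    Z <- diffusion_coords(W[idx, idx, drop = FALSE],
                          m = cfg$n_diffusion_components)
    out[idx, idx] <- as.matrix(dist(Z))
  }
  diag(out) <- 0
  out
}

# Eigen-coordinates such that Euclidean distance between rows equals the DPT
# distance. W is the (symmetrized) affinity of a connected component.
diffusion_coords <- function(W, m) {
  nc <- nrow(W)
  deg <- Matrix::rowSums(W)
  inv_sqrt <- 1 / sqrt(deg)
  Dih <- Matrix::Diagonal(x = inv_sqrt)
  S <- Dih %*% W %*% Dih                 # D^{-1/2} W D^{-1/2}
  S <- (S + Matrix::t(S)) / 2
  n_want <- min(m + 2L, nc)
  if (nc <= 64L || n_want >= nc - 1L) {
    es <- eigen(as.matrix(S), symmetric = TRUE)
    lam <- es$values
    V <- es$vectors
  } else {
    es <- tryCatch(RSpectra::eigs_sym(S, k = n_want, which = "LA"),
                   error = function(e)
                     stop("numerical error: eigendecomposition failed (",
                          conditionMessage(e), ")", call. = FALSE))
    ord <- order(es$values, decreasing = TRUE)
    lam <- es$values[ord]
    V <- es$vectors[, ord, drop = FALSE]
  }
  # drop stationary (or numerically duplicated) eigenvalues to avoid the
  # lambda/(1-lambda) blow-up
  keep <- lam < 1 - 1e-10
  lam <- lam[keep]
  V <- V[, keep, drop = FALSE]
  use <- seq_len(min(m, length(lam)))
  psi <- V[, use, drop = FALSE] * inv_sqrt
  sweep(psi, 2L, lam[use] / (1 - lam[use]), `*`)
}

# k nearest neighbors with deterministic index tie-breaking. FNN's kd-tree
# does not guarantee an order among exactly tied distances and can return
# the query point itself when coordinates are duplicated, so a few extra
# neighbors are requested, self-matches dropped, and ties re-sorted by
# index; rows that still come up short (heavy duplication) are fixed by an
# exact scan.
knn_index_dist <- function(X, k) {
  n <- nrow(X)
  kk <- min(k + 10L, n - 1L)
  nn <- FNN::get.knn(X, k = kk, algorithm = "kd_tree")
  idx <- matrix(0L, n, k)
  dd <- matrix(0, n, k)
  for (i in seq_len(n)) {
    cand_i <- nn$nn.index[i, ]
    cand_d <- nn$nn.dist[i, ]
    keep <- cand_i != i
    cand_i <- cand_i[keep]
    cand_d <- cand_d[keep]
    if (length(cand_i) < k) {
      d_all <- sqrt(colSums((t(X) - X[i, ])^2))
      d_all[i] <- Inf
      o <- order(d_all)[seq_len(k)]
      idx[i, ] <- o
      dd[i, ] <- d_all[o]
    } else {
      o <- order(cand_d, cand_i)[seq_len(k)]
      idx[i, ] <- cand_i[o]
      dd[i, ] <- cand_d[o]
    }
  }
  list(index = idx, dist = dd)
}

#' Replace unreachable distances by a multiple of the maximum finite distance
#'
#' Non-finite entries of a geodesic distance matrix (pairs of points in
#' disconnected graph components) are substituted with `factor` times the
#' maximum finite entry, preserving symmetry and the zero diagonal.
#'
#' @param dm Square symmetric distance matrix, possibly containing `NA`/`Inf`.
#' @param factor Positive multiplier (default 1.5).
#' @return A fully finite distance matrix.
#' @export
finite_fill <- function(dm, factor = 1.5) {
  assert_distance_matrix(dm)
  bad <- !is.finite(dm)
  if (!any(bad)) return(dm)
  finite_off <- dm[is.finite(dm) & upper.tri(dm)]
  if (length(finite_off) == 0L)
    stop("degenerate input: no finite off-diagonal distances", call. = FALSE)
  dm[bad] <- factor * max(finite_off)
  diag(dm) <- 0
  dm
}
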