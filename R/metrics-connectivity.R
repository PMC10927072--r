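#' Configuration for the degrees-of-connectivity score
#'
#' @param fraction_grid Strictly increasing fractions of n used as
#'   neighborhood sizes; default 0.05, 0.10, ..., 0.95.
#' @return A list of class `connectivity_config`.
#' @export
connectivity_config <- function(fraction_grid = seq(0.05, 0.95, by = 0.05)) {
  if (length(fraction_grid) < 2L || any(!is.finite(fraction_grid)) ||
      any(fraction_grid <= 0) || any(fraction_grid >= 1) ||
      any(diff(fraction_grid) <= 0))
    stop("`fraction_grid` must be strictly increasing fractions in (0, 1)",
         call. = FALSE)
  structure(list(fraction_grid = as.numeric(fraction_grid)),
            class = "connectivity_config")
}

# Rank matrix R[i, j] = position of j among i's Euclidean nearest neighbors
# (self excluded, ties broken by ascending index). The mutual-kNN graph at
# any k has an edge (i, j) exactly when max(R[i,j], R[j,i]) <= k.
mutual_rank_matrix <- function(X) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  R <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    o <- order(D[i, ])            # stable: ties resolve by ascending index
    o <- o[o != i]
    R[i, o] <- seq_len(n - 1L)
  }
  pmax(R, t(R))
}

#' Median reachability on the mutual k-nearest-neighbor graph
#'
#' Builds the symmetric mutual kNN graph (an edge joins i and j only when
#' each point is among the other's k Euclidean nearest neighbors, self
#' excluded, distance ties broken by ascending index). Each point's
#' reachability is the fraction of *other* points in its connected
#' component, `(component size - 1) / (n - 1)`, so an isolated point scores
#' 0. Returns the median reachability over all points. Reachability is
#' non-decreasing in k because kNN sets are nested.
#'
#' @param pc A [point_cloud()].
#' @param k Neighborhood size, `1 <= k <= n - 1`.
#' @return Median reachability in `[0, 1]`.
#' @export
mutual_knn_reachability <- function(pc, k) {
  pc <- as_point_cloud(pc)
  n <- nrow(pc)
  assert_count(k, "k", min = 1L)
  if (k > n - 1L) stop("`k` must be at most n - 1", call. = FALSE)
  M <- mutual_rank_matrix(unclass(pc))
  adj <- M <= k
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  median((sizes - 1) / (n - 1))
}

#' Score 5: area under the mutual-kNN reachability curve
#'
#' For every fraction f in `cfg$fraction_grid` the neighborhood size is
#' `k = max(1, round(f * n))` and the median mutual-kNN reachability is
#' evaluated; the score is the trapezoidal area under the (f, reachability)
#' curve divided by the grid span, so it lies in `[0, 1]`. In cluster-like
#' data each point can only reach its own cluster until k exceeds the
#' cluster size, depressing the curve; along a trajectory even small
#' neighborhoods chain the whole dataset together.
#'
#' Internally the full sweep is computed once: connected components of the
#' mutual graph at threshold k coincide with those of the minimum spanning
#' tree of the mutual-rank "distances", so a single MST supports all grid
#' values.
#'
#' @param pc A [point_cloud()].
#' @param cfg A [connectivity_config()].
#' @return Scalar score in `[0, 1]`.
#' @export
score_connectivity <- function(pc, cfg = connectivity_config()) {
  pc <- as_point_cloud(pc)
  n <- nrow(pc)
  if (n < 3L) stop("degenerate input: need n >= 3", call. = FALSE)
  M <- mutual_rank_matrix(unclass(pc))
  mst <- prim_mst(M)
  ks <- pmax(1L, as.integer(round(cfg$fraction_grid * n)))
  ks <- pmin(ks, n - 1L)
  ord <- order(mst$weight)
  ei <- mst$from[ord]; ej <- mst$to[ord]; ew <- mst$weight[ord]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  medians <- numeric(length(ks))
  ptr <- 1L
  for (q in seq_along(ks)) {
    while (ptr <= length(ew) && ew[ptr] <= ks[q]) {
      ri <- find(ei[ptr]); rj <- find(ej[ptr])
      if (ri != rj) parent[ri] <- rj
      ptr <- ptr + 1L
    }
    roots <- vapply(seq_len(n), find, integer(1))
    sizes <- table(roots)[as.character(roots)]
    medians[q] <- median((as.integer(sizes) - 1) / (n - 1))
  }
  f <- cfg$fraction_grid
  trapz(f, medians) / (f[length(f)] - f[1L])
}

# Prim's algorithm on a dense symmetric weight matrix.
prim_mst <- function(M) {
  n <- nrow(M)
  in_tree <- rep(FALSE, n)
  in_tree[1L] <- TRUE
  key <- M[1L, ]
  key[1L] <- Inf
  parent <- rep(1L, n)
  from <- to <- integer(n - 1L)
  weight <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    kk <- key
    kk[in_tree] <- Inf
    u <- which.min(kk)
    in_tree[u] <- TRUE
    from[s] <- parent[u]; to[s] <- u; weight[s] <- key[u]
    upd <- !in_tree & M[u, ] < key
    parent[upd] <- u
    key[upd] <- M[u, upd]
  }
  list(from = from, to = to, weight = weight)
}
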