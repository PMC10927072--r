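#' Configuration for the vector-magnitude score
#'
#' @param kmeans_fraction Fraction of points used as the number of K-means
#'   centers (default 0.05, i.e. K = 5% of n, at least 2).
#' @param stop_percentile Percentile of the pairwise center distances used as
#'   the walk stop threshold (default 20).
#' @param n_repeats Number of K-means repeats averaged (default 5).
#' @param pca_dim Dimensionality the data is reduced to when its ambient
#'   dimension exceeds it (default 5).
#' @param norm_p Exponent of the p-norm applied to the summed walk vector.
#'   `NULL` (default) means the dimension of the space the walk runs in:
#'   `pca_dim` when PCA reduction occurred, the ambient dimension otherwise.
#' @return A list of class `vector_walk_config`.
#' @export
vector_walk_config <- function(kmeans_fraction = 0.05, stop_percentile = 20,
                               n_repeats = 5L, pca_dim = 5L, norm_p = NULL) {
  assert_fraction(kmeans_fraction, "kmeans_fraction")
  if (!is.finite(stop_percentile) || stop_percentile <= 0 || stop_percentile >= 100)
    stop("`stop_percentile` must lie in (0, 100)", call. = FALSE)
  assert_count(n_repeats, "n_repeats", min = 1L)
  assert_count(pca_dim, "pca_dim", min = 1L)
  if (!is.null(norm_p)) assert_count(norm_p, "norm_p", min = 1L)
  structure(list(kmeans_fraction = kmeans_fraction,
                 stop_percentile = stop_percentile,
                 n_repeats = as.integer(n_repeats),
                 pca_dim = as.integer(pca_dim),
                 norm_p = norm_p),
            class = "vector_walk_config")
}

#' Greedy nearest-center walk
#'
#' Starting from `centers[start_index, ]`, repeatedly steps to the nearest
#' (Euclidean) not-yet-visited center, accumulating the step vectors, and
#' stops when the nearest unvisited center is farther than the stop
#' threshold (the `stop_percentile`-th percentile of all pairwise center
#' distances) or all centers have been visited. Centers are never revisited
#' (two mutually nearest centers would otherwise oscillate forever); ties
#' are broken by ascending row index. The returned sum telescopes to
#' (final visited center - start center).
#'
#' @param centers m x d numeric matrix of cluster centers (m >= 2).
#' @param start_index Row index (1-based) of the starting center.
#' @param stop_percentile Percentile in (0, 100) defining the stop threshold.
#' @return A d-vector: the sum of all step vectors (zero if the walk never
#'   leaves the start).
#' @export
walk_vector_sum <- function(centers, start_index = 1L, stop_percentile = 20) {
  centers <- as.matrix(centers)
  m <- nrow(centers)
  if (m < 2L) stop("need at least 2 centers", call. = FALSE)
  if (start_index < 1L || start_index > m)
    stop("`start_index` out of range", call. = FALSE)
  dmat <- as.matrix(dist(centers))
  threshold <- quantile(upper_entries(dmat), stop_percentile / 100,
                        names = FALSE)
  visited <- rep(FALSE, m)
  cur <- as.integer(start_index)
  visited[cur] <- TRUE
  total <- numeric(ncol(centers))
  repeat {
    cand <- which(!visited)
    if (length(cand) == 0L) break
    d_to <- dmat[cur, cand]
    nxt <- cand[which.min(d_to)]       # which.min takes the first tie: index order
    if (dmat[cur, nxt] > threshold) break
    total <- total + (centers[nxt, ] - centers[cur, ])
    visited[nxt] <- TRUE
    cur <- nxt
  }
  total
}

#' Score 3: vector magnitude of a greedy walk over K-means centers
#'
#' The point cloud is PCA-reduced to `cfg$pca_dim` dimensions when its
#' ambient dimension is larger, then each dimension is min-max normalized to
#' `[0, 1]` (a zero-range dimension maps to 0). For each of `cfg$n_repeats`
#' repeats, K-means with `K = max(2, round(kmeans_fraction * n))` centers is
#' run, a start center is drawn uniformly at random, [walk_vector_sum()] is
#' executed, and the p-norm `(sum |x_i|^p)^(1/p)` of the summed vector is
#' taken with `p = cfg$norm_p` (defaulting to the dimension of the walked
#' space). The score is the mean over repeats. A trajectory drives the walk
#' consistently along its direction of progression, giving a large summed
#' vector; in cluster-like data the steps point in unrelated directions and
#' largely cancel.
#'
#' @param pc A [point_cloud()].
#' @param cfg A [vector_walk_config()].
#' @param seed Integer seed; each repeat uses a derived sub-seed.
#' @return Non-negative scalar score.
#' @export
score_vector_magnitude <- function(pc, cfg = vector_walk_config(), seed = 1L) {
  pc <- as_point_cloud(pc)
  n <- nrow(pc)
  if (n < 3L) stop("degenerate input: need n >= 3", call. = FALSE)
  X <- unclass(pc)
  if (ncol(X) > cfg$pca_dim)
    X <- prcomp(X, center = TRUE, scale. = FALSE)$x[, seq_len(cfg$pca_dim),
                                                    drop = FALSE]
  rng <- apply(X, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  X <- sweep(X, 2L, rng[1L, ], `-`)
  pos <- span > 0
  X[, pos] <- sweep(X[, pos, drop = FALSE], 2L, span[pos], `/`)
  X[, !pos] <- 0
  p <- if (is.null(cfg$norm_p)) ncol(X) else cfg$norm_p
  K <- max(2L, as.integer(round(cfg$kmeans_fraction * n)))
  K <- min(K, n - 1L)
  mags <- vapply(seq_len(cfg$n_repeats), function(r) {
    with_seed(derive_seed(seed, r), {
      km <- kmeans_safe(X, K)
      start <- sample.int(nrow(km$centers), 1L)
      v <- walk_vector_sum(km$centers, start, cfg$stop_percentile)
      sum(abs(v)^p)^(1 / p)
    })
  }, numeric(1))
  mean(mags)
}

# kmeans can fail when the random initial centers collide on duplicated
# points; retry with fresh starts before giving up.
kmeans_safe <- function(X, K, tries = 5L) {
  for (t in seq_len(tries)) {
    km <- tryCatch(
      suppressWarnings(kmeans(X, centers = K, iter.max = 100L, nstart = 1L)),
      error = function(e) NULL)
    if (!is.null(km) && nrow(unique(km$centers)) >= 2L) return(km)
  }
  stop("kmeans failed to produce at least 2 distinct centers", call. = FALSE)
}
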