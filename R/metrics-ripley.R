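#' Configuration for the geodesic Ripley's K score
#'
#' @param n_thresholds Number of equally spaced distance thresholds
#'   (default 100).
#' @param reference Shape of the uniform reference region; only
#'   `"bounding_box"` (the axis-aligned bounding box of the data) is
#'   implemented.
#' @return A list of class `ripley_config`.
#' @export
ripley_config <- function(n_thresholds = 100L, reference = "bounding_box") {
  assert_count(n_thresholds, "n_thresholds", min = 2L)
  reference <- match.arg(reference, "bounding_box")
  structure(list(n_thresholds = as.integer(n_thresholds),
                 reference = reference),
            class = "ripley_config")
}

#' Normalized Ripley's K curve of a distance matrix
#'
#' For each threshold t the raw statistic counts the ordered pairs i != j
#' with `d_ij < t`, divided by n; the curve is then normalized to `[0, 1]`
#' by its maximum over the grid (the density constant of the classical
#' Ripley's K cancels under this normalization). The result is
#' non-decreasing in t.
#'
#' @param dm Finite symmetric distance matrix.
#' @param thresholds Ascending numeric vector of distance thresholds.
#' @return Numeric vector in `[0, 1]`, same length as `thresholds`.
#' @export
ripley_curve <- function(dm, thresholds) {
  assert_distance_matrix(dm, finite = TRUE)
  if (is.unsorted(thresholds))
    stop("`thresholds` must be ascending", call. = FALSE)
  n <- nrow(dm)
  sorted <- sort(upper_entries(dm))
  # ordered pairs with d < t (strict): 2 * (# upper-triangle entries < t)
  raw <- 2 * findInterval(thresholds, sorted, left.open = TRUE) / n
  # left.open = TRUE makes the count strict for thresholds equal to a distance
  mx <- max(raw)
  if (mx == 0)
    stop("degenerate curve: no pair falls below any threshold", call. = FALSE)
  raw / mx
}

#' Score 4: geodesic Ripley's K contrast against a uniform reference
#'
#' A seeded uniform sample of the same size n is drawn inside the
#' axis-aligned bounding box of the point cloud. DPT geodesic distance
#' matrices are computed for the data and for the reference; each is
#' summarized by a normalized [ripley_curve()] over `n_thresholds` equally
#' spaced thresholds running from 0 to that matrix's own maximum. The score
#' is the trapezoidal area under the elementwise absolute difference of the
#' two curves, with the x-axis the normalized threshold index on `[0, 1]`,
#' hence itself in `[0, 1]`. Aggregated, cluster-like data departs strongly
#' from the uniform reference and scores high; trajectory-like data scores
#' lower.
#'
#' @param pc A [point_cloud()].
#' @param cfg A [ripley_config()].
#' @param seed Integer seed for the uniform reference sample.
#' @param diffusion A [diffusion_config()] used for both distance matrices.
#' @param dm Optional precomputed finite DPT distance matrix of `pc`
#'   (avoids recomputation inside [score_all()]).
#' @return Scalar score in `[0, 1]`.
#' @export
score_ripley <- function(pc, cfg = ripley_config(), seed = 1L,
                         diffusion = diffusion_config(), dm = NULL) {
  pc <- as_point_cloud(pc)
  n <- nrow(pc)
  if (n < 3L) stop("degenerate input: need n >= 3", call. = FALSE)
  if (is.null(dm))
    dm <- finite_fill(dpt_distance_matrix(pc, diffusion),
                      diffusion$infinity_fill_factor)
  ref <- with_seed(seed, uniform_reference(unclass(pc)))
  dm_ref <- finite_fill(dpt_distance_matrix(point_cloud(ref), diffusion),
                        diffusion$infinity_fill_factor)
  grid <- function(d) seq(0, max(d), length.out = cfg$n_thresholds)
  k_obs <- ripley_curve(dm, grid(dm))
  k_ref <- ripley_curve(dm_ref, grid(dm_ref))
  x <- seq(0, 1, length.out = cfg$n_thresholds)
  trapz(x, abs(k_obs - k_ref))
}

# Uniform sample in the axis-aligned bounding box of X (same n and d).
uniform_reference <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  n <- nrow(X)
  u <- matrix(runif(n * ncol(X)), n, ncol(X))
  sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`)
}
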