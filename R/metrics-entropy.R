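#' Histogram specification for the entropy-based scores
#'
#' @param n_bins Number of equal-width bins (default 10).
#' @return A list of class `histogram_spec`.
#' @export
histogram_spec <- function(n_bins = 10L) {
  assert_count(n_bins, "n_bins", min = 2L)
  structure(list(n_bins = as.integer(n_bins)), class = "histogram_spec")
}

#' Shannon entropy of an equal-width histogram
#'
#' Bins span `[min(values), max(values)]` with `spec$n_bins` equal-width
#' bins, right-open except the last bin which is closed. Bin counts are
#' normalized to sum to 1 and the natural-log entropy
#' `H = -sum(p * log(p))` is returned (with `0 * log(0) = 0`). If all values
#' coincide the histogram is a single spike and the entropy is 0.
#'
#' @param values Numeric vector, at least one finite value.
#' @param spec A [histogram_spec()].
#' @return Entropy in nats, in `[0, log(n_bins)]`.
#' @export
#' @examples
#' histogram_entropy(1:10)              # one value per bin: log(10)
#' histogram_entropy(c(0, 0, 1))        # p = (2/3, 1/3)
histogram_entropy <- function(values, spec = histogram_spec()) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("degenerate input: no values to histogram", call. = FALSE)
  if (!all(is.finite(values)))
    stop("values must be finite", call. = FALSE)
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) return(0)
  breaks <- seq(lo, hi, length.out = spec$n_bins + 1L)
  bin <- findInterval(values, breaks, rightmost.closed = TRUE)
  p <- tabulate(bin, nbins = spec$n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Score 1: entropy of the pairwise-distance distribution
#'
#' The entropy of the histogram of all n(n-1)/2 pairwise geodesic distances.
#' Cluster-like data gives a multimodal distance distribution (short
#' within-cluster, long between-cluster) and hence lower entropy than the
#' smooth unimodal distribution of a trajectory.
#'
#' @param dm Finite symmetric distance matrix (apply [finite_fill()] first).
#' @param spec A [histogram_spec()].
#' @return Entropy in nats.
#' @export
score_pdist <- function(dm, spec = histogram_spec()) {
  assert_distance_matrix(dm, finite = TRUE)
  if (nrow(dm) < 3L) stop("degenerate input: need n >= 3", call. = FALSE)
  histogram_entropy(upper_entries(dm), spec)
}
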