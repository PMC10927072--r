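#' Merge heights of 0-dimensional persistent homology
#'
#' In the Vietoris-Rips filtration of a finite metric space every point is
#' born a separate connected component at threshold 0 and components merge as
#' the threshold grows; the n-1 finite death values of the 0-dimensional
#' barcode (the one infinite bar is discarded) are exactly the single-linkage
#' dendrogram merge heights, equivalently the minimum-spanning-tree edge
#' weights of the distance graph. Computed here through single-linkage
#' agglomeration.
#'
#' @param dm Finite symmetric distance matrix.
#' @return Ascending numeric vector of n-1 merge heights.
#' @export
zero_dim_merge_heights <- function(dm) {
  assert_distance_matrix(dm, finite = TRUE)
  if (nrow(dm) < 2L) stop("degenerate input: need n >= 2", call. = FALSE)
  hc <- hclust(as.dist(dm), method = "single")
  sort(hc$height)
}

#' Score 2: log-entropy of persistent-homology merge heights
#'
#' Histogram entropy of the [zero_dim_merge_heights()] of the geodesic
#' distance matrix, passed through a natural log. In cluster-like data most
#' merges happen at tiny thresholds and a few (the between-cluster bridges)
#' at large ones, concentrating the histogram and lowering the entropy; a
#' trajectory merges at a more uniform spread of thresholds. The entropy is
#' floored at `eps` before the log so that degenerate inputs return a finite
#' sentinel (`log(eps)`) instead of `-Inf`.
#'
#' @param dm Finite symmetric distance matrix.
#' @param spec A [histogram_spec()].
#' @param eps Floor applied to the entropy before the log.
#' @return `log(max(H, eps))`.
#' @export
score_homology <- function(dm, spec = histogram_spec(), eps = 1e-12) {
  heights <- zero_dim_merge_heights(dm)
  h <- histogram_entropy(heights, spec)
  log(max(h, eps))
}
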