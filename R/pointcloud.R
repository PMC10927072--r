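#' Construct a point cloud
#'
#' A point cloud is the universal input to all scoring metrics: an n x d
#' numeric matrix of coordinates, one row per cell/point, with an optional
#' vector of point identifiers. All downstream metrics require n >= 3 and
#' finite coordinates.
#'
#' @param coords Numeric matrix (n x d), all entries finite.
#' @param point_ids Optional character vector of length n.
#' @return An object of class `point_cloud` (a numeric matrix with a
#'   `point_ids` attribute).
#' @export
#' @examples
#' pc <- point_cloud(matrix(rnorm(20), ncol = 2))
point_cloud <- function(coords, point_ids = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("point cloud coordinates must all be finite", call. = FALSE)
  if (!is.null(point_ids)) {
    point_ids <- as.character(point_ids)
    if (length(point_ids) != nrow(coords))
      stop("`point_ids` length must equal the number of rows", call. = FALSE)
  }
  dimnames(coords) <- NULL
  structure(coords, point_ids = point_ids, class = c("point_cloud", "matrix", "array"))
}

as_point_cloud <- function(x) {
  if (inherits(x, "point_cloud")) x else point_cloud(x)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("point cloud: %d points x %d dimensions\n", nrow(x), ncol(x)))
  invisible(x)
}

# Subsetting keeps ids aligned but drops the class when dimensions collapse.
#' @export
`[.point_cloud` <- function(x, i, j, ..., drop = FALSE) {
  ids <- attr(x, "point_ids")
  out <- unclass(x)[i, j, drop = drop]
  if (!is.matrix(out)) return(out)
  if (!is.null(ids)) ids <- if (missing(i)) ids else ids[i]
  point_cloud(out, point_ids = ids)
}

#' Read/write a point cloud as a delimited numeric table
#'
#' Point clouds are persisted as headerless delimited numeric tables (one row
#' per point). The delimiter is auto-detected (tab or comma) on read. An
#' optional id sidecar file (`<path>.ids`, one id per line) stores point
#' identifiers.
#'
#' @param path File path.
#' @param pc A [point_cloud()].
#' @param sep Field delimiter used when writing.
#' @return `read_point_cloud` returns a [point_cloud()]; `write_point_cloud`
#'   returns `path` invisibly.
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  m <- as.matrix(read.table(path, sep = sep, header = FALSE))
  ids <- NULL
  sidecar <- paste0(path, ".ids")
  if (file.exists(sidecar)) ids <- readLines(sidecar)
  point_cloud(m, point_ids = ids)
}

#' @rdname read_point_cloud
#' @export
write_point_cloud <- function(pc, path, sep = "\t") {
  pc <- as_point_cloud(pc)
  write.table(unclass(pc), path, sep = sep, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  ids <- attr(pc, "point_ids")
  if (!is.null(ids)) writeLines(ids, paste0(path, ".ids"))
  invisible(path)
}
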