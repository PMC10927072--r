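#' Bundle of all metric configurations
#'
#' Collects the per-metric configuration objects consumed by [score_all()].
#'
#' @param histogram A [histogram_spec()].
#' @param diffusion A [diffusion_config()].
#' @param walk A [vector_walk_config()].
#' @param ripley A [ripley_config()].
#' @param connectivity A [connectivity_config()].
#' @return A list of class `score_config`.
#' @export
score_config <- function(histogram = histogram_spec(),
                         diffusion = diffusion_config(),
                         walk = vector_walk_config(),
                         ripley = ripley_config(),
                         connectivity = connectivity_config()) {
  stopifnot(inherits(histogram, "histogram_spec"),
            inherits(diffusion, "diffusion_config"),
            inherits(walk, "vector_walk_config"),
            inherits(ripley, "ripley_config"),
            inherits(connectivity, "connectivity_config"))
  structure(list(histogram = histogram, diffusion = diffusion, walk = walk,
                 ripley = ripley, connectivity = connectivity),
            class = "score_config")
}

#' Compute all five clusterness/trajectoriness scores
#'
#' Computes the shared DPT geodesic distance matrix once (with unreachable
#' pairs substituted by [finite_fill()]) and evaluates the five metrics:
#' `pdist_entropy` ([score_pdist()]), `homology` ([score_homology()]),
#' `vector_magnitude` ([score_vector_magnitude()]), `ripley`
#' ([score_ripley()]) and `connectivity` ([score_connectivity()]). All
#' randomness (K-means restarts, walk start centers, the Ripley uniform
#' reference) is derived from `seed`, so the result is deterministic.
#'
#' When the point cloud is smaller than `n_graph_neighbors + 1`, the kNN
#' neighborhood is shrunk to `n - 1` so that small subsets remain scorable.
#'
#' @param pc A [point_cloud()] with n >= 3.
#' @param configs A [score_config()].
#' @param seed Integer seed.
#' @return A named numeric vector of class `score_vector` with entries
#'   `pdist_entropy`, `homology`, `vector_magnitude`, `ripley`,
#'   `connectivity`, and attributes `n` and `seed`.
#' @export
score_all <- function(pc, configs = score_config(), seed = 1L) {
  pc <- as_point_cloud(pc)
  n <- nrow(pc)
  if (n < 3L) stop("degenerate input: need n >= 3", call. = FALSE)
  diff_cfg <- configs$diffusion
  if (n < diff_cfg$n_graph_neighbors + 1L) {
    diff_cfg$n_graph_neighbors <- n - 1L
  }
  run <- function(metric, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("metric '%s' failed: %s", metric, conditionMessage(e)),
           call. = FALSE))
  }
  dm <- run("dpt", finite_fill(dpt_distance_matrix(pc, diff_cfg),
                               diff_cfg$infinity_fill_factor))
  out <- c(
    pdist_entropy = run("pdist_entropy", score_pdist(dm, configs$histogram)),
    homology = run("homology", score_homology(dm, configs$histogram)),
    vector_magnitude = run("vector_magnitude",
                           score_vector_magnitude(pc, configs$walk,
                                                  derive_seed(seed, 300L))),
    ripley = run("ripley", score_ripley(pc, configs$ripley,
                                        derive_seed(seed, 400L),
                                        diffusion = diff_cfg, dm = dm)),
    connectivity = run("connectivity",
                       score_connectivity(pc, configs$connectivity))
  )
  structure(out, n = n, seed = as.integer(seed),
            class = c("score_vector", "numeric"))
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("five-metric score vector (n = %d, seed = %d)\n",
              attr(x, "n"), attr(x, "seed")))
  print(round(unclass(x)[seq_len(5)], 4))
  invisible(x)
}

score_names <- c("pdist_entropy", "homology", "vector_magnitude",
                 "ripley", "connectivity")

#' Write/read score records as a delimited table
#'
#' One row per scored dataset: the five score columns plus `seed` and `n`.
#'
#' @param scores A `score_vector`, a list of them, or a matrix/data.frame
#'   with the five score columns.
#' @param path File path (tab-separated, with header).
#' @param ids Optional row identifiers.
#' @return `write_scores` returns `path` invisibly; `read_scores` returns a
#'   data.frame.
#' @export
write_scores <- function(scores, path, ids = NULL) {
  df <- as_score_frame(scores, ids)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  missing_cols <- setdiff(score_names, names(df))
  if (length(missing_cols))
    stop("score table ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

as_score_frame <- function(scores, ids = NULL) {
  if (inherits(scores, "score_vector")) scores <- list(scores)
  if (is.list(scores) && all(vapply(scores, inherits, TRUE, "score_vector"))) {
    df <- as.data.frame(do.call(rbind, lapply(scores, function(s)
      unclass(s)[score_names])))
    df$seed <- vapply(scores, attr, integer(1), "seed")
    df$n <- vapply(scores, attr, integer(1), "n")
  } else {
    df <- as.data.frame(scores)
    stopifnot(all(score_names %in% names(df)))
  }
  if (!is.null(ids)) df <- cbind(id = ids, df)
  df
}
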