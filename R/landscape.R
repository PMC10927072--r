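#' Build the clusterness/trajectoriness geometric landscape
#'
#' Scores every simulated dataset with [score_all()], z-standardizes each of
#' the five score columns (they live on very different scales, so
#' unstandardized Euclidean distances would be dominated by a single
#' metric), and fits a 2-D UMAP embedding of the standardized scores
#' (Euclidean metric, 30 neighbors, minimum distance 0.6). The fitted UMAP
#' model is retained so new score vectors can be projected out-of-sample
#' with [project_scores()] and classified with [classify_dataset()].
#'
#' @param sims List of `sim_dataset` objects (>= 40, all four types
#'   present), e.g. from [sim_batch()].
#' @param seed Integer seed controlling both the per-dataset scoring
#'   sub-seeds and the UMAP optimization.
#' @param knn_k Number of embedded neighbors used by [classify_dataset()].
#' @param configs A [score_config()] used for all scoring.
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @param standardize Set to `FALSE` to embed the raw score columns.
#' @return A `landscape` object: score matrix, type labels, per-column
#'   standardization parameters, the N x 2 embedding, and the fitted UMAP
#'   model.
#' @export
build_landscape <- function(sims, seed = 1L, knn_k = 15L,
                            configs = score_config(),
                            n_neighbors = 30L, min_dist = 0.6,
                            standardize = TRUE) {
  if (length(sims) < 40L)
    stop("need at least 40 simulated datasets", call. = FALSE)
  labels <- vapply(sims, function(s) s$sim_type, character(1))
  if (!all(sim_types %in% labels))
    stop("all four simulation types must be present", call. = FALSE)
  assert_count(knn_k, "knn_k", min = 1L)
  scores <- matrix(NA_real_, length(sims), 5L,
                   dimnames = list(NULL, score_names))
  for (i in seq_along(sims)) {
    sv <- tryCatch(score_all(sims[[i]]$points, configs,
                             seed = derive_seed(seed, i)),
                   error = function(e)
                     stop(sprintf("scoring failed for sim %d (type %s, seed %d): %s",
                                  i, sims[[i]]$sim_type, sims[[i]]$seed,
                                  conditionMessage(e)), call. = FALSE))
    scores[i, ] <- unclass(sv)[score_names]
  }
  std <- standardize_fit(scores, enabled = standardize)
  Z <- standardize_apply(std, scores)
  umap_seed <- derive_seed(seed, 990L)
  model <- uwot::umap(Z, n_neighbors = n_neighbors, min_dist = min_dist,
                      metric = "euclidean", ret_model = TRUE,
                      seed = umap_seed, n_threads = 1, verbose = FALSE)
  emb <- matrix(as.numeric(model$embedding), nrow(model$embedding), 2L)
  structure(list(scores = scores, labels = labels, standardization = std,
                 embedding = emb, model = model,
                 knn_k = as.integer(knn_k), seed = as.integer(seed),
                 umap = list(n_neighbors = n_neighbors, min_dist = min_dist)),
            class = "landscape")
}

standardize_fit <- function(scores, enabled = TRUE) {
  if (!enabled)
    return(list(center = rep(0, ncol(scores)), scale = rep(1, ncol(scores)),
                enabled = FALSE))
  ctr <- colMeans(scores)
  scl <- apply(scores, 2L, sd)
  if (any(!is.finite(scl)) || any(scl == 0))
    stop("degenerate scores: a score column has zero variance", call. = FALSE)
  list(center = ctr, scale = scl, enabled = TRUE)
}

standardize_apply <- function(std, scores) {
  sweep(sweep(scores, 2L, std$center, `-`), 2L, std$scale, `/`)
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("geometric landscape: %d simulated datasets (%s)\n",
              nrow(x$scores),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            table(x$labels)), collapse = ", ")))
  invisible(x)
}

as_score_row <- function(sv) {
  if (inherits(sv, "score_vector")) sv <- unclass(sv)
  if (is.list(sv)) sv <- unlist(sv)
  if (is.null(names(sv))) {
    if (length(sv) != 5L) stop("score vector must have 5 entries", call. = FALSE)
    names(sv) <- score_names
  }
  matrix(as.numeric(sv[score_names]), 1L, 5L,
         dimnames = list(NULL, score_names))
}

#' Project a score vector onto the landscape embedding
#'
#' Applies the stored column standardization and the stored UMAP model's
#' out-of-sample transform. The transform is re-seeded from the landscape
#' seed on every call, so projection of a frozen landscape is deterministic.
#'
#' @param ls A fitted `landscape`.
#' @param sv A `score_vector` (or named numeric with the five score names).
#' @return Numeric 2-vector of embedding coordinates.
#' @export
project_scores <- function(ls, sv) {
  if (!inherits(ls, "landscape") || is.null(ls$model))
    stop("state error: landscape is not fitted (no stored UMAP model); ",
         "rebuild with build_landscape()", call. = FALSE)
  z <- standardize_apply(ls$standardization, as_score_row(sv))
  coords <- uwot::umap_transform(z, ls$model, n_threads = 1,
                                 seed = derive_seed(ls$seed, 991L),
                                 verbose = FALSE)
  as.numeric(coords[1L, ])
}

#' Classify a dataset as cluster-like or trajectory-like
#'
#' Projects the score vector onto the landscape with [project_scores()] and
#' inspects its `ls$knn_k` nearest embedded simulated datasets (Euclidean
#' distance in the 2-D embedding, ties broken by index).
#' `trajectory_neighbor_fraction` is the fraction of those neighbors whose
#' type is `clear_trajectory` or `noisy_trajectory`; the label is
#' `trajectory_like` when that fraction exceeds 0.5 and `cluster_like`
#' otherwise (an exact 0.5 tie counts as cluster-like).
#'
#' @inheritParams project_scores
#' @return A list of class `classification` with `label`,
#'   `trajectory_neighbor_fraction` and `embedding_coords`.
#' @export
classify_dataset <- function(ls, sv) {
  coords <- project_scores(ls, sv)
  d2 <- (ls$embedding[, 1L] - coords[1L])^2 + (ls$embedding[, 2L] - coords[2L])^2
  nn <- order(d2)[seq_len(min(ls$knn_k, nrow(ls$embedding)))]
  frac <- mean(ls$labels[nn] %in% c("clear_trajectory", "noisy_trajectory"))
  structure(list(label = if (frac > 0.5) "trajectory_like" else "cluster_like",
                 trajectory_neighbor_fraction = frac,
                 embedding_coords = coords),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("%s (trajectory neighbor fraction %.2f)\n",
              x$label, x$trajectory_neighbor_fraction))
  invisible(x)
}

#' Score and classify labeled subsets of a point cloud
#'
#' Treats each labeled subset (e.g. each cluster found by a clustering
#' algorithm) as an independent dataset: subsets with at least `min_size`
#' points are scored with [score_all()] and, when a landscape is supplied,
#' classified with [classify_dataset()]; smaller subsets are reported as
#' skipped with a warning, not errored.
#'
#' @param pc A [point_cloud()].
#' @param labels Subset id per point (length `nrow(pc)`).
#' @param ls A fitted `landscape`, or `NULL` to skip classification.
#' @param seed Integer seed; each subset gets a derived sub-seed.
#' @param configs A [score_config()].
#' @param min_size Minimum subset size (default 10).
#' @return A list with one entry per non-skipped subset: `id`, `n`,
#'   `scores` (a `score_vector`) and `classification` (or `NULL`). Skipped
#'   subset ids are in the `skipped` attribute.
#' @export
score_subsets <- function(pc, labels, ls = NULL, seed = 1L,
                          configs = score_config(), min_size = 10L) {
  pc <- as_point_cloud(pc)
  if (length(labels) != nrow(pc))
    stop("`labels` must have one entry per point", call. = FALSE)
  ids <- unique(labels)
  out <- list()
  skipped <- character(0)
  for (j in seq_along(ids)) {
    sel <- which(labels == ids[j])
    if (length(sel) < min_size) {
      warning(sprintf("subset '%s' has %d < %d points; skipped",
                      as.character(ids[j]), length(sel), min_size),
              call. = FALSE)
      skipped <- c(skipped, as.character(ids[j]))
      next
    }
    sub <- pc[sel, , drop = FALSE]
    sv <- score_all(sub, configs, seed = derive_seed(seed, j))
    out[[length(out) + 1L]] <- list(
      id = ids[j], n = length(sel), scores = sv,
      classification = if (!is.null(ls)) classify_dataset(ls, sv) else NULL)
  }
  if (length(out) == 0L)
    stop("degenerate input: every subset is below the size floor", call. = FALSE)
  structure(out, skipped = skipped)
}

#' Persist / restore a landscape
#'
#' The landscape is written as a directory: the score table with type
#' labels (`scores.tsv`), the standardization parameters and metadata
#' (`landscape.json`), the 2-D embedding (`embedding.tsv`), and the fitted
#' UMAP model (`umap_model`, a binary artifact produced by
#' [uwot::save_uwot()]).
#'
#' @param ls A `landscape`.
#' @param dir Directory path (created if needed).
#' @return `save_landscape` returns `dir` invisibly; `load_landscape`
#'   returns a `landscape`.
#' @export
save_landscape <- function(ls, dir) {
  stopifnot(inherits(ls, "landscape"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- as.data.frame(ls$scores)
  df$label <- ls$labels
  write.table(df, file.path(dir, "scores.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(ls$embedding, file.path(dir, "embedding.tsv"), sep = "\t",
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(standardization = ls$standardization, knn_k = ls$knn_k,
               seed = ls$seed, umap = ls$umap)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "landscape.json"))
  uwot::save_uwot(ls$model, file.path(dir, "umap_model"))
  invisible(dir)
}

#' @rdname save_landscape
#' @export
load_landscape <- function(dir) {
  need <- c("scores.tsv", "embedding.tsv", "landscape.json", "umap_model")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing landscape file: ", file.path(dir, f), call. = FALSE)
  df <- read.table(file.path(dir, "scores.tsv"), sep = "\t", header = TRUE)
  emb <- as.matrix(read.table(file.path(dir, "embedding.tsv"), sep = "\t"))
  meta <- jsonlite::fromJSON(file.path(dir, "landscape.json"))
  model <- uwot::load_uwot(file.path(dir, "umap_model"))
  structure(list(scores = as.matrix(df[, score_names]), labels = df$label,
                 standardization = meta$standardization,
                 embedding = unname(emb), model = model,
                 knn_k = as.integer(meta$knn_k),
                 seed = as.integer(meta$seed), umap = meta$umap),
            class = "landscape")
}
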