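# A single modest landscape shared by the tests in this file (scoring ~60
# sims dominates the cost, so build it once).
local_landscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sims <- sim_batch(15, master_seed = 301)
      cache <<- build_landscape(sims, seed = 77)
    }
    cache
  }
})

test_that("build_landscape produces a finite embedding with stored standardization", {
  ls <- local_landscape()
  expect_s3_class(ls, "landscape")
  expect_equal(dim(ls$embedding), c(60L, 2L))
  expect_true(all(is.finite(ls$embedding)))
  expect_equal(dim(ls$scores), c(60L, 5L))
  expect_length(ls$standardization$scale, 5L)
  expect_true(all(ls$standardization$scale > 0))
  # standardization parameters are a deterministic function of the scores
  z <- (ls$scores - matrix(ls$standardization$center, 60, 5, byrow = TRUE)) /
    matrix(ls$standardization$scale, 60, 5, byrow = TRUE)
  expect_equal(colMeans(z), rep(0, 5), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(apply(z, 2, sd), rep(1, 5), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("build_landscape enforces its preconditions", {
  sims <- sim_batch(15, master_seed = 301)
  expect_error(build_landscape(sims[1:20]), "at least 40")
  only_two <- sims[vapply(sims, function(s)
    s$sim_type %in% c("clear_clusters", "clear_trajectory"), logical(1))]
  expect_error(build_landscape(rep(only_two, 2)), "four")
})

test_that("projection of a training score vector lands near its embedded point", {
  ls <- local_landscape()
  hits <- 0L
  for (i in c(4, 23, 42, 55)) {
    sv <- setNames(ls$scores[i, ], colnames(ls$scores))
    xy <- project_scores(ls, sv)
    expect_true(all(is.finite(xy)))
    d <- sqrt(rowSums((ls$embedding - matrix(xy, 60, 2, byrow = TRUE))^2))
    if (rank(d, ties.method = "first")[i] <= 30) hits <- hits + 1L
    # projection is deterministic for a frozen landscape
    expect_identical(xy, project_scores(ls, sv))
  }
  expect_gte(hits, 3L)
})

test_that("an all-median score vector projects inside the inflated embedding envelope", {
  ls <- local_landscape()
  sv <- setNames(apply(ls$scores, 2, median), colnames(ls$scores))
  xy <- project_scores(ls, sv)
  lo <- apply(ls$embedding, 2, min)
  hi <- apply(ls$embedding, 2, max)
  pad <- 0.5 * (hi - lo)
  expect_true(all(xy >= lo - pad & xy <= hi + pad))
})

test_that("classification labels follow the trajectory-neighbor fraction with ties to cluster_like", {
  ls <- local_landscape()
  sv_c <- score_all(sim_clusters(seed = 9001)$points, seed = 5)
  sv_t <- score_all(sim_trajectory(seed = 9002)$points, seed = 5)
  cl_c <- classify_dataset(ls, sv_c)
  cl_t <- classify_dataset(ls, sv_t)
  expect_equal(cl_c$label, "cluster_like")
  expect_equal(cl_t$label, "trajectory_like")
  for (cl in list(cl_c, cl_t)) {
    expect_true(cl$trajectory_neighbor_fraction %in% ((0:15) / 15))
    expect_equal(cl$label,
                 if (cl$trajectory_neighbor_fraction > 0.5) "trajectory_like"
                 else "cluster_like")
  }
})

test_that("landscapes survive a save/load round-trip with identical classification", {
  ls <- local_landscape()
  dir <- file.path(withr::local_tempdir(), "ls")
  save_landscape(ls, dir)
  back <- load_landscape(dir)
  expect_equal(back$scores, ls$scores)
  expect_equal(back$embedding, ls$embedding, tolerance = 1e-12)
  expect_equal(back$labels, ls$labels)
  probe <- setNames(apply(ls$scores, 2, median), colnames(ls$scores))
  a <- classify_dataset(ls, probe)
  b <- classify_dataset(back, probe)
  expect_equal(a$label, b$label)
  expect_equal(a$trajectory_neighbor_fraction, b$trajectory_neighbor_fraction)
  expect_error(load_landscape(file.path(dir, "nope")), "missing landscape file")
})

test_that("score_subsets scores each labeled subset independently and skips small ones", {
  s <- sim_clusters(sim_config(n_clusters_range = c(3L, 3L)), seed = 41)
  pc <- s$points
  labels <- s$params$component
  res <- score_subsets(pc, labels, ls = NULL, seed = 2)
  expect_length(res, 3L)
  expect_equal(vapply(res, function(r) r$n, numeric(1)),
               as.numeric(s$params$counts))
  # single label: result equals score_all on the full cloud
  one <- score_subsets(pc, rep("all", nrow(pc)), ls = NULL, seed = 2)
  expect_length(one, 1L)
  expect_equal(unclass(one[[1]]$scores),
               unclass(score_all(pc, seed = clustraj:::derive_seed(2, 1))))
  # tiny subsets are skipped with a warning, not an error
  expect_warning(res2 <- score_subsets(pc, c(rep("tiny", 4), labels[-(1:4)]),
                                       ls = NULL, seed = 2), "skipped")
  expect_equal(attr(res2, "skipped"), "tiny")
  expect_error(suppressWarnings(score_subsets(pc[1:5, ], rep(1:5), ls = NULL)),
               "degenerate")
})
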