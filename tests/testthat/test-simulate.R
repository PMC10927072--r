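test_that("simulated datasets are 2-D, inside the size range, and byte-identical under a fixed seed", {
  cfg <- sim_config()
  for (gen in list(sim_clusters, sim_trajectory)) {
    for (noisy in c(FALSE, TRUE)) {
      a <- gen(cfg, noisy = noisy, seed = 77)
      b <- gen(cfg, noisy = noisy, seed = 77)
      expect_identical(unclass(a$points), unclass(b$points))
      expect_equal(ncol(a$points), 2L)
      expect_gte(nrow(a$points), cfg$n_points_range[1])
      expect_lte(nrow(a$points), cfg$n_points_range[2])
    }
  }
})

test_that("mixture draws conserve counts, proportions and the separation ratio", {
  for (seed in 1:20) {
    s <- sim_clusters(noisy = FALSE, seed = seed)
    p <- s$params
    expect_equal(sum(p$proportions), 1)
    expect_equal(sum(p$counts), p$n)
    expect_equal(length(p$component), p$n)
    if (p$n_components > 1) {
      ratio <- min(dist(p$means)) / max(p$sds)
      expect_gte(ratio, sim_config()$clear_separation_ratio - 1e-9)
    }
  }
})

test_that("clear-mode points stay within 4 component standard deviations", {
  hits <- 0L
  total <- 0L
  for (seed in 1:100) {
    s <- sim_clusters(noisy = FALSE, seed = seed)
    p <- s$params
    dev <- sqrt(rowSums((unclass(s$points) - p$means[p$component, , drop = FALSE])^2))
    hits <- hits + sum(dev <= 4 * p$sds[p$component])
    total <- total + p$n
  }
  expect_gte(hits / total, 0.999)
})

test_that("trajectory residuals recover the drawn noise level and zero noise is exact", {
  rel_err <- vapply(1:100, function(seed) {
    s <- sim_trajectory(noisy = FALSE, seed = seed)
    res <- unclass(s$points) - s$params$clean_points
    sd_hat <- sqrt(mean(res^2))
    abs(sd_hat - s$params$noise_sd) / s$params$noise_sd
  }, numeric(1))
  expect_lt(median(rel_err), 0.2)

  cfg0 <- sim_config(trajectory_noise_clear = 1e-12)
  s0 <- sim_trajectory(cfg0, noisy = FALSE, seed = 5)
  expect_lt(max(abs(unclass(s0$points) - s0$params$clean_points)), 1e-9)
})

test_that("bifurcations are recorded and both branches carry at least 10% of points", {
  n_bif <- 0L
  for (seed in 1:40) {
    s <- sim_trajectory(noisy = TRUE, seed = seed)
    p <- s$params
    expect_true(is.logical(p$bifurcated))
    if (p$bifurcated) {
      n_bif <- n_bif + 1L
      expect_gte(mean(p$branch == 2L), 0.10)
      expect_gte(mean(p$branch == 1L & p$arc_position > p$branch_point), 0.095)
    }
  }
  expect_gt(n_bif, 5)   # prob 0.5 over 40 draws
})

test_that("toggling noisy changes dispersion but not means or curve parameters", {
  for (seed in c(3, 14, 15)) {
    cc <- sim_clusters(noisy = FALSE, seed = seed)
    cn <- sim_clusters(noisy = TRUE, seed = seed)
    expect_identical(cc$params$means, cn$params$means)
    expect_identical(cc$params$counts, cn$params$counts)
    expect_true(all(cn$params$sds > cc$params$sds))
    tc <- sim_trajectory(noisy = FALSE, seed = seed)
    tn <- sim_trajectory(noisy = TRUE, seed = seed)
    for (f in c("amplitude", "frequency", "phase", "rotation"))
      expect_identical(tc$params[[f]], tn$params[[f]])
    expect_identical(tc$params$arc_position, tn$params$arc_position)
    expect_gt(tn$params$noise_sd, tc$params$noise_sd)
  }
})

test_that("sim_batch balances types exactly and is reproducible", {
  b1 <- sim_batch(5, master_seed = 9)
  b2 <- sim_batch(5, master_seed = 9)
  expect_length(b1, 20)
  types <- vapply(b1, function(s) s$sim_type, character(1))
  expect_equal(unname(table(types)[c("clear_clusters", "clear_trajectory",
                                     "noisy_clusters", "noisy_trajectory")]),
               array(rep(5L, 4)), ignore_attr = TRUE)
  expect_identical(lapply(b1, function(s) unclass(s$points)),
                   lapply(b2, function(s) unclass(s$points)))
  seeds <- vapply(b1, function(s) s$seed, integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
})
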