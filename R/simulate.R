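#' Simulation configuration
#'
#' Parameter ranges for the four types of 2-D benchmark datasets. Defaults
#' give datasets of 200-1000 points; cluster-like data draws 2-8 isotropic
#' Gaussian components whose minimum mean separation divided by the largest
#' component standard deviation equals the separation ratio (8 for clear
#' data — the closest pair of components sits ~4+4 standard deviations
#' apart, so clusters are visually disjoint — and drawn from 2-4 for noisy
#' data); trajectory-like data samples a sine
#' curve with Gaussian noise of 5% of the amplitude (clear) or 20-50%
#' (noisy), with half of the noisy trajectories bifurcating into two
#' branches.
#'
#' @param n_points_range Integer interval for the number of points.
#' @param n_clusters_range Integer interval for the number of Gaussian
#'   components.
#' @param clear_separation_ratio Separation ratio used in clear mode.
#' @param noisy_separation_ratio Interval the noisy-mode separation ratio is
#'   drawn from.
#' @param trajectory_noise_clear Noise standard deviation as a fraction of
#'   the sine amplitude in clear mode.
#' @param trajectory_noise_noisy Interval the noisy-mode noise fraction is
#'   drawn from.
#' @param bifurcation_prob Probability that a noisy trajectory bifurcates.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_points_range = c(200L, 1000L),
                       n_clusters_range = c(2L, 8L),
                       clear_separation_ratio = 8,
                       noisy_separation_ratio = c(2, 4),
                       trajectory_noise_clear = 0.05,
                       trajectory_noise_noisy = c(0.2, 0.5),
                       bifurcation_prob = 0.5) {
  stopifnot(length(n_points_range) == 2L, n_points_range[1] >= 3,
            diff(n_points_range) >= 0,
            length(n_clusters_range) == 2L, n_clusters_range[1] >= 1,
            diff(n_clusters_range) >= 0,
            clear_separation_ratio > 0,
            length(noisy_separation_ratio) == 2L,
            all(noisy_separation_ratio > 0),
            trajectory_noise_clear > 0,
            length(trajectory_noise_noisy) == 2L,
            all(trajectory_noise_noisy > 0))
  assert_fraction(bifurcation_prob, "bifurcation_prob", open = FALSE)
  structure(list(n_points_range = as.integer(n_points_range),
                 n_clusters_range = as.integer(n_clusters_range),
                 clear_separation_ratio = clear_separation_ratio,
                 noisy_separation_ratio = noisy_separation_ratio,
                 trajectory_noise_clear = trajectory_noise_clear,
                 trajectory_noise_noisy = trajectory_noise_noisy,
                 bifurcation_prob = bifurcation_prob),
            class = "sim_config")
}

sim_types <- c("clear_clusters", "clear_trajectory",
               "noisy_clusters", "noisy_trajectory")

new_sim_dataset <- function(points, sim_type, seed, params) {
  structure(list(points = points, sim_type = sim_type,
                 seed = as.integer(seed), params = params),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("simulated dataset: %s, n = %d, seed = %d\n",
              x$sim_type, nrow(x$points), x$seed))
  invisible(x)
}

#' Simulate a cluster-like 2-D dataset
#'
#' Samples a Gaussian mixture: the number of points and components are drawn
#' from their configured ranges, component means are placed sequentially in
#' the \eqn{[0,10]^2} square under a minimum-separation constraint
#' (dart-throwing with bounded retries), mixing proportions come from a flat
#' simplex draw, and each component is isotropic Gaussian. Component
#' standard deviations are scaled so that (minimum pairwise mean separation)
#' / (largest standard deviation) equals the separation ratio of the
#' requested noise level: 6 in clear mode, drawn from
#' `cfg$noisy_separation_ratio` in noisy mode. Holding the seed fixed and
#' toggling `noisy` therefore changes only the dispersion, never the means
#' or the per-point standard draws.
#'
#' @param cfg A [sim_config()].
#' @param noisy Logical: noisy (overlapping) or clear (well-separated) mode.
#' @param seed Integer seed; the draw is fully deterministic given it.
#' @return A `sim_dataset`: a 2-D [point_cloud()] plus the type label, the
#'   seed and the drawn generation parameters (including the per-point
#'   component assignment in `params$component`).
#' @export
sim_clusters <- function(cfg = sim_config(), noisy = FALSE, seed = 1L) {
  with_seed(seed, {
    n <- sample_range(cfg$n_points_range)
    ncomp <- sample_range(cfg$n_clusters_range)
    target_sep <- runif(1, 3, 5)
    means <- place_means(ncomp, box = 10, min_sep = target_sep)
    min_sep <- if (ncomp > 1) min(dist(means)) else 10
    ratio_noisy <- runif(1, cfg$noisy_separation_ratio[1],
                         cfg$noisy_separation_ratio[2])
    ratio <- if (noisy) ratio_noisy else cfg$clear_separation_ratio
    sd_scale <- runif(ncomp, 0.5, 1)
    sds <- (min_sep / ratio) * sd_scale
    props <- rexp(ncomp)
    props <- props / sum(props)
    counts <- as.vector(rmultinom(1, n, props))
    z <- matrix(rnorm(2 * n), n, 2)
    comp_of <- rep(seq_len(ncomp), counts)
    pts <- z * sds[comp_of] + means[comp_of, , drop = FALSE]
    new_sim_dataset(point_cloud(pts),
                    sim_type = if (noisy) "noisy_clusters" else "clear_clusters",
                    seed = seed,
                    params = list(n = n, n_components = ncomp, means = means,
                                  sds = sds, proportions = props,
                                  counts = counts, separation_ratio = ratio,
                                  min_mean_separation = min_sep,
                                  component = comp_of))
  })
}

sample_range <- function(r) {
  if (r[1] == r[2]) r[1] else r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
}

# Sequential dart-throwing placement of component means with a minimum
# separation; the separation target shrinks by 10% after each full restart.
place_means <- function(ncomp, box, min_sep, tries_per_mean = 200L,
                        restarts = 20L) {
  for (r in seq_len(restarts)) {
    means <- matrix(NA_real_, ncomp, 2)
    means[1, ] <- runif(2, 0, box)
    ok <- TRUE
    for (i in seq_len(ncomp)[-1]) {
      placed <- FALSE
      for (t in seq_len(tries_per_mean)) {
        cand <- runif(2, 0, box)
        d <- sqrt(colSums((t(means[seq_len(i - 1), , drop = FALSE]) - cand)^2))
        if (all(d >= min_sep)) {
          means[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(means)
    min_sep <- min_sep * 0.9
  }
  stop("generation error: could not place component means with the requested separation",
       call. = FALSE)
}

#' Simulate a trajectory-like 2-D dataset
#'
#' Samples arc positions uniformly along one period-window of a sine curve
#' with random amplitude, frequency and phase, adds isotropic Gaussian noise
#' whose standard deviation is a fraction of the amplitude (5% in clear
#' mode; drawn from `cfg$trajectory_noise_noisy` in noisy mode), and applies
#' a random planar rotation. In noisy mode, with probability
#' `cfg$bifurcation_prob` the trajectory bifurcates: a branch point is
#' placed at a random quantile (20-80%) of the arc positions, and half of
#' the points beyond it follow a second sine branch that re-draws amplitude,
#' frequency and phase while staying continuous at the branch point. Holding
#' the seed fixed and toggling `noisy` changes the noise level (and the
#' presence of a bifurcation) but not the curve parameters or arc positions.
#'
#' @inheritParams sim_clusters
#' @return A `sim_dataset`; `params` records the curve parameters, the
#'   noiseless positions, the arc position `t` of every point and (when
#'   bifurcated) the branch assignment.
#' @export
sim_trajectory <- function(cfg = sim_config(), noisy = FALSE, seed = 1L) {
  with_seed(seed, {
    n <- sample_range(cfg$n_points_range)
    amp <- runif(1, 1, 3)
    freq <- runif(1, 0.5, 1.5)
    phase <- runif(1, 0, 2 * pi)
    theta <- runif(1, 0, 2 * pi)
    tt <- runif(n, 0, 2 * pi)
    nf_noisy <- runif(1, cfg$trajectory_noise_noisy[1],
                      cfg$trajectory_noise_noisy[2])
    noise_frac <- if (noisy) nf_noisy else cfg$trajectory_noise_clear
    noise_sd <- noise_frac * amp
    z <- matrix(rnorm(2 * n), n, 2)
    bif_u <- runif(1)
    branch_q <- runif(1, 0.2, 0.8)
    amp2 <- runif(1, 1, 3)
    freq2 <- runif(1, 0.5, 1.5)
    phase2 <- runif(1, 0, 2 * pi)
    curve_y <- amp * sin(freq * tt + phase)
    branch <- rep(1L, n)
    bifurcated <- noisy && bif_u < cfg$bifurcation_prob
    t_branch <- NA_real_
    if (bifurcated) {
      t_branch <- quantile(tt, branch_q, names = FALSE)
      beyond <- which(tt > t_branch)
      pick <- beyond[sample.int(length(beyond), floor(length(beyond) / 2))]
      branch[pick] <- 2L
      y0 <- amp * sin(freq * t_branch + phase)   # continuity at the split
      curve_y[pick] <- y0 + amp2 * sin(freq2 * (tt[pick] - t_branch) + phase2) -
        amp2 * sin(phase2)
    }
    clean <- cbind(tt, curve_y)
    pts <- clean + z * noise_sd
    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    pts <- pts %*% rot
    clean_rot <- clean %*% rot
    new_sim_dataset(point_cloud(pts),
                    sim_type = if (noisy) "noisy_trajectory" else "clear_trajectory",
                    seed = seed,
                    params = list(n = n, amplitude = amp, frequency = freq,
                                  phase = phase, rotation = theta,
                                  noise_fraction = noise_frac,
                                  noise_sd = noise_sd, arc_position = tt,
                                  clean_points = clean_rot,
                                  bifurcated = bifurcated,
                                  branch_quantile = if (bifurcated) branch_q else NA_real_,
                                  branch_point = t_branch, branch = branch,
                                  branch2 = if (bifurcated)
                                    list(amplitude = amp2, frequency = freq2,
                                         phase = phase2) else NULL))
  })
}

#' Generate a balanced batch of simulated datasets
#'
#' Produces `counts_per_type` datasets for each of the four types
#' (`clear_clusters`, `clear_trajectory`, `noisy_clusters`,
#' `noisy_trajectory`), each with a distinct sub-seed derived from
#' `master_seed`, so the whole batch is reproducible.
#'
#' @param counts_per_type Number of datasets per type (>= 1).
#' @param master_seed Integer master seed.
#' @param cfg A [sim_config()].
#' @return A list of `4 * counts_per_type` `sim_dataset` objects, grouped by
#'   type in the order clear_clusters, clear_trajectory, noisy_clusters,
#'   noisy_trajectory.
#' @export
sim_batch <- function(counts_per_type, master_seed = 1L, cfg = sim_config()) {
  assert_count(counts_per_type, "counts_per_type", min = 1L)
  out <- vector("list", 4L * counts_per_type)
  idx <- 1L
  for (ty in sim_types) {
    for (j in seq_len(counts_per_type)) {
      s <- derive_seed(master_seed, idx)
      out[[idx]] <- switch(ty,
        clear_clusters = sim_clusters(cfg, noisy = FALSE, seed = s),
        clear_trajectory = sim_trajectory(cfg, noisy = FALSE, seed = s),
        noisy_clusters = sim_clusters(cfg, noisy = TRUE, seed = s),
        noisy_trajectory = sim_trajectory(cfg, noisy = TRUE, seed = s))
      idx <- idx + 1L
    }
  }
  out
}
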