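# Generator fidelity: confined Brownian motion, binding kinetics, rendering.

test_that("zero diffusion freezes every position", {
  sp <- species_params(d_free_um2_s = 0, d_bound_um2_s = 0)
  sim <- simulate_trajectories(quick_geom(), quick_sched(frames = 5),
                               sp, kinetic_params(U0 = 0, K = 1e-4), seed = 1)
  rng <- tapply(seq_len(nrow(sim$trajectories)), sim$trajectories$molecule_id,
                function(i) diff(range(sim$trajectories$x_um[i])) +
                  diff(range(sim$trajectories$y_um[i])))
  expect_true(all(rng == 0))
})

test_that("unconfined ensemble MSD matches 4*D*lag*dt within 3 SE", {
  D <- 2; dt <- 0.05
  traj <- unconfined_tracks(n = 400, steps = 60, D = D, dt = dt, seed = 21)
  for (lag in c(1, 3)) {
    # ensemble MSD across independent molecules at one lag (oracle: analytic)
    d2 <- unlist(tapply(seq_len(nrow(traj)), traj$molecule_id, function(i) {
      x <- traj$x_um[i]; y <- traj$y_um[i]
      (x[1 + lag] - x[1])^2 + (y[1 + lag] - y[1])^2
    }))
    se <- stats::sd(d2) / sqrt(length(d2))
    expect_lt(abs(mean(d2) - 4 * D * lag * dt), 3 * se)
  }
})

test_that("no trajectory ever exits the pit disc; long-lag MSD plateaus", {
  geom <- pit_geometry(n_pits = 4, pitch_um = 4)
  sched <- long_sched(400)
  sp <- species_params(d_free_um2_s = 20, n_probes_per_pit = 5)
  sim <- simulate_trajectories(geom, sched, sp,
                               kinetic_params(U0 = 0, K = 1e-4), seed = 5)
  tr <- sim$trajectories
  centers <- rbind(c(2, 2), c(6, 2), c(2, 6), c(6, 6))
  r2 <- (tr$x_um - centers[tr$pit_id, 1])^2 +
    (tr$y_um - centers[tr$pit_id, 2])^2
  R <- geom$diameter_um / 2
  expect_true(all(r2 <= R^2 + 1e-9))
  # disc-confinement plateau <= 2 R^2 at long lags
  msd_long <- mean(unlist(tapply(seq_len(nrow(tr)), tr$molecule_id,
    function(i) msd_oracle(tr$x_um[i], tr$y_um[i], 200))))
  expect_lt(msd_long, 2 * R^2)
  expect_gt(msd_long, 0.5 * R^2)  # saturated, not collapsed
})

test_that("binding obeys the stated kinetic structure", {
  geom <- pit_geometry()
  sched <- quick_sched(frames = 3, n_videos = 5, interval = 600)
  sp <- species_params()
  # U0 = 0: no binding ever
  s0 <- simulate_trajectories(geom, sched, sp, kinetic_params(U0 = 0, K = 1e-3),
                              seed = 2)
  expect_true(all(s0$trajectories$state == "free"))
  # bound count is non-decreasing over time (no rewinding by default)
  s1 <- simulate_trajectories(geom, sched, sp,
                              kinetic_params(U0 = 20, K = 1e-3), seed = 3)
  per_video <- tapply(s1$trajectories$state == "bound",
                      s1$trajectories$video_index, sum)
  expect_true(all(diff(per_video) >= 0))
  # U0 > P0 rejected
  expect_error(kinetic_params(U0 = 120, K = 1e-3), "U0")
})

test_that("ensemble bound fraction follows U0*(1-exp(-K*t)) within 3 SE", {
  # scaled-down version of the fidelity check (full version in acceptance)
  set.seed(9)
  geom <- pit_geometry(); sched <- quick_sched(frames = 2, n_videos = 6,
                                               interval = 1200)
  kin <- kinetic_params(U0 = 10, K = 5e-4)
  b <- replicate(60, true_bound_per_100(
    simulate_trajectories(geom, sched, species_params(), kin))$bound_per_100)
  tv <- video_times(sched)
  theory <- eq1_model(tv, 10, 5e-4)
  for (j in 2:length(tv)) {
    se <- stats::sd(b[j, ]) / sqrt(ncol(b))
    expect_lt(abs(mean(b[j, ]) - theory[j]), 3 * se)
  }
})

test_that("identical seed and config give bit-identical output", {
  args <- list(quick_geom(), quick_sched(), species_params(),
               kinetic_params(U0 = 25, K = 1e-3))
  s1 <- do.call(simulate_trajectories, c(args, seed = 77))
  s2 <- do.call(simulate_trajectories, c(args, seed = 77))
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("rewinding releases probes and breaks monotonicity when enabled", {
  geom <- pit_geometry()
  sched <- quick_sched(frames = 2, n_videos = 8, interval = 1200)
  sim <- simulate_trajectories(geom, sched, species_params(),
                               kinetic_params(U0 = 20, K = 2e-3), seed = 8,
                               rewind_rate = 5e-4)
  gt <- sim$ground_truth$binding
  expect_true(any(is.finite(gt$t_unbind)))
  expect_true(all(gt$t_unbind >= gt$t_bind))
})

test_that("rendering: background-only, stationary argmax, and motion blur", {
  geom <- pit_geometry(n_pits = 1, pitch_um = 3)
  sched <- quick_sched(frames = 4, n_videos = 1)
  # zero emitters: expected frame equals the background everywhere
  sp_empty <- species_params(n_probes_per_pit = 0)
  sim0 <- simulate_trajectories(geom, sched, sp_empty,
                                kinetic_params(U0 = 0, K = 1e-4))
  stk0 <- render_video(sim0, noise = FALSE)[["1"]]
  expect_true(all(stk0 == 10))
  # with Poisson noise the mean matches the background rate
  set.seed(4)
  stkn <- render_video(sim0, noise = TRUE)[["1"]]
  expect_equal(mean(stkn), 10, tolerance = 0.05)
  # one stationary emitter, no noise: frame argmax at the emitter pixel
  sp1 <- species_params(d_free_um2_s = 0, d_bound_um2_s = 0,
                        n_probes_per_pit = 1)
  sim1 <- simulate_trajectories(geom, sched, sp1,
                                kinetic_params(U0 = 0, K = 1e-4), seed = 6)
  stk1 <- render_video(sim1, noise = FALSE)[["1"]]
  pos <- sim1$trajectories[1, c("x_um", "y_um")]
  amax <- which(stk1[, , 1] == max(stk1[, , 1]), arr.ind = TRUE)[1, ]
  expect_equal(unname(amax["col"]), floor(pos$x_um / 0.1) + 1)
  expect_equal(unname(amax["row"]), floor(pos$y_um / 0.1) + 1)
  # fast emitter at 50 ms exposure: fitted spot width exceeds the PSF sigma
  spot_width <- function(d) {
    spf <- species_params(d_free_um2_s = d, d_bound_um2_s = 0,
                          n_probes_per_pit = 1, psf_sigma_um = 0.15)
    simf <- simulate_trajectories(geom, sched, spf,
                                  kinetic_params(U0 = 0, K = 1e-4), seed = 11,
                                  n_substeps = 10)
    stk <- render_video(simf, noise = FALSE)[["1"]]
    det <- detect_spots(stk[, , 1], 0.1, 0.15, threshold_sd = 3)
    mean(det$width_um)
  }
  expect_gt(spot_width(20), spot_width(1e-4))
  expect_gt(spot_width(20), 0.15)
})
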