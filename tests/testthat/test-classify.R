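# Threshold calibration, bound/free labelling, binding counts.

test_that("fully separated samples give a mid-plateau threshold", {
  m <- calibrate_threshold(c(0.9, 1.0, 1.1), c(19, 20, 21))
  expect_gt(m$d_threshold, 1.1)
  expect_lt(m$d_threshold, 19)
  # midpoint of the zero-error plateau, up to one grid step (1% of range)
  expect_equal(m$d_threshold, (1.1 + 19) / 2, tolerance = 0.2)
  expect_equal(m$misclassified, 0)
})

test_that("identical populations are rejected", {
  x <- c(1, 2, 3)
  expect_error(calibrate_threshold(x, x), "not separable")
  expect_error(calibrate_threshold(numeric(0), x), "non-empty")
})

test_that("grid search lands near the analytic two-Gaussian crossing", {
  # equal-size lognormal populations with equal log-SD: the density crossing
  # (equal-misclassification point) is the geometric mean of the medians
  set.seed(101)
  bound <- rlnorm(4000, meanlog = log(1), sdlog = 0.5)
  free <- rlnorm(4000, meanlog = log(20), sdlog = 0.5)
  m <- calibrate_threshold(bound, free)
  analytic <- sqrt(1 * 20)
  expect_lt(abs(m$d_threshold - analytic) / analytic, 0.05)
})

test_that("labelling uses a strict below-threshold rule", {
  est <- data.frame(trajectory_id = 1:3, d_hat = c(0, 2, 2 - 1e-12))
  m <- calibrate_threshold(method = "fixed", d_threshold = 2)
  lab <- classify_trajectories(est, m)
  expect_equal(lab$label, c("bound", "free", "bound"))
})

test_that("binding counts are per 100 probes with both denominators", {
  m <- calibrate_threshold(method = "fixed", d_threshold = 2)
  sched <- quick_sched(interval = 60)
  lab0 <- data.frame(trajectory_id = 1:200, video_index = 1L,
                     d_hat = 10, label = "free")
  expect_equal(count_binding(lab0, sched)$bound_per_100, 0)
  lab1 <- data.frame(trajectory_id = 1:350, video_index = 1L,
                     d_hat = c(rep(0, 7), rep(10, 343)),
                     label = c(rep("bound", 7), rep("free", 343)))
  cnt <- count_binding(lab1, sched)
  expect_equal(cnt$bound_per_100, 2.0)
  expect_equal(cnt$t_s, 0)
  # declared denominator overrides the observed trajectory count
  cnt2 <- count_binding(lab1, sched, denominator = "declared",
                        n_probes_declared = 700)
  expect_equal(cnt2$bound_per_100, 1.0)
})

test_that("classification is monotone and permutation-invariant", {
  set.seed(55)
  m <- calibrate_threshold(method = "fixed", d_threshold = 3)
  sched <- quick_sched()
  est <- data.frame(trajectory_id = 1:120,
                    video_index = rep(1:3, each = 40),
                    d_hat = runif(120, 0, 10))
  c1 <- count_binding(classify_trajectories(est, m), sched)
  est_lower <- est; est_lower$d_hat <- est$d_hat * 0.5
  c2 <- count_binding(classify_trajectories(est_lower, m), sched)
  expect_true(all(c2$bound_per_100 >= c1$bound_per_100))
  perm <- est[sample(nrow(est)), ]
  c3 <- count_binding(classify_trajectories(perm, m), sched)
  expect_equal(c3, c1)
})

test_that("end-to-end bound-fraction bias < 5% absolute at 20x separation", {
  sim <- simulate_trajectories(pit_geometry(),
                               quick_sched(frames = 40, n_videos = 3,
                                           interval = 1200),
                               species_params(),  # D ratio 20
                               kinetic_params(U0 = 20, K = 1e-3), seed = 71)
  est <- estimate_diffusion(as_trajectories(sim), dt = 0.05)
  ref_b <- reference_diffusion_sample(pit_geometry(), quick_sched(frames = 40),
                                      species_params(), "bound", 100)
  ref_f <- reference_diffusion_sample(pit_geometry(), quick_sched(frames = 40),
                                      species_params(), "free", 100)
  lab <- classify_trajectories(est, calibrate_threshold(ref_b, ref_f))
  inferred <- mean(lab$label == "bound")
  truth <- mean(lab$state == "bound")
  expect_lt(abs(inferred - truth), 0.05)
  # per-trajectory agreement is itself high
  expect_gt(mean((lab$label == "bound") == (lab$state == "bound")), 0.95)
})
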