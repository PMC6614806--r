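# Time-course assembly and binding-model fitting.

test_that("time-course assembly computes mean and SEM over replicates", {
  counts <- rbind(
    data.frame(video_index = 1L, t_s = 0, bound_per_100 = c(2, 4),
               n_probes = 100, field = 1:2),
    data.frame(video_index = 2L, t_s = 60, bound_per_100 = c(3, 3),
               n_probes = 100, field = 1:2))
  tc <- assemble_time_course(counts)
  expect_equal(tc$mean_bound, c(3, 3))
  expect_equal(tc$sem_bound, c(1, 0))   # {2,4} -> SEM 1; identical -> 0
  expect_equal(tc$n_videos, c(2L, 2L))
  single <- data.frame(video_index = 1L, t_s = 0, bound_per_100 = 5,
                       n_probes = 100)
  expect_warning(tc1 <- assemble_time_course(single), "single replicate")
  expect_equal(tc1$sem_bound, 0)
})

test_that("replicate SEM is compatible with binomial sampling", {
  cfg <- recovery_config(seed = 303)
  run <- suppressMessages(run_synthetic_experiment(cfg))
  tc <- run$time_course
  late <- nrow(tc)  # largest signal, most stable proportion
  p <- tc$mean_bound[late] / 100
  pred <- 100 * sqrt(p * (1 - p) / 100) / sqrt(10)
  expect_lt(tc$sem_bound[late], 3 * pred + 1e-9)
  expect_gt(tc$sem_bound[late], pred / 3 - 1e-9)
})

test_that("noiseless model inversion is exact to better than 1e-6", {
  t <- seq(0, 7200, length.out = 10)
  for (p in list(c(5, 1e-3), c(10, 5e-4), c(2, 2e-4))) {
    tc <- data.frame(t_s = t, mean_bound = eq1_model(t, p[1], p[2]),
                     sem_bound = 0)
    f <- suppressMessages(fit_eq1(tc))
    expect_lt(abs(f$U0_hat - p[1]) / p[1], 1e-6)
    expect_lt(abs(f$K_hat - p[2]) / p[2], 1e-6)
    expect_true(f$converged)
  }
})

test_that("fitted curve is anchored at 0 and saturates at U0_hat", {
  t <- seq(0, 7200, length.out = 12)
  set.seed(7)
  tc <- data.frame(t_s = t,
                   mean_bound = pmax(eq1_model(t, 8, 6e-4) + rnorm(12, 0, 0.3), 0),
                   sem_bound = 0.3)
  f <- fit_eq1(tc)
  expect_equal(eq1_model(0, f$U0_hat, f$K_hat), 0)
  expect_equal(eq1_model(1e9, f$U0_hat, f$K_hat), f$U0_hat)
  expect_true(all(diff(eq1_model(t, f$U0_hat, f$K_hat)) >= 0))
})

test_that("all-zero time course flags U0 = 0 with unidentifiable K", {
  tc <- data.frame(t_s = seq(0, 600, by = 100), mean_bound = 0, sem_bound = 0)
  expect_warning(f <- fit_eq1(tc), "unidentifiable")
  expect_equal(f$U0_hat, 0)
  expect_false(f$identifiable)
  expect_error(fit_eq1(tc[1:3, ]), ">= 4")
})

test_that("early-time data pin down the product U0*K", {
  # times covering < 5% of the saturation curve: U0, K separately sloppy,
  # but the initial slope U0*K is recovered
  U0 <- 10; K <- 5e-4
  t <- seq(0, 0.05 / K, length.out = 8)
  set.seed(3)
  tc <- data.frame(t_s = t,
                   mean_bound = eq1_model(t, U0, K) * (1 + rnorm(8, 0, 0.01)),
                   sem_bound = 0)
  f <- suppressMessages(suppressWarnings(fit_eq1(tc)))
  expect_lt(abs(f$U0_hat * f$K_hat - U0 * K) / (U0 * K), 0.05)
})

test_that("rate-constant derivation and its error propagation", {
  f0 <- list(U0_hat = 0, K_hat = 0.01, cov = matrix(0, 2, 2))
  expect_equal(derive_rate_constant(f0, P0 = 100)$k, 1e-4)
  expect_equal(derive_rate_constant(f0, P0 = 100)$se_k, 0)
  expect_error(derive_rate_constant(list(U0_hat = 100, K_hat = 1,
                                         cov = matrix(0, 2, 2)), P0 = 100),
               "excess-probe")
  # delta method vs Monte-Carlo oracle from the fit covariance
  U0 <- 10; K <- 5e-4; P0 <- 100
  cov <- matrix(c(0.5^2, 0.3 * 0.5 * 2e-5, 0.3 * 0.5 * 2e-5, (2e-5)^2), 2)
  fit <- list(U0_hat = U0, K_hat = K, cov = cov)
  first_order <- derive_rate_constant(fit, P0)
  set.seed(11)
  L <- chol(cov)
  draws <- matrix(rnorm(2 * 1e4), ncol = 2) %*% L
  k_mc <- (K + draws[, 2]) / (P0 - (U0 + draws[, 1]))
  expect_lt(abs(stats::sd(k_mc) - first_order$se_k) / first_order$se_k, 0.1)
})

test_that("slow rewinding (<= 0.1 K) biases U0_hat by < 15%", {
  K <- 1e-3; U0 <- 20
  errs <- sapply(1:3, function(i) {
    cfg <- recovery_config(seed = 400 + i, U0 = U0, K = K)
    cfg$kinetics$rewind_rate <- 0.1 * K
    r <- suppressMessages(run_synthetic_experiment(cfg))
    (r$fit$U0_hat - U0) / U0
  })
  expect_lt(abs(stats::median(errs)), 0.15)
})
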