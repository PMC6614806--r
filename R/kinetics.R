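# Binding time-course assembly and fitting of the saturating
# pseudo-first-order model B(t) = U0 * (1 - exp(-K t)), K = k (P0 - U0).

#' Evaluate the binding model
#' @param t Time, s.
#' @param U0 Initial unwound-plasmid concentration, per 100 probes.
#' @param K Observed rate, s^-1.
#' @return Bound complexes per 100 probes.
#' @export
eq1_model <- function(t, U0, K) U0 * (1 - exp(-K * t))

#' Assemble a binding time course from replicate videos
#'
#' Per time point: mean and standard error of the mean of
#' \code{bound_per_100} over replicate videos, plus the SEM of the
#' measurement times (nonzero only if replicate timestamps differ).
#'
#' @param counts Data frame from \code{\link{count_binding}}, stacked over
#'   replicates; grouping is by \code{video_index}.
#' @param replicate Optional replicate-id column name (bookkeeping only).
#' @return An object of class \code{binding_time_course}: data frame with
#'   t_s, mean_bound, sem_bound, sem_time, n_videos.
#' @export
assemble_time_course <- function(counts, replicate = NULL) {
  stopifnot(all(c("video_index", "t_s", "bound_per_100") %in% names(counts)))
  sem <- function(x) if (length(x) > 1)
    stats::sd(x) / sqrt(length(x)) else 0
  grp <- split(counts, counts$video_index)
  singles <- any(vapply(grp, nrow, integer(1)) == 1L)
  if (singles)
    warning("single replicate at one or more time points; SEM reported as 0")
  out <- do.call(rbind, lapply(grp, function(g) data.frame(
    t_s = mean(g$t_s),
    mean_bound = mean(g$bound_per_100),
    sem_bound = sem(g$bound_per_100),
    sem_time = sem(g$t_s),
    n_videos = nrow(g)
  )))
  out <- out[order(out$t_s), ]
  rownames(out) <- NULL
  class(out) <- c("binding_time_course", "data.frame")
  out
}

# transformed objective: theta = (qlogis(U0/P0), log K); keeps U0 in [0, P0]
# and K >= 0 by reparameterization rather than clipping
.eq1_obj <- function(theta, t, b, w, P0) {
  U0 <- P0 * stats::plogis(theta[1]); K <- exp(theta[2])
  sum(w * (b - eq1_model(t, U0, K))^2)
}

#' Fit the binding model to a time course
#'
#' Weighted nonlinear least squares of \eqn{B(t) = U_0(1 - e^{-Kt})} with
#' weights \eqn{1/\mathrm{SEM}^2} (unit weights, with a message, if any SEM
#' is zero). Initialization: \eqn{U_0} from the maximum observed signal, K
#' from a log-linear fit of \eqn{-\log(1 - B/U_0)} vs t, plus five jittered
#' restarts; the best converged start wins. Bounds \eqn{U_0 \in [0, P_0]},
#' \eqn{K \ge 0} are enforced by parameter transformation. Standard errors
#' and the \eqn{(U_0, K)} covariance come from the weighted Jacobian at the
#' optimum; joint identifiability is checked via its condition number.
#'
#' @param tc A \code{\link{binding_time_course}} (or data frame with t_s,
#'   mean_bound, sem_bound).
#' @param P0 Initial probe concentration, per 100 probes (default 100).
#' @param n_restarts Number of jittered restarts.
#' @return An object of class \code{pitbind_fit}: U0_hat, K_hat, k_hat and
#'   standard errors, the (U0, K) covariance, residuals, convergence and
#'   identifiability flags.
#' @export
fit_eq1 <- function(tc, P0 = 100, n_restarts = 5L) {
  stopifnot(all(c("t_s", "mean_bound") %in% names(tc)))
  t <- tc$t_s; b <- tc$mean_bound
  if (length(t) < 4) stop("need >= 4 time points")
  sem <- if ("sem_bound" %in% names(tc)) tc$sem_bound else rep(0, length(t))
  if (any(sem <= 0)) {
    message("zero SEM present; using unit weights")
    w <- rep(1, length(t))
  } else w <- 1 / sem^2

  if (all(b <= 0)) {
    out <- list(U0_hat = 0, K_hat = NA_real_, k_hat = NA_real_,
                se_U0 = NA_real_, se_K = NA_real_, se_k = NA_real_,
                cov = matrix(NA_real_, 2, 2,
                             dimnames = list(c("U0", "K"), c("U0", "K"))),
                residuals = b, fitted = rep(0, length(b)),
                converged = TRUE, identifiable = FALSE, P0 = P0,
                n_points = length(t))
    class(out) <- "pitbind_fit"
    warning("time course is identically zero: U0_hat = 0, K unidentifiable")
    return(out)
  }

  # primary start: U0 ~ max signal; K from log-linear early decay
  U0s <- min(max(b) * 1.05, P0 * 0.999)
  frac <- pmin(pmax(b / U0s, 1e-6), 1 - 1e-6)
  pos <- t > 0
  Ks <- if (sum(pos) >= 2) {
    cf <- stats::lm(log(1 - frac[pos]) ~ 0 + t[pos])$coefficients
    max(-unname(cf), 1e-8)
  } else 1e-4
  starts <- list(c(stats::qlogis(U0s / P0), log(Ks)))
  # deterministic jitter (no RNG side effects on the caller's stream)
  jit <- expand.grid(a = c(-1, 0, 1), b = c(-1.5, 1.5))
  for (i in seq_len(min(n_restarts, nrow(jit))))
    starts[[i + 1]] <- starts[[1]] + c(jit$a[i], jit$b[i])

  best <- NULL
  for (s in starts) {
    opt <- tryCatch(
      stats::optim(s, .eq1_obj, t = t, b = b, w = w, P0 = P0,
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      polish <- tryCatch(
        stats::optim(opt$par, .eq1_obj, t = t, b = b, w = w, P0 = P0,
                     method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) opt)
      if (polish$value <= opt$value) opt <- polish
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  if (is.null(best)) stop("fit failed to converge from all starts")

  U0_hat <- P0 * stats::plogis(best$par[1])
  K_hat <- exp(best$par[2])
  fitted <- eq1_model(t, U0_hat, K_hat)
  resid <- b - fitted

  # Jacobian in natural parameters (U0, K)
  J <- cbind(1 - exp(-K_hat * t), U0_hat * t * exp(-K_hat * t))
  sw <- sqrt(w)
  Jw <- J * sw
  sv <- svd(Jw)$d
  identifiable <- sv[2] > 1e-8 * sv[1]
  if (U0_hat > 0.99 * P0) {
    # ran to the upper bound: the data show no saturation, so U0 and K are
    # only constrained through their product and k = K/(P0 - U0) is unusable
    identifiable <- FALSE
    warning("U0_hat is at the P0 boundary; saturation not observed")
  }
  dof <- max(length(t) - 2L, 1L)
  s2 <- sum(w * resid^2) / dof
  cov <- tryCatch(s2 * solve(crossprod(Jw)),
                  error = function(e) matrix(NA_real_, 2, 2))
  dimnames(cov) <- list(c("U0", "K"), c("U0", "K"))
  if (!identifiable)
    warning("U0 and K are poorly jointly identifiable (Jacobian nearly singular)")

  out <- list(U0_hat = U0_hat, K_hat = K_hat,
              se_U0 = sqrt(cov[1, 1]), se_K = sqrt(cov[2, 2]),
              cov = cov, residuals = resid, fitted = fitted,
              converged = best$convergence == 0, identifiable = identifiable,
              P0 = P0, n_points = length(t), rss = best$value)
  kk <- tryCatch(derive_rate_constant(out, P0), error = function(e)
    list(k = NA_real_, se_k = NA_real_))
  out$k_hat <- kk$k; out$se_k <- kk$se_k
  class(out) <- "pitbind_fit"
  out
}

#' @export
print.pitbind_fit <- function(x, ...) {
  cat("Binding-model fit  B(t) = U0 (1 - exp(-K t))\n")
  cat(sprintf("  U0 = %.4g +/- %.3g per 100 probes\n", x$U0_hat, x$se_U0))
  cat(sprintf("  K  = %.4g +/- %.3g /s\n", x$K_hat, x$se_K))
  cat(sprintf("  k  = %.4g +/- %.3g (per-100-probes)^-1 s^-1  [K = k (P0 - U0), P0 = %g]\n",
              x$k_hat, x$se_k, x$P0))
  cat(sprintf("  n = %d points; converged: %s; identifiable: %s\n",
              x$n_points, x$converged, x$identifiable))
  invisible(x)
}

#' Derive the true rate constant from a fit
#'
#' \eqn{k = K / (P_0 - U_0)}; uncertainty by first-order (delta-method)
#' propagation using the \eqn{(U_0, K)} covariance.
#'
#' @param fit A \code{pitbind_fit} (or list with U0_hat, K_hat, cov).
#' @param P0 Initial probe concentration; must exceed \code{U0_hat}.
#' @return List with \code{k} and \code{se_k}.
#' @export
derive_rate_constant <- function(fit, P0 = fit$P0) {
  U0 <- fit$U0_hat; K <- fit$K_hat
  if (is.na(K)) return(list(k = NA_real_, se_k = NA_real_))
  if (P0 <= U0) stop("excess-probe assumption violated: P0 <= U0_hat")
  k <- K / (P0 - U0)
  g <- c(K / (P0 - U0)^2, 1 / (P0 - U0))   # (dk/dU0, dk/dK)
  se_k <- if (all(is.finite(fit$cov)))
    sqrt(max(drop(t(g) %*% fit$cov %*% g), 0)) else NA_real_
  list(k = k, se_k = se_k)
}
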