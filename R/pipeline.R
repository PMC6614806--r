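# End-to-end orchestration: synth -> (render -> track) -> classify ->
# kinetics, with JSON run configs, stage logging, and run manifests.

.default_config <- function() list(
  seed = 1L,
  n_fields = 10L,                 # replicate fields of view ("videos" averaged per time point)
  mode = "trajectories",          # or "video" (render + detect + link)
  condition = list(nacl_mM = 137.5, tris_mM = 12, hepes_mM = 25, ph = 8.0,
                   crowder = list(species = "none", mw_da = 0,
                                  conc_wv_pct = 0),
                   temperature_c = 37),
  geometry = list(diameter_um = 3, depth_um = 0.5, pitch_um = 6, n_pits = 25),
  schedule = list(exposure_s = 0.05, frames_per_video = 100,
                  intra_video_interval_s = 0.05, video_interval_s = 60,
                  total_duration_s = 7200),
  species = list(d_free_um2_s = 20, d_bound_um2_s = 1, n_probes_per_pit = 4,
                 n_plasmids_per_pit = 1, photons_per_frame = 500,
                 background_photons = 10, psf_sigma_um = 0.15,
                 pixel_size_um = 0.1),
  kinetics = list(U0 = 10, K = 5e-4, P0 = 100, rewind_rate = 0,
                  bleach_rate = 0),
  classify = list(d_threshold = NULL, n_lags = 4, min_track_length = 10,
                  denominator = "observed", n_reference = 200),
  track = list(threshold_sd = 5, max_disp_um = 1.5, max_gap = 1,
               n_substeps = 4),
  write_trajectories = FALSE,
  write_video = FALSE,
  label = NULL
)

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Build a run configuration
#'
#' Named arguments override the package defaults (see the methods vignette
#' for the rationale behind each default). Nested blocks merge recursively.
#'
#' @param ... Top-level config entries (seed, n_fields, mode, condition,
#'   geometry, schedule, species, kinetics, classify, track, label, ...).
#' @return A validated config list of class \code{pitbind_config}.
#' @export
run_config <- function(...) {
  cfg <- .merge_config(.default_config(), list(...))
  # validate by constructing the domain objects
  invisible(.config_objects(cfg))
  class(cfg) <- c("pitbind_config", "list")
  cfg
}

#' Read a run configuration from JSON
#' @param path Path to a JSON config file.
#' @return A \code{pitbind_config}.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

.config_objects <- function(cfg) {
  cond <- cfg$condition
  crw <- do.call(crowder, cond$crowder)
  list(
    condition = solution_condition(
      nacl_mM = cond$nacl_mM,
      buffer = buffer_model(cond$tris_mM, cond$hepes_mM, cond$ph),
      crowd = crw, temperature_c = cond$temperature_c),
    geom = do.call(pit_geometry, cfg$geometry),
    sched = do.call(acquisition_schedule, cfg$schedule),
    sp = do.call(species_params, cfg$species),
    kin = do.call(kinetic_params, Filter(
      function(x) !is.null(x) && !anyNA(x),
      cfg$kinetics[intersect(names(cfg$kinetics),
                             c("U0", "K", "k", "P0"))])),
    rewind_rate = if (is.null(cfg$kinetics$rewind_rate)) 0
                  else cfg$kinetics$rewind_rate,
    bleach_rate = if (is.null(cfg$kinetics$bleach_rate)) 0
                  else cfg$kinetics$bleach_rate
  )
}

#' Reference diffusion-estimate sample for threshold calibration
#'
#' Simulates single-state molecules (all free or all bound) under the run's
#' geometry/schedule and runs them through the MSD estimator, yielding the
#' condition-matched reference samples the two-population calibration needs.
#'
#' @param geom,sched,sp Run configuration objects.
#' @param state "free" or "bound".
#' @param n Number of reference molecules.
#' @return Data frame of diffusion estimates.
#' @export
reference_diffusion_sample <- function(geom, sched, sp, state = c("free", "bound"),
                                       n = 200) {
  state <- match.arg(state)
  D <- if (state == "free") sp$d_free_um2_s else sp$d_bound_um2_s
  R <- geom$diameter_um / 2
  p0 <- if (is.finite(R)) .runif_disc(n, R) else matrix(0, n, 2)
  bm <- cpp_reflected_bm(p0[, 1], p0[, 2], rep(D, n),
                         sched$frames_per_video - 1L,
                         sched$intra_video_interval_s, R)
  traj <- data.frame(
    trajectory_id = rep(seq_len(n), times = sched$frames_per_video),
    frame = rep(seq_len(sched$frames_per_video) - 1L, each = n),
    x_um = as.vector(bm$x), y_um = as.vector(bm$y)
  )
  estimate_diffusion(traj, dt = sched$intra_video_interval_s)
}

# one replicate field through sim -> estimates, trajectory-input mode
.field_trajectory_mode <- function(objs, cfg) {
  sim <- simulate_trajectories(objs$geom, objs$sched, objs$sp, objs$kin,
                               rewind_rate = objs$rewind_rate,
                               bleach_rate = objs$bleach_rate)
  traj <- as_trajectories(sim)
  est <- estimate_diffusion(traj, dt = objs$sched$intra_video_interval_s,
                            n_lags = cfg$classify$n_lags,
                            min_track_length = cfg$classify$min_track_length)
  list(sim = sim, traj = traj, est = est)
}

# one replicate field through render -> detect -> link, video-input mode
.field_video_mode <- function(objs, cfg) {
  sim <- simulate_trajectories(objs$geom, objs$sched, objs$sp, objs$kin,
                               n_substeps = cfg$track$n_substeps)
  stacks <- render_video(sim)
  det_all <- list()
  for (v in names(stacks)) {
    det <- detect_spots(stacks[[v]], objs$sp$pixel_size_um,
                        objs$sp$psf_sigma_um,
                        threshold_sd = cfg$track$threshold_sd,
                        video_index = as.integer(v))
    det_all[[v]] <- det
  }
  det <- do.call(rbind, det_all)
  linked <- link_trajectories(det, max_disp_um = cfg$track$max_disp_um,
                              max_gap = cfg$track$max_gap)
  # unique trajectory ids across videos come from link_trajectories already
  est <- estimate_diffusion(linked, dt = objs$sched$intra_video_interval_s,
                            n_lags = cfg$classify$n_lags,
                            min_track_length = cfg$classify$min_track_length)
  list(sim = sim, traj = linked, est = est, stacks = stacks)
}

#' Run a complete synthetic experiment
#'
#' Executes the full chain for \code{n_fields} replicate fields of view:
#' simulate (optionally render + detect + link), estimate diffusion,
#' calibrate/apply the bound-complex threshold, count binding per video,
#' assemble the time course, and fit the binding model. Reruns with the same
#' config are bit-identical (one seeded generator, documented draw order).
#'
#' @param cfg A \code{\link{run_config}} (or plain list passed through it).
#' @param outdir Optional output directory; when given, writes ground truth,
#'   labels, counts, time course, fit report and a manifest (CSV/JSON).
#' @param quiet Suppress per-stage logging.
#' @return List of class \code{pitbind_run}: config, threshold model, counts,
#'   time_course, fit, per-field ground truth, condition summary.
#' @export
run_synthetic_experiment <- function(cfg, outdir = NULL, quiet = TRUE) {
  if (!inherits(cfg, "pitbind_config")) cfg <- do.call(run_config, cfg)
  objs <- .config_objects(cfg)
  log_ <- function(...) if (!quiet) message(sprintf(...))
  set.seed(cfg$seed)

  # threshold: fixed from config, else calibrated on condition-matched
  # single-state reference samples (drawn first in the seed order)
  if (!is.null(cfg$classify$d_threshold)) {
    thr <- calibrate_threshold(method = "fixed",
                               d_threshold = cfg$classify$d_threshold,
                               calibration_condition = objs$condition)
  } else {
    ref_b <- reference_diffusion_sample(objs$geom, objs$sched, objs$sp,
                                        "bound", cfg$classify$n_reference)
    ref_f <- reference_diffusion_sample(objs$geom, objs$sched, objs$sp,
                                        "free", cfg$classify$n_reference)
    thr <- calibrate_threshold(ref_b, ref_f,
                               calibration_condition = objs$condition)
  }
  log_("stage classify: threshold %.4g um^2/s (%s)", thr$d_threshold,
       thr$method)

  counts_all <- list(); gt_all <- list(); labels_all <- list()
  traj_all <- if (isTRUE(cfg$write_trajectories)) list() else NULL
  n_declared <- objs$geom$n_pits * objs$sp$n_probes_per_pit
  for (fld in seq_len(cfg$n_fields)) {
    res <- if (cfg$mode == "video") .field_video_mode(objs, cfg)
           else .field_trajectory_mode(objs, cfg)
    lab <- classify_trajectories(res$est, thr)
    cnt <- count_binding(lab, objs$sched,
                         denominator = cfg$classify$denominator,
                         n_probes_declared = n_declared)
    cnt$field <- fld
    lab$field <- fld
    counts_all[[fld]] <- cnt
    labels_all[[fld]] <- lab
    gt <- res$sim$ground_truth$binding
    gt$field <- fld
    gt_all[[fld]] <- gt
    if (!is.null(traj_all)) {
      tr <- res$traj; tr$field <- fld; traj_all[[fld]] <- tr
    }
    log_("stage field %d: %d trajectories, %d bound", fld, nrow(lab),
         sum(lab$label == "bound"))
  }
  counts <- do.call(rbind, counts_all)
  tc <- assemble_time_course(counts)
  log_("stage kinetics: %d time points, %d fields", nrow(tc), cfg$n_fields)
  fit <- fit_eq1(tc, P0 = objs$kin$P0)

  # Delete-one-field jackknife for the parameter uncertainties. The curve-fit
  # (Jacobian) covariance treats time points as independent, but a field's
  # realized unwound-site count shifts its whole time course coherently, so
  # between-field variance (including the generator's binomial site loading)
  # is invisible to residuals. Resampling whole fields captures it.
  if (cfg$n_fields >= 3 && !is.na(fit$K_hat)) {
    theta <- vapply(seq_len(cfg$n_fields), function(f) {
      tcf <- assemble_time_course(counts[counts$field != f, ])
      ff <- suppressWarnings(suppressMessages(fit_eq1(tcf, P0 = objs$kin$P0)))
      c(ff$U0_hat, ff$K_hat)
    }, numeric(2))
    n <- cfg$n_fields
    dev <- theta - rowMeans(theta)
    cov_j <- (n - 1) / n * tcrossprod(dev)
    dimnames(cov_j) <- dimnames(fit$cov)
    fit$cov <- cov_j
    fit$se_U0 <- sqrt(cov_j[1, 1]); fit$se_K <- sqrt(cov_j[2, 2])
    kk <- tryCatch(derive_rate_constant(fit, objs$kin$P0),
                   error = function(e) list(k = fit$k_hat, se_k = NA_real_))
    fit$k_hat <- kk$k; fit$se_k <- kk$se_k
    fit$se_method <- "jackknife_fields"
    fit$ci95_U0 <- fit$U0_hat +
      c(-1, 1) * stats::qt(0.975, n - 1) * fit$se_U0
  }

  out <- list(config = cfg, condition = objs$condition, threshold = thr,
              counts = counts, time_course = tc, fit = fit,
              ground_truth = do.call(rbind, gt_all),
              labels = do.call(rbind, labels_all))
  if (!is.null(traj_all)) out$trajectories <- do.call(rbind, traj_all)
  class(out) <- "pitbind_run"
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

#' Write a run's outputs to a directory
#' @param run A \code{pitbind_run}.
#' @param outdir Output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$ground_truth, file.path(outdir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(run$labels, file.path(outdir, "labels.csv"),
                   row.names = FALSE)
  utils::write.csv(run$counts, file.path(outdir, "binding_counts.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$time_course),
                   file.path(outdir, "time_course.csv"), row.names = FALSE)
  if (!is.null(run$trajectories))
    utils::write.csv(run$trajectories, file.path(outdir, "trajectories.csv"),
                     row.names = FALSE)
  fit <- run$fit
  utils::write.csv(data.frame(
    label = if (is.null(run$config$label)) NA else run$config$label,
    U0_hat = fit$U0_hat, se_U0 = fit$se_U0, K_hat = fit$K_hat,
    se_K = fit$se_K, k_hat = fit$k_hat, se_k = fit$se_k,
    n_points = fit$n_points, converged = fit$converged,
    identifiable = fit$identifiable),
    file.path(outdir, "fit_report.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    U0_hat = fit$U0_hat, se_U0 = fit$se_U0, K_hat = fit$K_hat,
    se_K = fit$se_K, k_hat = fit$k_hat, se_k = fit$se_k,
    cov = fit$cov, converged = fit$converged,
    identifiable = fit$identifiable, P0 = fit$P0,
    d_threshold = run$threshold$d_threshold,
    condition = list(
      total_ionic_strength_mM = total_ionic_strength(run$condition),
      excluded_volume_pct = excluded_volume_fraction(run$condition$crowder),
      crowder_conc_wv_pct = run$condition$crowder$conc_wv_pct,
      nacl_mM = run$condition$nacl_mM)),
    file.path(outdir, "fit.json"), auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(outdir, "config.json")
  jsonlite::write_json(unclass(run$config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  jsonlite::write_json(list(
    package = "pitbind",
    version = as.character(utils::packageVersion("pitbind")),
    r_version = R.version.string,
    seed = run$config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = unique(c(list.files(outdir), "manifest.json"))),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE)
  invisible(outdir)
}

#' @export
print.pitbind_run <- function(x, ...) {
  cat(sprintf("pitbind_run: %d fields, %d time points\n",
              x$config$n_fields, nrow(x$time_course)))
  print(x$fit)
  invisible(x)
}

#' Summarize fitted kinetics across conditions
#'
#' The package's analogue of the study's panel-B figures: a table of fitted
#' initial unwound-site concentrations and rate constants against a condition
#' covariate, with propagated uncertainties and an inverse-variance weighted
#' linear trend test on k (the paper-level question being whether the rate
#' constant varies with condition at all).
#'
#' @param runs List of \code{pitbind_run} objects, or paths to run
#'   directories containing \code{fit.json}.
#' @param covariate One of "excluded_volume_pct", "crowder_conc_wv_pct",
#'   "total_ionic_strength_mM", "nacl_mM".
#' @return Data frame (one row per run) with attribute \code{k_trend}
#'   (slope, se, 95\% CI, and whether the CI covers zero).
#' @export
compare_conditions <- function(runs, covariate = "total_ionic_strength_mM") {
  if (length(runs) < 1) stop("need at least one completed run")
  rows <- lapply(runs, function(r) {
    if (is.character(r)) {
      j <- jsonlite::read_json(file.path(r, "fit.json"), simplifyVector = TRUE)
      data.frame(covariate = j$condition[[covariate]], U0_hat = j$U0_hat,
                 se_U0 = j$se_U0, k_hat = j$k_hat, se_k = j$se_k)
    } else {
      covs <- list(
        total_ionic_strength_mM = total_ionic_strength(r$condition),
        excluded_volume_pct = excluded_volume_fraction(r$condition$crowder),
        crowder_conc_wv_pct = r$condition$crowder$conc_wv_pct,
        nacl_mM = r$condition$nacl_mM)
      data.frame(covariate = covs[[covariate]], U0_hat = r$fit$U0_hat,
                 se_U0 = r$fit$se_U0, k_hat = r$fit$k_hat,
                 se_k = r$fit$se_k)
    }
  })
  tab <- do.call(rbind, rows)
  names(tab)[1] <- covariate
  tab <- tab[order(tab[[covariate]]), ]
  rownames(tab) <- NULL
  if (nrow(tab) >= 3 && all(is.finite(tab$k_hat)) && all(tab$se_k > 0)) {
    fit <- stats::lm(tab$k_hat ~ tab[[covariate]], weights = 1 / tab$se_k^2)
    slope <- stats::coef(fit)[2]
    se <- sqrt(diag(stats::vcov(fit)))[2]
    ci <- slope + c(-1, 1) * stats::qt(0.975, nrow(tab) - 2) * se
    attr(tab, "k_trend") <- list(slope = unname(slope), se = unname(se),
                                 ci = unname(ci),
                                 covers_zero = ci[1] <= 0 && ci[2] >= 0)
  }
  tab
}
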