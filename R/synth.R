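# Ground-truthed synthetic data: pit-confined two-species Brownian
# trajectories with stochastic probe binding at unwound plasmid sites,
# following the saturating pseudo-first-order model
#   B(t) = U0 * (1 - exp(-K * t)),  K = k * (P0 - U0).

#' Nanopit array geometry
#'
#' Cylindrical glass pits in which molecules diffuse. The assay pits are
#' 3 um diameter by 500 nm deep; motion is simulated in 2-D (the imaging
#' plane), treating the shallow axial extent as fully projected. Use
#' \code{diameter_um = Inf} for unconfined motion.
#'
#' @param diameter_um Pit diameter, um.
#' @param depth_um Pit depth, um (bookkeeping only; motion is 2-D).
#' @param pitch_um Center-to-center pit spacing, um.
#' @param n_pits Number of pits in the field of view.
#' @return An object of class \code{pit_geometry}.
#' @export
pit_geometry <- function(diameter_um = 3, depth_um = 0.5, pitch_um = 6,
                         n_pits = 25) {
  if (diameter_um <= 0 || depth_um <= 0) stop("pit dimensions must be > 0")
  if (n_pits < 1) stop("n_pits must be >= 1")
  if (is.finite(diameter_um) && pitch_um < diameter_um)
    stop("pitch_um must be >= diameter_um")
  structure(list(diameter_um = diameter_um, depth_um = depth_um,
                 pitch_um = pitch_um, n_pits = as.integer(n_pits)),
            class = "pit_geometry")
}

#' Acquisition schedule
#'
#' Videos are taken at regular intervals over the experiment (every minute
#' over ~2 h in the assay), each a burst of frames at fixed exposure (50 ms).
#' Frame count per video is an engineering default (100), giving trajectories
#' long enough for stable MSD estimation.
#'
#' @param exposure_s Exposure time per frame, s.
#' @param frames_per_video Frames in each video burst.
#' @param intra_video_interval_s Frame-to-frame interval within a video, s.
#' @param video_interval_s Interval between video starts, s.
#' @param total_duration_s Total experiment duration, s.
#' @return An object of class \code{acquisition_schedule}.
#' @export
acquisition_schedule <- function(exposure_s = 0.05, frames_per_video = 100,
                                 intra_video_interval_s = exposure_s,
                                 video_interval_s = 60,
                                 total_duration_s = 7200) {
  if (exposure_s <= 0) stop("exposure_s must be > 0")
  if (intra_video_interval_s < exposure_s)
    stop("intra_video_interval_s must be >= exposure_s")
  if (video_interval_s < frames_per_video * intra_video_interval_s)
    stop("video_interval_s must cover a whole video burst")
  if (total_duration_s < video_interval_s)
    stop("total_duration_s must be >= video_interval_s")
  structure(list(exposure_s = exposure_s,
                 frames_per_video = as.integer(frames_per_video),
                 intra_video_interval_s = intra_video_interval_s,
                 video_interval_s = video_interval_s,
                 total_duration_s = total_duration_s),
            class = "acquisition_schedule")
}

#' Video start times of a schedule
#' @param sched An \code{\link{acquisition_schedule}}.
#' @return Numeric vector of video start times, s.
#' @export
video_times <- function(sched) {
  seq(0, sched$total_duration_s, by = sched$video_interval_s)
}

#' Molecular species parameters
#'
#' Diffusion coefficients of the two populations and imaging parameters.
#' Defaults (free probe 20 um^2/s, bound complex 1 um^2/s) are chosen to make
#' the populations cleanly separable at 50 ms sampling; they are engineering
#' defaults, not measured values.
#'
#' @param d_free_um2_s Free-probe diffusion coefficient, um^2/s.
#' @param d_bound_um2_s Bound-complex diffusion coefficient, um^2/s.
#' @param n_probes_per_pit Probes loaded per pit.
#' @param n_plasmids_per_pit Plasmids per pit.
#' @param photons_per_frame Expected signal photons per emitter per frame.
#' @param background_photons Expected background photons per pixel per frame.
#' @param psf_sigma_um Gaussian PSF standard deviation, um.
#' @param pixel_size_um Camera pixel size, um.
#' @return An object of class \code{species_params}.
#' @export
species_params <- function(d_free_um2_s = 20, d_bound_um2_s = 1,
                           n_probes_per_pit = 4, n_plasmids_per_pit = 1,
                           photons_per_frame = 500, background_photons = 10,
                           psf_sigma_um = 0.15, pixel_size_um = 0.1) {
  if (!(d_free_um2_s >= d_bound_um2_s && d_bound_um2_s >= 0))
    stop("need d_free >= d_bound >= 0")
  if (d_free_um2_s == d_bound_um2_s && d_free_um2_s > 0)
    warning("d_free == d_bound > 0: populations will not be separable")
  if (n_probes_per_pit < 0 || n_plasmids_per_pit < 0) stop("counts must be >= 0")
  if (psf_sigma_um <= 0 || pixel_size_um <= 0)
    stop("psf_sigma_um and pixel_size_um must be > 0")
  structure(list(d_free_um2_s = d_free_um2_s, d_bound_um2_s = d_bound_um2_s,
                 n_probes_per_pit = as.integer(n_probes_per_pit),
                 n_plasmids_per_pit = as.integer(n_plasmids_per_pit),
                 photons_per_frame = photons_per_frame,
                 background_photons = background_photons,
                 psf_sigma_um = psf_sigma_um, pixel_size_um = pixel_size_um),
            class = "species_params")
}

#' Kinetic parameters of the binding model
#'
#' The binding time course follows \eqn{B(t) = U_0 (1 - e^{-Kt})} with
#' \eqn{K = k (P_0 - U_0)}, where \eqn{U_0} is the initial concentration of
#' unwound plasmids, \eqn{P_0} the initial probe concentration, and \eqn{k}
#' the true second-order rate constant. All concentrations are in
#' "per 100 probes" units (so \eqn{P_0 = 100} by convention), making k's
#' units (per-100-probes)^-1 s^-1. Supply either K or k.
#'
#' @param U0 Initial unwound-plasmid concentration, per 100 probes.
#' @param K Observed exponential rate, s^-1.
#' @param k True rate constant, (per-100-probes)^-1 s^-1.
#' @param P0 Initial probe concentration, per 100 probes (default 100).
#' @return An object of class \code{kinetic_params}.
#' @examples
#' kinetic_params(U0 = 10, K = 5e-4)
#' @export
kinetic_params <- function(U0, K = NULL, k = NULL, P0 = 100) {
  if (U0 < 0 || U0 > P0) stop("need 0 <= U0 <= P0")
  if (is.null(K) && is.null(k)) stop("supply K or k")
  if (!is.null(K) && !is.null(k) &&
      abs(K - k * (P0 - U0)) > 1e-9 * max(K, 1e-12))
    stop("inconsistent K and k: K = k * (P0 - U0) must hold")
  if (is.null(K)) K <- k * (P0 - U0)
  if (is.null(k)) k <- if (P0 > U0) K / (P0 - U0) else NA_real_
  if (K < 0) stop("K must be >= 0")
  structure(list(P0 = P0, U0 = U0, K = K, k = k), class = "kinetic_params")
}

# uniform draw inside a disc of radius R (exact, via inverse-CDF in r)
.runif_disc <- function(n, R) {
  r <- R * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

# pit centers laid out on a square grid with the given pitch
.pit_centers <- function(geom) {
  if (!is.finite(geom$diameter_um))
    return(cbind(rep(0, geom$n_pits), rep(0, geom$n_pits)))
  ncol_ <- ceiling(sqrt(geom$n_pits))
  idx <- seq_len(geom$n_pits) - 1L
  cbind((idx %% ncol_) * geom$pitch_um + geom$pitch_um / 2,
        (idx %/% ncol_) * geom$pitch_um + geom$pitch_um / 2)
}

#' Simulate pit-confined probe trajectories with stochastic binding
#'
#' Each probe performs 2-D Gaussian-step Brownian motion (per-step, per-axis
#' variance \eqn{2 D \Delta t}) specularly reflected at the pit wall. Each
#' plasmid is unwound with probability such that the expected number of
#' unwound sites equals \code{kin$U0} per 100 probes; each unwound site draws
#' an exponential waiting time with rate \code{kin$K} and captures one free
#' probe in its pit at that moment (one probe per site, no rewinding), so the
#' ensemble-expected bound count follows \eqn{U_0 (1 - e^{-Kt})} exactly.
#' A probe's diffusion coefficient switches from \code{d_free} to
#' \code{d_bound} once bound; its state within a video is its state at the
#' video start (videos last seconds, binding unfolds over hours).
#'
#' Because consecutive videos are separated by times much longer than the
#' in-pit mixing time \eqn{R^2/4D}, positions are re-equilibrated (uniform in
#' the pit disc) at each video start rather than propagated between videos.
#'
#' @param geom A \code{\link{pit_geometry}}.
#' @param sched An \code{\link{acquisition_schedule}}.
#' @param sp A \code{\link{species_params}}.
#' @param kin A \code{\link{kinetic_params}}; \code{U0 <= P0} required.
#' @param seed Optional integer seed (one seeded generator drives every draw,
#'   in documented order: site unwinding, binding times, probe assignment,
#'   rewinding times, bleaching times, then per-video initial positions and
#'   steps).
#' @param n_substeps Sub-steps per frame interval (> 1 stores sub-positions
#'   for motion-blur rendering in an attribute).
#' @param rewind_rate Site rewinding rate, s^-1 (default 0: binding is
#'   irreversible, matching the fitted model's assumption). When positive, a
#'   bound complex releases its probe after an Exp(rewind_rate) waiting time
#'   as its site transiently rewinds; the site then re-opens and re-binds at
#'   rate K (binding-limited cycling, stationary occupancy K/(K +
#'   rewind_rate)). Used to quantify the negligible-rewinding assumption.
#' @param bleach_rate Photobleaching rate per probe, s^-1 (default 0: the
#'   assay's oxygen-scavenging system suppresses bleaching). Bleached probes
#'   stop appearing in trajectories.
#' @return A list of class \code{pitbind_sim}: \code{trajectories} (data frame
#'   with molecule_id, video_index, frame, t_s, x_um, y_um, pit_id, state),
#'   \code{ground_truth} (kinetic params, per-site unwinding/binding table,
#'   per-molecule binding times), plus the input configuration.
#' @export
simulate_trajectories <- function(geom, sched, sp, kin, seed = NULL,
                                  n_substeps = 1L, rewind_rate = 0,
                                  bleach_rate = 0) {
  stopifnot(inherits(geom, "pit_geometry"), inherits(sched, "acquisition_schedule"),
            inherits(sp, "species_params"), inherits(kin, "kinetic_params"))
  if (kin$U0 > kin$P0) stop("U0 must be <= P0")
  if (!is.null(seed)) set.seed(seed)
  n_substeps <- as.integer(n_substeps)

  n_pits <- geom$n_pits
  n_probes <- n_pits * sp$n_probes_per_pit
  n_plasmids <- n_pits * sp$n_plasmids_per_pit
  if (n_probes == 0) {   # empty scene (e.g. background-only renders)
    out <- list(
      trajectories = data.frame(molecule_id = integer(), video_index = integer(),
                                frame = integer(), t_s = numeric(),
                                x_um = numeric(), y_um = numeric(),
                                pit_id = integer(), state = character()),
      ground_truth = list(kin = kin,
                          sites = data.frame(), binding = data.frame(
                            molecule_id = integer(), pit_id = integer(),
                            t_bind = numeric(), t_unbind = numeric(),
                            t_bleach = numeric()),
                          n_probes = 0L),
      geom = geom, sched = sched, sp = sp, n_substeps = n_substeps)
    class(out) <- "pitbind_sim"
    return(out)
  }

  # per-plasmid unwinding probability: E[sites] = U0/100 * n_probes
  q <- if (n_plasmids > 0) kin$U0 * n_probes / (100 * n_plasmids) else 0
  if (q > 1)
    stop("U0 too large for the plasmid loading: need ",
         "n_plasmids_per_pit >= U0 * n_probes_per_pit / 100")

  probe_pit <- rep(seq_len(n_pits), each = sp$n_probes_per_pit)
  sites <- if (n_plasmids > 0) data.frame(
    pit_id = rep(seq_len(n_pits), each = sp$n_plasmids_per_pit),
    plasmid_id = seq_len(n_plasmids),
    unwound = stats::runif(n_plasmids) < q
  ) else data.frame(pit_id = integer(), plasmid_id = integer(),
                    unwound = logical())
  sites$t_bind <- ifelse(sites$unwound & kin$K > 0,
                         stats::rexp(nrow(sites), rate = kin$K), Inf)

  # each unwound site captures one free probe in its pit, in time order
  t_bind_probe <- rep(Inf, n_probes)
  if (any(is.finite(sites$t_bind))) {
    ord <- order(sites$t_bind)
    for (i in ord) {
      if (!is.finite(sites$t_bind[i])) next
      cand <- which(probe_pit == sites$pit_id[i] & !is.finite(t_bind_probe))
      if (length(cand) == 0L) next  # no free probe left in this pit
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      t_bind_probe[pick] <- sites$t_bind[i]
    }
  }

  t_unbind <- rep(Inf, n_probes)
  intervals <- NULL
  if (rewind_rate > 0) {
    intervals <- vector("list", n_probes)
    for (i in which(is.finite(t_bind_probe))) {
      t0 <- t_bind_probe[i]; on <- numeric(0); off <- numeric(0)
      while (t0 <= sched$total_duration_s) {
        on <- c(on, t0)
        t0 <- t0 + stats::rexp(1, rewind_rate)   # bound period ends
        off <- c(off, t0)
        t0 <- t0 + stats::rexp(1, kin$K)         # site re-opens, re-binds
      }
      intervals[[i]] <- cbind(on = on, off = off)
    }
    first_off <- vapply(intervals, function(m)
      if (is.null(m) || nrow(m) == 0) Inf else m[1, 2], numeric(1))
    t_unbind <- first_off
  }
  t_bleach <- if (bleach_rate > 0)
    stats::rexp(n_probes, rate = bleach_rate) else rep(Inf, n_probes)

  R <- geom$diameter_um / 2
  centers <- .pit_centers(geom)
  tv <- video_times(sched)
  n_videos <- length(tv)
  Fpv <- sched$frames_per_video
  dt <- sched$intra_video_interval_s
  dt_sub <- dt / n_substeps
  n_steps <- (Fpv - 1L) * n_substeps

  per_video <- vector("list", n_videos)
  sub_list <- if (n_substeps > 1L) vector("list", n_videos) else NULL
  cur <- if (is.finite(R)) .runif_disc(n_probes, R) else matrix(0, n_probes, 2)
  for (v in seq_len(n_videos)) {
    bound <- if (is.null(intervals)) t_bind_probe <= tv[v] else
      vapply(intervals, function(m)
        !is.null(m) && nrow(m) > 0 && any(m[, 1] <= tv[v] & tv[v] < m[, 2]),
        logical(1))
    Dv <- ifelse(bound, sp$d_bound_um2_s, sp$d_free_um2_s)
    if (v > 1L) {
      # between videos (minutes apart): confined diffusing molecules are
      # re-equilibrated (gap >> in-pit mixing time R^2/4D); unconfined ones
      # take an exact Gaussian increment over the gap; D = 0 stays put
      gap <- sched$video_interval_s - (Fpv - 1L) * dt
      moving <- Dv > 0
      if (is.finite(R)) {
        if (any(moving)) cur[moving, ] <- .runif_disc(sum(moving), R)
      } else if (any(moving)) {
        sdg <- sqrt(2 * Dv[moving] * gap)
        cur[moving, 1] <- cur[moving, 1] + stats::rnorm(sum(moving), 0, sdg)
        cur[moving, 2] <- cur[moving, 2] + stats::rnorm(sum(moving), 0, sdg)
      }
    }
    bm <- cpp_reflected_bm(cur[, 1], cur[, 2], Dv, n_steps, dt_sub, R)
    cur <- cbind(bm$x[, n_steps + 1L], bm$y[, n_steps + 1L])
    keep <- seq.int(1L, n_steps + 1L, by = n_substeps)  # frame-time samples
    xf <- bm$x[, keep, drop = FALSE] + centers[probe_pit, 1]
    yf <- bm$y[, keep, drop = FALSE] + centers[probe_pit, 2]
    per_video[[v]] <- data.frame(
      molecule_id = rep(seq_len(n_probes), times = Fpv),
      video_index = v,
      frame = rep(seq_len(Fpv) - 1L, each = n_probes),
      t_s = tv[v] + rep(seq_len(Fpv) - 1L, each = n_probes) * dt,
      x_um = as.vector(xf), y_um = as.vector(yf),
      pit_id = rep(probe_pit, times = Fpv),
      state = ifelse(bound, "bound", "free")[rep(seq_len(n_probes), Fpv)]
    )
    if (bleach_rate > 0)
      per_video[[v]] <- per_video[[v]][
        rep(t_bleach > tv[v], times = Fpv), , drop = FALSE]
    if (n_substeps > 1L)
      sub_list[[v]] <- list(x = bm$x + centers[probe_pit, 1],
                            y = bm$y + centers[probe_pit, 2],
                            bound = bound)
  }
  traj <- do.call(rbind, per_video)
  out <- list(
    trajectories = traj,
    ground_truth = list(kin = kin, sites = sites,
                        binding = data.frame(molecule_id = seq_len(n_probes),
                                             pit_id = probe_pit,
                                             t_bind = t_bind_probe,
                                             t_unbind = t_unbind,
                                             t_bleach = t_bleach),
                        n_probes = n_probes, intervals = intervals),
    geom = geom, sched = sched, sp = sp,
    n_substeps = n_substeps
  )
  if (n_substeps > 1L) out$substeps <- sub_list
  class(out) <- "pitbind_sim"
  out
}

#' @export
print.pitbind_sim <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("pitbind_sim: %d probes, %d pits, %d videos x %d frames\n",
              gt$n_probes, x$geom$n_pits,
              length(unique(x$trajectories$video_index)),
              x$sched$frames_per_video))
  cat(sprintf("  truth: U0 = %g per 100 probes, K = %g /s (%d sites bound)\n",
              gt$kin$U0, gt$kin$K, sum(is.finite(gt$binding$t_bind))))
  invisible(x)
}

#' Ground-truth bound fraction per video
#'
#' Bound probes per 100 probes at each video start, from the generator's
#' binding times (not from classification).
#'
#' @param sim A \code{pitbind_sim}.
#' @return Data frame with video_index, t_s, bound_per_100.
#' @export
true_bound_per_100 <- function(sim) {
  tv <- video_times(sim$sched)
  gt <- sim$ground_truth$binding
  data.frame(video_index = seq_along(tv), t_s = tv,
             bound_per_100 = vapply(tv, function(t)
               100 * sum(gt$t_bind <= t & t < gt$t_unbind) / nrow(gt),
               numeric(1)))
}

#' Simulate a topoisomer gel-lane intensity profile
#'
#' Renders the bands of a \code{\link{topoisomer_distribution}} as narrow
#' Gaussian peaks on a synthetic migration axis (equal band spacing; the real
#' mobility-vs-linking-number calibration is out of scope, which is why band
#' positions are returned for the fitting step) plus additive Gaussian noise.
#'
#' @param dist A \code{\link{topoisomer_distribution}}.
#' @param noise_sd Additive noise SD, in units of the unit-peak envelope.
#' @param seed Optional integer seed.
#' @param band_spacing Distance between adjacent bands on the axis.
#' @param band_sigma Width (SD) of each band peak.
#' @param axis_step Sampling step of the profile.
#' @return List with \code{profile} (position, intensity),
#'   \code{band_positions}, \code{band_dlk}, and the input distribution.
#' @export
simulate_gel_lane <- function(dist, noise_sd = 0, seed = NULL,
                              band_spacing = 10, band_sigma = 1.5,
                              axis_step = 0.25) {
  stopifnot(inherits(dist, "topo_distribution"))
  if (!is.null(seed)) set.seed(seed)
  pad <- 5 * band_sigma
  pos_bands <- pad + band_spacing * (dist$band_dlk - min(dist$band_dlk))
  axis <- seq(0, max(pos_bands) + pad, by = axis_step)
  intensity <- rep(0, length(axis))
  for (i in seq_along(pos_bands))
    intensity <- intensity + dist$band_intensities[i] *
      exp(-(axis - pos_bands[i])^2 / (2 * band_sigma^2))
  if (noise_sd > 0)
    intensity <- intensity + stats::rnorm(length(axis), 0, noise_sd)
  list(profile = data.frame(position = axis, intensity = intensity),
       band_positions = pos_bands, band_dlk = dist$band_dlk, dist = dist)
}
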