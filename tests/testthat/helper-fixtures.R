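# Shared small-scale fixtures. Everything is generated in code; sizes are
# chosen so the whole suite stays well inside the CI time budget.

quick_geom <- function(...) pit_geometry(n_pits = 4, pitch_um = 4, ...)

quick_sched <- function(frames = 20, n_videos = 3, interval = 60) {
  acquisition_schedule(frames_per_video = frames,
                       video_interval_s = interval,
                       total_duration_s = interval * max(n_videos - 1, 1))
}

# single-video schedule with an arbitrary number of frames
long_sched <- function(frames) {
  acquisition_schedule(frames_per_video = frames,
                       video_interval_s = frames * 0.05,
                       total_duration_s = frames * 0.05)
}

unconfined_geom <- function(n_pits = 1) {
  pit_geometry(diameter_um = Inf, pitch_um = Inf, n_pits = n_pits)
}

# simulate n unconfined single-state tracks of `steps` steps at dt, return
# the trajectory table (one trajectory per molecule)
unconfined_tracks <- function(n, steps, D, dt = 0.05, seed = 1) {
  geom <- unconfined_geom()
  sched <- acquisition_schedule(frames_per_video = steps + 1,
                                intra_video_interval_s = dt,
                                exposure_s = dt,
                                video_interval_s = (steps + 1) * dt,
                                total_duration_s = (steps + 1) * dt)
  sp <- species_params(d_free_um2_s = D, d_bound_um2_s = 0,
                       n_probes_per_pit = n)
  sim <- simulate_trajectories(geom, sched, sp,
                               kinetic_params(U0 = 0, K = 1e-6), seed = seed)
  as_trajectories(sim)
}

# brute-force time-averaged MSD oracle (plain R, independent of the C++ path)
msd_oracle <- function(x, y, lag) {
  n <- length(x) - lag
  mean((x[(1 + lag):(n + lag)] - x[1:n])^2 +
         (y[(1 + lag):(n + lag)] - y[1:n])^2)
}

# parameter-recovery experiment config (time sampling scaled to every 10 min;
# see the methods vignette for the scaling rationale). Supply K or k.
recovery_config <- function(seed, U0 = 10, K = 5e-4, k = NULL, n_fields = 10,
                            d_threshold = recovery_threshold()) {
  kin <- if (is.null(k)) list(U0 = U0, K = K)
         else list(U0 = U0, K = NA, k = k)
  run_config(seed = seed, n_fields = n_fields,
             schedule = list(video_interval_s = 600, frames_per_video = 50,
                             total_duration_s = 7200),
             kinetics = kin,
             classify = list(d_threshold = d_threshold))
}

# one condition-matched two-population calibration, shared across recovery
# runs (cached: calibration is deterministic given the seed)
recovery_threshold <- local({
  thr <- NULL
  function() {
    if (is.null(thr)) {
      set.seed(424242)
      sched <- acquisition_schedule(video_interval_s = 600,
                                    frames_per_video = 50,
                                    total_duration_s = 7200)
      ref_b <- reference_diffusion_sample(pit_geometry(), sched,
                                          species_params(), "bound", 300)
      ref_f <- reference_diffusion_sample(pit_geometry(), sched,
                                          species_params(), "free", 300)
      thr <<- calibrate_threshold(ref_b, ref_f)$d_threshold
    }
    thr
  }
})
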