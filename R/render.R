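# Fluorescence video rendering: emitters convolved with a Gaussian PSF,
# motion blur by sub-step averaging, constant background, Poisson shot noise.

# Photons deposited by one emitter at (x0, y0): Gaussian PSF integrated over
# pixel areas (difference of normal CDFs), restricted to a +/- 5 sigma window.
.add_emitter <- function(img, x0, y0, photons, psf_sigma, pixel_size) {
  w <- ncol(img); h <- nrow(img)
  halo <- 5 * psf_sigma
  c0 <- max(1L, floor((x0 - halo) / pixel_size) + 1L)
  c1 <- min(w, ceiling((x0 + halo) / pixel_size))
  r0 <- max(1L, floor((y0 - halo) / pixel_size) + 1L)
  r1 <- min(h, ceiling((y0 + halo) / pixel_size))
  if (c0 > c1 || r0 > r1) return(img)
  xe <- (c0 - 1):c1 * pixel_size           # pixel edges, x
  ye <- (r0 - 1):r1 * pixel_size
  px <- diff(stats::pnorm(xe, mean = x0, sd = psf_sigma))
  py <- diff(stats::pnorm(ye, mean = y0, sd = psf_sigma))
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + photons * outer(py, px)
  img
}

#' Render fluorescence videos from simulated trajectories
#'
#' Produces one 16-bit image stack per video. Each frame integrates emitter
#' positions over the exposure (motion blur via the simulation's sub-steps,
#' if present), convolves with a Gaussian PSF (integrated per pixel), adds a
#' constant background, and applies Poisson shot noise. Coordinates: pixel
#' (r, c) spans x in [(c-1), c] * pixel_size, y likewise (x right, y down).
#'
#' @param sim A \code{pitbind_sim} from \code{\link{simulate_trajectories}}
#'   (run with \code{n_substeps > 1} for motion blur).
#' @param videos Which video indices to render (default: all).
#' @param image_size_px Image side length in pixels (default: covers the pit
#'   array plus a 1 um margin).
#' @param noise Apply Poisson noise (\code{FALSE} gives the expected image).
#' @param seed Optional integer seed for the shot noise.
#' @return Named list of integer arrays (rows, cols, frames), one per video.
#' @export
render_video <- function(sim, videos = NULL, image_size_px = NULL,
                         noise = TRUE, seed = NULL) {
  stopifnot(inherits(sim, "pitbind_sim"))
  if (!is.null(seed)) set.seed(seed)
  sp <- sim$sp
  traj <- sim$trajectories
  if (is.null(videos)) videos <- sort(unique(traj$video_index))
  if (is.null(image_size_px)) {
    extent <- if (nrow(traj) > 0) max(traj$x_um, traj$y_um) + 1
      else if (is.finite(sim$geom$diameter_um))
        ceiling(sqrt(sim$geom$n_pits)) * sim$geom$pitch_um
      else 10
    image_size_px <- ceiling(extent / sp$pixel_size_um)
  }
  if (length(videos) == 0) videos <- seq_along(video_times(sim$sched))
  n_sub <- sim$n_substeps
  Fpv <- sim$sched$frames_per_video
  out <- list()
  for (v in videos) {
    stack <- array(0, dim = c(image_size_px, image_size_px, Fpv))
    if (n_sub > 1L && !is.null(sim$substeps)) {
      sx <- sim$substeps[[v]]$x; sy <- sim$substeps[[v]]$y
      for (f in seq_len(Fpv)) {
        img <- matrix(sp$background_photons, image_size_px, image_size_px)
        cols <- ((f - 1L) * n_sub + 1L):min(f * n_sub, ncol(sx))
        for (i in seq_len(nrow(sx))) for (s in cols)
          img <- .add_emitter(img, sx[i, s], sy[i, s],
                              sp$photons_per_frame / length(cols),
                              sp$psf_sigma_um, sp$pixel_size_um)
        stack[, , f] <- img
      }
    } else {
      tv <- traj[traj$video_index == v, ]
      for (f in seq_len(Fpv)) {
        img <- matrix(sp$background_photons, image_size_px, image_size_px)
        tf <- tv[tv$frame == f - 1L, ]
        for (i in seq_len(nrow(tf)))
          img <- .add_emitter(img, tf$x_um[i], tf$y_um[i],
                              sp$photons_per_frame,
                              sp$psf_sigma_um, sp$pixel_size_um)
        stack[, , f] <- img
      }
    }
    if (noise) {
      stack[] <- stats::rpois(length(stack), lambda = stack)
    }
    stack[] <- pmin(round(stack), 65535)
    out[[as.character(v)]] <- stack
  }
  out
}
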