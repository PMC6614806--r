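# Spot detection, trajectory linking, and MSD-based diffusion estimation.

# separable Gaussian blur with replicate-edge padding
.blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  h <- nrow(img); w <- ncol(img)
  pad <- img[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in 0:(2L * r)) out <- out + k[j + 1] * pad[(1L + j):(h + j), , drop = FALSE]
  pad <- out[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (j in 0:(2L * r)) out <- out + k[j + 1] * pad[, (1L + j):(w + j), drop = FALSE]
  out
}

# strict-threshold local maxima over a 3x3 neighborhood
.local_maxima <- function(img) {
  h <- nrow(img); w <- ncol(img)
  padded <- matrix(-Inf, h + 2, w + 2)
  padded[2:(h + 1), 2:(w + 1)] <- img
  res <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (img >= padded[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)])
  }
  res
}

#' Detect fluorescent spots in an image stack
#'
#' Band-pass (difference-of-Gaussians) filtering, local-maximum candidate
#' selection above a robust intensity threshold, and sub-pixel centroid
#' refinement on the background-subtracted image. One detection per
#' resolvable emitter per frame.
#'
#' @param stack 3-D array (rows, cols, frames) or a single matrix.
#' @param pixel_size_um Pixel size, um.
#' @param psf_sigma_um Approximate PSF sigma, um (sets the band-pass scales).
#' @param threshold_sd Detection threshold in robust (MAD) noise SDs of the
#'   band-passed image.
#' @param video_index Video index recorded in the output.
#' @param centroid_radius_px Half-width of the centroid refinement window.
#' @return Data frame: video_index, frame (0-based), x_um, y_um, intensity,
#'   width_um.
#' @export
detect_spots <- function(stack, pixel_size_um, psf_sigma_um = 0.15,
                         threshold_sd = 5, video_index = 1L,
                         centroid_radius_px = NULL) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  if (length(stack) == 0 || length(dim(stack)) != 3)
    stop("stack must be a non-empty (rows, cols, frames) array")
  sig_px <- max(psf_sigma_um / pixel_size_um, 0.8)
  if (is.null(centroid_radius_px)) centroid_radius_px <- ceiling(2.5 * sig_px)
  res <- vector("list", dim(stack)[3])
  for (f in seq_len(dim(stack)[3])) {
    img <- stack[, , f]
    dog <- .blur(img, sig_px) - .blur(img, 2 * sig_px)
    noise <- stats::mad(dog)
    if (noise == 0) noise <- stats::sd(dog)
    if (is.na(noise) || noise == 0) noise <- .Machine$double.eps
    cand <- which(.local_maxima(dog) & dog > threshold_sd * noise, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    bg <- stats::median(img)
    rows <- list()
    h <- nrow(img); w <- ncol(img); rad <- centroid_radius_px
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1]; c <- cand[i, 2]
      rr <- max(1, r - rad):min(h, r + rad)
      cc <- max(1, c - rad):min(w, c + rad)
      win <- pmax(img[rr, cc, drop = FALSE] - bg, 0)
      tot <- sum(win)
      if (tot <= 0) next
      xc <- sum(win %*% (cc - 0.5)) / tot   # pixel-center coordinates
      yc <- sum((rr - 0.5) %*% win) / tot
      vx <- sum(win %*% ((cc - 0.5) - xc)^2) / tot
      vy <- sum(((rr - 0.5) - yc)^2 %*% win) / tot
      rows[[length(rows) + 1]] <- c(f - 1, xc * pixel_size_um,
                                    yc * pixel_size_um, tot,
                                    sqrt((vx + vy) / 2) * pixel_size_um)
    }
    if (length(rows))
      res[[f]] <- do.call(rbind, rows)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(video_index = integer(), frame = integer(),
                      x_um = numeric(), y_um = numeric(),
                      intensity = numeric(), width_um = numeric()))
  m <- do.call(rbind, res)
  data.frame(video_index = as.integer(video_index), frame = as.integer(m[, 1]),
             x_um = m[, 2], y_um = m[, 3], intensity = m[, 4],
             width_um = m[, 5])
}

#' Link detections into trajectories by greedy nearest-neighbor assignment
#'
#' Frame-to-frame links are assigned in order of increasing displacement
#' (ties: lower detection row index, then lower trajectory id), rejecting
#' displacements above \code{max_disp_um}; tracks may bridge up to
#' \code{max_gap} missing frames; unlinked detections start new trajectories.
#' Linking never crosses video boundaries (videos are minutes apart).
#'
#' @param detections Data frame from \code{\link{detect_spots}}.
#' @param max_disp_um Maximum per-link displacement, um.
#' @param max_gap Maximum number of bridged missing frames (default 1).
#' @return The detections with a \code{trajectory_id} column, ordered by
#'   trajectory and frame.
#' @export
link_trajectories <- function(detections, max_disp_um, max_gap = 1L) {
  if (nrow(detections) == 0) {
    detections$trajectory_id <- integer(0)
    return(detections)
  }
  detections <- detections[order(detections$video_index, detections$frame), ]
  detections$trajectory_id <- NA_integer_
  next_id <- 1L
  for (v in unique(detections$video_index)) {
    idx_v <- which(detections$video_index == v)
    frames <- sort(unique(detections$frame[idx_v]))
    # active tracks: id -> (x, y, last frame)
    act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
    act_f <- integer(0)
    for (f in frames) {
      di <- idx_v[detections$frame[idx_v] == f]
      live <- which(f - act_f <= max_gap + 1L)
      assigned_det <- rep(FALSE, length(di))
      used_track <- rep(FALSE, length(live))
      if (length(live) && length(di)) {
        dx <- outer(act_x[live], detections$x_um[di], "-")
        dy <- outer(act_y[live], detections$y_um[di], "-")
        dist <- sqrt(dx^2 + dy^2)
        cand <- which(dist <= max_disp_um, arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(dist[cand], cand[, 2], act_id[live][cand[, 1]])
          for (ci in ord) {
            tr <- cand[ci, 1]; de <- cand[ci, 2]
            if (used_track[tr] || assigned_det[de]) next
            used_track[tr] <- TRUE; assigned_det[de] <- TRUE
            id <- act_id[live[tr]]
            detections$trajectory_id[di[de]] <- id
            act_x[live[tr]] <- detections$x_um[di[de]]
            act_y[live[tr]] <- detections$y_um[di[de]]
            act_f[live[tr]] <- f
          }
        }
      }
      if (any(!assigned_det)) {
        new_d <- di[!assigned_det]
        ids <- next_id + seq_along(new_d) - 1L
        next_id <- next_id + length(new_d)
        detections$trajectory_id[new_d] <- ids
        act_id <- c(act_id, ids)
        act_x <- c(act_x, detections$x_um[new_d])
        act_y <- c(act_y, detections$y_um[new_d])
        act_f <- c(act_f, rep(f, length(new_d)))
      }
    }
  }
  detections[order(detections$trajectory_id, detections$frame), ]
}

#' Convert a simulation to a trajectory table
#'
#' Each (molecule, video) pair becomes one trajectory: videos are separated
#' by minutes, so positions are not continuous across them.
#'
#' @param sim A \code{pitbind_sim}.
#' @return Trajectory data frame with a unique \code{trajectory_id}.
#' @export
as_trajectories <- function(sim) {
  stopifnot(inherits(sim, "pitbind_sim"))
  tr <- sim$trajectories
  n_mol <- sim$ground_truth$n_probes
  tr$trajectory_id <- (tr$video_index - 1L) * n_mol + tr$molecule_id
  tr[order(tr$trajectory_id, tr$frame), ]
}

# MSD at lags 1..n_lags for one gapped track (exact frame lags)
.msd_gapped <- function(frame, x, y, n_lags) {
  msd <- rep(NA_real_, n_lags); np <- integer(n_lags)
  for (l in seq_len(n_lags)) {
    j <- match(frame + l, frame)
    ok <- !is.na(j)
    np[l] <- sum(ok)
    if (np[l] > 0)
      msd[l] <- mean((x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2)
  }
  list(msd = msd, n_pairs = np)
}

#' Estimate per-trajectory diffusion coefficients from the MSD
#'
#' Computes the time-averaged MSD at lags 1..\code{n_lags} and fits
#' \eqn{MSD(\ell) = 4 D \ell \Delta t} through the origin by weighted least
#' squares (weights \eqn{n_{pairs}(\ell)/\ell}, down-weighting long, noisy
#' lags). Short lags limit confinement bias at 50 ms sampling. Negative
#' fitted slopes clamp to \code{d_hat = 0} with \code{clamped = TRUE}.
#'
#' @param traj Trajectory data frame with columns trajectory_id, frame,
#'   x_um, y_um (e.g. from \code{\link{link_trajectories}} or
#'   \code{\link{as_trajectories}}).
#' @param dt Frame interval, s.
#' @param n_lags Number of MSD lags in the fit (default 4).
#' @param min_track_length Minimum points per track; shorter tracks are
#'   dropped with a warning.
#' @return Data frame: trajectory_id, video_index (if available), d_hat,
#'   se_d, n_points, clamped.
#' @export
estimate_diffusion <- function(traj, dt, n_lags = 4L,
                               min_track_length = 10L) {
  stopifnot(all(c("trajectory_id", "frame", "x_um", "y_um") %in% names(traj)))
  traj <- traj[order(traj$trajectory_id, traj$frame), ]
  ids <- unique(traj$trajectory_id)
  len <- as.integer(table(factor(traj$trajectory_id, levels = ids)))
  short <- len < min_track_length
  if (any(short))
    warning(sum(short), " trajectories shorter than ", min_track_length,
            " points were skipped")
  keep_ids <- ids[!short]
  if (!length(keep_ids))
    return(data.frame(trajectory_id = ids[0], video_index = integer(),
                      d_hat = numeric(), se_d = numeric(),
                      n_points = integer(), clamped = logical()))
  traj <- traj[traj$trajectory_id %in% keep_ids, ]
  len <- len[!short]
  # contiguous-frame fast path (C++); exact-lag R path for gapped tracks
  start0 <- c(0L, cumsum(len)[-length(len)])
  gap_free <- !as.logical(tapply(traj$frame, factor(traj$trajectory_id,
                                                    levels = keep_ids),
                                 function(f) any(diff(f) != 1L)))
  g <- cpp_msd_grouped(traj$x_um, traj$y_um, start0, len, n_lags)
  msd <- g$msd; npair <- g$n_pairs
  if (any(!gap_free)) {
    for (i in which(!gap_free)) {
      sel <- (start0[i] + 1L):(start0[i] + len[i])
      r <- .msd_gapped(traj$frame[sel], traj$x_um[sel], traj$y_um[sel], n_lags)
      msd[i, ] <- r$msd; npair[i, ] <- r$n_pairs
    }
  }
  lags <- seq_len(n_lags)
  d_hat <- se_d <- numeric(length(keep_ids))
  for (i in seq_along(keep_ids)) {
    ok <- !is.na(msd[i, ]) & npair[i, ] > 0
    l <- lags[ok]; m <- msd[i, ok]; w <- npair[i, ok] / l
    sl <- sum(w * l * m) / sum(w * l^2)
    res <- m - sl * l
    dof <- max(sum(ok) - 1L, 1L)
    var_sl <- sum(w^2 * l^2 * res^2) / sum(w * l^2)^2 * sum(ok) / dof
    d_hat[i] <- sl / (4 * dt)
    se_d[i] <- sqrt(max(var_sl, 0)) / (4 * dt)
  }
  clamped <- d_hat < 0
  d_hat[clamped] <- 0
  out <- data.frame(trajectory_id = keep_ids, d_hat = d_hat, se_d = se_d,
                    n_points = len, clamped = clamped)
  for (extra in c("video_index", "pit_id", "state", "molecule_id")) {
    if (extra %in% names(traj))
      out[[extra]] <- traj[[extra]][match(keep_ids, traj$trajectory_id)]
  }
  out
}
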