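# Bound/free classification by threshold diffusion coefficient, and binding
# counts per 100 probes per video.

#' Calibrate a threshold diffusion coefficient from reference populations
#'
#' With \code{method = "two_population"}, brute-force grid search for the
#' threshold minimizing total misclassification (bound molecules at or above
#' the threshold plus free molecules below it) over a grid between the two
#' sample medians, with grid step 1\% of the inter-median range. The returned
#' threshold is the midpoint of the minimal-error plateau; the procedure is
#' deterministic. Crowded conditions (e.g. 20\% w/v PEG, which slows free
#' probes) are handled by recalibrating on condition-matched reference
#' samples and storing one threshold per condition.
#'
#' @param d_bound_sample Diffusion estimates of known bound complexes
#'   (numeric vector or a data frame with a \code{d_hat} column).
#' @param d_free_sample Likewise for known free probes.
#' @param method "two_population" (calibrated) or "fixed" (pass-through of
#'   \code{d_threshold}).
#' @param d_threshold Threshold for \code{method = "fixed"}, um^2/s.
#' @param calibration_condition Optional \code{\link{solution_condition}}
#'   recorded with the model.
#' @param grid_frac Grid step as a fraction of the inter-median range.
#' @return An object of class \code{threshold_model}.
#' @export
calibrate_threshold <- function(d_bound_sample = NULL, d_free_sample = NULL,
                                method = c("two_population", "fixed"),
                                d_threshold = NULL,
                                calibration_condition = NULL,
                                grid_frac = 0.01) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(d_threshold) || d_threshold <= 0)
      stop("fixed method requires d_threshold > 0")
    return(structure(list(d_threshold = d_threshold, method = "fixed",
                          calibration_condition = calibration_condition),
                     class = "threshold_model"))
  }
  db <- if (is.data.frame(d_bound_sample)) d_bound_sample$d_hat else d_bound_sample
  df_ <- if (is.data.frame(d_free_sample)) d_free_sample$d_hat else d_free_sample
  if (!length(db) || !length(df_)) stop("both reference samples must be non-empty")
  mb <- stats::median(db); mf <- stats::median(df_)
  if (mb >= mf) stop("populations not separable")
  grid <- seq(mb, mf, by = grid_frac * (mf - mb))
  err <- vapply(grid, function(thr)
    sum(db >= thr) + sum(df_ < thr), numeric(1))
  best <- which(err == min(err))
  # midpoint of the (contiguous) minimal-error plateau
  runs <- split(best, cumsum(c(1, diff(best) != 1)))
  plateau <- runs[[which.max(lengths(runs))]]
  thr <- (grid[min(plateau)] + grid[max(plateau)]) / 2
  structure(list(d_threshold = thr, method = "two_population",
                 calibration_condition = calibration_condition,
                 misclassified = min(err),
                 n_reference = length(db) + length(df_)),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("threshold_model (%s): d_threshold = %.4g um^2/s\n",
              x$method, x$d_threshold))
  invisible(x)
}

#' Classify trajectories as bound complexes or free probes
#'
#' A molecule is a bound probe-plasmid complex iff its diffusion estimate is
#' strictly below the threshold; the boundary case \code{d_hat == d_threshold}
#' is assigned "free". Deterministic; one label per trajectory (binding is
#' treated as irreversible).
#'
#' @param estimates Data frame from \code{\link{estimate_diffusion}}.
#' @param model A \code{\link{calibrate_threshold}} result.
#' @return \code{estimates} with a \code{label} column ("bound"/"free").
#' @export
classify_trajectories <- function(estimates, model) {
  stopifnot(inherits(model, "threshold_model"), "d_hat" %in% names(estimates))
  estimates$label <- ifelse(estimates$d_hat < model$d_threshold,
                            "bound", "free")
  estimates
}

#' Count binding events per 100 probes per video
#'
#' @param labeled Labeled estimates from \code{\link{classify_trajectories}};
#'   must carry \code{video_index}.
#' @param sched An \code{\link{acquisition_schedule}} (supplies video start
#'   times).
#' @param denominator "observed" uses the number of classified trajectories
#'   per video; "declared" uses \code{n_probes_declared} (for regimes where
#'   fast free probes blur beyond detectability and deflate the observed
#'   denominator).
#' @param n_probes_declared Probe count per video for the declared mode.
#' @return Data frame: video_index, t_s, bound_per_100, n_probes.
#' @export
count_binding <- function(labeled, sched,
                          denominator = c("observed", "declared"),
                          n_probes_declared = NULL) {
  denominator <- match.arg(denominator)
  stopifnot("video_index" %in% names(labeled), "label" %in% names(labeled))
  if (denominator == "declared" && is.null(n_probes_declared))
    stop("declared denominator requires n_probes_declared")
  tv <- video_times(sched)
  vids <- sort(unique(labeled$video_index))
  rows <- lapply(vids, function(v) {
    sub <- labeled[labeled$video_index == v, ]
    n <- if (denominator == "observed") nrow(sub) else n_probes_declared
    if (n == 0) {
      warning("no trajectories in video ", v, "; skipped")
      return(NULL)
    }
    data.frame(video_index = v, t_s = tv[v],
               bound_per_100 = 100 * sum(sub$label == "bound") / n,
               n_probes = n)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
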