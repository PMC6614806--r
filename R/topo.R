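# Topoisomer distribution analysis: linking-number / superhelical-density
# conversions and Gaussian-envelope fitting of gel-lane band intensities.

#' Superhelical density from linking-number difference
#'
#' \eqn{\sigma = \Delta Lk / Lk_0} with \eqn{Lk_0 =} plasmid length / helical
#' repeat. Default helical repeat is 10.5 bp/turn (B-DNA).
#'
#' @param dlk Linking-number difference \eqn{\Delta Lk}, turns.
#' @param plasmid_length_bp Plasmid length, bp (pUC19 = 2686).
#' @param helical_repeat_bp Helical repeat, bp/turn.
#' @return Superhelical density (dimensionless).
#' @examples
#' sigma_from_dlk(-25.8, 2686) # ~ -0.101
#' @export
sigma_from_dlk <- function(dlk, plasmid_length_bp = 2686,
                           helical_repeat_bp = 10.5) {
  if (plasmid_length_bp <= 0) stop("plasmid_length_bp must be > 0")
  dlk / (plasmid_length_bp / helical_repeat_bp)
}

#' @rdname sigma_from_dlk
#' @param sigma Superhelical density.
#' @export
dlk_from_sigma <- function(sigma, plasmid_length_bp = 2686,
                           helical_repeat_bp = 10.5) {
  if (plasmid_length_bp <= 0) stop("plasmid_length_bp must be > 0")
  sigma * (plasmid_length_bp / helical_repeat_bp)
}

#' Gaussian topoisomer distribution
#'
#' A preparation of closed circular plasmids carries a Gaussian distribution
#' of superhelical densities, characterized by its mean \eqn{\langle\sigma\rangle}
#' and standard deviation \eqn{s_\sigma}. Band intensities are the Gaussian
#' envelope evaluated at integer \eqn{\Delta Lk} (topoisomers differ by whole
#' linking numbers), normalized to unit peak.
#'
#' @param mean_sigma Mean superhelical density (negative = underwound).
#' @param sd_sigma Standard deviation of superhelical density; must be > 0.
#' @param plasmid_length_bp Plasmid length, bp.
#' @param helical_repeat_bp Helical repeat, bp/turn.
#' @param n_sd Half-width of the retained band grid, in units of sd.
#' @return An object of class \code{topo_distribution} with fields
#'   \code{band_dlk}, \code{band_intensities}, \code{lk0}, and the inputs.
#' @examples
#' topoisomer_distribution(-0.101, 0.004)
#' @export
topoisomer_distribution <- function(mean_sigma, sd_sigma,
                                    plasmid_length_bp = 2686,
                                    helical_repeat_bp = 10.5, n_sd = 4) {
  if (plasmid_length_bp <= 0) stop("plasmid_length_bp must be > 0")
  if (sd_sigma <= 0) stop("sd_sigma must be > 0")
  lk0 <- plasmid_length_bp / helical_repeat_bp
  mu_dlk <- mean_sigma * lk0
  sd_dlk <- sd_sigma * lk0
  band_dlk <- seq(floor(mu_dlk - n_sd * sd_dlk), ceiling(mu_dlk + n_sd * sd_dlk))
  intens <- exp(-(band_dlk - mu_dlk)^2 / (2 * sd_dlk^2))
  intens <- intens / max(intens)
  structure(list(plasmid_length_bp = plasmid_length_bp,
                 helical_repeat_bp = helical_repeat_bp, lk0 = lk0,
                 mean_sigma = mean_sigma, sd_sigma = sd_sigma,
                 band_dlk = band_dlk, band_intensities = intens),
            class = "topo_distribution")
}

#' Fit a Gaussian topoisomer envelope to a gel-lane intensity profile
#'
#' Integrates background-subtracted intensity in a window around each band
#' position (local linear baseline through the window edges), then fits a
#' Gaussian envelope over the caller-supplied \eqn{\Delta Lk} assignment by
#' weighted least squares, and converts the fitted mean/SD to superhelical
#' density units. The fit is invariant to global intensity scaling.
#'
#' @param profile Two-column data frame (position, intensity), or path to a
#'   CSV with those columns.
#' @param band_positions Migration-axis positions of the resolvable bands.
#' @param band_dlk Integer \eqn{\Delta Lk} assigned to each band (same length).
#' @param plasmid_length_bp,helical_repeat_bp Conversion constants.
#' @param window_halfwidth Half-width of the integration window; default is
#'   45\% of the minimal band spacing.
#' @return A list with \code{mean_sigma}, \code{sd_sigma}, \code{mean_dlk},
#'   \code{sd_dlk}, per-band integrated intensities, and the fit object.
#' @export
fit_band_distribution <- function(profile, band_positions, band_dlk,
                                  plasmid_length_bp = 2686,
                                  helical_repeat_bp = 10.5,
                                  window_halfwidth = NULL) {
  if (is.character(profile))
    profile <- utils::read.csv(profile)
  stopifnot(ncol(profile) >= 2)
  names(profile)[1:2] <- c("position", "intensity")
  if (length(band_positions) < 3)
    stop("envelope not identifiable: need >= 3 resolvable bands")
  if (length(band_dlk) != length(band_positions))
    stop("band_dlk and band_positions must have equal length")
  if (is.null(window_halfwidth))
    window_halfwidth <- 0.45 * min(diff(sort(band_positions)))

  band_int <- vapply(band_positions, function(p) {
    sel <- profile$position >= p - window_halfwidth &
      profile$position <= p + window_halfwidth
    if (sum(sel) < 3) return(0)
    x <- profile$position[sel]; y <- profile$intensity[sel]
    # local linear baseline through the window-edge intensities
    ne <- max(2L, ceiling(sum(sel) * 0.1))
    i1 <- seq_len(ne); i2 <- seq.int(length(x) - ne + 1L, length(x))
    bx <- c(mean(x[i1]), mean(x[i2])); by <- c(mean(y[i1]), mean(y[i2]))
    base <- by[1] + (by[2] - by[1]) * (x - bx[1]) / (bx[2] - bx[1])
    sum(pmax(y - base, 0)) * mean(diff(x))
  }, numeric(1))

  if (sum(band_int > 0) < 3)
    stop("envelope not identifiable: fewer than 3 bands with signal")

  # moment starting values, then weighted nonlinear refinement
  w <- band_int / sum(band_int)
  mu0 <- sum(w * band_dlk)
  sd0 <- sqrt(max(sum(w * (band_dlk - mu0)^2), 1e-6))
  a0 <- max(band_int)
  df <- data.frame(d = band_dlk, y = band_int)
  fit <- tryCatch(
    stats::nls(y ~ a * exp(-(d - mu)^2 / (2 * s^2)), data = df,
               start = list(a = a0, mu = mu0, s = sd0),
               weights = pmax(band_int, 1e-12 * a0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE),
               algorithm = "port",
               lower = c(a = 0, mu = -Inf, s = 1e-6)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    mu_hat <- unname(cf["mu"]); sd_hat <- unname(cf["s"])
  } else {
    mu_hat <- mu0; sd_hat <- sd0
  }
  lk0 <- plasmid_length_bp / helical_repeat_bp
  list(mean_sigma = mu_hat / lk0, sd_sigma = sd_hat / lk0,
       mean_dlk = mu_hat, sd_dlk = sd_hat,
       band_dlk = band_dlk, band_intensities = band_int, fit = fit)
}
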