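# Solution-condition bookkeeping: ionic strength, crowder excluded volume,
# semidilute crossover.
#
# Unit conventions used throughout the package:
#   concentrations        mM (millimolar)
#   % w/v                 g solute per 100 mL solution, expressed as percent
#   % v/v                 mL excluded volume per 100 mL solution, as percent
#   specific excluded volume  mL/g, so  % v/v = % w/v * (mL/g)
#   temperature           degrees Celsius

# Ethylene oxide repeat unit of PEG, Da.
PEG_MONOMER_MW <- 44.05

# Calibrated specific excluded volumes (mL/g), keyed by species and nominal
# molecular weight. The 8 kDa PEG value is back-derived from the published
# 1% w/v -> 1.31% v/v correspondence for that crowder.
.sev_table <- data.frame(
  species = "PEG",
  mw_da = 8000,
  sev_ml_per_g = 1.31,
  stringsAsFactors = FALSE
)

# Calibrated buffer ionic contributions (mM). Only NaCl dissociates fully at
# pH 8.0; Tris and HEPES contribute partially. The reference composition
# (12 mM Tris + 25 mM HEPES, pH 8.0) contributes 12.5 mM of dissociated ions.
.buffer_table <- data.frame(
  tris_mM = 12, hepes_mM = 25, ph = 8.0, ionic_mM = 12.5
)

#' Buffer composition and its ionic contribution
#'
#' Describes the Tris/HEPES buffering system and the total concentration of
#' dissociated buffer ions it contributes to the solution's ionic strength.
#' By default the contribution is a calibrated lookup (12.5 mM for the
#' reference 12 mM Tris + 25 mM HEPES composition at pH 8.0); it is not
#' computed from Henderson-Hasselbalch ionization because standard pKa values
#' do not reproduce the calibrated figure. An explicit
#' \code{ionic_contribution_mM} overrides the lookup, and
#' \code{method = "henderson-hasselbalch"} selects an approximate computed
#' mode (see \code{\link{hh_ionic_contribution}}).
#'
#' @param tris_mM Tris concentration, mM.
#' @param hepes_mM HEPES concentration, mM.
#' @param ph Solution pH.
#' @param ionic_contribution_mM Optional explicit ionic contribution, mM.
#' @param method "calibrated" (lookup/override) or "henderson-hasselbalch".
#' @return An object of class \code{buffer_model}.
#' @examples
#' buffer_model() # reference composition, 12.5 mM
#' @export
buffer_model <- function(tris_mM = 12, hepes_mM = 25, ph = 8.0,
                         ionic_contribution_mM = NULL,
                         method = c("calibrated", "henderson-hasselbalch")) {
  method <- match.arg(method)
  stopifnot(is.numeric(tris_mM), is.numeric(hepes_mM), length(ph) == 1)
  if (tris_mM < 0 || hepes_mM < 0)
    stop("buffer concentrations must be non-negative")
  if (is.null(ionic_contribution_mM)) {
    if (method == "henderson-hasselbalch") {
      ionic_contribution_mM <- hh_ionic_contribution(tris_mM, hepes_mM, ph)
    } else {
      hit <- .buffer_table$tris_mM == tris_mM &
        .buffer_table$hepes_mM == hepes_mM &
        abs(.buffer_table$ph - ph) < 1e-9
      if (!any(hit))
        stop("no calibrated ionic contribution for this buffer composition; ",
             "supply ionic_contribution_mM explicitly")
      ionic_contribution_mM <- .buffer_table$ionic_mM[which(hit)[1]]
    }
  }
  if (ionic_contribution_mM < 0)
    stop("ionic_contribution_mM must be >= 0")
  structure(list(tris_mM = tris_mM, hepes_mM = hepes_mM, ph = ph,
                 ionic_contribution_mM = ionic_contribution_mM),
            class = "buffer_model")
}

#' Henderson-Hasselbalch buffer ionization (approximate, optional mode)
#'
#' Computes the dissociated-ion contribution of Tris (pKa 8.07) and HEPES
#' (pKa 7.48) at a given pH as \code{tris * f_cationic + hepes * f_anionic}.
#' This mode is provided for exploration only; it does not reproduce the
#' calibrated 12.5 mM reference value and is not used for any reported
#' quantity.
#'
#' @param tris_mM,hepes_mM Buffer concentrations, mM.
#' @param ph Solution pH.
#' @param pka_tris,pka_hepes Acid dissociation constants.
#' @return Ionic contribution, mM.
#' @export
hh_ionic_contribution <- function(tris_mM, hepes_mM, ph,
                                  pka_tris = 8.07, pka_hepes = 7.48) {
  f_tris <- 1 / (1 + 10^(ph - pka_tris))    # protonated (cationic) fraction
  f_hepes <- 1 / (1 + 10^(pka_hepes - ph))  # sulfonate-deprotonated fraction
  tris_mM * f_tris + hepes_mM * f_hepes
}

#' Crowding agent description
#'
#' An inert polymer (PEG or PVP) occupying solution volume. The specific
#' excluded volume (mL of excluded volume per gram of polymer) defaults to a
#' calibrated constant for 8 kDa PEG (1.31 mL/g); other species require an
#' explicit value. The degree of polymerization \code{n_monomers} defaults to
#' \code{mw_da / 44.05} (ethylene oxide repeat) for PEG and is used only by
#' \code{\link{crossover_concentration}}.
#'
#' @param species "PEG", "PVP" or "none".
#' @param mw_da Polymer molecular weight, Da.
#' @param conc_wv_pct Concentration, % w/v (g per 100 mL, as percent).
#' @param specific_excluded_volume mL/g; calibrated default for 8 kDa PEG.
#' @param n_monomers Degree of polymerization N (dimensionless).
#' @return An object of class \code{crowder}.
#' @examples
#' excluded_volume_fraction(crowder("PEG", 8000, 10)) # 13.1
#' @export
crowder <- function(species = c("none", "PEG", "PVP"), mw_da = 0,
                    conc_wv_pct = 0, specific_excluded_volume = NULL,
                    n_monomers = NULL) {
  species <- match.arg(species)
  if (conc_wv_pct < 0) stop("conc_wv_pct must be >= 0")
  if (species == "none") {
    specific_excluded_volume <- 0
    n_monomers <- NA_real_
    conc_wv_pct <- 0
  } else {
    if (is.null(specific_excluded_volume)) {
      hit <- .sev_table$species == species & .sev_table$mw_da == mw_da
      if (!any(hit))
        stop("no calibrated specific excluded volume for ", species, " ",
             mw_da, " Da; supply specific_excluded_volume (mL/g)")
      specific_excluded_volume <- .sev_table$sev_ml_per_g[which(hit)[1]]
    }
    if (specific_excluded_volume <= 0)
      stop("specific_excluded_volume must be > 0 for a real crowder")
    if (is.null(n_monomers)) {
      n_monomers <- if (species == "PEG" && mw_da > 0)
        mw_da / PEG_MONOMER_MW else NA_real_
    }
    if (!is.na(n_monomers) && n_monomers < 1)
      stop("n_monomers must be >= 1")
  }
  structure(list(species = species, mw_da = mw_da, conc_wv_pct = conc_wv_pct,
                 specific_excluded_volume = specific_excluded_volume,
                 n_monomers = n_monomers),
            class = "crowder")
}

#' Experimental solution condition
#'
#' @param nacl_mM NaCl concentration, mM.
#' @param buffer A \code{\link{buffer_model}}.
#' @param crowd A \code{\link{crowder}}.
#' @param temperature_c Temperature, degrees C (default 37, the assay
#'   temperature).
#' @return An object of class \code{solution_condition}.
#' @examples
#' total_ionic_strength(solution_condition(137.5)) # 150
#' @export
solution_condition <- function(nacl_mM = 137.5, buffer = buffer_model(),
                               crowd = crowder("none"), temperature_c = 37) {
  if (nacl_mM < 0) stop("nacl_mM must be >= 0")
  if (temperature_c <= 0 || temperature_c >= 100)
    stop("temperature_c must lie in (0, 100)")
  stopifnot(inherits(buffer, "buffer_model"), inherits(crowd, "crowder"))
  structure(list(nacl_mM = nacl_mM, buffer = buffer, crowder = crowd,
                 temperature_c = temperature_c),
            class = "solution_condition")
}

#' Total ionic strength of a solution condition
#'
#' NaCl dissociates fully; the buffer contributes its calibrated
#' dissociated-ion concentration. For the reference buffer this reproduces
#' the 22.5-150 mM experimental range as NaCl goes from 10 to 137.5 mM.
#'
#' @param cond A \code{\link{solution_condition}}.
#' @return Total ionic strength, mM.
#' @export
total_ionic_strength <- function(cond) {
  stopifnot(inherits(cond, "solution_condition"))
  cond$nacl_mM + cond$buffer$ionic_contribution_mM
}

#' Excluded-volume fraction of a crowder
#'
#' Linear conversion from mass concentration to occupied volume:
#' \code{\% v/v = \% w/v x specific_excluded_volume (mL/g)} (since % w/v is
#' g per 100 mL, multiplying by mL/g gives mL per 100 mL directly).
#'
#' @param crowd A \code{\link{crowder}}.
#' @return Excluded volume, % v/v.
#' @export
excluded_volume_fraction <- function(crowd) {
  stopifnot(inherits(crowd, "crowder"))
  crowd$conc_wv_pct * crowd$specific_excluded_volume
}

#' Semidilute crossover concentration
#'
#' Flory scaling \eqn{c^* = N^{-4/5}} for the polymer overlap concentration,
#' expressed as % w/v. N is the degree of polymerization and must be supplied
#' by the caller (directly or via the crowder's \code{n_monomers}); the
#' function makes no claim about any particular printed value of c*.
#'
#' @param x A \code{\link{crowder}} or a numeric N.
#' @return Crossover concentration, % w/v.
#' @examples
#' crossover_concentration(32) # 6.25
#' @export
crossover_concentration <- function(x) {
  n <- if (inherits(x, "crowder")) x$n_monomers else x
  if (is.null(n) || anyNA(n)) stop("degree of polymerization N is not set")
  if (any(n < 1)) stop("N must be >= 1")
  100 * n^(-4 / 5)
}

#' @export
print.solution_condition <- function(x, ...) {
  cat(sprintf("solution_condition: %.4g mM NaCl + buffer (%.4g mM ions) = %.4g mM total\n",
              x$nacl_mM, x$buffer$ionic_contribution_mM,
              total_ionic_strength(x)))
  if (x$crowder$species != "none")
    cat(sprintf("  crowder: %s %g Da, %.4g%% w/v (%.4g%% v/v excluded)\n",
                x$crowder$species, x$crowder$mw_da, x$crowder$conc_wv_pct,
                excluded_volume_fraction(x$crowder)))
  cat(sprintf("  temperature: %g C\n", x$temperature_c))
  invisible(x)
}
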