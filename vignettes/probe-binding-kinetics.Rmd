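---
title: "Methods: simulating and analyzing probe-plasmid binding in nanopit confinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing probe-plasmid binding in nanopit confinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitbind)
```

## The assay and the model

`pitbind` implements the analysis chain for a single-molecule assay of
supercoil-induced DNA site unwinding. Negatively supercoiled plasmids (e.g.
pUC19) carry an AT-rich site that can open under torsional stress; a
fluorescently labeled oligonucleotide probe hybridizes only when the site is
open. Plasmids and probes are confined together in femtoliter glass nanopits
(3 µm diameter x 500 nm deep) and imaged repeatedly (videos every minute
over ~2 h, 50 ms exposure). A probe bound to a plasmid diffuses far more
slowly than a free probe, so each tracked molecule can be classified
bound/free from its fitted diffusion coefficient, and the per-video count of
bound complexes per 100 probes forms a binding time course.

Because probes are in excess and unwinding/rewinding is slow compared to
binding, the bound concentration follows the saturating pseudo-first-order
law

$$B(t) = U_0\,(1 - e^{-Kt}), \qquad K = k\,(P_0 - U_0),$$

where $U_0$ is the initial concentration of unwound (open-site) plasmids,
$P_0$ the initial probe concentration, $K$ the observed exponential rate and
$k$ the true second-order rate constant. Fitting $B(t)$ yields $U_0$ and $K$;
$k$ follows by the identity above. The scientific decomposition the pipeline
supports is exactly this: whether a condition changes *unwinding* ($U_0$) or
the *rate of binding to an open site* ($k$).

All concentrations are kept in "per 100 probes" units ($P_0 = 100$), so $k$
has units (per-100-probes)$^{-1}$ s$^{-1}$. Absolute molar concentrations
are not recoverable from the assay and are not attempted.

## Units

| quantity | unit |
|---|---|
| concentrations (NaCl, buffer ions) | mM |
| crowder concentration | % w/v = g per 100 mL, as percent |
| excluded volume | % v/v; `% v/v = % w/v x specific excluded volume (mL/g)` |
| lengths | µm |
| diffusion coefficients | µm²/s |
| times | s |
| binding quantities ($B$, $U_0$, $P_0$) | per 100 probes |

## Condition bookkeeping

`total_ionic_strength()` adds fully dissociated NaCl to a *calibrated*
buffer contribution: 12.5 mM for the reference 12 mM Tris + 25 mM HEPES at
pH 8.0, reproducing the assay's 22.5-150 mM range for 10-137.5 mM NaCl. The
contribution is a lookup, not a Henderson-Hasselbalch computation: standard
pKa values (Tris 8.07, HEPES 7.48) give ~26 mM, not 12.5 mM, and the
ionization treatment behind the calibrated figure is not published. An
explicit `hh_ionic_contribution()` mode exists for exploration but feeds no
reported quantity.

`excluded_volume_fraction()` is linear in concentration with a specific
excluded volume of 1.31 mL/g for 8 kDa PEG, back-derived from the published
1% w/v -> 1.31% v/v correspondence; it reproduces the full series
(0, 1, 5, 10, 20) % w/v -> (0, 1.31, 6.55, 13.1, 26.2) % v/v.

`crossover_concentration()` evaluates the Flory overlap scaling
$c^* = N^{-4/5}$. The degree of polymerization $N$ is caller-supplied:
$N = MW/44$ for 8 kDa PEG gives $c^* \approx 1.6\%$ w/v, which does **not**
reproduce the ~4% figure sometimes quoted for this polymer, and no
definition of $N$ that does is available to us. The function therefore makes
no claim beyond the scaling law itself.

## The synthetic-data generator: what it emulates

`simulate_trajectories()` is the stated world the analysis is tested
against:

* **Motion.** 2-D Gaussian-step Brownian motion (per-axis step variance
  $2D\Delta t$), specularly reflected at the pit wall (radial fold
  $r \to 2R - r$, accurate for steps small relative to $R$). The 500 nm
  depth is treated as fully projected: it is ~6x smaller than the pit
  diameter and the analysis uses lateral MSDs only.
* **Binding.** Each plasmid is unwound with probability chosen so the
  expected number of open sites equals $U_0$ per 100 probes. Each open site
  draws an Exp($K$) waiting time and captures one free probe in its pit.
  This makes the ensemble-mean bound count *exactly*
  $U_0(1-e^{-Kt})$ — the model the kinetics module fits — rather than the
  slightly biased true bimolecular process; the difference is the
  excess-probe approximation the model itself makes. Rewinding is off by
  default. With `rewind_rate` $> 0$, a bound complex releases its probe
  after an Exp(rewind) time and the site re-opens and re-binds at rate $K$
  (binding-limited cycling, stationary occupancy $K/(K+r)$); this is used to
  quantify the negligible-rewinding assumption (bias in $\hat U_0$ stays
  below 15% for $r \le 0.1K$).
* **Sampling.** Videos are short (seconds) relative to the binding dynamics
  (hours), so a molecule's state is fixed at its state at video start.
  Between videos, confined diffusing molecules are re-equilibrated uniformly
  in the pit disc (the in-pit mixing time $R^2/4D \lesssim 1$ s is far below
  the inter-video gap); unconfined molecules take an exact Gaussian
  increment over the gap; zero-diffusion molecules stay put.
* **Imaging.** `render_video()` integrates emitters over the exposure
  (sub-step averaging for motion blur), convolves with a Gaussian PSF
  integrated per pixel, adds constant background, and applies Poisson shot
  noise, yielding 16-bit stacks (`write_tiff()`/`read_tiff()` provide
  minimal uncompressed multi-page TIFF I/O since no R TIFF package is
  available in the target environment).
* **Gels.** `simulate_gel_lane()` renders a topoisomer distribution —
  Gaussian envelope over integer $\Delta Lk$ — as narrow bands on a
  synthetic migration axis with additive noise. Band spacing is uniform;
  real chloroquine-gel mobility calibration is out of scope, which is why
  `fit_band_distribution()` takes the band -> $\Delta Lk$ assignment from
  the caller.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| pit geometry | 3 µm x 500 nm, pitch 6 µm, 25 pits | assay geometry; pitch/field size are plumbing |
| schedule | video/60 s, 2 h, 50 ms exposure | assay schedule |
| frames per video | 100 | not published; gives stable >= 20-point MSD estimates |
| $D_{free}$, $D_{bound}$ | 20, 1 µm²/s | not published; separable at 50 ms sampling, overridable |
| probes / plasmids per pit | 4 / 1 | not published; sets the counting denominator |
| photons, background | 500, 10 per frame | typical sCMOS-era single-molecule SNR |
| PSF sigma, pixel | 0.15, 0.1 µm | diffraction-limited visible-light imaging |
| photobleaching | off | the assay's PCA/PCD oxygen scavenger suppresses it |

What a green test does **not** establish: the generator has no 3-D PSF or
defocus, no flow or drift, no heterogeneous backgrounds, no aggregation, and
its free/bound populations are exactly two monodisperse diffusive states.
Real data violate all of these to some degree; the suite validates the
*estimators*, not the microscope.

## Tracking and classification

`detect_spots()` band-passes each frame (difference of Gaussians at the PSF
scale), takes 3x3 local maxima above a robust (MAD-based) threshold, and
refines positions by background-subtracted centroid — localization error is
well under a quarter pixel at realistic SNR. `link_trajectories()` is greedy
nearest-neighbor with a displacement gate and 1-frame gap closing, with
deterministic tie-breaking (smallest displacement, then detection index).
Identity preservation requires sub-occupancy pits: with several molecules
per 3 µm pit, any close approach can scramble NN identities, and at the
default free-probe diffusivity (20 µm²/s) a probe moves ~2 µm per 50 ms
frame and cannot be linked at all. That regime is physical — the assay
itself only tracks probes once crowder slows them — and the pipeline's
trajectory-input mode exists precisely so kinetic studies need not route
through rendering and tracking.

`estimate_diffusion()` fits the time-averaged MSD through the origin over
lags 1-4 (weights $n_{pairs}/\ell$); short-lag fitting limits confinement
bias, which is nonetheless substantial for fast species in 1.5 µm-radius
pits (the estimate saturates near the confinement plateau — a property the
tests assert rather than hide). Negative slopes clamp to zero with a flag.
Tracks shorter than 10 points are excluded.

`calibrate_threshold()` reproduces the two-population procedure: a
brute-force grid (step 1% of the inter-median range) minimizing total
misclassification over condition-matched reference samples, returning the
midpoint of the minimal-error plateau. Recalibration per condition mirrors
the assay's 20%-PEG recalibration, where crowding slows free probes enough
to shift the boundary. Classification is strict: `d_hat < threshold` is
bound; the boundary case is free. One label per trajectory (binding is
irreversible in the fitted model).

## Kinetics fitting and its error model

`fit_eq1()` minimizes weighted least squares (weights $1/\mathrm{SEM}^2$,
unit weights if any SEM is zero) under the reparameterization
$U_0 = P_0\,\mathrm{logistic}(\theta_1)$, $K = e^{\theta_2}$, so bounds are
enforced by transformation, not clipping. Initialization: $U_0$ from the
maximum observed signal, $K$ from a log-linear fit of $-\log(1 - B/U_0)$,
plus five deterministic jittered restarts; Nelder-Mead then BFGS polish at
`reltol` $10^{-14}$, which inverts noiseless data to ~$10^{-9}$ relative.
Joint identifiability is checked via the condition number of the weighted
Jacobian; an all-zero time course short-circuits to $\hat U_0 = 0$ with $K$
flagged unidentifiable.

Two error models coexist deliberately:

* `fit_eq1()` reports the **curve-fit (Jacobian) covariance** — correct for
  independent point noise, and the module's contract.
* `run_synthetic_experiment()` replaces the SEs with a **delete-one-field
  jackknife** when >= 3 replicate fields exist. The realized number of
  unwound sites in a field is a binomial draw that shifts that field's whole
  time course coherently; point-wise residuals cannot see this shared
  component, and the Jacobian SE under-covers badly (~25% instead of 95% in
  calibration simulations). Resampling whole fields captures it (measured
  coverage 0.90 at 20 seeds), in the same spirit as the assay's
  SEM-over-videos error bars. The reported `ci95_U0` uses the t quantile
  with fields-1 degrees of freedom.

`derive_rate_constant()` propagates $(U_0, K)$ uncertainty to
$k = K/(P_0-U_0)$ by the delta method; Monte-Carlo propagation agrees within
10% for the SE/estimate ratios encountered.

## Topoisomer analysis

`fit_band_distribution()` integrates baseline-subtracted intensity per band
(local linear baseline through the window edges, window 45% of the minimal
band spacing), then fits a Gaussian envelope over $\Delta Lk$ by weighted
nonlinear least squares (moment starting values, `nls` port algorithm) and
converts to superhelical density with $Lk_0 = L/h$ (helical repeat
$h = 10.5$ bp/turn by default — standard B-DNA, not published for the
assay). Round trips at the three assay densities
($\langle\sigma\rangle = -0.07, -0.101, -0.132$) recover the mean within 1%
and the spread within 10% at 2% peak noise.

## Scaling choices in the test suite

The acceptance-grade simulations scale the acquisition grid to videos every
10 minutes (13 time points over 2 h) with 50 frames per video and one
calibrated threshold shared across replicate experiments of a condition.
This keeps 200 full synthetic experiments (10 fields each, counts from the
classify stage) inside a ~5 minute single-CPU budget while leaving the
kinetic content untouched ($Kt$ still spans 0-3.6, tracks still exceed the
20-point classification regime). The threshold-calibration acceptance check
uses $10^5$ reference molecules per population: the empirical
misclassification minimizer converges at a cube-root rate, and smaller
samples test the Monte-Carlo noise floor rather than the grid search.

## Known limitations

* Greedy NN linking degrades above ~1 molecule per pit; no multi-hypothesis
  or LAP linker is provided.
* The MSD estimator is deliberately simple (no MLE/CVE); its confinement
  bias is characterized, not corrected.
* Misclassification of diffusion states is uncorrected in the counts; the
  default stated world is cleanly separable, and condition-matched
  recalibration is the provided mitigation.
* The buffer ionization constant and the PEG specific excluded volume are
  calibrations, not derivations.
* Gel mobility is a synthetic axis; only the envelope over an assigned
  $\Delta Lk$ grid is fit.
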