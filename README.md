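# pitbind

Single-molecule probe–plasmid binding kinetics in nanopit confinement.

## What this is for

Supercoiled plasmids can locally unwind at AT-rich sites; a fluorescent
oligonucleotide probe binds only when the site is open. In the assay this
package models, plasmids and probes are trapped in femtoliter glass nanopits
(3 µm × 500 nm), imaged every minute over ~2 h at 50 ms exposure, and each
tracked molecule is classified bound or free from its diffusion coefficient.
The count of bound complexes per 100 probes versus time follows the
pseudo-first-order law

    B(t) = U0 (1 − exp(−K t)),    K = k (P0 − U0)

with `U0` the initial concentration of unwound plasmids, `P0` the probe
concentration (100 by unit convention), `K` the observed rate and `k` the
true rate constant. Fitting the time course separates *unwinding* (`U0`)
from the *rate of binding to an open site* (`k`) — the decomposition needed
to say whether a solution condition (ionic strength, crowding agent) acts on
DNA structure or on the reaction itself.

The package is for researchers who want to analyze such data, or to test
such analyses against a fully ground-truthed simulator. It provides:

* **conditions** — ionic-strength and crowder excluded-volume accounting
  (`solution_condition`, `total_ionic_strength`, `excluded_volume_fraction`,
  `crossover_concentration`);
* **synth** — pit-confined two-species Brownian simulation with stochastic
  binding (`simulate_trajectories`), fluorescence video rendering
  (`render_video`, `write_tiff`/`read_tiff`), topoisomer gel lanes
  (`simulate_gel_lane`);
* **track** — spot detection, greedy NN linking, MSD diffusion estimation
  (`detect_spots`, `link_trajectories`, `estimate_diffusion`);
* **classify** — two-population threshold calibration and binding counts
  (`calibrate_threshold`, `classify_trajectories`, `count_binding`);
* **kinetics** — time-course assembly and model fitting
  (`assemble_time_course`, `fit_eq1`, `derive_rate_constant`);
* **topo** — superhelical-density conversions and Gaussian topoisomer
  envelope fitting (`sigma_from_dlk`, `fit_band_distribution`);
* **pipeline** — end-to-end runs, condition comparison and a CLI
  (`run_synthetic_experiment`, `compare_conditions`, `pitbind_cli`).

## Worked example

```r
library(pitbind)

# Solution-condition bookkeeping
cond <- solution_condition(nacl_mM = 137.5, crowd = crowder("PEG", 8000, 10))
cond
#> solution_condition: 137.5 mM NaCl + buffer (12.5 mM ions) = 150 mM total
#>   crowder: PEG 8000 Da, 10% w/v (13.1% v/v excluded)
#>   temperature: 37 C

# A full synthetic experiment: 10 replicate fields of 25 pits, videos every
# 10 min over 2 h, ground-truth U0 = 10 per 100 probes, K = 5e-4 /s
cfg <- run_config(seed = 1, n_fields = 10,
  schedule = list(video_interval_s = 600, frames_per_video = 50,
                  total_duration_s = 7200),
  kinetics = list(U0 = 10, K = 5e-4))
run <- run_synthetic_experiment(cfg)
run
#> pitbind_run: 10 fields, 13 time points
#> Binding-model fit  B(t) = U0 (1 - exp(-K t))
#>   U0 = 8.493 +/- 0.721 per 100 probes
#>   K  = 0.0005277 +/- 5.49e-05 /s
#>   k  = 5.767e-06 +/- 5.79e-07 (per-100-probes)^-1 s^-1  [K = k (P0 - U0), P0 = 100]
#>   n = 13 points; converged: TRUE; identifiable: TRUE

# Topoisomer gel round trip at the assay's middle supercoiling density
lane <- simulate_gel_lane(topoisomer_distribution(-0.101, 0.004),
                          noise_sd = 0.02, seed = 1)
gel <- fit_band_distribution(lane$profile, lane$band_positions, lane$band_dlk)
sprintf("mean sigma = %.4f, s_sigma = %.5f", gel$mean_sigma, gel$sd_sigma)
#> "mean sigma = -0.1010, s_sigma = 0.00405"
```

Reading the fit: the recovered `U0` estimates the realized unwound-site
concentration of this experiment (pit loading is binomial, so individual
experiments scatter around the nominal 10; the reported ± is a
between-field jackknife SE whose 95% intervals cover the generator truth at
the calibrated rate), `K` recovers the generator rate within its
uncertainty, and the gel fit returns the generator's ⟨σ⟩ = −0.101,
s_σ = 0.004 to well within 1% / 10%.

## Command line

```sh
Rscript -e 'pitbind::pitbind_cli()' run-all --config cfg.json --outdir out
Rscript -e 'pitbind::pitbind_cli()' gel-fit lane.csv --bands bands.csv --outdir out
```

Verbs: `simulate`, `track`, `classify`, `fit`, `run-all`, `compare`,
`gel-fit`; flags `--config` (JSON), `--seed`, `--outdir`, `--log-level`.
Run outputs are CSV/JSON with a manifest recording seed, config hash and
package version; reruns with the same config are bit-identical.

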