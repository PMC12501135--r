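# eibdyn

Working memory load reshapes both the brain's metabolic milieu and its
network dynamics. `eibdyn` implements, end to end and on fully synthetic
data, an analysis coupling the kinetics of the cortical
excitation–inhibition balance — EIB = Glx / GABA+, estimated by
sliding-window edited functional MRS — with the temporal dynamics of
seed-based coactivation patterns (CAPs) in BOLD fMRI, across rest and
0-/1-/2-back task sessions, together with the signal-detection behavioral
scoring that accompanies such designs.

It is aimed at researchers who want a tested, reproducible reference
implementation of this pipeline: every stage is an ordinary R function, the
synthetic-data generator provides ground truth for parameter-recovery
tests, and the `analysis/` scripts run the whole study design at desk
scale.

## What it computes

- **Edited-spectrum quantification.** MEGA-PRESS ON−OFF difference spectra
  are peak-fitted (Gaussian + linear baseline for GABA+ at 3.0 ppm, a
  Gaussian doublet near 3.75 ppm for Glx), water-referenced and
  tissue-corrected:
  `conc = (A / A_water) · W_pure · (f_GM·0.78 + f_WM·0.65 + f_CSF·0.97) / (1 − f_CSF)`,
  with an optional macromolecule correction (GABA+ × 0.55). Subjects are
  excluded when |z| ≥ 1 in two or more quality-metric cells (SNR / fit
  error per metabolite and session).
- **EIB kinetics.** Sliding windows of 60 ON/OFF pairs shifted by 3 pairs
  (12 s) yield 18 dynamic frames per task session and, after trimming 3
  leading pairs, 12 frames at rest. Per-frame EIB is median-interpolated
  for outliers, normalized to the first frame, and summarized by the
  trapezoidal AUC of (curve − 1).
- **Visibility-graph features.** The time-directed natural visibility graph
  of the EIB curve gives the mean out-degree (temporal-gradient surrogate)
  and the Kullback–Leibler divergence between out- and in-degree
  distributions (irreversibility / non-stationarity index).
- **CAP dynamics.** Frames where a 10 mm spherical seed exceeds z = 1 are
  clustered by correlation-equivalent k-means, with k chosen by consensus
  clustering (1 − PAC); CAPs get template matches (accepted at r > 0.3) and
  per-session temporal metrics — occurrences, resilience, in-/out-degree,
  betweenness on the transition graph, CAP₀ included — plus an fMRS-matched
  persistence-probability curve.
- **Coupling and inference.** Partial least squares correlation between the
  CAP-metric block (5 metrics × 4 sessions) and the EIB-feature block
  (2 features × 4 sessions), with permutation p-values and 10,000-resample
  bootstrap loading CIs; Kruskal–Wallis tests with Dunn-style mean-rank
  post hocs and BH/Bonferroni corrections.
- **Behavior.** Log-linear d′ and an RT-penalized continuous trial score
  (hits 1 − RTn on 400–800 ms; misses 0; correct rejections 1; false
  alarms 0.25 × (1 − RTn)), windowed on the fMRS grid.

## Worked example

```r
library(eibdyn)

design <- session_design("2back")              # 112 ON/OFF pairs
profile <- kinetic_profile("2back", seed = 1)  # load-dependent Glx/GABA+ kinetics
series <- simulate_metabolite_series(profile, design)
session <- simulate_edited_session(series, peak_params(noise_sd = 0.3),
                                   design, seed = 1)

grid <- window_indices(design$n_on_off_pairs)  # 18 frames
curve <- eib_curve(session, grid)
round(curve$auc, 3)
#> [1] 0.163
f <- visibility_features(curve)
round(unlist(f), 3)
#> mean_out_degree             kld        n_frames
#>           2.333           0.249          18.000
```

The positive AUC says the normalized EIB curve ran above its first-frame
baseline for most of the session (the imposed 2-back excitatory drift);
the mean out-degree near 2.3 and the moderate KLD describe a smooth but
time-asymmetric, mildly non-stationary trajectory.

The numbered scripts in `analysis/` run the full synthetic cohort
(12 subjects × 4 sessions) and write their tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

`02_kinetics.R`, for instance, ends with the condition-mean AUCs
(`rest 0.016, 0back 0.049, 1back 0.145, 2back 0.218` for the default
cohort seed), and `07_inference.R` prints the Kruskal–Wallis load effect
on those AUCs with its post hoc table.

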