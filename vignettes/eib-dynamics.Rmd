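---
title: "Methods: EIB kinetics, CAP dynamics, and their coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EIB kinetics, CAP dynamics, and their coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eibdyn)
```

`eibdyn` implements an analysis that couples the kinetics of the cortical
excitation–inhibition balance (EIB), measured by sliding-window edited
functional MRS, with the temporal dynamics of seed-based coactivation
patterns (CAPs) in BOLD fMRI under graded working-memory load. This
vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic generators do
and do not emulate.

## The measurement model

Edited MEGA-PRESS acquisitions alternate editing-ON and editing-OFF
averages; the ON−OFF difference isolates the GABA+ peak at 3.0 ppm (the
`+` marks co-edited macromolecules) and the Glx (glutamate + glutamine)
signal near 3.75 ppm. The package fits the difference spectrum by
nonlinear least squares: a single Gaussian plus linear baseline over
2.8–3.2 ppm for GABA+, and two equal-width Gaussians with a fixed
0.08 ppm split plus linear baseline over 3.55–3.95 ppm for Glx
(`fit_diff_spectrum()`). Areas are the analytic Gaussian integrals
`a·σ·√(2π)` of the fitted parameters, which makes the noiseless
generator–fitter loop exactly invertible — the basis of the
parameter-recovery tests.

Quality metrics follow the edited-MRS conventions: SNR = fitted amplitude
divided by twice the SD of the 9–10 ppm noise region, and fit error =
100 × SD(residual)/amplitude. These are simplified stand-ins for the
metrics of full spectral-fitting suites and are not numerically
comparable to them; they are used relatively, through the group z-score
exclusion rule (`qc_exclusion()`): a (session, metric) cell is flagged at
|z| ≥ 1 and a subject is excluded at two or more flagged cells. We read
the two published clauses ("two quality metrics, or one session for the
same metric") as this single threshold, which makes neither clause
redundant.

Water-referenced, tissue-corrected concentrations use the standard
literature constants (pure-water 55,556 mM; relative water visibilities
0.78/0.65/0.97 for GM/WM/CSF; CSF-fraction renormalization). Relaxation
terms are omitted deliberately: they cancel in the Glx/GABA+ ratio that
all downstream analyses consume. The optional macromolecule correction
multiplies GABA+ by 0.55 (45% of the edited peak attributed to MM).

## Sliding-window kinetics

One ON/OFF pair spans 2 TR = 4 s; pair *k* sits at (k − 0.5)·4 s.
Windows of 60 pairs shifted by 3 pairs (12 s) give 18 dynamic frames for
112-pair task sessions. Rest sessions have 96 pairs; to carry the same
12-s grid they are trimmed to 12 frames. `window_indices()` removes
*leading* pairs — exactly `n_pairs − (window + (target − 1)·step)` of
them (3 at rest) — so the retained windows sit flush with the session
end. Trimming the start rather than the end reflects the steady-state
rationale (the earliest averages are the least stationary); a
`target_frames` argument exposes the choice.

Per frame, EIB is computed from that frame's fitted Glx and GABA+ and
only then is the EIB curve normalized by its first frame. The alternative
(ratio of normalized curves) differs numerically and was rejected to pin
one deterministic order. Outlier frames — beyond 2 robust SDs
(1.4826 × MAD) of the curve median — are replaced by the median of their
neighbors before normalization; the operation is idempotent and a no-op
on clean curves. The curve summary is the trapezoidal AUC of
(normalized − 1) with unit frame spacing, so a flat curve scores exactly
0 and reflecting a curve about baseline negates its AUC.

## Visibility-graph features

The limited number of frames makes slope- or peak-based kinetic summaries
fragile, so temporal structure is read from the natural visibility graph:
time points a < b connect when every intermediate point lies strictly
below the chord between them (collinear points are *not* mutually
visible, per the original definition), with edges directed forward in
time. Two features summarize the graph: the mean out-degree (a surrogate
for the temporal gradient) and the Kullback–Leibler divergence between
the out- and in-degree distributions (temporal irreversibility;
palindromic curves score exactly 0). For the KLD, both distributions are
restricted to their common support and renormalized before the sum — the
raw restricted sum can be negative, and the renormalized form is
guaranteed non-negative by Gibbs' inequality. Boundary nodes (the first
node's in-degree 0, the last node's out-degree 0) are included by
default and exposed as a switch. The implementation is the O(n²)
running-maximum-slope scan; the test suite checks it edge-for-edge
against an O(n³) brute-force oracle on random series.

## CAP decomposition and temporal metrics

The seed time course is the mean over a 10 mm sphere (voxel centers
within the radius), z-scored per session; frames with z > 1 — strict,
positive tail — are selected. We read the published phrase about
"absolute z-score CAP" as describing map z-scoring, not two-sided frame
selection; a `two_sided` switch is provided. Selected frames are
row-normalized (zero mean, unit norm — making Euclidean k-means
correlation-equivalent) and clustered with 20 restarts. The number of
clusters is chosen by consensus clustering: 100 subsamples of 80% of the
frames per candidate k, co-assignment consensus matrices, and stability
1 − PAC with PAC the share of consensus entries in (0.1, 0.9); ties go
to the smaller k. CAP maps are arithmetic means of the raw member
frames; z-maps divide by the voxel standard error. Template matching
accepts the best Pearson correlation only when r strictly exceeds 0.3.

Temporal metrics treat the full label sequence (CAP₀ included) with T
frames and T − 1 transitions: occurrences (% of frames), resilience
(self-transitions / (T − 1)), in-degree (entries / (T − 1)), out-degree
(exits / (T − 1)), and betweenness centrality on the directed transition
graph with distances 1/count, normalized by the K(K − 1) ordered node
pairs. The (T − 1) normalization reproduces the magnitude regime of
published CAP tables (occurrences ~15%, resilience ~0.04, degrees
~0.01); the conservation identities
Σ(resilience + in-degree) = Σ(resilience + out-degree) = 1 are tested on
random sequences. The persistence curve maps the fMRS window grid
proportionally onto the fMRI timeline (equal window counts, lengths and
steps scaled and rounded to frames) and reports, per window, the
conditional self-transition probability of the CAP — 0 when the CAP
never starts a transition there. An occupancy-based alternative was
considered and rejected as the default because it conflates dwell time
with stability.

## PLSC coupling

The X block holds the 5 CAP metrics × 4 sessions (metric-major column
order), the Y block the 2 EIB visibility features × 4 sessions, both
column z-scored; missing cells are an explicit error, never imputed.
The cross-block matrix R = YᵀX/(n − 1) is decomposed by SVD; scores are
XV and YU; sign is fixed by making each component's largest-|loading| X
entry positive. Permutation inference shuffles Y's rows and uses each
component's singular value as its null statistic with the add-one
estimator p = (1 + #{null ≥ obs})/(1 + n_perm) — never exactly zero. No
Procrustes realignment is applied to permuted components, a documented
limitation for components beyond the first (only the first is
interpreted). Bootstrap resampling of subjects, sign-aligned to the
original loadings, yields percentile 95% CIs; a loading is "reliable"
when its CI excludes zero. Whether the published EIB block used one
composite score or both visibility features per session is ambiguous;
both-features is the default and a KLD-only block remains possible by
passing a reduced feature table.

## Behavior

d′ uses the log-linear adjustment on *all* rates — (hits + 0.5)/(n + 1) —
not only perfect ones, for continuity across subjects; this is flagged in
the output and the perfect-scores-only variant can be obtained by
pre-adjusting counts. The continuous trial score normalizes RT between
400 and 800 ms: hits score 1 − RTn (a ≥ 800 ms correct response ties a
miss at 0; a configurable floor exists), misses 0, correct rejections 1,
and false alarms 0.25 × (1 − RTn) — the fastest false alarm scores 0.25,
slower ones strictly less, the published range and monotonicity with the
penalty form pinned here. Behavioral curves reuse the fMRS window grid
mapped onto the trial timeline (one trial each 2.5 s), with empty
windows carrying the previous value forward under a warning.

## Synthetic generators: what they emulate, and what not

The generators provide every input with known ground truth. Metabolite
series evaluate positive load-scaled shapes — by default a saturating
Glx rise (+10% × load within minutes) and a biphasic GABA+ transient
(+6% × load peaking near 150 s) — at pair midpoints, add Gaussian noise
(3% of baseline per pair) and inject rare extreme outliers (1% of pairs,
|z| > 4) to exercise the median-interpolation stage. Spectra are pure
Gaussian lineshapes on a 1024-point 0.5–10.5 ppm axis: no J-evolution,
no basis sets, no phase or eddy-current artifacts, so passing recovery
tests demonstrates the pipeline's arithmetic, not robustness to real
spectral pathology. BOLD sessions follow a latent Markov chain whose
non-active state dominates (self-transition 0.9) and whose active states
are seed-coupled, with ring-structured inter-state transitions — the
sparse, structured transition graphs of empirical CAP sequences, which
keep betweenness centrality informative; there is no hemodynamic
convolution and no spatial autocorrelation. Behavioral sessions place
exactly 9 congruent trials in each of 4 blocks of 44 and draw responses
from per-load hit/false-alarm rates with truncated-normal RTs.

The CAP and EIB generators are *independent* by construction, so the
demo cohort's PLSC is a true null — the expected outcome there is a
non-significant first component, and the pipeline's PLSC calibration is
tested exactly on that property.

## Problem sizes and numerical choices

The bundled analysis runs 12 subjects × 4 sessions with 10³-voxel BOLD
grids, consensus clustering on up to 400 subsampled frames (50
subsamples, k ∈ 2..6), 1,000 permutations and 10,000 bootstrap
resamples; the whole `analysis/` sequence completes in a few minutes on
one CPU. These sizes are the package's choices for a desk-scale
reference cohort; every knob (grid, frames, permutations, k range) is an
ordinary argument. Alignment ties in the cross-correlation search break
toward zero shift; non-convergent peak fits return a flagged result with
infinite fit error rather than an exception; k-means empty clusters
trigger up to five restarts; and all generators and inference routines
are pure functions of their parameters and seeds, so identical
configurations reproduce identical outputs bit for bit.

## Limitations

Group-level findings from the original human cohorts (effect sizes,
χ² statistics, covariance shares) are functions of those datasets and
are not reproduced by the synthetic cohort; the package instead
verifies its machinery by parameter recovery, null calibration, and
structural constants. The spectral fitter is deliberately minimal; real
edited-MRS data should be quantified with a dedicated fitting suite and
fed to the kinetics stage as per-pair or per-window concentrations. The
fMRS→fMRI window mapping assumes proportional timelines, and the DLPFC
seed coordinate must be supplied by the user for real data.
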