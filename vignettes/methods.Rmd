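---
title: "Methods: PPI effective connectivity under focused-ultrasound suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPI effective connectivity under focused-ultrasound suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusefc)
```

# The problem

Low-intensity transcranial focused ultrasound (FUS) can suppress the
evoked response of a deep target such as the thalamic VPL nucleus while
fMRI records the whole brain. Comparing connectivity between a
heat-only and a heat + FUS condition then asks a causal question: which
cortical regions depend on the thalamic relay, and how does the network
reorganize when the relay is dampened? `fusefc` implements the analysis
chain for that comparison on ROI-level BOLD time series, together with
a synthetic generator that plants the structure the analysis is
supposed to find, so every stage is testable without data access.

# Models and procedures

## Dose arithmetic

A nested pulse scheme (pulses at a fast PRF inside trains repeated at a
slow rate) has duty cycle
$DC = (\tau_p f_\mathrm{fast}) (\tau_t f_\mathrm{slow})$.
Time-averaged acoustic power is $P_{ta} = P_{el}\,\eta\,DC$ and the
cranial thermal index is $TIC = 1000\,P_{ta} / (40\, D_{eq})$ with
$D_{eq}$ the equivalent aperture in cm. Per-pulse cosine ramps are
metadata and deliberately do not reduce the computed duty cycle: the
reference arithmetic (12.5% duty, 0.83 W, TIC 5.6 at 11.1 W, 60%
efficiency, 3.7 cm) ignores them, and functions return full precision,
leaving 2-significant-figure rounding to reports. The equivalent
aperture never follows from transducer geometry here — it is a user
input, because no simple cone model reproduces the quoted value. Only
the TIC 5.0–6.0 advisory band (10-s limit) ships as a default; other
bands are user configuration, not guesses.

## Preprocessing

Stages mirror standard block-design conditioning: drop the first five
volumes (10 s at TR 2 s), subtract the per-column OLS line and the
mean, select the smallest leading set of principal components of
nuisance-voxel signals reaching 70% cumulative variance, regress
confounds out (residuals provably orthogonal to every confound), and
low-pass filter with a zero-phase Chebyshev Type II design.

Two numerical choices deserve note. First, at TR 2 s a 0.25 Hz cut-off
*equals* the Nyquist frequency, making the stated filter degenerate;
the stopband edge is clamped to 0.995 × Nyquist with a warning, which
preserves the intent (low-pass conditioning) while remaining
well-posed. Second, order (5), stopband attenuation (40 dB) and
forward–backward application are conventions — the source protocol
names none — exposed in `lowpass_filter()` and `pipeline_config()`.
No IIR-design package exists in this stack, so the design is
implemented from the analog inverse-Chebyshev prototype via the
bilinear transform and is pinned in the tests to coefficients from an
independent reference implementation.

## Activation GLM and response parameterization

The canonical HRF is a difference of gamma densities (peak delay 6 s,
undershoot delay 16 s, dispersions 1 s, undershoot ratio 1/6 — the
conventional values, since none are specified by the protocol), scaled
to unit peak. Task regressors are boxcars convolved at a fine grid
(dt = 0.1 s) and decimated to the TR grid; betas therefore have the
units of "signal per unit of convolved boxcar". Mass-univariate OLS
yields t and two-sided p per series; activation requires conjunctively
`t > 2` *and* BH-FDR `q ≤ 0.05` (the reference phrasing is ambiguous
about the order; the conjunction is at least as strict as either
reading) with ≥ 2 contiguous voxels under face (6) connectivity,
config-overridable to 18/26. The FDR family is all in-mask voxels of
one run's map, since runs are analysed separately before group
inference.

Percent signal change uses the mean over the final 10 s of each rest
period as baseline (avoiding post-stimulus undershoot contamination;
"all rest volumes" is available). Cycle averages align 46-s epochs
(16-s block + 30-s rest) at block onsets; the two-gamma fit
$a_1 G(t-\ell_1;k_1,\theta_1) - a_2 G(t-\ell_2;k_2,\theta_2)$ uses
unit-peak gamma bumps so amplitudes stay in PSC units, bounds
($a \ge 0$, lags in the window, $k \in [1,12]$, $\theta \in [0.1,4]$ s,
$\ell_2 = \ell_1 + \delta$, $\delta \ge 0.5$ s so $\ell_1 < \ell_2$ by
construction), and five optimizer starts — one data-driven, two fixed
canonical, two jittered — because the data-driven start alone
occasionally converges to a zero-amplitude local optimum on noisy
cycle averages. The convergence flag is honest; the pipeline falls
back to the canonical HRF with a warning when a degenerate (all-zero)
kernel emerges.

## PPI effective connectivity

The seed signal is the mean PSC over suprathreshold seed voxels (or
the seed ROI column), detrended and demeaned. The demeaned per-condition
boxcar is convolved with an HRF — by default the kernel obtained by
fitting the two-gamma model to the seed's heat cycle average, with the
canonical HRF as a config alternative — and multiplied element-wise
with the seed. Masking the product to each condition's cycles (block +
following rest; partial trailing cycles dropped) yields PPI regressors
with disjoint supports. The multiplication happens at the BOLD level:
no deconvolution to a "neural" level is attempted, by design. The EFC
GLM retains the task main effects and intercept as covariates
(standard PPI practice; the protocol is silent on this, so it is a
package choice, flagged as such), and the coefficient on a condition's
PPI column is that condition's EFC β.

Group inference is two-stage summary statistics: run-level betas are
averaged within subject (unweighted by run count) and a one-sample t
test is applied across subject means; a single subject degrades to
run-level inference with a warning. Condition contrasts within a run
use `contrast_test()` on the GLM covariance. The Mann–Whitney–Wilcoxon
test uses the tie-corrected U, exact permutation enumeration for
combined n ≤ 20 and a tie-corrected normal approximation with
continuity correction beyond.

## Clustering and network comparison

Per-ROI feature vectors concatenate the two-gamma amplitudes and lags,
the mean EFC β, and the full 46-s cycle-averaged PSC at TR resolution
(23 samples — the resolution is unstated upstream, so the native one
is used). Each feature dimension is z-scored across ROIs before the
correlation distance $d = 1 - r$: mixing percent units, seconds and
beta units without standardization would let the PSC block dominate.
WPGMA merges the closest pair, with the merged cluster's distance to
any third cluster the unweighted mean of its two parts' distances;
ties break lexicographically by smallest leaf name, so results are
order-independent. Cophenetic distance is the height of the lowest
common merge; the cophenetic correlation compares it with the input
distances over the upper triangle (flagged degenerate for a single
pair). The dendrogram cut at $d = 0.7$ defines subnetworks. The
pipeline clusters the cortical target ROIs only: the thalamic seed
anchors the EFC analysis but is not itself a network member.

Inter-ROI correlation matrices are Pearson r between ROI time courses
restricted to one condition's cycles (conditions differ, so masking is
the default; the full-run alternative is a one-argument change).
The r > 0.3 threshold is a reporting mask, not removal — sub-threshold
entries stay available to the comparison statistics. Dice similarity
interprets the compared sets as suprathreshold *edge* sets per
condition (the only reading under which the pairwise |Δr| ≤ 0.15
validity criterion is well defined); an empty union returns a flagged
NA rather than a division error. Correlation-power change sums
$crH^2 - crHF^2$ over the heat-suprathreshold edge set by default
("all" and "union" variants exist for sensitivity analysis), and
thresholds apply to signed r throughout. Edge export keeps r > 0.5.

# The synthetic world

`default_design()` lays out 16-s blocks and 30-s rests, three
conditions (heat, heat + FUS, FUS-only) × 7 repetitions in seeded
random order after a 30-s lead-in. The reference protocol's numbers
(21 blocks × 46 s vs 337 × 2 s volumes) cannot coexist, so repetitions
and run length are independent knobs: the default run covers the full
schedule (498 volumes), and `n_volumes = 337` truncates trailing
events. The FUS-only condition is generated with zero evoked response
and ignored downstream.

`default_truth()` states the world: a thalamic seed (VPL) plus 19
cortical ROIs in two subnetworks (seed + 9, and 10); evoked amplitude
0.25 per unit of convolved boxcar for both heat conditions (≈ 1.4%
peak PSC under the unit-peak HRF — a realistic block response); shared
latent N(0,1) signals per subnetwork with weight 1 plus per-ROI private
latents (sd 0.5, keeping within-subnetwork correlations realistically
below 1); AR(1) noise (φ = 0.3, sd 0.2), linear drift 0.002 per volume,
six smooth motion-like nuisance series with small random projections
into the signals, and a baseline level of 100 so PSC conversion is
well-posed.

Suppression (factor s = 0.6 by default) acts on the seed-coupled set —
the seed plus its subnetwork — in three places: (i) their heat + FUS
evoked amplitudes are multiplied by 1 − s; (ii) the non-seed coupled
ROIs' shared-latent gain drops to 1 − s during heat + FUS cycles; and
(iii) each coupled target receives an explicit interaction term
`interaction_strength · g_c · mask_c(t) · task_c(t) · seed(t)` with
g = 1 under heat and 1 − s under heat + FUS. (ii) and (iii) are the
package's additions to a bare amplitude-suppression model: correlations
are scale-invariant, so suppressing evoked amplitudes alone changes
*neither* inter-ROI correlation power nor PPI betas in the planted
direction — both claims were verified empirically before the design
was fixed. The seed's own latent gain stays constant; modulating it
inflates the heat-condition PPI regressor variance and cancels the
planted ordering.

What a green test establishes: that the estimators recover exactly this
structure — boxcar-driven double-gamma responses, stationary Gaussian
latents, linear mixing, AR(1) noise. Real data add habituation,
physiological noise spectra, motion in image space, registration error
and inter-subject variability, none of which are emulated; recovery
here is a necessary, not sufficient, validation.

# Numerical and testing choices

* All randomness flows from explicit integer seeds; per-stage seeds are
  derived from one top-level seed and recorded, and the full pipeline
  report serializes to byte-identical JSON under a fixed seed.
* The clustering-recovery experiment correlates *task-residualized*
  series (task regressors regressed out first): the planted
  subnetworks are latent structures, and without residualization the
  common evoked response leaves the cross-subnetwork cophenetic
  distance (~0.77) marginal against the 0.7 cut.
* Oracles are independent of the paths they check: WPGMA against both
  a leaf-weight brute force and `stats::hclust(method = "mcquitty")`,
  BH against `p.adjust`, MWW against exhaustive enumeration and
  `wilcox.test`, the GLM against explicit normal equations, Newick
  export against `ape`, and the filter against frozen reference
  coefficients.
* Calibration experiments (2000-volume FDR null, 500-seed PPI null)
  run at the stated replication counts on deliberately small
  per-replicate problems (48-voxel volumes, 6-ROI runs) to stay inside
  the test-time budget.

# Known limitations

* No prewhitening: GLM inference assumes iid residuals, as in the
  source protocol; with AR(1) noise the run-level p-values are mildly
  anticonservative (group inference does not inherit this).
* Volumes live in memory as 4D arrays with plain-text export; no NIfTI
  I/O (no NIfTI-capable R package in the supported stack).
* Registration, slice timing, spatial smoothing, acoustic/thermal field
  simulation and atlas annotation are out of scope.
* The two-gamma optimizer is multi-start local search; pathological
  cycle averages can defeat it, which the honest `converged` flag and
  the pipeline's canonical-HRF fallback make visible rather than hide.
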