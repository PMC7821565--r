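---
title: "Methods: from raw optics to prefrontal connectivity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw optics to prefrontal connectivity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsconn)
```

## Overview

`fnirsconn` analyzes two-wavelength fNIRS recordings of the prefrontal
cortex collected during a two-phase task: a long watchkeeping
(sustained-attention) phase ending when a target is spotted, and a shorter
decision phase ending with an evasive maneuver. The pipeline converts raw
optical intensities to hemoglobin concentration changes, suppresses
artifacts, divides each recording into six task periods (watch1–4,
decision1–2), estimates a partial-correlation network per period, reduces
each network to two graph metrics — connection density and mean local
clustering — and relates those metrics to behavioral outcomes. Because
recordings of this kind are rarely shareable, the package includes a
generator that produces synthetic recordings with *known* connectivity
ground truth; all quantitative claims about the pipeline are statements
about what it recovers from that generator.

## Signal model and preprocessing

**Optical density.** For each channel and wavelength,
$OD(t) = -\log_{10}(I(t)/I_0)$. We take $I_0$ to be the *geometric* mean
intensity of the recording (equivalently, the mean log-intensity is
subtracted). For the small fluctuations typical of cortical hemodynamics
the geometric and arithmetic means agree to second order; the geometric
choice makes $OD$ changes exactly zero-mean, so the forward model
(`simulate_optics()`) and the inverse (`to_optical_density()` +
`apply_mbll()`) compose to the identity at machine precision for zero-mean
concentration inputs. Concentration changes are therefore deviations from
the recording mean.

**Artifact repair.** Spikes and discontinuities are flagged by a robust
z-score: the residual about a moving-window running median (10 s window),
scaled by a moving-window MAD with a floor of $10^{-12}$ (so constant
channels produce no flags). Samples exceeding $|z| > 5$ are replaced by
linear interpolation between the nearest clean neighbors, and the mask is
kept for audit. The threshold is conservative; no published criterion
exists for this step, so the mask rather than the threshold is the
contract. A channel with more than half its samples flagged fails loudly —
the analysis assumes acceptable signal quality on all 15 channels.

**Low-pass filter.** A 4th-order Butterworth at 0.4 Hz, applied
forward–backward (zero phase, magnitude response squared). Only the cutoff
is externally prescribed; the order and zero-phase realization are this
package's design, standard in fNIRS practice, and are pinned by contract
tests instead of by implementation details: ≤ 1% attenuation at 0.05 Hz,
≥ 99% attenuation at 1.2 Hz (the cardiac band), symmetric impulse
response, DC gain exactly 1. The per-channel mean is removed before
filtering and restored afterwards, which makes the DC contract exact and
avoids offset-driven start-up transients (`signal::filtfilt` zero-pads
rather than matching initial conditions).

**Modified Beer–Lambert law.** Per channel and sample the two-wavelength
system
$\Delta OD(\lambda) = (\varepsilon_{HbO}(\lambda)\,\Delta HbO +
\varepsilon_{Hbb}(\lambda)\,\Delta Hbb)\cdot DPF(\lambda)\cdot d$
is solved for $(\Delta HbO, \Delta Hbb)$, with differential pathlength
factors 7.25 (760 nm) and 6.38 (850 nm) and source–detector separation
$d$ = 30 mm by default (a conventional adult prefrontal separation; the
solve is linear in $1/d$, so every exactness test is distance-agnostic via
round trips). Extinction coefficients are the standard tabulated values
packaged in `inst/extdata/extinction_hb.csv`; since no specific table is
prescribed for this analysis, all exactness guarantees are round-trip
based and hold for any invertible table.

**CBSI.** Correlation-based signal improvement treats HbO and Hbb as
carrying a common-mode artifact (head motion) on top of physiologically
anticorrelated signals. Per channel and scope window,
$\alpha = sd(HbO)/sd(Hbb)$, $CBSI_{HbO} = (HbO - \alpha\,Hbb)/2$, and the
implied $CBSI_{Hbb} = -CBSI_{HbO}/\alpha$, which is perfectly
anticorrelated with $CBSI_{HbO}$ within the window by construction. The
scope is configurable (`global` or `per_period`, default `per_period`).
The per-period default is this package's interpretation of an empirical
puzzle: post-CBSI HbO–Hbb correlations reported for real recordings of
this task fall between −0.78 and −0.98, which is impossible under a
single-scope CBSI (forced −1); applying CBSI per task period and then
correlating over the whole record reproduces magnitudes below 1 because
$\alpha$ varies between windows. This is a documented interpretation, not
an established fact about the original processing.

The fixed stage order is OD → repair → low-pass → mBLL → CBSI; it is not
configurable.

## Segmentation and ROI averages

Events are half-open boundaries: a period $[t_0, t_1)$ includes $t_0$ and
excludes $t_1$, so boundary samples are never double-counted. The watch
phase is divided into four contiguous periods of equal length and the
decision phase into two; when the sample count is not divisible, the first
$r$ periods receive one extra sample (deterministic, order-preserving).
ROI averages are the mean over the five ROI channels (left 1–5, central
6–10, right 11–15) of each channel's period mean of $CBSI_{HbO}$;
interpolated samples are included and counted. The 3-standard-deviation
outlier screen (`screen_outliers()`) uses the sample SD with the candidate
included, single pass — the simplest reading of the rule; it is applied to
the cell-level analysis table, since whether it preceded or followed ROI
averaging in the original analysis is unstated.

## Connectivity networks

Per period, the 15×15 partial-correlation matrix is computed from the
inverse of the sample correlation matrix,
$\rho_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$, which equals the
correlation of the residuals of channels $i$ and $j$ after regressing each
on the other 13 channels (the estimator is tested against that
residual-regression definition directly). With ~2600 samples per watch
period and 15 channels the correlation matrix is comfortably
well-conditioned; a ridge on the correlation diagonal is available and is
raised automatically (to $10^{-4}$, with a message) on near-singularity. A
zero-variance channel is an error rather than a dropped node, because all
downstream formulas assume the full 15-node montage.

Thresholding removes negative partial correlations and keeps edges with
$\rho \ge 0.28$, the fixed criterion used in the original analysis.
Values exactly at the criterion produce an edge (deterministic boundary
convention, stated in the docs). The stated rationale for 0.28 — the
one-tailed Pearson critical value at $p < .05$, $N = 40$ — does not equal
the closed-form value at either plausible degrees-of-freedom choice
($r^*(df{=}38) \approx 0.264$; partial-correlation $r^*(df{=}25) \approx
0.323$); the package therefore keeps 0.28 as the faithful default and
offers `critical_r()` as a documented alternative without asserting which
df the original analysis used.

## Graph metrics

Density is $D = \sum_{ij} a_{ij} / (n(n-1))$ over ordered pairs —
identical to (number of edges)/$\binom{n}{2}$, an identity that is
unit-tested because the printed form of the constant in the source
material is typographically ambiguous. Local clustering is
$C_i = \sum_{j,h} a_{ij}a_{ih}a_{jh} / (k_i(k_i-1))$ (the numerator is
$(A^3)_{ii}$, twice the triangle count), and $C$ is the mean over nodes;
nodes with degree < 2 contribute 0, following the convention of the
standard brain-connectivity tooling the original analysis cites, since the
printed formula is undefined there.

## Group level

Connection-frequency maps count, per channel pair and period, the
participants whose binary network contains that edge, binned as red (≥ 22
participants), orange (17–21), green (13–16), blue (≤ 12). The published
description leaves a one-integer gap ("less than 12" blue but green
starting at 13); blue is taken as ≤ 12 so the bins partition the integers.
Arc diagrams render the counts; the TSV of counts and the legend metadata
are the testable surface, and the image is a faithful view of them.

Behavior regressions are OLS of distance (nautical miles) on density and
clustering with intercept, reporting raw and standardized coefficients,
$t$, two-sided $p$, partial correlations (residual definition), $R^2$,
adjusted $R^2$ and $F$. $p$-values are reported but never drive any
automated decision. Only standardized quantities are comparable to the
original tables, which print no intercepts or raw coefficients.

## The synthetic generator

The generator defines the conditions under which the pipeline's recovery
claims are made.

**Ground truth.** `make_ground_truth()` builds a Gaussian graphical model:
identity precision, $-s$ at each requested edge, then (if needed) a common
diagonal ridge chosen in closed form so the smallest eigenvalue reaches
$10^{-3}$. The ridge guarantees feasibility for arbitrary edge sets at the
cost of shrinking realized partial correlations to $s/(1+\text{ridge})$;
the realized value is reported as the truth. The precision is finally
rescaled by a diagonal congruence so the implied covariance has unit
diagonal — this changes no partial correlation and no zero pattern, but
keeps channel variances at 1 (without it, a ridged precision implies
marginal variances up to $10^3$, drowning every noise component).

**Hemodynamics.** The network-driven HbO component is drawn i.i.d. over
samples from the model's covariance (sample partial correlations converge
to the population truth at rate $1/\sqrt{n}$; at $n = 10{,}000$ the
maximum absolute deviation stays below 0.05). Superposed are sinusoidal
cardiac (1.2 Hz), Mayer-wave (0.1 Hz) and respiratory (0.3 Hz) components
with uniform random phase per channel, polynomial drift, exponential-decay
motion spikes at Poisson times, and white noise. Hbb is $-0.6 \times$ the
clean HbO plus *the same* motion spikes plus independent noise: the
common-mode spikes are what give CBSI something to remove (a purely
independent Hbb noise would make CBSI strictly counterproductive), and the
imperfect anticorrelation matches what real recordings show. Defaults
(amplitudes in µM): cardiac 0.3, Mayer 0.2, respiration 0.2, drift 0.3,
spikes amplitude 8 at 0.5/min with 1 s decay, white noise 0.2, against a
unit-variance network component. No amplitude or spectral parameters are
published for this task's noise environment; these are conventional
magnitudes, chosen once, not fitted. The generator deliberately has no
evoked-response model (no hemodynamic response function); it targets
correlational structure only.

**Scenario.** Watch phase 1170 s (the task's average 19 min 42 s),
decision phase 284 s (2 × 142 s), 8.9 Hz. Event markers are placed at the
phase boundaries. A per-period truth override regenerates the network
component at period boundaries so a sparser decision-phase truth can be
planted.

**Behavior.** Distances are linear in density and clustering plus Gaussian
noise; `noise_sd_for_r2()` sets the residual SD so the cohort-level
population $R^2$ hits a target (0.3 in the experiments, matching the
order of variance explained in the original regressions). The watch4
scenario uses a positive density coefficient and the decision2 scenario a
negative one, the direction the original analysis reports.

## Recovery experiments and what they show

`recovery_experiment()` plants, per participant, a watch-phase truth of
~12 edges (density ≈ 0.11) and a decision-phase truth of ~5 edges
(≈ 0.05), edge strength 0.5, jittered ±3 edges per participant to create
cohort variance. These sizes are a deliberate choice: with the prescribed
ridge construction, realized partial correlations fall as graph density
grows (≈ 0.30 at 20 edges, straddling the 0.28 criterion), so recovery at
the fixed threshold is only a meaningful claim for sparse truths where
realized strengths stay ≳ 0.33. Period-length draws (2600 watch / 1264
decision samples, i.e. 292.5 s and 142 s at 8.9 Hz) are estimated and
thresholded, giving edge sensitivity ≈ 0.998 and false-positive rate ≈ 0
over 20 seeds, a null-truth recovered density of ≈ 0, a lower mean
density in decision than watch periods in 20/20 seeds, and correct
regression coefficient signs in ≥ 98% of 50 cohorts of 36.

These experiments run on the network-driven draws directly, without the
nuisance-noise stack — they measure the estimator and threshold, under the
generator's correlational ground truth. The full noisy path (optics →
preprocessing → networks) is exercised separately (`run_pipeline()`, CBSI
and filter tests), and it behaves differently in one honest respect: the
0.4 Hz low-pass leaves the series strongly autocorrelated, which reduces
the effective sample size per period and widens the sampling spread of
partial correlations, so the fixed 0.28 threshold admits extra edges
(demo-scale runs recover density ≈ 0.17–0.21 against a 0.114 truth) and
low-frequency physiological components that survive the filter attenuate
true partial correlations. Fixed-threshold binary networks inherit both
effects; they are properties of the method, not implementation defects,
and they are why the recovery claims are stated at the estimator level.

## Numerical choices and edge cases

- Problem sizes: tests use shortened scenarios (40–600 s phases, cohorts
  of 3–6) for all plumbing checks, full period lengths (2600/1264 samples)
  for recovery claims, and 36-participant cohorts over 50 seeds for the
  regression experiment.
- Determinism: every stochastic operation takes an explicit seed; helper
  RNG use saves and restores the global RNG state; the demo pipeline's
  tabular artifacts are bit-identical across reruns (MD5-checked
  manifest). On-disk numeric serialization uses 17 significant digits, so
  write/read round trips are bit-exact.
- Degenerate inputs: zero-variance channels are errors at CBSI and at the
  correlation stage (dead channel vs. silently dropping a node); an
  all-constant artifact-repair channel produces no flags (MAD floor);
  cells with zero SD produce no outlier flags; regression requires ≥ 4
  complete cases and non-collinear predictors. In the sign-recovery
  experiment, sparse decision-phase truths can give a cohort with
  all-zero clustering; the harness then falls back to a density-only
  model, since the density sign is the quantity under test.
- The infeasibility guard in `make_ground_truth()` rejects strength/edge
  combinations needing a ridge above 10 (realized strength would be under
  a tenth of the request).

## Known limitations

- The generator's network component is temporally white; real
  hemodynamics are band-limited, so real effective sample sizes per
  period are smaller than the nominal counts used in recovery claims.
- CBSI removes only common-mode artifacts; channel-specific motion is
  untouched. No short-separation regression or accelerometer fusion is
  implemented (absent from the original montage).
- Only undirected, lag-zero association is modeled; no Granger/DCM-style
  directed connectivity, no weighted-graph metrics beyond density and
  clustering.
- The fixed 0.28 criterion is kept for fidelity; under filtering-induced
  autocorrelation it is anticonservative (see above), and `critical_r()`
  with an honest effective sample size would be the principled
  replacement.
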