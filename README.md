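# fnirsconn

Functional connectivity analysis for prefrontal fNIRS recordings of
sustained-attention and decision-making tasks.

## The problem

During long watchkeeping tasks (e.g. monitoring an empty sea for a target
vessel, then deciding on an evasive maneuver), prefrontal activity and the
coupling between cortical sites reorganize. A 15-channel, two-wavelength
(760/850 nm) fNIRS montage over the prefrontal cortex, sampled at 8.9 Hz,
captures this as per-channel oxy-/deoxyhemoglobin concentration changes.
`fnirsconn` implements the full analysis chain from raw optical intensities
to task-period connectivity networks and group-level summaries, for
researchers who want a tested, reproducible version of this pipeline plus a
synthetic-data generator with known ground truth to validate every stage.

## The pipeline

1. **Optical density**: `OD(t) = -log10(I(t)/I0)` per channel and
   wavelength, baseline `I0` = the recording's (geometric) mean intensity.
2. **Artifact repair**: moving-window median/MAD robust z-scores; samples
   with `|z| > 5` are linearly interpolated (mask persisted).
3. **Low-pass**: zero-phase 4th-order Butterworth at 0.4 Hz, suppressing
   cardiac oscillations (1–1.5 Hz) by more than 40 dB.
4. **Modified Beer–Lambert law**: per sample, solve
   `dOD(λ) = (ε_HbO(λ)·ΔHbO + ε_Hbb(λ)·ΔHbb)·DPF(λ)·d`
   with DPF 7.25 (760 nm) and 6.38 (850 nm).
5. **CBSI**: per channel and task period, `α = sd(HbO)/sd(Hbb)` and
   `CBSI_HbO = (HbO − α·Hbb)/2`, forcing perfect HbO/Hbb anticorrelation
   within each window to cancel common-mode motion artifacts.
6. **Segmentation**: the watch phase `[0, target_spotted)` splits into
   watch1–4 and the decision phase `[target_spotted, course_change)` into
   decision1–2, all of equal duration (half-open intervals).
7. **Connectivity**: per period, the 15×15 partial-correlation matrix
   (`ρ_ij = −Ω_ij/√(Ω_ii Ω_jj)` from the inverse correlation matrix Ω),
   thresholded at partial r ≥ 0.28 (negatives removed) into a binary
   adjacency matrix; `critical_r()` provides a sample-size-based
   alternative criterion.
8. **Graph metrics**: connection density `D = Σ_ij a_ij / (n(n−1))` and
   mean local clustering `C = (1/n) Σ_i Σ_jh a_ij a_ih a_jh / (k_i(k_i−1))`
   (nodes with `k_i < 2` contribute 0).
9. **Group level**: connection-frequency maps with arc-diagram rendering
   (bins: ≥22 participants red, 17–21 orange, 13–16 green, ≤12 blue), and
   OLS regression of behavioral distances on `D` and `C` with standardized
   betas, partial correlations, and R².

The synthetic generator (`make_ground_truth()`, `simulate_hemodynamics()`,
`simulate_optics()`, `simulate_behavior()`) produces recordings whose
channel dependence follows a known Gaussian graphical model, superposed
with cardiac/Mayer/respiratory oscillations, drift, common-mode motion
spikes, and white noise, so recovery of the planted structure can be
measured end to end (`recovery_experiment()`).

## Worked example

```r
library(fnirsconn)

truth <- make_ground_truth(15, n_edges = 12, strength = 0.5, seed = 7)
hemo  <- simulate_hemodynamics(truth, noise_spec(),
                               scenario_spec(watch_duration_s = 292.5,
                                             decision_duration_s = 142,
                                             seed = 7))
rec   <- simulate_optics(hemo)
pp    <- preprocess_recording(rec)
seg   <- segment_periods(rec$events, rec$fs, nrow(pp$hbo))
nets  <- period_networks(pp, seg, criterion = 0.28, participant = "p01")
metrics_table(nets)[, 1:4]
```

```
  participant_id    period   density clustering
1            p01    watch1 0.1904762 0.00000000
2            p01    watch2 0.2000000 0.04000000
3            p01    watch3 0.1714286 0.00000000
4            p01    watch4 0.2095238 0.00000000
5            p01 decision1 0.1904762 0.05555556
6            p01 decision2 0.2000000 0.00000000
```

Twelve planted edges correspond to a true density of 12/105 ≈ 0.114. Run
through the full noisy pipeline, per-period densities come out higher
(~0.17–0.21): the 0.4 Hz low-pass leaves the series strongly
autocorrelated, which widens the sampling spread of the per-period partial
correlations, and the fixed 0.28 criterion then admits some spurious
edges. This is a property of fixed-threshold binary networks, not of the
estimator; on network-driven draws without nuisance noise the planted
structure is recovered almost exactly (below), and the methods vignette
discusses the trade-off.

```r
rep <- recovery_experiment(seeds = 1:20, n_participants = 6,
                           run_regressions = FALSE)
rep
#> recovery_report: 20 seeds x 6 participants
#>   edge sensitivity 0.999, FPR 0.0000
#>   density bias -0.0001, clustering bias -0.0002
#>   density lower in decision periods: 100% of seeds
```

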