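---
title: "mtkit methods: polarity, bundles, binding, and trace segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mtkit methods: polarity, bundles, binding, and trace segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtkit)
```

This vignette documents the statistical methods behind each `mtkit`
module: what is estimated, how, and where the estimators are expected to
break down. All examples run on seeded synthetic data from the package's
own generators, so every number shown here is reproducible.

## 1. Polarity from particle angles

A RELION-style particle table assigns each segment of a picked filament
an in-plane angle `psi_deg` and an out-of-plane `tilt_deg`. The in-plane
direction of a particle is the unit vector

$$u = (\cos\psi, \sin\psi),$$

and its reliability scales with how side-on the view is, so each particle
is weighted by $\sin(\mathrm{tilt})$. Particles with
$\sin(\mathrm{tilt}) < 0.1$ are nearly end-on: their in-plane angle is
ill-determined and they are excluded (`min_sin_tilt` in `mt_config()`).

Per filament, `filament_polarity()` computes a weighted circular mean of
the particle directions. Because a picked filament can mix segments
assigned in both polarities, the consensus is chosen between the two
antipodal candidates by maximizing the weighted resultant length; the
fraction of particles that had to be flipped is reported as `n_flipped`.
The **coherence** of a filament is the weighted mean resultant length in
the doubled-angle (axial) representation, which is invariant to polarity
flips; filaments below `coherence_threshold` (default 0.8) are flagged
`confident = FALSE` and excluded from downstream pairing.

```{r polarity}
sim <- gen_bundle_star(n_pairs = 3, seed = 1)
fl <- sim$particles |> group_filaments() |> fit_axes() |> filament_polarity()
fl[, c("micrograph_id", "tube_id", "angle_deg", "coherence", "confident")]
```

## 2. Bundle detection and orientation

`fit_axis()` fits a straight axis to a filament's particle coordinates by
total least squares (the leading singular vector of the centered
coordinate matrix), which treats x and y symmetrically — appropriate when
both coordinates carry comparable picking error.

`find_pairs()` examines all filament pairs within a micrograph and keeps
those that run side by side: both members confident, axes nearly
parallel, and sufficient longitudinal overlap. For a kept pair,
`gap_distance()` reports the **edge gap**: the distance between filament
centerlines minus one filament diameter (25 nm), i.e. the wall-to-wall
spacing. `classify_pair()` then compares consensus polarities: an
inter-polarity angle below 90° is *parallel*, above 90° *antiparallel*,
and within ±1° of 90° *ambiguous*.

`bundle_summary()` aggregates the pair table: counts per class, gap
statistics and histogram, and an exact binomial test of the parallel
fraction against 0.5, the null expectation if bundling were indifferent
to relative polarity.

```{r bundles}
simb <- gen_bundle_star(n_pairs = 40, fraction_parallel = 0.5,
                        angle_noise_deg = 0, coord_noise_nm = 0,
                        tilt_noise_deg = 0, seed = 2)
trace_bundles(simb$particles)$summary
```

With noise switched off the recovered classes and gaps match the
generator's serialized ground truth exactly; the test suite asserts this.

## 3. Binding and bundling biochemistry

Co-sedimentation densitometry reduces to `band_fraction(pellet,
supernatant)`, the background-corrected pellet fraction. `fit_isotherm()`
fits the single-site isotherm

$$f = \frac{B_\max \cdot L}{K_d + L}$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`), per replicate
and pooled. A quadratic model accounting for ligand depletion is
available via `model = "quadratic"` for tight binders measured near the
receptor concentration. Diagnostics (`flat data`, concentration span
narrower than the fitted $K_d$ range) are surfaced as warnings rather
than silent failures. `tidy()` returns per-replicate parameters,
`glance()` the one-row summary, and `autoplot()` the data with the fitted
curve on a log concentration axis.

`sec_oligomer()` calibrates a size-exclusion column by regressing
$\log_{10}(\mathrm{MW})$ on elution volume over the standards, then
interpolates the sample's apparent MW and divides by the theoretical
monomer MW, rounding to the nearest integer oligomeric state. Requests
outside the calibrated volume range are refused (extrapolation on a
log-linear fit is not trustworthy).

```{r sec}
stds <- tibble::tibble(mw_kDa = c(66, 29, 12.4), elution_mL = c(10, 12, 13.9))
sec_oligomer(stds, sample_elution_mL = 10.0, theoretical_mw_kDa = 34)
```

## 4. Trace segmentation

This is the numerically hardest module. A length-versus-time trace with
sampling interval 1 s and additive Gaussian noise of ~20 nm must be
partitioned into phases (growth / pause / shrinkage) well enough that
the mean growth rate is recovered within a few percent even when true
growth moves only ~1.7 nm/s — i.e. a per-sample displacement less than a
tenth of the noise standard deviation.

`segment_trace()` builds an initial segmentation from windowed velocity
classification against a pause band, then refines it with a piecewise-
linear changepoint stack. Every decision in the stack is driven by a
single noise scale $\hat\sigma$, estimated robustly from the median
absolute deviation of second differences
($\hat\sigma = \mathrm{MAD}(\Delta^2 y)/(0.6745\sqrt{6})$), and a common
contrast level $z = 3$:

1. **Boundary refinement.** Each interior boundary is moved to the
   sample that minimizes the exact two-line residual sum of squares
   (RSS) in its neighborhood.
2. **Boundary pruning.** A boundary is removed when the slope contrast
   across it, $|b_1-b_2| / (\sigma\sqrt{1/S_{xx,1}+1/S_{xx,2}})$, falls
   below $z$ — i.e. when the two lines are statistically the same line.
3. **Splitting.** Binary segmentation inserts a boundary inside a phase
   when the best two-line fit beats the one-line fit by at least
   $\sigma^2 (z^2 + 2\log k)$ for a phase of $k$ samples; the $\log k$
   term is a Bonferroni-style correction for searching $k$ candidate
   positions.
4. **Minimum-duration absorption.** Phases shorter than `min_phase_s`
   are merged into a neighbor, *except* short shrinkage phases that are
   distinguishable from both neighbors at level $z$: catastrophe-
   shortening events are brief, steep and real, and must not be averaged
   away. Short positive-slope excursions get no such protection — at
   this noise level they are overwhelmingly noise spikes.
5. **Flicker rejection.** An interior phase is kept only if the
   three-line fit (left / phase / right) beats the single-line fit by
   twice the split penalty; otherwise the phase and both its boundaries
   are deleted. This removes few-sample "steep growth" artifacts that
   survive pairwise tests by splitting their evidence across two
   boundaries.
6. **Level-aware merging.** Adjacent phases of the same kind are merged
   only if doing so costs less RSS than the split penalty. Blind
   same-kind merging is wrong for pauses: two pauses at different
   heights, separated by a step, would otherwise refit into a single
   bogus shallow-growth line.
7. A final split / refine / absorb cycle catches boundaries exposed by
   the earlier merges.

```{r dynamics}
tr <- tibble::tibble(time_s = 0:119,
                     length_nm = c(10 * (0:59), 10 * 59 - 30 * (1:60)))
segment_trace(tr)
```

`event_statistics()` then counts growth→shrinkage transitions as
catastrophes and shrinkage→growth transitions as rescues, dividing by
total growth time and total shrinkage time respectively, and averages
per-phase growth rates weighted by duration.

### Known limitation

At the slow-growth regime (~1.7 nm/s with frequent pauses), a 30-second
growth burst rises only ~50 nm — about 2.5 noise standard deviations.
Bursts near the detection threshold are found preferentially when noise
makes them look shallower or are truncated at their steep core, which
biases the recovered mean growth rate *downward* by roughly 5–10% in
this regime. This is a selection effect at the information limit of the
data, not a fixable bug: sharpening the thresholds to reach such bursts
admits noise spikes that bias the estimate upward by far more. The
acceptance tolerance for this condition (10%) reflects that floor; the
two fast conditions (~14–15 nm/s) recover within ~1%.

## 5. Synthetic generators and ground truth

`gen_traces()` simulates each trace as a continuous-time Markov chain
over {growth, shrinkage, pause} with exponential holding times
(catastrophe, rescue, pause entry/exit rates), integrates the piecewise-
constant velocity, reflects length at zero, samples on the regular grid
and adds Gaussian noise. `gen_bundle_star()` lays out filament pairs
with controlled polarity composition, gap range and angular noise, and
emits a valid particle STAR table. `gen_cosed()` draws replicate
densitometry with multiplicative noise around an exact isotherm. Every
generator:

- is deterministic given `seed`, and restores the caller's RNG state;
- returns `truth` alongside `data`, serializable with
  `write_ground_truth()` / `read_ground_truth()` so recovery tests never
  depend on re-deriving what was simulated.

The test suite checks the chain generator against an analytic oracle:
the long-run phase occupancy must match the stationary distribution of
the rate matrix (solved directly from $Q^\top \pi = 0$,
$\sum_i \pi_i = 1$).

### Problem sizes

| Quantity | Typical size |
|---|---|
| Particles per STAR file | ~3,500 (177 pairs × ~10 particles/filament) |
| Isotherm fit | 8 concentrations × 3 replicates, 200 simulations |
| Dynamics | 50 traces × 600 samples |

All documented analyses run in well under a minute on a single core;
the full acceptance script (`scripts/acceptance.R`) takes ~30 s.
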