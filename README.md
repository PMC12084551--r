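# mtkit

Tidy analysis toolkit for cytoskeletal filament experiments. `mtkit` covers
the quantitative workflow of a microtubule-bundling study end to end:

- **STAR I/O** — read and write RELION-style particle STAR files (both the
  flat 3.0 layout and the 3.1 `data_optics` layout), with validated column
  mapping to a tidy particle tibble.
- **Polarity** — convert per-particle Euler angles into in-plane direction
  vectors, down-weight near-end-on views, and form a per-filament consensus
  direction by weighted circular averaging with an axial two-orientation
  confidence test. Arrow overlays are available as ggplot2 layers or
  standalone SVG.
- **Bundles** — fit filament axes by total least squares, detect filament
  pairs that run side by side in the same micrograph, measure wall-to-wall
  edge gaps, classify pairs as parallel / antiparallel / ambiguous, and
  summarize the composition with an exact binomial test against a 50:50
  mixture.
- **Biochemistry** — co-sedimentation densitometry (`band_fraction`),
  single-site isotherm Kd fitting with hyperbolic and quadratic (ligand
  depletion) models, dose-response summaries, and size-exclusion
  chromatography calibration to an oligomeric state.
- **Dynamics** — segment length-versus-time traces into growth, pause and
  shrinkage phases with a noise-adaptive piecewise-linear changepoint stack,
  then compute dynamic-instability statistics (growth rate, catastrophe and
  rescue frequencies, pause times).
- **Synthetic data** — seeded generators for every pipeline stage
  (`gen_bundle_star`, `gen_cosed`, `gen_traces`), each returning the data
  plus serialized ground truth, so recovery can be tested quantitatively.
- **CLI** — an `exec/mtkit` front end exposing the pipelines to shell
  scripts (`polarity`, `bundles`, `binding`, `dynamics`, `sec`, `simulate`).

Functions take and return tibbles, model objects support broom-style
`tidy()` / `glance()`, and result classes have `autoplot()` methods.

## Worked example

Simulate a micrograph set of 177 bundled filament pairs (91 parallel),
trace polarity, and summarize the bundle composition:

```r
library(mtkit)

sim <- gen_bundle_star(n_pairs = 177, fraction_parallel = 91 / 177, seed = 42)
res <- trace_bundles(sim$particles)
res$summary
#> Bundle summary: 177 pairs (91 parallel, 86 antiparallel, 0 ambiguous)
#>   fraction parallel 0.514 (exact binomial p = 0.7638 vs 0.5)
#>   edge gap [nm]: min 1.860, max 14.145, mean 7.540, sd 3.440
```

Fit a binding isotherm to simulated co-sedimentation data:

```r
cs <- gen_cosed(kd_uM = 0.69, seed = 1)
d <- cs$data
d$fraction_bound <- band_fraction(d$pellet, d$supernatant)
fit <- fit_isotherm(d)
fit
#> Single-site isotherm fit (hyperbolic model)
#>   Kd = 0.68 +/- 0.0554 uM (mean +/- SD over 3 replicates)
#>   Bmax = 1 +/- 0.0187
#>   pooled: Kd = 0.676 uM, Bmax = 1, rms residual 0.034
autoplot(fit)   # data + fitted curve on a log concentration axis
```

Estimate oligomeric state from a SEC calibration:

```r
stds <- tibble::tibble(mw_kDa = c(66, 29, 12.4), elution_mL = c(10, 12, 13.9))
sec_oligomer(stds, sample_elution_mL = 10.0, theoretical_mw_kDa = 34)
#> SEC: apparent MW 66.8 kDa / theoretical 34.0 kDa = 1.96 -> 2-mer
```

Segment noisy dynamics traces and recover the growth rate:

```r
tr <- gen_traces(v_g = 14.73, v_s = -300, f_cat = 0.005, f_res = 0.02,
                 duration_s = 600, n_traces = 50, length_noise_nm = 20,
                 seed = 11)
st <- event_statistics(segment_traces(tr$data))
dplyr::select(st, growth_rate_mean, growth_rate_sem, f_cat, n_cat)
#> # A tibble: 1 x 4
#>   growth_rate_mean growth_rate_sem   f_cat n_cat
#>              <dbl>           <dbl>   <dbl> <int>
#> 1             14.7          0.0478 0.00394   115
```

Lattice arithmetic helpers are also exported:

```r
dimer_rise_delta(83.96, 82.25)$delta_display
#> [1] "1.7"
```

## Command line

```sh
exec/mtkit simulate bundles --seed 42 --out simdir/
exec/mtkit bundles  --star simdir/particles.star --out bundles/
exec/mtkit binding  --csv densitometry.csv --out fit/
exec/mtkit sec      --standards standards.csv --elution 10 --mw 34 --out sec/
```

Every run also writes a `manifest.json` recording the command, flags,
effective configuration, seed, input checksums, and package version.

Run `exec/mtkit` with no arguments for the full usage summary.

## Methods

The segmentation algorithm, its noise model, and the generators' design are
described in the package vignette (`vignettes/mtkit-methods.Rmd`), including
known limitations of growth-rate recovery for slow, pause-riddled traces.

## License

MIT. See `LICENSE`.
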