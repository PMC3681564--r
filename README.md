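# fmlr2d

Model-based profiling of 2D ¹H–¹³C HSQC NMR ensembles for plant cell-wall
analysis: fast maximum-likelihood reconstruction (FMLR) of every signal in a
stack of related spectra, region-of-interest (ROI) segmentation of the fitted
amplitudes into a feature matrix, lignin S:G:H composition, and many-to-one
group statistics.

## Who this is for

Labs running comparative HSQC studies of complex polymeric material (cell
walls, lignins, other broad-linewidth systems) who need reproducible,
operator-light quantification of dozens of components across tens of
spectra — including unassigned but resolved regions — and group-level
statistics computed directly on a meaningful feature set.

## The method in brief

Each 2D signal is a five-parameter time-domain model: amplitude `A`,
frequencies `ω_H`, `ω_C`, and decay rates `α_H`, `α_C`, built from the basis
`exp(iωt)·exp(-αt^η)` per dimension (`η` fixed per analysis; `η = 1` gives
Lorentzian lines of FWHM `α/π` Hz). The model FID is pushed through the same
per-dimension processing operator `F^d` (apodization → zero-fill → FT →
phase) as the data, so the fit happens in the processed-spectrum domain.
Reconstruction is greedy: peak-pick the residual above a threshold that
halves every iteration down to a floor of 4 × noise SD, seed each pick with
prototype linewidths (box-constrained to 1/2–2× the prototype, e.g.
40–160 Hz for an 80 Hz prototype), and refine clusters by bounded
least squares with analytic Jacobians.

Fitted amplitudes are assigned to ROIs by peak-centre containment, with a
"gravity metric" (Σ source·peer amplitude / distance) resolving overlapping
boxes. Feature matrices are normalized per spectrum by lignin content

    L = [S2/6] + [S'2/6] + 2[G2] + 2[G'2] + [H2/6]

and composition follows the same weights
(`%S = 100([S2/6]+[S'2/6])/L`, etc.). Group differences are tested per ROI
by one-way ANOVA with Dunnett many-to-one adjustment (seeded Monte Carlo
multivariate-t, simultaneous 95% intervals).

## Worked example

Simulate a wild-type-vs-mutant study with a known syringyl-to-guaiacyl
shift, reconstruct it, and test the composition difference:

```r
library(fmlr2d)

sim <- simulate_ensemble(
  list(sim_group("WT",   5, c(S = 28, G = 70,   H = 2)),
       sim_group("f5h1", 5, c(S = 3,  G = 94.9, H = 2.1))),
  signal_rois = character(0), snr = 50, seed = 1)

rois <- bundled_roi_template()
axes <- default_axes()
ops  <- default_ops(axes)

dec <- deconvolve_ensemble(sim$ensemble, rois, prototype_config(80, 80), ops)
dec
#> <deconvolution_result: 55 signals (275 parameters), 8 iterations, noise SD 40>

sig <- assign_signals(dec$signals, rois)
fm  <- build_feature_matrix(sig, rois,
                            sapply(sim$ensemble, `[[`, "sample_id"),
                            sapply(sim$ensemble, `[[`, "group_label"))
dunnett_sgh(fm, "WT", seed = 1)
#>   roi_id label group        delta      ci_low     ci_high   p_adj n_ref n_group
#> 1  pct_S    %S  f5h1 -25.95743595 -27.7234462 -24.1914257 0.00000     5       5
#> 2  pct_G    %G  f5h1  25.86225089  23.7916847  27.9328171 0.00000     5       5
#> 3  pct_H    %H  f5h1   0.09518506  -0.4259127   0.6162828 0.68336     5       5
```

The simulated −25 percentage-point drop in %S (matched by the rise in %G) is
recovered with tight simultaneous intervals and Dunnett-adjusted
significance; %H, unchanged by construction, is correctly non-significant.

A command-line driver wrapping the same functions ships at
`inst/cli/fmlr_profile.R`
(`simulate / deconvolve / features / normalize / stats / report`), writing
CSV/JSON outputs plus a manifest per stage.

## Package layout

- `R/axes.R`, `R/processing.R`, `R/lineshape.R`, `R/model.R` — axis
  calibration, the `F^d` operator, damped-sinusoid bases, 2D synthesis and
  analytic Jacobians.
- `R/fmlr.R` — noise estimation, prototype fitting, peak picking, cluster
  refinement, ensemble deconvolution.
- `R/roi.R`, `R/features.R` — ROI tables, containment and gravity
  assignment, feature matrices, direct integration.
- `R/stats.R` — normalizations, lignin content and S:G:H, Dunnett
  comparisons, Pearson screens.
- `R/simulate.R` — ground-truth generator and signal matching.
- `R/io.R` — JSON spectrum containers and CSV tables.
- `vignettes/cell-wall-profiling.Rmd` — the methods vignette (model,
  assumptions, design decisions, limitations).
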