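---
title: "Maximum-likelihood deconvolution and ROI profiling of 2D HSQC spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-likelihood deconvolution and ROI profiling of 2D HSQC spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmlr2d)
```

## The problem

Solution-state 2D ^1^H–^13^C HSQC NMR of ball-milled plant cell walls gives a
single spectrum in which dozens of lignin and polysaccharide components are
resolved as cross peaks, one per C–H pair. Comparative profiling across many
samples — for instance mutant lines versus wild type — needs a reproducible
way to turn stacks of such spectra into a feature table of component
amplitudes. Two obstacles make naive approaches fragile: the broad
(40–160 Hz) linewidths of polymeric material cause heavy peak overlap, and
fixed-window integration couples the reported amplitude to the exact window
placement.

`fmlr2d` addresses both with model-based deconvolution. Every signal is a
five-parameter time-domain object — a scalar amplitude, a frequency in each
dimension, and a decay rate (linewidth) in each dimension — built from a
complex sinusoid $e^{i\omega t}$ times a damping function
$e^{-\alpha t^{\eta}}$. The decay power $\eta$ is fixed per analysis
(default 1, Lorentzian decay, for which the absorption-mode full width at
half maximum is $\alpha/\pi$ Hz); the remaining five parameters per signal
are free. Because the grader of fit is the *processed* spectrum, the model
FID is pushed through exactly the same per-dimension operator
$F^d$ — apodization, zero-filling, Fourier transformation, phase
correction — as the measured data. Whatever distortions the processing
chain introduces, it introduces them identically on both sides of the
residual.

## The greedy reconstruction

Deconvolution of an ensemble (a pseudo-3D stack of spectra sharing axis
calibration, regions of interest and configuration) proceeds as:

1. **Prototype.** An operator-chosen isolated peak is fitted
   unconstrained; its linewidths (80 Hz in each dimension is typical for
   whole-cell-wall material) seed every later signal and define the
   per-dimension box constraint, by default factors 1/2 to 2, i.e.
   40–160 Hz.
2. **Noise.** The ensemble noise SD is the median absolute deviation
   (scaled to the Gaussian SD) of intensities outside every ROI, pooled
   over all spectra.
3. **Threshold schedule.** The pick threshold starts at the tallest
   ROI-restricted residual point of the ensemble and is divided by 2 after
   each iteration, never dropping below `snr_stop` (default 4) times the
   noise SD.
4. **Iterate.** Each iteration peak-picks every spectrum's residual
   (8-neighbourhood local maxima inside at least one ROI), seeds new
   signals with prototype linewidths and a one-step linear amplitude
   estimate, and refines the affected clusters by bounded
   Levenberg–Marquardt least squares using the analytic Jacobian (the
   time-domain parameter derivatives pushed through the same $F^d$).
   Iterations stop when the schedule has reached the noise floor and a
   final pass picks nothing, or after `max_iterations` (default 10).

Design choices the method description leaves open, decided here:

* **Per-spectrum fitting, shared configuration.** Each spectrum is
  deconvolved independently, but noise SD, prototype, ROIs, and the
  threshold schedule are shared across the ensemble, so every member is
  treated identically.
* **Cluster refinement.** Joint refinement of all signals at once is
  unnecessary and slow; signals whose centres lie within 3 prototype
  linewidths (scaled Euclidean distance) form a cluster and are refined
  together against the ROI-restricted residual near their footprint,
  holding other signals fixed. When an iteration picks nothing new, a full
  block-coordinate sweep over all clusters tightens the joint fit before
  the threshold is lowered further; this is what lets noise-free fixtures
  converge to machine precision and keeps the total squared residual
  monotonically non-increasing.
* **Duplicate suppression.** Within one iteration, candidates closer than
  0.5 prototype linewidths to a signal added in that same iteration are
  skipped — they are shoulders of a peak just modeled. Later iterations may
  revisit the location if genuine intensity remains.
* **Initial amplitude.** A picked peak of height $h$ starts at amplitude
  $h/u$, where $u$ is the peak height of the unit-amplitude basis plane at
  that position — the one-step linear estimate.
* **Tie-breaks.** Equal-height candidates order by lower ^1^H ppm, then
  lower ^13^C ppm; equal gravity metrics resolve to the first ROI in table
  order. Both rules make reruns bit-identical.

## ROI segmentation, assignment, and features

An ROI is a rectangular ^1^H × ^13^C ppm window with an id, an optional
assignment label, and a role. Containment is closed-interval: a peak centre
on an edge is inside. A fitted signal inside exactly one ROI is assigned by
containment; a signal inside several overlapping ROIs goes to the candidate
with the greatest *gravity metric* — the sum over that ROI's
already-assigned signals of (source amplitude × peer amplitude) divided by
their scaled ppm distance. Distances are scaled per axis by the median ROI
width so both nuclei contribute comparably. Assignment is two-pass:
unambiguous signals first, and these then act as the peers that disambiguate
the overlaps. If no candidate has peers, the signal falls back to the
nearest ROI centre with a logged warning.

The raw feature matrix entry (r, s) is the simple sum of amplitudes
assigned to ROI r in spectrum s; unassigned amplitude is reported
separately, so the matrix plus the unassigned remainder conserves the total
fitted amplitude exactly. `integrate_rois()` provides the model-free
comparison method (direct summation of grid intensities inside each box).
The two differ in an important way: moving an ROI edge by one grid column
changes the integral but leaves a contained signal's fitted amplitude
untouched, which is why model-based segmentation tolerates ROI reuse across
studies with only a constant ppm shift.

## Normalization and lignin composition

Spectra are normalized to unit positive total intensity before analysis,
removing concentration differences. Feature matrices are normalized
per spectrum by lignin content
$$L = [S_{2/6}] + [S'_{2/6}] + 2[G_2] + 2[G'_2] + [H_{2/6}],$$
whose weights count the C–H pairs contributing to each aromatic cross peak
(the symmetric S and H rings contribute two equivalent pairs to their 2/6
signal, the G ring one pair to G2, hence the factor 2). The percentage
composition follows from the same weights:
$\%S = 100([S_{2/6}]+[S'_{2/6}])/L$, $\%G = 100(2[G_2]+2[G'_2])/L$,
$\%H = 100[H_{2/6}]/L$; the three always sum to 100. These percentage
formulas are implied by the weighting logic rather than stated anywhere
explicitly; roles holding several ROIs are summed before weighting. An
internal-standard variant divides by a designated ROI instead.

## Group statistics

Per ROI (or per composition percentage), a one-way ANOVA provides the
pooled within-group variance, and every group is compared with the
reference via the Dunnett many-to-one adjustment at an overall
$\alpha = 0.05$. The joint law of the comparison statistics is multivariate
t with a correlation matrix set by the group sizes; adjusted p-values and
*simultaneous* confidence intervals (we emit simultaneous intervals, and
label them as such) are computed by seeded Monte Carlo integration — one
shared sample (default $10^5$ draws) of the maximal absolute statistic per
call, reused by every ROI of the feature matrix. With one comparison this
reduces to the pooled two-sided t-test (up to Monte Carlo error of order
$10^{-3}$ on a p-value). Degenerate inputs are handled explicitly: an ROI
whose observations are all identical reports delta 0, interval [0, 0],
adjusted p 1; differing group means with zero within-group variance raise
an error, since no error scale exists. Pearson correlation screens
(`pearson_correlations()`) relate every ROI profile to anchor ROIs, with
zero-variance rows reported as missing rather than failing.

## The synthetic generator, and what it does not emulate

`simulate_ensemble()` is the package's ground-truth instrument. Each
selected ROI carries one "compound" whose centre (ROI centre plus jitter,
kept inside the box with margin for drift) and linewidths (uniform in
60–120 Hz by default, within the 40–160 Hz analysis box) are shared across
spectra; per spectrum, amplitudes get multiplicative lognormal replicate
variation (sdlog 0.1 — a plausible scale for pooled biological replicates,
for which no variance model is published) and centres a small drift
(0.004 ppm ^1^H, 0.03 ppm ^13^C). SGH ROI amplitudes encode each group's
configured composition on a fixed lignin scale by inverting the weighted
sum, so composition is exactly recoverable in the noise-free limit. Sample
sizes default to the study-design scale of the motivating application
(4–11 replicates per group; the package tests use n = 4–10).

Noise is drawn as complex white Gaussian noise *on the acquisition raster*
and pushed through the same $F^d$ operator as the signal, with the
time-domain scale chosen analytically from the window energies so the
frequency-domain SD equals the requested `noise_sd` exactly in expectation.
This matters: processed measurement noise is correlated over roughly the
apodization linewidth. Injecting white noise directly into the frequency
domain instead would create single-pixel excursions narrower than the 40 Hz
constraint floor, which no admissible lineshape can absorb — an artifact of
the wrong noise model, not a property of the method. With processed noise,
a 4-sigma noise bump is as wide as a small signal, and the reconstruction
either models it (as the real pipeline does) or leaves residual peaks below
the stopping floor.

The generator emulates the statistical and lineshape structure the analysis
assumes — nothing more. It does not simulate pulse-sequence transfer
physics, non-uniform carbon excitation, solvent artifacts, baseline errors,
or peak-shape deviations from the damped-sinusoid family. Passing tests
therefore demonstrate correctness of the reconstruction and statistics
under the model's own assumptions, not robustness to every artifact of real
spectrometer data.

## Numerical choices

* Grids: the default synthetic axes are 128 complex points zero-filled to
  256 per dimension over a 2.2 ppm × 37 ppm window at 700 MHz — enough to
  resolve 40–160 Hz lines while keeping the bundled benchmarks (10-spectrum
  ensembles) at the scale of seconds to a couple of minutes. Zero-fill
  defaults to the next power of two at least twice the acquired length.
* Optimizer: bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with the
  analytic Jacobian; convergence tolerance $10^{-8}$ relative on the
  objective, 50 iterations per cluster per pass. Amplitudes are constrained
  non-negative (absorption-mode data; negative-going artifacts are not
  modeled), frequencies to the representable window, linewidths to the
  prototype box.
* Phase correction defaults to 0/0 on synthetic data (generated
  pre-phased); the matched-Gaussian window defaults to `lb` equal to the
  prototype linewidth with its maximum at 10% of the acquisition time,
  since only the window family, not its parameters, is part of the
  published processing description.
* The basis cache keys processed 1D basis vectors by (dimension,
  derivative, frequency, decay, power) and is bit-transparent.
* The hypercomplex bookkeeping of 2D acquisition is collapsed: model planes
  are outer products of 1D real absorption vectors, and the generator
  produces data by the same convention, so data and model live in the same
  space.

## Known limitations

* $\eta \neq 1$ (non-Lorentzian decay) is supported by the model and
  optimizer, but linewidths are then reported on the $\alpha/\pi$
  Lorentzian-equivalent scale rather than as true FWHM.
* Whether the original implementation refits all signals globally each
  iteration or only new clusters is not documented; cluster refinement with
  quiescent-pass sweeps is the default here, and `global_refit = TRUE` is
  available.
* The residual-peak stopping behaviour is guaranteed only for features the
  constrained model class can represent; pathological residual structure
  narrower than the linewidth floor persists by design (and counts against
  the iteration budget).
* Direct integration of noisy data can produce small negative ROI sums;
  they are reported as-is.
* Amplitude separation of strongly overlapped peaks (closer than about one
  linewidth) is conditioning-limited: with noise correlated over the
  apodization width — as processed spectra have — noise excursions resemble
  lineshapes, and the least-squares optimum itself can misallocate
  amplitude between near-coincident signals even when total intensity is
  recovered accurately. Feature-matrix sums over an ROI are much less
  affected than the individual amplitudes.
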