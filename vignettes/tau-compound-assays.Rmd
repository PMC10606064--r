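---
title: "Quantifying Tau-targeted compounds: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Tau-targeted compounds: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauassay)
library(dplyr)
```

`tauassay` packages the quantitative workflow used to characterise small
molecules directed against the microtubule-associated protein Tau: how
tightly they bind (fluorescence quenching), how well they suppress Tau
fibrillation (thioflavin-S kinetics), how strongly they inhibit cell
metabolism (MTT viability), and what they do to cell motility and to the
microtubule cytoskeleton (track metrics, image quantification).  Every
assay has a seeded synthetic generator with known ground truth, so each
estimator can be validated end to end without instrument data.  This
vignette records the models, their assumptions, and the numerical choices
that were genuinely open.

## Binding by tyrosine fluorescence quenching

Full-length Tau has no tryptophan; its intrinsic fluorescence is carried
by tyrosines emitting near 303 nm.  A ligand that quenches this signal
reports its own binding.  When only a fraction of the fluorophores is
accessible to the ligand, the regular Stern–Volmer plot
$F_0/F = 1 + K[Q]$ curves, and the signal follows the two-population
model

$$F([Q]) = \frac{f_a F_0}{1 + K[Q]} + (1 - f_a)\,F_0 ,$$

with $f_a$ the accessible fraction, $K$ the association constant and
$K_D = 1/K$ the dissociation constant.  The modified Stern–Volmer
transform makes this a straight line,

$$\frac{F_0}{\Delta F} = \frac{1}{f_a K}\cdot\frac{1}{[Q]} + \frac{1}{f_a},$$

and `fit_modified_stern_volmer()` estimates the parameters by unweighted
ordinary least squares on the transformed points, i.e. the graphical
procedure that practitioners apply to these titrations.  Choices worth
stating:

* **Unweighted OLS.** The reciprocal transform inflates the variance of
  low-concentration points; a weighted fit would down-weight them.  We
  keep the fit unweighted because that is the procedure the transform is
  meant to standardise, and offer `fit_quench_nls()` — direct nonlinear
  least squares on the untransformed model — as an independent
  cross-check (tests require the two routes to agree on clean data).
* **Exclusions rather than clipping.** Points with $\Delta F \le 0$
  (noise at low $[Q]$) are dropped and counted; clipping them would bias
  the intercept, hence $f_a$.
* **Inner-filter correction.** Observed intensities are corrected as
  $F = F_{obs}\exp((A_{ex}+A_{em})/2)$ when absorbance columns are
  supplied; absent absorbances produce an `"uncorrected"` flag rather
  than an error, since the correction is constant across the titration
  when only the protein absorbs.  The generator attenuates by the exact
  inverse, so the correction round-trips to machine precision.
* **Linearity flag.** Strongly curved modified Stern–Volmer plots mean
  the two-population interpretation fails (some ligands do this); fits
  with $r^2$ below `linearity_min` (default 0.95) are flagged
  `"nonlinear"`, and the threshold is a parameter because no universal
  criterion exists.
* **Uncertainties.** Standard errors of $f_a$ and $K_D$ come from the OLS
  coefficient covariance by the delta method.

```{r quench-example}
truth <- quench_truth(f_a = 0.12, K = 1 / 2.4e-6, noise_cv = 0, seed = 1)
titr <- simulate_titration(truth, c(0, 2, 5, 10, 20, 50, 100) * 1e-6)
glance(fit_modified_stern_volmer(titr))
```

## Aggregation kinetics and the inhibition IC50

Heparin-induced assembly of Tau filaments followed by thioflavin-S
fluorescence rises to a plateau; each well is fitted with the empirical
exponential form $Y = Y_0 + A e^{t/\tau}$ (signed convention: $A < 0$,
$\tau < 0$), by Levenberg–Marquardt with starting values $Y_0$ = last
point, $A$ = first − last, $\tau$ = −span/3, an iteration cap of 500 and
relative tolerance $10^{-10}$.  The fitted $Y_0$ is the plateau.  For
non-converging wells, `plateau_value()` falls back to the mean of the
last three points (configurable).  No nucleation–elongation mechanism is
implied: the empirical plateau is the contract.

Percent inhibition compares plateaus against the untreated control over
an explicit dye background,

$$\mathrm{inh} = 100\,\frac{Y_{0,\mathrm{ctrl}} - Y_{0,\mathrm{treated}}}
{Y_{0,\mathrm{ctrl}} - \mathrm{baseline}},$$

capped at 100.  The baseline defaults to the control fit's time-zero
intercept ($Y_0 + A$); whether the correct reference is dye-only
background or time-zero signal is an assay-specific question, so it is a
parameter of `ths_inhibition_analysis()`.  This definition is the only
one that reads "full suppression of assembly" as exactly 100 %, and it is
invariant under adding a constant to all three intensities.

The IC50 is read off an OLS line of inhibition against
$\log_{10}$ concentration: the concentration where the fitted line
crosses 50 %.  Two points deserve emphasis:

* **Saturated points are excluded.**  The dose law is linear in
  concentration until full inhibition; wells pinned at the 100 % cap
  carry no slope information and would bias the line.
* **Panel placement matters.**  The inhibition readout is linear in $C$
  but the regression is linear in $\log_{10} C$; this mismatch gives the
  estimator a deterministic curvature bias that grows quadratically with
  the panel's width on the log axis.  Measured on noiseless data, a
  2-fold geometric series misses the generator truth by 8–31 % depending
  on placement, while a six-point bracket within ±0.1 decade of the 50 %
  point recovers it to about 1 %.  `ths_panel_concentrations()` encodes
  that bracket and is the default panel for recovery-grade experiments.
  A literal alternative reading of the IC50 rule ("ten to the power of
  the slope") is recorded as `ic50_literal` for comparison but is
  dimensionally inconsistent and never reported as the estimate.

```{r ths-example}
agg <- aggregation_truth(half_inhibition_conc = 17.3, noise_cv = 0, seed = 1)
panel <- simulate_ths_panel(agg, ths_panel_concentrations(17.3))
res <- ths_inhibition_analysis(panel)
glance(res$ic50_fit)
```

The generator's dose law — inhibition linear in the ligand/Tau ratio up
to a plateau at full inhibition, parameterised by its 50 % point — is the
behaviour these assays exhibit; the time grid defaults to a reading every
15 min for 8.75 h (36 points) at 2 µM Tau.  `dissolution_trend()` covers
the companion assay on preformed filaments, classifying wells as
dissolving or stable by a sign test on successive differences at
configurable $\alpha$.

## Viability by the median-effect method

MTT plates are normalised as blank-corrected treated/untreated absorbance
ratios (`normalize_plate()`, replicates averaged before the ratio).  The
IC50 is estimated by the Chou–Talalay linearisation

$$\log_{10}\frac{f_a}{f_u} = m\,\log_{10} D - m\,\log_{10} D_m,$$

with $f_a = 1 - $ viability, $f_u = $ viability, slope $m$ and median
effect dose $D_m$ (= IC50 by definition of the plot).  Doses with
viability at or beyond the (0, 1) limits are excluded with a logged
count, never clipped: clipping fabricates dynamic range.  Apparent
stimulation (viability > 1) is likewise flagged upstream and excluded.
No four-parameter logistic alternative is fitted; the median-effect model
is the contract.  Fit standard errors (delta method) are reported
separately from any across-replicate spread the caller computes.

```{r viability-example}
dr <- simulate_viability(m = 1, Dm = 1.6, doses = 0.2 * 2^(0:6),
                         noise_cv = 0, seed = 1)
glance(fit_median_effect(dr))
```

## Migration metrics

Tracks are time-stamped 2-D positions, 61 frames over 600 min by default.
Per track: total distance (path length), distance to origin (net
translocation), velocity = total distance / 600 min, and directional
persistence = distance to origin / total distance.  The 600 min
denominator is the assay's fixed convention; a cell lost before the end
of recording uses its own elapsed time and is flagged.  Persistence of a
motionless track is defined as 0 (flagged degenerate) so population means
stay defined.  Positions are not smoothed.  `population_summary()` gives
group mean ± s.e.m., percent change against a reference group, and
Wilcoxon rank-sum p-values.

The generator is a persistent random walk: headings accumulate
wrapped-Gaussian increments with variance $2\,\Delta t/P$ (step-to-step
direction correlation $e^{-\Delta t/P}$ for persistence time $P$), and
step lengths are gamma-distributed about mean speed × $\Delta t$ (shape
4, a 50 % per-step coefficient of variation typical of single cells;
shape `Inf` gives noiseless steps).  It reproduces the statistical
structure the metrics assume — stationary speed, finite directional
memory — but not stage drift, cell division, or collisions; passing
tests certify the estimators, not those artefacts.

## Microtubule surface fraction

The imaging readout is the percent of the cell surface occupied by the
microtubule network.  The actin channel defines the cell (Otsu
binarisation, hole filling, largest connected component — a single-cell
contract; multi-cell segmentation is out of scope), and the tubulin
channel is thresholded by Otsu **within the cell mask only**; the ratio
of foreground to cell pixels is the readout.  The Otsu search is an
exhaustive scan over a 256-bin histogram minimising the intra-class
variance, with per-bin moment sums kept exact (no midpoint
approximation), so it coincides with a brute-force scan over every
distinct intensity whenever bins resolve the intensity levels; tests
enforce that agreement on enumerated toy rasters and against an
independent implementation.  The returned cut sits mid-gap between the
two classes, making `raster > threshold` reproduce the optimal split
exactly.  A local (circular-ROI) variant is available for unevenly lit
crops; it is quadratic in the radius per pixel and intended for small
images.  Constant-offset background subtraction is exposed and off by
default, since background handling upstream of thresholding is rarely
specified quantitatively.

The synthetic image is a disk-shaped cell with a filament-like tubulin
foreground: cell pixels are ranked by distance to random chords and
exactly the required number become foreground, so ground-truth coverage
is exact at pixel resolution.  With noise at 10 % of contrast on a
512×512 frame the pipeline recovers a 39 % ground truth to a fraction of
a percentage point; a test sweeps coverage over 31–41 % (the
physiological range of tubulin in microtubules) with noise up to 20 % of
contrast and requires mean absolute error ≤ 2 points.

```{r imaging-example}
img <- simulate_cell_image(
  image_truth(width = 128, height = 128, mt_coverage_of_cell = 0.39,
              noise_sd = 15, seed = 7))
microtubule_surface_ratio(img)
```

## Determinism, seeds and problem sizes

Every generator takes a mandatory integer seed and evaluates under a
local RNG scope (`withr::with_seed`), so global RNG state is never read
or written: identical (truth, seed) gives identical data, and changing
the seed changes only the noise, never the noiseless expectation.
`run_pipeline()` composes the five stages from one configuration
(validated, unknown keys rejected) and is byte-deterministic given
(config, seed).

Test-suite problem sizes are chosen to exercise the estimators' sampling
behaviour while keeping the default run light: 1000 seeded titration
replicates for the $K_D$ bias check, 500 replicates each for plateau
coverage and viability spread, 200 synthetic images at 128×128 for the
coverage sweep, and 80 tracks per population (the per-experiment cell
count typical of these motility assays) for the velocity contrast.

## Known limitations

* The quench fit assumes static quenching of two populations; it does
  not separate static from dynamic quenching (no lifetime data) and is
  single-temperature (no van't Hoff analysis).
* The ThS model is empirical; lag-phase/nucleation features and seeding
  assays are out of scope, and strongly sigmoidal wells will fit poorly
  (flagged by convergence status).
* The IC50 log-linear readout is only locally consistent with the linear
  dose law; keep panels bracketed around the anticipated 50 % point.
* The imaging module quantifies a single cell per frame and does no
  flat-field correction; real micrographs with uneven illumination
  should use the local-threshold variant or be corrected upstream.
* Synthetic data emulate the statistical structure of plate-reader and
  microscope output (multiplicative CV noise, additive image noise), not
  instrument-specific artefacts (photobleaching, drift, well-edge
  effects); green tests certify estimator correctness under the stated
  models, not robustness to those artefacts.
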