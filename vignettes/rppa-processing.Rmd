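---
title: "Processing RPPA slides: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing RPPA slides: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rppaquant)
```

## The joint response model

A reverse-phase protein array slide prints each sample as a serial
dilution series and probes the whole slide with one antibody. Spot
intensity is a saturating function of protein amount, so the package
models every spot on a slide with a single three-parameter logistic curve

$$ y_{ij} = \alpha + \frac{\beta}{1 + e^{-\gamma (x_i + d_j)}} + \varepsilon_{ij}, $$

where $x_i$ is series $i$'s relative log2 concentration, $d_j =
-(j-1)\log_2 f$ the known offset of dilution step $j$ at factor $f$,
$\alpha$ the baseline intensity, $\beta$ the dynamic range and $\gamma$
the slope per log2 unit. The key assumptions are: one common curve per
slide (antibody binding kinetics do not differ by sample), known dilution
offsets, and additive homoscedastic intensity noise (the fit is unweighted
least squares). The midpoint of the curve is pinned at $x = 0$; without
that anchor a shift of all $x_i$ could be traded against a horizontal
shift of the curve. Concentrations are therefore *relative*: comparable
within a slide, with no absolute unit.

Fitting works in two phases. First, alternating optimization: given the
positions, the three curve parameters are refit by nonlinear least squares
(Levenberg–Marquardt); given the curve, each $x_i$ is updated
independently by bounded one-dimensional minimization over $[-15, 15]$
log2 units. The alternation stops when the relative RSS decrease falls
below `rss_tolerance` (default `1e-8`), when the RSS becomes negligible
against the total sum of squares (below `1e-14` of it — on noise-free data
the RSS decays geometrically toward zero and a purely relative criterion
would never trigger), or after `max_iterations` (default 100). Second, a
joint Levenberg–Marquardt refinement over all parameters at once, with an
analytic Jacobian, started from the alternating solution *and* from the
deterministic initialization, keeping the better optimum. The second start
matters: on small slides the alternation occasionally wanders into the
degenerate near-linear basin ($\gamma \to 0$ with a compensating huge
$\beta$), and refinement from the initialization recovers the proper
logistic optimum. The test suite verifies against an independent
simultaneous optimizer that the full path attains the joint least-squares
optimum to within $10^{-6}$ relative RSS.

Initialization is deterministic and scale-aware: $\alpha_0$ and
$\alpha_0 + \beta_0$ at the 5th and 95th intensity percentiles,
$\gamma_0 = 1$, and each $x_i$ at the inverse logistic of its series'
clamped mean intensity. Negative net intensities are retained — censoring
them would bias $\alpha$ upward.

### Standard errors, flags, exclusions

The standard error of $\hat x_i$ is curvature-based:
$\mathrm{se}(\hat x_i) = \sigma / \sqrt{\sum_j g'(\hat x_i + d_j)^2}$
with $g'$ the response slope and $\sigma^2$ the residual variance of the
slide fit. A series whose intensities all sit above
$\alpha + 0.99\,\beta$ (or below $\alpha + 0.01\,\beta$) is flagged
`Saturated` (`BelowDetection`) and clamped to the position bound: the
inverse logistic is uninformative at the asymptotes, and 1%/99% of the
dynamic range is where its derivative has effectively vanished at typical
noise levels. A non-converged fit flags everything `PoorFit` but still
returns estimates.

Users may exclude known-bad series from curve construction (the same list
applies to every slide of a batch); excluded series are afterwards
projected onto the frozen curve, so they still receive estimates. By
construction, estimates of the remaining series are identical to a run in
which the excluded series is absent — the suggested workflow is to inspect
`fit_diagnostics()`' residual ranking, choose exclusions, and re-run.
Curve fitting requires at least `min_series = 8` non-excluded series: the
three curve parameters plus the identifiability anchor need support beyond
the per-series positions. Positive controls and noise replicates are
genuine dilution series and participate in the fit by default
(`fit_options(fit_spot_types=)`); negative controls, buffer and blank
spots never do. A slide whose intensity range is at or below `min_signal`
(default `1e-3` fluorescence units) is rejected as "no signal" rather
than fitted.

## Design inference

The slide design — grid dimensions, dilution ladder, series roster, spot
type map — is inferred from the first file (lexicographic order) that
parses cleanly, and every subsequent slide must match it exactly;
mismatches are per-slide errors, not reinterpretations. The dilution
factor is the ratio of consecutive declared dilutions, required to agree
within `1e-6` relative — a deliberate tripwire for hand-edited files. A
single dilution step per sample is rejected: the joint model needs serial
dilutions. The expected input dialect is fixed (tab-separated, header
`Order, Main.Row, Main.Col, Sub.Row, Sub.Col, Series.Id, Spot.Type,
Dilution, Net.Value, Raw.Value, Background.Value`) so outputs are
reproducible byte for byte.

## Spatial adjustment

Print and staining artifacts vary smoothly over the slide surface.
Technical-replicate spots expose them: spots of replicate series at the
same dilution step print the same material, so each control's log2
deviation from its group's 10%-trimmed mean is pure bias plus noise. The
deviations are smoothed over the physical grid (main-by-sub coordinates
flattened to rows and columns; scanner X/Y positions are ignored as
dialect-dependent) by degree-1 loess — local linear regression with
tricube weights — at `span = 0.75`. A large span is intentional: the
surface should capture slide-scale trends, not chase individual spots; the
no-signal guard in the tests (median $|\log_2 m| \le 0.1$ on i.i.d. noise)
would catch an overfitting smoother. The smoothed surface is exponentiated
to a multiplicative correction $m(r,c)$, clamped to $[0.25, 4]$, and
median-centered so that a global intensity shift — which is the curve
fit's business, not the spatial stage's — is never removed. Correction
divides net intensity; whether the original correction in this lineage is
multiplicative on intensity or additive on log intensity is not something
the data distinguish at these noise levels, and multiplicative keeps raw
and corrected values on the same scale. The stage is optional and off by
default; it needs at least `min_controls = 10` usable controls, and warns
when controls cover less than a quarter of the grid (the surface is then
extrapolated). It runs before curve fitting, so fitted concentrations see
bias-corrected intensities.

## The noise metric

Replicate series all print one sample, so the spread of their estimated
concentrations is measurement error. The metric is their sample standard
deviation (n−1), computed on **log2 concentration estimates**, not raw
intensities: that places it on the same scale as the sample output, makes
it comparable across antibodies with different dynamic ranges, and is the
scale on which downstream analysis operates. This scale choice is a
package decision and worth stating prominently, since intensity-scale
replicate SDs are not comparable across slides. Saturated or
below-detection replicates carry no concentration information and are
dropped with a warning; with fewer than two usable replicates the metric
is `NA`. The replicate mean expression is reported alongside, and
`noise_expression_independence()` gives the descriptive across-slide
correlation between the two — low correlation is what justifies using one
noise value per slide. No automatic rejection threshold is applied:
"too noisy" is a judgment relative to a facility's history.

Calibration: the delta method predicts the sampling SD of a replicate
estimate as $\sigma_y / \sqrt{\sum_j g'(x_{rep} + d_j)^2}$. On synthetic
slides the reported metric falls in the 95% chi-square band around that
prediction (acceptance tests), so the metric reads directly in log2 units
of measurement error.

## Loading normalization

Samples differ in total protein loaded; the correction operates on the
assembled samples-by-antibodies log2 matrix. Three methods ship: `none`
(bit-identical pass-through, so any downstream correction can be applied
instead), `median_centering` (each sample shifted so its cross-antibody
median equals the grand median), and `median_polish_loading` (iterative
row/column median sweeps; only the fitted sample effects are removed,
antibody effects and the overall level are retained). The polish stops
when the largest swept median falls below `tol` (default `1e-10`) or
after `max_iter` (default 50) sweeps; on noisy matrices the sweeps
eventually oscillate below any practical tolerance, in which case the last
iterate is returned with a warning — the remaining movement is orders of
magnitude below the data scale. All methods are idempotent and
permutation-equivariant, and both the raw and normalized matrices are
written. Median-based loading correction presumes a sample's median across
antibodies is loading-dominated; with few antibodies or wildly varying
panels that assumption weakens, which is why `none` is a first-class
option. Normalizations requiring extra input channels (e.g. total-protein
stains) are out of scope.

## Batch processing

Stages run in a fixed order — read, validate, optional spatial
adjustment, curve fit (never skippable), optional noise metric, matrix
assembly, loading normalization, output writing — with the per-slide
stages parallelized across worker processes (per-slide granularity: slides
are independent and similar in cost). Every stage is deterministic, so
numeric outputs are byte-identical for any worker count. Each slide runs
inside its own error boundary: a failure is recorded with its stage and
message in `errors.txt` and the batch continues, with surviving slides
producing exactly what they would in a batch without the failed one.
Warnings are collected per slide into `warnings.txt`; both files always
exist, and both carry ISO-8601 event timestamps (they are the only outputs
not byte-stable across re-runs). The process exit convention in the CLI is
0 with partial results, 2 only when no slide succeeded.

## The synthetic generator

`sim_scenario()` / `generate_slide()` emulate the data model the pipeline
assumes: intensities are the logistic response at the true concentrations,
multiplied by an optional smooth spatial field (left-right gradient or
radial blob, median-centered), optionally distorted by planted outlier
factors, plus additive Gaussian intensity noise (an intensity-proportional
option exists for robustness checks). Defaults are chosen as a realistic
production-scale slide: a 4x12 grid of 4x4 sub-grids (768 spots), 96
sample series with true concentrations uniform over $[-4, 4]$ log2 units,
4 two-fold dilution steps, curve $(\alpha, \beta, \gamma) = (200, 40000,
0.8)$ — baseline and dynamic range in typical scanner fluorescence counts —
24 technical-replicate series at $x = 0$, and noise sd equal to 1% of the
dynamic range. Replicate spots sit on a deterministic two-dimensional
stratified lattice so they cover the surface, which the spatial stage
requires. Truth tables (concentrations, curve, spatial field, noiseless
intensities) accompany every generated file.

What the generator does *not* emulate bounds what passing tests show:
noise on real slides is spatially correlated and
intensity-dependent beyond the proportional option; antibody
cross-reactivity, secondary-antibody background and edge effects are
absent; the spatial fields are smooth by construction, matching the
smoother's assumptions; and real designs vary in ways the single-design
assumption forbids. Recovery results on synthetic slides therefore
demonstrate correctness of the implementation under the model's own
assumptions, not performance on degraded real-world arrays.

## Problem sizes and numerical choices

The test suite runs full-design slides (96 samples) for the recovery,
noise-calibration, spatial and exclusion checks — 10, 10, 20 and 1 seeded
slides respectively — and compact slides (12–24 series) for the
batch/worker and oracle-equivalence checks, where slide size is irrelevant
to the property under test; the loading-recovery checks operate on
40-sample-by-20-antibody matrices across 10 seeds. The acceptance script
uses the same designs at slightly reduced replication. Tie-breaks and
degenerate inputs are handled explicitly: flat intensity ranges error out
rather than fit, all-NA matrix rows pass through loading normalization
unchanged with a warning, too few spatial controls fall back to the
identity surface, and fewer than two usable replicates give an `NA` noise
metric. Position bounds of $\pm 15$ log2 units cover any concentration a
four-step two-fold design can distinguish, with the saturation flags
marking everything the data cannot.

## Known limitations

Only the three-parameter logistic response is implemented (no 5-parameter
logistic, monotone spline or loess response variants); uncertainty in
$\hat x$ is curvature-based, ignoring curve-parameter uncertainty, and so
is slightly anticonservative; the loading-method registry is deliberately
small; scanner image files are never read — quantification happens
upstream — and per-slide dilution ladders that deviate from the first
valid slide are rejected rather than accommodated.
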