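---
title: "Calibrating microarray scanner response with an autofluorescence-aware power law"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating microarray scanner response with an autofluorescence-aware power law}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scancal)
```

## The problem

Microarray scanners read out fluorescence through a photomultiplier tube
(PMT), and interpreting spot intensities quantitatively requires knowing how
signal counts relate to the number of fluorophores in a spot. Commercial
calibration slides carry columns of replicate spots with Cy3/Cy5 dye at known
surface densities (a two-fold dilution series spanning eight orders of
magnitude), so scanning one without hybridization traces out the response
curve directly. The catch is that the spotting buffer on such slides
autofluoresces: at low dye densities the measured intensity flattens onto a
plateau that reflects the slide, not the detector. A calibration analysis
that ignores this offset concludes — wrongly — that the PMT is grossly
nonlinear at low intensities and that most biological signals fall below the
scanner's sensitivity threshold.

## The model

`scancal` models the scanner response to fluorophore surface density $x$
(fluorophores/µm²) as

$$SI(x) = B\,x^{a} + g$$

with three parameters:

* $B$ — the **sensitivity**, counts per (fluorophores/µm²)$^a$. It scales
  with the PMT gain setting, roughly proportionally.
* $a$ — the **curvature** exponent, dimensionless. $a = 1$ is a perfectly
  linear detector in non-transformed coordinates; fitted values for real
  scanners sit between about 0.74 and 0.99.
* $g$ — the **autofluorescence offset**, counts. It is a property of the
  slide (buffer batch), not of the detector, so it should not change with
  PMT gain — a falsifiable prediction the diagnostics check.

Subtracting $g$ linearizes the curve in log–log coordinates with slope $a$,
which is also how starting values are obtained. The model reproduces the
lower plateau ($SI \approx g$ wherever $B x^a \ll g$) without attributing it
to the PMT, and `usableRange()` turns it into practical bounds: densities
below $(k g / B)^{1/a}$ are drowned in background (default $k = 3$), and
densities above $((c - g)/B)^{1/a}$ clip at the detector ceiling $c$
(65535 counts for 16-bit scanners). For a representative Cy3 fit
($B = 106$, $a = 0.95$, $g = 11.9$) the $k=3$ floor is 0.318
fluorophores/µm², below which the slide's dilution series 20–27 fall — the
deepest third of the series carries no usable dye signal, and inverting
intensities to densities (`invertSignal()`) is deliberately refused at or
below $g$.

## Fitting

Calibration data span many orders of magnitude in both axes, so ordinary
least squares would be dominated entirely by the few brightest spots.
`fitResponse()` therefore minimizes the sum of squared *relative* residuals

$$E = \sum_i \left(\frac{SI_i - \widehat{SI}(x_i)}{\widehat{SI}(x_i)}\right)^2,$$

equivalently weighted least squares with weights $1/\widehat{SI}^2$. The
precise algebraic form of the historical merit function this reconstructs is
not recoverable from the sources that motivated it; relative least squares is
the natural reading of "weighted least squares" over data with this span,
and is labelled a reconstruction here.

Numerical choices:

* **Optimizer** — bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
  $B > 0$, $a \in [0.1, 2]$, $g \ge 0$; convergence at relative merit change
  $< 10^{-10}$ or parameter step $< 10^{-8}$, at most 10000 evaluations.
  Convergence status is reported honestly in the `FitResult`.
* **Initialization** — $g_0$ = median signal of blank spots (falling back to
  the lowest-density column), then a log–log regression of $\log(SI - g_0)$
  on $\log x$ over spots with $SI > 2 g_0$ gives $a_0$ (slope) and $B_0$
  (exponentiated intercept). If nothing rises above $2 g_0$ the data are
  entirely below the autofluorescence floor and fitting refuses with an
  all-background error.
* **Multi-start** — five starts perturbing $a_0$ by factors 0.8–1.2; lowest
  final merit wins, ties broken toward the smaller $a$.
* **Data policy** — buffer and marker spots (no defined nominal density)
  never enter the fit; blank spots enter at $x = 0$ and inform $g$;
  saturated spots (signal ≥ ceiling) are excluded by default. Spot-level
  data are fitted by default with a `seriesMeans` option, since whether
  historical fits used spots or series means is unrecorded.
* **Determinism** — usable observations are sorted into a canonical
  $(x, SI)$ order before optimization, so the result is bit-identical under
  permutation of input rows.

`bootstrapFit()` adds percentile confidence intervals by resampling spots
with replacement within each series (preserving the dilution design) and
refitting from the point estimate; it is reproducible under a fixed seed and
flags instability when under half the refits succeed.

## The simulator

`makeSlideLayout()` and `simulateScan()` emulate the standard 32-column
calibration slide: columns 1–27 the two-fold dilution from
$1.47 \times 10^5$ down to $2.19 \times 10^{-3}$ fluorophores/µm², column 28
spotting buffer (the intended negative control), columns 29–31 blank,
column 32 a position marker. Defaults are 20 replicate spots per column —
the vendor documentation records no replicate count, so this is a choice,
made once, of a realistic column depth — and a 65535-count ceiling.

Each spot draws
$SI = \min\{\text{base} \cdot L + N,\; \text{ceiling}\}$, clamped at zero,
where base is the model prediction ($g$ plus a configurable extra offset for
buffer spots; a fixed bright level, by default the ceiling, for position
markers), $L$ is mean-1 lognormal noise with configurable CV (default 0.10),
and $N$ is optional additive Gaussian noise. The multiplicative-lognormal
choice produces the roughly constant log-scale scatter seen in real scans
and recovers the deterministic model exactly at CV 0. Seeds are mandatory
and scoped (the global RNG stream is untouched). Integer quantization is
available but off by default, since fitting operates on raw continuous
intensities.

What the simulator does *not* emulate — spot morphology and gridding,
spatial gradients across the slide, channel crosstalk, photobleaching, or
any gain-dependent noise floor — bounds what passing tests show: parameter
recovery on these simulations demonstrates that the estimator inverts the
assumed generative model at realistic noise, not that any physical scanner
obeys that model.

## Layout auditing

`readGal()` parses GAL (GenePix Array List, ATF container) layout files,
`readSlideDescription()` parses manual-style description tables (accepting
the vendor's exponent spacing, "1.47E + 05"), and
`checkLayoutConsistency()` audits one against the other column by column:
densities within a relative tolerance (default 1%, compared symmetrically),
roles by identity, and role-versus-density conflicts — a column the manual
calls "Buffer" while the layout file assigns it a dye concentration —
reported as mismatches quoting both sources. Vendor documentation for real
slides of this type contains exactly such a conflict, as well as an offset
in where the two sources start the dilution series; the audit reports
discrepancies and deliberately never attempts to resolve them.

## Diagnostics

`gainInvariance()` asks whether a parameter is constant across fits at
different PMT gains: the spread statistic is the maximum pairwise relative
difference, and the verdict is "invariant" when all bootstrap intervals
pairwise overlap, or — without intervals — when the spread is under a 15%
threshold. The thresholds are tool policy: the underlying scientific claims
are qualitative, and 15% separates cleanly the observed behaviour of $g$
(spread ~2% across gains) from $B$ (spread several-fold).
`curvatureComparison()` applies the same machinery to $a$ across channels
and gains and reports each fit's deviation from the straight line $a = 1$.
`channelRatioProfile()` evaluates the background-corrected two-channel ratio
$B_1 x^{a_1} / B_2 x^{a_2}$ over a density grid (default: the slide's
dilution densities within the shared usable range): when $a_1 = a_2$ the
ratio is exactly $B_1/B_2$ everywhere — the condition under which plain
intensity ratios describe expression changes without calibration — and the
constancy verdict uses a max/min threshold of 1.05.

`diagnose()` bundles fits into a report (parameter table, invariance
verdicts with their numeric evidence, usable ranges), and `scancalCli()`
exposes `simulate`, `fit`, `diagnose` and `check-layout` subcommands for
shell use (`exec/scancal`), with every random step seeded by flags.

## Problem sizes

The shipped tests fit scans of 640 spots (32 columns × 20 replicates, the
standard slide at its default depth), run 50-repetition coverage
experiments at 200 bootstrap resamples each, and use $10^4$ replicates per
column for law-of-large-numbers checks; a single point fit takes a few tens
of milliseconds.

## Known limitations

* **Relative least squares is biased under multiplicative noise.** At a
  fixed density, minimizing relative residuals converges to
  $\mathbb{E}[y^2]/\mathbb{E}[y] = f \cdot (1 + \mathrm{CV}^2)$, so with 10%
  multiplicative noise the fitted $B$ and $g$ estimate values inflated by
  1% ($a$ is unaffected). This is far inside the 5% recovery tolerance that
  matters in practice, but it has a measurable consequence for uncertainty
  quantification: with 20 replicates per column the 1% inflation is about
  one sampling standard deviation for $B$, so nominal-95% percentile
  bootstrap intervals cover the *generating* $B$ in only ~80% of repeated
  experiments (~84% for $g$; ~98% for $a$). The intervals correctly cover
  the estimand of the merit function; resampling cannot detect the
  estimand's offset from the generating value. Users needing unbiased
  absolute sensitivity should fit series means (`seriesMeans = TRUE`),
  which shrinks the inflation to $\mathrm{CV}^2/n_\mathrm{rep}$ — the
  spot-level default is kept because it is the method's historical form.
* Saturated spots are excluded, not treated as censored observations; at
  very high gain this discards the entire upper dilution range.
* The model is phenomenological: it does not model PMT voltage physics, the
  "shoulder" some scanners show in one channel, or heteroscedastic noise.
* Fits assume the slide's nominal densities are exact; errors in the
  dilution series itself propagate directly into $a$.
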