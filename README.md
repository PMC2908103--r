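# scancal

Microarray scanner response calibration with an autofluorescence-aware
power law.

## What problem this solves

Quantitative interpretation of microarray intensities requires knowing how
a scanner's photomultiplier (PMT) maps fluorophore quantity to signal
counts. Calibration slides — glass spotted with columns of Cy3/Cy5 dye in a
two-fold dilution series over eight orders of magnitude — let you measure
that response directly, but the spotting buffer on such slides
autofluoresces. Ignore that offset and the response curve appears to
plateau at low intensities, the scanner looks grossly nonlinear, and most
biological signals seem to fall below the sensitivity threshold. None of
that is a property of the detector.

`scancal` is for anyone fitting calibration-slide scans (or evaluating
whether such slides are worth using at all): it models the response as

    SI(x) = B * x^a + g

where `x` is fluorophore surface density (fluorophores/µm²), `B` the PMT
sensitivity (scales with gain), `a` the curvature exponent (`a = 1` is a
linear detector), and `g` the slide's autofluorescence offset in counts
(a property of the slide, so invariant to PMT gain — a prediction the
package's diagnostics test). Because the data span many decades, fitting
minimizes the sum of squared *relative* residuals,

    E = sum_i [ (SI_i - fit(x_i)) / fit(x_i) ]^2

(weighted least squares with weights 1/fit²), with saturated spots
excluded and blank spots informing `g`.

The package provides:

* the forward/inverse model and saturation handling (`predictSignal`,
  `idealSignal`, `invertSignal`, `applySaturation`);
* robust fitting with multi-start initialization and stratified bootstrap
  intervals (`fitResponse`, `bootstrapFit`);
* a calibration-slide simulator with a known ground truth, lognormal
  multiplicative noise and 16-bit saturation (`makeSlideLayout`,
  `simulateScan`, `writeFixtureBundle`);
* GAL (GenePix Array List) and intensity-table I/O plus an audit that
  flags discrepancies between a vendor's manual and its layout file
  (`readGal`, `readIntensityTable`, `checkLayoutConsistency`);
* diagnostics: gain invariance of `g`, curvature invariance of `a`,
  usable density ranges, two-channel ratio constancy (`gainInvariance`,
  `curvatureComparison`, `usableRange`, `channelRatioProfile`,
  `diagnose`), and a command-line interface (`exec/scancal`).

## Worked example

Simulate one scan of the standard 32-column slide (20 replicate spots per
column, 10% multiplicative noise, 16-bit ceiling) from a known truth, then
refit it:

```r
library(scancal)

truth  <- ScannerModel(B = 106, a = 0.95, g = 11.90,
                       channel = "Cy3", pmtGain = 100)
layout <- makeSlideLayout(replicatesPerColumn = 20)
obs    <- simulateScan(layout, SimulationConfig(truth, noiseCV = 0.10,
                                                seed = 42))
fit    <- bootstrapFit(obs, nBoot = 200, seed = 43)
fit
#> FitResult: B = 106.855, a = 0.949807, g = 11.9887
#>   merit E = 4.29535 over 440 spots (160 saturated excluded); converged: TRUE
#>   95% bootstrap CI (200 resamples):
#>     B: [104.88, 108.834]
#>     a: [0.944357, 0.954797]
#>     g: [11.7619, 12.2146]

r <- usableRange(fittedModel(fit), k = 3)
sprintf("usable density range: %.3f to %.0f fluorophores/um^2",
        r$lower, r$upper)
#> "usable density range: 0.318 to 861 fluorophores/um^2"
```

Reading: all three generating parameters are recovered within ~1% and the
intervals cover them. The 160 excluded spots are the eight brightest
dilution columns, which clip at 65535 counts at this gain. The usable
range says spots dimmer than 0.318 fluorophores/µm² (the slide's dilution
series 20–27) sit within 3× of the autofluorescence floor and carry no
usable dye signal — the low-density plateau is the slide's artifact, not
PMT nonlinearity — while densities above ~861 saturate the detector.

`plotFit(fit, obs)` draws the classic log–log view: data, the fitted
curve, and the background-free ideal response that diverges from it below
the plateau.

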