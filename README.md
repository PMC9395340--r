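# pulmoflow

Automated quantification of the **right-to-left distribution of pulmonary
blood flow** from dynamic contrast X-ray angiography.

In congenital heart disease (tetralogy of Fallot, transposition of the great
arteries), pulmonary arterial branch stenosis shifts flow away from one lung,
and the right:left split drives the decision to treat. The split is
conventionally measured by lung perfusion scintigraphy — a separate
nuclear-medicine examination. `pulmoflow` computes it instead from the
angiography frames already acquired in the catheter lab, deterministically and
in well under a second, for interventional cardiologists and for image-analysis
researchers who want every intermediate of the computation exposed and
testable.

## Method

Let the acquisition run at frame rate $f$ (reference: 30 frames/s, 1024×1024
matrix) with a pre-injection baseline (mask) frame.

1. Subtract the mask from every frame (sign auto-detected so contrast makes
   the signal rise).
2. Average two fixed, equal rectangular ROIs — right lung
   $(9, 103, 358, 922)$, left lung $(665, 103, 1014, 922)$ at reference
   scale, proportionally rescaled otherwise — into time–signal intensity
   curves $R(k)$, $L(k)$, with frame $k = 1$ the first frame after injection.
3. Find the 6-frame (200 ms) window maximizing the OLS slope of the
   **combined** curve $(R+L)/2$; extend it by 4 frames on each side into a
   14-frame candidate range; within that range re-select each side's 6-frame
   maximum-slope window **independently** (the two lungs' inflow can differ
   by up to ~100 ms).
4. Fit OLS slopes $s_R$, $s_L$ over the selected windows and report

   $$\text{right\%} = 100\,\frac{s_R}{s_R + s_L}, \qquad
     \text{left\%} = 100 - \text{right\%}.$$

The package also ships a synthetic two-lung angiography simulator
(gamma-variate first-pass kinetics, configurable true split, onset delay,
pulsatility, noise, rendered frame stacks) used as ground truth throughout
the test suite, readers/writers for multi-page TIFF, uncompressed multi-frame
DICOM, CSV TIC tables and JSON results, cohort agreement statistics, and a
command-line interface (`inst/cli/pulmoflow.R`) with `analyze`, `simulate`
and `evaluate` subcommands.

## Worked example

A bundled synthetic TIC table reproduces the situation the two-stage window
search exists for: the right lung's inflow lags the left by 0.1 s (3 frames).

```r
library(pulmoflow)
tab <- loadTicTable(system.file("extdata", "worked_example_tic_synthetic.csv",
                                package = "pulmoflow"), frameRate = 30)
analyzeFlowSplit(tab)
#> Flow-split analysis
#>   representative window: frames 21-26 (combined TIC)
#>   right window: frames 24-29, slope 0.009824
#>   left  window: frames 21-26, slope 0.014666
#>   right:left = 40:60  (40.1143 : 59.8857)
```

The combined curve anchors the search at frames 21–26; the left window stays
there while the right window shifts three frames later to 24–29, tracking the
delayed inflow. The slope pair yields a right share of 40.11 %, reported as
**40:60**. A rendered end-to-end run:

```r
sim <- renderFrames(syntheticSpec(trueRightPercent = 60, imageSize = 96,
                                  nFrames = 45, noiseSigma = 0))
ratioRounded(analyzeFlowSplit(sim$sequence))
#> right  left
#>    60    40
```

Cohort agreement against a reference modality, on the bundled seven-patient
comparison table:

```r
ev <- evaluateCohort(system.file("extdata", "flow_split_comparison.csv",
                                 package = "pulmoflow"))
ev$comparison
#> Agreement over 7 patients: slope 1.2641, intercept -14.0171, r 0.9429
#>   RMSE paired 6.8348, regression-residual 5.8195
ev$windows
#> Window timing: mean start 0.659 s; right-left start diff mean 0.71 frames (0.024 s), max 3 frames
```

## Documentation

The methods vignette (`vignettes/flow-split-methods.Rmd`) describes the
model and its assumptions, the tunable parameters, what the simulator does
and does not emulate, the numerical choices and known limitations.
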