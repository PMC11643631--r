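# segclock

Quantification of single-cell segmentation-clock dynamics in zebrafish
presomitic mesoderm (PSM) cells — for developmental biologists and image
analysts who measure oscillatory reporter traces in isolated cultured
cells or in cells tracked through the embryo.

During somitogenesis, Her/Hes-family genes oscillate in every PSM cell.
Cells slow their oscillations as they mature, then arrest the clock as
they differentiate (marked by the onset of a Mesp reporter); at tissue
level this produces the clock's kinematic wave pattern. `segclock`
implements the measurement workflow behind this picture:

* **Brightfield single-cell segmentation**: CLAHE contrast enhancement,
  an edge-preserving guided filter (3×3, smoothing 0.001), a
  morphological gradient (disk radius 2), Otsu thresholding,
  central-blob selection, and a morphological Chan–Vese active contour
  (300 iterations, smooth factor 1, contraction bias 0.1), with
  per-frame QC flags replacing manual confirmation.
* **Oscillation analysis**: an explicit oscillatory-window rule, peak and
  trough detection under width/distance/prominence constraints, and
  sub-frame refinement by the vertex of the parabola through each raw
  maximum and its neighbours,
  `t* = t + (Δ/2)·(I₋ − I₊)/(I₋ − 2I₀ + I₊)`.
  Cycles are defined between successive refined peaks; the per-cell
  outputs are the peak count `K`, periods `Pₙ`, peak/trough intensities
  `I⁺ₙ`, `I⁻ₙ`, successive ratios `Pₙ₊₁/Pₙ` and `I⁺ₙ₊₁/I⁺ₙ`, and the
  last-peak (clock-arrest) time, with left-censoring for arrests that
  pre-date acquisition.
* **Mesp onset calling**: clear-rise classification against baseline and
  noise, and a thresholded sustained-rise onset time; works with
  oscillations disabled (clock-mutant arm) and from max-in-ROI traces.
* **Embryo kymographs**: projection of tracked cells onto a reference
  curve (nearest Euclidean point, arc-length from the posterior tail
  tip), temporal alignment, event kymographs (last peak / onset) in
  10-µm bins, and intra-somite rostro-caudal phase profiles.
* **Cohort reporting**: the four culture inclusion criteria, mean/SD/COV
  of peak counts, quadrant densities of ratio pairs, and descriptive
  condition comparisons with seeded bootstrap CIs.
* **An intrinsic-timer synthetic-data generator** whose condition presets
  (culture PSM2/3/4, tailbud, embryo PSM4, +FGF, *her1⁻/⁻;her7⁻/⁻*) are
  calibrated to published summary statistics, so the full pipeline runs
  and is tested without the original imaging data.

## Worked example

```r
library(segclock)

preset  <- clockPreset("culture_psm4")   # calibrated culture condition
cohort  <- generateCohort(preset, n = 30, seed = 1)
analysis <- analyzeCohort(cohort)        # windows, peaks, cycles, ratios
onsets   <- analyzeOnsets(cohort)        # Mesp clear-rise + onset times
cohortStats(analysis$cells, analysis$ratios, onsets)
```

```
CohortStats: 30 cells, 4.93 +/- 1.70 peaks (COV 0.34)
  last peak 360 +/- 118 min (0 censored)
  quadrants (%): UR 61.4, UL 12.5, LR 18.2, LL 8.0
  Mesp onset 387 min (called fraction 0.80)
```

Each simulated cell oscillated 1–8 times before arresting; this cohort
averaged 4.9 detected peaks (coefficient of variation 0.34). Most
successive cycle pairs fall in the upper-right quadrant — the period grew
*and* the peak intensity rose from one cycle to the next, the signature
slowing-with-rising-amplitude dynamic — and the Mesp differentiation
reporter switched on around the time of the last Her1 peak in the 80% of
cells with a clear rise.

A brightfield scene round trip:

```r
prog  <- drawCellProgram(preset, seed = 7)
scene <- generateBrightfieldScene(prog, preset, seed = 2, nFrames = 6)
seg   <- segmentSequence(scene@frames)
trace <- extractIntensities(seg$masks, scene@her1Stack, scene@mespStack,
                            preset@frameInterval, preset@imagingStartOffset)
```

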