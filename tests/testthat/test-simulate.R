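# Intrinsic-timer generator: cell programs, rendered traces, cohorts.

test_that("degenerate peak-count distributions give the forced structure", {
  p <- clockPreset("culture_psm4")
  p@nPeaksSD <- 0; p@nPeaksMean <- 1          # exactly one peak
  prog <- drawCellProgram(p, seed = 1)
  expect_length(prog@peakTimes, 1L)
  expect_length(prog@periods, 0L)
  expect_equal(prog@arrestTime, prog@peakTimes[1])

  p2 <- clockPreset("culture_psm4")
  p2@slowProb <- 1                            # forced monotone slowing
  p2@nPeaksMean <- 6; p2@nPeaksSD <- 0
  for (s in 1:20) {
    pr <- drawCellProgram(p2, seed = s)
    expect_true(all(diff(pr@periods) > 0))
  }
})

test_that("empirical peak-count mean matches the preset mean (MC oracle)", {
  p <- clockPreset("culture_psm4")
  K <- vapply(seq_len(4000), function(i)
    length(drawCellProgram(p, seed = splitSeed(99, i))@peakTimes), 1L)
  se <- sd(K) / sqrt(length(K))
  expect_lt(abs(mean(K) - expectedPeakCount(p)), 2 * se + 1e-9)
})

test_that("programs satisfy the timer invariants", {
  p <- clockPreset("culture_psm4")
  for (s in 1:40) {
    pr <- drawCellProgram(p, seed = s)
    expect_true(all(diff(pr@peakTimes) > 0))
    expect_equal(pr@periods, diff(pr@peakTimes))
    expect_length(pr@peakAmplitudes, length(pr@peakTimes))
    expect_true(all(pr@peakAmplitudes > 0))
    expect_equal(pr@arrestTime, max(pr@peakTimes))
    if (!is.na(pr@onsetTime)) expect_true(pr@clearRise)
  }
})

test_that("rendered traces place pulses and onsets where the program says", {
  p <- clockPreset("culture_psm4", noiseSD = 0)
  prog <- new("CellProgram", cellId = "x", peakTimes = 100,
              periods = numeric(0), peakAmplitudes = 100, arrestTime = 100,
              onsetTime = NA_real_, clearRise = FALSE,
              conditionName = "culture_psm4",
              survivedPast5h = TRUE, divided = FALSE)
  tr <- renderTraces(prog, p, seed = 1)
  expect_equal(tr$times[which.max(tr$her1)], 100)   # global max at the pulse
  expect_equal(tr$mesp, rep(p@mespBaseline, length(tr$times)))  # no onset
})

test_that("noiseless local maxima recover program peak times (brute force)", {
  p <- clockPreset("culture_psm4", noiseSD = 0)
  for (s in c(2, 5, 11)) {
    prog <- drawCellProgram(p, seed = s)
    tr <- renderTraces(prog, p, seed = s + 1)
    found <- tr$times[bruteLocalMaxima(tr$her1)]
    # every program peak has a local maximum within half a frame interval
    for (pt in prog@peakTimes)
      expect_lte(min(abs(found - pt)), p@frameInterval / 2 + 1e-9)
  }
})

test_that("aliasing is warned about when frames undersample the periods", {
  p <- clockPreset("culture_psm4", noiseSD = 0)
  prog <- drawCellProgram(p, seed = 3)
  p@frameInterval <- max(prog@periods)     # far above shortest period / 2
  expect_warning(renderTraces(prog, p, seed = 1), "aliasing")
})

test_that("cohort generation is seed-deterministic and n is validated", {
  p <- clockPreset("culture_psm4")
  expect_error(generateCohort(p, n = 0, seed = 1), "positive")
  a <- generateCohort(p, n = 6, seed = 42)
  b <- generateCohort(p, n = 6, seed = 42)
  expect_identical(SummarizedExperiment::assay(a, "her1"),
                   SummarizedExperiment::assay(b, "her1"))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
  d <- generateCohort(p, n = 6, seed = 43)
  expect_false(identical(SummarizedExperiment::assay(a, "her1"),
                         SummarizedExperiment::assay(d, "her1")))
})

test_that("planted inclusion failures appear at the configured rate", {
  p <- clockPreset("culture_psm4")
  coh <- generateCohort(p, n = 600, seed = 7, failureFraction = 0.1)
  cd <- SummarizedExperiment::colData(coh)
  failed <- !cd$survived_past_5h | cd$divided
  se <- sqrt(0.1 * 0.9 / 600)
  expect_lt(abs(mean(failed) - 0.1), 2 * se)
})

test_that("cohort CSV round-trips traces exactly", {
  coh <- generateCohort(clockPreset("culture_psm4"), n = 4, seed = 5)
  tp <- tempfile(fileext = ".csv"); mp <- tempfile(fileext = ".csv")
  writeCohortCSV(coh, tp, mp)
  back <- readTraceCSV(tp)
  expect_equal(back$times, cohortTimes(coh))
  expect_equal(unname(back$her1),
               unname(SummarizedExperiment::assay(coh, "her1")),
               tolerance = 1e-12)
})

test_that("successive-ratio fractions converge to the preset probabilities", {
  p <- clockPreset("culture_psm4")
  ratios <- unlist(lapply(1:800, function(i) {
    pr <- drawCellProgram(p, seed = splitSeed(1234, i))
    if (length(pr@periods) >= 2) pr@periods[-1] / pr@periods[-length(pr@periods)]
  }))
  se <- sqrt(0.81 * 0.19 / length(ratios))
  expect_lt(abs(mean(ratios > 1) - 0.81), 2 * se + 1e-9)
})

test_that("onset delays follow the preset distribution and clear-rise rate", {
  p <- clockPreset("culture_psm4")
  progs <- lapply(1:800, function(i) drawCellProgram(p, seed = splitSeed(55, i)))
  clear <- vapply(progs, function(x) x@clearRise, TRUE)
  se <- sqrt(0.8 * 0.2 / length(clear))
  expect_lt(abs(mean(clear) - p@clearRiseProb), 2 * se + 0.01)
  deltas <- vapply(progs[clear], function(x) x@onsetTime - x@arrestTime, 1)
  # two-sample KS against a reference sample from the stated normal
  set.seed(1)
  ref <- rnorm(2000, p@onsetDelayMean, p@onsetDelaySD)
  ks <- suppressWarnings(stats::ks.test(deltas, ref))
  expect_gt(ks$p.value, 0.001)
})

test_that("the clock-mutant preset draws onsets without any peaks", {
  p <- clockPreset("her1her7_mutant")
  progs <- lapply(1:200, function(i) drawCellProgram(p, seed = splitSeed(9, i)))
  expect_true(all(vapply(progs, function(x) length(x@peakTimes), 1L) == 0L))
  on <- vapply(progs, function(x) x@onsetTime, 1)
  expect_lt(abs(mean(on, na.rm = TRUE) - 305), 2 * 70 / sqrt(sum(!is.na(on))))
})
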