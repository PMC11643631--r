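# Inclusion filtering, cohort statistics, quadrants, comparisons, pipeline.

test_that("inclusion criteria exclude the documented failure modes", {
  p <- clockPreset("culture_psm4")
  coh <- generateCohort(p, n = 60, seed = 47, failureFraction = 0.15)
  an <- analyzeCohort(coh)
  meta <- as.data.frame(SummarizedExperiment::colData(coh))
  her1 <- SummarizedExperiment::assay(coh, "her1")
  incl <- inclusionFilter(meta, an$cells, her1, cohortTimes(coh))
  # planted failures are excluded for exactly their planted reason
  planted <- meta$cell_id[!meta$survived_past_5h | meta$divided]
  expect_true(all(!planted %in% incl$included))
  died <- meta$cell_id[!meta$survived_past_5h]
  divided <- meta$cell_id[meta$divided]
  tally <- setNames(incl$tally$count, incl$tally$reason)
  expect_equal(unname(tally["died_before_5h"]), length(died))
  expect_equal(unname(tally["divided"]), length(divided))
  # missing metadata excludes with reason "incomplete"
  meta2 <- meta; meta2$survived_past_5h[1] <- NA
  incl2 <- inclusionFilter(meta2, an$cells, her1, cohortTimes(coh))
  expect_false(meta2$cell_id[1] %in% incl2$included)
  expect_true("incomplete" %in% incl2$tally$reason)
})

test_that("cells that never express or never arrest are excluded", {
  p <- clockPreset("her1her7_mutant")
  coh <- generateCohort(p, n = 10, seed = 3)
  an <- analyzeCohort(coh)
  meta <- as.data.frame(SummarizedExperiment::colData(coh))
  her1 <- SummarizedExperiment::assay(coh, "her1")
  incl <- inclusionFilter(meta, an$cells, her1, cohortTimes(coh))
  expect_length(incl$included, 0L)
  expect_true(all(incl$tally$reason == "no_arrested_oscillation"))
})

test_that("COV is SD over mean, rounded only at the report layer", {
  cells <- data.frame(cell_id = letters[1:4], n_peaks = c(3L, 4L, 5L, 6L),
                      last_peak_time = c(200, 250, 300, 350),
                      censored = FALSE, oscillatory = TRUE)
  st <- cohortStats(cells)
  expect_equal(st$covPeaks, sd(c(3, 4, 5, 6)) / 4.5, tolerance = 1e-12)
  expect_equal(st$covPeaksRounded, round(st$covPeaks, 2))
  # identical cells: zero SD, zero COV
  same <- cells; same$n_peaks <- 4L
  stSame <- cohortStats(same)
  expect_equal(stSame$sdPeaks, 0)
  expect_equal(stSame$covPeaks, 0)
  expect_error(cohortStats(cells[0, ]), "empty")
})

test_that("quadrant fractions follow the boundary rule and sum to 100", {
  r <- data.frame(period_ratio = c(1.2, 0.9, 1.2, 0.9),
                  intensity_ratio = c(1.1, 1.1, 0.8, 0.8))
  q <- quadrantDensity(r)
  expect_equal(unname(q$fractions), c(25, 25, 25, 25))
  expect_equal(sum(q$fractions), 100)
  # all in the upper right
  rUR <- data.frame(period_ratio = rep(1.1, 7), intensity_ratio = rep(1.2, 7))
  expect_equal(unname(quadrantDensity(rUR)$fractions["upper_right"]), 100,
               ignore_attr = TRUE)
  # pairs exactly on a boundary go to the ">" side
  rB <- data.frame(period_ratio = 1, intensity_ratio = 1)
  expect_equal(unname(quadrantDensity(rB)$fractions["upper_right"]), 100,
               ignore_attr = TRUE)
  # invariant to pair order
  q2 <- quadrantDensity(r[sample(4), ])
  expect_equal(sort(q2$fractions), sort(q$fractions))
  expect_error(quadrantDensity(data.frame(period_ratio = NA_real_,
                                          intensity_ratio = NA_real_)),
               "no ratio pairs")
})

test_that("independent ratio draws obey the quadrant product law", {
  set.seed(61)
  n <- 2000
  r <- data.frame(period_ratio = exp(rnorm(n, 0.1 * qnorm(0.8), 0.1)),
                  intensity_ratio = exp(rnorm(n, 0.15 * qnorm(0.7), 0.15)))
  q <- quadrantDensity(r)
  target <- 0.8 * 0.7 * 100
  se <- sqrt(0.56 * 0.44 / n) * 100
  expect_lt(abs(q$fractions["upper_right"] - target), 2 * se + 1)
})

test_that("condition comparisons report differences with seeded bootstrap CIs", {
  cells <- data.frame(cell_id = sprintf("c%02d", 1:20),
                      n_peaks = rep(c(3L, 4L, 5L, 6L), 5),
                      last_peak_time = seq(200, 390, by = 10),
                      censored = FALSE, oscillatory = TRUE)
  # identical cohorts: zero differences, CIs cover 0
  cmp <- compareConditions(cells, cells, nBoot = 200, seed = 1)
  expect_true(all(cmp$difference == 0))
  expect_true(all(cmp$ci_lo <= 0 & cmp$ci_hi >= 0))
  # same seed gives identical CIs
  cmp2 <- compareConditions(cells, cells, nBoot = 200, seed = 1)
  expect_identical(cmp, cmp2)
  expect_error(compareConditions(cells[0, ], cells), "empty")
})

test_that("FGF versus control recovers a positive peak-count difference", {
  ctl <- analyzeCohort(generateCohort(clockPreset("culture_psm4_control"),
                                      n = 44, seed = 71))
  fgf <- analyzeCohort(generateCohort(clockPreset("culture_psm4_fgf"),
                                      n = 54, seed = 72))
  cmp <- compareConditions(ctl$cells, fgf$cells, ctl$ratios, fgf$ratios,
                           nBoot = 500, seed = 2)
  d <- cmp[cmp$quantity == "mean_peaks", ]
  expect_gt(d$difference, 0)
  expect_gt(d$ci_lo, 0)
  dlp <- cmp[cmp$quantity == "mean_last_peak_min", ]
  expect_gt(dlp$difference, 0)
})

test_that("the pipeline driver writes the configured bundle deterministically", {
  out1 <- tempfile(); out2 <- tempfile()
  cfg <- list(preset = "culture_psm4", n = 8, seed = 5, outdir = out1)
  runPipeline(cfg)
  expect_true(file.exists(file.path(out1, "traces.csv")))
  expect_true(file.exists(file.path(out1, "stats.json")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_false(file.exists(file.path(out1, "masks.tif")))
  cfg$outdir <- out2
  runPipeline(cfg)
  expect_identical(readLines(file.path(out1, "traces.csv")),
                   readLines(file.path(out2, "traces.csv")))
  expect_identical(readLines(file.path(out1, "stats.json")),
                   readLines(file.path(out2, "stats.json")))
  # simulate-only config: cohort CSVs, nothing else
  out3 <- tempfile()
  runPipeline(list(preset = "culture_psm4", n = 4, seed = 5,
                   stages = "simulate", outdir = out3))
  expect_true(file.exists(file.path(out3, "traces.csv")))
  expect_false(file.exists(file.path(out3, "cycle_cells.csv")))
})

test_that("seed splitting is deterministic, bounded and collision-light", {
  s1 <- splitSeed(42, 1:5000)
  s2 <- splitSeed(42, 1:5000)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 <= 2147483645))
  expect_equal(anyDuplicated(s1), 0L)
  expect_false(any(splitSeed(43, 1:5000) == s1))
})
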