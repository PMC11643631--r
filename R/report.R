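# Cohort-level reporting: inclusion filtering, summary statistics,
# quadrant densities of successive-cycle ratio pairs, condition
# comparisons with bootstrap CIs, and the pipeline driver.

#' Apply the cell-culture inclusion criteria
#'
#' A cell is retained when it (1) survived more than 5 h post-dissociation,
#' (2) was the only cell in its field of view, (3) did not divide, and
#' (4) expressed and arrested Her1 — operationalised as at least one
#' detected peak followed by a sustained decline of the smoothed trace
#' below half the last peak height. Cells with missing metadata are
#' excluded with reason \code{"incomplete"}.
#'
#' @param meta per-cell metadata data.frame with columns \code{cell_id},
#'   \code{survived_past_5h}, \code{divided} and optionally
#'   \code{multi_cell}.
#' @param cells per-cell analysis table (from \code{\link{analyzeCohort}})
#'   with \code{n_peaks} and \code{last_peak_time}.
#' @param her1 trace matrix used for the arrest check (columns named by
#'   cell).
#' @param times frame times matching \code{her1}.
#' @return list with \code{included} (character cell ids) and \code{tally}
#'   (data.frame reason/count).
#' @export
inclusionFilter <- function(meta, cells, her1, times) {
  reasons <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$cell_id[i]
    if (is.na(meta$survived_past_5h[i]) || is.na(meta$divided[i])) {
      reasons[i] <- "incomplete"; next
    }
    if (!meta$survived_past_5h[i]) { reasons[i] <- "died_before_5h"; next }
    if (!is.null(meta$multi_cell) && isTRUE(meta$multi_cell[i])) {
      reasons[i] <- "multiple_cells"; next
    }
    if (meta$divided[i]) { reasons[i] <- "divided"; next }
    j <- match(id, cells$cell_id)
    if (is.na(j) || is.na(cells$n_peaks[j]) || cells$n_peaks[j] < 1L) {
      reasons[i] <- "no_arrested_oscillation"; next
    }
    k <- match(id, colnames(her1))
    if (!is.na(k) && !cells$censored[j]) {
      v <- her1[, k]
      ok <- !is.na(v)
      sm <- stats::runmed(v[ok], 3L)
      tAfter <- times[ok] > cells$last_peak_time[j]
      lastHeight <- max(sm[times[ok] <= cells$last_peak_time[j] + 1e-9], sm[1])
      if (!any(tAfter) || min(sm[tAfter]) > lastHeight / 2) {
        reasons[i] <- "no_arrested_oscillation"; next
      }
    }
    reasons[i] <- ""
  }
  tallyTab <- table(reasons[reasons != ""])
  list(included = meta$cell_id[reasons == ""],
       tally = data.frame(reason = names(tallyTab),
                          count = as.integer(tallyTab)))
}

#' Cohort summary statistics
#'
#' Sample mean, SD (n-1 denominator) and coefficient of variation
#' (COV = SD/mean, rounded to 2 decimals at the report layer) of the peak
#' counts; last-peak statistics excluding censored cells; quadrant
#' fractions of the successive-cycle ratio pairs; onset statistics.
#'
#' @param cells per-cell table (\code{\link{analyzeCohort}}), already
#'   filtered to the included subset.
#' @param ratios successive-cycle ratio-pair table.
#' @param onsets optional onset table (\code{\link{analyzeOnsets}}).
#' @return list of class \code{"CohortStats"}.
#' @export
cohortStats <- function(cells, ratios = NULL, onsets = NULL) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0L) stop("empty cohort")
  np <- cells$n_peaks[!is.na(cells$n_peaks)]
  meanP <- mean(np); sdP <- sd(np)
  if (length(np) == 1L) sdP <- 0
  lp <- cells$last_peak_time[!is.na(cells$last_peak_time) & !cells$censored]
  out <- list(
    nCells = nrow(cells),
    meanPeaks = meanP, sdPeaks = sdP,
    covPeaks = if (meanP > 0) sdP / meanP else NA_real_,
    covPeaksRounded = if (meanP > 0) round(sdP / meanP, 2) else NA_real_,
    meanLastPeak = if (length(lp)) mean(lp) else NA_real_,
    sdLastPeak = if (length(lp) > 1L) sd(lp) else NA_real_,
    censoredCount = sum(cells$censored, na.rm = TRUE),
    quadrants = if (!is.null(ratios) && nrow(ratios))
      quadrantDensity(ratios)$fractions else NULL,
    onset = NULL
  )
  if (!is.null(onsets)) {
    on <- onsets$onset_min[!is.na(onsets$onset_min)]
    out$onset <- list(calledFraction = mean(onsets$clear_rise),
                      meanOnset = if (length(on)) mean(on) else NA_real_,
                      sdOnset = if (length(on) > 1L) sd(on) else NA_real_)
  }
  class(out) <- "CohortStats"
  out
}

#' @export
print.CohortStats <- function(x, ...) {
  cat(sprintf("CohortStats: %d cells, %.2f +/- %.2f peaks (COV %.2f)\n",
              x$nCells, x$meanPeaks, x$sdPeaks, x$covPeaksRounded))
  if (!is.na(x$meanLastPeak))
    cat(sprintf("  last peak %.0f +/- %.0f min (%d censored)\n",
                x$meanLastPeak, if (is.na(x$sdLastPeak)) 0 else x$sdLastPeak,
                x$censoredCount))
  if (!is.null(x$quadrants))
    cat(sprintf("  quadrants (%%): UR %.1f, UL %.1f, LR %.1f, LL %.1f\n",
                x$quadrants["upper_right"], x$quadrants["upper_left"],
                x$quadrants["lower_right"], x$quadrants["lower_left"]))
  if (!is.null(x$onset))
    cat(sprintf("  Mesp onset %.0f min (called fraction %.2f)\n",
                x$onset$meanOnset, x$onset$calledFraction))
  invisible(x)
}

#' Quadrant density of successive-cycle ratio pairs
#'
#' Quadrant boundaries sit at ratio = 1 on both axes (x: period ratio,
#' y: intensity ratio); pairs exactly on a boundary are assigned to the
#' ">" side. Fractions are reported as percentages and sum to 100.
#'
#' @param ratios data.frame with \code{period_ratio} and
#'   \code{intensity_ratio}; rows with either ratio missing are dropped.
#' @param gridBins number of bins per axis for the density grid.
#' @return list with \code{fractions} (named percentages), \code{n}, and
#'   \code{grid} (2D count matrix over log2-ratio bins).
#' @export
quadrantDensity <- function(ratios, gridBins = 20L) {
  ok <- complete.cases(ratios[, c("period_ratio", "intensity_ratio")])
  p <- ratios$period_ratio[ok]
  s <- ratios$intensity_ratio[ok]
  if (!length(p)) stop("no ratio pairs with both ratios defined")
  slow <- p >= 1
  rise <- s >= 1
  frac <- c(upper_right = mean(slow & rise),
            upper_left = mean(!slow & rise),
            lower_right = mean(slow & !rise),
            lower_left = mean(!slow & !rise)) * 100
  lim <- max(abs(log2(c(p, s)))) + 1e-9
  brk <- seq(-lim, lim, length.out = gridBins + 1L)
  xi <- pmin(pmax(findInterval(log2(p), brk, rightmost.closed = TRUE), 1L),
             gridBins)
  yi <- pmin(pmax(findInterval(log2(s), brk, rightmost.closed = TRUE), 1L),
             gridBins)
  grid <- matrix(0L, gridBins, gridBins)
  for (i in seq_along(xi)) grid[xi[i], yi[i]] <- grid[xi[i], yi[i]] + 1L
  list(fractions = frac, n = length(p), grid = grid)
}

#' Compare two cohorts descriptively with bootstrap CIs
#'
#' Paired report of mean peak counts, mean last-peak times, and
#' slowing/rise fractions, with seeded nonparametric bootstrap confidence
#' intervals on each difference (B minus A). No hypothesis-test p-values
#' are produced; the comparison is descriptive.
#'
#' @param cellsA,cellsB per-cell tables of the two cohorts.
#' @param ratiosA,ratiosB optional ratio-pair tables.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @param level CI level.
#' @return data.frame: quantity, value_a, value_b, difference, ci_lo, ci_hi.
#' @export
compareConditions <- function(cellsA, cellsB, ratiosA = NULL, ratiosB = NULL,
                              nBoot = 2000L, seed = 1L, level = 0.95) {
  if (!nrow(cellsA) || !nrow(cellsB)) stop("empty cohort")
  set.seed(seed)
  alpha <- (1 - level) / 2
  bootCI <- function(a, b, stat) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (!length(a) || !length(b)) return(c(NA_real_, NA_real_))
    d <- replicate(nBoot, stat(sample(b, replace = TRUE)) -
                     stat(sample(a, replace = TRUE)))
    as.numeric(quantile(d, c(alpha, 1 - alpha), names = FALSE))
  }
  rows <- list()
  addRow <- function(name, a, b, stat) {
    ci <- bootCI(a, b, stat)
    va <- stat(a[!is.na(a)]); vb <- stat(b[!is.na(b)])
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = name, value_a = va, value_b = vb,
      difference = vb - va, ci_lo = ci[1], ci_hi = ci[2])
  }
  addRow("mean_peaks", cellsA$n_peaks, cellsB$n_peaks, mean)
  lpA <- cellsA$last_peak_time[!cellsA$censored]
  lpB <- cellsB$last_peak_time[!cellsB$censored]
  addRow("mean_last_peak_min", lpA, lpB, mean)
  if (!is.null(ratiosA) && !is.null(ratiosB) &&
      nrow(ratiosA) && nrow(ratiosB)) {
    addRow("fraction_period_ratio_gt1",
           as.numeric(ratiosA$period_ratio >= 1),
           as.numeric(ratiosB$period_ratio >= 1), mean)
    addRow("fraction_intensity_ratio_gt1",
           as.numeric(ratiosA$intensity_ratio >= 1),
           as.numeric(ratiosB$intensity_ratio >= 1), mean)
  }
  do.call(rbind, rows)
}

#' Run the configured pipeline end to end
#'
#' Stages: \code{simulate} (cohort generation), \code{trace} (peak/cycle
#' analysis), \code{onset} (Mesp onset calls), \code{report} (inclusion
#' filter + cohort statistics). All outputs are CSV/JSON files under
#' \code{outdir}, together with a run manifest recording the preset, seed
#' and package version. Identical configs and seeds yield identical output
#' files.
#'
#' @param config list (or YAML path) with fields \code{preset}, \code{n},
#'   \code{seed}, optional \code{failureFraction}, \code{stages} (subset of
#'   \code{c("simulate", "trace", "onset", "report")}), \code{outdir}.
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$preset), !is.null(config$n),
            !is.null(config$seed))
  stages <- config$stages
  if (is.null(stages)) stages <- c("simulate", "trace", "onset", "report")
  outdir <- if (is.null(config$outdir)) "." else config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ff <- if (is.null(config$failureFraction)) 0 else config$failureFraction
  preset <- clockPreset(config$preset)
  res <- list()
  res$cohort <- generateCohort(preset, config$n, config$seed,
                               failureFraction = ff)
  if ("simulate" %in% stages)
    writeCohortCSV(res$cohort, file.path(outdir, "traces.csv"),
                   file.path(outdir, "cells_meta.csv"))
  if (any(c("trace", "onset", "report") %in% stages)) {
    res$analysis <- analyzeCohort(res$cohort)
    if ("trace" %in% stages) {
      write.csv(res$analysis$cells, file.path(outdir, "cycle_cells.csv"),
                row.names = FALSE)
      write.csv(res$analysis$cycles, file.path(outdir, "cycles_long.csv"),
                row.names = FALSE)
      write.csv(res$analysis$ratios, file.path(outdir, "ratio_pairs.csv"),
                row.names = FALSE)
    }
  }
  if (any(c("onset", "report") %in% stages)) {
    res$onsets <- analyzeOnsets(res$cohort)
    if ("onset" %in% stages) {
      ova <- onsetVsArrest(res$analysis$cells, res$onsets)
      out <- merge(res$onsets, ova$perCell[, c("cell_id", "delta_min")],
                   by = "cell_id", all.x = TRUE)
      write.csv(out, file.path(outdir, "onsets.csv"), row.names = FALSE)
    }
  }
  if ("report" %in% stages) {
    meta <- as.data.frame(SummarizedExperiment::colData(res$cohort))
    her1 <- SummarizedExperiment::assay(res$cohort, "her1")
    incl <- inclusionFilter(meta, res$analysis$cells, her1,
                            cohortTimes(res$cohort))
    keep <- res$analysis$cells$cell_id %in% incl$included
    res$stats <- cohortStats(res$analysis$cells[keep, , drop = FALSE],
                             res$analysis$ratios[
                               res$analysis$ratios$cell_id %in%
                                 incl$included, , drop = FALSE],
                             res$onsets[res$onsets$cell_id %in%
                                          incl$included, , drop = FALSE])
    res$inclusion <- incl
    jsonlite::write_json(unclass(res$stats)[c("nCells", "meanPeaks",
                                              "sdPeaks", "covPeaksRounded",
                                              "meanLastPeak", "sdLastPeak",
                                              "censoredCount")],
                         file.path(outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(incl$tally, file.path(outdir, "exclusions.csv"),
              row.names = FALSE)
  }
  manifest <- list(preset = config$preset, n = config$n, seed = config$seed,
                   failureFraction = ff, stages = stages,
                   package_version =
                     as.character(utils::packageVersion("segclock")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(res)
}
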