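# Cycle quantification: per-cell cycle tables, successive ratios,
# left-censoring of last-peak times, and first-peak-aligned summaries.

#' Build the cycle table of one cell from its peak set
#'
#' Cycles are defined between successive refined peaks: cycle \eqn{n} runs
#' from peak \eqn{n} to peak \eqn{n+1}, its period is the refined peak-time
#' difference, its peak intensity (I+) is the refined height of peak
#' \eqn{n}, and its trough intensity (I-) the refined depth of the trough
#' between the two peaks. Successive ratios are
#' \code{period[n+1]/period[n]} and \code{iplus[n+1]/iplus[n]} for
#' \eqn{n = 1..K-2}.
#'
#' @param peakSet result of the internal peak detection (list with
#'   \code{peaks} and \code{troughs} data.frames) or a data.frame of
#'   refined peaks.
#' @param t0Offset minutes added to detected times (0 when the trace's time
#'   axis is already absolute).
#' @param cellId label for the output tables.
#' @return list with \code{cell} (one-row data.frame: cell_id, n_peaks,
#'   last_peak_time, censored, oscillatory), \code{cycles} (cell_id, cycle,
#'   period, iplus, iminus) and \code{ratios} (cell_id, pair, period_ratio,
#'   intensity_ratio).
#' @export
buildCycleTable <- function(peakSet, t0Offset = 0, cellId = "cell") {
  peaks <- if (is.data.frame(peakSet)) peakSet else peakSet$peaks
  troughs <- if (is.data.frame(peakSet)) emptyPeakFrame() else peakSet$troughs
  K <- nrow(peaks)
  cell <- data.frame(cell_id = cellId, n_peaks = K,
                     last_peak_time = if (K) max(peaks$time) + t0Offset
                       else NA_real_,
                     censored = FALSE, oscillatory = K > 0)
  cycles <- data.frame(cell_id = character(0), cycle = integer(0),
                       period = numeric(0), iplus = numeric(0),
                       iminus = numeric(0))
  ratios <- data.frame(cell_id = character(0), pair = integer(0),
                       period_ratio = numeric(0), intensity_ratio = numeric(0))
  if (K >= 2L) {
    periods <- diff(peaks$time)
    stopifnot(all(periods > 0))
    iminus <- if (nrow(troughs) == K - 1L) troughs$height
      else rep(NA_real_, K - 1L)
    cycles <- data.frame(cell_id = cellId, cycle = seq_len(K - 1L),
                         period = periods,
                         iplus = peaks$height[seq_len(K - 1L)],
                         iminus = iminus)
    if (K >= 3L) {
      n <- seq_len(K - 2L)
      ratios <- data.frame(cell_id = cellId, pair = n,
                           period_ratio = periods[n + 1L] / periods[n],
                           intensity_ratio = peaks$height[n + 1L] /
                             peaks$height[n])
    }
  }
  list(cell = cell, cycles = cycles, ratios = ratios)
}

#' Run the full peak/cycle analysis over a cohort
#'
#' Per cell: optional linear interpolation of short gaps (<= \code{maxGap}
#' frames; longer gaps reject the trace), oscillatory-window determination
#' (culture mode) or whole-trace analysis with one shared parameter set
#' (embryo mode), peak and trough detection, sub-frame parabolic
#' refinement, and cycle-table construction.
#'
#' @param cohort a \linkS4class{ClockCohort} (or a list with \code{times}
#'   and a \code{her1} matrix, as returned by \code{\link{readTraceCSV}}).
#' @param mode \code{"culture"} or \code{"embryo"} peak-detection variant;
#'   defaults to \code{"embryo"} for the embryo preset, else culture.
#' @param widthMin,distanceMin,prominenceK detector parameters (frames,
#'   frames, noise-SD multiples); \code{NULL} uses the mode's defaults
#'   (culture: width 2, distance 3, prominence 5x noise; embryo: width 3,
#'   distance 10, prominence 3x noise).
#' @param maxGap largest missing-value gap (frames) interpolated.
#' @return list with data.frames \code{cells}, \code{cycles}, \code{ratios}
#'   (see \code{\link{buildCycleTable}}); \code{cells} gains a
#'   \code{rejected} column for traces with uninterpolatable gaps.
#' @examples
#' coh <- generateCohort(clockPreset("culture_psm4"), n = 3, seed = 1)
#' analyzeCohort(coh)$cells
#' @export
analyzeCohort <- function(cohort, mode = NULL, widthMin = NULL,
                          distanceMin = NULL, prominenceK = NULL,
                          maxGap = 2L) {
  if (is(cohort, "ClockCohort")) {
    times <- cohortTimes(cohort)
    her1 <- SummarizedExperiment::assay(cohort, "her1")
    preset <- S4Vectors::metadata(cohort)$preset
    if (is.null(mode))
      mode <- if (!is.null(preset) && preset@frameInterval < 5)
        "embryo" else "culture"
    envWindow <- if (!is.null(preset))
      max(5L, round(preset@p0 / preset@frameInterval) + 1L) else 5L
  } else {
    times <- cohort$times
    her1 <- cohort$her1
    if (is.null(mode)) mode <- "culture"
    envWindow <- 5L
  }
  ids <- colnames(her1)
  if (is.null(ids)) ids <- sprintf("cell%04d", seq_len(ncol(her1)))
  cellRows <- vector("list", ncol(her1))
  cycleRows <- vector("list", ncol(her1))
  ratioRows <- vector("list", ncol(her1))
  for (i in seq_len(ncol(her1))) {
    v <- her1[, i]
    # trim leading/trailing missing runs (track start/end, cell death);
    # only interior gaps are interpolated
    have <- which(!is.na(v))
    if (length(have) < 10L) {
      cellRows[[i]] <- data.frame(cell_id = ids[i], n_peaks = NA_integer_,
                                  last_peak_time = NA_real_, censored = FALSE,
                                  oscillatory = FALSE, rejected = TRUE)
      next
    }
    span <- have[1L]:have[length(have)]
    filled <- fillShortGaps(v[span], maxGap)
    if (is.null(filled)) {
      cellRows[[i]] <- data.frame(cell_id = ids[i], n_peaks = NA_integer_,
                                  last_peak_time = NA_real_, censored = FALSE,
                                  oscillatory = FALSE, rejected = TRUE)
      next
    }
    ps <- tracePeakSet(times[span], filled, mode = mode, widthMin = widthMin,
                       distanceMin = distanceMin, prominenceK = prominenceK,
                       envelopeWindow = envWindow)
    ct <- buildCycleTable(ps, t0Offset = 0, cellId = ids[i])
    ct$cell$rejected <- FALSE
    cellRows[[i]] <- ct$cell
    cycleRows[[i]] <- ct$cycles
    ratioRows[[i]] <- ct$ratios
  }
  list(cells = do.call(rbind, cellRows),
       cycles = do.call(rbind, cycleRows),
       ratios = do.call(rbind, ratioRows))
}

# interpolate interior NA gaps of length <= maxGap; NULL if a longer gap
# exists (caller trims leading/trailing runs first)
fillShortGaps <- function(v, maxGap) {
  if (!anyNA(v)) return(v)
  r <- rle(is.na(v))
  if (any(r$lengths[r$values] > maxGap)) return(NULL)
  idx <- which(!is.na(v))
  stats::approx(idx, v[idx], xout = seq_along(v), rule = 2)$y
}

#' Apply the left-censoring rule for last peaks before acquisition start
#'
#' Cells whose trace begins already past the last oscillation peak — no
#' peak was detected, yet the trace starts elevated above its final
#' baseline by more than \code{k} noise SDs and never rises further
#' (i.e. it is already decaying from frame 1) — get
#' \code{last_peak_time = acquisitionStart} and \code{censored = TRUE}.
#' Cells whose trace starts mid-oscillation but still shows detected peaks
#' are not censored; their detected last peak is within the movie.
#' Downstream period statistics exclude censored cells while last-peak
#' box plots include them.
#'
#' @param cells per-cell table from \code{\link{analyzeCohort}}.
#' @param her1 matrix of traces (frames x cells, columns matching
#'   \code{cells$cell_id}).
#' @param acquisitionStart acquisition start time, minutes.
#' @param k noise-SD multiple for "elevated" and "never rises".
#' @return the \code{cells} table with updated \code{last_peak_time} and
#'   \code{censored}.
#' @export
applyLeftCensoring <- function(cells, her1, acquisitionStart, k = 3) {
  stopifnot(is.data.frame(cells), is.matrix(her1))
  for (i in seq_len(nrow(cells))) {
    if (!is.na(cells$n_peaks[i]) && cells$n_peaks[i] > 0L) next
    j <- match(cells$cell_id[i], colnames(her1))
    if (is.na(j)) next
    v <- her1[, j]
    v <- v[!is.na(v)]
    if (length(v) < 10L) next
    sm <- stats::runmed(v, 3L)
    noise <- robustNoiseSD(v)
    tailBase <- median(tail(sm, 6L))
    startsElevated <- sm[1L] > tailBase + k * max(noise, 1e-12)
    neverRises <- max(sm) - sm[1L] < k * max(noise, 1e-12)
    if (startsElevated && neverRises) {
      cells$last_peak_time[i] <- acquisitionStart
      cells$censored[i] <- TRUE
    }
  }
  cells
}

#' Per-cycle summary after aligning all cells by their first peak
#'
#' Cycle index 1 is each cell's first detected cycle; per cycle index the
#' median and 25th/75th percentiles of the period, I+ and I- are reported
#' over the cells that possess that cycle.
#'
#' @param cycles long cycle table from \code{\link{analyzeCohort}}.
#' @return data.frame: cycle, n_cells, then median/q25/q75 of period,
#'   iplus, iminus.
#' @export
alignByFirstPeak <- function(cycles) {
  stopifnot(is.data.frame(cycles), nrow(cycles) > 0)
  out <- lapply(split(cycles, cycles$cycle), function(d) {
    q <- function(x, p) as.numeric(quantile(x, p, na.rm = TRUE, names = FALSE))
    data.frame(cycle = d$cycle[1L], n_cells = nrow(d),
               period_median = median(d$period),
               period_q25 = q(d$period, 0.25), period_q75 = q(d$period, 0.75),
               iplus_median = median(d$iplus),
               iplus_q25 = q(d$iplus, 0.25), iplus_q75 = q(d$iplus, 0.75),
               iminus_median = median(d$iminus, na.rm = TRUE),
               iminus_q25 = q(d$iminus, 0.25), iminus_q75 = q(d$iminus, 0.75))
  })
  res <- do.call(rbind, out)
  res[order(res$cycle), , drop = FALSE]
}
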