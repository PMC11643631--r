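# Mesp differentiation-marker onset: clear-rise classification,
# thresholded sustained-rise onset calling, and the onset-vs-arrest
# relation. All constants of the onset rule are explicit parameters.

#' Classify whether a Mesp trace shows a clear intensity rise
#'
#' Baseline is the median of the first \code{baselineFrames} frames; noise
#' is the robust SD of that segment, floored by the whole-trace
#' first-difference estimate (a handful of baseline frames can
#' underestimate the noise badly, and the trace is flat outside the rise,
#' so the global estimate is a safe lower bound). A clear rise requires
#' the smoothed maximum to exceed the baseline by at least
#' \code{max(k * noise, f * baseline)}.
#'
#' @param values Mesp trace (>= 20 samples).
#' @param baselineFrames frames used for the baseline (default 6).
#' @param k noise-SD multiple.
#' @param f baseline fraction.
#' @param smoothWindow moving-median window.
#' @return list with \code{clearRise}, \code{riseMagnitude},
#'   \code{baseline}, \code{noise}.
#' @export
classifyClearRise <- function(values, baselineFrames = 6L, k = 5, f = 0.5,
                              smoothWindow = 3L) {
  v <- values[!is.na(values)]
  if (length(v) < 20L) stop("at least 20 samples required")
  if (length(v) < baselineFrames) stop("trace shorter than the baseline window")
  base <- median(v[seq_len(baselineFrames)])
  noise <- max(robustNoiseSD(v[seq_len(baselineFrames)]), robustNoiseSD(v))
  sm <- movingMedian(v, smoothWindow)
  rise <- max(sm) - base
  list(clearRise = rise >= max(k * noise, f * abs(base)),
       riseMagnitude = max(rise, 0), baseline = base, noise = noise)
}

#' Detect the Mesp signal-onset time
#'
#' Earliest time at which the moving-median-smoothed trace exceeds
#' \code{baseline + kOn * noise} and stays above for \code{sustain}
#' consecutive frames. Intended to be called on traces classified as
#' clear-rise; a clear-rise trace in which the criterion is never met is
#' flagged inconsistent (forcing a parameter review) rather than silently
#' assigned an onset.
#'
#' @param times sample times, minutes.
#' @param values Mesp trace values.
#' @param baselineFrames,kOn,sustain,smoothWindow rule constants.
#' @return list with \code{onsetTime} (minutes or NA), \code{clearRise},
#'   \code{riseMagnitude}, \code{baseline}, \code{inconsistent}.
#' @export
detectOnset <- function(times, values, baselineFrames = 6L, kOn = 3,
                        sustain = 3L, smoothWindow = 3L) {
  cls <- classifyClearRise(values, baselineFrames = baselineFrames,
                           smoothWindow = smoothWindow)
  out <- list(onsetTime = NA_real_, clearRise = cls$clearRise,
              riseMagnitude = cls$riseMagnitude, baseline = cls$baseline,
              inconsistent = FALSE)
  if (!cls$clearRise) return(out)
  v <- values
  ok <- !is.na(v)
  sm <- rep(NA_real_, length(v))
  sm[ok] <- movingMedian(v[ok], smoothWindow)
  thresh <- cls$baseline + kOn * max(cls$noise, 1e-12)
  above <- !is.na(sm) & sm > thresh
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= sustain) {
      out$onsetTime <- times[i - sustain + 1L]
      return(out)
    }
  }
  out$inconsistent <- TRUE
  out
}

#' Onset time relative to clock arrest
#'
#' Signed difference onset minus last-peak time per cell, with a cohort
#' summary: the distribution of the differences, the fraction positive
#' (onset after arrest), and tallies of cells lacking either event.
#'
#' @param cells per-cell table with \code{cell_id} and
#'   \code{last_peak_time} (e.g. from \code{\link{analyzeCohort}}).
#' @param onsets per-cell table with \code{cell_id} and \code{onset_min}
#'   (e.g. from \code{\link{analyzeOnsets}}).
#' @return list with \code{perCell} (cell_id, onset_min, last_peak_time,
#'   delta_min), \code{fractionPositive}, \code{nBothEvents},
#'   \code{nMissingOnset}, \code{nMissingArrest}.
#' @export
onsetVsArrest <- function(cells, onsets) {
  m <- merge(cells[, c("cell_id", "last_peak_time")],
             onsets[, c("cell_id", "onset_min")], by = "cell_id")
  both <- complete.cases(m[, c("last_peak_time", "onset_min")])
  d <- m$onset_min - m$last_peak_time
  list(perCell = data.frame(cell_id = m$cell_id, onset_min = m$onset_min,
                            last_peak_time = m$last_peak_time,
                            delta_min = d),
       fractionPositive = if (any(both)) mean(d[both] > 0) else NA_real_,
       nBothEvents = sum(both),
       nMissingOnset = sum(is.na(m$onset_min)),
       nMissingArrest = sum(is.na(m$last_peak_time)))
}

#' Per-frame maximum intensity within a fixed ROI
#'
#' The maximum-intensity-in-ROI trace variant used for the clock-mutant
#' arm, where no segmentation mask exists.
#'
#' @param stack H x W x T fluorescence array.
#' @param roi ROI as \code{c(x, y, w, h)}, 0-based pixel coordinates,
#'   half-open (x = column, y = row).
#' @return numeric trace of per-frame ROI maxima.
#' @export
onsetFromRoiMax <- function(stack, roi) {
  stopifnot(length(dim(stack)) == 3L, length(roi) == 4L)
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w <= 0 || h <= 0) stop("empty ROI")
  rows <- (y + 1):(y + h)
  cols <- (x + 1):(x + w)
  if (min(rows) < 1 || max(rows) > dim(stack)[1] ||
      min(cols) < 1 || max(cols) > dim(stack)[2])
    stop("ROI outside image bounds")
  vapply(seq_len(dim(stack)[3]),
         function(t) max(stack[rows, cols, t]), numeric(1))
}

#' Run clear-rise classification and onset detection over a cohort
#'
#' @param cohort a \linkS4class{ClockCohort} (or list with \code{times} and
#'   a \code{mesp} matrix).
#' @param ... passed to \code{\link{detectOnset}}.
#' @return data.frame: cell_id, clear_rise, onset_min, rise_magnitude,
#'   inconsistent.
#' @examples
#' coh <- generateCohort(clockPreset("her1her7_mutant"), n = 4, seed = 1)
#' analyzeOnsets(coh)
#' @export
analyzeOnsets <- function(cohort, ...) {
  if (is(cohort, "ClockCohort")) {
    times <- cohortTimes(cohort)
    mesp <- SummarizedExperiment::assay(cohort, "mesp")
  } else {
    times <- cohort$times
    mesp <- cohort$mesp
  }
  ids <- colnames(mesp)
  if (is.null(ids)) ids <- sprintf("cell%04d", seq_len(ncol(mesp)))
  rows <- lapply(seq_len(ncol(mesp)), function(i) {
    oc <- detectOnset(times, mesp[, i], ...)
    data.frame(cell_id = ids[i], clear_rise = oc$clearRise,
               onset_min = oc$onsetTime, rise_magnitude = oc$riseMagnitude,
               inconsistent = oc$inconsistent)
  })
  do.call(rbind, rows)
}
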