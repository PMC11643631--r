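#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats dnorm pnorm qnorm rnorm runif rlnorm median mad
#'   quantile sd cor uniroot complete.cases
#' @importFrom utils head tail read.csv write.csv
NULL

#' Generator preset for one experimental condition
#'
#' A \code{GeneratorPreset} bundles every parameter of the intrinsic-timer
#' generator for one condition: the truncated discrete distribution of the
#' number of Her1 peaks per cell, the initial cycle period, lognormal
#' distributions of the successive period ratio \eqn{r_k} and peak-intensity
#' ratio \eqn{s_k} (parameterised by the probability of exceeding 1 and a
#' log-scale spread), the first-peak delay, the Mesp onset delay relative to
#' clock arrest, imaging timing, and intensity-noise scale.
#'
#' Times are minutes post-dissociation for culture presets and minutes from
#' movie start (or tailbud exit, in flows) for the embryo preset.
#'
#' @slot conditionName label of the condition.
#' @slot nPeaksMean,nPeaksSD mean/SD of the latent normal behind the
#'   discretised truncated peak-count distribution.
#' @slot nPeaksSupport integer support of the peak-count distribution.
#' @slot p0 initial period, minutes.
#' @slot p0SDlog lognormal spread of the per-cell initial period.
#' @slot slowProb probability that a successive period ratio exceeds 1.
#' @slot slowSDlog log-scale SD of the period-ratio distribution.
#' @slot riseProb probability that a successive peak-intensity ratio exceeds 1.
#' @slot riseSDlog log-scale SD of the intensity-ratio distribution.
#' @slot delayMean,delaySD,delayMin first-peak delay: latent normal mean/SD
#'   and lower truncation bound, minutes.
#' @slot onsetDelayMean,onsetDelaySD Mesp onset time minus last-peak time,
#'   minutes (may be negative).
#' @slot onsetDirectMean,onsetDirectSD direct onset-time distribution used
#'   when oscillations are disabled, minutes.
#' @slot clearRiseProb probability a cell shows a detectable Mesp rise.
#' @slot frameInterval minutes between frames.
#' @slot imagingStartOffset minutes post-dissociation at the first frame.
#' @slot noiseSD additive Gaussian intensity noise, a.u.
#' @slot oscillationEnabled logical; \code{FALSE} for the clock-mutant preset.
#' @slot duration total simulated minutes.
#' @slot baseline,amp0,amp0SDlog Her1 baseline and first-peak amplitude, a.u.
#' @slot pulseWidthFrac Gaussian pulse sigma as a fraction of the local period.
#' @slot mespBaseline,mespAmplitude,mespTau Mesp trace shape parameters.
#' @slot trackEnd minutes after the Mesp onset (or 1.5x this after arrest,
#'   for cells without onset) at which the cell's record ends, emulating
#'   embryo tracks that stop at somite formation; \code{Inf} for culture
#'   movies that run to the end of acquisition.
#' @exportClass GeneratorPreset
setClass("GeneratorPreset",
  representation(
    conditionName = "character",
    nPeaksMean = "numeric", nPeaksSD = "numeric", nPeaksSupport = "integer",
    p0 = "numeric", p0SDlog = "numeric",
    slowProb = "numeric", slowSDlog = "numeric",
    riseProb = "numeric", riseSDlog = "numeric",
    delayMean = "numeric", delaySD = "numeric", delayMin = "numeric",
    onsetDelayMean = "numeric", onsetDelaySD = "numeric",
    onsetDirectMean = "numeric", onsetDirectSD = "numeric",
    clearRiseProb = "numeric",
    frameInterval = "numeric", imagingStartOffset = "numeric",
    noiseSD = "numeric",
    oscillationEnabled = "logical",
    duration = "numeric",
    baseline = "numeric", amp0 = "numeric", amp0SDlog = "numeric",
    pulseWidthFrac = "numeric",
    mespBaseline = "numeric", mespAmplitude = "numeric", mespTau = "numeric",
    trackEnd = "numeric"
  )
)

setValidity("GeneratorPreset", function(object) {
  msg <- character()
  if (object@p0 <= 0) msg <- c(msg, "p0 must be positive")
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be positive")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  probs <- c(object@slowProb, object@riseProb, object@clearRiseProb)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  if (length(object@nPeaksSupport) < 1L || any(object@nPeaksSupport < 1L))
    msg <- c(msg, "peak-count support must be positive integers")
  if (any(diff(object@nPeaksSupport) != 1L))
    msg <- c(msg, "peak-count support must be contiguous")
  if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Latent program of a single simulated cell
#'
#' The generator's ground-truth description of one cell: peak times,
#' per-cycle periods and amplitudes, the arrest time (equal to the last
#' peak time when oscillations are enabled), the Mesp onset time (or
#' \code{NA} when the cell shows no clear rise), and cohort metadata used
#' by the inclusion filter.
#'
#' @slot cellId label.
#' @slot peakTimes strictly increasing peak times, minutes.
#' @slot periods successive peak-time differences, minutes.
#' @slot peakAmplitudes positive peak amplitudes, a.u.
#' @slot arrestTime minutes; last peak time, or \code{NA} for non-oscillating cells.
#' @slot onsetTime Mesp onset, minutes; \code{NA} when absent.
#' @slot clearRise logical, whether a Mesp rise is rendered.
#' @slot conditionName preset label.
#' @slot survivedPast5h,divided inclusion metadata flags.
#' @exportClass CellProgram
setClass("CellProgram",
  representation(
    cellId = "character",
    peakTimes = "numeric",
    periods = "numeric",
    peakAmplitudes = "numeric",
    arrestTime = "numeric",
    onsetTime = "numeric",
    clearRise = "logical",
    conditionName = "character",
    survivedPast5h = "logical",
    divided = "logical"
  )
)

setValidity("CellProgram", function(object) {
  msg <- character()
  pt <- object@peakTimes
  if (length(pt) > 1L) {
    if (any(diff(pt) <= 0)) msg <- c(msg, "peakTimes must be strictly increasing")
    if (length(object@periods) != length(pt) - 1L ||
        max(abs(object@periods - diff(pt))) > 1e-8)
      msg <- c(msg, "periods must equal diff(peakTimes)")
  }
  if (length(object@peakAmplitudes) != length(pt))
    msg <- c(msg, "one amplitude per peak required")
  if (length(pt) && any(object@peakAmplitudes <= 0))
    msg <- c(msg, "amplitudes must be positive")
  if (length(pt) && !is.na(object@arrestTime) &&
      abs(object@arrestTime - max(pt)) > 1e-8)
    msg <- c(msg, "arrestTime must equal the last peak time")
  if (length(msg)) msg else TRUE
})

#' Cohort of simulated (or measured) single-cell traces
#'
#' A \linkS4class{SummarizedExperiment} subclass holding the Her1 and Mesp
#' intensity matrices (frames in rows, cells in columns), per-frame times in
#' \code{rowData(x)$t_min}, per-cell metadata (including generator ground
#' truth) in \code{colData}, and the preset, master seed and the list of
#' \linkS4class{CellProgram} objects in \code{metadata}.
#'
#' @exportClass ClockCohort
setClass("ClockCohort", contains = "SummarizedExperiment")

#' Synthetic brightfield/fluorescence scene for one cell
#'
#' @slot frames brightfield stack, array H x W x T in [0, 1].
#' @slot masks ground-truth binary stack, H x W x T.
#' @slot her1Stack,mespStack fluorescence stacks, a.u.
#' @slot program the \linkS4class{CellProgram} rendered in the scene.
#' @slot times frame times, minutes.
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(
    frames = "array", masks = "array",
    her1Stack = "array", mespStack = "array",
    program = "CellProgram", times = "numeric"
  )
)

setValidity("SyntheticScene", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an H x W x T array")
  if (!identical(dim(object@masks), d)) return("masks must match frames")
  if (!identical(dim(object@her1Stack), d) ||
      !identical(dim(object@mespStack), d))
    return("fluorescence stacks must match frames")
  if (length(object@times) != d[3L]) return("one time per frame required")
  TRUE
})

#' Reference curve (e.g. a segmented notochord) used for projections
#'
#' Per frame an ordered polyline (posterior to anterior) with cumulative
#' arc-length per vertex, in micrometres.
#'
#' @slot vertices list (one element per frame) of 2-column x/y matrices.
#' @slot frames integer frame indices matching \code{vertices}.
#' @exportClass ReferenceCurve
setClass("ReferenceCurve",
  representation(vertices = "list", frames = "integer")
)

setValidity("ReferenceCurve", function(object) {
  if (length(object@vertices) != length(object@frames))
    return("one vertex matrix per frame required")
  for (v in object@vertices) {
    if (!is.matrix(v) || ncol(v) != 2L || nrow(v) < 2L)
      return("each frame needs a 2-column matrix with >= 2 vertices")
    if (any(sqrt(rowSums(diff(v)^2)) <= 0))
      return("arc-length must be strictly increasing along vertices")
  }
  TRUE
})

#' Event kymograph against a reference curve
#'
#' Rows are time points (aligned curve segments), columns are arc-length
#' bins; entries are mean event times (last peak or Mesp onset) of the cells
#' whose event fell in that bin, \code{NA} where empty. \code{counts} holds
#' the per-bin occupancy so totals are conserved under re-binning.
#'
#' @slot values matrix of mean event values.
#' @slot counts matrix of bin occupancies.
#' @slot binWidth micrometres per bin.
#' @slot event \code{"last_peak"} or \code{"onset"}.
#' @slot binStarts arc-length at the left edge of each bin column.
#' @slot rowTimes time (minutes) of each row.
#' @exportClass ClockKymograph
setClass("ClockKymograph",
  representation(
    values = "matrix", counts = "matrix",
    binWidth = "numeric", event = "character",
    binStarts = "numeric", rowTimes = "numeric"
  )
)

setValidity("ClockKymograph", function(object) {
  if (!identical(dim(object@values), dim(object@counts)))
    return("values and counts must have identical dimensions")
  if (object@binWidth <= 0) return("binWidth must be positive")
  TRUE
})

setMethod("show", "GeneratorPreset", function(object) {
  cat("GeneratorPreset '", object@conditionName, "'\n", sep = "")
  cat(sprintf("  peaks: discretised N(%.2f, %.2f) on %d..%d%s\n",
              object@nPeaksMean, object@nPeaksSD,
              min(object@nPeaksSupport), max(object@nPeaksSupport),
              if (object@oscillationEnabled) "" else " (oscillation disabled)"))
  cat(sprintf("  p0 = %g min, P(period ratio > 1) = %.2f, P(intensity ratio > 1) = %.2f\n",
              object@p0, object@slowProb, object@riseProb))
  cat(sprintf("  frames every %g min from %g min, duration %g min, noise SD %g a.u.\n",
              object@frameInterval, object@imagingStartOffset,
              object@duration, object@noiseSD))
})

setMethod("show", "CellProgram", function(object) {
  cat("CellProgram '", object@cellId, "' (", object@conditionName, ")\n", sep = "")
  cat(sprintf("  %d peak(s)", length(object@peakTimes)))
  if (length(object@peakTimes))
    cat(sprintf(", arrest at %.1f min", object@arrestTime))
  cat(if (is.na(object@onsetTime)) ", no Mesp onset\n"
      else sprintf(", Mesp onset at %.1f min\n", object@onsetTime))
})

setMethod("show", "SyntheticScene", function(object) {
  d <- dim(object@frames)
  cat(sprintf("SyntheticScene: %d x %d px, %d frames, cell '%s'\n",
              d[1], d[2], d[3], object@program@cellId))
})

setMethod("show", "ReferenceCurve", function(object) {
  cat(sprintf("ReferenceCurve: %d frame(s), %d-%d vertices, length %.1f um (frame 1)\n",
              length(object@frames),
              min(vapply(object@vertices, nrow, 1L)),
              max(vapply(object@vertices, nrow, 1L)),
              sum(sqrt(rowSums(diff(object@vertices[[1L]])^2)))))
})

setMethod("show", "ClockKymograph", function(object) {
  cat(sprintf("ClockKymograph (%s): %d rows x %d bins of %g um, %d cells placed\n",
              object@event, nrow(object@values), ncol(object@values),
              object@binWidth, sum(object@counts)))
})
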