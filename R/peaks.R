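# Oscillation peak detection: oscillatory-window determination, local
# maxima with width/distance/prominence constraints, and sub-frame
# parabolic peak refinement.

#' Determine the oscillatory window of a trace
#'
#' Automated surrogate for by-eye window selection. The rolling
#' half-envelope (half of the rolling peak-to-trough range, i.e. a local
#' amplitude estimate) is compared to the baseline noise. A trace counts
#' as oscillatory only if its maximal local amplitude reaches
#' \code{minAmplitudeK} noise SDs (pure noise has an expected local
#' half-range near 2.3 SDs, so flat-plus-noise traces fail this floor);
#' the window is then the contiguous run of frames around the envelope
#' maximum where the local amplitude exceeds \code{k} noise SDs.
#'
#' @param values numeric trace (>= 10 samples).
#' @param k window-extent threshold in noise SDs (k = 0 extends the window
#'   over the whole trace wherever any variation exists).
#' @param envelopeWindow rolling window length in frames (about one period).
#' @param quietFrames frames used for the baseline-noise estimate.
#' @param minAmplitudeK amplitude floor, in noise SDs, for a trace to count
#'   as oscillatory at all.
#' @return list with \code{oscillatory} (logical), \code{start}, \code{end}
#'   (frame indices; NA when non-oscillatory).
#' @export
detectOscillatoryWindow <- function(values, k = 3, envelopeWindow = 5L,
                                    quietFrames = 12L, minAmplitudeK = 5) {
  if (length(values) < 10L) stop("at least 10 samples required")
  vv <- values
  nav <- is.na(vv)
  if (any(nav)) vv[nav] <- median(vv, na.rm = TRUE)
  noise <- noiseEstimate(vv, quietFrames)
  env <- rollingEnvelope(vv, envelopeWindow) / 2
  peakAmp <- max(env)
  if (peakAmp <= 0 || peakAmp < minAmplitudeK * noise)
    return(list(oscillatory = FALSE, start = NA_integer_, end = NA_integer_))
  above <- env > k * noise
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iMax <- which.max(env)
  run <- which(r$values & starts <= iMax & ends >= iMax)
  if (!length(run)) {
    # k above the amplitude floor: fall back to the run nearest the max
    run <- which(r$values)[which.min(abs(starts[r$values] - iMax))]
    if (!length(run) || is.na(run))
      return(list(oscillatory = FALSE, start = NA_integer_, end = NA_integer_))
  }
  list(oscillatory = TRUE, start = starts[run], end = ends[run])
}

# candidate local maxima with plateau handling (midpoint of flat tops)
localMaxima <- function(v) {
  n <- length(v)
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) {
        out <- c(out, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# topographic prominence of a peak: height above the higher of the two
# bases (minima between the peak and the nearest higher terrain or edge)
peakProminence <- function(v, idx) {
  n <- length(v)
  h <- v[idx]
  left <- idx
  leftMin <- h
  while (left > 1L) {
    left <- left - 1L
    if (v[left] > h) break
    if (v[left] < leftMin) leftMin <- v[left]
  }
  right <- idx
  rightMin <- h
  while (right < n) {
    right <- right + 1L
    if (v[right] > h) break
    if (v[right] < rightMin) rightMin <- v[right]
  }
  h - max(leftMin, rightMin)
}

# interpolated width (in samples) at half prominence
peakWidth <- function(v, idx, prom) {
  h <- v[idx]
  ref <- h - prom / 2
  i <- idx
  while (i > 1L && v[i - 1L] > ref) i <- i - 1L
  leftX <- if (i == 1L) 1 else
    (i - 1L) + (ref - v[i - 1L]) / (v[i] - v[i - 1L])
  j <- idx
  n <- length(v)
  while (j < n && v[j + 1L] > ref) j <- j + 1L
  rightX <- if (j == n) n else
    j + (v[j] - ref) / (v[j] - v[j + 1L])
  rightX - leftX
}

#' Find peaks satisfying width, distance and prominence constraints
#'
#' Local maxima of the trace filtered by minimum topographic prominence,
#' minimum width at half prominence, and minimum inter-peak distance
#' (higher peaks win). The same single parameter set is intended to be
#' applied across all traces of an arm. Troughs are found by running this
#' on the negated trace.
#'
#' @param values numeric trace.
#' @param widthMin minimum width at half prominence, in frames.
#' @param distanceMin minimum distance between retained peaks, in frames.
#' @param prominenceMin minimum prominence, in intensity units.
#' @return integer vector of raw peak indices (sorted).
#' @export
findTracePeaks <- function(values, widthMin = 1, distanceMin = 1,
                           prominenceMin = 0) {
  v <- values
  nav <- is.na(v)
  if (any(nav)) v[nav] <- min(v, na.rm = TRUE)
  cand <- localMaxima(v)
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) peakProminence(v, i), numeric(1))
  keep <- prom >= prominenceMin & prom > 0
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(integer(0))
  if (widthMin > 0) {
    wid <- vapply(seq_along(cand),
                  function(k) peakWidth(v, cand[k], prom[k]), numeric(1))
    cand <- cand[wid >= widthMin]
  }
  if (!length(cand)) return(integer(0))
  if (distanceMin > 1) {
    ord <- order(-v[cand])
    kept <- logical(length(cand))
    blocked <- logical(length(cand))
    for (k in ord) {
      if (blocked[k]) next
      kept[k] <- TRUE
      blocked[abs(cand - cand[k]) < distanceMin & seq_along(cand) != k] <- TRUE
    }
    cand <- cand[kept]
  }
  sort(cand)
}

#' Sub-frame parabolic refinement of a raw peak
#'
#' Fits the parabola through the sample at the raw maximum and its two
#' neighbours; the vertex gives the refined time and height:
#' \deqn{t^* = t + \frac{\Delta}{2}\,\frac{I_- - I_+}{I_- - 2 I_0 + I_+}}
#' A flat top (zero denominator) or a boundary peak returns the raw sample
#' unrefined.
#'
#' @param times sample times (uniform spacing).
#' @param values sample values.
#' @param rawIndex index of the raw peak.
#' @return list with \code{time}, \code{height}, \code{refined} (logical).
#' @export
refinePeakParabolic <- function(times, values, rawIndex) {
  n <- length(values)
  if (rawIndex <= 1L || rawIndex >= n)
    return(list(time = times[rawIndex], height = values[rawIndex],
                refined = FALSE))
  im <- values[rawIndex - 1L]; i0 <- values[rawIndex]; ip <- values[rawIndex + 1L]
  denom <- im - 2 * i0 + ip
  if (denom == 0)
    return(list(time = times[rawIndex], height = i0, refined = FALSE))
  delta <- times[rawIndex + 1L] - times[rawIndex]
  shift <- (delta / 2) * (im - ip) / denom
  # vertex height of the parabola through the three samples
  a <- denom / (2 * delta^2)
  height <- i0 - a * shift^2
  list(time = times[rawIndex] + shift, height = height, refined = TRUE)
}

# detect + refine peaks and alternating troughs of one trace
# mode "culture": restrict to the oscillatory window first
# mode "embryo": full trace, single parameter set
tracePeakSet <- function(times, values, mode = c("culture", "embryo"),
                         widthMin = NULL, distanceMin = NULL,
                         prominenceK = NULL, envelopeK = 3,
                         envelopeWindow = 5L) {
  mode <- match.arg(mode)
  if (is.null(widthMin)) widthMin <- if (mode == "embryo") 3 else 1
  if (is.null(distanceMin)) distanceMin <- if (mode == "embryo") 10 else 3
  if (is.null(prominenceK)) prominenceK <- 6
  noise <- noiseEstimate(values)
  lo <- 1L; hi <- length(values)
  window <- list(oscillatory = TRUE, start = lo, end = hi)
  if (mode == "culture") {
    window <- detectOscillatoryWindow(values, k = envelopeK,
                                      envelopeWindow = envelopeWindow)
    if (!window$oscillatory)
      return(list(peaks = emptyPeakFrame(), troughs = emptyPeakFrame(),
                  window = window, noise = noise))
    lo <- window$start; hi <- window$end
  }
  sub <- values[lo:hi]
  promMin <- prominenceK * noise
  rawPeaks <- findTracePeaks(sub, widthMin, distanceMin, promMin) + lo - 1L
  peaks <- refineIndices(times, values, rawPeaks)
  troughs <- emptyPeakFrame()
  if (nrow(peaks) >= 2L) {
    rawTroughs <- findTracePeaks(-sub, widthMin, distanceMin, promMin) + lo - 1L
    troughs <- alternatingTroughs(times, values, rawPeaks, rawTroughs)
  }
  list(peaks = peaks, troughs = troughs, window = window, noise = noise)
}

emptyPeakFrame <- function() {
  data.frame(raw_index = integer(0), time = numeric(0),
             height = numeric(0), refined = logical(0))
}

refineIndices <- function(times, values, idx) {
  if (!length(idx)) return(emptyPeakFrame())
  res <- lapply(idx, function(i) refinePeakParabolic(times, values, i))
  data.frame(raw_index = idx,
             time = vapply(res, `[[`, numeric(1), "time"),
             height = vapply(res, `[[`, numeric(1), "height"),
             refined = vapply(res, `[[`, logical(1), "refined"))
}

# enforce peak/trough alternation: one trough per inter-peak interval,
# the deepest candidate (fallback: the raw minimum sample), refined on the
# negated trace
alternatingTroughs <- function(times, values, rawPeaks, rawTroughs) {
  out <- vector("list", length(rawPeaks) - 1L)
  for (k in seq_len(length(rawPeaks) - 1L)) {
    lo <- rawPeaks[k]; hi <- rawPeaks[k + 1L]
    inBetween <- rawTroughs[rawTroughs > lo & rawTroughs < hi]
    idx <- if (length(inBetween)) inBetween[which.min(values[inBetween])]
      else (lo:hi)[which.min(values[lo:hi])]
    r <- refinePeakParabolic(times, -values, idx)
    out[[k]] <- data.frame(raw_index = idx, time = r$time,
                           height = -r$height, refined = r$refined)
  }
  do.call(rbind, out)
}
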