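# Intrinsic-timer oscillator simulation: per-cell programs, rendered
# Her1/Mesp traces, and whole cohorts.

#' Draw the latent program of one cell
#'
#' Draws the number of peaks K from the preset's truncated discretised
#' normal, the first-peak delay from a lower-truncated normal, successive
#' periods through lognormal period ratios (\code{period[k+1] =
#' r_k * period[k]}), peak amplitudes through lognormal intensity ratios,
#' and the Mesp onset as last-peak time + delay, present with probability
#' \code{clearRiseProb}. With oscillations disabled (clock-mutant preset)
#' no peaks are drawn and the onset time is drawn directly.
#'
#' @param preset a \linkS4class{GeneratorPreset}.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param cellId label stored in the program.
#' @return a \linkS4class{CellProgram}.
#' @examples
#' drawCellProgram(clockPreset("culture_psm4"), seed = 1)
#' @export
drawCellProgram <- function(preset, seed, cellId = "cell") {
  stopifnot(is(preset, "GeneratorPreset"))
  validObject(preset)
  set.seed(seed)
  if (!preset@oscillationEnabled) {
    clear <- runif(1) < preset@clearRiseProb
    onset <- if (clear)
      rnorm(1, preset@onsetDirectMean, preset@onsetDirectSD) else NA_real_
    return(new("CellProgram",
               cellId = cellId, peakTimes = numeric(0), periods = numeric(0),
               peakAmplitudes = numeric(0), arrestTime = NA_real_,
               onsetTime = onset, clearRise = clear,
               conditionName = preset@conditionName,
               survivedPast5h = TRUE, divided = FALSE))
  }
  support <- preset@nPeaksSupport
  pmf <- discNormPmf(preset@nPeaksMean, preset@nPeaksSD, support)
  K <- support[findInterval(runif(1), cumsum(pmf), left.open = TRUE) + 1L]
  delay <- rtruncnormLower(1, preset@delayMean, preset@delaySD, preset@delayMin)
  p1 <- preset@p0 * exp(rnorm(1, 0, preset@p0SDlog) - preset@p0SDlog^2 / 2)
  rk <- exp(rnorm(max(K - 2L, 0L),
                  preset@slowSDlog * qnormClamped(preset@slowProb), preset@slowSDlog))
  periods <- if (K >= 2L) p1 * cumprod(c(1, rk)) else numeric(0)
  peakTimes <- delay + c(0, cumsum(periods))
  a1 <- preset@amp0 * exp(rnorm(1, 0, preset@amp0SDlog) - preset@amp0SDlog^2 / 2)
  sk <- exp(rnorm(max(K - 1L, 0L),
                  preset@riseSDlog * qnormClamped(preset@riseProb), preset@riseSDlog))
  amplitudes <- a1 * cumprod(c(1, sk))
  arrest <- max(peakTimes)
  clear <- runif(1) < preset@clearRiseProb
  onset <- if (clear)
    arrest + rnorm(1, preset@onsetDelayMean, preset@onsetDelaySD) else NA_real_
  new("CellProgram",
      cellId = cellId, peakTimes = peakTimes, periods = periods,
      peakAmplitudes = amplitudes, arrestTime = arrest,
      onsetTime = onset, clearRise = clear,
      conditionName = preset@conditionName,
      survivedPast5h = TRUE, divided = FALSE)
}

# noiseless Her1 intensity at times t: baseline + Gaussian pulses at the
# peak times, pulse sigma tied to the local period
her1Signal <- function(program, preset, t) {
  v <- rep(preset@baseline, length(t))
  pt <- program@peakTimes
  if (!length(pt)) return(v)
  per <- program@periods
  for (k in seq_along(pt)) {
    local <- if (!length(per)) preset@p0
      else if (k == 1L) per[1L]
      else if (k == length(pt)) per[length(per)]
      else (per[k - 1L] + per[k]) / 2
    sig <- preset@pulseWidthFrac * local
    v <- v + program@peakAmplitudes[k] * exp(-(t - pt[k])^2 / (2 * sig^2))
  }
  v
}

# noiseless Mesp intensity: flat baseline, saturating rise from onset
mespSignal <- function(program, preset, t) {
  v <- rep(preset@mespBaseline, length(t))
  if (is.na(program@onsetTime)) return(v)
  after <- t >= program@onsetTime
  v[after] <- v[after] + preset@mespAmplitude *
    (1 - exp(-(t[after] - program@onsetTime) / preset@mespTau))
  v
}

#' Render the Her1 and Mesp traces of one cell
#'
#' Samples the program's noiseless signals on the preset's frame grid
#' (from \code{imagingStartOffset} to \code{duration} every
#' \code{frameInterval} minutes) and adds Gaussian noise of SD
#' \code{noiseSD}. A warning is issued if the frame interval is at or above
#' half the shortest period (aliasing risk).
#'
#' @param program a \linkS4class{CellProgram}.
#' @param preset the \linkS4class{GeneratorPreset} the program was drawn from.
#' @param seed integer seed for the noise; deterministic given the seed.
#' @return list with \code{times} (minutes) and numeric vectors \code{her1}
#'   and \code{mesp}.
#' @export
renderTraces <- function(program, preset, seed) {
  stopifnot(is(program, "CellProgram"), is(preset, "GeneratorPreset"))
  if (length(program@periods) &&
      preset@frameInterval >= min(program@periods) / 2)
    warning("frame interval >= half the shortest period: aliasing likely")
  times <- seq(preset@imagingStartOffset, preset@duration,
               by = preset@frameInterval)
  set.seed(seed)
  her1 <- her1Signal(program, preset, times) +
    rnorm(length(times), 0, preset@noiseSD)
  mesp <- mespSignal(program, preset, times) +
    rnorm(length(times), 0, preset@noiseSD)
  list(times = times, her1 = her1, mesp = mesp)
}

#' Generate a cohort of simulated cells
#'
#' Draws \code{n} independent cell programs and rendered traces with
#' per-cell seeds derived from the master seed by counter-based splitting.
#' A configurable fraction of cells is planted as inclusion-filter failures
#' (alternating early death, i.e. the trace is truncated before 5 h, and
#' division), to exercise downstream filtering.
#'
#' @param preset a \linkS4class{GeneratorPreset}.
#' @param n number of cells (> 0).
#' @param seed master seed.
#' @param failureFraction fraction of cells planted as inclusion failures.
#' @return a \linkS4class{ClockCohort}.
#' @examples
#' coh <- generateCohort(clockPreset("culture_psm4"), n = 5, seed = 1)
#' SummarizedExperiment::colData(coh)
#' @export
generateCohort <- function(preset, n, seed, failureFraction = 0) {
  stopifnot(is(preset, "GeneratorPreset"))
  if (n <= 0) stop("n must be positive")
  stopifnot(failureFraction >= 0, failureFraction <= 1)
  times <- seq(preset@imagingStartOffset, preset@duration,
               by = preset@frameInterval)
  her1 <- matrix(NA_real_, length(times), n)
  mesp <- matrix(NA_real_, length(times), n)
  programs <- vector("list", n)
  set.seed(splitSeed(seed, 0))
  failMask <- runif(n) < failureFraction
  failKind <- rep(c("died", "divided"), length.out = n)
  for (i in seq_len(n)) {
    id <- sprintf("%s_c%04d", preset@conditionName, i)
    prog <- drawCellProgram(preset, splitSeed(seed, 2L * i - 1L), cellId = id)
    if (failMask[i]) {
      if (failKind[i] == "died") prog@survivedPast5h <- FALSE
      else prog@divided <- TRUE
    }
    tr <- renderTraces(prog, preset, splitSeed(seed, 2L * i))
    if (is.finite(preset@trackEnd) && preset@oscillationEnabled) {
      # embryo-style tracks end at somite formation, shortly after onset
      endT <- if (!is.na(prog@onsetTime)) prog@onsetTime + preset@trackEnd
        else prog@arrestTime + 1.5 * preset@trackEnd
      gone <- tr$times > endT
      tr$her1[gone] <- NA_real_
      tr$mesp[gone] <- NA_real_
    }
    if (!prog@survivedPast5h) {
      # death before 5 h post-dissociation: no signal afterwards
      dead <- tr$times > 300
      tr$her1[dead] <- NA_real_
      tr$mesp[dead] <- NA_real_
    }
    her1[, i] <- tr$her1
    mesp[, i] <- tr$mesp
    programs[[i]] <- prog
  }
  cd <- S4Vectors::DataFrame(
    cell_id = vapply(programs, function(p) p@cellId, character(1)),
    condition = preset@conditionName,
    n_peaks_true = vapply(programs, function(p) length(p@peakTimes), 1L),
    arrest_true = vapply(programs, function(p) p@arrestTime, 1),
    onset_true = vapply(programs, function(p) p@onsetTime, 1),
    clear_rise_true = vapply(programs, function(p) p@clearRise, TRUE),
    survived_past_5h = vapply(programs, function(p) p@survivedPast5h, TRUE),
    divided = vapply(programs, function(p) p@divided, TRUE)
  )
  rownames(cd) <- cd$cell_id
  colnames(her1) <- colnames(mesp) <- cd$cell_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(her1 = her1, mesp = mesp),
    rowData = S4Vectors::DataFrame(frame = seq_along(times), t_min = times),
    colData = cd,
    metadata = list(preset = preset, seed = seed, programs = programs)
  )
  new("ClockCohort", se)
}

#' Ground-truth programs of a cohort
#' @param cohort a \linkS4class{ClockCohort}.
#' @return list of \linkS4class{CellProgram} objects.
#' @export
cellPrograms <- function(cohort) {
  stopifnot(is(cohort, "ClockCohort"))
  S4Vectors::metadata(cohort)$programs
}

#' Frame times of a cohort, in minutes
#' @param cohort a \linkS4class{ClockCohort}.
#' @return numeric vector of frame times.
#' @export
cohortTimes <- function(cohort) {
  stopifnot(is(cohort, "ClockCohort"))
  SummarizedExperiment::rowData(cohort)$t_min
}

#' Write a cohort's traces and metadata to CSV
#'
#' Long-format trace table (cell_id, frame, t_min, her1, mesp) plus a
#' per-cell metadata table.
#'
#' @param cohort a \linkS4class{ClockCohort}.
#' @param tracePath,metaPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeCohortCSV <- function(cohort, tracePath, metaPath) {
  t_min <- cohortTimes(cohort)
  her1 <- SummarizedExperiment::assay(cohort, "her1")
  mesp <- SummarizedExperiment::assay(cohort, "mesp")
  long <- data.frame(
    cell_id = rep(colnames(her1), each = nrow(her1)),
    frame = rep(seq_len(nrow(her1)), ncol(her1)),
    t_min = rep(t_min, ncol(her1)),
    her1 = as.vector(her1),
    mesp = as.vector(mesp)
  )
  write.csv(long, tracePath, row.names = FALSE)
  write.csv(as.data.frame(SummarizedExperiment::colData(cohort)),
            metaPath, row.names = FALSE)
  invisible(c(tracePath, metaPath))
}

#' Read a long-format trace CSV back into matrices
#'
#' @param tracePath CSV written by \code{\link{writeCohortCSV}} (or with the
#'   same columns).
#' @return list with \code{times}, \code{her1} and \code{mesp} matrices
#'   (frames x cells).
#' @export
readTraceCSV <- function(tracePath) {
  long <- read.csv(tracePath)
  need <- c("cell_id", "frame", "t_min", "her1", "mesp")
  if (!all(need %in% names(long)))
    stop("trace CSV must contain columns: ", paste(need, collapse = ", "))
  cells <- unique(long$cell_id)
  frames <- sort(unique(long$frame))
  her1 <- matrix(NA_real_, length(frames), length(cells),
                 dimnames = list(NULL, cells))
  mesp <- her1
  for (i in seq_along(cells)) {
    sub <- long[long$cell_id == cells[i], ]
    sub <- sub[order(sub$frame), ]
    her1[, i] <- sub$her1
    mesp[, i] <- sub$mesp
  }
  times <- long$t_min[match(frames, long$frame)]
  list(times = times, her1 = her1, mesp = mesp)
}
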