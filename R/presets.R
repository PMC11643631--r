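# Condition presets of the intrinsic-timer generator.
#
# Each preset is calibrated so that the *expected* observables of the
# generated cohort equal the condition's published summary statistics:
# the truncated discretised-normal peak-count distribution is solved for
# its latent mean so that E[K] hits the target, and (where a last-peak
# time is a calibration target) the first-peak delay is solved so that
# E[last peak] = E[delay] + p0 * E[sum_{j=0}^{K-2} m^j], with m the mean
# of the lognormal period-ratio distribution. Calibration is closed-form /
# root-finding on exact expectations, not Monte-Carlo.

# pmf of the discretised normal truncated to an integer support
discNormPmf <- function(mu, sigma, support) {
  if (sigma <= 0) {
    k0 <- min(max(round(mu), min(support)), max(support))
    return(as.numeric(support == k0))
  }
  p <- pnorm(support + 0.5, mu, sigma) - pnorm(support - 0.5, mu, sigma)
  p / sum(p)
}

discNormMean <- function(mu, sigma, support)
  sum(support * discNormPmf(mu, sigma, support))

# solve the latent mean so the truncated discretised mean equals target
calibratePeakMean <- function(targetMean, sigma, support) {
  if (sigma <= 0) return(targetMean)
  lo <- min(support) - 4 * sigma - 1
  hi <- max(support) + 4 * sigma + 1
  uniroot(function(mu) discNormMean(mu, sigma, support) - targetMean,
          c(lo, hi), tol = 1e-10)$root
}

# qnorm with probabilities clamped away from {0, 1} so degenerate
# "always slows"/"never slows" presets stay finite
qnormClamped <- function(p) qnorm(pmin(pmax(p, 1e-9), 1 - 1e-9))

# mean of the lognormal ratio distribution given P(ratio > 1) and sdlog
ratioMean <- function(probGT1, sdlog)
  exp(sdlog * qnormClamped(probGT1) + sdlog^2 / 2)

# E[sum of periods] = p0 * E[ sum_{j=0}^{K-2} m^j ] over the K pmf
expectedPeriodSum <- function(p0, m, pmf, support) {
  g <- vapply(support, function(K)
    if (K < 2L) 0 else sum(m^(0:(K - 2L))), numeric(1))
  p0 * sum(pmf * g)
}

# exact variance of the period sum S = p0 * J * X, with J the per-cell
# lognormal p0 jitter and X = sum_{j=0}^{K-2} prod_{i<=j} r_i over iid
# lognormal ratios: E[X^2 | K] = sum_{j,l} m2^min(j,l) * m^|j-l|
varPeriodSum <- function(p0, p0sdlog, probGT1, sdlog, pmf, support) {
  muR <- sdlog * qnormClamped(probGT1)
  m <- exp(muR + sdlog^2 / 2)
  m2 <- exp(2 * muR + 2 * sdlog^2)
  ex <- vapply(support, function(K)
    if (K < 2L) 0 else sum(m^(0:(K - 2L))), numeric(1))
  ex2 <- vapply(support, function(K) {
    if (K < 2L) return(0)
    j <- 0:(K - 2L)
    sum(outer(j, j, function(a, b) m2^pmin(a, b) * m^abs(a - b)))
  }, numeric(1))
  ES <- p0 * sum(pmf * ex)
  ES2 <- p0^2 * exp(p0sdlog^2) * sum(pmf * ex2)
  ES2 - ES^2
}

# variance of a lower-truncated normal
truncnormVar <- function(mean, sd, lo) {
  if (sd <= 0) return(0)
  a <- (lo - mean) / sd
  lam <- exp(dnorm(a, log = TRUE) - pnorm(a, lower.tail = FALSE, log.p = TRUE))
  sd^2 * (1 + a * lam - lam^2)
}

# solve the latent (mu, sigma) of a lower-truncated normal with the given
# truncated mean and SD; the truncated SD cannot exceed (mean - lo) in the
# exponential-tail limit, so the target SD is capped at 90 percent of that
solveTruncNorm <- function(targetMean, targetSD, lo) {
  stopifnot(targetMean > lo)
  targetSD <- min(targetSD, 0.9 * (targetMean - lo))
  muFor <- function(sigma) {
    lower <- lo - sigma^2 / max(targetMean - lo, 1e-3) - 10 * sigma - 1
    uniroot(function(mu) truncnormMean(mu, sigma, lo) - targetMean,
            c(lower, targetMean + 5 * sigma + 1), tol = 1e-8)$root
  }
  sigma <- uniroot(function(s)
    sqrt(truncnormVar(muFor(s), s, lo)) - targetSD,
    c(targetSD / 5, targetSD * 30), tol = 1e-8)$root
  c(mu = muFor(sigma), sigma = sigma)
}

# solve the latent delay mean so E[last peak] equals the printed target
calibrateDelayMean <- function(targetLastPeak, delaySD, delayMin,
                               p0, m, pmf, support) {
  es <- expectedPeriodSum(p0, m, pmf, support)
  targetDelay <- targetLastPeak - es
  if (delaySD <= 0) return(targetDelay)
  f <- function(mu) truncnormMean(mu, delaySD, delayMin) - targetDelay
  uniroot(f, c(delayMin - 12 * delaySD, targetDelay + 12 * delaySD),
          tol = 1e-8)$root
}

presetTable <- function() {
  list(
    # untreated posterior-quarter PSM cells in culture:
    # 4.4 +/- 1.6 peaks, 81% of successive cycles slow, 72% rise in intensity
    culture_psm4 = list(
      peaks = c(4.4, 1.6), support = 1:8, slow = 0.81, rise = 0.72,
      p0 = 45, frame = 10, offset = 70, duration = 960,
      delay = c(120, 50, 90), lastPeakTarget = NA,
      onsetDelay = c(12, 40), clearRise = 0.8, osc = TRUE),
    # FGF-arm control well: 4.0 +/- 1.8 peaks, mean last peak 269 min,
    # onset-calibrated (mean Mesp onset 281 min = 269 + 12)
    culture_psm4_control = list(
      peaks = c(4.0, 1.8), support = 1:8, slow = 0.81, rise = 0.73,
      p0 = 45, frame = 10, offset = 70, duration = 960,
      delay = c(NA, NA, 90), lastPeakTarget = 269, lastPeakSD = 116,
      onsetDelay = c(12, 30), clearRise = 0.8, osc = TRUE),
    # FGF8-treated well: extended program, 6.4 +/- 3.5 peaks,
    # mean last peak 568 min; ratio probabilities per the treated arm
    culture_psm4_fgf = list(
      peaks = c(6.4, 3.5), support = 1:16, slow = 0.65, rise = 0.66,
      p0 = 45, frame = 10, offset = 70, duration = 960,
      delay = c(NA, NA, 90), lastPeakTarget = 568, lastPeakSD = 185,
      onsetDelay = c(12, 40), clearRise = 0.8, osc = TRUE),
    # more-anterior quarters and tailbud: fewer peaks / earlier arrest
    # (absolute values unpublished; chosen to exercise left-censoring)
    culture_psm2 = list(
      peaks = c(2.0, 1.0), support = 1:8, slow = 0.81, rise = 0.72,
      p0 = 45, frame = 10, offset = 70, duration = 960,
      delay = c(40, 30, 5), lastPeakTarget = NA,
      onsetDelay = c(12, 40), clearRise = 0.8, osc = TRUE),
    culture_psm3 = list(
      peaks = c(3.0, 1.2), support = 1:8, slow = 0.81, rise = 0.72,
      p0 = 45, frame = 10, offset = 70, duration = 960,
      delay = c(80, 40, 20), lastPeakTarget = NA,
      onsetDelay = c(12, 40), clearRise = 0.8, osc = TRUE),
    # tailbud cells arrest with timing similar to PSM4 from the same embryos
    culture_tb = list(
      peaks = c(4.4, 1.6), support = 1:8, slow = 0.81, rise = 0.72,
      p0 = 45, frame = 10, offset = 70, duration = 960,
      delay = c(120, 50, 90), lastPeakTarget = NA,
      onsetDelay = c(12, 40), clearRise = 0.8, osc = TRUE),
    # PSM4 cells tracked in the embryo: 3.4 +/- 1.0 peaks, 79% slow,
    # 92% rise; 1.5-min stacks, movie-time axis
    embryo_psm4 = list(
      peaks = c(3.4, 1.0), support = 1:8, slow = 0.79, rise = 0.92,
      p0 = 30, frame = 1.5, offset = 0, duration = 450,
      delay = c(60, 30, 15), lastPeakTarget = NA,
      onsetDelay = c(25, 15), clearRise = 0.8, osc = TRUE,
      trackEnd = 40),
    # her1-/-;her7-/- clock mutant: no oscillations; Mesp onset drawn
    # directly, 305 +/- 70 min post-dissociation
    her1her7_mutant = list(
      peaks = c(0, 0), support = 1:1, slow = 0.5, rise = 0.5,
      p0 = 45, frame = 10, offset = 70, duration = 960,
      delay = c(0, 0, 0), lastPeakTarget = NA,
      onsetDelay = c(0, 0), clearRise = 0.8, osc = FALSE,
      onsetDirect = c(305, 70))
  )
}

#' Names of the built-in condition presets
#' @return character vector of preset names.
#' @export
clockPresetNames <- function() names(presetTable())

#' Build a calibrated condition preset
#'
#' Returns the \linkS4class{GeneratorPreset} for one of the built-in
#' conditions. Calibrated quantities (latent peak-count mean; first-peak
#' delay where a mean last-peak time is targeted) are solved at call time
#' from the condition's published summary statistics.
#'
#' @param name one of \code{clockPresetNames()}.
#' @param noiseSD additive intensity noise SD (a.u.); 0 gives noiseless traces.
#' @return a \linkS4class{GeneratorPreset}.
#' @examples
#' clockPreset("culture_psm4")
#' @export
clockPreset <- function(name = clockPresetNames(), noiseSD = 2) {
  name <- match.arg(name)
  def <- presetTable()[[name]]
  support <- as.integer(def$support)
  slowSDlog <- 0.10
  riseSDlog <- 0.15
  p0SDlog <- 0.10
  if (def$osc) {
    muK <- calibratePeakMean(def$peaks[1], def$peaks[2], support)
    pmf <- discNormPmf(muK, def$peaks[2], support)
    m <- ratioMean(def$slow, slowSDlog)
    delay <- def$delay
    if (!is.na(def$lastPeakTarget)) {
      if (!is.null(def$lastPeakSD)) {
        # match the printed last-peak mean AND SD: the delay absorbs the
        # variance not explained by the period sum
        es <- expectedPeriodSum(def$p0, m, pmf, support)
        vs <- varPeriodSum(def$p0, p0SDlog, def$slow, slowSDlog,
                           pmf, support)
        targetSD <- sqrt(max(def$lastPeakSD^2 - vs, 25))
        sol <- solveTruncNorm(def$lastPeakTarget - es, targetSD, delay[3])
        delay[1] <- sol[["mu"]]
        delay[2] <- sol[["sigma"]]
      } else {
        delay[1] <- calibrateDelayMean(def$lastPeakTarget, delay[2],
                                       delay[3], def$p0, m, pmf, support)
      }
    }
  } else {
    muK <- 0
    delay <- def$delay
  }
  onsetDirect <- if (!is.null(def$onsetDirect)) def$onsetDirect else c(NA_real_, NA_real_)
  new("GeneratorPreset",
      conditionName = name,
      nPeaksMean = muK, nPeaksSD = def$peaks[2], nPeaksSupport = support,
      p0 = def$p0, p0SDlog = p0SDlog,
      slowProb = def$slow, slowSDlog = slowSDlog,
      riseProb = def$rise, riseSDlog = riseSDlog,
      delayMean = delay[1], delaySD = delay[2], delayMin = delay[3],
      onsetDelayMean = def$onsetDelay[1], onsetDelaySD = def$onsetDelay[2],
      onsetDirectMean = onsetDirect[1], onsetDirectSD = onsetDirect[2],
      clearRiseProb = def$clearRise,
      frameInterval = def$frame, imagingStartOffset = def$offset,
      noiseSD = noiseSD,
      oscillationEnabled = def$osc,
      duration = def$duration,
      baseline = 20, amp0 = 100, amp0SDlog = 0.2,
      pulseWidthFrac = 0.25,
      mespBaseline = 10, mespAmplitude = 80, mespTau = 20,
      trackEnd = if (!is.null(def$trackEnd)) def$trackEnd else Inf)
}

#' Expected peak count of a preset
#'
#' Exact mean of the preset's truncated discretised peak-count distribution.
#'
#' @param preset a \linkS4class{GeneratorPreset}.
#' @return expected number of peaks per cell.
#' @export
expectedPeakCount <- function(preset) {
  stopifnot(is(preset, "GeneratorPreset"))
  if (!preset@oscillationEnabled) return(0)
  discNormMean(preset@nPeaksMean, preset@nPeaksSD, preset@nPeaksSupport)
}

#' Expected last-peak time of a preset
#'
#' E[first-peak delay] + p0 * E[sum of expected period ratios], minutes.
#'
#' @param preset a \linkS4class{GeneratorPreset}.
#' @return expected last-peak time, minutes.
#' @export
expectedLastPeakTime <- function(preset) {
  stopifnot(is(preset, "GeneratorPreset"))
  if (!preset@oscillationEnabled) return(NA_real_)
  pmf <- discNormPmf(preset@nPeaksMean, preset@nPeaksSD, preset@nPeaksSupport)
  m <- ratioMean(preset@slowProb, preset@slowSDlog)
  truncnormMean(preset@delayMean, preset@delaySD, preset@delayMin) +
    expectedPeriodSum(preset@p0, m, pmf, preset@nPeaksSupport)
}

#' Read a preset, possibly overridden, from a YAML config
#'
#' The config names a base preset and optionally overrides scalar fields
#' (e.g. \code{noiseSD}, \code{duration}, \code{clearRiseProb}).
#'
#' @param path YAML file with fields \code{preset} and optional overrides.
#' @return a \linkS4class{GeneratorPreset}.
#' @export
readPresetConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$preset))
    stop("config must name a base 'preset'")
  preset <- clockPreset(cfg$preset,
                        noiseSD = if (!is.null(cfg$noiseSD)) cfg$noiseSD else 2)
  for (field in intersect(names(cfg), slotNames("GeneratorPreset"))) {
    value <- cfg[[field]]
    slot(preset, field) <- if (is.numeric(slot(preset, field)))
      as.numeric(value) else value
  }
  validObject(preset)
  preset
}
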