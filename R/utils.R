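#' Derive a per-unit seed from a master seed
#'
#' Counter-based seed splitting: each (master, index) pair maps to a distinct
#' 31-bit seed through exact double-precision integer arithmetic, so cohorts
#' are reproducible independently of how many units are drawn.
#'
#' @param master master seed (any non-negative integer).
#' @param index 1-based counter.
#' @return an integer seed in 1..2147483645.
#' @export
splitSeed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index), all(index >= 0))
  x <- (master %% 2147483647) * 48271 + index * 69621
  as.integer(x %% 2147483645) + 1L
}

#' Robust noise estimate of a sampled trace
#'
#' Scaled MAD of first differences (\code{mad(diff(x)) / sqrt(2)}): the
#' median absolute successive difference is driven by frame-to-frame noise
#' rather than by smooth signal structure, so slow oscillations inflate it
#' only mildly while a flat majority of frames pins it to the noise floor.
#'
#' @param values numeric trace values.
#' @return robust noise SD (a.u.).
#' @export
robustNoiseSD <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 5L) return(0)
  stats::mad(diff(values)) / sqrt(2)
}

# baseline-noise estimate for detection thresholds: pooled first/last
# quiet-segment estimate, floored by the whole-trace estimate (quiet
# segments can be contaminated by oscillation in either tail, but rarely
# in both plus the full trace simultaneously)
noiseEstimate <- function(values, quietFrames = 12L) {
  v <- values[!is.na(values)]
  if (length(v) < 5L) return(0)
  d <- c(diff(head(v, quietFrames)), diff(tail(v, quietFrames)))
  pooled <- stats::mad(d) / sqrt(2)
  min(pooled, robustNoiseSD(v))
}

#' Moving median smoother
#'
#' @param values numeric vector.
#' @param window odd window length in frames.
#' @return smoothed vector of the same length (edges use shorter windows).
#' @export
movingMedian <- function(values, window = 3L) {
  stopifnot(window >= 1L)
  n <- length(values)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- median(values[lo:hi], na.rm = TRUE)
  }
  out
}

# rolling peak-to-trough envelope (centered window, edges use partial windows)
rollingEnvelope <- function(values, window) {
  n <- length(values)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    v <- values[lo:hi]
    out[i] <- max(v, na.rm = TRUE) - min(v, na.rm = TRUE)
  }
  out
}

# inverse-CDF draw from a normal truncated below at `lo` (exact, no rejection)
rtruncnormLower <- function(n, mean, sd, lo) {
  if (sd <= 0) return(rep(max(mean, lo), n))
  a <- pnorm(lo, mean, sd)
  u <- runif(n, a, 1)
  qnorm(u, mean, sd)
}

# mean of a lower-truncated normal (log-space Mills ratio for stability)
truncnormMean <- function(mean, sd, lo) {
  if (sd <= 0) return(max(mean, lo))
  a <- (lo - mean) / sd
  r <- exp(dnorm(a, log = TRUE) -
             pnorm(a, lower.tail = FALSE, log.p = TRUE))
  mean + sd * r
}

#' Label 8-connected foreground components of a binary image
#'
#' @param x binary matrix (non-zero is foreground).
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(x) {
  stopifnot(is.matrix(x))
  h <- nrow(x); w <- ncol(x)
  fg <- x != 0
  labels <- matrix(0L, h, w)
  cur <- 0L
  offs <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  idx <- which(fg)
  for (start in idx) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    labels[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((p - 1L) %% h) + 1L
      cc <- ((p - 1L) %/% h) + 1L
      for (k in 1:8) {
        rr <- r + offs[k, 1L]; c2 <- cc + offs[k, 2L]
        if (rr >= 1L && rr <= h && c2 >= 1L && c2 <= w) {
          q <- (c2 - 1L) * h + rr
          if (fg[q] && labels[q] == 0L) {
            labels[q] <- cur
            queue <- c(queue, q)
          }
        }
      }
    }
  }
  labels
}

# Jaccard index of two binary masks
jaccardIndex <- function(a, b) {
  a <- a != 0; b <- b != 0
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}

# coerce an EBImage Image (or matrix) to a plain base matrix
asMat <- function(x) {
  if (is(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x)) x <- matrix(x, dim(x)[1L], dim(x)[2L])
  x
}

# disk structuring element: {(dx, dy): dx^2 + dy^2 <= r^2}
diskKernel <- function(radius) {
  stopifnot(radius >= 1)
  d <- -radius:radius
  outer(d, d, function(i, j) as.numeric(i^2 + j^2 <= radius^2))
}
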