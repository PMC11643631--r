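# shared fixtures built in code

# trace made of Gaussian pulses at given times, no noise
pulseTrace <- function(times, peakTimes, amps, sigma, baseline = 0) {
  v <- rep(baseline, length(times))
  for (k in seq_along(peakTimes))
    v <- v + amps[k] * exp(-(times - peakTimes[k])^2 / (2 * sigma^2))
  v
}

# independent brute-force local maxima scan (interior strict maxima)
bruteLocalMaxima <- function(v) {
  idx <- integer(0)
  for (i in 2:(length(v) - 1L))
    if (v[i] > v[i - 1L] && v[i] > v[i + 1L]) idx <- c(idx, i)
  idx
}

# independent 8-connected labeling by repeated scanning (slow, simple)
bruteLabel8 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (x[r0, c0] == 0 || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    frontier <- matrix(c(r0, c0), 1L)
    lab[r0, c0] <- cur
    while (nrow(frontier)) {
      nxt <- NULL
      for (i in seq_len(nrow(frontier))) {
        r <- frontier[i, 1L]; cc <- frontier[i, 2L]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; c2 <- cc + dc
          if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w &&
              x[rr, c2] != 0 && lab[rr, c2] == 0L) {
            lab[rr, c2] <- cur
            nxt <- rbind(nxt, c(rr, c2))
          }
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(0), 0L, 2L) else nxt
    }
  }
  lab
}

# a small culture cohort shared by several test files (generated once)
sharedCultureCohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateCohort(clockPreset("culture_psm4"), n = 40, seed = 421)
    cache
  }
})
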