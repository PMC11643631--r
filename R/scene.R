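# Synthetic brightfield + fluorescence scenes with ground-truth masks.

#' Generate a synthetic brightfield scene for one cell
#'
#' Renders a textured blob (dark rim, brighter interior texture, background
#' speckle) that drifts by less than 10\% of the image width around the
#' centre, one frame per sample of the cell's rendered traces, together
#' with ground-truth masks and matching Her1/Mesp fluorescence stacks whose
#' masked mean equals the rendered trace value (up to pixel noise).
#'
#' @param program a \linkS4class{CellProgram}.
#' @param preset the matching \linkS4class{GeneratorPreset}.
#' @param seed integer seed; scenes are deterministic given the seed.
#' @param size image side in pixels (>= 64).
#' @param radius blob radius in pixels.
#' @param texture SD of the interior/background texture (0 for a clean disc).
#' @param nFrames number of frames to render (default: full trace length).
#' @return a \linkS4class{SyntheticScene}.
#' @export
generateBrightfieldScene <- function(program, preset, seed, size = 96L,
                                     radius = 14, texture = 0.03,
                                     nFrames = NULL) {
  stopifnot(is(program, "CellProgram"), is(preset, "GeneratorPreset"))
  if (size < 64L) stop("image size must be at least 64 x 64")
  if (2 * radius > 0.6 * size) stop("blob radius too large for the frame")
  times <- seq(preset@imagingStartOffset, preset@duration,
               by = preset@frameInterval)
  if (!is.null(nFrames)) times <- times[seq_len(min(nFrames, length(times)))]
  T <- length(times)
  set.seed(seed)
  her1v <- her1Signal(program, preset, times)
  mespv <- mespSignal(program, preset, times)
  # centre drift: bounded random walk, < 10% of width from centre
  maxDrift <- 0.09 * size
  step <- matrix(rnorm(2 * T, 0, 0.4), T, 2)
  drift <- apply(step, 2, cumsum)
  if (is.null(dim(drift))) drift <- matrix(drift, 1L)
  drift <- pmin(pmax(drift, -maxDrift), maxDrift)
  frames <- array(0, c(size, size, T))
  masks <- array(0, c(size, size, T))
  her1s <- array(0, c(size, size, T))
  mesps <- array(0, c(size, size, T))
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  for (t in seq_len(T)) {
    cx <- size / 2 + drift[t, 1]
    cy <- size / 2 + drift[t, 2]
    d <- sqrt((xs - cx)^2 + (ys - cy)^2)
    mask <- d <= radius
    bf <- matrix(0.5, size, size)
    if (texture > 0)
      bf <- bf + matrix(rnorm(size^2, 0, texture / 2), size, size)
    bf[mask] <- 0.58
    if (texture > 0)
      bf[mask] <- bf[mask] + rnorm(sum(mask), 0, texture)
    rim <- d > radius - 1 & d <= radius + 0.5
    bf[rim] <- 0.18
    frames[, , t] <- pmin(pmax(bf, 0), 1)
    masks[, , t] <- mask
    h <- matrix(5, size, size)
    h[mask] <- her1v[t]
    m <- matrix(2, size, size)
    m[mask] <- mespv[t]
    if (preset@noiseSD > 0) {
      h <- h + matrix(rnorm(size^2, 0, preset@noiseSD), size, size)
      m <- m + matrix(rnorm(size^2, 0, preset@noiseSD), size, size)
    }
    her1s[, , t] <- h
    mesps[, , t] <- m
  }
  new("SyntheticScene", frames = frames, masks = masks,
      her1Stack = her1s, mespStack = mesps,
      program = program, times = times)
}

#' Write a scene as multi-page TIFFs
#'
#' Brightfield and mask stacks are written as-is (already in [0, 1]);
#' fluorescence stacks are scaled by \code{fluorScale} into [0, 1].
#'
#' @param scene a \linkS4class{SyntheticScene}.
#' @param dir output directory (created if needed).
#' @param fluorScale divisor applied to fluorescence values before writing.
#' @return invisibly, the four file paths.
#' @export
writeSceneTIFF <- function(scene, dir, fluorScale = 1000) {
  stopifnot(is(scene, "SyntheticScene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  asPages <- function(a) lapply(seq_len(dim(a)[3]), function(t) a[, , t])
  clamp <- function(a) pmin(pmax(a, 0), 1)
  paths <- file.path(dir, c("brightfield.tif", "mask.tif",
                            "her1.tif", "mesp.tif"))
  tiff::writeTIFF(asPages(clamp(scene@frames)), paths[1], bits.per.sample = 16L)
  tiff::writeTIFF(asPages(scene@masks), paths[2], bits.per.sample = 8L)
  tiff::writeTIFF(asPages(clamp(scene@her1Stack / fluorScale)), paths[3],
                  bits.per.sample = 16L)
  tiff::writeTIFF(asPages(clamp(scene@mespStack / fluorScale)), paths[4],
                  bits.per.sample = 16L)
  invisible(paths)
}

#' Read a multi-page TIFF as an H x W x T array
#'
#' @param path TIFF file.
#' @param scale multiplier applied to the stored [0, 1] values.
#' @return numeric array H x W x T.
#' @export
readStackTIFF <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (t in seq_along(pages)) {
    p <- pages[[t]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    arr[, , t] <- p
  }
  arr * scale
}
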