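# Embryo-like cell flows: cells exit the tailbud, advect anteriorly along
# a reference curve while their intrinsic timer runs, and are assigned to
# somites by arc-length bins at arrest.

#' Configuration of a synthetic embryo flow
#'
#' @param nCells number of cells.
#' @param advectionSpeed anterior-ward advection speed, um/min.
#' @param tbExitMean,tbExitSD distribution of tailbud-exit times, minutes.
#' @param somiteLength somite length in um (arc-length bin width at arrest).
#' @param frameInterval minutes between frames (default 1.5, 90-s stacks).
#' @param duration movie length, minutes.
#' @param lateralOffsetSD SD of the cells' signed lateral offset, um.
#' @return a list with class \code{"EmbryoFlowConfig"}.
#' @export
embryoFlowConfig <- function(nCells = 50L, advectionSpeed = 1,
                             tbExitMean = 60, tbExitSD = 30,
                             somiteLength = 50, frameInterval = 1.5,
                             duration = 450, lateralOffsetSD = 5) {
  stopifnot(nCells > 0, somiteLength > 0, frameInterval > 0, duration > 0)
  structure(list(nCells = as.integer(nCells), advectionSpeed = advectionSpeed,
                 tbExitMean = tbExitMean, tbExitSD = tbExitSD,
                 somiteLength = somiteLength, frameInterval = frameInterval,
                 duration = duration, lateralOffsetSD = lateralOffsetSD),
            class = "EmbryoFlowConfig")
}

#' Build a reference curve
#'
#' A gently curved posterior-to-anterior polyline, identical in every frame
#' (the projection machinery accepts arbitrary per-frame curves; the
#' generator uses a static one).
#'
#' @param length total arc extent in um.
#' @param nVertices vertices per frame.
#' @param nFrames number of frames.
#' @param amplitude lateral bow of the curve, um.
#' @return a \linkS4class{ReferenceCurve}.
#' @export
referenceCurve <- function(length = 600, nVertices = 61L, nFrames = 1L,
                           amplitude = 30) {
  s <- seq(0, length, length.out = nVertices)
  v <- cbind(x = s, y = amplitude * sin(pi * s / length))
  new("ReferenceCurve",
      vertices = rep(list(v), nFrames),
      frames = seq_len(nFrames))
}

#' Generate an embryo-like track table
#'
#' Each cell exits the tailbud at its drawn time, then advects anteriorly
#' along the reference curve at \code{advectionSpeed}; its intrinsic-timer
#' program (drawn from \code{preset}) starts at exit. Cells are assigned to
#' somites by arc-length bins of width \code{somiteLength} at their arrest
#' position. With \code{noiseScale = 0} every stochastic spread collapses
#' to its mean, giving a deterministic flow.
#'
#' @param cfg an \code{\link{embryoFlowConfig}}.
#' @param preset a \linkS4class{GeneratorPreset} (typically
#'   \code{clockPreset("embryo_psm4")}).
#' @param seed master seed.
#' @param curve a \linkS4class{ReferenceCurve}; defaults to
#'   \code{referenceCurve()}.
#' @param noiseScale multiplier on all distribution spreads (0 = deterministic).
#' @return list with \code{tracks} (data.frame: cell_id, frame, t_min, x, y,
#'   z, her1, mesp, arc_um, somite), \code{cells} (per-cell data.frame with
#'   exit time, arrest time, onset time, somite, arrest arc-length) and the
#'   \code{curve}.
#' @export
generateEmbryoFlow <- function(cfg, preset, seed, curve = referenceCurve(),
                               noiseScale = 1) {
  stopifnot(inherits(cfg, "EmbryoFlowConfig"), is(preset, "GeneratorPreset"))
  if (noiseScale != 1) {
    preset@nPeaksSD <- preset@nPeaksSD * noiseScale
    preset@p0SDlog <- preset@p0SDlog * noiseScale
    preset@slowSDlog <- max(preset@slowSDlog * noiseScale, 1e-9)
    preset@riseSDlog <- max(preset@riseSDlog * noiseScale, 1e-9)
    preset@delaySD <- preset@delaySD * noiseScale
    preset@onsetDelaySD <- preset@onsetDelaySD * noiseScale
    preset@noiseSD <- preset@noiseSD * noiseScale
  }
  times <- seq(0, cfg$duration, by = cfg$frameInterval)
  set.seed(splitSeed(seed, 0))
  exits <- if (cfg$tbExitSD * noiseScale > 0)
    rtruncnormLower(cfg$nCells, cfg$tbExitMean, cfg$tbExitSD * noiseScale, 0)
  else seq(0, cfg$tbExitMean * 2, length.out = cfg$nCells)
  lateral <- rnorm(cfg$nCells, 0, cfg$lateralOffsetSD * noiseScale)
  rows <- vector("list", cfg$nCells)
  cells <- vector("list", cfg$nCells)
  v1 <- curve@vertices[[1L]]
  for (i in seq_len(cfg$nCells)) {
    id <- sprintf("flow_c%04d", i)
    prog <- drawCellProgram(preset, splitSeed(seed, 2L * i - 1L), cellId = id)
    tr <- renderTraces(prog, preset, splitSeed(seed, 2L * i))
    # timer-relative trace resampled onto movie time after exit
    arc <- pmax(times - exits[i], 0) * cfg$advectionSpeed
    rel <- times - exits[i]
    her1 <- approxTrace(tr$times, tr$her1, rel, preset@baseline)
    mesp <- approxTrace(tr$times, tr$mesp, rel, preset@mespBaseline)
    arrestAbs <- if (is.na(prog@arrestTime)) NA_real_ else
      exits[i] + prog@arrestTime
    onsetAbs <- if (is.na(prog@onsetTime)) NA_real_ else
      exits[i] + prog@onsetTime
    arrestArc <- if (is.na(arrestAbs)) NA_real_ else
      max(arrestAbs - exits[i], 0) * cfg$advectionSpeed
    # somite membership is set by the cell's anterior-ward station in the
    # somite-fixed frame: earlier tailbud exit -> more anterior station
    somitePos <- cfg$advectionSpeed * (cfg$duration - exits[i])
    somite <- as.integer(floor(somitePos / cfg$somiteLength))
    pos <- curvePointAt(v1, arc)
    # displace laterally along the local normal
    rows[[i]] <- data.frame(
      cell_id = id, frame = seq_along(times), t_min = times,
      x = pos[, 1] + lateral[i] * pos[, 3],
      y = pos[, 2] + lateral[i] * pos[, 4],
      z = 0,
      her1 = her1, mesp = mesp,
      arc_um = arc, somite = somite
    )
    cells[[i]] <- data.frame(
      cell_id = id, tb_exit_min = exits[i],
      n_peaks_true = length(prog@peakTimes),
      arrest_min = arrestAbs, onset_min = onsetAbs,
      arrest_arc_um = arrestArc, somite_pos_um = somitePos, somite = somite
    )
  }
  list(tracks = do.call(rbind, rows),
       cells = do.call(rbind, cells),
       curve = curve)
}

# linear interpolation of a rendered trace onto relative times; baseline
# before the trace starts, last value held afterwards
approxTrace <- function(srcTimes, srcValues, relTimes, baseline) {
  out <- rep(baseline, length(relTimes))
  inside <- relTimes >= srcTimes[1]
  if (any(inside))
    out[inside] <- stats::approx(srcTimes, srcValues,
                                 xout = pmin(relTimes[inside],
                                             srcTimes[length(srcTimes)]),
                                 rule = 2)$y
  out
}

# position (x, y) and unit normal (nx, ny) at arc-length s along a polyline
curvePointAt <- function(vertices, s) {
  seg <- sqrt(rowSums(diff(vertices)^2))
  cum <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cum[length(cum)])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(seg))
  f <- (s - cum[i]) / seg[i]
  p0 <- vertices[i, , drop = FALSE]
  p1 <- vertices[i + 1L, , drop = FALSE]
  x <- p0[, 1] + f * (p1[, 1] - p0[, 1])
  y <- p0[, 2] + f * (p1[, 2] - p0[, 2])
  tx <- (p1[, 1] - p0[, 1]) / seg[i]
  ty <- (p1[, 2] - p0[, 2]) / seg[i]
  cbind(x, y, -ty, tx)
}

#' Write / read a track table CSV
#'
#' @param tracks track table data.frame.
#' @param path CSV path.
#' @return invisibly the path (write), or the data.frame (read).
#' @export
writeTrackTable <- function(tracks, path) {
  write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrackTable
#' @export
readTrackTable <- function(path) {
  tr <- read.csv(path)
  need <- c("cell_id", "frame", "t_min", "x", "y")
  if (!all(need %in% names(tr)))
    stop("track table must contain columns: ", paste(need, collapse = ", "))
  tr
}

#' Write / read a reference-curve CSV (frame, vertex_index, x, y)
#'
#' @param curve a \linkS4class{ReferenceCurve}.
#' @param path CSV path.
#' @return invisibly the path (write), or a \linkS4class{ReferenceCurve} (read).
#' @export
writeCurveCSV <- function(curve, path) {
  rows <- do.call(rbind, lapply(seq_along(curve@frames), function(i) {
    v <- curve@vertices[[i]]
    data.frame(frame = curve@frames[i], vertex_index = seq_len(nrow(v)),
               x = v[, 1], y = v[, 2])
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCurveCSV
#' @export
readCurveCSV <- function(path) {
  df <- read.csv(path)
  frames <- sort(unique(df$frame))
  verts <- lapply(frames, function(f) {
    sub <- df[df$frame == f, ]
    sub <- sub[order(sub$vertex_index), ]
    cbind(x = sub$x, y = sub$y)
  })
  new("ReferenceCurve", vertices = verts, frames = as.integer(frames))
}
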