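# Kymograph construction: projection of tracked cells onto a reference
# curve, temporal alignment of curve segments, event kymographs, and
# intra-somite phase profiles.

#' Project a point onto a reference-curve frame
#'
#' Nearest point over all polyline segments (perpendicular foot or segment
#' endpoint), arc-length measured from the posterior end; ties are broken
#' toward the smaller arc-length. The lateral offset is the unsigned
#' Euclidean distance from the point to its projection.
#'
#' @param point numeric \code{c(x, y)} in um.
#' @param curveFrame 2-column vertex matrix of one curve frame.
#' @return list with \code{arcLength} and \code{lateralOffset}, um.
#' @export
projectToCurve <- function(point, curveFrame) {
  stopifnot(length(point) == 2L, is.matrix(curveFrame), ncol(curveFrame) == 2L)
  seg <- diff(curveFrame)
  segLen <- sqrt(rowSums(seg^2))
  if (all(segLen == 0)) stop("degenerate zero-length curve")
  cum <- c(0, cumsum(segLen))
  bestDist <- Inf; bestArc <- NA_real_
  for (i in seq_len(nrow(seg))) {
    if (segLen[i] == 0) next
    p0 <- curveFrame[i, ]
    d <- point - p0
    t <- sum(d * seg[i, ]) / segLen[i]^2
    t <- min(max(t, 0), 1)
    foot <- p0 + t * seg[i, ]
    dist <- sqrt(sum((point - foot)^2))
    arc <- cum[i] + t * segLen[i]
    if (dist < bestDist - 1e-12 ||
        (abs(dist - bestDist) <= 1e-12 && arc < bestArc)) {
      bestDist <- dist; bestArc <- arc
    }
  }
  list(arcLength = bestArc, lateralOffset = bestDist)
}

#' Project all tracked cells of a table onto a reference curve
#'
#' 2D lateral projection: the z column, if present, is ignored after an
#' optional max-extent flattening upstream. Each (cell, frame) row gains
#' its arc-length position and unsigned lateral offset.
#'
#' @param tracks track table (cell_id, frame, t_min, x, y, ...).
#' @param curve a \linkS4class{ReferenceCurve}; frames without a dedicated
#'   curve use the last available one.
#' @return the track table with added \code{arc_length} and
#'   \code{lateral_offset} columns.
#' @export
projectTracks <- function(tracks, curve) {
  stopifnot(is(curve, "ReferenceCurve"))
  arc <- lat <- numeric(nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    fi <- match(tracks$frame[i], curve@frames)
    if (is.na(fi)) fi <- length(curve@vertices)
    pr <- projectToCurve(c(tracks$x[i], tracks$y[i]), curve@vertices[[fi]])
    arc[i] <- pr$arcLength
    lat[i] <- pr$lateralOffset
  }
  tracks$arc_length <- arc
  tracks$lateral_offset <- lat
  tracks
}

#' Align projected curve segments over time
#'
#' Maps each frame's projected arc-length positions to a common origin by
#' subtracting a per-frame anchor (default 0: the posterior tail tip; a
#' configured landmark such as the anterior-most formed somite boundary
#' can be supplied per frame).
#'
#' @param projected projected track table (from \code{\link{projectTracks}}).
#' @param anchor either a single number, a numeric vector indexed by frame,
#'   or a function \code{frame -> anchor arc-length}.
#' @return the table with an added \code{aligned_arc} column; frames with
#'   no cells simply contribute no rows.
#' @export
alignSegments <- function(projected, anchor = 0) {
  a <- if (is.function(anchor)) {
    vapply(projected$frame, anchor, numeric(1))
  } else if (length(anchor) > 1L) {
    anchor[projected$frame]
  } else rep(anchor, nrow(projected))
  projected$aligned_arc <- projected$arc_length - a
  projected
}

#' Build an event kymograph
#'
#' Rows are time points (frames), columns are aligned arc-length bins of
#' width \code{binWidth}; each cell with an event (last peak or Mesp
#' onset) is placed in the row nearest its event time at the bin of its
#' position then, and bins holding several cells store the mean event
#' value. Occupancy counts are kept alongside so cell totals are conserved
#' under re-binning.
#'
#' @param projected aligned projected track table (needs \code{aligned_arc}).
#' @param events per-cell data.frame: \code{cell_id}, \code{event_min}.
#' @param binWidth bin width, um (default 10).
#' @param event label stored on the kymograph (\code{"last_peak"} or
#'   \code{"onset"}).
#' @return a \linkS4class{ClockKymograph}.
#' @export
buildEventKymograph <- function(projected, events, binWidth = 10,
                                event = c("last_peak", "onset")) {
  event <- match.arg(event)
  stopifnot(binWidth > 0, all(c("cell_id", "event_min") %in% names(events)))
  if (!"aligned_arc" %in% names(projected))
    projected$aligned_arc <- projected$arc_length
  frames <- sort(unique(projected$frame))
  times <- vapply(frames, function(f)
    projected$t_min[match(f, projected$frame)], numeric(1))
  ev <- events[!is.na(events$event_min), , drop = FALSE]
  arcRange <- range(projected$aligned_arc, na.rm = TRUE)
  binStarts <- seq(floor(arcRange[1] / binWidth) * binWidth,
                   arcRange[2], by = binWidth)
  nb <- length(binStarts)
  vals <- matrix(NA_real_, length(frames), nb)
  sums <- matrix(0, length(frames), nb)
  counts <- matrix(0L, length(frames), nb)
  for (i in seq_len(nrow(ev))) {
    sub <- projected[projected$cell_id == ev$cell_id[i], , drop = FALSE]
    if (!nrow(sub)) next
    j <- which.min(abs(sub$t_min - ev$event_min[i]))
    row <- match(sub$frame[j], frames)
    bin <- findInterval(sub$aligned_arc[j], binStarts)
    bin <- min(max(bin, 1L), nb)
    sums[row, bin] <- sums[row, bin] + ev$event_min[i]
    counts[row, bin] <- counts[row, bin] + 1L
  }
  filled <- counts > 0
  vals[filled] <- sums[filled] / counts[filled]
  new("ClockKymograph", values = vals, counts = counts,
      binWidth = binWidth, event = event, binStarts = binStarts,
      rowTimes = times)
}

#' Intra-somite phase profile of backtracked cells
#'
#' For cells labelled with a somite and an arrest-time/position, computes
#' each cell's normalised rostro-caudal coordinate within its somite
#' (0 = rostral/anterior edge, 1 = caudal/posterior edge) and pairs it with
#' the event time; the cohort summary is the Spearman rank correlation of
#' position versus event time, computed within each somite and aggregated
#' across somites weighted by cell count, so that cells pooled from
#' several somites measure the intra-somite gradient only (a positive
#' value means caudal cells arrest later, i.e. the arriving wave's phase
#' profile; somites whose cells all arrest simultaneously contribute a
#' zero trend).
#'
#' @param cells per-cell data.frame with \code{cell_id}, \code{somite},
#'   \code{somite_pos_um} (anterior-ward station in the somite-fixed frame)
#'   and \code{event_min} (last peak or onset time).
#' @param somiteLength somite length, um.
#' @return list with \code{profile} (cell_id, somite, rc_position,
#'   event_min), \code{rankCorrelation}, \code{nExcluded} (unlabelled cells).
#' @export
somitePhaseProfile <- function(cells, somiteLength) {
  stopifnot(somiteLength > 0)
  ok <- !is.na(cells$somite) & !is.na(cells$somite_pos_um) &
    !is.na(cells$event_min)
  sub <- cells[ok, , drop = FALSE]
  rc <- ((sub$somite + 1) * somiteLength - sub$somite_pos_um) / somiteLength
  profile <- data.frame(cell_id = sub$cell_id, somite = sub$somite,
                        rc_position = rc, event_min = sub$event_min)
  perSomite <- vapply(split(seq_len(nrow(sub)), sub$somite), function(ix) {
    if (length(ix) < 2L) return(c(NA_real_, 0))
    x <- rc[ix]; y <- sub$event_min[ix]
    r <- if (stats::sd(x) == 0) NA_real_
      else if (stats::sd(y) == 0) 0
      else cor(x, y, method = "spearman")
    c(r, length(ix) - 1)
  }, numeric(2))
  w <- perSomite[2, ] * !is.na(perSomite[1, ])
  rho <- if (sum(w) > 0)
    sum(perSomite[1, ] * w, na.rm = TRUE) / sum(w) else NA_real_
  list(profile = profile, rankCorrelation = rho, nExcluded = sum(!ok))
}

#' Write a kymograph as CSV and a rendered PNG
#'
#' @param kymo a \linkS4class{ClockKymograph}.
#' @param csvPath matrix CSV output path.
#' @param pngPath optional PNG heat-map output path.
#' @return invisibly the CSV path.
#' @importFrom grDevices png dev.off hcl.colors
#' @importFrom graphics image
#' @export
writeKymograph <- function(kymo, csvPath, pngPath = NULL) {
  stopifnot(is(kymo, "ClockKymograph"))
  df <- as.data.frame(kymo@values)
  names(df) <- sprintf("bin_%g", kymo@binStarts)
  df <- cbind(t_min = kymo@rowTimes, df)
  write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(pngPath)) {
    grDevices::png(pngPath, width = 640, height = 480)
    graphics::image(x = kymo@rowTimes, y = kymo@binStarts, z = kymo@values,
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "time (min)", ylab = "arc length (um)",
                    main = sprintf("%s kymograph", kymo@event))
    grDevices::dev.off()
  }
  invisible(csvPath)
}
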