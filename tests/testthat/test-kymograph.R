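# Projection onto a reference curve, alignment, kymographs, phase profiles.

test_that("projection satisfies its point contracts", {
  curve <- cbind(x = c(0, 10, 20, 30), y = c(0, 0, 0, 0))
  # a point on the curve projects to itself
  pr <- projectToCurve(c(12, 0), curve)
  expect_equal(pr$lateralOffset, 0)
  expect_equal(pr$arcLength, 12)
  # lateral offset is the Euclidean distance
  pr2 <- projectToCurve(c(12, 5), curve)
  expect_equal(pr2$lateralOffset, 5)
  expect_equal(pr2$arcLength, 12)
  # equidistant from the two parallel arms of a U: smaller arc-length wins
  ushape <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 8, 8))
  tie <- projectToCurve(c(4, 4), ushape)     # 4 um from both arms
  expect_equal(tie$lateralOffset, 4)
  expect_equal(tie$arcLength, 4)             # foot on the first arm
  # degenerate curve errors
  expect_error(projectToCurve(c(1, 1), cbind(c(2, 2), c(3, 3))), "degenerate")
})

test_that("projection equals dense resampling of the curve (oracle)", {
  curve <- referenceCurve(length = 80, nVertices = 9, amplitude = 12)
  v <- curve@vertices[[1]]
  seg <- sqrt(rowSums(diff(v)^2))
  cum <- c(0, cumsum(seg))
  # dense resampling at 0.01 um
  dense <- do.call(rbind, lapply(seq_len(nrow(v) - 1L), function(i) {
    f <- seq(0, 1, by = 0.01 / seg[i])
    cbind(v[i, 1] + f * (v[i + 1, 1] - v[i, 1]),
          v[i, 2] + f * (v[i + 1, 2] - v[i, 2]),
          cum[i] + f * seg[i])
  }))
  set.seed(9)
  for (rep in 1:25) {
    pt <- c(runif(1, -5, 85), runif(1, -20, 25))
    pr <- projectToCurve(pt, v)
    d <- sqrt((dense[, 1] - pt[1])^2 + (dense[, 2] - pt[2])^2)
    j <- which.min(d)
    expect_lt(abs(pr$lateralOffset - d[j]), 0.02)
    expect_lt(abs(pr$arcLength - dense[j, 3]), 0.05)
  }
})

test_that("projection is idempotent", {
  curve <- referenceCurve(length = 100, nVertices = 11)
  v <- curve@vertices[[1]]
  set.seed(2)
  for (rep in 1:10) {
    pt <- c(runif(1, 0, 100), runif(1, -30, 30))
    pr <- projectToCurve(pt, v)
    foot <- segclock:::curvePointAt(v, pr$arcLength)
    pr2 <- projectToCurve(c(foot[1, 1], foot[1, 2]), v)
    expect_lt(pr2$lateralOffset, 1e-6)
    expect_equal(pr2$arcLength, pr$arcLength, tolerance = 1e-6)
  }
})

test_that("segment alignment is invariant to matched uniform shifts", {
  tracks <- data.frame(cell_id = rep(c("a", "b"), each = 2),
                       frame = c(1, 2, 1, 2), t_min = c(0, 10, 0, 10),
                       x = c(10, 10, 30, 30), y = 0)
  curve <- referenceCurve(length = 100, nVertices = 21, amplitude = 0)
  pr <- projectTracks(tracks, curve)
  al0 <- alignSegments(pr, anchor = 0)
  # static cells, static curve: identical rows over time
  expect_equal(al0$aligned_arc[al0$frame == 1], al0$aligned_arc[al0$frame == 2])
  # uniform shift of cells with matching anchor shift leaves rows unchanged
  shifted <- pr
  shifted$arc_length <- shifted$arc_length + 7
  alS <- alignSegments(shifted, anchor = 7)
  expect_equal(alS$aligned_arc, al0$aligned_arc)
})

test_that("event kymographs bin, average and conserve cells", {
  tracks <- data.frame(cell_id = c("a", "b", "c"), frame = 1, t_min = 100,
                       x = c(5, 7, 42), y = 0)
  curve <- referenceCurve(length = 100, nVertices = 21, amplitude = 0)
  pr <- alignSegments(projectTracks(tracks, curve))
  ev <- data.frame(cell_id = c("a", "b", "c"), event_min = c(100, 120, 90))
  ky <- buildEventKymograph(pr, ev, binWidth = 10, event = "last_peak")
  # two cells fall in one bin -> mean event value
  expect_equal(ky@values[1, 1], 110)
  expect_equal(ky@counts[1, 1], 2L)
  # conservation: occupancy equals number of cells with events
  expect_equal(sum(ky@counts), 3L)
  # single cell, single event -> single filled bin
  ky1 <- buildEventKymograph(pr[pr$cell_id == "c", , drop = FALSE],
                             ev[3, , drop = FALSE], binWidth = 10)
  expect_equal(sum(ky1@counts), 1L)
  expect_equal(sum(!is.na(ky1@values)), 1L)
  # re-binning changes resolution but not totals
  ky5 <- buildEventKymograph(pr, ev, binWidth = 5)
  expect_equal(sum(ky5@counts), sum(ky@counts))
})

test_that("the arrest front progresses posteriorly along the axis over time", {
  p <- clockPreset("embryo_psm4")
  # a wide exit-time spread so station differences dominate timer noise
  cfg <- embryoFlowConfig(nCells = 40, tbExitMean = 150, tbExitSD = 100)
  fl <- generateEmbryoFlow(cfg, p, seed = 5)
  ok <- !is.na(fl$cells$arrest_min)
  # anterior (early-exit) cells arrest first; successive arrests happen at
  # progressively more posterior stations, as somites form front to back
  r <- cor(fl$cells$arrest_min[ok], fl$cells$somite_pos_um[ok],
           method = "spearman")
  expect_lt(r, -0.5)
})

test_that("somite phase profiles behave per the flow model", {
  p <- clockPreset("embryo_psm4")
  fl0 <- generateEmbryoFlow(embryoFlowConfig(nCells = 20), p, seed = 5,
                            noiseScale = 0)
  c0 <- data.frame(cell_id = fl0$cells$cell_id, somite = fl0$cells$somite,
                   somite_pos_um = fl0$cells$somite_pos_um,
                   event_min = fl0$cells$arrest_min)
  # strictly later exit => strictly later arrest: monotone profile
  expect_equal(somitePhaseProfile(c0, 50)$rankCorrelation, 1)
  # simultaneous arrest: no trend
  cSim <- c0; cSim$event_min <- 250
  expect_equal(somitePhaseProfile(cSim, 50)$rankCorrelation, 0)
  # single cell: one profile row
  p1 <- somitePhaseProfile(c0[1, , drop = FALSE], 50)
  expect_equal(nrow(p1$profile), 1L)
  # unlabelled cells are excluded and counted
  cNA <- c0; cNA$somite[1] <- NA
  expect_equal(somitePhaseProfile(cNA, 50)$nExcluded, 1L)
})

test_that("deterministic flows satisfy the monotone exit/arrest contract", {
  p <- clockPreset("embryo_psm4")
  fl0 <- generateEmbryoFlow(embryoFlowConfig(nCells = 20), p, seed = 5,
                            noiseScale = 0)
  o <- order(fl0$cells$tb_exit_min)
  expect_true(all(diff(fl0$cells$arrest_min[o]) >= 0))
  # zero advection keeps every cell at its initial arc position
  flStatic <- generateEmbryoFlow(embryoFlowConfig(nCells = 5,
                                                  advectionSpeed = 0),
                                 p, seed = 5)
  expect_true(all(flStatic$tracks$arc_um == 0))
  # identical exit time and seed give identical peak counts
  expect_equal(fl0$cells$n_peaks_true,
               rep(fl0$cells$n_peaks_true[1], nrow(fl0$cells)))
})

test_that("curve and track CSV round trips preserve structure", {
  curve <- referenceCurve(length = 100, nVertices = 6, nFrames = 2)
  cp <- tempfile(fileext = ".csv")
  writeCurveCSV(curve, cp)
  back <- readCurveCSV(cp)
  expect_equal(back@vertices[[1]], curve@vertices[[1]], tolerance = 1e-9,
               ignore_attr = TRUE)
  p <- clockPreset("embryo_psm4")
  fl <- generateEmbryoFlow(embryoFlowConfig(nCells = 3), p, seed = 2)
  tp <- tempfile(fileext = ".csv")
  writeTrackTable(fl$tracks, tp)
  tr <- readTrackTable(tp)
  expect_equal(nrow(tr), nrow(fl$tracks))
  expect_error(readTrackTable(cp), "columns")
})

test_that("kymograph CSV/PNG writer produces the declared outputs", {
  tracks <- data.frame(cell_id = c("a", "b"), frame = 1, t_min = 50,
                       x = c(5, 42), y = 0)
  curve <- referenceCurve(length = 100, nVertices = 21, amplitude = 0)
  pr <- alignSegments(projectTracks(tracks, curve))
  ev <- data.frame(cell_id = c("a", "b"), event_min = c(100, 90))
  ky <- buildEventKymograph(pr, ev, binWidth = 10)
  csv <- tempfile(fileext = ".csv"); png <- tempfile(fileext = ".png")
  writeKymograph(ky, csv, png)
  expect_true(file.exists(csv) && file.exists(png))
  expect_equal(nrow(read.csv(csv)), nrow(ky@values))
})
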