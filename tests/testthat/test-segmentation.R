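# Brightfield segmentation chain.

test_that("gradient preprocessing honors its contracts", {
  expect_error(preprocessGradient(array(0, c(4, 4, 2))), "2D")
  # constant image -> all-zero gradient
  g <- preprocessGradient(matrix(5, 24, 24))
  expect_true(all(g == 0))
  # single bright pixel -> non-zero response near it, zero far away
  x <- matrix(0, 32, 32); x[16, 16] <- 1
  params <- segmentationParams(claheTiles = 1L)  # plain guided filter path
  g <- preprocessGradient(x, params)
  expect_true(all(g >= 0))
  expect_gt(max(g[12:20, 12:20]), 0)
  expect_equal(max(g[1:8, 1:8]), 0)
})

test_that("morphological gradient equals the brute-force disk oracle", {
  set.seed(31)
  x <- matrix(runif(32 * 32), 32, 32)
  params <- segmentationParams(claheTiles = 1L)
  g <- preprocessGradient(x, params)
  # oracle: max-over-disk minus min-over-disk of the filtered image
  # (the chain first rescales the frame to [0, 1])
  x01 <- (x - min(x)) / diff(range(x))
  f <- guidedFilter(x01, params$guidedFilterRadius, params$guidedFilterEps)
  r <- params$gradientDiskRadius
  oracle <- matrix(0, 32, 32)
  for (i in 1:32) for (j in 1:32) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 > r^2) next
      ii <- min(max(i + di, 1), 32); jj <- min(max(j + dj, 1), 32)
      vals <- c(vals, f[ii, jj])
    }
    oracle[i, j] <- max(vals) - min(vals)
  }
  expect_equal(g, pmax(oracle, 0), tolerance = 1e-8)
})

test_that("Otsu threshold matches exhaustive search and its edge contracts", {
  x <- matrix(c(10, 10, 200, 200, 10, 200, 10, 200), 4)
  b <- otsuThreshold(x)
  expect_equal(b, matrix(as.numeric(x == 200), 4))
  expect_error(otsuThreshold(matrix(7, 3, 3)), "constant")

  # 8-level toy image: exhaustive between-class variance oracle
  set.seed(12)
  y <- matrix(sample(1:8, 100, replace = TRUE,
                     prob = c(8, 6, 4, 1, 1, 3, 6, 7)), 10)
  b <- otsuThreshold(y)
  vals <- as.vector(y)
  bc <- function(cut) {
    lo <- vals <= cut
    if (!any(lo) || all(lo)) return(-Inf)
    mean(lo) * mean(!lo) * (mean(vals[lo]) - mean(vals[!lo]))^2
  }
  cuts <- 1:7
  best <- cuts[which.max(vapply(cuts, bc, 1))]  # which.max takes lowest tie
  expect_equal(b, matrix(as.numeric(y > best), 10))

  # inverting intensities inverts the fore/background assignment
  binv <- otsuThreshold(-y)
  expect_equal(binv, 1 - b)
})

test_that("central-blob selection keeps the right component", {
  # single central blob is unchanged
  x <- matrix(0, 20, 20); x[9:12, 9:12] <- 1
  m <- selectCentralBlob(x)
  expect_equal(unclass(m)[,], x[,])
  # a larger corner blob (not touching the central one) loses to it
  x2 <- x; x2[1:6, 1:6] <- 1
  m2 <- selectCentralBlob(x2)
  expect_equal(sum(m2), 16)   # 36-px corner blob excluded: not central
  expect_equal(m2[10, 10], 1)
  expect_equal(m2[2, 2], 0)
  # two central blobs: larger one wins, checked against brute-force labels
  x3 <- matrix(0, 30, 30)
  x3[10:14, 9:16] <- 1            # 40 px
  x3[17:25, 9:18] <- 1            # 90 px
  m3 <- selectCentralBlob(x3)
  lab <- bruteLabel8(x3)
  areas <- table(lab[lab > 0])
  bigLabel <- as.integer(names(areas)[which.max(areas)])
  expect_equal(unclass(m3)[,], matrix(as.numeric(lab == bigLabel), 30)[,])
  # nothing near the centre -> no cell found
  x4 <- matrix(0, 20, 20); x4[1:2, 1:2] <- 1
  expect_error(selectCentralBlob(x4), "no cell found")
})

test_that("8-connected labeling matches the brute-force oracle", {
  set.seed(8)
  for (rep in 1:5) {
    x <- matrix(rbinom(18 * 18, 1, 0.35), 18)
    a <- labelComponents(x)
    b <- bruteLabel8(x)
    expect_equal(max(a), max(b))
    # same partition: component memberships agree up to label names
    for (l in seq_len(max(a)))
      expect_equal(length(unique(b[a == l])), 1L)
  }
})

test_that("active contour identity, recovery and shrink-bias contracts", {
  # 0 iterations returns the init mask unchanged
  img <- matrix(0, 40, 40); img[15:25, 15:25] <- 1
  init <- matrix(0, 40, 40); init[14:26, 14:26] <- 1
  p0 <- segmentationParams(acIterations = 0L)
  expect_equal(refineActiveContour(img, init, p0), init)
  # sharp-edged uniform blob, init on the blob: near-exact recovery
  truth <- matrix(0, 40, 40); truth[15:25, 15:25] <- 1
  out <- refineActiveContour(img, init, segmentationParams())
  expect_gte(sum(out * truth) / sum(pmax(out, truth)), 0.95)
  # stronger contraction bias cannot grow the region
  set.seed(2)
  noisy <- img + matrix(rnorm(1600, 0, 0.08), 40)
  a1 <- sum(refineActiveContour(noisy, init,
                                segmentationParams(acContractionBias = 0.1)))
  a3 <- sum(refineActiveContour(noisy, init,
                                segmentationParams(acContractionBias = 0.3)))
  expect_lte(a3, a1)
  # empty init is rejected
  expect_error(refineActiveContour(img, matrix(0, 40, 40),
                                   segmentationParams()), "empty")
})

test_that("sequence segmentation tracks the synthetic cell accurately", {
  p <- clockPreset("culture_psm4", noiseSD = 0)
  prog <- drawCellProgram(p, seed = 11)
  sc <- generateBrightfieldScene(prog, p, seed = 3, nFrames = 4)
  seg <- segmentSequence(sc@frames)
  js <- vapply(1:4, function(t)
    segclock:::jaccardIndex(seg$masks[, , t], sc@masks[, , t]), 1)
  expect_gte(mean(js), 0.8)
  expect_false(any(seg$qc$flagged))
})

test_that("identical repeated frames give identical masks (determinism)", {
  p <- clockPreset("culture_psm4", noiseSD = 0)
  prog <- drawCellProgram(p, seed = 11)
  sc <- generateBrightfieldScene(prog, p, seed = 3, nFrames = 1)
  frames <- array(sc@frames[, , 1], c(dim(sc@frames)[1:2], 3L))
  seg <- segmentSequence(frames)
  expect_identical(seg$masks[, , 1], seg$masks[, , 2])
  expect_identical(seg$masks[, , 1], seg$masks[, , 3])
})

test_that("a disappearing cell flags later frames and frame-1 failure rejects", {
  p <- clockPreset("culture_psm4", noiseSD = 0)
  prog <- drawCellProgram(p, seed = 11)
  sc <- generateBrightfieldScene(prog, p, seed = 3, nFrames = 2)
  frames <- sc@frames
  frames[, , 2] <- 0.5                    # cell gone
  expect_warning(seg <- segmentSequence(frames), "vanished")
  expect_true(seg$qc$flagged[2])
  blank <- array(0.5, c(96, 96, 2))
  expect_error(segmentSequence(blank), "constant|no cell")
})

test_that("masked intensity extraction follows its contracts", {
  masks <- array(0, c(8, 8, 2)); masks[3:5, 3:5, 1] <- 1; masks[4, 4, 2] <- 1
  her1 <- array(7, c(8, 8, 2)); mesp <- array(1, c(8, 8, 2))
  her1[4, 4, 2] <- 42
  tr <- extractIntensities(masks, her1, mesp, frameInterval = 10,
                           imagingStartOffset = 70)
  expect_equal(tr$her1, c(7, 42))          # uniform 7; single-pixel mask
  expect_equal(tr$t_min, c(70, 80))
  # empty mask gives a missing value
  masks[, , 2] <- 0
  tr2 <- extractIntensities(masks, her1, mesp)
  expect_true(is.na(tr2$her1[2]) && tr2$flagged[2])
  # max-in-ROI variant
  trMax <- extractIntensities(array(1, c(8, 8, 2)) * masks, her1, mesp,
                              summary = "max")
  expect_equal(trMax$her1[1], 7)
})

test_that("extracted trace matches the rendered program trace (generator oracle)", {
  p <- clockPreset("culture_psm4", noiseSD = 0)
  prog <- drawCellProgram(p, seed = 11)
  sc <- generateBrightfieldScene(prog, p, seed = 3, nFrames = 6)
  seg <- segmentSequence(sc@frames)
  tr <- extractIntensities(seg$masks, sc@her1Stack, sc@mespStack,
                           p@frameInterval, p@imagingStartOffset)
  truth <- segclock:::her1Signal(prog, p, tr$t_min)
  expect_gte(cor(tr$her1, truth), 0.95)
})
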