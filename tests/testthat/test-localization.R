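test_that("blood pool center and radius are recovered on the phantom", {
  ms <- sharedMidSlice()
  ph <- ms$phantom
  tab <- ms$loc@table
  expect_true(all(tab$confidence > 0))
  for (s in seq_len(nrow(tab))) {
    expect_lt(abs(tab$centerRow[s] - ph$truth@centerPx[1]), 2)
    expect_lt(abs(tab$centerCol[s] - ph$truth@centerPx[2]), 2)
    expect_lt(abs(tab$radiusPx[s] - ph$truth@endoRadiusPx[1]), 2)
  }
})

test_that("a static series yields no moving object", {
  ph <- generatePhantom(phantomSpec(
    nSlices = 3, nPhases = 3, imageShape = c(48, 48),
    endoRadiusEdMm = 12, wallThicknessEdMm = 5, peakContraction = 0,
    noiseSigma = 0, valveDescentMm = 0))
  expect_error(detectLVBloodPool(ph$series),
               class = "AlgorithmFailure")
})

test_that("the round moving disk beats a non-round moving component", {
  # two bright moving objects: a disk and a thin bar
  n <- 64
  mk <- function(t) {
    r <- matrix(seq_len(n) - 1, n, n)
    c <- t(r)
    img <- matrix(20, n, n)
    rad <- 9 - 1.5 * t
    disk <- sqrt((r - 22)^2 + (c - 22)^2) <= rad
    bar <- abs(r - 48) <= 1.5 & abs(c - 34) <= 13 - 2 * t
    img[disk] <- 200
    img[bar] <- 200
    img
  }
  fr <- array(0, c(n, n, 3))
  for (t in 0:2) fr[, , t + 1] <- mk(t)
  slice <- new("CineSlice", frames = fr,
               geometry = new("SliceGeometry", origin = c(0, 0, 0),
                              rowDir = c(1, 0, 0), colDir = c(0, 1, 0),
                              pixelSpacing = c(2, 2), thickness = 8,
                              gap = 2, sliceIndex = 0))
  cand <- bloodPoolCandidates(slice)
  expect_gte(nrow(cand), 2)
  # the stated score formula ranks the disk first
  byScore <- cand[order(-cand$score), ]
  expect_lt(abs(byScore$centerRow[1] - 22), 2)
  expect_lt(abs(byScore$centerCol[1] - 22), 2)
  barRow <- which(abs(cand$centerRow - 48) < 3)
  expect_true(length(barRow) >= 1)
  expect_lt(cand$roundness[barRow[1]], 0.5)
  # independent recomputation of the score product
  expect_equal(cand$score,
               cand$roundness * cand$brightness * cand$motion)
})

test_that("blood-pool detection is translation-equivariant", {
  ph <- generatePhantom(phantomSpec(
    nSlices = 3, nPhases = 4, imageShape = c(64, 64),
    endoRadiusEdMm = 14, wallThicknessEdMm = 6, noiseSigma = 2,
    valveDescentMm = 4))
  loc1 <- detectLVBloodPool(ph$series)
  shift <- function(m, dr, dc) {
    out <- matrix(m[1, 1], nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  shifted <- ph$series
  shifted@shortAxis <- lapply(shifted@shortAxis, function(sl) {
    for (t in seq_len(dim(sl@frames)[3]))
      sl@frames[, , t] <- shift(sl@frames[, , t], 5, 3)
    sl
  })
  loc2 <- detectLVBloodPool(shifted)
  expect_equal(loc2@table$centerRow, loc1@table$centerRow + 5,
               tolerance = 1e-8)
  expect_equal(loc2@table$centerCol, loc1@table$centerCol + 3,
               tolerance = 1e-8)
})

test_that("valve anchors track the phantom corners within 2 mm", {
  ms <- sharedMidSlice()
  ph <- ms$phantom
  mv <- detectMitralValvePoints(ph$series)
  n <- dim(mv$anchors)[3]
  truth <- array(0, c(4, 3, n))
  truth[1:2, , ] <- ph$truth@anchors2ch
  truth[3:4, , ] <- ph$truth@anchors4ch
  for (t in seq_len(n)) {
    det <- mv$anchors[, , t]
    for (v in list(1:2, 3:4)) {
      d1 <- max(sqrt(rowSums((det[v, ] - truth[v, , t])^2)))
      d2 <- max(sqrt(rowSums((det[v, ] - truth[rev(v), , t])^2)))
      expect_lt(min(d1, d2), 2)
    }
  }
})

test_that("static phantom anchors are constant over phases", {
  ph <- generatePhantom(phantomSpec(
    nSlices = 3, nPhases = 4, imageShape = c(64, 64),
    endoRadiusEdMm = 14, wallThicknessEdMm = 6, peakContraction = 0,
    noiseSigma = 0, valveDescentMm = 0))
  mv <- detectMitralValvePoints(ph$series)
  for (t in 2:4)
    expect_equal(mv$anchors[, , t], mv$anchors[, , 1], tolerance = 1e-9)
})

test_that("a corrupted phase is flagged and interpolated", {
  ph <- generatePhantom(testSpec(seed = 11))
  ser <- ph$series
  set.seed(99)
  shape <- dim(ser@longAxis2ch@frames)[1:2]
  # replace one frame entirely by structureless noise
  ser@longAxis2ch@frames[, , 4] <-
    matrix(abs(rnorm(prod(shape), 120, 80)), shape[1], shape[2])
  mv <- detectMitralValvePoints(ser)
  expect_true(any(mv$flagged))
  n <- dim(mv$anchors)[3]
  for (t in seq_len(n)) {
    det <- mv$anchors[1:2, , t]
    truth <- ph$truth@anchors2ch[, , t]
    d1 <- max(sqrt(rowSums((det - truth)^2)))
    d2 <- max(sqrt(rowSums((det - truth[2:1, ])^2)))
    expect_lt(min(d1, d2), 3)
  }
})

test_that("plane fitting is exact for coplanar points and matches the
           brute-force grid oracle otherwise", {
  square <- rbind(c(0, 0, 5), c(1, 0, 5), c(1, 1, 5), c(0, 1, 5))
  bp <- fitBasePlane(array(square, c(4, 3, 1)))
  expect_equal(basePlaneResidual(bp, 0), 0, tolerance = 1e-12)
  expect_equal(abs(bp@normals[1, 3]), 1)

  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1))
  bp2 <- fitBasePlane(array(pts, c(4, 3, 1)))
  rssFit <- basePlaneResidual(bp2, 0)
  rssGrid <- bruteForcePlaneRss(pts)
  # the analytic fit cannot be worse than the 2-degree grid minimum
  expect_lte(rssFit, rssGrid + 1e-9)
  expect_lt(abs(rssFit - rssGrid), 0.05 * max(rssGrid, 1e-6))
})

test_that("plane fit equivariance and degeneracy handling", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0.2), c(0, 1, -0.1), c(1, 1, 0.4))
  bp <- fitBasePlane(array(pts, c(4, 3, 1)))
  v <- c(3, -2, 7)
  bpT <- fitBasePlane(array(sweep(pts, 2, -v), c(4, 3, 1)))
  expect_equal(bpT@normals[1, ], bp@normals[1, ], tolerance = 1e-9)
  expect_equal(bpT@offsets[1], bp@offsets[1] + sum(bp@normals[1, ] * v),
               tolerance = 1e-9)
  # residual is invariant under rigid rotation of the anchor set
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  bpR <- fitBasePlane(array(pts %*% t(R), c(4, 3, 1)))
  expect_equal(basePlaneResidual(bpR, 0), basePlaneResidual(bp, 0),
               tolerance = 1e-9)
  col <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))
  expect_error(fitBasePlane(array(col, c(4, 3, 1))), "collinear")
})
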