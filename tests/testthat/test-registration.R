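test_that("registering an image to itself gives zero fields", {
  img <- blobImage()
  f <- registerPair(img, img)
  expect_true(all(f@forwardRow == 0) && all(f@forwardCol == 0))
  expect_true(all(f@inverseRow == 0) && all(f@inverseCol == 0))
  expect_false(f@flagged)
})

test_that("constant images return a flagged zero field", {
  img <- matrix(5, 32, 32)
  expect_warning(f <- registerPair(img, img + 0), "constant")
  expect_true(f@flagged)
  expect_true(all(f@forwardRow == 0))
})

test_that("a known integer shift is recovered within 0.5 px", {
  fixed <- blobImage(64, 32, 32)
  moving <- blobImage(64, 35, 32)
  f <- registerPair(fixed, moving)
  blob <- fixed > 20
  expect_lt(abs(mean(f@forwardRow[blob]) - 3), 0.5)
  expect_lt(abs(mean(f@forwardCol[blob])), 0.5)
  expect_lt(inverseConsistencyResidual(f), 0.1)
})

test_that("a radial contraction of the annulus is recovered", {
  ms <- sharedMidSlice()
  ph <- ms$phantom
  fr <- ms$slice@frames
  f <- registerPair(fr[, , 1], fr[, , 5])
  truthD <- phantomTruthDisplacement(ph$truth, 4, dim(fr)[1:2])
  shape <- dim(fr)[1:2]
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  rho <- sqrt((r - ph$truth@centerPx[1])^2 + (c - ph$truth@centerPx[2])^2)
  annulus <- rho >= ph$truth@endoRadiusPx[5] & rho <= ph$truth@epiRadiusPx[1]
  err <- sqrt((f@forwardRow - truthD$ur)^2 + (f@forwardCol - truthD$uc)^2)
  expect_lt(mean(err[annulus]), 0.5)
})

test_that("warping respects the identity, integer shifts, and inversion", {
  img <- blobImage(48, 24, 24, sigma = 8)
  zero <- matrix(0, 48, 48)
  fId <- new("DeformationField", forwardRow = zero, forwardCol = zero,
             inverseRow = zero, inverseCol = zero, flagged = FALSE)
  expect_identical(warpImage(img, fId), img)

  sh <- new("DeformationField", forwardRow = zero + 2, forwardCol = zero,
            inverseRow = zero - 2, inverseCol = zero, flagged = FALSE)
  w <- warpImage(img, sh)
  expect_equal(w[1:46, ], img[3:48, ], tolerance = 1e-12)

  fixed <- blobImage(64, 32, 32)
  moving <- blobImage(64, 34, 33)
  f <- registerPair(fixed, moving)
  roundTrip <- warpImage(warpImage(moving, f, "forward"), f, "inverse")
  expect_lt(mean(abs(roundTrip - moving)) / diff(range(moving)), 0.02)
})

test_that("slice-series fields track the phantom and close the cycle", {
  ms <- sharedMidSlice()
  ph <- ms$phantom
  fields <- ms$fields
  shape <- dim(ms$slice@frames)[1:2]
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  rho <- sqrt((r - ph$truth@centerPx[1])^2 + (c - ph$truth@centerPx[2])^2)
  rMid <- (ph$truth@endoRadiusPx[1] + ph$truth@epiRadiusPx[1]) / 2
  ring <- abs(rho - rMid) < 2
  for (t in seq_along(fields)) {
    td <- phantomTruthDisplacement(ph$truth, t - 1, shape)
    err <- sqrt((fields[[t]]@forwardRow - td$ur)^2 +
                  (fields[[t]]@forwardCol - td$uc)^2)
    expect_gt(mean(err[ring] < 0.5), 0.9)
    expect_lt(inverseConsistencyResidual(fields[[t]]), 0.1)
  }
  expect_lt(attr(fields, "cycleResidual"), 0.5)
})

test_that("a static series yields zero fields everywhere", {
  fr <- array(rep(blobImage(40, 20, 20, sigma = 6), 3), c(40, 40, 3))
  slice <- new("CineSlice", frames = fr,
               geometry = new("SliceGeometry", origin = c(0, 0, 0),
                              rowDir = c(1, 0, 0), colDir = c(0, 1, 0),
                              pixelSpacing = c(2, 2), thickness = 8,
                              gap = 2, sliceIndex = 0))
  fields <- registerSliceSeries(slice)
  for (f in fields) {
    expect_true(all(f@forwardRow == 0))
    expect_true(all(f@forwardCol == 0))
  }
  expect_equal(attr(fields, "cycleResidual"), 0)
})

test_that("swapping fixed and moving yields the inverse field", {
  fixed <- blobImage(64, 32, 32)
  moving <- blobImage(64, 35, 34)
  f <- registerPair(fixed, moving)
  g <- registerPair(moving, fixed)
  support <- fixed > 20  # displacement is determined where there is signal
  expect_lt(mean(sqrt((g@forwardRow - f@inverseRow)^2 +
                        (g@forwardCol - f@inverseCol)^2)[support]), 0.2)
})

test_that("reversing a two-phase series inverts its field", {
  ms <- sharedMidSlice()
  fr <- ms$slice@frames[, , c(4, 5)]
  geom <- ms$slice@geometry
  fwd <- registerSliceSeries(new("CineSlice", frames = fr,
                                 geometry = geom))
  rev <- registerSliceSeries(new("CineSlice", frames = fr[, , 2:1],
                                 geometry = geom))
  ph <- ms$phantom
  shape <- dim(fr)[1:2]
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  rho <- sqrt((r - ph$truth@centerPx[1])^2 + (c - ph$truth@centerPx[2])^2)
  wall <- rho >= ph$truth@endoRadiusPx[5] & rho <= ph$truth@epiRadiusPx[1]
  expect_lt(mean(sqrt((rev[[2]]@forwardRow - fwd[[2]]@inverseRow)^2 +
                        (rev[[2]]@forwardCol -
                           fwd[[2]]@inverseCol)^2)[wall]), 0.2)
})

test_that("registration is deterministic", {
  ms <- sharedMidSlice()
  fr <- ms$slice@frames
  f1 <- registerPair(fr[, , 1], fr[, , 4])
  f2 <- registerPair(fr[, , 1], fr[, , 4])
  expect_identical(f1@forwardRow, f2@forwardRow)
  expect_identical(f1@inverseCol, f2@inverseCol)
})
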