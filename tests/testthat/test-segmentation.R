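test_that("region models recover the phantom intensities", {
  ph <- generatePhantom(testSpec(noiseSigma = 2, seed = 3))
  loc <- detectLVBloodPool(ph$series)
  s <- 3
  m <- estimateRegionModels(ph$series@shortAxis[[s]], loc@masks[[s]],
                            loc@table$centerRow[s], loc@table$centerCol[s],
                            loc@table$radiusPx[s])
  expect_lt(abs(m@means[["blood"]] - 200), 5)
  expect_lt(abs(m@means[["myo"]] - 100), 5)
  expect_lt(abs(m@means[["bg"]] - 20), 5)
  expect_equal(m@means[["pv"]],
               (m@means[["blood"]] + m@means[["myo"]]) / 2)
  expect_true(m@means[["blood"]] > m@means[["myo"]])
  expect_true(m@means[["myo"]] > m@means[["bg"]])
  expect_error(estimateRegionModels(ph$series@shortAxis[[s]],
                                    matrix(FALSE, 80, 80), 40, 40, 10),
               "empty")
})

test_that("edge possibility vanishes on uniform images and peaks on the
           endocardial boundary", {
  ms <- sharedMidSlice()
  expect_true(all(edgePossibility(matrix(7, 40, 40), ms$models) == 0))

  ph <- ms$phantom
  ep <- edgePossibility(ms$slice@frames[, , 1], ms$models)
  ctr <- ph$truth@centerPx
  th <- seq(0, 2 * pi, length.out = 64)[-64]
  rEndo <- ph$truth@endoRadiusPx[1]
  onEdge <- cbind(round(ctr[1] + rEndo * sin(th)) + 1,
                  round(ctr[2] + rEndo * cos(th)) + 1)
  interior <- cbind(round(ctr[1] + 0.5 * rEndo * sin(th)) + 1,
                    round(ctr[2] + 0.5 * rEndo * cos(th)) + 1)
  frac <- mean(ep[onEdge] > ep[interior])
  expect_gte(frac, 0.95)
})

test_that("polar resampling localizes a circular edge and respects
           bounds and rotational symmetry", {
  n <- 65
  ctr <- c(32, 32)
  r <- matrix(seq_len(n) - 1, n, n)
  c <- t(r)
  rho <- sqrt((r - ctr[1])^2 + (c - ctr[2])^2)
  R <- 14.3
  ep <- exp(-(rho - R)^2 / 2)
  pol <- toPolar(ep, ctr, rMax = 25, nAngles = 48, nRadii = 50)
  expect_true(all(pol@cost >= 1e-3 - 1e-12) && all(pol@cost <= 1))
  for (a in seq_len(48)) {
    bin <- which.min(pol@cost[a, ])
    expect_lt(abs(pol@radii[bin] - R), 1)
  }
  # rotating the image by 90 degrees about the center permutes rows
  ep90 <- t(ep)[, rev(seq_len(n))]  # 90-degree rotation
  pol90 <- toPolar(ep90, ctr, rMax = 25, nAngles = 48, nRadii = 50)
  shift <- 12  # 48 angles / 4
  expect_equal(pol90@cost[((seq_len(48) - 1 + shift) %% 48) + 1, ],
               pol@cost, tolerance = 1e-9)
  expect_error(toPolar(ep, c(-5, 3), rMax = 10), "center")
})

test_that("the closed-path optimum is exact on forced and enumerated
           instances", {
  cost <- matrix(1, 4, 3)
  cost[, 2] <- 0.1
  pol <- new("PolarImage", cost = rbind(cost, cost, cost, cost,
                                        cost, cost, cost, cost),
             center = c(0, 0), radii = 1:3)
  # need >= 32 angles for the class; replicate the 4-angle pattern
  expect_equal(unname(shortestClosedPath(pol)@cost), 0.1 * 32)
  res <- cinestrain:::`.cs_closed_path`
  direct <- res(cost, 1L)
  expect_equal(direct$cost, 0.4)
  expect_true(all(direct$radii == 2))

  set.seed(42)
  for (i in 1:100) {
    cm <- matrix(runif(6 * 8), 6, 8)
    dp <- res(cm, 1L)
    expect_equal(dp$cost, bruteClosedPathCost(cm, 1), tolerance = 1e-12)
  }
  for (i in 1:5) {
    cm <- matrix(runif(6 * 8), 6, 8)
    dp <- res(cm, 2L)
    expect_equal(dp$cost, bruteClosedPathCost(cm, 2), tolerance = 1e-12)
  }
})

test_that("uniform cost ties break to the smallest constant radius", {
  pol <- new("PolarImage", cost = matrix(0.5, 36, 10), center = c(0, 0),
             radii = seq(2, 20, length.out = 10))
  p <- shortestClosedPath(pol)
  expect_true(all(p@radiusPx == pol@radii[1]))
})

test_that("adding a constant to all costs shifts path cost without
           changing the optimum", {
  set.seed(5)
  cm <- matrix(runif(36 * 8, 0.1, 0.9), 36, 8)
  pol <- new("PolarImage", cost = cm, center = c(0, 0), radii = 1:8)
  p1 <- shortestClosedPath(pol)
  pol2 <- new("PolarImage", cost = cm + 0.05, center = c(0, 0),
              radii = 1:8)
  p2 <- shortestClosedPath(pol2)
  expect_equal(p2@radiusPx, p1@radiusPx)
  expect_equal(p2@cost, p1@cost + 0.05 * 36, tolerance = 1e-9)
})

test_that("phantom contours match the analytic radii within a pixel", {
  ms <- sharedMidSlice()
  ph <- ms$phantom
  for (t in seq_along(ms$family)) {
    endo <- ms$family[[t]]$endo
    epi <- ms$family[[t]]$epi
    expect_lt(max(abs(endo@radiusPx - ph$truth@endoRadiusPx[t])), 1)
    expect_lt(max(abs(epi@radiusPx - ph$truth@epiRadiusPx[t])), 1)
    expect_true(all(epi@radiusPx >= endo@radiusPx))
  }
})

test_that("a static phantom yields identical contours at every phase", {
  ph <- generatePhantom(phantomSpec(
    nSlices = 3, nPhases = 4, imageShape = c(64, 64),
    endoRadiusEdMm = 14, wallThicknessEdMm = 6, peakContraction = 0.12,
    noiseSigma = 0, valveDescentMm = 4))
  # static in the sense of zero fields: pass identical frames
  fr0 <- ph$series@shortAxis[[2]]@frames[, , 1]
  fr <- array(rep(fr0, 4), c(dim(fr0), 4))
  slice <- new("CineSlice", frames = fr,
               geometry = ph$series@shortAxis[[2]]@geometry)
  loc <- detectLVBloodPool(ph$series)
  fields <- registerSliceSeries(slice)
  fam <- segmentSlice(slice, fields, sharedMidSlice()$models,
                      loc@table$centerRow[2], loc@table$centerCol[2],
                      loc@table$radiusPx[2])
  for (t in 2:4) {
    expect_equal(fam[[t]]$endo@radiusPx, fam[[1]]$endo@radiusPx)
    expect_equal(fam[[t]]$epi@radiusPx, fam[[1]]$epi@radiusPx)
  }
})

test_that("one corrupted phase does not derail the other contours", {
  ms <- sharedMidSlice()
  ph <- ms$phantom
  fr <- ms$slice@frames
  set.seed(123)
  fr[, , 3] <- pmax(fr[, , 3] + matrix(rnorm(prod(dim(fr)[1:2]), 0, 60),
                                       dim(fr)[1], dim(fr)[2]), 0)
  slice <- new("CineSlice", frames = fr, geometry = ms$slice@geometry)
  fields <- registerSliceSeries(slice)
  loc <- ms$loc
  fam <- segmentSlice(slice, fields, ms$models,
                      loc@table$centerRow[ms$s], loc@table$centerCol[ms$s],
                      loc@table$radiusPx[ms$s])
  for (t in seq_along(fam)) {
    if (t == 3) next
    expect_lt(max(abs(fam[[t]]$endo@radiusPx - ph$truth@endoRadiusPx[t])),
              2)
  }
})

test_that("segmentStudy covers accepted slices, is deterministic, and
           excludes blank slices", {
  rep <- sharedReport()
  cs <- rep@contours
  expect_s4_class(cs, "ContourSet")
  expect_equal(length(cs@contours), 5)
  expect_equal(cs@nPhases, 8)
  for (fam in cs@contours)
    for (ph in fam) {
      expect_s4_class(ph$endo, "Contour")
      expect_s4_class(ph$epi, "Contour")
      expect_true(all(ph$epi@radiusPx >= ph$endo@radiusPx))
    }

  # blank basal slice is excluded from the accepted range
  ph2 <- generatePhantom(phantomSpec(
    nSlices = 5, nPhases = 4, imageShape = c(64, 64),
    endoRadiusEdMm = 14, wallThicknessEdMm = 6, noiseSigma = 2,
    valveDescentMm = 4))
  ser <- ph2$series
  ser@shortAxis[[5]]@frames[] <- 20
  loc <- detectLVBloodPool(ser)
  expect_equal(sum(loc@table$confidence > 0), 4)
  cs2 <- segmentStudy(ser, loc)
  expect_equal(sort(cs2@acceptedSlices), 0:3)
  expect_equal(length(cs2@contours), 4)
})
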