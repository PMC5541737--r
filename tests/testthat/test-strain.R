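fieldFromDisplacement <- function(ur, uc) {
  inv <- cinestrain:::`.cs_invert_field`(ur, uc, 20L)
  new("DeformationField", forwardRow = ur, forwardCol = uc,
      inverseRow = inv$ur, inverseCol = inv$uc, flagged = FALSE)
}

scalingField <- function(n, lambda, center = (n - 1) / 2) {
  r <- matrix(seq_len(n) - 1, n, n)
  c <- t(r)
  fieldFromDisplacement((lambda - 1) * (r - center),
                        (lambda - 1) * (c - center))
}

test_that("Green-Lagrange tensor closed forms: zero, uniform scaling,
           rigid rotation", {
  n <- 41
  zero <- matrix(0, n, n)
  E0 <- lagrangianStrainField(fieldFromDisplacement(zero, zero))
  expect_true(all(E0@Exx == 0) && all(E0@Eyy == 0) && all(E0@Exy == 0))

  Es <- lagrangianStrainField(scalingField(n, 0.8))
  inner <- 5:(n - 5)
  expect_equal(max(abs(Es@Exx[inner, inner] + 0.18)), 0, tolerance = 1e-9)
  expect_equal(max(abs(Es@Eyy[inner, inner] + 0.18)), 0, tolerance = 1e-9)
  expect_equal(max(abs(Es@Exy[inner, inner])), 0, tolerance = 1e-9)

  th <- 10 * pi / 180
  ctr <- (n - 1) / 2
  r <- matrix(seq_len(n) - 1, n, n) - ctr
  c <- t(matrix(seq_len(n) - 1, n, n)) - ctr
  ur <- (cos(th) * r - sin(th) * c) - r
  uc <- (sin(th) * r + cos(th) * c) - c
  Er <- lagrangianStrainField(fieldFromDisplacement(ur, uc))
  expect_lt(max(abs(Er@Exx[inner, inner])), 1e-6)
  expect_lt(max(abs(Er@Eyy[inner, inner])), 1e-6)
  expect_lt(max(abs(Er@Exy[inner, inner])), 1e-6)
})

test_that("polar conversion respects axis alignment and isotropy", {
  n <- 41
  ctr <- c(20, 20)
  tens <- new("StrainTensorField", Exx = matrix(0.3, n, n),
              Eyy = matrix(-0.1, n, n), Exy = matrix(0, n, n), phase = 1)
  pol <- polarStrain(tens, ctr)
  # pixel offset along the row (x) axis: radial = x
  expect_equal(pol@Err[31, 21], 0.3)
  expect_equal(pol@Ecc[31, 21], -0.1)
  # pixel offset along the col (y) axis: radial = y
  expect_equal(pol@Err[21, 31], -0.1)
  expect_equal(pol@Ecc[21, 31], 0.3)
  expect_true(is.na(pol@Ecc[21, 21]))

  iso <- new("StrainTensorField", Exx = matrix(0.07, n, n),
             Eyy = matrix(0.07, n, n), Exy = matrix(0, n, n), phase = 1)
  piso <- polarStrain(iso, ctr)
  ok <- !is.na(piso@Ecc)
  expect_equal(range(piso@Ecc[ok]), c(0.07, 0.07), tolerance = 1e-12)
  expect_equal(range(piso@Err[ok]), c(0.07, 0.07), tolerance = 1e-12)
})

test_that("pure radial contraction gives the analytic circumferential
           Green strain on the annulus", {
  ms <- sharedMidSlice()
  ph <- ms$phantom
  lam <- ph$truth@lambda[5]
  n <- dim(ms$slice@frames)[1]
  f <- scalingField(n, lam, center = ph$truth@centerPx[1])
  pol <- polarStrain(lagrangianStrainField(f), ph$truth@centerPx)
  expected <- 0.5 * (lam^2 - 1)
  r <- matrix(seq_len(n) - 1, n, n)
  c <- t(r)
  rho <- sqrt((r - ph$truth@centerPx[1])^2 + (c - ph$truth@centerPx[2])^2)
  annulus <- rho >= ph$truth@endoRadiusPx[5] &
    rho <= ph$truth@epiRadiusPx[1] & !is.na(pol@Ecc)
  expect_gt(mean(abs(pol@Ecc[annulus] - expected) < 0.01), 0.9)
})

test_that("mid-slice selection picks the middle of the accepted range,
           ties toward the base", {
  mk <- function(acc) new("ContourSet", contours = list(),
                          acceptedSlices = acc, nPhases = 2,
                          totalCost = 0)
  expect_equal(selectMidSlice(mk(2:8)), 5)
  expect_equal(selectMidSlice(mk(3:6)), 5)
  expect_equal(selectMidSlice(mk(3:6), "base_to_apex"), 4)
  expect_equal(selectMidSlice(mk(4)), 4)
})

test_that("uniform 0.8 scaling reports exactly -20% engineering strain", {
  n <- 81
  ctr <- c(40, 40)
  fam <- lapply(1:2, function(t) list(
    endo = new("Contour", radiusPx = rep(12, 48), center = ctr, cost = 0,
               kind = "endo", phase = t - 1),
    epi = new("Contour", radiusPx = rep(20, 48), center = ctr, cost = 0,
              kind = "epi", phase = t - 1)))
  zero <- matrix(0, n, n)
  fields <- list(fieldFromDisplacement(zero, zero), scalingField(n, 0.8))
  sc <- midwallStrainCurve(fam, fields)
  expect_equal(sc@strainPercent[1], 0)
  expect_equal(sc@strainPercent[2], -20, tolerance = 1e-6)
  expect_equal(sc@peakPercent, sc@strainPercent[2])
  # Ecc of -0.18 converts to -20% engineering strain
  expect_equal((sqrt(1 + 2 * -0.18) - 1) * 100, -20)
  # mean-then-convert and convert-then-mean agree here (uniform field)
  sc2 <- midwallStrainCurve(fam, fields, meanFirst = FALSE)
  expect_equal(sc2@strainPercent[2], -20, tolerance = 1e-6)
})

test_that("phantom strain curve recovers the contraction and stays
           cyclic and translation-invariant", {
  rep <- sharedReport()
  truth <- sharedPhantom()$truth
  expect_equal(rep@strainCurve[1], 0)
  expect_lt(abs(rep@peakStrainPercent - min(truth@midwallStrainTruth)), 2)
  n <- length(rep@strainCurve)
  # cyclic: returns near the truth value at the cycle end
  expect_lt(abs(rep@strainCurve[n] - truth@midwallStrainTruth[n]), 1)
})

test_that("rigid per-phase translation leaves the strain curve
           unchanged", {
  ms <- sharedMidSlice()
  base <- midwallStrainCurve(ms$family, ms$fields,
                             sliceIndex = 2)
  shifted <- lapply(seq_along(ms$fields), function(t) {
    f <- ms$fields[[t]]
    if (t == 1) return(f)
    dr <- 1.5
    fieldFromDisplacement(f@forwardRow + dr, f@forwardCol)
  })
  tr <- midwallStrainCurve(ms$family, shifted, sliceIndex = 2)
  expect_lt(max(abs(tr@strainPercent - base@strainPercent)), 0.2)
})

test_that("zero motion yields identically zero Lagrangian and Eulerian
           curves", {
  n <- 49
  zero <- matrix(0, n, n)
  fId <- fieldFromDisplacement(zero, zero)
  fam <- lapply(1:3, function(t) list(
    endo = new("Contour", radiusPx = rep(8, 48), center = c(24, 24),
               cost = 0, kind = "endo", phase = t - 1),
    epi = new("Contour", radiusPx = rep(14, 48), center = c(24, 24),
              cost = 0, kind = "epi", phase = t - 1)))
  fields <- list(fId, fId, fId)
  expect_true(all(midwallStrainCurve(fam, fields)@strainPercent == 0))
  expect_true(all(eulerianStrainCurve(fam, fields) == 0))
})

test_that("Lagrangian and Eulerian strain agree for small deformations
           and diverge for large ones", {
  mkCase <- function(pc) {
    n <- 81
    ctr <- 40
    nph <- 6
    lam <- 1 - pc * 0.5 * (1 - cos(2 * pi * (0:(nph - 1)) / nph))
    fields <- lapply(lam, function(l) scalingField(n, l, center = ctr))
    fam <- lapply(seq_len(nph), function(t) list(
      endo = new("Contour", radiusPx = rep(12, 48), center = c(ctr, ctr),
                 cost = 0, kind = "endo", phase = t - 1),
      epi = new("Contour", radiusPx = rep(20, 48), center = c(ctr, ctr),
                cost = 0, kind = "epi", phase = t - 1)))
    lagr <- midwallStrainCurve(fam, fields)@strainPercent
    eul <- eulerianStrainCurve(fam, fields)
    max(abs(lagr - eul))
  }
  expect_lte(mkCase(0.02), 0.1)
  expect_gt(mkCase(0.25), 0.5)
})
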