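# Shared fixtures, generated once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache))
    assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# the reference study conditions used throughout the suite: a mid-size
# contracting phantom with noise
testSpec <- function(...) {
  args <- utils::modifyList(
    list(nSlices = 5, nPhases = 8, imageShape = c(80, 80),
         pixelSpacingMm = 2, endoRadiusEdMm = 20,
         wallThicknessEdMm = 10, peakContraction = 0.2,
         noiseSigma = 3, valveDescentMm = 8, seed = 7),
    list(...))
  do.call(phantomSpec, args)
}

sharedPhantom <- function() cached("phantom", generatePhantom(testSpec()))

sharedReport <- function() cached("report", {
  runPipeline(sharedPhantom()$series)
})

# per-phase fields + localization for the mid short-axis slice
sharedMidSlice <- function() cached("midslice", {
  ph <- sharedPhantom()
  loc <- detectLVBloodPool(ph$series)
  s <- 3
  slice <- ph$series@shortAxis[[s]]
  fields <- registerSliceSeries(slice)
  models <- estimateRegionModels(slice, loc@masks[[s]],
                                 loc@table$centerRow[s],
                                 loc@table$centerCol[s],
                                 loc@table$radiusPx[s])
  family <- segmentSlice(slice, fields, models, loc@table$centerRow[s],
                         loc@table$centerCol[s], loc@table$radiusPx[s])
  list(phantom = ph, loc = loc, slice = slice, fields = fields,
       models = models, family = family, s = s)
})

# smooth Gaussian blob image for registration tests
blobImage <- function(n = 64, centerRow = 32, centerCol = 32, sigma = 10,
                      amp = 200) {
  r <- matrix(seq_len(n) - 1, n, n)
  c <- t(r)
  amp * exp(-((r - centerRow)^2 + (c - centerCol)^2) / (2 * sigma^2))
}

# exhaustive-enumeration oracle for the minimum-cost closed polar path
bruteClosedPathCost <- function(cost, smoothness) {
  na <- nrow(cost)
  nr <- ncol(cost)
  best <- Inf
  rec <- function(path, acc) {
    k <- length(path)
    if (k == na) {
      if (abs(path[na] - path[1]) <= smoothness && acc < best)
        best <<- acc
      return(invisible())
    }
    last <- path[k]
    for (r in max(1, last - smoothness):min(nr, last + smoothness))
      rec(c(path, r), acc + cost[k + 1, r])
  }
  for (s in seq_len(nr)) rec(s, cost[1, s])
  best
}

# brute-force grid search over unit normals (2 degree steps) for the
# least-squares plane fit
bruteForcePlaneRss <- function(pts) {
  best <- Inf
  for (thDeg in seq(0, 178, by = 2)) {
    for (phDeg in seq(-88, 90, by = 2)) {
      th <- thDeg * pi / 180
      phi <- phDeg * pi / 180
      n <- c(cos(phi) * cos(th), cos(phi) * sin(th), sin(phi))
      d <- pts %*% n - mean(pts %*% n)
      rss <- sum(d^2)
      if (rss < best) best <- rss
    }
  }
  best
}

mkGeom <- function(sliceIndex = 0, spacing = c(1, 1), thickness = 8,
                   gap = 2) {
  new("SliceGeometry", origin = c(0, 0, sliceIndex * (thickness + gap)),
      rowDir = c(1, 0, 0), colDir = c(0, 1, 0), pixelSpacing = spacing,
      thickness = thickness, gap = gap, sliceIndex = sliceIndex)
}

circleContour <- function(radiusPx, nAngles = 96, center = c(50, 50),
                          kind = "endo", phase = 0) {
  new("Contour", radiusPx = rep(radiusPx, nAngles), center = center,
      cost = 0, kind = kind, phase = phase)
}


# a synthetic 5-slice cylinder study: radius 20 mm, spacing 10 mm
cylinderFixture <- function(nPhases = 2) {
  sax <- lapply(0:4, function(i) {
    new("CineSlice", frames = array(1, c(101, 101, nPhases)) +
          array(seq_len(101 * 101 * nPhases) %% 2, c(101, 101, nPhases)),
        geometry = mkGeom(i))
  })
  la <- sax[[1]]
  series <- new("CineSeries", shortAxis = sax, longAxis2ch = la,
                longAxis4ch = la, id = "cyl", sliceOrder = "apex_to_base")
  fam <- lapply(seq_len(nPhases), function(t)
    list(endo = circleContour(20, phase = t - 1),
         epi = circleContour(26, kind = "epi", phase = t - 1)))
  contours <- new("ContourSet",
                  contours = stats::setNames(rep(list(fam), 5),
                                             paste0("s", 0:4)),
                  acceptedSlices = 0:4, nPhases = nPhases, totalCost = 0)
  list(series = series, contours = contours)
}

planeAtZ <- function(z, nPhases = 2) {
  new("BasePlane", normals = matrix(rep(c(0, 0, -1), each = nPhases),
                                    nPhases, 3),
      offsets = rep(-z, nPhases),
      anchors = array(rep(c(10, 0, z, 0, 10, z, -10, 0, z, 0, -10, z),
                          nPhases), c(4, 3, nPhases)),
      flagged = rep(FALSE, nPhases))
}

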