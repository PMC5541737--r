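#' @include AllClasses.R utils.R
NULL

#' Construct a phantom specification
#'
#' Convenience constructor over [PhantomSpec-class]; any unset argument
#' keeps the class default.
#'
#' @param ... named slots of [PhantomSpec-class] to override.
#' @return a validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(nSlices = 5, nPhases = 8, peakContraction = 0.2)
#' @export
phantomSpec <- function(...) new("PhantomSpec", ...)

# raised-cosine activation pulse: 0 at phase 0, 1 at mid cycle, cyclic
contractionPulse <- function(phase, nPhases) {
  0.5 * (1 - cos(2 * pi * phase / nPhases))
}

# per-phase radial scale factor relative to end diastole
phantomLambda <- function(spec) {
  t <- seq_len(spec@nPhases) - 1
  1 - spec@peakContraction * contractionPulse(t, spec@nPhases)
}

# world z of the valve (base) plane per phase; apex is at low z
phantomBaseZ <- function(spec) {
  spacing <- spec@thicknessMm + spec@gapMm
  zTop <- (spec@nSlices - 1) * spacing + spacing / 2
  t <- seq_len(spec@nPhases) - 1
  zTop - spec@valveDescentMm * contractionPulse(t, spec@nPhases)
}

#' Analytic mid-wall strain of the phantom
#'
#' Engineering circumferential strain of the mid-wall circle,
#' `(r_mid(t) - r_mid(0)) / r_mid(0) * 100`, in percent.
#'
#' @param spec a [PhantomSpec-class].
#' @param phase 0-based phase index (vectorized).
#' @return strain in percent.
#' @examples
#' analyticMidwallStrain(phantomSpec(peakContraction = 0.15, nPhases = 16), 8)
#' @export
analyticMidwallStrain <- function(spec, phase) {
  stopifnot(all(phase >= 0), all(phase < spec@nPhases))
  lam <- 1 - spec@peakContraction * contractionPulse(phase, spec@nPhases)
  (lam - 1) * 100
}

# anti-aliased disk/annulus short-axis frame (no noise); radii in px
renderShortAxisFrame <- function(shape, centerPx, endoPx, epiPx, spec) {
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  rho <- sqrt((r - centerPx[1])^2 + (c - centerPx[2])^2)
  aEndo <- clamp(endoPx - rho + 0.5, 0, 1)   # 1-px partial-volume ramp
  aEpi <- clamp(epiPx - rho + 0.5, 0, 1)
  img <- spec@intensityBg + (spec@intensityMyo - spec@intensityBg) * aEpi +
    (spec@intensityBlood - spec@intensityMyo) * aEndo
  if (spec@papillaries) {
    for (off in list(c(-0.4, -0.25), c(0.35, 0.3))) {
      pr <- centerPx[1] + off[1] * endoPx
      pc <- centerPx[2] + off[2] * endoPx
      pd <- sqrt((r - pr)^2 + (c - pc)^2)
      aPap <- clamp(0.18 * endoPx - pd + 0.5, 0, 1)
      img <- img - (spec@intensityBlood - spec@intensityMyo) * aPap * aEndo
    }
  }
  img
}

# long-axis frame: bright cavity column capped by the moving valve edge,
# wrapped in a darker myocardial shell; coordinates along (inPlane, z)
renderLongAxisFrame <- function(shape, geom, endoMm, epiMm, zApex, zBase,
                                wallMm, spec, axis) {
  s <- spec@pixelSpacingMm
  rowIdx <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  colIdx <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  z <- geom@origin[3] + rowIdx * s
  x <- geom@origin[axis] + colIdx * s
  axEndo <- clamp((endoMm - abs(x)) / s + 0.5, 0, 1)
  axEpi <- clamp((epiMm - abs(x)) / s + 0.5, 0, 1)
  azTop <- clamp((zBase - z) / s + 0.5, 0, 1)
  azCav <- azTop * clamp((z - zApex) / s + 0.5, 0, 1)
  azMyo <- azTop * clamp((z - (zApex - wallMm)) / s + 0.5, 0, 1)
  aBlood <- axEndo * azCav
  aMyo <- axEpi * azMyo
  spec@intensityBg + (spec@intensityMyo - spec@intensityBg) * aMyo +
    (spec@intensityBlood - spec@intensityMyo) * aBlood
}

#' Generate a synthetic cine study with analytic ground truth
#'
#' Builds a short-axis stack showing a bright circular blood pool inside a
#' darker myocardial annulus, contracting with a raised-cosine pulse
#' (mid-wall radius `r(t) = r_ED * (1 - peakContraction * w(t))`, `w(0) = 0`,
#' `max w = 1` at mid cycle), plus 2-chamber and 4-chamber long-axis views
#' whose basal (valve) edge descends by `valveDescentMm * w(t)`. Region
#' boundaries are anti-aliased over one pixel so a genuine partial-volume
#' intensity class exists. Seeded Gaussian noise is added; generation is
#' bit-reproducible for a fixed spec.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `series` (a [CineSeries-class]) and `truth`
#'   (a [PhantomTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(nSlices = 3, nPhases = 4,
#'                                   imageShape = c(48, 48), noiseSigma = 0))
#' ph$truth@efTruthPercent
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  s <- spec@pixelSpacingMm
  shape <- spec@imageShape
  spacing <- spec@thicknessMm + spec@gapMm
  lam <- phantomLambda(spec)
  endoMm <- spec@endoRadiusEdMm * lam
  epiMm <- (spec@endoRadiusEdMm + spec@wallThicknessEdMm) * lam
  if (max(epiMm) / s + 2 > min(shape) / 2)
    stop("phantom annulus exceeds the image bounds")
  centerPx <- c((shape[1] - 1) / 2, (shape[2] - 1) / 2)
  zBase <- phantomBaseZ(spec)
  zApex <- -spec@thicknessMm / 2
  wallMm <- spec@wallThicknessEdMm * lam

  set.seed(spec@seed)
  saxGeoms <- lapply(seq_len(spec@nSlices) - 1, function(i) {
    new("SliceGeometry",
        origin = c(-centerPx[1] * s, -centerPx[2] * s, i * spacing),
        rowDir = c(1, 0, 0), colDir = c(0, 1, 0), pixelSpacing = c(s, s),
        thickness = spec@thicknessMm, gap = spec@gapMm, sliceIndex = i)
  })
  sax <- lapply(saxGeoms, function(g) {
    fr <- array(0, c(shape, spec@nPhases))
    for (t in seq_len(spec@nPhases)) {
      img <- renderShortAxisFrame(shape, centerPx, endoMm[t] / s,
                                  epiMm[t] / s, spec)
      if (spec@noiseSigma > 0)
        img <- img + matrix(stats::rnorm(prod(shape), 0, spec@noiseSigma),
                            shape[1], shape[2])
      fr[, , t] <- pmax(img, 0)
    }
    new("CineSlice", frames = fr, geometry = g)
  })

  zMid <- (spec@nSlices - 1) * spacing / 2
  z0 <- zMid - centerPx[1] * s
  laGeom <- function(colDir, origin) {
    new("SliceGeometry", origin = origin, rowDir = c(0, 0, 1),
        colDir = colDir, pixelSpacing = c(s, s), thickness = 6, gap = 0,
        sliceIndex = 0)
  }
  g2 <- laGeom(c(1, 0, 0), c(-centerPx[2] * s, 0, z0))
  g4 <- laGeom(c(0, 1, 0), c(0, -centerPx[2] * s, z0))
  renderLA <- function(g, axis) {
    fr <- array(0, c(shape, spec@nPhases))
    for (t in seq_len(spec@nPhases)) {
      img <- renderLongAxisFrame(shape, g, endoMm[t], epiMm[t], zApex,
                                 zBase[t], wallMm[t], spec, axis)
      if (spec@noiseSigma > 0)
        img <- img + matrix(stats::rnorm(prod(shape), 0, spec@noiseSigma),
                            shape[1], shape[2])
      fr[, , t] <- pmax(img, 0)
    }
    new("CineSlice", frames = fr, geometry = g)
  }
  la2 <- renderLA(g2, axis = 1)
  la4 <- renderLA(g4, axis = 2)

  series <- new("CineSeries", shortAxis = sax, longAxis2ch = la2,
                longAxis4ch = la4, id = sprintf("phantom-%d", spec@seed),
                sliceOrder = "apex_to_base")

  zSlices <- (seq_len(spec@nSlices) - 1) * spacing
  volume <- vapply(seq_len(spec@nPhases), function(t) {
    frac <- clamp((zBase[t] - zSlices) / spacing + 0.5, 0, 1)
    sum(pi * endoMm[t]^2 * spacing * frac) / 1000
  }, numeric(1))
  anchors <- function(axis) {
    a <- array(0, c(2, 3, spec@nPhases))
    for (t in seq_len(spec@nPhases)) {
      p1 <- p2 <- c(0, 0, zBase[t])
      p1[axis] <- -endoMm[t]; p2[axis] <- endoMm[t]
      a[1, , t] <- p1; a[2, , t] <- p2
    }
    a
  }
  truth <- new("PhantomTruth",
               midwallStrainTruth = (lam - 1) * 100,
               volumeTruthMl = volume,
               efTruthPercent = (max(volume) - min(volume)) / max(volume) * 100,
               lambda = lam, basePlaneZ = zBase, centerPx = centerPx,
               endoRadiusPx = endoMm / s, epiRadiusPx = epiMm / s,
               anchors2ch = anchors(1), anchors4ch = anchors(2))
  list(series = series, truth = truth)
}

#' Analytic phantom displacement field
#'
#' The true forward displacement (phase 0 to `phase`) of the phantom's
#' radial contraction: `u(x) = (lambda(t) - 1) * (x - center)` in pixels.
#'
#' @param truth a [PhantomTruth-class].
#' @param phase 0-based phase.
#' @param shape image shape (rows, cols).
#' @return list of matrices `ur`, `uc` (px).
#' @export
phantomTruthDisplacement <- function(truth, phase, shape) {
  lam <- truth@lambda[phase + 1]
  r <- matrix(seq_len(shape[1]) - 1, shape[1], shape[2])
  c <- matrix(seq_len(shape[2]) - 1, shape[1], shape[2], byrow = TRUE)
  list(ur = (lam - 1) * (r - truth@centerPx[1]),
       uc = (lam - 1) * (c - truth@centerPx[2]))
}
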