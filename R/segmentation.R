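#' @include AllClasses.R utils.R
NULL

#' Estimate gray-level region models from a localized slice
#'
#' Histogram statistics of the LV regions at the reference phase: the
#' blood model from the detected pool mask, the myocardium model from an
#' annular ring at 1-1.5x the pool radius (excluding the pool), the
#' background model from the image border band, and the partial-volume
#' class as the blood/myocardium mixture midpoint.
#'
#' @param slice a [CineSlice-class].
#' @param mask logical blood-pool mask at the reference phase.
#' @param centerRow,centerCol,radiusPx pool localization (0-based px).
#' @return a [RegionModels-class].
#' @export
estimateRegionModels <- function(slice, mask, centerRow, centerCol,
                                 radiusPx) {
  if (!any(mask)) stop("empty blood-pool mask")
  f0 <- slice@frames[, , 1]
  r <- matrix(seq_len(nrow(f0)) - 1, nrow(f0), ncol(f0))
  c <- matrix(seq_len(ncol(f0)) - 1, nrow(f0), ncol(f0), byrow = TRUE)
  rho <- sqrt((r - centerRow)^2 + (c - centerCol)^2)
  # trim one pixel off the pool and keep the ring clear of both
  # boundaries, so partial-volume pixels do not bias the class means
  core <- mask & rho <= radiusPx - 1
  if (!any(core)) core <- mask
  ring <- rho >= 1.1 * radiusPx & rho <= 1.4 * radiusPx & !mask
  border <- r < 3 | c < 3 | r >= nrow(f0) - 3 | c >= ncol(f0) - 3
  mb <- mean(f0[core]); sb <- max(stats::sd(f0[core]), 1e-3)
  mm <- mean(f0[ring]); sm <- max(stats::sd(f0[ring]), 1e-3)
  mg <- mean(f0[border]); sg <- max(stats::sd(f0[border]), 1e-3)
  new("RegionModels",
      means = c(blood = mb, myo = mm, bg = mg, pv = (mb + mm) / 2),
      sds = c(blood = sb, myo = sm, bg = sg,
              pv = (sb + sm) / 2 + abs(mb - mm) / 8))
}

#' Edge-possibility map of one frame
#'
#' For each pixel, the normalized gradient magnitude weighted by the
#' likelihood that the two intensities flanking the pixel along the
#' gradient direction form an ordered (blood, myocardium) or
#' (myocardium, background) pair, under Gaussian region models. High
#' values mark plausible endocardial or epicardial edges.
#'
#' @param image numeric matrix.
#' @param models a [RegionModels-class].
#' @param delta flanking-sample offset (px) along the gradient direction.
#' @return matrix of values in \[0, 1\].
#' @export
edgePossibility <- function(image, models, delta = 1.5) {
  g <- .cs_gradient(image)
  mag <- sqrt(g$dr^2 + g$dc^2)
  mx <- max(mag)
  if (mx < .Machine$double.eps) return(matrix(0, nrow(image), ncol(image)))
  ur <- ifelse(mag > 0, g$dr / pmax(mag, 1e-12), 0)
  uc <- ifelse(mag > 0, g$dc / pmax(mag, 1e-12), 0)
  rows <- matrix(seq_len(nrow(image)) - 1, nrow(image), ncol(image))
  cols <- matrix(seq_len(ncol(image)) - 1, nrow(image), ncol(image),
                 byrow = TRUE)
  # gradient points toward the brighter side
  bright <- .cs_sample_bilinear(image, rows + delta * ur, cols + delta * uc)
  dark <- .cs_sample_bilinear(image, rows - delta * ur, cols - delta * uc)
  post <- function(x) {
    m <- models@means; s <- models@sds
    dens <- vapply(c("blood", "myo", "bg", "pv"), function(k)
      stats::dnorm(x, m[[k]], s[[k]]), numeric(length(x)))
    tot <- rowSums(dens) + 1e-300
    list(blood = dens[, 1] / tot, myo = dens[, 2] / tot,
         bg = dens[, 3] / tot)
  }
  pb <- post(bright)
  pd <- post(dark)
  w <- pmax(pb$blood * pd$myo, pb$myo * pd$bg)
  matrix((as.vector(mag) / mx) * w, nrow(image), ncol(image))
}

#' Resample an edge-possibility map to polar space
#'
#' Bilinear sampling along rays from `center`; each node's cost is
#' `1 - edge_possibility`, clamped to `[1e-3, 1]`, so strong edges are
#' cheap to traverse.
#'
#' @param edgeMap edge-possibility matrix (values in \[0, 1\]).
#' @param center (row, col) 0-based pixel center.
#' @param rMax outer sampling radius (px).
#' @param nAngles,nRadii polar grid size.
#' @param rMin inner sampling radius (px); defaults to one radial bin.
#' @return a [PolarImage-class].
#' @export
toPolar <- function(edgeMap, center, rMax, nAngles = 96, nRadii = 64,
                    rMin = rMax / nRadii) {
  stopifnot(rMax > 0, rMin >= 0, rMin < rMax)
  if (center[1] < 0 || center[1] > nrow(edgeMap) - 1 ||
      center[2] < 0 || center[2] > ncol(edgeMap) - 1)
    stop("polar center lies outside the image")
  th <- polarAngles(nAngles)
  radii <- seq(rMin, rMax, length.out = nRadii)
  rows <- center[1] + outer(sin(th), radii)
  cols <- center[2] + outer(cos(th), radii)
  ep <- matrix(.cs_sample_bilinear(edgeMap, as.vector(rows),
                                   as.vector(cols)), nAngles, nRadii)
  new("PolarImage", cost = clamp(1 - ep, 1e-3, 1), center = center,
      radii = radii)
}

#' Minimum-cost closed contour in a polar cost image
#'
#' One radius bin per angle, radial jumps bounded by `smoothness` bins per
#' angle step (including the closing step back to the first angle); the
#' optimum over all start bins is found by dynamic programming on the
#' polar graph (a DAG in the angle direction, so Dijkstra reduces to one
#' sweep per candidate start bin). Path cost is the sum of the traversed
#' node costs. Ties are broken toward the smaller mean radius, then the
#' lexicographically smaller radius sequence.
#'
#' @param polar a [PolarImage-class].
#' @param smoothness max radius-bin change per angle step (>= 1).
#' @param kind contour label, `"endo"` or `"epi"`.
#' @param phase phase index stored on the contour.
#' @return a [Contour-class].
#' @export
shortestClosedPath <- function(polar, smoothness = 1, kind = "endo",
                               phase = 0, refine = TRUE) {
  stopifnot(smoothness >= 1)
  if (ncol(polar@cost) < 1) stop("infeasible polar image: no radii")
  res <- .cs_closed_path(polar@cost, as.integer(smoothness))
  radius <- polar@radii[res$radii]
  if (refine && length(polar@radii) >= 3) {
    # sub-bin localization: parabolic interpolation of the cost profile
    # around each chosen bin (bounded to half a bin)
    dr <- polar@radii[2] - polar@radii[1]
    nb <- length(polar@radii)
    for (a in seq_along(radius)) {
      b <- res$radii[a]
      if (b > 1 && b < nb) {
        cm <- polar@cost[a, b - 1]
        c0 <- polar@cost[a, b]
        cp <- polar@cost[a, b + 1]
        den <- cm - 2 * c0 + cp
        if (den > 1e-12) {
          off <- 0.5 * (cm - cp) / den
          radius[a] <- radius[a] + clamp(off, -0.5, 0.5) * dr
        }
      }
    }
  }
  new("Contour", radiusPx = radius, center = polar@center,
      cost = res$cost, kind = kind, phase = phase)
}

# map contour points through fields: seed phase p -> reference -> phase q
propagateContourPoints <- function(rows, cols, fieldP, fieldQ) {
  refR <- rows + .cs_sample_bilinear(fieldP@inverseRow, rows, cols)
  refC <- cols + .cs_sample_bilinear(fieldP@inverseCol, rows, cols)
  list(row = refR + .cs_sample_bilinear(fieldQ@forwardRow, refR, refC),
       col = refC + .cs_sample_bilinear(fieldQ@forwardCol, refR, refC))
}

# resample propagated Cartesian points onto the polar angular grid by
# nearest-angle binning; empty bins filled by circular interpolation
binToPolarGrid <- function(rows, cols, center, nAngles) {
  dr <- rows - center[1]
  dc <- cols - center[2]
  th <- atan2(dr, dc) %% (2 * pi)
  rad <- sqrt(dr^2 + dc^2)
  bin <- (round(th / (2 * pi) * nAngles) %% nAngles) + 1
  out <- rep(NA_real_, nAngles)
  agg <- tapply(rad, bin, mean)
  out[as.integer(names(agg))] <- agg
  if (anyNA(out)) {
    idx <- seq_len(nAngles)
    good <- which(!is.na(out))
    for (i in idx[is.na(out)]) {
      d <- pmin((good - i) %% nAngles, (i - good) %% nAngles)
      out[i] <- mean(out[good[d == min(d)]])
    }
  }
  out
}

# cost of a radius-per-angle contour on a polar cost image (nearest bins)
contourCostOnPolar <- function(radius, polar) {
  nb <- length(polar@radii)
  dr <- polar@radii[2] - polar@radii[1]
  bins <- clamp(round((radius - polar@radii[1]) / dr) + 1, 1, nb)
  sum(polar@cost[cbind(seq_along(radius), bins)])
}

#' Segment one slice with temporally consistent contours
#'
#' For each candidate seed phase, endo- and epicardial contours are
#' extracted on that phase by [shortestClosedPath()] (endocardium searched
#' in `endoBand x radius`, epicardium outside the endocardial path up to
#' `epiBandMax x radius`), propagated to every other phase through the
#' deformation fields, and re-scored on each target phase's polar cost
#' image; the candidate family with the smallest summed cost wins.
#' Epicardium >= endocardium is enforced by radial clamping after
#' propagation.
#'
#' @param slice a [CineSlice-class].
#' @param fields per-phase [DeformationField-class] list from
#'   [registerSliceSeries()].
#' @param models a [RegionModels-class].
#' @param centerRow,centerCol,radiusPx blood-pool localization for the
#'   slice.
#' @param params list of segmentation parameters: `nAngles` (96),
#'   `nRadii` (64), `smoothness` (1), `endoBand` (c(0.3, 1.3)),
#'   `epiBandMax` (2), `epiMarginPx` (2), `seedStride` (1).
#' @return list over phases of `list(endo =, epi =)` [Contour-class]
#'   pairs, with attribute `seedPhase` and `totalCost`.
#' @export
segmentSlice <- function(slice, fields, models, centerRow, centerCol,
                         radiusPx, params = list()) {
  p <- utils::modifyList(list(nAngles = 96, nRadii = 64, smoothness = 1,
                              endoBand = c(0.3, 1.3), epiBandMax = 2,
                              epiMarginPx = 2, seedStride = 1), params)
  n <- dim(slice@frames)[3]
  stopifnot(length(fields) == n)
  center <- c(centerRow, centerCol)
  rMaxImg <- min(centerRow, centerCol, nrow(slice@frames[, , 1]) - 1 -
                   centerRow, ncol(slice@frames[, , 1]) - 1 - centerCol)
  rEndoMax <- min(p$endoBand[2] * radiusPx, rMaxImg)
  rEpiMax <- min(p$epiBandMax * radiusPx, rMaxImg)
  endoPolar <- vector("list", n)
  epiPolar <- vector("list", n)
  for (t in seq_len(n)) {
    ep <- edgePossibility(slice@frames[, , t], models)
    endoPolar[[t]] <- toPolar(ep, center, rEndoMax, p$nAngles, p$nRadii,
                              rMin = p$endoBand[1] * radiusPx)
    epiPolar[[t]] <- toPolar(ep, center, rEpiMax, p$nAngles, p$nRadii,
                             rMin = p$endoBand[1] * radiusPx)
  }
  seeds <- seq(1, n, by = p$seedStride)
  bestTotal <- Inf
  best <- NULL
  violAll <- TRUE
  for (s in seeds) {
    endoS <- shortestClosedPath(endoPolar[[s]], p$smoothness, "endo", s - 1)
    # epicardium: forbid radii inside the endocardial path + margin
    epol <- epiPolar[[s]]
    pen <- epol@cost
    dr <- epol@radii[2] - epol@radii[1]
    for (a in seq_len(p$nAngles)) {
      forbidden <- epol@radii < endoS@radiusPx[a] + p$epiMarginPx
      pen[a, forbidden] <- 1e3
    }
    epolPen <- new("PolarImage", cost = pen, center = epol@center,
                   radii = epol@radii)
    epiS <- shortestClosedPath(epolPen, p$smoothness, "epi", s - 1)
    th <- polarAngles(p$nAngles)
    total <- 0
    fam <- vector("list", n)
    nViol <- 0
    for (q in seq_len(n)) {
      if (q == s) {
        endoR <- endoS@radiusPx
        epiR <- epiS@radiusPx
      } else {
        pe <- propagateContourPoints(
          center[1] + endoS@radiusPx * sin(th),
          center[2] + endoS@radiusPx * cos(th), fields[[s]], fields[[q]])
        pp <- propagateContourPoints(
          center[1] + epiS@radiusPx * sin(th),
          center[2] + epiS@radiusPx * cos(th), fields[[s]], fields[[q]])
        endoR <- binToPolarGrid(pe$row, pe$col, center, p$nAngles)
        epiR <- binToPolarGrid(pp$row, pp$col, center, p$nAngles)
      }
      nViol <- nViol + sum(epiR < endoR)
      epiR <- pmax(epiR, endoR + p$epiMarginPx)
      ce <- contourCostOnPolar(endoR, endoPolar[[q]])
      cp <- contourCostOnPolar(epiR, epiPolar[[q]])
      total <- total + ce + cp
      fam[[q]] <- list(
        endo = new("Contour", radiusPx = endoR, center = center,
                   cost = ce, kind = "endo", phase = q - 1),
        epi = new("Contour", radiusPx = epiR, center = center,
                  cost = cp, kind = "epi", phase = q - 1))
    }
    if (nViol <= 0.10 * n * p$nAngles) violAll <- FALSE
    if (total < bestTotal) {
      bestTotal <- total
      best <- fam
      attr(best, "seedPhase") <- s - 1
      attr(best, "nViolations") <- nViol
    }
  }
  if (violAll)
    stop(algorithmFailure(
      "no contour family keeps the epicardium outside the endocardium",
      stage = "segmentation"))
  attr(best, "totalCost") <- bestTotal
  best
}

#' Segment every accepted slice of a study
#'
#' Runs [registerSliceSeries()] and [segmentSlice()] on each slice with
#' positive localization confidence; the accepted range is the largest
#' contiguous run of such slices. Fully deterministic.
#'
#' @param series a [CineSeries-class].
#' @param loc an [LVLocalization-class] from [detectLVBloodPool()].
#' @param fieldsBySlice optional precomputed list (one entry per
#'   short-axis slice) of per-phase field lists; computed when NULL.
#' @param regParams a [RegistrationParams-class].
#' @param segParams list of [segmentSlice()] parameters.
#' @return a [ContourSet-class].
#' @export
segmentStudy <- function(series, loc, fieldsBySlice = NULL,
                         regParams = registrationParams(),
                         segParams = list()) {
  conf <- loc@table$confidence > 0
  runs <- rle(conf)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  okRuns <- which(runs$values)
  if (!length(okRuns))
    stop(algorithmFailure("no accepted slices", stage = "segmentation"))
  kBest <- okRuns[which.max(runs$lengths[okRuns])]
  accepted <- starts[kBest]:ends[kBest]
  n <- nPhases(series)
  contours <- list()
  total <- 0
  for (s in accepted) {
    slice <- series@shortAxis[[s]]
    fields <- if (!is.null(fieldsBySlice)) fieldsBySlice[[s]] else
      registerSliceSeries(slice, regParams)
    models <- estimateRegionModels(slice, loc@masks[[s]],
                                   loc@table$centerRow[s],
                                   loc@table$centerCol[s],
                                   loc@table$radiusPx[s])
    fam <- tryCatch(
      segmentSlice(slice, fields, models, loc@table$centerRow[s],
                   loc@table$centerCol[s], loc@table$radiusPx[s],
                   segParams),
      AlgorithmFailure = function(e) {
        e$message <- paste0(e$message, " (slice index ",
                            loc@table$slice[s], ")")
        stop(e)
      })
    total <- total + attr(fam, "totalCost")
    contours[[paste0("s", loc@table$slice[s])]] <- fam
  }
  new("ContourSet", contours = contours,
      acceptedSlices = loc@table$slice[accepted], nPhases = n,
      totalCost = total)
}
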