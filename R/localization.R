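#' @include AllClasses.R utils.R
NULL

# temporal standard-deviation map (motion saliency) of a frame stack
temporalSdMap <- function(frames) {
  n <- dim(frames)[3]
  m <- rowMeans(frames, dims = 2)
  m2 <- rowMeans(frames^2, dims = 2)
  sqrt(pmax(m2 - m^2, 0) * n / max(n - 1, 1))
}

#' Score candidate blood-pool components on one cine slice
#'
#' Builds the motion-saliency map (temporal standard deviation), thresholds
#' it by Otsu, thresholds the temporal-maximum image by Otsu within the
#' high-motion region, labels the resulting bright components and scores
#' each as `roundness x brightness x motion`, with roundness
#' `4*pi*area/perimeter^2`, brightness the component's mean temporal-maximum
#' intensity normalized by the image maximum, and motion the component's
#' mean saliency normalized by the saliency maximum.
#'
#' @param slice a [CineSlice-class].
#' @return data.frame with one row per candidate: centerRow, centerCol
#'   (0-based px), radiusPx (equivalent-disk radius of the hole-filled
#'   component), roundness, brightness, motion, score; zero rows when the
#'   slice contains no moving bright object.
#' @export
bloodPoolCandidates <- function(slice) {
  fr <- slice@frames
  empty <- data.frame(centerRow = numeric(0), centerCol = numeric(0),
                      radiusPx = numeric(0), roundness = numeric(0),
                      brightness = numeric(0), motion = numeric(0),
                      score = numeric(0))
  sdMap <- temporalSdMap(fr)
  thMotion <- otsuThreshold(sdMap)
  if (is.na(thMotion)) return(empty)
  motionMask <- sdMap > thMotion
  tmax <- apply(fr, c(1, 2), max)
  vals <- tmax[motionMask]
  if (length(vals) < 10) return(empty)
  thBright <- otsuThreshold(matrix(vals, ncol = 1))
  if (is.na(thBright)) {
    # all moving pixels share one brightness: split against the image floor
    thBright <- (min(vals) + min(tmax)) / 2
    if (!is.finite(thBright) || thBright >= min(vals)) return(empty)
  }
  bright <- tmax > thBright
  labelsImg <- EBImage::bwlabel(EBImage::Image(bright * 1))
  labels <- as.matrix(EBImage::imageData(labelsImg))
  nlab <- max(labels)
  if (nlab == 0) return(empty)
  shp <- EBImage::computeFeatures.shape(labelsImg)
  out <- empty
  for (l in seq_len(nlab)) {
    comp <- labels == l
    area <- shp[l, "s.area"]
    if (area < 9) next
    perim <- max(shp[l, "s.perimeter"], 1)
    roundness <- min(4 * pi * area / perim^2, 1)
    filled <- EBImage::fillHull(EBImage::Image((labels == l) * 1)) > 0
    idx <- which(filled, arr.ind = TRUE)
    motion <- mean(sdMap[comp]) / max(sdMap)
    brightness <- mean(tmax[comp]) / max(tmax)
    out <- rbind(out, data.frame(
      centerRow = mean(idx[, 1]) - 1, centerCol = mean(idx[, 2]) - 1,
      radiusPx = sqrt(sum(filled) / pi), roundness = roundness,
      brightness = brightness, motion = motion,
      score = roundness * brightness * motion))
  }
  out <- out[order(-out$score), , drop = FALSE]
  attr(out, "brightThreshold") <- thBright
  out
}

# reference-phase (phase 0) blood-pool mask around a detected center,
# thresholded at the blood/myocardium level found by the candidate stage
referencePhaseMask <- function(slice, centerRow, centerCol, th) {
  f0 <- slice@frames[, , 1]
  if (is.na(th)) return(matrix(FALSE, nrow(f0), ncol(f0)))
  labels <- as.matrix(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image((f0 > th) * 1))))
  l <- labels[round(centerRow) + 1, round(centerCol) + 1]
  if (l == 0) return(matrix(FALSE, nrow(f0), ncol(f0)))
  as.matrix(EBImage::fillHull(EBImage::Image((labels == l) * 1)) > 0)
}

#' Detect the LV blood pool across the short-axis stack
#'
#' The blood pool is found per slice as a moving, bright, round connected
#' component (see [bloodPoolCandidates()]); the final per-slice choice is
#' the candidate chain maximizing the summed score subject to the
#' cross-slice consistency constraint that adjacent accepted centers lie
#' within `max(radius_px, 10 px)` of each other. Slices with no acceptable
#' candidate get confidence 0.
#'
#' @param series a [CineSeries-class].
#' @return an [LVLocalization-class].
#' @section Errors: raises an `AlgorithmFailure` condition when fewer than
#'   3 slices have positive confidence (the semi-automated fallback path).
#' @export
detectLVBloodPool <- function(series) {
  slices <- series@shortAxis
  cands <- lapply(slices, bloodPoolCandidates)
  S <- length(slices)
  # DP over slices; candidate 0 = "none" with score 0
  nc <- vapply(cands, nrow, integer(1))
  score <- function(s, k) if (k == 0) 0 else cands[[s]]$score[k]
  compatible <- function(s, k, s2, k2) {
    if (k == 0 || k2 == 0) return(TRUE)
    a <- cands[[s]][k, ]; b <- cands[[s2]][k2, ]
    d <- sqrt((a$centerRow - b$centerRow)^2 + (a$centerCol - b$centerCol)^2)
    d <= max(a$radiusPx, b$radiusPx, 10)
  }
  best <- vector("list", S)
  best[[1]] <- list(val = vapply(0:nc[1], function(k) score(1, k),
                                 numeric(1)), prev = rep(NA, nc[1] + 1))
  if (S > 1) for (s in 2:S) {
    val <- numeric(nc[s] + 1); prev <- integer(nc[s] + 1)
    for (k in 0:nc[s]) {
      cv <- -Inf; cp <- 0
      for (k2 in 0:nc[s - 1]) {
        if (!compatible(s, k, s - 1, k2)) next
        v <- best[[s - 1]]$val[k2 + 1]
        if (v > cv) { cv <- v; cp <- k2 }
      }
      val[k + 1] <- cv + score(s, k); prev[k + 1] <- cp
    }
    best[[s]] <- list(val = val, prev = prev)
  }
  choice <- integer(S)
  choice[S] <- which.max(best[[S]]$val) - 1
  if (S > 1) for (s in (S - 1):1)
    choice[s] <- best[[s + 1]]$prev[choice[s + 1] + 1]
  tab <- data.frame(slice = vapply(slices,
                                   function(x) x@geometry@sliceIndex,
                                   numeric(1)),
                    centerRow = NA_real_, centerCol = NA_real_,
                    radiusPx = NA_real_, confidence = 0)
  masks <- vector("list", S)
  for (s in seq_len(S)) {
    if (choice[s] > 0) {
      cc <- cands[[s]][choice[s], ]
      tab$centerRow[s] <- cc$centerRow
      tab$centerCol[s] <- cc$centerCol
      tab$radiusPx[s] <- cc$radiusPx
      tab$confidence[s] <- clamp(cc$score, 0, 1)
      masks[[s]] <- referencePhaseMask(slices[[s]], cc$centerRow,
                                       cc$centerCol,
                                       attr(cands[[s]], "brightThreshold"))
    } else {
      masks[[s]] <- matrix(FALSE, dim(slices[[s]]@frames)[1],
                           dim(slices[[s]]@frames)[2])
    }
  }
  if (sum(tab$confidence > 0) < 3)
    stop(algorithmFailure(
      "blood pool detected on fewer than 3 slices", stage = "localization"))
  new("LVLocalization", table = tab, masks = masks)
}

# cyclic 3-point moving median along the phase axis
movingMedian3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  vapply(seq_len(n), function(i) {
    stats::median(x[c((i - 2) %% n + 1, i, i %% n + 1)])
  }, numeric(1))
}

# anchors of one long-axis view: per phase, the two basal corner points of
# the bright moving cavity, in world mm (2 x 3 x n_phases). axisRC is the
# LV long-axis direction in (row, col) image coordinates (the projection
# of the short-axis stack normal onto this view); when NULL the component's
# principal axis is used instead.
valveAnchorsOneView <- function(slice, axisRC = NULL) {
  fr <- slice@frames
  n <- dim(fr)[3]
  sdMap <- temporalSdMap(fr)
  thMotion <- otsuThreshold(sdMap)
  if (is.na(thMotion)) thMotion <- Inf
  motionMask <- sdMap > thMotion
  # robust temporal maximum: a high quantile over phases, so one
  # corrupted frame cannot dominate the intensity model
  tmax <- apply(fr, c(1, 2), stats::quantile, probs = 0.9, names = FALSE)
  vals <- if (any(motionMask)) tmax[motionMask] else as.vector(tmax)
  thBright <- otsuThreshold(matrix(vals, ncol = 1))
  if (is.na(thBright)) thBright <- stats::quantile(tmax, 0.75)
  anchors <- array(NA_real_, c(2, 3, n))
  for (t in seq_len(n)) {
    mask <- fr[, , t] > thBright
    labels <- as.matrix(EBImage::imageData(
      EBImage::bwlabel(EBImage::Image(mask * 1))))
    nlab <- max(labels)
    if (nlab == 0) next
    sizes <- tabulate(labels[labels > 0], nbins = nlab)
    l <- which.max(sizes)
    idx <- which(labels == l, arr.ind = TRUE) - 1  # 0-based (row, col)
    ctr <- colMeans(idx)
    cen <- sweep(idx, 2, ctr)
    if (is.null(axisRC)) {
      ev <- eigen(stats::cov(cen), symmetric = TRUE)
      major <- ev$vectors[, 1]
    } else {
      major <- axisRC / sqrt(sum(axisRC^2))
    }
    minor <- c(-major[2], major[1])
    proj <- cen %*% major
    # basal end = the extreme with the larger motion saliency (the valve
    # edge moves; the apical cap does not)
    span <- diff(range(proj))
    hi <- idx[proj >= max(proj) - 0.15 * span, , drop = FALSE]
    lo <- idx[proj <= min(proj) + 0.15 * span, , drop = FALSE]
    sdAt <- function(p) mean(sdMap[cbind(p[, 1] + 1, p[, 2] + 1)])
    basal <- if (sdAt(hi) >= sdAt(lo)) "hi" else "lo"
    # flip the axes so "major" points toward the basal end
    if (basal == "lo") { major <- -major; proj <- -proj }
    mproj <- cen %*% minor
    # subpixel threshold-crossing refinement: walk from pixel p outward
    # along unit direction d to where intensity falls through the threshold
    img <- fr[, , t]
    stepOf <- function(v) {
      s <- round(v / max(abs(v)))
      if (all(s == 0)) s <- sign(v)
      s
    }
    refine <- function(p, d) {
      at <- function(q) {
        q <- pmin(pmax(q, 0), c(nrow(img) - 1, ncol(img) - 1))
        img[q[1] + 1, q[2] + 1]
      }
      iIn <- at(p - d); i0 <- at(p); i1 <- at(p + d); i2 <- at(p + 2 * d)
      # half-way level between the inside and outside plateaus: the true
      # (anti-aliased) boundary, independent of the detection threshold
      lvl <- (max(iIn, i0) + i2) / 2
      if (i0 >= lvl && i1 < lvl) return(clamp((i0 - lvl) / (i0 - i1), 0, 1))
      if (i1 >= lvl && i2 < lvl)
        return(1 + clamp((i1 - lvl) / (i1 - i2), 0, 1))
      0
    }
    stepMaj <- stepOf(major)
    if (sum(stepMaj * major) < 0) stepMaj <- -stepMaj
    stepMin <- stepOf(minor)
    # basal edge position: refined major-axis coordinate at the central
    # third of the rim (robust to the cut corners of the thresholded mask)
    minorSpan <- max(abs(mproj))
    rimSel <- proj >= max(proj) - 1.5 & abs(mproj) <= 0.34 * minorSpan
    if (!any(rimSel)) rimSel <- proj >= max(proj) - 1.5
    rim <- idx[rimSel, , drop = FALSE]
    zRef <- stats::median(proj[rimSel] +
                            apply(rim, 1, refine, d = stepMaj) *
                              sum(stepMaj * major))
    # lateral cavity edges: refined minor-axis coordinate in a band a few
    # pixels below the rim, per side
    lateral <- function(sideSign) {
      sMin <- stepMin * sideSign
      if (sum(sMin * minor) * sideSign < 0) sMin <- -sMin
      band <- proj <= max(proj) - 2 & proj >= max(proj) - 6 &
        sign(mproj) == sideSign
      if (!any(band)) band <- sign(mproj) == sideSign
      bandIdx <- idx[band, , drop = FALSE]
      bandM <- mproj[band]
      # outermost pixel per major-axis row
      key <- round(proj[band])
      sel <- vapply(split(seq_along(bandM), key), function(ii)
        ii[which.max(bandM[ii] * sideSign)], integer(1))
      stats::median(bandM[sel] +
                      apply(bandIdx[sel, , drop = FALSE], 1, refine,
                            d = sMin) * sum(sMin * minor))
    }
    m1 <- lateral(-1)
    m2 <- lateral(1)
    p1 <- ctr + zRef * major + m1 * minor
    p2 <- ctr + zRef * major + m2 * minor
    anchors[1, , t] <- pixelToWorld(slice@geometry, p1[1], p1[2])
    anchors[2, , t] <- pixelToWorld(slice@geometry, p2[1], p2[2])
  }
  anchors
}

#' Detect the mitral-valve anchor points on the long-axis views
#'
#' On each long-axis view and phase, the bright moving cavity component is
#' found, its principal axis computed, the basal end identified as the
#' extreme with the larger motion saliency, and the two corner points of
#' the cavity's basal rim taken as valve anchors. Anchor tracks are
#' smoothed with a cyclic 3-phase moving median; a phase whose anchors
#' jump by more than 15 mm from the previous phase is replaced by linear
#' interpolation of its neighbors and flagged.
#'
#' @param series a [CineSeries-class].
#' @return list with `anchors` (4 x 3 x n_phases array of world points:
#'   rows 1-2 from the 2-chamber view, rows 3-4 from the 4-chamber view)
#'   and `flagged` (per-phase logical).
#' @export
detectMitralValvePoints <- function(series) {
  normal <- sliceNormal(series@shortAxis[[1]]@geometry)
  axisFor <- function(slice) {
    g <- slice@geometry
    a <- c(sum(normal * g@rowDir), sum(normal * g@colDir))
    if (sqrt(sum(a^2)) < 0.1) NULL else a
  }
  a2 <- valveAnchorsOneView(series@longAxis2ch,
                            axisFor(series@longAxis2ch))
  a4 <- valveAnchorsOneView(series@longAxis4ch,
                            axisFor(series@longAxis4ch))
  n <- dim(a2)[3]
  anchors <- array(NA_real_, c(4, 3, n))
  anchors[1:2, , ] <- a2
  anchors[3:4, , ] <- a4
  flagged <- rep(FALSE, n)
  # outliers are flagged on the raw per-phase anchors, before smoothing
  jump <- function(t1, t2) {
    max(sqrt(rowSums((anchors[, , t2] - anchors[, , t1])^2)))
  }
  for (t in 2:n) {
    if (anyNA(anchors[, , t]) ||
        (!anyNA(anchors[, , t - 1]) && jump(t - 1, t) > 15))
      flagged[t] <- TRUE
  }
  for (t in which(flagged)) {
    prev <- t - 1
    while (prev >= 1 && flagged[prev]) prev <- prev - 1
    nxt <- t + 1
    while (nxt <= n && flagged[nxt]) nxt <- nxt + 1
    if (prev >= 1 && nxt <= n) {
      w <- (t - prev) / (nxt - prev)
      anchors[, , t] <- (1 - w) * anchors[, , prev] + w * anchors[, , nxt]
    } else if (prev >= 1) anchors[, , t] <- anchors[, , prev]
    else if (nxt <= n) anchors[, , t] <- anchors[, , nxt]
  }
  # cyclic 3-phase moving median as outlier rejection on the repaired
  # tracks: raw positions are kept when they agree with the local median
  # (within 2 mm), so genuine motion extremes are not flattened
  for (k in 1:4) for (d in 1:3) {
    med <- movingMedian3(anchors[k, d, ])
    off <- abs(anchors[k, d, ] - med) > 2
    anchors[k, d, off] <- med[off]
  }
  list(anchors = anchors, flagged = flagged)
}

#' Fit the time-resolved mitral-valve base plane
#'
#' Per phase, the plane minimizing the sum of squared point-to-plane
#' distances over the four anchors (total least squares via the smallest
#' principal component); the unit normal is oriented toward the apex.
#'
#' @param anchors 4 x 3 x n_phases array of world anchor points, or the
#'   list returned by [detectMitralValvePoints()].
#' @param apexToBase world direction from apex to base (the normal is
#'   flipped so its dot product with this axis is negative).
#' @return a [BasePlane-class].
#' @export
fitBasePlane <- function(anchors, apexToBase = c(0, 0, 1)) {
  flagged <- NULL
  if (is.list(anchors)) {
    flagged <- anchors$flagged
    anchors <- anchors$anchors
  }
  stopifnot(length(dim(anchors)) == 3, dim(anchors)[1] == 4,
            dim(anchors)[2] == 3)
  n <- dim(anchors)[3]
  if (is.null(flagged)) flagged <- rep(FALSE, n)
  normals <- matrix(0, n, 3)
  offsets <- numeric(n)
  for (t in seq_len(n)) {
    pts <- anchors[, , t]
    ctr <- colMeans(pts)
    cen <- sweep(pts, 2, ctr)
    ev <- eigen(crossprod(cen), symmetric = TRUE)
    if (ev$values[2] < 1e-6 * max(ev$values[1], 1))
      stop("degenerate anchors: points are collinear")
    nrm <- ev$vectors[, 3]
    if (sum(nrm * apexToBase) > 0) nrm <- -nrm
    normals[t, ] <- nrm
    offsets[t] <- sum(nrm * ctr)
  }
  new("BasePlane", normals = normals, offsets = offsets,
      anchors = anchors, flagged = flagged)
}

#' Sum of squared point-to-plane distances of a fitted base plane
#'
#' @param plane a [BasePlane-class].
#' @param phase 0-based phase.
#' @return the residual sum of squares (mm^2).
#' @export
basePlaneResidual <- function(plane, phase) {
  pts <- plane@anchors[, , phase + 1]
  d <- pts %*% plane@normals[phase + 1, ] - plane@offsets[phase + 1]
  sum(d^2)
}
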