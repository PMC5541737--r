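#' @include AllClasses.R
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Map 0-based pixel indices to world coordinates
#'
#' @param geom a [SliceGeometry-class].
#' @param row,col 0-based pixel indices (possibly fractional).
#' @return n x 3 matrix of world positions (mm).
#' @export
pixelToWorld <- function(geom, row, col) {
  stopifnot(length(row) == length(col))
  sp <- geom@pixelSpacing
  t(geom@origin +
      outer(geom@rowDir, row * sp[1]) + outer(geom@colDir, col * sp[2]))
}

#' Map world coordinates to 0-based pixel indices on a slice plane
#'
#' Projects onto the plane spanned by the slice's direction vectors.
#'
#' @param geom a [SliceGeometry-class].
#' @param xyz n x 3 matrix of world positions (mm).
#' @return data.frame with `row` and `col` (0-based, fractional).
#' @export
worldToPixel <- function(geom, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  d <- sweep(xyz, 2, geom@origin)
  data.frame(row = as.vector(d %*% geom@rowDir) / geom@pixelSpacing[1],
             col = as.vector(d %*% geom@colDir) / geom@pixelSpacing[2])
}

# slice normal (rowDir x colDir)
sliceNormal <- function(geom) {
  r <- geom@rowDir; c <- geom@colDir
  c(r[2] * c[3] - r[3] * c[2], r[3] * c[1] - r[1] * c[3],
    r[1] * c[2] - r[2] * c[1])
}

# world position of the slice center
sliceCenterWorld <- function(geom, shape) {
  as.vector(pixelToWorld(geom, (shape[1] - 1) / 2, (shape[2] - 1) / 2))
}

# effective slab spacing used for Simpson stacking: thickness + gap
sliceSpacing <- function(geom) geom@thickness + geom@gap

# Otsu threshold of a numeric matrix; returns NA for (near-)constant input
otsuThreshold <- function(x) {
  rng <- range(x)
  if (!is.finite(diff(rng)) || diff(rng) < .Machine$double.eps * 100)
    return(NA_real_)
  xs <- (x - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1), levels = 256)
  rng[1] + th * diff(rng)
}

# uniform polar angle grid (radians), n angles over [0, 2*pi)
polarAngles <- function(n) 2 * pi * (seq_len(n) - 1) / n

# Cartesian (row, col) pixel coordinates of a polar contour
contourToCartesian <- function(contour) {
  th <- polarAngles(length(contour@radiusPx))
  data.frame(row = contour@center[1] + contour@radiusPx * sin(th),
             col = contour@center[2] + contour@radiusPx * cos(th))
}

# stable hex digest of an R object via canonical JSON + md5
canonicalHash <- function(x) {
  sortRec <- function(v) {
    if (is.list(v) && !is.null(names(v)))
      lapply(v[order(names(v))], sortRec)
    else v
  }
  js <- jsonlite::toJSON(sortRec(x), auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

#' Pearson product-moment correlation
#'
#' Thin wrapper used by the reproducibility harness.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson: zero variance")
  stats::cor(x, y, method = "pearson")
}
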