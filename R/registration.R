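#' @include AllClasses.R utils.R
NULL

#' Construct registration parameters
#'
#' @param ... named slots of [RegistrationParams-class] to override.
#' @return a validated [RegistrationParams-class].
#' @export
registrationParams <- function(...) new("RegistrationParams", ...)

zeroField <- function(shape, flagged = FALSE) {
  z <- matrix(0, shape[1], shape[2])
  new("DeformationField", forwardRow = z, forwardCol = z,
      inverseRow = z, inverseCol = z, flagged = flagged)
}

# blur + decimate by 2
downsample2 <- function(img) {
  img <- .cs_gauss_blur(img, 1.0)
  img[seq(1, nrow(img), by = 2), seq(1, ncol(img), by = 2), drop = FALSE]
}

# bilinear resize of a matrix to a target shape
resizeBilinear <- function(m, shape) {
  sr <- if (shape[1] > 1) (nrow(m) - 1) / (shape[1] - 1) else 0
  sc <- if (shape[2] > 1) (ncol(m) - 1) / (shape[2] - 1) else 0
  rows <- rep((seq_len(shape[1]) - 1) * sr, times = shape[2])
  cols <- rep((seq_len(shape[2]) - 1) * sc, each = shape[1])
  matrix(.cs_sample_bilinear(m, rows, cols), shape[1], shape[2])
}

# one pyramid level of local-cross-correlation gradient descent
lccDescend <- function(fixed, moving, ur, uc, params) {
  hw <- (params@ccWindowPx - 1) / 2
  eps <- 1e-8
  for (it in seq_len(params@nIterationsPerLevel)) {
    mw <- .cs_warp(moving, ur, uc)
    g <- .cs_gradient(mw)
    fb <- .cs_box_mean(fixed, hw)
    mb <- .cs_box_mean(mw, hw)
    A <- .cs_box_mean(fixed * mw, hw) - fb * mb
    B <- .cs_box_mean(fixed * fixed, hw) - fb * fb
    C <- .cs_box_mean(mw * mw, hw) - mb * mb
    denom <- B * C
    # variance floor relative to the strongest local contrast: windows
    # whose variance is negligible against it carry no reliable
    # correlation signal and get zero force
    ok <- B > pmax(1e-4 * max(B), eps) & C > pmax(1e-4 * max(C), eps)
    scal <- ifelse(ok,
                   2 * A / denom * ((fixed - fb) - (A / C) * (mw - mb)), 0)
    fr <- scal * g$dr
    fc <- scal * g$dc
    mag <- sqrt(fr * fr + fc * fc)
    mx <- max(mag)
    if (mx < eps) break
    fr <- fr * (params@stepSizePx / mx)
    fc <- fc * (params@stepSizePx / mx)
    fr <- .cs_gauss_blur(fr, params@updateSigmaPx)
    fc <- .cs_gauss_blur(fc, params@updateSigmaPx)
    ur <- .cs_gauss_blur(ur + fr, params@smoothingSigmaPx)
    uc <- .cs_gauss_blur(uc + fc, params@smoothingSigmaPx)
    if (mean(sqrt(fr * fr + fc * fc)) < params@convergenceTol) break
  }
  list(ur = ur, uc = uc)
}

#' Register one image pair by inverse-consistent local cross-correlation
#'
#' Iterative non-rigid registration: at each step the analytic gradient of
#' the windowed cross-correlation with respect to the displacement is taken
#' as a force field, a normalized gradient-descent step is applied, the
#' update and the accumulated field are Gaussian-smoothed (the discretized
#' PDE regularization), and the inverse field is re-estimated by the
#' fixed-point update `inv(x) <- -fwd(x + inv(x))`. The scheme is run
#' coarse-to-fine over a Gaussian pyramid and is fully deterministic.
#'
#' The returned forward displacement maps fixed-frame coordinates to
#' moving-frame coordinates: `moving(x + u(x)) ~ fixed(x)`.
#'
#' @param fixed,moving numeric matrices of the same shape.
#' @param params a [RegistrationParams-class].
#' @return a [DeformationField-class]; for constant images a zero field is
#'   returned with `flagged = TRUE`.
#' @export
registerPair <- function(fixed, moving, params = registrationParams()) {
  stopifnot(all(dim(fixed) == dim(moving)), all(is.finite(fixed)),
            all(is.finite(moving)))
  if (stats::sd(fixed) < 1e-12 || stats::sd(moving) < 1e-12) {
    warning("constant image: returning zero deformation field")
    return(zeroField(dim(fixed), flagged = TRUE))
  }
  nLev <- max(1, min(params@nPyramidLevels,
                     floor(log2(min(dim(fixed)) / 16)) + 1))
  pyrF <- list(fixed); pyrM <- list(moving)
  for (l in seq_len(nLev - 1)) {
    pyrF[[l + 1]] <- downsample2(pyrF[[l]])
    pyrM[[l + 1]] <- downsample2(pyrM[[l]])
  }
  ur <- matrix(0, nrow(pyrF[[nLev]]), ncol(pyrF[[nLev]]))
  uc <- ur
  for (l in rev(seq_len(nLev))) {
    if (l < nLev) {
      shape <- dim(pyrF[[l]])
      fac <- (shape - 1) / (dim(ur) - 1)
      ur <- resizeBilinear(ur, shape) * fac[1]
      uc <- resizeBilinear(uc, shape) * fac[2]
    }
    res <- lccDescend(pyrF[[l]], pyrM[[l]], ur, uc, params)
    ur <- res$ur; uc <- res$uc
  }
  inv <- .cs_invert_field(ur, uc, params@invertIterations)
  new("DeformationField", forwardRow = ur, forwardCol = uc,
      inverseRow = inv$ur, inverseCol = inv$uc, flagged = FALSE)
}

composeDisp <- function(a, b) .cs_compose(a$ur, a$uc, b$ur, b$uc)

fieldFromDisp <- function(d, invertIterations = 5, flagged = FALSE) {
  inv <- .cs_invert_field(d$ur, d$uc, invertIterations)
  new("DeformationField", forwardRow = d$ur, forwardCol = d$uc,
      inverseRow = inv$ur, inverseCol = inv$uc, flagged = flagged)
}

#' Register a full cine slice: per-phase fields anchored at phase 0
#'
#' Two passes of sequential neighbor-pair registrations are composed: pass
#' A chains phase 0 forward in time, pass B reaches each phase backward
#' through the cycle end (closing the loop with a phase 0 to last-phase
#' registration). The final per-phase displacement is the arithmetic
#' average of the two passes' displacement fields, which makes the
#' recovered motion pattern cyclic; the inverse is re-derived from the
#' averaged forward field.
#'
#' @param slice a [CineSlice-class] with at least 2 phases.
#' @param params a [RegistrationParams-class].
#' @return list of [DeformationField-class], one per phase (phase 0 is the
#'   identity); attribute `cycleResidual` holds the mean magnitude (px) of
#'   the full-cycle composed field, a measure of cyclicity.
#' @export
registerSliceSeries <- function(slice, params = registrationParams()) {
  fr <- slice@frames
  n <- dim(fr)[3]
  stopifnot(n >= 2)
  shape <- dim(fr)[1:2]
  flagged <- FALSE
  reg <- function(i, j) {  # displacement mapping phase i coords -> phase j
    f <- withCallingHandlers(
      registerPair(fr[, , i + 1], fr[, , j + 1], params),
      warning = function(w) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    list(ur = f@forwardRow, uc = f@forwardCol)
  }
  zero <- list(ur = matrix(0, shape[1], shape[2]),
               uc = matrix(0, shape[1], shape[2]))
  # pass A: 0 -> t by chaining neighbor pairs forward
  passA <- vector("list", n)
  passA[[1]] <- zero
  for (t in seq_len(n - 1))
    passA[[t + 1]] <- composeDisp(passA[[t]], reg(t - 1, t))
  # pass B: 0 -> t through the cycle end (0 -> n-1 -> ... -> t)
  passB <- vector("list", n)
  passB[[n]] <- reg(0, n - 1)
  if (n > 2)
    for (t in rev(seq_len(n - 2)))
      passB[[t + 1]] <- composeDisp(passB[[t + 2]], reg(t + 1, t))
  rawCycle <- composeDisp(passB[[2]], reg(1, 0))
  fields <- vector("list", n)
  fields[[1]] <- zeroField(shape, flagged = flagged)
  for (t in seq_len(n - 1)) {
    avg <- list(ur = (passA[[t + 1]]$ur + passB[[t + 1]]$ur) / 2,
                uc = (passA[[t + 1]]$uc + passB[[t + 1]]$uc) / 2)
    fields[[t + 1]] <- fieldFromDisp(avg, params@invertIterations, flagged)
  }
  cyc <- zero
  for (t in seq_len(n))
    cyc <- composeDisp(cyc, incrementDisp(fields, t - 1))
  attr(fields, "cycleResidual") <- mean(sqrt(cyc$ur^2 + cyc$uc^2))
  attr(fields, "rawChainResidual") <- mean(sqrt(rawCycle$ur^2 +
                                                  rawCycle$uc^2))
  fields
}

# displacement increment phase t -> t+1 (cyclic) derived from the
# phase-0-anchored family: w(x) = u_{t+1}(y) - u_t(y) at y = x + inv_t(x),
# which equals compose(inv_t, fwd_{t+1})
incrementDisp <- function(fields, t) {
  n <- length(fields)
  a <- fields[[t + 1]]
  b <- fields[[(t + 1) %% n + 1]]
  .cs_compose(a@inverseRow, a@inverseCol, b@forwardRow, b@forwardCol)
}

#' Warp an image through a deformation field
#'
#' Bilinear interpolation; out-of-bounds samples take the nearest edge
#' value. `direction = "forward"` resamples with the forward displacement
#' (pulling the target frame back onto the reference grid when the field
#' maps reference to target coordinates); `"inverse"` uses the inverse.
#'
#' @param image numeric matrix.
#' @param field a [DeformationField-class] of matching shape.
#' @param direction `"forward"` or `"inverse"`.
#' @return the warped matrix.
#' @export
warpImage <- function(image, field, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  stopifnot(all(dim(image) == dim(field@forwardRow)))
  if (direction == "forward")
    .cs_warp(image, field@forwardRow, field@forwardCol)
  else
    .cs_warp(image, field@inverseRow, field@inverseCol)
}

#' Inverse-consistency residual of a deformation field
#'
#' Mean magnitude (px) of `inv(x) + fwd(x + inv(x))`, i.e. the deviation
#' of forward-after-inverse from the identity.
#'
#' @param field a [DeformationField-class].
#' @return mean residual in pixels.
#' @export
inverseConsistencyResidual <- function(field) {
  res <- .cs_compose(field@inverseRow, field@inverseCol,
                     field@forwardRow, field@forwardCol)
  mean(sqrt(res$ur^2 + res$uc^2))
}
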