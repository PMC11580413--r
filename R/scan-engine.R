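# Imaging procedure: first-contact (zero-force) topography by grayscale
# dilation with the tip shape, force volumes over (x, y, z) tip positions,
# and constant-force image extraction.

#' @useDynLib softAFM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Largest lateral offset at which a feature can touch the tip
#'
#' Inverts the tip profile at height \code{hMax}: a sample feature of height
#' at most \code{hMax} can only contact the tip within this radius of the
#' tip axis, which bounds the search in the closest-vertical-distance
#' computation.
#'
#' @param tip a \linkS4class{TipGeometry}.
#' @param hMax maximum feature height (nm), >= 0.
#' @return Lateral radius (nm).
#' @export
boundaryRadius <- function(tip, hMax) {
  if (any(hMax < 0)) stop("hMax must be nonnegative")
  R <- tip@R
  theta <- tip@theta
  z_t <- R * (1 - sin(theta))
  ifelse(hMax <= z_t,
         sqrt(pmax(hMax * (2 * R - hMax), 0)),
         R * cos(theta) + (hMax - z_t) * tan(theta))
}

#' Apex height at first tip-sample contact
#'
#' For a lateral tip position, the closest vertical approach before touching
#' the sample: the maximum over sample cells of (sample height - tip profile
#' at the cell's lateral offset), floored at 0 where the substrate is hit
#' first. This equals the grayscale dilation of the height field by the
#' reflected tip shape. Only cells within \code{\link{boundaryRadius}} of
#' the axis can contribute and are searched.
#'
#' @param tip a \linkS4class{TipGeometry}.
#' @param sample a \linkS4class{HeightField}.
#' @param position lateral position \code{c(x, y)} (nm) or an n x 2 matrix.
#' @return Apex height(s) at first contact (nm).
#' @export
closestVerticalDistance <- function(tip, sample, position) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  rhoB <- boundaryRadius(tip, max(sample@heights))
  z <- cvd_scan(sample@x, sample@y, sample@heights, tip@R, tip@theta,
                pos, rhoB)
  if (is.matrix(position)) z else z[1]
}

#' Zero-force (unindented) AFM topography
#'
#' The trajectory of the tip apex over the rigid, undeformed sample: the
#' dilation of the surface by the tip shape. This is the zero-indentation
#' limit of the imaging model and isolates pure tip-convolution broadening.
#'
#' @param tip a \linkS4class{TipGeometry}.
#' @param sample a \linkS4class{HeightField}.
#' @param scanX,scanY scan-grid node positions (nm); default the sample grid.
#' @return An \linkS4class{AFMImage} with \code{mode = "zero-force"}.
#' @export
zeroForceTopography <- function(tip, sample, scanX = NULL, scanY = NULL) {
  if (is.null(scanX)) scanX <- sample@x
  if (is.null(scanY)) scanY <- sample@y
  pos <- as.matrix(expand.grid(x = scanX, y = scanY))
  z <- closestVerticalDistance(tip, sample, pos)
  AFMImage(scanX, scanY, matrix(z, length(scanX), length(scanY)),
           mode = "zero-force",
           metadata = list(tip = tip, sample = sample@metadata))
}

#' Default indentation grid
#'
#' Zero followed by geometrically spaced depths up to \code{fraction * R}
#' (default the spherical-validity limit 0.65 R).
#'
#' @param tip a \linkS4class{TipGeometry}.
#' @param n number of points including zero; default 30.
#' @param fraction maximum depth as a fraction of R; default 0.65.
#' @return Indentation depths (nm).
#' @export
defaultDeltaGrid <- function(tip, n = 30L, fraction = 0.65) {
  dmax <- fraction * tip@R
  c(0, exp(seq(log(dmax / 200), log(dmax), length.out = n - 1L)))
}

#' Sample tip-sample forces over three-dimensional tip positions
#'
#' For every lateral scan position, the apex is lowered from its
#' first-contact height through the indentation grid and the vertical force
#' evaluated by the selected engine, yielding F(x, y, z) ready for
#' constant-force contour extraction.
#'
#' @param sample a \linkS4class{HeightField}.
#' @param tip a \linkS4class{TipGeometry}.
#' @param material a \linkS4class{Material}.
#' @param scanX,scanY scan-grid node positions (nm); default the sample grid.
#' @param deltaGrid indentation depths (nm) starting at 0; default
#'   \code{\link{defaultDeltaGrid}}.
#' @param engine \code{"local-analytic"} or \code{"halfspace"}
#'   (see \code{\link{forceCurveAt}}).
#' @param ... passed to \code{\link{forceCurveAt}}.
#' @return A \linkS4class{ForceVolume}.
#' @export
buildForceVolume <- function(sample, tip, material, scanX = NULL, scanY = NULL,
                             deltaGrid = NULL,
                             engine = c("local-analytic", "halfspace"), ...) {
  engine <- match.arg(engine)
  if (is.null(scanX)) scanX <- sample@x
  if (is.null(scanY)) scanY <- sample@y
  if (is.null(deltaGrid)) deltaGrid <- defaultDeltaGrid(tip)
  pos <- as.matrix(expand.grid(x = scanX, y = scanY))
  zc <- closestVerticalDistance(tip, sample, pos)
  F <- matrix(0, nrow(pos), length(deltaGrid))
  for (k in seq_len(nrow(pos))) {
    fc <- tryCatch(
      forceCurveAt(sample, tip, material, pos[k, ], deltaGrid,
                   engine = engine, ...),
      error = function(e) stop(sprintf(
        "force engine failed at x = %.4g, y = %.4g: %s",
        pos[k, 1], pos[k, 2], conditionMessage(e))))
    F[k, ] <- fc@force
  }
  new("ForceVolume", positions = pos, firstContact = zc, delta = deltaGrid,
      force = F, tip = tip, material = material, engine = engine,
      metadata = list(scanX = scanX, scanY = scanY, sample = sample@metadata))
}

#' Extract a constant-force AFM image from a force volume
#'
#' Per scan position, the apex height at which the vertical force equals the
#' set-point is located on a monotone (shape-preserving) cubic interpolant of
#' F(delta); the image height is first-contact height minus that
#' indentation. Columns whose sampled force never reaches the set-point are
#' flagged saturated and mapped to the substrate-contact floor. Optionally
#' the height map is resampled laterally with bicubic (tensor-product
#' cubic-spline) interpolation.
#'
#' @param volume a \linkS4class{ForceVolume}.
#' @param setpoint force set-point: pN, or F/(E* R^2) when
#'   \code{dimensionless = TRUE}.
#' @param dimensionless interpret \code{setpoint} as F/(E* R^2).
#' @param upsample integer lateral resampling factor (1 = off).
#' @return An \linkS4class{AFMImage} with \code{mode = "iso-force"}.
#' @export
isoforceImage <- function(volume, setpoint, dimensionless = FALSE,
                          upsample = 1L) {
  spAbs <- if (dimensionless) {
    setpoint * reducedModulus(volume@material) * volume@tip@R^2
  } else {
    setpoint
  }
  n <- nrow(volume@positions)
  d <- volume@delta
  hgt <- numeric(n)
  sat <- logical(n)
  for (k in seq_len(n)) {
    Fk <- cummax(volume@force[k, ])
    if (spAbs <= 0) {
      hgt[k] <- volume@firstContact[k]
    } else if (spAbs > max(Fk)) {
      sat[k] <- TRUE
      hgt[k] <- 0  # substrate-contact floor
    } else {
      # monotone cubic in z (equivalently in delta), then root-find
      keep <- c(TRUE, diff(Fk) > 0)
      sp <- splinefun(d[keep], Fk[keep], method = "hyman")
      dstar <- uniroot(function(dd) sp(dd) - spAbs,
                       range(d[keep]), tol = 1e-12)$root
      hgt[k] <- volume@firstContact[k] - dstar
    }
  }
  if (sum(sat) > 0)
    warning(sprintf("%d column(s) saturated: setpoint above sampled force range",
                    sum(sat)))
  sx <- volume@metadata$scanX
  sy <- volume@metadata$scanY
  H <- matrix(hgt, length(sx), length(sy))
  S <- matrix(sat, length(sx), length(sy))
  if (upsample > 1L) {
    rs <- bicubicResample(sx, sy, H, as.integer(upsample))
    sx <- rs$x
    sy <- rs$y
    H <- rs$z
    S <- matrix(FALSE, length(sx), length(sy))
  }
  AFMImage(sx, sy, H, setpoint = spAbs, mode = "iso-force", saturated = S,
           metadata = list(tip = volume@tip, material = volume@material,
                           engine = volume@engine,
                           setpointRel = spAbs /
                             (reducedModulus(volume@material) * volume@tip@R^2)))
}

# Tensor-product cubic-spline resampling of a height map.
bicubicResample <- function(x, y, z, factor) {
  xo <- seq(min(x), max(x), length.out = (length(x) - 1L) * factor + 1L)
  if (length(y) > 1L) {
    yo <- seq(min(y), max(y), length.out = (length(y) - 1L) * factor + 1L)
    tmp <- apply(z, 2, function(col) splinefun(x, col, method = "natural")(xo))
    out <- t(apply(tmp, 1, function(row) splinefun(y, row, method = "natural")(yo)))
  } else {
    yo <- y
    out <- matrix(splinefun(x, z[, 1], method = "natural")(xo), ncol = 1L)
  }
  list(x = xo, y = yo, z = out)
}
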