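# Quantification of simulated images and force data: apparent width (FWHM),
# apparent volume, cosine-series content of periodic profiles, and apparent
# Young's moduli from force-curve fits.

#' Full width at half maximum of a profile
#'
#' The width of the half-maximum crossing around the profile's unique global
#' maximum, with sub-grid linear interpolation. The baseline is the
#' substrate level (0), not the profile minimum, matching
#' feature-on-substrate usage.
#'
#' @param profile numeric heights (nm), or a data.frame with columns
#'   \code{x} and \code{height}.
#' @param x node positions (nm) when \code{profile} is numeric; default
#'   unit spacing.
#' @return Width (nm).
#' @examples
#' x <- seq(-5, 5, by = 0.01)
#' fwhm(data.frame(x = x, height = pmax(5^2 - x^2, 0)^0.5))  # ~5 sqrt(3)
#' @export
fwhm <- function(profile, x = NULL) {
  if (is.data.frame(profile)) {
    x <- profile$x
    h <- profile$height
  } else {
    h <- as.numeric(profile)
    if (is.null(x)) x <- seq_along(h)
  }
  if (max(h) <= 0) stop("profile never rises above the baseline")
  half <- max(h) / 2
  imax <- which.max(h)
  crossing <- function(idx) {
    # first half-max crossing walking outward from the maximum
    for (k in seq_along(idx)[-1]) {
      i0 <- idx[k - 1]
      i1 <- idx[k]
      if ((h[i0] - half) * (h[i1] - half) <= 0 && h[i0] != h[i1])
        return(x[i0] + (half - h[i0]) * (x[i1] - x[i0]) / (h[i1] - h[i0]))
    }
    x[idx[length(idx)]]  # never crosses: clip at profile edge
  }
  left <- crossing(rev(seq_len(imax)))
  right <- crossing(seq(imax, length(h)))
  right - left
}

#' Apparent volume of an imaged feature
#'
#' Trapezoidal integral of the height map over its above-baseline footprint,
#' as in grain-size analysis of AFM data. The footprint is either every
#' pixel above the substrate (\code{"full"}) or the region above half the
#' maximum height (\code{"halfmax"}).
#'
#' @param image an \linkS4class{AFMImage} or \linkS4class{HeightField}.
#' @param footprint footprint rule.
#' @return Volume (nm^3).
#' @export
apparentVolume <- function(image, footprint = c("full", "halfmax")) {
  footprint <- match.arg(footprint)
  x <- image@x
  y <- image@y
  h <- image@heights
  if (length(y) < 2L) stop("apparentVolume needs a two-dimensional image")
  thr <- if (footprint == "full") 0 else max(h) / 2
  hm <- h
  hm[hm <= thr] <- 0
  if (all(hm == 0)) {
    warning("empty footprint")
    return(0)
  }
  rowInt <- apply(hm, 1, function(row) pracma::trapz(y, row))
  pracma::trapz(x, rowInt)
}

#' Cosine-series coefficients of a periodic profile
#'
#' Projects one period of a uniformly sampled profile onto the cosine series
#' h(x) = A_0 + sum_{n>=1} A_n cos(2 pi n x / lambda_1). The profile must be
#' symmetric about x = 0 for the sine content to vanish; A_0 is the mean
#' offset. If the sampling includes both period endpoints the duplicate is
#' dropped.
#'
#' @param profile data.frame with \code{x}, \code{height}, or numeric heights.
#' @param x node positions (nm) when \code{profile} is numeric.
#' @param N truncation order; default 50.
#' @param period fundamental wavelength (nm); default \code{length(h) * dx}.
#'   When the samples span the full period inclusive of both endpoints the
#'   duplicate last sample is dropped.
#' @return A \linkS4class{FourierSpectrum}.
#' @export
fourierCoefficients <- function(profile, x = NULL, N = 50L, period = NULL) {
  if (is.data.frame(profile)) {
    x <- profile$x
    h <- profile$height
  } else {
    h <- as.numeric(profile)
    if (is.null(x)) stop("x positions are required")
  }
  d <- diff(x)
  if (any(d <= 0) || (max(d) - min(d)) > 1e-8 * max(d))
    stop("profile must be uniformly sampled")
  dx <- d[1]
  if (is.null(period)) {
    period <- length(h) * dx
  } else if (abs((x[length(x)] - x[1]) - period) < dx / 2) {
    # both period endpoints sampled: drop the duplicate
    h <- h[-length(h)]
    x <- x[-length(x)]
  }
  if (abs(length(h) * dx - period) > dx / 2)
    stop("samples must cover exactly one period")
  M <- length(h)
  if (M < 2L * N + 2L)
    warning("fewer than 2N + 2 samples per period; high orders may alias")
  A <- numeric(N + 1L)
  A[1] <- mean(h)
  for (n in seq_len(N))
    A[n + 1L] <- (2 / M) * sum(h * cos(2 * pi * n * x / period))
  new("FourierSpectrum", A = A, lambda1 = period, N = as.integer(N))
}

#' Reconstruct a profile from its cosine series
#'
#' @param spectrum a \linkS4class{FourierSpectrum}.
#' @param x positions (nm).
#' @return Heights (nm).
#' @export
reconstructProfile <- function(spectrum, x) {
  out <- rep(spectrum@A[1], length(x))
  for (n in seq_len(spectrum@N))
    out <- out + spectrum@A[n + 1L] * cos(2 * pi * n * x / spectrum@lambda1)
  out
}

#' Aggregate magnitude of higher-order Fourier content
#'
#' Summarizes the amplitudes A_2..A_N: an ideal image of a pure sinusoid has
#' zero higher-order content, while tip convolution and indentation inject
#' harmonics. Default aggregator is the root mean square; \code{"rss"} gives
#' the root sum of squares.
#'
#' @param spectrum a \linkS4class{FourierSpectrum}.
#' @param N highest order included; default the spectrum's order (>= 2).
#' @param method aggregator.
#' @return Scalar magnitude (nm).
#' @export
higherOrderContent <- function(spectrum, N = spectrum@N,
                               method = c("rms", "rss")) {
  method <- match.arg(method)
  if (N < 2L) stop("N must be >= 2")
  N <- min(N, spectrum@N)
  a <- spectrum@A[3:(N + 1L)]
  switch(method,
         rms = sqrt(mean(a^2)),
         rss = sqrt(sum(a^2)))
}

# Model force at E = 1 MPa (all laws are linear in E*, so this is an exact
# template for the one-parameter fit).
modelTemplate <- function(model, delta, R, theta, r, nu) {
  m1 <- Material(1, nu)
  switch(model,
         hertz = hertzForce(m1, R, delta, r = r),
         sneddon = sneddonForce(m1, TipGeometry(R, theta), delta, r = r),
         double_contact = doubleContactForce(m1, R, r, delta))
}

#' Fit an apparent Young's modulus to a force curve
#'
#' Least-squares fit of the selected contact model with the Young's modulus
#' as the only free parameter (R, theta, r fixed), minimized over log E to
#' enforce positivity. Following common AFM practice, the Hertz fit defaults
#' to the tip radius R in place of the effective radius R* (\code{r = Inf});
#' pass a finite \code{r} to use the true R*, and \code{model =
#' "double_contact"} requires finite \code{r}. Points are optionally clipped
#' to a dimensionless force ceiling F/(E_ref* R^2) computed with a reference
#' material (closed interval).
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param model contact model.
#' @param R tip radius (nm).
#' @param theta cone half-angle (radians), for the Sneddon model.
#' @param r sample radius of curvature (nm); \code{Inf} unless stated.
#' @param nu Poisson ratio assumed in the fit; default 0.3.
#' @param forceCeilingRel optional ceiling on F/(E_ref* R^2).
#' @param refMaterial reference \linkS4class{Material} for the ceiling.
#' @return List with \code{E} (MPa), \code{residual} (sum of squares, pN^2),
#'   \code{n} points used, and \code{model}.
#' @examples
#' m <- Material(100, 0.3)
#' d <- seq(0, 0.5, length.out = 20)[-1]
#' fitModulus(ForceCurve(d, hertzForce(m, 2, d)), "hertz", R = 2)$E  # 100
#' @export
fitModulus <- function(curve, model = c("hertz", "sneddon", "double_contact"),
                       R, theta = 20 * pi / 180, r = Inf, nu = 0.3,
                       forceCeilingRel = NULL, refMaterial = NULL) {
  model <- match.arg(model)
  if (model == "double_contact" && !is.finite(r))
    stop("double_contact requires finite r")
  delta <- curve@delta
  F <- curve@force
  if (!is.null(forceCeilingRel)) {
    if (is.null(refMaterial)) stop("forceCeilingRel needs refMaterial")
    keep <- F / (reducedModulus(refMaterial) * R^2) <= forceCeilingRel
    delta <- delta[keep]
    F <- F[keep]
  }
  if (length(delta) < 5L) stop("need at least 5 points below the force ceiling")
  tmpl <- modelTemplate(model, delta, R, theta, r, nu)
  ssr <- function(logE) sum((F - exp(logE) * tmpl)^2)
  opt <- optimize(ssr, interval = log(c(1e-6, 1e9)), tol = 1e-12)
  list(E = exp(opt$minimum), residual = opt$objective, n = length(delta),
       model = model)
}

#' Apparent Young's modulus versus scan position
#'
#' Fits \code{\link{fitModulus}} to every scan position of a force volume,
#' clipping each curve to a dimensionless force ceiling computed with the
#' volume's generating material. Positions whose fit fails (too few points
#' under the ceiling) are recorded with \code{NA} rather than aborting the
#' map.
#'
#' @param volume a \linkS4class{ForceVolume}.
#' @param model contact model for the fit.
#' @param forceCeilingRel ceiling on F/(E* R^2); default 0.1.
#' @param r sample radius of curvature passed to the fit; default \code{Inf}
#'   (Hertz-with-R convention).
#' @return data.frame with columns \code{x}, \code{y}, \code{E_AFM},
#'   \code{residual}, \code{n}; attributes \code{model} and
#'   \code{forceCeilingRel}.
#' @export
modulusMap <- function(volume, model = "hertz", forceCeilingRel = 0.1,
                       r = Inf) {
  pos <- volume@positions
  out <- data.frame(x = pos[, 1], y = pos[, 2], E_AFM = NA_real_,
                    residual = NA_real_, n = NA_integer_)
  for (k in seq_len(nrow(pos))) {
    fit <- tryCatch(
      fitModulus(forceCurve(volume, k), model, R = volume@tip@R,
                 theta = volume@tip@theta, r = r,
                 nu = volume@material@nu,
                 forceCeilingRel = forceCeilingRel,
                 refMaterial = volume@material),
      error = function(e) NULL)
    if (!is.null(fit)) {
      out$E_AFM[k] <- fit$E
      out$residual[k] <- fit$residual
      out$n[k] <- fit$n
    }
  }
  attr(out, "model") <- model
  attr(out, "forceCeilingRel") <- forceCeilingRel
  out
}
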