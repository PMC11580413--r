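# Closed-form and semi-analytic force-indentation laws: Hertz sphere contact,
# conical Sneddon with a pluggable spherical-sample correction, and the
# double-contact (series-compliance) model for supported spheres.

#' Effective contact radius of tip and sample
#'
#' 1/R* = 1/R + 1/r; \code{r = Inf} describes a locally flat sample
#' (R* = R).
#'
#' @param R tip radius (nm).
#' @param r sample radius of curvature (nm), possibly \code{Inf}.
#' @return R* (nm).
#' @export
effectiveRadius <- function(R, r = Inf) {
  if (R <= 0) stop("R must be positive")
  if (!is.infinite(r) && r <= 0) stop("r must be positive or Inf")
  1 / (1 / R + 1 / r)
}

#' Hertz sphere-indentation force
#'
#' F = (4/3) E* sqrt(R*) delta^(3/2), the Hertz law for a rigid sphere of
#' radius R pressed into an elastic surface of local radius r, with
#' effective radius 1/R* = 1/R + 1/r and reduced modulus E* = E/(1 - nu^2).
#' Units: nm, MPa, pN (1 MPa nm^2 = 1 pN).
#'
#' @param material a \linkS4class{Material}.
#' @param R tip radius (nm).
#' @param delta indentation (nm), nonnegative; vectorized.
#' @param r sample radius of curvature (nm); default \code{Inf} (flat).
#' @return Force (pN).
#' @examples
#' hertzForce(Material(100, 0.3), R = 10, delta = 0.5)
#' @export
hertzForce <- function(material, R, delta, r = Inf) {
  if (any(delta < 0)) stop("delta must be nonnegative")
  Rstar <- effectiveRadius(R, r)
  (4 / 3) * reducedModulus(material) * sqrt(Rstar) * delta^1.5
}

# Hertz inverse: indentation producing force F at effective radius Reff.
hertzDelta <- function(material, Reff, F) {
  (3 * F / (4 * reducedModulus(material) * sqrt(Reff)))^(2 / 3)
}

#' Conical Sneddon force with spherical-sample correction
#'
#' F = (2/pi) E* tan(theta) delta^2 f(delta): the rigid-cone Sneddon law,
#' multiplied by an empirical correction f(delta) that adapts the cone model
#' to samples of finite radius of curvature r. The correction is supplied as
#' a function \code{f(delta, R = NA, r = NA)}; the default \code{f = NULL}
#' means f = 1, the exact Sneddon law for a flat sample (r -> Inf).
#'
#' @param material a \linkS4class{Material}.
#' @param tip a \linkS4class{TipGeometry} (only the cone angle is used).
#' @param delta indentation (nm), nonnegative; vectorized.
#' @param r sample radius of curvature (nm); default \code{Inf}.
#' @param f optional correction function of \code{(delta, R, r)}.
#' @return Force (pN).
#' @export
sneddonForce <- function(material, tip, delta, r = Inf, f = NULL) {
  if (any(delta < 0)) stop("delta must be nonnegative")
  if (!is.infinite(r) && r <= 0) stop("r must be positive or Inf")
  base <- (2 / pi) * reducedModulus(material) * tan(tip@theta) * delta^2
  if (is.null(f) || is.infinite(r)) return(base)
  base * f(delta, R = tip@R, r = r)
}

#' Double-contact forward displacement
#'
#' Total measured displacement delta(F) = delta_I(F) + delta_C(F) for a
#' transmitted force F carried in series by two Hertzian contacts: the
#' tip-sample contact (effective radius \code{RI}) and the sample-substrate
#' contact (effective radius \code{RC}). Both contacts use the sample's
#' reduced modulus (tip and substrate rigid).
#'
#' @param material a \linkS4class{Material}.
#' @param F transmitted force (pN); vectorized.
#' @param RI effective radius of the tip-sample contact (nm).
#' @param RC effective radius of the sample-substrate contact (nm).
#' @return List with \code{delta}, \code{deltaI}, \code{deltaC} (nm).
#' @export
doubleContactDelta <- function(material, F, RI, RC) {
  if (any(F < 0)) stop("F must be nonnegative")
  dI <- hertzDelta(material, RI, F)
  dC <- hertzDelta(material, RC, F)
  list(delta = dI + dC, deltaI = dI, deltaC = dC)
}

#' Double-contact force at measured indentation
#'
#' Inverts the series-compliance relation delta(F) = delta_I(F) + delta_C(F)
#' for a rigid spherical tip (radius R) on an elastic sphere (radius r)
#' resting on a rigid substrate: the tip contact is Hertzian with
#' 1/R* = 1/R + 1/r, the base contact Hertzian with radius r. Because
#' delta(F) is strictly increasing the root is unique; it is bracketed by
#' [0, F_Hertz(delta; R*)] and solved to 1e-12 relative tolerance.
#'
#' @param material a \linkS4class{Material}.
#' @param R tip radius (nm).
#' @param r sample sphere radius (nm); \code{Inf} reduces exactly to the
#'   Hertz law (the base compression vanishes).
#' @param delta measured indentation (nm), nonnegative; vectorized.
#' @return Force (pN).
#' @examples
#' m <- Material(100, 0.3)
#' doubleContactForce(m, R = 1, r = 3, delta = 0.2) < hertzForce(m, 1, 0.2, r = 3)
#' @export
doubleContactForce <- function(material, R, r, delta) {
  if (is.infinite(r)) return(hertzForce(material, R, delta))  # deltaC -> 0
  if (!is.finite(r) || r <= 0) stop("r must be positive")
  if (any(delta < 0)) stop("delta must be nonnegative")
  RI <- effectiveRadius(R, r)
  vapply(delta, function(d) {
    if (d == 0) return(0)
    upper <- hertzForce(material, R, d, r = r)  # delta_I alone needs more force
    g <- function(F) doubleContactDelta(material, F, RI, r)$delta - d
    # g(0) = -d < 0, g(upper) >= 0 since delta(F_Hertz) >= delta_I(F_Hertz) = d
    sol <- uniroot(g, c(0, upper), tol = 1e-12 * max(upper, 1),
                   check.conv = TRUE, maxiter = 2000L)
    sol$root
  }, numeric(1))
}

#' Nondimensionalize a force curve
#'
#' Rescales to the dimensionless force F/(E* R^2) versus dimensionless
#' indentation delta/R. In the package's nm/MPa/pN unit system
#' 1 MPa nm^2 = 1 pN, so no conversion factor appears.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param material a \linkS4class{Material}.
#' @param R tip radius (nm).
#' @return data.frame with \code{delta_rel} (delta/R) and \code{force_rel}
#'   (F/(E* R^2)).
#' @export
nondimensionalize <- function(curve, material, R) {
  if (R <= 0) stop("R must be positive")
  data.frame(delta_rel = curve@delta / R,
             force_rel = curve@force / (reducedModulus(material) * R^2))
}

#' Rebuild a force curve from its dimensionless form
#'
#' Inverse of \code{\link{nondimensionalize}}.
#'
#' @param nd data.frame with \code{delta_rel}, \code{force_rel}.
#' @inheritParams nondimensionalize
#' @return A \linkS4class{ForceCurve}.
#' @export
dimensionalize <- function(nd, material, R) {
  ForceCurve(nd$delta_rel * R, nd$force_rel * reducedModulus(material) * R^2)
}

#' Read / write force curves as CSV
#'
#' Two-column CSV (\code{delta_nm}, \code{force_pN}) with header; the split
#' columns \code{deltaI_nm}/\code{deltaC_nm} are written when present.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param path file path.
#' @return \code{readForceCurve} returns a \linkS4class{ForceCurve};
#'   \code{writeForceCurve} returns \code{path} invisibly.
#' @export
writeForceCurve <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeForceCurve
#' @export
readForceCurve <- function(path) {
  df <- read.csv(path)
  if (!all(c("delta_nm", "force_pN") %in% names(df)))
    stop("expected columns delta_nm, force_pN")
  ForceCurve(df$delta_nm, df$force_pN,
             deltaI = if ("deltaI_nm" %in% names(df)) df$deltaI_nm else numeric(0),
             deltaC = if ("deltaC_nm" %in% names(df)) df$deltaC_nm else numeric(0))
}
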