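#' @import methods
#' @importFrom stats approx optimize setNames splinefun uniroot rnorm
#' @importFrom utils read.table write.table read.csv write.csv modifyList
NULL

#' Rigid AFM tip: cone with a spherical cap
#'
#' The probe is modelled as a rigid cone of half-opening angle \code{theta}
#' terminated by a spherical cap of radius \code{R}. The cap meets the cone
#' tangentially at lateral offset \code{rho_t = R cos(theta)} and height
#' \code{z_t = R (1 - sin(theta))} above the apex, so the profile and its
#' first derivative are continuous.
#'
#' @slot R spherical-cap radius (nm).
#' @slot theta cone half-opening angle (radians), in (0, pi/2).
#' @export
setClass("TipGeometry", representation(R = "numeric", theta = "numeric"))

setValidity("TipGeometry", function(object) {
  if (length(object@R) != 1L || !is.finite(object@R) || object@R <= 0)
    return("R must be a single positive number (nm)")
  if (length(object@theta) != 1L || !is.finite(object@theta) ||
      object@theta <= 0 || object@theta >= pi / 2)
    return("theta must lie in (0, pi/2) radians")
  TRUE
})

#' Construct a tip geometry
#'
#' @param R spherical-cap radius (nm).
#' @param theta cone half-opening angle; radians unless \code{degrees = TRUE}.
#' @param degrees interpret \code{theta} in degrees.
#' @return A \linkS4class{TipGeometry}.
#' @examples
#' tip <- TipGeometry(R = 2, theta = 20, degrees = TRUE)
#' tangentPoint(tip)
#' @export
TipGeometry <- function(R, theta, degrees = FALSE) {
  if (degrees) theta <- theta * pi / 180
  new("TipGeometry", R = as.numeric(R), theta = as.numeric(theta))
}

#' @describeIn TipGeometry spherical-cap radius (nm).
#' @param tip a \code{TipGeometry}.
#' @export
tipRadius <- function(tip) tip@R

#' @describeIn TipGeometry cone half-opening angle (radians).
#' @export
coneAngle <- function(tip) tip@theta

#' @describeIn TipGeometry tangent point where cap meets cone:
#'   \code{c(rho = R cos(theta), z = R (1 - sin(theta)))} (nm).
#' @export
tangentPoint <- function(tip) {
  c(rho = tip@R * cos(tip@theta), z = tip@R * (1 - sin(tip@theta)))
}

setMethod("show", "TipGeometry", function(object) {
  tp <- tangentPoint(object)
  cat(sprintf(
    "TipGeometry: R = %g nm, theta = %.3g deg (tangent at rho = %.4g, z = %.4g nm)\n",
    object@R, object@theta * 180 / pi, tp[["rho"]], tp[["z"]]))
})

#' Linear-elastic sample material
#'
#' @slot E Young's modulus (MPa).
#' @slot nu Poisson ratio (dimensionless), in [0, 0.5).
#' @export
setClass("Material", representation(E = "numeric", nu = "numeric"))

setValidity("Material", function(object) {
  if (length(object@E) != 1L || !is.finite(object@E) || object@E <= 0)
    return("E must be a single positive number (MPa)")
  if (length(object@nu) != 1L || object@nu < 0 || object@nu >= 0.5)
    return("nu must lie in [0, 0.5)")
  TRUE
})

#' Construct a material
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return A \linkS4class{Material}.
#' @examples
#' m <- Material(E = 100, nu = 0.3)
#' reducedModulus(m)  # E / (1 - nu^2)
#' @export
Material <- function(E, nu = 0.3) new("Material", E = as.numeric(E), nu = as.numeric(nu))

#' @describeIn Material reduced (indentation) modulus E* = E / (1 - nu^2), MPa.
#' @param material a \code{Material}.
#' @export
reducedModulus <- function(material) material@E / (1 - material@nu^2)

#' @describeIn Material Young's modulus E (MPa).
#' @export
youngsModulus <- function(material) material@E

#' @describeIn Material Poisson ratio.
#' @export
poissonRatio <- function(material) material@nu

setMethod("show", "Material", function(object) {
  cat(sprintf("Material: E = %g MPa, nu = %g (E* = %.4g MPa)\n",
              object@E, object@nu, reducedModulus(object)))
})

#' Single-valued sample top surface on a uniform lateral grid
#'
#' Heights are measured from the rigid substrate plane (z = 0) and are the
#' upper envelope of the sample: undercuts are discarded, consistent with a
#' vertical-approach AFM model. The grid is uniform in each direction; a
#' profile (1-D sample) is represented with a single y node.
#'
#' @slot x,y lateral node positions (nm), uniformly spaced.
#' @slot heights matrix of surface heights (nm), \code{length(x)} rows by
#'   \code{length(y)} columns, all >= 0.
#' @slot metadata free-form list (analytic radii, wavelength, provenance ...).
#' @export
setClass("HeightField",
         representation(x = "numeric", y = "numeric", heights = "matrix",
                        metadata = "list"))

setValidity("HeightField", function(object) {
  if (!is.numeric(object@heights)) return("heights must be numeric")
  if (nrow(object@heights) != length(object@x) ||
      ncol(object@heights) != length(object@y))
    return("heights must be length(x) x length(y)")
  if (any(object@heights < -1e-9)) return("heights must be >= 0")
  for (v in list(object@x, object@y)) {
    if (length(v) > 1L) {
      d <- diff(v)
      if (any(d <= 0) || (max(d) - min(d)) > 1e-9 * max(d))
        return("grid must be strictly increasing and uniformly spaced")
    }
  }
  TRUE
})

#' Construct a height field
#'
#' @param x,y lateral node positions (nm).
#' @param heights matrix (nm), \code{length(x)} x \code{length(y)}.
#' @param metadata list of optional annotations.
#' @return A \linkS4class{HeightField}.
#' @export
HeightField <- function(x, y, heights, metadata = list()) {
  heights <- as.matrix(heights)
  heights[heights < 0] <- 0
  new("HeightField", x = as.numeric(x), y = as.numeric(y),
      heights = heights, metadata = metadata)
}

#' @describeIn HeightField x node positions (nm).
#' @param object a \code{HeightField}.
#' @export
gridX <- function(object) object@x

#' @describeIn HeightField y node positions (nm).
#' @export
gridY <- function(object) object@y

#' @describeIn HeightField matrix of heights (nm).
#' @export
heights <- function(object) object@heights

#' @describeIn HeightField grid spacing \code{c(dx, dy)} (nm); NA along a
#'   singleton direction.
#' @export
cellSize <- function(object) {
  c(dx = if (length(object@x) > 1L) object@x[2] - object@x[1] else NA_real_,
    dy = if (length(object@y) > 1L) object@y[2] - object@y[1] else NA_real_)
}

setMethod("show", "HeightField", function(object) {
  cat(sprintf("HeightField: %d x %d nodes, x in [%.4g, %.4g] nm, max height %.4g nm\n",
              length(object@x), length(object@y),
              min(object@x), max(object@x), max(object@heights)))
})

#' Atoms as spheres: centers plus van der Waals radii
#'
#' Coordinates and radii are in Angstrom; conversion to the package's nm
#' convention happens when a height field is rasterized.
#'
#' @slot element element symbols.
#' @slot xyz n x 3 matrix of centers (Angstrom).
#' @slot radius van der Waals radii (Angstrom), all > 0.
#' @export
setClass("AtomSet",
         representation(element = "character", xyz = "matrix", radius = "numeric"))

setValidity("AtomSet", function(object) {
  n <- length(object@element)
  if (nrow(object@xyz) != n || ncol(object@xyz) != 3L)
    return("xyz must be an n x 3 matrix")
  if (length(object@radius) != n || any(object@radius <= 0))
    return("radius must be positive, one per atom")
  TRUE
})

#' Construct an atom set
#'
#' @param element element symbols.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param radius optional radii (Angstrom); looked up per element when missing.
#' @return An \linkS4class{AtomSet}.
#' @export
AtomSet <- function(element, xyz, radius = NULL) {
  xyz <- as.matrix(xyz)
  if (is.null(radius)) radius <- vdwRadius(element)
  new("AtomSet", element = as.character(element), xyz = xyz,
      radius = as.numeric(radius))
}

#' @describeIn AtomSet number of atoms.
#' @param x an \code{AtomSet}.
#' @export
setMethod("length", "AtomSet", function(x) length(x@element))

#' @describeIn AtomSet atom centers (Angstrom).
#' @param object an \code{AtomSet}.
#' @export
atomCoords <- function(object) object@xyz

#' @describeIn AtomSet van der Waals radii (Angstrom).
#' @export
atomRadii <- function(object) object@radius

#' @describeIn AtomSet element symbols.
#' @export
atomElements <- function(object) object@element

setMethod("show", "AtomSet", function(object) {
  cat(sprintf("AtomSet: %d atoms (%s), extent %.4g x %.4g x %.4g A\n",
              length(object), paste(unique(object@element), collapse = ","),
              diff(range(object@xyz[, 1])), diff(range(object@xyz[, 2])),
              diff(range(object@xyz[, 3]))))
})

#' Force-indentation curve at one lateral position
#'
#' Indentation \code{delta} is the total tip displacement from first contact
#' (nm); \code{force} the vertical tip-sample force (pN). When the
#' displacement split is known, \code{deltaI} (tip-sample indentation) and
#' \code{deltaC} (base compression) satisfy delta = deltaI + deltaC and the
#' transmitted force is common to both contacts.
#'
#' @slot delta indentation samples (nm), nonnegative, strictly increasing.
#' @slot force force samples (pN), nonnegative, nondecreasing.
#' @slot deltaI,deltaC optional displacement split (nm); length 0 when absent.
#' @slot metadata list (position, engine, material, tip ...).
#' @export
setClass("ForceCurve",
         representation(delta = "numeric", force = "numeric",
                        deltaI = "numeric", deltaC = "numeric",
                        metadata = "list"))

setValidity("ForceCurve", function(object) {
  if (length(object@delta) != length(object@force))
    return("delta and force must have equal length")
  if (any(object@delta < 0)) return("delta must be nonnegative")
  if (is.unsorted(object@delta, strictly = TRUE))
    return("delta must be strictly increasing")
  if (any(object@force < -1e-9)) return("force must be nonnegative")
  # nondecreasing up to a small tolerance for measurement noise
  if (length(object@force) > 1L &&
      any(diff(object@force) < -0.05 * max(object@force, 1)))
    return("force must be nondecreasing")
  if (length(object@deltaI)) {
    if (length(object@deltaI) != length(object@delta) ||
        length(object@deltaC) != length(object@delta))
      return("deltaI/deltaC must match delta in length")
    if (max(abs(object@deltaI + object@deltaC - object@delta)) > 1e-6)
      return("deltaI + deltaC must equal delta")
  }
  TRUE
})

#' Construct a force curve
#'
#' @param delta indentation (nm).
#' @param force force (pN).
#' @param deltaI,deltaC optional displacement split (nm).
#' @param metadata list of annotations.
#' @return A \linkS4class{ForceCurve}.
#' @export
ForceCurve <- function(delta, force, deltaI = numeric(0), deltaC = numeric(0),
                       metadata = list()) {
  new("ForceCurve", delta = as.numeric(delta), force = as.numeric(force),
      deltaI = as.numeric(deltaI), deltaC = as.numeric(deltaC),
      metadata = metadata)
}

#' @describeIn ForceCurve number of samples.
#' @param x a \code{ForceCurve}.
#' @export
setMethod("length", "ForceCurve", function(x) length(x@delta))

#' @describeIn ForceCurve indentation samples (nm).
#' @param object a \code{ForceCurve}.
#' @export
indentation <- function(object) object@delta

#' @describeIn ForceCurve force samples (pN).
#' @export
forces <- function(object) object@force

#' @describeIn ForceCurve as a data.frame (delta_nm, force_pN).
#' @export
setMethod("as.data.frame", "ForceCurve", function(x, ...) {
  df <- data.frame(delta_nm = x@delta, force_pN = x@force)
  if (length(x@deltaI)) {
    df$deltaI_nm <- x@deltaI
    df$deltaC_nm <- x@deltaC
  }
  df
})

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve: %d points, delta up to %.4g nm, force up to %.4g pN\n",
              length(object), max(object@delta, 0), max(object@force, 0)))
})

#' Force sampled over three-dimensional tip-apex positions
#'
#' For each lateral scan position, forces are sampled at apex heights
#' \code{firstContact - delta}: indentation zero corresponds to the apex
#' height at which the (rigid) tip first touches the undeformed sample, and
#' force is zero at and above that height.
#'
#' @slot positions n x 2 matrix of lateral scan positions (nm).
#' @slot firstContact apex height at first contact per position (nm).
#' @slot delta common indentation grid (nm), starting at 0.
#' @slot force n x length(delta) matrix of forces (pN).
#' @slot tip,material provenance objects.
#' @slot engine force engine used ("halfspace" or "local-analytic").
#' @slot metadata list.
#' @export
setClass("ForceVolume",
         representation(positions = "matrix", firstContact = "numeric",
                        delta = "numeric", force = "matrix",
                        tip = "TipGeometry", material = "Material",
                        engine = "character", metadata = "list"))

setValidity("ForceVolume", function(object) {
  n <- nrow(object@positions)
  if (ncol(object@positions) != 2L) return("positions must be n x 2")
  if (length(object@firstContact) != n) return("firstContact length mismatch")
  if (nrow(object@force) != n || ncol(object@force) != length(object@delta))
    return("force must be n x length(delta)")
  if (object@delta[1] != 0) return("delta grid must start at 0")
  if (max(abs(object@force[, 1])) > 1e-9)
    return("force at zero indentation must be 0")
  TRUE
})

#' @describeIn ForceVolume lateral scan positions (nm).
#' @param object a \code{ForceVolume}.
#' @export
scanPositions <- function(object) object@positions

#' @describeIn ForceVolume indentation grid (nm).
#' @export
deltaGrid <- function(object) object@delta

#' @describeIn ForceVolume apex heights at first contact (nm).
#' @export
firstContact <- function(object) object@firstContact

#' @describeIn ForceVolume force matrix (positions x delta), pN.
#' @export
forceMatrix <- function(object) object@force

#' @describeIn ForceVolume extract the force curve of one scan position.
#' @param i scan-position index.
#' @export
forceCurve <- function(object, i) {
  ForceCurve(object@delta, object@force[i, ],
             metadata = list(position = object@positions[i, ],
                             firstContact = object@firstContact[i],
                             engine = object@engine))
}

setMethod("show", "ForceVolume", function(object) {
  cat(sprintf("ForceVolume: %d positions x %d indentations (engine %s), max force %.4g pN\n",
              nrow(object@positions), length(object@delta), object@engine,
              max(object@force)))
})

#' Simulated AFM topography
#'
#' Either the zero-force (unindented, tip-dilated) trace of the surface or a
#' contour of equal vertical force at a given set-point.
#'
#' @slot x,y lateral node positions (nm).
#' @slot heights apex-height topography (nm), \code{length(x)} x \code{length(y)}.
#' @slot setpoint force set-point (pN; NA for zero-force mode).
#' @slot mode "zero-force" or "iso-force".
#' @slot saturated logical matrix flagging columns where the set-point exceeded
#'   the sampled force range.
#' @slot metadata list (tip, material, engine, dimensionless setpoint ...).
#' @export
setClass("AFMImage",
         representation(x = "numeric", y = "numeric", heights = "matrix",
                        setpoint = "numeric", mode = "character",
                        saturated = "matrix", metadata = "list"))

setValidity("AFMImage", function(object) {
  if (nrow(object@heights) != length(object@x) ||
      ncol(object@heights) != length(object@y))
    return("heights must be length(x) x length(y)")
  if (!object@mode %in% c("zero-force", "iso-force"))
    return("mode must be 'zero-force' or 'iso-force'")
  if (any(object@heights < -1e-9)) return("heights must be >= 0")
  TRUE
})

AFMImage <- function(x, y, heights, setpoint = NA_real_, mode = "zero-force",
                     saturated = NULL, metadata = list()) {
  heights <- as.matrix(heights)
  heights[heights < 0] <- 0
  if (is.null(saturated))
    saturated <- matrix(FALSE, nrow(heights), ncol(heights))
  new("AFMImage", x = as.numeric(x), y = as.numeric(y), heights = heights,
      setpoint = as.numeric(setpoint), mode = mode, saturated = saturated,
      metadata = metadata)
}

#' @describeIn AFMImage image heights (nm).
#' @param object an \code{AFMImage}.
#' @export
imageHeights <- function(object) object@heights

#' @describeIn AFMImage force set-point (pN; NA in zero-force mode).
#' @export
setpoint <- function(object) object@setpoint

#' @describeIn AFMImage extract the central profile along x (at the y node
#'   closest to \code{at}).
#' @param at y position (nm) of the profile; default mid-grid.
#' @export
imageProfile <- function(object, at = NULL) {
  if (is.null(at)) at <- object@y[(length(object@y) + 1L) %/% 2L]
  j <- which.min(abs(object@y - at))
  data.frame(x = object@x, height = object@heights[, j])
}

setMethod("show", "AFMImage", function(object) {
  cat(sprintf("AFMImage (%s%s): %d x %d pixels, max height %.4g nm\n",
              object@mode,
              if (is.na(object@setpoint)) "" else
                sprintf(", setpoint %.4g pN", object@setpoint),
              length(object@x), length(object@y), max(object@heights)))
})

#' Cosine-series content of a periodic topography profile
#'
#' Coefficients A_n of h(x) = A_0 + sum_n A_n cos(k_n x), k_n = 2 pi n /
#' lambda_1, for a profile symmetric about x = 0 (sine content vanishes).
#'
#' @slot A amplitudes A_0..A_N (nm).
#' @slot lambda1 fundamental wavelength (nm).
#' @slot N truncation order.
#' @export
setClass("FourierSpectrum",
         representation(A = "numeric", lambda1 = "numeric", N = "integer"))

setValidity("FourierSpectrum", function(object) {
  if (length(object@A) != object@N + 1L) return("A must have N + 1 entries")
  if (object@lambda1 <= 0) return("lambda1 must be positive")
  TRUE
})

#' @describeIn FourierSpectrum amplitudes A_0..A_N (nm).
#' @param object a \code{FourierSpectrum}.
#' @export
amplitudes <- function(object) setNames(object@A, paste0("A", 0:object@N))

#' @describeIn FourierSpectrum wave numbers k_n = 2 pi n / lambda_1 (1/nm).
#' @export
waveNumbers <- function(object) 2 * pi * (0:object@N) / object@lambda1

setMethod("show", "FourierSpectrum", function(object) {
  cat(sprintf("FourierSpectrum: lambda1 = %g nm, N = %d, A0 = %.4g, A1 = %.4g nm\n",
              object@lambda1, object@N, object@A[1], object@A[2]))
})
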