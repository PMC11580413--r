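# Tip and sample geometry: profiles, parametric height fields, molecular
# envelopes, and the idealized B-DNA fixture.

#' Height of the tip surface above its apex
#'
#' Evaluates the rotationally symmetric tip profile z(rho): the spherical
#' branch \code{R - sqrt(R^2 - rho^2)} for \code{rho <= R cos(theta)}, and the
#' conical branch \code{z_t + (rho - rho_t) / tan(theta)} beyond the tangent
#' point. The two branches join with continuous value and slope.
#'
#' @param tip a \linkS4class{TipGeometry}.
#' @param rho lateral offsets from the tip axis (nm), nonnegative.
#' @return Heights above the apex (nm), same length as \code{rho}.
#' @examples
#' tip <- TipGeometry(1, 20, degrees = TRUE)
#' tipProfile(tip, c(0, cos(pi / 9), 2))
#' @export
tipProfile <- function(tip, rho) {
  if (any(rho < 0)) stop("rho must be nonnegative")
  R <- tip@R
  theta <- tip@theta
  rho_t <- R * cos(theta)
  z_t <- R * (1 - sin(theta))
  z <- ifelse(rho <= rho_t,
              R - sqrt(pmax(R^2 - rho^2, 0)),
              z_t + (rho - rho_t) / tan(theta))
  z
}

#' Maximum indentation for which contact stays on the spherical cap
#'
#' Below this depth the conical part of the tip cannot touch the sample, so
#' sphere-indenter contact models apply exactly. Equals
#' \code{R (1 - sin(theta))}, the tangent-point height.
#'
#' @param tip a \linkS4class{TipGeometry}.
#' @return Depth (nm).
#' @examples
#' sphericalValidityLimit(TipGeometry(1, 20, degrees = TRUE))  # ~0.658
#' @export
sphericalValidityLimit <- function(tip) tip@R * (1 - sin(tip@theta))

#' Hemispherical sample resting on the substrate
#'
#' Builds the height field h(x, y) = sqrt(r^2 - x^2 - y^2) inside the
#' footprint and 0 outside, centered on the grid origin.
#'
#' @param r hemisphere radius (nm).
#' @param spacing lateral grid spacing (nm); default \code{r / 25}.
#' @param extent half-width of the square grid (nm); default \code{2 r}.
#' @return A \linkS4class{HeightField} with \code{metadata$radius = r}.
#' @export
makeHemisphere <- function(r, spacing = r / 25, extent = 2 * r) {
  if (r <= 0) stop("r must be positive")
  if (2 * r / spacing < 8)
    warning("grid too coarse to resolve the hemisphere (fewer than 8 cells across)")
  x <- gridAxis(extent, spacing)
  h <- outer(x, x, function(xx, yy) {
    s <- r^2 - xx^2 - yy^2
    ifelse(s > 0, sqrt(pmax(s, 0)), 0)
  })
  HeightField(x, x, h, metadata = list(shape = "hemisphere", radius = r))
}

#' Sinusoidal surface, periodic in x
#'
#' h(x, y) = A (1 + cos(2 pi x / lambda)) / 2: crests of height A (the
#' peak-to-trough amplitude) at x = 0 mod lambda, troughs at height 0,
#' uniform along y.
#'
#' @param lambda wavelength (nm).
#' @param amplitude peak-to-trough amplitude A (nm); default \code{lambda}.
#' @param width extent along y (nm); default \code{4 * lambda}.
#' @param spacing grid spacing (nm); default \code{lambda / 64}.
#' @param nPeriods number of periods along x; default 4.
#' @return A \linkS4class{HeightField} with wavelength/amplitude metadata.
#' @export
makeSinusoid <- function(lambda, amplitude = lambda, width = 4 * lambda,
                         spacing = lambda / 64, nPeriods = 4) {
  if (lambda <= 0) stop("lambda must be positive")
  halfx <- nPeriods * lambda / 2
  x <- gridAxis(halfx, spacing)
  y <- gridAxis(width / 2, spacing)
  hx <- amplitude * (1 + cos(2 * pi * x / lambda)) / 2
  h <- matrix(hx, nrow = length(x), ncol = length(y))
  HeightField(x, y, h,
              metadata = list(shape = "sinusoid", lambda = lambda,
                              amplitude = amplitude))
}

# Symmetric grid axis including 0, spacing-uniform.
gridAxis <- function(halfwidth, spacing) {
  n <- ceiling(halfwidth / spacing)
  seq(-n, n) * spacing
}

#' Rasterize a molecule into a height field
#'
#' The sample surface is the upper envelope over all atom spheres,
#' h = max_i [z_i + sqrt(r_i^2 - d_i^2)] for lateral distance d_i <= r_i.
#' The molecule is first rested on the substrate (its lowest envelope point
#' at z = 0) and then lowered by \code{cleaveFraction} of its height,
#' emulating partial embedding in a rigid base; negative heights are clipped.
#' Atom coordinates (Angstrom) are converted to nm.
#'
#' @param atoms an \linkS4class{AtomSet} oriented with the substrate in the
#'   xy-plane and height along z.
#' @param spacing lateral bin size (nm); default 0.55 nm.
#' @param cleaveFraction fraction of the molecular height embedded in the
#'   substrate, in [0, 1); default 0.
#' @param extent optional \code{c(xmin, xmax, ymin, ymax)} (nm); default the
#'   molecular footprint.
#' @return A \linkS4class{HeightField} (nm).
#' @export
moleculeHeightField <- function(atoms, spacing = 0.55, cleaveFraction = 0,
                                extent = NULL) {
  if (length(atoms) == 0L) stop("empty AtomSet")
  if (cleaveFraction < 0 || cleaveFraction >= 1)
    stop("cleaveFraction must lie in [0, 1)")
  xyz <- atoms@xyz / 10  # Angstrom -> nm
  rad <- atoms@radius / 10
  # rest on substrate: lowest envelope point at z = 0
  z0 <- min(xyz[, 3] - rad)
  zc <- xyz[, 3] - z0
  height <- max(zc + rad)
  shift <- cleaveFraction * height
  if (all(zc + rad - shift <= 0)) stop("all atoms cleaved away")
  if (is.null(extent))
    extent <- c(min(xyz[, 1] - rad), max(xyz[, 1] + rad),
                min(xyz[, 2] - rad), max(xyz[, 2] + rad))
  # nodes at integer multiples of the bin size, covering the full extent
  x <- seq(floor(extent[1] / spacing), ceiling(extent[2] / spacing)) * spacing
  y <- seq(floor(extent[3] / spacing), ceiling(extent[4] / spacing)) * spacing
  h <- envelopeHeights(x, y, xyz[, 1], xyz[, 2], zc, rad) - shift
  h[h < 0] <- 0
  # continuum proxy for the molecular cross-section curvature: half the
  # envelope height (cylinder radius); atomic-scale surface bumps are below
  # the continuum description and would misrepresent the elastic response
  HeightField(x, y, h,
              metadata = list(shape = "molecule", nAtoms = length(atoms),
                              cleaveFraction = cleaveFraction,
                              effectiveRadius = max(h) / 2))
}

# Upper envelope of atom spheres on a grid (vectorized over atoms per node
# block; atoms counts here are modest).
envelopeHeights <- function(x, y, ax, ay, az, ar) {
  h <- matrix(0, length(x), length(y))
  for (i in seq_along(ax)) {
    dx2 <- (x - ax[i])^2
    sel_x <- which(dx2 < ar[i]^2)
    if (!length(sel_x)) next
    dy2 <- (y - ay[i])^2
    sel_y <- which(dy2 < ar[i]^2)
    if (!length(sel_y)) next
    d2 <- outer(dx2[sel_x], dy2[sel_y], "+")
    cap <- az[i] + sqrt(pmax(ar[i]^2 - d2, 0))
    cap[d2 >= ar[i]^2] <- -Inf
    h[sel_x, sel_y] <- pmax(h[sel_x, sel_y], cap)
  }
  h
}

# UFF-derived van der Waals radii (Angstrom, half the UFF vdW distance x_I).
.uffRadii <- c(H = 1.443, C = 1.925, N = 1.830, O = 1.750, P = 2.074,
               S = 2.018, F = 1.682, CL = 1.953, BR = 2.098, I = 2.250,
               "NA" = 1.491, MG = 1.510, K = 1.906, CA = 1.700, ZN = 1.462,
               FE = 1.456)

#' Van der Waals radius lookup
#'
#' Bundled UFF-derived element radii; unknown elements fall back to 1.7
#' Angstrom with a warning.
#'
#' @param element element symbols (case-insensitive).
#' @return Radii (Angstrom).
#' @export
vdwRadius <- function(element) {
  key <- toupper(trimws(element))
  r <- .uffRadii[key]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(key[unknown]), collapse = ", "),
            "; using fallback radius 1.7 Angstrom")
    r[unknown] <- 1.7
  }
  unname(r)
}

#' Idealized straight B-DNA segment
#'
#' Builds a deterministic pseudo-atomic model of a linear B-form double helix
#' from canonical helical parameters: rise 3.4 Angstrom and twist 36 degrees
#' per base pair, two antiparallel strands whose backbones are offset by 154
#' degrees around the axis (producing distinct major and minor grooves), and
#' a small set of pseudo-atoms per nucleotide spanning the phosphate backbone
#' (radial distance ~8.9 Angstrom) down to the base-pair core. This is a
#' synthetic, idealized stand-in for a crystallographic B-DNA structure: it
#' reproduces the canonical envelope (diameter ~2 nm, 10 bp per turn,
#' grooves) but no sequence-specific atomic detail.
#'
#' @param nBp number of base pairs (>= 1).
#' @param axis helix-axis direction: \code{"x"} (lying on the substrate,
#'   ready for imaging) or \code{"z"}.
#' @return An \linkS4class{AtomSet} (Angstrom).
#' @examples
#' dna <- buildBDNA(10)  # one full helical turn
#' @export
buildBDNA <- function(nBp, axis = c("x", "z")) {
  if (nBp < 1) stop("nBp must be >= 1")
  axis <- match.arg(axis)
  rise <- 3.4        # Angstrom per bp
  twist <- 36 * pi / 180
  grooveOffset <- 154 * pi / 180  # strand-2 backbone angular offset
  # pseudo-atoms per nucleotide: element, radial distance (Angstrom),
  # angular offset from the backbone reference (radians)
  unit <- data.frame(
    element = c("P", "O", "C", "C", "N", "C"),
    rdist   = c(8.9, 7.6, 6.2, 4.6, 3.0, 1.4),
    aoff    = c(0.0, 0.12, 0.22, 0.32, 0.42, 0.52)
  )
  elements <- character(0)
  coords <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(nBp)) {
    phi <- (i - 1) * twist
    z <- (i - 1) * rise
    for (strand in c(0, 1)) {
      base <- phi + strand * grooveOffset
      sgn <- if (strand == 0) 1 else -1
      ang <- base + sgn * unit$aoff
      elements <- c(elements, unit$element)
      coords <- rbind(coords,
                      cbind(unit$rdist * cos(ang), unit$rdist * sin(ang), z))
    }
  }
  if (axis == "x") coords <- coords[, c(3, 1, 2)]  # axis along x, height z
  # center laterally so the molecule sits on the origin of the scan frame
  coords[, 1] <- coords[, 1] - mean(range(coords[, 1]))
  coords[, 2] <- coords[, 2] - mean(range(coords[, 2]))
  AtomSet(elements, coords)
}
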