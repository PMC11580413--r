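# Boundary-element elastic contact: a rigid indenter of arbitrary profile on
# an elastic half-space, discretized as uniform rectangular pressure patches
# with the Love/Boussinesq influence solution, solved by a Polonsky-Keer
# style projected conjugate-gradient iteration. FFT accelerates the
# kernel-pressure products.

#' Initial tip-sample vertical separation on a grid
#'
#' The gap at a given tip position: tip surface height minus sample surface
#' height per cell. Negative values denote geometric overlap that the
#' elastic solve must resolve.
#'
#' @slot x,y lateral node positions (nm), uniformly spaced.
#' @slot gap matrix of separations (nm), \code{length(x)} x \code{length(y)}.
#' @export
setClass("GapFunction",
         representation(x = "numeric", y = "numeric", gap = "matrix"))

setValidity("GapFunction", function(object) {
  if (nrow(object@gap) != length(object@x) ||
      ncol(object@gap) != length(object@y))
    return("gap must be length(x) x length(y)")
  if (any(!is.finite(object@gap))) return("gap values must be finite")
  TRUE
})

#' @rdname GapFunction-class
#' @param x,y lateral node positions (nm).
#' @param gap matrix of separations (nm).
#' @export
GapFunction <- function(x, y, gap) {
  new("GapFunction", x = as.numeric(x), y = as.numeric(y), gap = as.matrix(gap))
}

#' Solution of a half-space contact problem
#'
#' @slot pressure contact pressure per cell (MPa), nonnegative.
#' @slot totalForce integrated normal force (pN).
#' @slot contactMask logical matrix of cells in contact.
#' @slot displacement elastic surface displacement per cell (nm).
#' @slot residual final complementarity residual.
#' @slot iterations iterations used.
#' @export
setClass("ContactSolution",
         representation(pressure = "matrix", totalForce = "numeric",
                        contactMask = "matrix", displacement = "matrix",
                        residual = "numeric", iterations = "integer"))

#' @describeIn ContactSolution total normal force (pN).
#' @param object a \code{ContactSolution}.
#' @export
totalForce <- function(object) object@totalForce

#' @describeIn ContactSolution pressure field (MPa).
#' @export
contactPressure <- function(object) object@pressure

#' @describeIn ContactSolution logical contact mask.
#' @export
contactMask <- function(object) object@contactMask

setMethod("show", "ContactSolution", function(object) {
  cat(sprintf(
    "ContactSolution: F = %.5g pN, %d cells in contact, residual %.2g (%d iterations)\n",
    object@totalForce, sum(object@contactMask), object@residual,
    object@iterations))
})

# Love solution: normal surface deflection at (x, y) due to uniform unit
# pressure over the rectangle [-a, a] x [-b, b] on an elastic half-space,
# times pi E*. Four-corner combination of F(xi, eta) = xi asinh-type terms.
loveDeflection <- function(x, y, a, b) {
  Fc <- function(xi, eta) {
    s <- sqrt(xi^2 + eta^2)
    t1 <- ifelse(abs(xi) < 1e-300, 0, xi * log(eta + s))
    t2 <- ifelse(abs(eta) < 1e-300, 0, eta * log(xi + s))
    t1 + t2
  }
  Fc(x + a, y + b) + Fc(x - a, y - b) - Fc(x + a, y - b) - Fc(x - a, y + b)
}

# FFT convolution machinery for the block-Toeplitz influence matrix.
# Returns a closure computing u = K p (deflection in nm for pressure in MPa).
makeKernelMultiplier <- function(nx, ny, dx, dy, Estar) {
  px <- 2L * nx
  py <- 2L * ny
  offx <- c(0:(nx - 1L), -(nx:1L)) * dx
  offy <- c(0:(ny - 1L), -(ny:1L)) * dy
  ker <- outer(offx, offy, function(X, Y) loveDeflection(X, Y, dx / 2, dy / 2)) /
    (pi * Estar)
  kerHat <- stats::fft(ker)
  function(p) {
    pp <- matrix(0, px, py)
    pp[1:nx, 1:ny] <- p
    conv <- Re(stats::fft(kerHat * stats::fft(pp), inverse = TRUE)) / (px * py)
    conv[1:nx, 1:ny]
  }
}

#' Rigid indenter on an elastic half-space: constrained contact solve
#'
#' Solves the frictionless normal contact problem for the gap function at a
#' prescribed rigid approach: find a nonnegative pressure field such that
#' the deformed gap \code{gap + u(p)} is nonnegative and complementary to
#' the pressure (cells in contact close exactly, cells out of contact carry
#' no pressure). Deflections follow the Boussinesq half-space response,
#' integrated exactly over uniform rectangular pressure patches; the
#' constrained system is solved with a projected conjugate-gradient
#' active-set iteration.
#'
#' @param gap a \linkS4class{GapFunction}; negative entries denote overlap at
#'   the prescribed approach.
#' @param material a \linkS4class{Material}.
#' @param tol relative force tolerance for convergence; default 1e-6.
#' @param maxIter iteration cap; default 10000.
#' @return A \linkS4class{ContactSolution}.
#' @examples
#' # sphere R = 10 nm pressed 0.5 nm into a flat half-space
#' x <- seq(-3.2, 3.2, by = 0.1)
#' sphere <- outer(x, x, function(a, b) (a^2 + b^2) / (2 * 10))
#' sol <- halfspaceContactSolve(GapFunction(x, x, sphere - 0.5), Material(1, 0))
#' totalForce(sol)  # ~ (4/3) sqrt(10) 0.5^1.5 = 1.49 pN
#' @export
halfspaceContactSolve <- function(gap, material, tol = 1e-6, maxIter = 10000L) {
  nx <- length(gap@x)
  ny <- length(gap@y)
  dx <- if (nx > 1) gap@x[2] - gap@x[1] else stop("grid must have >= 2 x nodes")
  dy <- if (ny > 1) gap@y[2] - gap@y[1] else stop("grid must have >= 2 y nodes")
  Estar <- reducedModulus(material)
  h <- gap@gap
  cellArea <- dx * dy
  if (all(h >= 0)) {
    z <- matrix(0, nx, ny)
    return(new("ContactSolution", pressure = z, totalForce = 0,
               contactMask = z > 0, displacement = z, residual = 0,
               iterations = 0L))
  }
  Kmul <- makeKernelMultiplier(nx, ny, dx, dy, Estar)
  # initial guess: pressure proportional to overlap
  p <- pmax(-h, 0) * Estar / (2 * max(dx, dy))
  t <- matrix(0, nx, ny)
  Gold <- 1
  useCG <- FALSE
  Fold <- sum(p) * cellArea
  res <- Inf
  it <- 0L
  u <- Kmul(p)
  for (it in seq_len(maxIter)) {
    g <- h + u
    S <- p > 0
    if (!any(S)) S <- h < 0
    G <- sum(g[S]^2)
    beta <- if (useCG) G / Gold else 0
    t <- ifelse(S, g + beta * t, 0)
    Gold <- G
    r <- Kmul(t)
    num <- sum(g[S] * t[S])
    den <- sum(r[S] * t[S])
    if (!is.finite(den) || den <= 0) {  # restart with steepest descent
      t <- ifelse(S, g, 0)
      r <- Kmul(t)
      num <- sum(g[S] * t[S])
      den <- sum(r[S] * t[S])
      if (den <= 0) break
    }
    tau <- num / den
    p <- p - tau * t
    neg <- p < 0
    p[neg] <- 0
    # bring interpenetrating out-of-contact cells into contact
    g <- h + Kmul(p)
    ol <- (p == 0) & (g < 0)
    if (any(ol)) {
      p[ol] <- p[ol] - tau * g[ol]
      useCG <- FALSE
    } else {
      useCG <- TRUE
    }
    u <- Kmul(p)
    Fnew <- sum(p) * cellArea
    res <- abs(Fnew - Fold) / max(Fnew, .Machine$double.eps)
    comp <- max(-min(h + u), 0) / max(-min(h), .Machine$double.eps)
    Fold <- Fnew
    if (res < tol && comp < 100 * tol && !any(ol)) break
  }
  if (it == maxIter && res >= tol)
    stop(sprintf("halfspaceContactSolve did not converge: residual %.3g after %d iterations",
                 res, it))
  # warn when the contact patch touches the solver window
  mask <- p > 0
  if (any(mask[1, ]) || any(mask[nx, ]) || any(mask[, 1]) || any(mask[, ny]))
    warning("contact patch touches the solver window boundary; enlarge the window")
  new("ContactSolution", pressure = p, totalForce = sum(p) * cellArea,
      contactMask = mask, displacement = u, residual = res, iterations = it)
}

# Local curvature radius of the sample surface at a grid node, from centered
# second differences of the height field (mean of the two axis curvatures).
# Returns Inf for locally flat or concave surfaces; uses analytic metadata
# when the sample declares it.
localSampleRadius <- function(sample, i, j) {
  md <- sample@metadata
  h <- sample@heights
  if (identical(md$shape, "hemisphere") && h[i, j] > 0) return(md$radius)
  if (!is.null(md$effectiveRadius) && h[i, j] > 0) return(md$effectiveRadius)
  d <- cellSize(sample)
  kx <- ky <- 0
  if (i > 1 && i < nrow(h) && is.finite(d[["dx"]]))
    kx <- -(h[i + 1, j] - 2 * h[i, j] + h[i - 1, j]) / d[["dx"]]^2
  if (j > 1 && j < ncol(h) && is.finite(d[["dy"]]))
    ky <- -(h[i, j + 1] - 2 * h[i, j] + h[i, j - 1]) / d[["dy"]]^2
  k <- (kx + ky) / 2
  if (k <= 1e-12) Inf else 1 / k
}

#' Force-indentation curve at a lateral tip position
#'
#' For each indentation depth the tip apex is placed at (first-contact
#' height - delta) and the tip-sample force computed by the selected engine:
#' \describe{
#'   \item{local-analytic}{Hertz (or conical Sneddon) law driven by the
#'     sample's local radius of curvature at the contact point; fast,
#'     exact for ideal sphere-on-sphere geometry.}
#'   \item{halfspace}{the boundary-element half-space contact solve of
#'     \code{\link{halfspaceContactSolve}} on the full gap function; captures
#'     side contact and non-paraboloid geometry.}
#' }
#'
#' @param sample a \linkS4class{HeightField}.
#' @param tip a \linkS4class{TipGeometry}.
#' @param material a \linkS4class{Material}.
#' @param position lateral tip position \code{c(x, y)} (nm).
#' @param deltaGrid indentation depths (nm), nondecreasing, starting at 0.
#' @param engine force engine.
#' @param law analytic law for the local-analytic engine.
#' @param window half-width of the local solver window (nm) for the
#'   halfspace engine; default sized from the tip boundary radius.
#' @param tol,maxIter passed to \code{\link{halfspaceContactSolve}}.
#' @return A \linkS4class{ForceCurve}.
#' @export
forceCurveAt <- function(sample, tip, material, position, deltaGrid,
                         engine = c("local-analytic", "halfspace"),
                         law = c("hertz", "sneddon"), window = NULL,
                         tol = 1e-6, maxIter = 10000L) {
  engine <- match.arg(engine)
  law <- match.arg(law)
  if (deltaGrid[1] != 0 || any(diff(deltaGrid) < 0) || any(deltaGrid < 0))
    stop("deltaGrid must be nonnegative, nondecreasing, and start at 0")
  if (position[1] < min(sample@x) || position[1] > max(sample@x) ||
      position[2] < min(sample@y) || position[2] > max(sample@y))
    stop("lateral position outside the sample grid")
  zc <- closestVerticalDistance(tip, sample, position)
  if (engine == "local-analytic") {
    cp <- contactPoint(tip, sample, position)
    rloc <- localSampleRadius(sample, cp$i, cp$j)
    F <- if (law == "hertz") {
      hertzForce(material, tip@R, deltaGrid, r = rloc)
    } else {
      sneddonForce(material, tip, deltaGrid, r = rloc)
    }
    return(ForceCurve(deltaGrid, F,
                      metadata = list(position = position, engine = engine,
                                      firstContact = zc, localRadius = rloc)))
  }
  # halfspace engine: local window around the tip position
  hmax <- max(sample@heights)
  if (is.null(window))
    window <- boundaryRadius(tip, hmax) +
      3 * sqrt(tip@R * max(deltaGrid, tip@R / 10))
  d <- cellSize(sample)
  dx <- d[["dx"]]
  dy <- if (is.finite(d[["dy"]])) d[["dy"]] else dx
  selx <- which(abs(sample@x - position[1]) <= window)
  sely <- if (length(sample@y) > 1)
    which(abs(sample@y - position[2]) <= window) else 1L
  if (length(selx) < 2) stop("solver window too small for the sample grid")
  hs <- sample@heights[selx, sely, drop = FALSE]
  if (length(sely) == 1L) {
    # extrude a profile sample uniformly in y for the 2-D solve
    ys <- gridAxis(window, dx)
    hs <- matrix(hs[, 1], nrow = length(selx), ncol = length(ys))
  } else {
    ys <- sample@y[sely]
  }
  xs <- sample@x[selx]
  tipz <- outer(xs, ys, function(a, b)
    tipProfile(tip, sqrt((a - position[1])^2 + (b - position[2])^2)))
  gap0 <- tipz + zc - hs  # >= 0 everywhere at first contact
  F <- numeric(length(deltaGrid))
  for (k in seq_along(deltaGrid)) {
    if (deltaGrid[k] == 0) next
    sol <- halfspaceContactSolve(GapFunction(xs, ys, gap0 - deltaGrid[k]),
                                 material, tol = tol, maxIter = maxIter)
    F[k] <- totalForce(sol)
  }
  F <- cummax(F)  # enforce monotone force against residual solver noise
  ForceCurve(deltaGrid, F,
             metadata = list(position = position, engine = engine,
                             firstContact = zc))
}

# Grid node where the tip first touches the sample at this lateral position.
contactPoint <- function(tip, sample, position) {
  dxs <- outer(sample@x - position[1], sample@y - position[2],
               function(a, b) sqrt(a^2 + b^2))
  score <- sample@heights - tipProfile(tip, dxs)
  idx <- which(score == max(score), arr.ind = TRUE)[1, ]
  list(i = idx[[1]], j = idx[[2]], clearance = max(score))
}
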