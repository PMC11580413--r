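# Readers/writers (PDB, height maps, images), run configuration, and the
# named presets reproducing the package's standard study conditions.

#' Read atoms from a PDB file
#'
#' Parses ATOM/HETATM records via bio3d, keeping model 1 only and alternate
#' locations 'A' or blank. Elements come from the element column with
#' fallback to the atom-name field; van der Waals radii are assigned from
#' the bundled UFF-derived table (\code{\link{vdwRadius}}).
#'
#' @param path PDB file path.
#' @return An \linkS4class{AtomSet} (Angstrom).
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms parsed from ", path)
  elem <- trimws(at$elesy)
  blank <- is.na(elem) | elem == ""
  if (any(blank))  # fall back to the first letter of the atom name
    elem[blank] <- substr(gsub("[^A-Za-z].*$", "", trimws(at$elety[blank])), 1, 1)
  AtomSet(elem, cbind(at$x, at$y, at$z))
}

#' Write an atom set to a PDB file
#'
#' @param atoms an \linkS4class{AtomSet}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePDB <- function(atoms, path) {
  n <- length(atoms)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(atoms@xyz)),
                   type = rep("ATOM", n), elety = atoms@element,
                   resid = rep("MOL", n), resno = rep(1L, n),
                   elesy = atoms@element)
  invisible(path)
}

# Plain-text matrix serialization shared by height fields and images.
writeMatrixMap <- function(x, y, z, path, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin %.10g %.10g", x[1], y[1]),
               sprintf("# spacing %.10g %.10g",
                       if (length(x) > 1) x[2] - x[1] else 0,
                       if (length(y) > 1) y[2] - y[1] else 0),
               "# units nm", extra), con)
  write.table(z, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

readMatrixMap <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  origin <- as.numeric(strsplit(sub("# origin ", "", hdr[1]), " ")[[1]])
  spacing <- as.numeric(strsplit(sub("# spacing ", "", hdr[2]), " ")[[1]])
  z <- as.matrix(read.table(text = lines[!grepl("^#", lines)]))
  dimnames(z) <- NULL
  x <- origin[1] + spacing[1] * (seq_len(nrow(z)) - 1L)
  y <- if (ncol(z) > 1) origin[2] + spacing[2] * (seq_len(ncol(z)) - 1L)
       else origin[2]
  list(x = x, y = y, z = z, header = hdr)
}

#' Read / write height fields as plain-text matrices
#'
#' A small commented header records grid origin, spacing, and units (nm);
#' the matrix body has one row per x node.
#'
#' @param object a \linkS4class{HeightField}.
#' @param path file path.
#' @return \code{readHeightField} returns a \linkS4class{HeightField}.
#' @export
writeHeightField <- function(object, path) {
  writeMatrixMap(object@x, object@y, object@heights, path)
}

#' @rdname writeHeightField
#' @export
readHeightField <- function(path) {
  m <- readMatrixMap(path)
  HeightField(m$x, m$y, m$z)
}

#' Write an AFM image (text matrix and/or tidy CSV)
#'
#' @param image an \linkS4class{AFMImage}.
#' @param path output path; extension \code{.csv} selects the tidy
#'   (x, y, height) format, anything else the plain-matrix format.
#' @return \code{path}, invisibly.
#' @export
writeAFMImage <- function(image, path) {
  if (grepl("\\.csv$", path)) {
    df <- expand.grid(x = image@x, y = image@y)
    df$height <- as.vector(image@heights)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  writeMatrixMap(image@x, image@y, image@heights, path,
                 extra = sprintf("# mode %s setpoint_pN %.10g",
                                 image@mode, image@setpoint))
}

#' Simulation run configuration
#'
#' Bundles tip, material, sample specification, scan and indentation grids,
#' engine, and force set-points; round-trips losslessly through YAML.
#'
#' @slot tip a \linkS4class{TipGeometry}.
#' @slot material a \linkS4class{Material}.
#' @slot sample list: \code{type} ("hemisphere", "sinusoid", "bdna", "pdb")
#'   plus type-specific parameters.
#' @slot scan list: \code{x}, \code{y} scan-node vectors (nm).
#' @slot delta list: \code{n} points and \code{fraction} of R.
#' @slot engine force engine.
#' @slot setpoints force set-points (pN).
#' @slot seed integer seed for stochastic components.
#' @slot name preset name.
#' @export
setClass("RunConfig",
         representation(tip = "TipGeometry", material = "Material",
                        sample = "list", scan = "list", delta = "list",
                        engine = "character", setpoints = "numeric",
                        seed = "integer", name = "character"))

setValidity("RunConfig", function(object) {
  if (!object@engine %in% c("local-analytic", "halfspace"))
    return("engine must be 'local-analytic' or 'halfspace'")
  if (any(object@setpoints < 0)) return("setpoints must be nonnegative")
  TRUE
})

RunConfig <- function(tip, material, sample, scan, delta = list(n = 30L, fraction = 0.65),
                      engine = "local-analytic", setpoints = numeric(0),
                      seed = 1L, name = "custom") {
  new("RunConfig", tip = tip, material = material, sample = sample,
      scan = scan, delta = delta, engine = engine,
      setpoints = as.numeric(setpoints), seed = as.integer(seed), name = name)
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig '%s': sample %s, R = %g nm, theta = %g deg, engine %s\n",
              object@name, object@sample$type, object@tip@R,
              object@tip@theta * 180 / pi, object@engine))
})

#' Write / read a run configuration as YAML
#'
#' @param config a \linkS4class{RunConfig}.
#' @param path file path.
#' @return \code{readRunConfig} returns a \linkS4class{RunConfig}.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(list(
    name = config@name,
    tip = list(R = config@tip@R, theta_deg = config@tip@theta * 180 / pi),
    material = list(E = config@material@E, nu = config@material@nu),
    sample = config@sample,
    scan = config@scan,
    delta = config@delta,
    engine = config@engine,
    setpoints = config@setpoints,
    seed = config@seed), path, precision = 15L)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  RunConfig(TipGeometry(y$tip$R, y$tip$theta_deg, degrees = TRUE),
            Material(y$material$E, y$material$nu),
            sample = y$sample, scan = y$scan, delta = y$delta,
            engine = y$engine, setpoints = unlist(y$setpoints),
            seed = y$seed, name = y$name)
}

#' Named presets for the package's standard study conditions
#'
#' \describe{
#'   \item{spherePreset}{sphere-on-support indentation validation: tip R = 1
#'     nm, cone angle 20 deg, elastic sphere r/R = 3, E = 100 MPa, nu = 0.3.}
#'   \item{hemispherePreset}{elastic hemisphere r = 5 nm on the substrate,
#'     default R/r = 0.2, E = 100 MPa, nu = 0.3.}
#'   \item{sinusoidPreset}{1-D sinusoidal surface, lambda = 10 nm,
#'     peak-to-trough amplitude = lambda, width 4 lambda, default R = 1 nm.}
#'   \item{dnaPreset}{idealized 80-bp B-DNA on a 5 nm x 20 nm base: tip
#'     R = 1.8 nm, half-angle 5 deg, 0.55 nm bins, 240 scan positions,
#'     bottom 20 percent of the molecule embedded, set-point 100 pN.}
#' }
#'
#' @param R tip radius (nm) where overridable.
#' @param rOverR sample-to-tip radius ratio for \code{spherePreset}.
#' @return A \linkS4class{RunConfig}.
#' @export
hemispherePreset <- function(R = 1) {
  r <- 5
  RunConfig(TipGeometry(R, 20, degrees = TRUE), Material(100, 0.3),
            sample = list(type = "hemisphere", r = r, spacing = 0.2),
            scan = list(x = seq(-2 * r, 2 * r, by = 0.5), y = 0),
            setpoints = c(0.1, 0.23) * (100 / 0.91) * R^2,
            name = "hemisphere")
}

#' @rdname hemispherePreset
#' @export
sinusoidPreset <- function(R = 1) {
  lambda <- 10
  RunConfig(TipGeometry(R, 20, degrees = TRUE), Material(100, 0.3),
            sample = list(type = "sinusoid", lambda = lambda,
                          amplitude = lambda, spacing = lambda / 64),
            scan = list(x = seq(-lambda / 2, lambda / 2, by = lambda / 32),
                        y = 0),
            setpoints = 0.227 * (100 / 0.91) * R^2,
            name = "sinusoid")
}

#' @rdname hemispherePreset
#' @export
spherePreset <- function(R = 1, rOverR = 3) {
  RunConfig(TipGeometry(R, 20, degrees = TRUE), Material(100, 0.3),
            sample = list(type = "sphere", r = rOverR * R),
            scan = list(x = 0, y = 0),
            name = "sphere-validation")
}

#' @rdname hemispherePreset
#' @export
dnaPreset <- function() {
  # 240 scan positions: 30 along the molecular axis (20 nm base length) x 8
  # across (0.55 nm bins spanning the molecule's footprint)
  RunConfig(TipGeometry(1.8, 5, degrees = TRUE), Material(100, 0.3),
            sample = list(type = "bdna", nBp = 80, spacing = 0.55,
                          cleaveFraction = 0.2,
                          base = list(width = 5, length = 20)),
            scan = list(x = seq(-10, 10, length.out = 30),
                        y = seq(-1.925, 1.925, by = 0.55)),
            delta = list(n = 16L, fraction = 0.65),
            engine = "local-analytic",
            setpoints = 100,
            name = "dna")
}

#' Build the sample height field described by a run configuration
#'
#' @param config a \linkS4class{RunConfig}.
#' @return A \linkS4class{HeightField}.
#' @export
buildSample <- function(config) {
  s <- config@sample
  switch(s$type,
         hemisphere = makeHemisphere(s$r, spacing = s$spacing %||% (s$r / 25)),
         sinusoid = makeSinusoid(s$lambda, amplitude = s$amplitude %||% s$lambda,
                                 spacing = s$spacing %||% (s$lambda / 64)),
         bdna = {
           atoms <- buildBDNA(s$nBp %||% 80L, axis = "x")
           ext <- if (!is.null(s$base))
             c(-s$base$length / 2, s$base$length / 2,
               -s$base$width / 2, s$base$width / 2)
           moleculeHeightField(atoms, spacing = s$spacing %||% 0.55,
                               cleaveFraction = s$cleaveFraction %||% 0.2,
                               extent = ext)
         },
         pdb = {
           atoms <- readPDB(s$path)
           moleculeHeightField(atoms, spacing = s$spacing %||% 0.55,
                               cleaveFraction = s$cleaveFraction %||% 0)
         },
         stop("unknown sample type: ", s$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a configured simulation end-to-end
#'
#' Builds the sample, samples the force volume over the configured scan
#' grid, and extracts the zero-force topography plus one constant-force
#' image per set-point.
#'
#' @param config a \linkS4class{RunConfig}.
#' @return List with \code{sample} (\linkS4class{HeightField}),
#'   \code{volume} (\linkS4class{ForceVolume}), \code{zeroForce}
#'   (\linkS4class{AFMImage}), and \code{images} (list of
#'   \linkS4class{AFMImage}, one per set-point).
#' @export
runSimulation <- function(config) {
  sample <- buildSample(config)
  scanX <- config@scan$x
  scanY <- config@scan$y
  # clamp the scan grid to the sample extent
  scanX <- scanX[scanX >= min(sample@x) & scanX <= max(sample@x)]
  scanY <- scanY[scanY >= min(sample@y) & scanY <= max(sample@y)]
  if (!length(scanY)) scanY <- sample@y[(length(sample@y) + 1L) %/% 2L]
  deltaGrid <- defaultDeltaGrid(config@tip, n = config@delta$n %||% 30L,
                                fraction = config@delta$fraction %||% 0.65)
  volume <- buildForceVolume(sample, config@tip, config@material,
                             scanX = scanX, scanY = scanY,
                             deltaGrid = deltaGrid, engine = config@engine)
  zf <- zeroForceTopography(config@tip, sample, scanX, scanY)
  images <- lapply(config@setpoints, function(sp)
    suppressWarnings(isoforceImage(volume, sp)))
  list(sample = sample, volume = volume, zeroForce = zf, images = images)
}
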