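# Shared fixtures and independent oracles.

tip20 <- function(R = 1) TipGeometry(R, 20, degrees = TRUE)

mat100 <- function() Material(100, 0.3)

# unit reduced modulus: E* = E / (1 - nu^2) = 1
matUnit <- function() Material(1, 0)

# Brute-force dilation oracle: exhaustive maximization over ALL sample cells,
# no rho_boundary cutoff, plain R.
bruteDilation <- function(tip, sample, position) {
  d <- outer(gridX(sample) - position[1], gridY(sample) - position[2],
             function(a, b) sqrt(a^2 + b^2))
  max(0, max(heights(sample) - tipProfile(tip, d)))
}

# Brute-force molecular envelope oracle: per-node maximization over atoms
# (coordinates/radii in Angstrom, heights in nm, molecule rested on z = 0).
bruteEnvelope <- function(atoms, x, y) {
  xyz <- atomCoords(atoms) / 10
  r <- atomRadii(atoms) / 10
  z <- xyz[, 3] - min(xyz[, 3] - r)
  h <- matrix(0, length(x), length(y))
  for (i in seq_len(length(atoms))) {
    for (ix in seq_along(x)) {
      for (iy in seq_along(y)) {
        d2 <- (x[ix] - xyz[i, 1])^2 + (y[iy] - xyz[i, 2])^2
        if (d2 < r[i]^2)
          h[ix, iy] <- max(h[ix, iy], z[i] + sqrt(r[i]^2 - d2))
      }
    }
  }
  h
}

# log-log slope of F(delta) over one decade
loglogSlope <- function(f, d0, d1) {
  (log(f(d1)) - log(f(d0))) / (log(d1) - log(d0))
}

# square wave in phase with cos, jump samples set to the midpoint value so the
# discrete profile is exactly symmetric about x = 0
squareWave <- function(x, lambda) {
  cs <- cos(2 * pi * x / lambda)
  ifelse(abs(cs) < 1e-9, 0, sign(cs))
}
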