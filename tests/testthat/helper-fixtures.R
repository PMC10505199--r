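## Shared fixtures, built in code at test time.

## perfect-lattice monolayer (single crystal, no jitter)
latticeMonolayer <- function(a = 10, box = c(60, 60)) {
  tessellate(triangularLattice(a, box, margin = a), box)
}

## small irregular monolayer from seeded uniform points
toyMonolayer <- function(n = 20, box = c(50, 50), seed = 42) {
  pts <- hexanematic:::withSeed(seed, {
    cbind(runif(n, -5, box[1] + 5), runif(n, -5, box[2] + 5))
  })
  tessellate(pts, box)
}

## random simple polygon: jittered star-convex vertex set around a center
randomPolygon <- function(nv = 8, seed = 1) {
  hexanematic:::withSeed(seed, {
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 0.5, 2)
    cbind(rad * cos(ang), rad * sin(ang))
  })
}

## rotate polygon vertices about a point
rotatePolygon <- function(xy, alpha, center = c(0, 0)) {
  rel <- sweep(xy, 2L, center)
  cs <- cos(alpha); sn <- sin(alpha)
  sweep(cbind(cs * rel[, 1] - sn * rel[, 2],
              sn * rel[, 1] + cs * rel[, 2]), 2L, -center)
}

## brute-force independent evaluation of the p-fold shape function
gammaBrute <- function(xy, p, center) {
  dx <- xy[, 1] - center[1]; dy <- xy[, 2] - center[2]
  r <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  sum(r^p * exp(1i * p * phi)) / sum(r^p)
}
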