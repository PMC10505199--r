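## Coarse-graining of the per-cell shape function into the scale-dependent
## shape parameter
##
##   Gamma_p(r, R) = (1/N_disk) sum_c gamma_p(r_c) Theta(R - |r - r_c|) ,
##
## sampled on a square grid of spacing R_cc/2 inside the field of view,
## with the coarse-graining radius increased in steps of R_cc/2. The
## grid-averaged magnitude per radius,
##
##   mean|Gamma_p(R)| = (1/N_grid) sum_n |Gamma_p(r_n, R)| ,
##
## quantifies p-atic order at scale R; the hexanematic crossover R_x is the
## radius at which the hexatic (p = 6) and nematic (p = 2) profiles meet.
##
## Conventions: Theta is the strict step as printed (Theta(0) = 0, so cells
## exactly at distance R are excluded); border cells never contribute
## gamma_p; grid nodes with an empty disk are NA and excluded from the
## grid average; no minimum occupancy beyond N_disk >= 1.

#' Square sampling grid for coarse-graining
#'
#' Nodes on a square lattice of spacing exactly `R_cc / 2`, covering a
#' field of view of `fov` (default 124 x 124 um, clipped to the monolayer
#' box when the box is smaller) centered in the box. The nodes are sampling
#' positions, not cell centers.
#'
#' @param monolayer a [Monolayer-class] with `rcc` available.
#' @param fov length-1 or -2 field-of-view size (um).
#' @return A list: `grid` (N x 2 node matrix, x-fastest), `dim`
#'   (c(nx, ny)), `spacing` (um), `origin` (lower-left node).
#' @export
makeGrid <- function(monolayer, fov = 124) {
  r <- rcc(monolayer)
  if (!is.finite(r) || r <= 0) stop("monolayer has no valid R_cc")
  spacing <- r / 2
  box <- boxSize(monolayer)
  fov <- rep(as.numeric(fov), length.out = 2L)
  fov <- pmin(fov, box)
  if (any(fov < spacing)) stop("field of view smaller than one grid cell")
  n <- floor(fov / spacing) + 1L
  origin <- (box - fov) / 2
  gx <- origin[1] + spacing * (seq_len(n[1]) - 1L)
  gy <- origin[2] + spacing * (seq_len(n[2]) - 1L)
  gg <- cbind(x = rep(gx, times = n[2]), y = rep(gy, each = n[1]))
  list(grid = gg, dim = as.integer(n), spacing = spacing, origin = origin)
}

#' Default coarse-graining radius ladder
#'
#' `R = R_cc/2, R_cc, 3 R_cc/2, ...` up to `maxRadius` (default: half the
#' field-of-view diagonal).
#'
#' @param rcc mean cell-cell distance (um).
#' @param fov field-of-view size, length 1 or 2 (um).
#' @param maxRadius optional ceiling (um).
#' @return Numeric vector of radii.
#' @export
radiusLadder <- function(rcc, fov = 124, maxRadius = NULL) {
  fov <- rep(as.numeric(fov), length.out = 2L)
  if (is.null(maxRadius)) maxRadius <- sqrt(sum(fov^2)) / 2
  seq(rcc / 2, maxRadius, by = rcc / 2)
}

#' Coarse-grained shape parameter on a grid
#'
#' Evaluates Gamma_p at every grid node and every radius of the ladder:
#' the complex mean of gamma_p over interior cells whose centroid lies
#' strictly within the disk. Nodes with an empty disk are NA.
#'
#' @param monolayer a [Monolayer-class].
#' @param records a [shapeTable()] for the monolayer (computed when NULL).
#' @param p symmetry order (one integer).
#' @param radii radius ladder (um); default [radiusLadder()] on the
#'   monolayer's R_cc and `fov`.
#' @param grid a [makeGrid()] result; default grid on `fov`.
#' @param fov field of view for the defaults (um).
#' @param com reference-point convention, see [gammaP()].
#' @return A [CoarseField-class].
#' @export
coarseGamma <- function(monolayer, records = NULL, p = 6L, radii = NULL,
                        grid = NULL, fov = 124, com = c("area", "vertex-mean")) {
  com <- match.arg(com)
  p <- as.integer(p)
  if (is.null(records)) records <- shapeTable(monolayer, p = p, com = com)
  if (is.null(grid)) grid <- makeGrid(monolayer, fov = fov)
  if (is.null(radii)) radii <- radiusLadder(rcc(monolayer), fov = fov)
  recI <- records[!records$is_border, , drop = FALSE]
  ids <- cellIds(monolayer)
  ctr <- centroids(monolayer)[match(recI$cell_id, ids), , drop = FALSE]
  gam <- complex(real = recI[[paste0("re_gamma", p)]],
                 imaginary = recI[[paste0("im_gamma", p)]])
  gg <- grid$grid
  ## node x cell distances
  d <- sqrt(outer(gg[, 1], ctr[, 1], "-")^2 + outer(gg[, 2], ctr[, 2], "-")^2)
  nR <- length(radii)
  vals <- matrix(NA_complex_, nrow(gg), nR)
  cnts <- matrix(0L, nrow(gg), nR)
  for (k in seq_len(nR)) {
    inc <- d < radii[k]  # Theta as printed: strict inequality
    nd <- rowSums(inc)
    s <- inc %*% gam
    vals[, k] <- ifelse(nd > 0L, s / nd, NA_complex_)
    cnts[, k] <- as.integer(nd)
  }
  new("CoarseField", p = p, radii = as.numeric(radii), rcc = rcc(monolayer),
      grid = gg, gridDim = grid$dim, values = vals, counts = cnts)
}

#' Grid-averaged magnitude profile of a coarse field
#'
#' Magnitude first, then the average over grid nodes, per radius; NA nodes
#' (empty disks) are excluded from the average. Radii at which every node
#' is empty are dropped with a warning.
#'
#' @param field a [CoarseField-class].
#' @return A data.frame with columns `radius`, `radius_norm` (R / R_cc),
#'   `mean_abs` and `n_nodes`.
#' @export
meanAbsProfile <- function(field) {
  a <- abs(fieldValues(field))
  nn <- colSums(!is.na(a))
  m <- colMeans(a, na.rm = TRUE)
  drop <- nn == 0L
  if (any(drop)) {
    warning(sprintf("%d radii dropped: all grid disks empty", sum(drop)))
  }
  data.frame(radius = radii(field)[!drop],
             radius_norm = radii(field)[!drop] / field@rcc,
             mean_abs = m[!drop],
             n_nodes = nn[!drop])
}

#' Locate the hexanematic crossover on a pair of profiles
#'
#' Finds the first radius interval on which `Delta(R) = mean|Gamma_6| -
#' mean|Gamma_2|` changes sign from positive to non-positive and returns
#' the linearly interpolated root, normalized by R_cc. When Delta never
#' changes sign the result is NA with status `"hexatic-dominated"`
#' (Delta > 0 throughout) or `"nematic-dominated"` (Delta <= 0 already at
#' the smallest radius).
#'
#' @param profile6,profile2 [meanAbsProfile()] data.frames on the same
#'   radius ladder (p = 6 and p = 2).
#' @param rcc mean cell-cell distance (um) used for normalization.
#' @return A [CrossoverProfile-class].
#' @export
hexanematicCrossover <- function(profile6, profile2, rcc) {
  if (nrow(profile6) != nrow(profile2) ||
      any(abs(profile6$radius - profile2$radius) > 1e-9)) {
    stop("profiles are on different radius ladders")
  }
  delta <- profile6$mean_abs - profile2$mean_abs
  r <- profile6$radius
  rx <- NA_real_
  status <- "hexatic-dominated"
  if (delta[1] <= 0) {
    status <- "nematic-dominated"
  } else {
    cross <- which(delta[-length(delta)] > 0 & delta[-1L] <= 0)
    if (length(cross)) {
      i <- cross[1L]
      t <- delta[i] / (delta[i] - delta[i + 1L])
      rx <- (r[i] + t * (r[i + 1L] - r[i])) / rcc
      status <- "crossover"
    }
  }
  new("CrossoverProfile", radii = r, radiiNorm = r / rcc,
      meanAbs6 = profile6$mean_abs, meanAbs2 = profile2$mean_abs,
      delta = delta, rCrossNorm = rx, status = status, rcc = rcc)
}

#' Full crossover analysis of a monolayer
#'
#' Computes the shape table, the sampling grid, the coarse fields for
#' p = 6 and p = 2 on a shared ladder, their magnitude profiles and the
#' crossover scale.
#'
#' @param monolayer a [Monolayer-class].
#' @param fov field of view (um), default 124.
#' @param maxRadius optional ladder ceiling (um).
#' @param com reference-point convention, see [gammaP()].
#' @return A list: `profile` ([CrossoverProfile-class]), `field6`,
#'   `field2` ([CoarseField-class]), `records` (shape table).
#' @export
crossoverAnalysis <- function(monolayer, fov = 124, maxRadius = NULL,
                              com = c("area", "vertex-mean")) {
  com <- match.arg(com)
  records <- shapeTable(monolayer, p = c(2L, 6L), com = com)
  grid <- makeGrid(monolayer, fov = fov)
  fovEff <- pmin(rep(as.numeric(fov), length.out = 2L), boxSize(monolayer))
  radii <- radiusLadder(rcc(monolayer), fov = fovEff, maxRadius = maxRadius)
  f6 <- coarseGamma(monolayer, records, p = 6L, radii = radii, grid = grid)
  f2 <- coarseGamma(monolayer, records, p = 2L, radii = radii, grid = grid)
  p6 <- meanAbsProfile(f6)
  p2 <- meanAbsProfile(f2)
  ## align ladders in case trailing radii were dropped on one side only
  common <- intersect(round(p6$radius, 9), round(p2$radius, 9))
  p6 <- p6[round(p6$radius, 9) %in% common, , drop = FALSE]
  p2 <- p2[round(p2$radius, 9) %in% common, , drop = FALSE]
  list(profile = hexanematicCrossover(p6, p2, rcc(monolayer)),
       field6 = f6, field2 = f2, records = records)
}

#' Plot a crossover profile
#'
#' Base-graphics view of the hexatic and nematic magnitude profiles against
#' R / R_cc, with the crossover marked.
#'
#' @param x a [CrossoverProfile-class].
#' @param ... passed to [graphics::matplot()].
#' @export
plotCrossover <- function(x, ...) {
  graphics::matplot(x@radiiNorm, cbind(x@meanAbs6, x@meanAbs2), type = "b",
                    pch = c(16, 17), lty = 1, col = c("firebrick", "navy"),
                    xlab = expression(R / R[cc]),
                    ylab = expression(group("|", bar(Gamma[p]), "|")), ...)
  graphics::legend("topright", legend = c(expression(Gamma[6]), expression(Gamma[2])),
                   col = c("firebrick", "navy"), pch = c(16, 17), bty = "n")
  if (!is.na(x@rCrossNorm)) graphics::abline(v = x@rCrossNorm, lty = 2)
  invisible(x)
}
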