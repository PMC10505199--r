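## Topological defects of the coarse-grained p-fold orientation field
## theta = Arg(Gamma_p) / p, detected by the winding number around each
## unit plaquette of the sampling grid:
##
##   s = (1/2 pi) sum_{n=1}^{4} wrap[ theta(r_{n+1}) - theta(r_n) ] ,
##
## with each difference wrapped to the symmetric principal branch
## (-pi/p, pi/p] of the 2 pi / p-periodic orientation. s is a multiple of
## 1/p; elementary defects carry +-1/p (+-1/2 nematic, +-1/6 hexatic).

#' Orientation field of a coarse field at one radius
#'
#' `theta = Arg(Gamma_p) / p`, folded into `[0, 2 pi / p)`, as a matrix in
#' grid layout (rows = x index, columns = y index). Nodes with missing or
#' zero Gamma_p are NA (orientation undefined).
#'
#' @param field a [CoarseField-class].
#' @param radiusIndex index into `radii(field)`.
#' @return List: `theta` (nx x ny matrix), `radius`, `p`, `grid` info.
#' @export
orientationField <- function(field, radiusIndex = 1L) {
  stopifnot(radiusIndex >= 1L, radiusIndex <= length(radii(field)))
  v <- fieldValues(field)[, radiusIndex]
  p <- symmetryOrder(field)
  th <- (Arg(v) %% (2 * pi)) / p
  th[!is.na(v) & Mod(v) == 0] <- NA_real_
  nd <- field@gridDim
  list(theta = matrix(th, nrow = nd[1], ncol = nd[2]),
       radius = radii(field)[radiusIndex], p = p,
       grid = gridPositions(field), dim = nd)
}

## wrap a p-atic angle difference to the branch (-pi/p, pi/p]
wrapPatic <- function(d, p) {
  period <- 2 * pi / p
  pi / p - ((pi / p - d) %% period)
}

#' Winding number of one plaquette
#'
#' Given the four corner orientations of a grid plaquette in
#' counterclockwise order, sums the branch-wrapped consecutive differences
#' (closing the loop) and divides by 2 pi. The result is snapped to the
#' nearest multiple of 1/p.
#'
#' @param theta numeric length-4 corner orientations (radians).
#' @param p symmetry order.
#' @return Winding number s, a multiple of 1/p (possibly 0).
#' @export
windingNumber <- function(theta, p) {
  if (length(theta) != 4L || any(!is.finite(theta))) {
    stop("windingNumber needs 4 finite corner angles")
  }
  d <- wrapPatic(diff(c(theta, theta[1L])), p)
  s <- sum(d) / (2 * pi)
  sSnap <- round(s * p) / p
  if (abs(s - sSnap) > 1e-6) {
    warning(sprintf("winding %.8f not a multiple of 1/%d within tolerance", s, p))
  }
  sSnap
}

#' Detect topological defects of a coarse field
#'
#' Scores every plaquette of the sampling grid at one coarse-graining
#' radius; plaquettes with nonzero winding are recorded at their centers.
#' Plaquettes with any undefined corner (empty disk or zero field) are
#' skipped. The defect density is expressed per 100 interior cells.
#'
#' @param field a [CoarseField-class].
#' @param radiusIndex index into `radii(field)`.
#' @param nCells number of interior cells the density refers to (required
#'   for a meaningful density; NA gives NA density).
#' @return A [DefectSet-class].
#' @export
findDefects <- function(field, radiusIndex = 1L, nCells = NA_integer_) {
  of <- orientationField(field, radiusIndex)
  th <- of$theta
  p <- of$p
  nx <- of$dim[1]; ny <- of$dim[2]
  gx <- matrix(of$grid[, 1], nx, ny)
  gy <- matrix(of$grid[, 2], nx, ny)
  pos <- NULL; ch <- numeric()
  nSkipped <- 0L
  for (i in seq_len(nx - 1L)) {
    for (j in seq_len(ny - 1L)) {
      corners <- c(th[i, j], th[i + 1L, j], th[i + 1L, j + 1L], th[i, j + 1L])
      if (any(!is.finite(corners))) { nSkipped <- nSkipped + 1L; next }
      s <- windingNumber(corners, p)
      if (s != 0) {
        pos <- rbind(pos, c((gx[i, j] + gx[i + 1L, j + 1L]) / 2,
                            (gy[i, j] + gy[i + 1L, j + 1L]) / 2))
        ch <- c(ch, s)
      }
    }
  }
  if (nSkipped > 0L) {
    warning(sprintf("%d plaquettes skipped (undefined orientation at a corner)", nSkipped))
  }
  if (is.null(pos)) pos <- matrix(numeric(), 0L, 2L)
  colnames(pos) <- c("x", "y")
  new("DefectSet", p = p, radius = of$radius, positions = pos,
      charges = ch, nCells = as.integer(nCells),
      densityPer100 = if (is.na(nCells)) NA_real_ else 100 * length(ch) / nCells)
}

#' Defect density along the coarse-graining radius ladder
#'
#' Computes the full crossover analysis of a monolayer, then detects
#' defects of the p-fold orientation field at every ladder radius. The
#' density at the crossover scale is evaluated at the ladder radius
#' nearest to R_x (the winding number is defined only on the ladder
#' grids); it is NA when the profile has no crossover.
#'
#' @param monolayer a [Monolayer-class].
#' @param p symmetry order (2 or 6).
#' @param fov field of view (um).
#' @param analysis optionally, a precomputed [crossoverAnalysis()] result
#'   for this monolayer (with matching `fov`).
#' @return A list: `profile` (data.frame radius, radius_norm,
#'   n_defects, n_positive, n_negative, density_per_100), `atCrossover`
#'   (one-row data.frame or NULL), `defectSets` (list of
#'   [DefectSet-class]), `rCrossNorm`.
#' @export
defectDensityVsRadius <- function(monolayer, p = 2L, fov = 124, analysis = NULL) {
  if (is.null(analysis)) analysis <- crossoverAnalysis(monolayer, fov = fov)
  field <- if (as.integer(p) == 6L) analysis$field6 else analysis$field2
  nInt <- nCells(monolayer, interior = TRUE)
  rr <- radii(field)
  sets <- vector("list", length(rr))
  rows <- vector("list", length(rr))
  for (k in seq_along(rr)) {
    ds <- suppressWarnings(findDefects(field, radiusIndex = k, nCells = nInt))
    sets[[k]] <- ds
    rows[[k]] <- data.frame(radius = rr[k], radius_norm = rr[k] / rcc(monolayer),
                            n_defects = length(defectCharges(ds)),
                            n_positive = sum(defectCharges(ds) > 0),
                            n_negative = sum(defectCharges(ds) < 0),
                            density_per_100 = defectDensity(ds))
  }
  prof <- do.call(rbind, rows)
  rx <- crossoverScale(analysis$profile)
  atX <- NULL
  if (!is.na(rx)) {
    k <- which.min(abs(rr / rcc(monolayer) - rx))
    atX <- cbind(prof[k, , drop = FALSE], r_cross_norm = rx)
  }
  list(profile = prof, atCrossover = atX, defectSets = sets, rCrossNorm = rx)
}

#' Synthetic p-atic defect orientation field
#'
#' Builds the orientation field of a superposition of point defects:
#' `theta(r) = theta0 + sum_k s_k * atan2(y - y_k, x - x_k)`, folded to
#' `[0, 2 pi / p)`, where each charge `s_k` is a multiple of 1/p. Used for
#' testing and illustration.
#'
#' @param grid an N x 2 node matrix (as from [makeGrid()]).
#' @param centers k x 2 matrix of defect positions.
#' @param charges length-k charges (multiples of 1/p).
#' @param p symmetry order.
#' @param theta0 constant background orientation.
#' @return Numeric vector of orientations, one per node, in
#'   `[0, 2 pi / p)`.
#' @export
defectPhaseField <- function(grid, centers, charges, p, theta0 = 0) {
  th <- rep(theta0, nrow(grid))
  for (k in seq_len(nrow(centers))) {
    th <- th + charges[k] * atan2(grid[, 2] - centers[k, 2],
                                  grid[, 1] - centers[k, 1])
  }
  th %% (2 * pi / p)
}

#' Wrap a CoarseField around an externally supplied orientation field
#'
#' Builds a [CoarseField-class] whose phase encodes a given orientation
#' field (unit magnitude), so the defect machinery can run on analytic
#' fields.
#'
#' @param theta orientation values per node, in radians.
#' @param grid a [makeGrid()]-style list with `grid` and `dim`.
#' @param p symmetry order.
#' @param radius nominal radius to record (um).
#' @param rcc nominal mean cell-cell distance (um).
#' @return A [CoarseField-class] with a single radius.
#' @export
fieldFromOrientation <- function(theta, grid, p, radius = 1, rcc = 1) {
  vals <- matrix(exp(1i * p * theta), ncol = 1L)
  new("CoarseField", p = as.integer(p), radii = radius, rcc = rcc,
      grid = grid$grid, gridDim = as.integer(grid$dim), values = vals,
      counts = matrix(1L, nrow(grid$grid), 1L))
}
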