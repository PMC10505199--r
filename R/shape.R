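## Per-cell shape descriptors: the shape index p0 = P / sqrt(A) and the
## complex p-fold shape function
##
##   gamma_p = sum_v |r_v|^p exp(i p phi_v) / sum_v |r_v|^p ,
##
## where r_v is the v-th vertex relative to the cell's center of mass and
## phi_v its angular coordinate. |gamma_p| <= 1 measures the resemblance to
## a regular p-gon (rod for p = 2); Arg(gamma_p)/p is the cell's p-fold
## orientation. gamma_p is translation- and scale-invariant and
## rotation-covariant: rotating the cell by alpha multiplies gamma_p by
## exp(i p alpha).

#' Shape index of a cell
#'
#' `p0 = P / sqrt(A)`: perimeter over the square root of the area.
#' Scale-invariant; bounded below by the disk value `2 sqrt(pi) ~ 3.5449`;
#' a regular hexagon gives ~3.7224. Larger values indicate elongated or
#' irregular cells.
#'
#' @param polygon a [CellPolygon-class] or an n x 2 vertex matrix.
#' @return The dimensionless shape index.
#' @examples
#' shapeIndex(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # square: 4
#' @export
shapeIndex <- function(polygon) {
  xy <- if (is(polygon, "CellPolygon")) polygon@vertices else as.matrix(polygon)
  A <- polygonArea(xy)
  if (A <= 0) stop("shape index undefined for zero-area polygon")
  polygonPerimeter(xy) / sqrt(A)
}

#' p-fold shape function of a polygon
#'
#' The complex shape function evaluated on the polygon's vertices relative
#' to its center of mass. The center of mass is the area centroid by
#' default; the arithmetic vertex mean is available via `com` (the two
#' differ for irregular polygons).
#'
#' @param polygon a [CellPolygon-class] or an n x 2 vertex matrix (>= 3
#'   vertices).
#' @param p integer symmetry order, `p >= 1`.
#' @param com reference point: `"area"` (area centroid) or
#'   `"vertex-mean"`.
#' @return A single complex number with `Mod(.) <= 1`.
#' @examples
#' Mod(gammaP(regularPolygon(6), 6))  # 1
#' Mod(gammaP(regularPolygon(6), 2))  # 0
#' @export
gammaP <- function(polygon, p, com = c("area", "vertex-mean")) {
  com <- match.arg(com)
  xy <- if (is(polygon, "CellPolygon")) polygon@vertices else as.matrix(polygon)
  if (nrow(xy) < 3L) stop("gamma_p needs at least 3 vertices")
  p <- as.integer(p)
  if (p < 1L) stop("p must be a positive integer")
  ctr <- polygonCentroid(xy, method = if (com == "area") "area" else "vertex-mean")
  z <- complex(real = xy[, 1] - ctr[1], imaginary = xy[, 2] - ctr[2])
  r <- Mod(z)
  if (all(r < .Machine$double.eps)) stop("all vertices coincide with the reference point")
  w <- r^p
  sum(w * exp(1i * p * Arg(z))) / sum(w)
}

#' p-fold orientation of a polygon
#'
#' `Arg(gamma_p) / p`, folded into `[0, 2 pi / p)`.
#'
#' @inheritParams gammaP
#' @return Orientation angle in radians.
#' @export
pFoldOrientation <- function(polygon, p, com = c("area", "vertex-mean")) {
  g <- gammaP(polygon, p, com)
  (Arg(g) %% (2 * pi)) / p
}

#' Per-cell shape record table of a monolayer
#'
#' Computes, for every cell, the shape index and the complex shape
#' functions for each requested `p`, returning one row per cell with
#' columns `cell_id`, `is_border`, `p0`, and per p: `re_gamma<p>`,
#' `im_gamma<p>`, `abs_gamma<p>`, `theta<p>` (the p-fold orientation).
#'
#' @param monolayer a [Monolayer-class].
#' @param p integer vector of symmetry orders (default `c(2, 6)`).
#' @param com reference-point convention, see [gammaP()].
#' @return A `data.frame`, one row per cell (border cells included and
#'   flagged; downstream ensemble statistics exclude them).
#' @export
shapeTable <- function(monolayer, p = c(2L, 6L), com = c("area", "vertex-mean")) {
  com <- match.arg(com)
  cells <- cellPolygons(monolayer)
  out <- data.frame(cell_id = cellIds(monolayer),
                    is_border = isBorder(monolayer),
                    p0 = vapply(cells, shapeIndex, numeric(1)))
  for (pp in as.integer(p)) {
    g <- vapply(cells, function(cp) gammaP(cp, pp, com), complex(1))
    out[[paste0("re_gamma", pp)]] <- Re(g)
    out[[paste0("im_gamma", pp)]] <- Im(g)
    out[[paste0("abs_gamma", pp)]] <- Mod(g)
    out[[paste0("theta", pp)]] <- (Arg(g) %% (2 * pi)) / pp
  }
  out
}

#' Ensemble-averaged shape function magnitude
#'
#' The arithmetic mean of `|gamma_p|` over cells: magnitudes first, then
#' the average (the order matters -- phases never cancel here). Border
#' cells are excluded when a [Monolayer-class] or a [shapeTable()] with the
#' `is_border` column is given.
#'
#' @param x a [Monolayer-class], a [shapeTable()] data.frame, or a numeric
#'   vector of `|gamma_p|` values.
#' @param p symmetry order (ignored when `x` is already a vector of
#'   magnitudes).
#' @param com reference-point convention, see [gammaP()].
#' @return Mean magnitude in `[0, 1]`.
#' @export
ensembleAverage <- function(x, p, com = c("area", "vertex-mean")) {
  if (is(x, "Monolayer")) x <- shapeTable(x, p = p, com = com)
  if (is.data.frame(x)) {
    col <- paste0("abs_gamma", as.integer(p))
    if (!col %in% names(x)) stop("shape table lacks column ", col)
    vals <- x[[col]][!x$is_border]
  } else {
    vals <- as.numeric(x)
  }
  if (!length(vals)) stop("ensemble average of an empty cell set")
  mean(vals)
}

#' Mean cell-cell distance of a monolayer
#'
#' The mean Euclidean centroid-to-centroid distance over unordered neighbor
#' pairs in which both cells are interior (each pair counted once). With
#' `per = "cell"`, the mean of per-cell mean neighbor distances is returned
#' instead (both conventions are reported in the field; the pairwise one is
#' the package default).
#'
#' @param monolayer a [Monolayer-class] with adjacency.
#' @param per `"pair"` (default) or `"cell"`.
#' @return R_cc in um.
#' @export
meanCellCellDistance <- function(monolayer, per = c("pair", "cell")) {
  per <- match.arg(per)
  ids <- cellIds(monolayer)
  ctr <- centroids(monolayer)
  pairs <- neighborPairs(monolayer, interiorOnly = TRUE)
  if (nrow(pairs) == 0L) stop("no interior neighbor pairs: cannot compute R_cc")
  i <- match(pairs[, 1L], ids); j <- match(pairs[, 2L], ids)
  d <- sqrt(rowSums((ctr[i, , drop = FALSE] - ctr[j, , drop = FALSE])^2))
  if (per == "pair") return(mean(d))
  ## per-cell mean first, then average over interior cells with neighbors
  interior <- ids[!isBorder(monolayer)]
  acc <- tapply(c(d, d), c(pairs[, 1L], pairs[, 2L]), mean)
  mean(acc[as.character(interior[interior %in% as.integer(names(acc))])])
}

#' Neighbor-count distribution
#'
#' Probability distribution of the number of nearest neighbors per interior
#' cell (the vertex count of an interior cell equals its neighbor count in
#' a junction tiling).
#'
#' @param monolayer a [Monolayer-class].
#' @return A named numeric vector of probabilities summing to 1, names =
#'   neighbor counts.
#' @export
neighborDistribution <- function(monolayer) {
  counts <- lengths(adjacencyList(monolayer))[!isBorder(monolayer)]
  if (!length(counts)) return(numeric(0))
  tab <- table(counts)
  pr <- as.numeric(tab) / sum(tab)
  names(pr) <- names(tab)
  pr
}
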