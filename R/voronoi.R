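## Voronoi tessellation of a planar point set, clipped to a rectangular box.
##
## Each cell is computed by Sutherland-Hodgman clipping of the box rectangle
## against the perpendicular-bisector half-planes of nearby seed points.
## Edge provenance is tracked through the clipping, so the neighbor relation
## (cells sharing a Voronoi edge) and box contact (border cells) come out of
## the construction exactly, with no tolerance-based vertex matching.
## Cells are convex throughout, which the early-termination bound relies on:
## once half the distance to the next candidate seed exceeds the cell's
## circumradius, no further seed can clip the cell.

## Clip a convex polygon (vertices V, edge labels E with E[i] labelling the
## edge V[i] -> V[i+1]) by the half-plane dot(x, nrm) <= cval. The newly
## created edge along the clip line is labelled `newLabel`.
clipHalfPlane <- function(V, E, nrm, cval, newLabel, eps) {
  d <- V %*% nrm - cval
  inside <- d <= eps
  if (all(inside)) return(list(V = V, E = E))
  if (!any(inside)) return(list(V = NULL, E = NULL))
  k <- nrow(V)
  outV <- matrix(0, k + 2L, 2L)
  outE <- integer(k + 2L)
  m <- 0L
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (inside[i]) {
      m <- m + 1L; outV[m, ] <- V[i, ]; outE[m] <- E[i]
      if (!inside[j]) {
        ## leaving: exit intersection starts the closing edge
        t <- d[i] / (d[i] - d[j])
        m <- m + 1L; outV[m, ] <- V[i, ] + t * (V[j, ] - V[i, ]); outE[m] <- newLabel
      }
    } else if (inside[j]) {
      ## entering: remainder of this edge keeps its label
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L; outV[m, ] <- V[i, ] + t * (V[j, ] - V[i, ]); outE[m] <- E[i]
    }
  }
  list(V = outV[seq_len(m), , drop = FALSE], E = outE[seq_len(m)])
}

#' Voronoi cells of a point set, clipped to a box
#'
#' Computes, for every seed point, its Voronoi cell intersected with the
#' rectangle `[0, box[1]] x [0, box[2]]`. Seeds may lie outside the box
#' (margin seeds); seeds whose cell does not intersect the box yield NULL.
#'
#' @param points n x 2 matrix of seed positions (um).
#' @param box length-2 numeric `(width, height)`; the box has its origin at
#'   (0, 0).
#' @return A list with one entry per seed: NULL, or a list with `vertices`
#'   (CCW m x 2 matrix), `neighbors` (indices into `points` of seeds sharing
#'   an edge of positive length), and `onBox` (TRUE if the cell touches the
#'   box boundary).
#' @keywords internal
voronoiCells <- function(points, box) {
  n <- nrow(points)
  scale <- max(box)
  eps <- 1e-9 * scale
  lenEps <- 1e-7 * scale
  boxV <- rbind(c(0, 0), c(box[1], 0), c(box[1], box[2]), c(0, box[2]))
  boxE <- c(-1L, -2L, -3L, -4L)  # bottom, right, top, left
  out <- vector("list", n)
  for (i in seq_len(n)) {
    pi. <- points[i, ]
    d2 <- (points[, 1] - pi.[1])^2 + (points[, 2] - pi.[2])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    V <- boxV; E <- boxE
    for (j in ord) {
      dij <- sqrt(d2[j])
      ## circumradius of current cell around the seed
      rmax2 <- max((V[, 1] - pi.[1])^2 + (V[, 2] - pi.[2])^2)
      if ((dij / 2)^2 > rmax2) break
      nrm <- points[j, ] - pi.
      cval <- (sum(points[j, ]^2) - sum(pi.^2)) / 2
      cl <- clipHalfPlane(V, E, nrm, cval, j, eps)
      V <- cl$V; E <- cl$E
      if (is.null(V) || nrow(V) < 3L) { V <- NULL; break }
    }
    if (is.null(V)) next
    ## drop zero-length edges (clipping slivers)
    elen <- sqrt(rowSums((rbind(V[-1L, , drop = FALSE], V[1L, , drop = FALSE]) - V)^2))
    keep <- elen > lenEps
    if (sum(keep) < 3L) next
    V <- V[keep, , drop = FALSE]; E <- E[keep]
    out[[i]] <- list(vertices = V, edgeLabels = E,
                     neighbors = sort(unique(E[E > 0L])),
                     onBox = any(E < 0L))
  }
  out
}

#' Tessellate seed points into a Monolayer
#'
#' Voronoi tessellation of the seeds, clipped to the box. The cells
#' partition the box (confluency): areas sum to the box area. Cells touching
#' the box boundary are flagged as border cells, and the adjacency is the
#' shared-Voronoi-edge relation. The mean cell-cell distance of the interior
#' cells is computed and stored.
#'
#' @param points n x 2 matrix of seed positions (um), n >= 16. Seeds may
#'   extend beyond the box (margin).
#' @param box length-2 numeric `(width, height)` in um.
#' @param pixelSize um/px to record on the monolayer (NA for pure ground
#'   truth).
#' @return A [Monolayer-class].
#' @examples
#' pts <- triangularLattice(10, c(50, 50), margin = 10)
#' ml <- tessellate(pts, c(50, 50))
#' nCells(ml)
#' @export
tessellate <- function(points, box, pixelSize = NA_real_) {
  points <- as.matrix(points)
  if (nrow(points) < 16L) {
    stop("tessellation needs at least 16 seed points, got ", nrow(points))
  }
  ## degenerate input checks
  dup <- duplicatedPoints(points, tol = 1e-9 * max(box))
  if (length(dup)) {
    stop("duplicate seed points at indices: ", paste(dup, collapse = ", "))
  }
  if (allCollinear(points)) {
    stop("seed points are collinear (indices 1..", nrow(points), "); cannot tessellate")
  }
  cells <- voronoiCells(points, box)
  keep <- which(!vapply(cells, is.null, logical(1)))
  if (length(keep) < 1L) stop("no Voronoi cell intersects the box")
  id <- integer(nrow(points)); id[keep] <- seq_along(keep)
  cps <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    cl <- cells[[keep[k]]]
    nb <- id[cl$neighbors]
    nb <- nb[nb > 0L]
    cps[[k]] <- CellPolygon(cellId = k, vertices = cl$vertices,
                            neighborIds = nb,
                            isBorder = cl$onBox || touchesBox(cl$vertices, box))
  }
  Monolayer(cells = cps, box = box, pixelSize = pixelSize)
}

## indices of points participating in a duplicate pair
duplicatedPoints <- function(points, tol) {
  n <- nrow(points)
  if (n > 4000L) return(integer())  # generator-scale inputs are pre-cleaned
  d <- as.matrix(stats::dist(points))
  diag(d) <- Inf
  which(apply(d < tol, 1L, any))
}

allCollinear <- function(points) {
  if (nrow(points) < 3L) return(TRUE)
  p0 <- points[1L, ]
  v <- sweep(points[-1L, , drop = FALSE], 2L, p0)
  cr <- v[1, 1] * v[, 2] - v[1, 2] * v[, 1]
  all(abs(cr) < 1e-9 * max(abs(v)))
}

## clip a convex labelled polygon to the rectangle [0, box[1]] x [0, box[2]];
## new edges along the rectangle get negative labels; NULL when outside
clipToBox <- function(V, E, box) {
  eps <- 1e-9 * max(box)
  sides <- list(list(nrm = c(0, -1), cval = 0,      lab = -1L),  # bottom
                list(nrm = c(1, 0),  cval = box[1], lab = -2L),  # right
                list(nrm = c(0, 1),  cval = box[2], lab = -3L),  # top
                list(nrm = c(-1, 0), cval = 0,      lab = -4L))  # left
  for (s in sides) {
    cl <- clipHalfPlane(V, E, s$nrm, s$cval, s$lab, eps)
    V <- cl$V; E <- cl$E
    if (is.null(V) || nrow(V) < 3L) return(NULL)
  }
  elen <- sqrt(rowSums((rbind(V[-1L, , drop = FALSE], V[1L, , drop = FALSE]) - V)^2))
  keep <- elen > 1e-7 * max(box)
  if (sum(keep) < 3L) return(NULL)
  list(V = V[keep, , drop = FALSE], E = E[keep])
}

## TRUE when any vertex lies (numerically) on the box boundary
touchesBox <- function(V, box) {
  eps <- 1e-7 * max(box)
  any(V[, 1] < eps | V[, 1] > box[1] - eps |
      V[, 2] < eps | V[, 2] > box[2] - eps)
}
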