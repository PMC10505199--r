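## Planar polygon primitives shared by the generator, the segmentation and
## the shape descriptors. All functions take an n x 2 matrix of vertices in
## micrometres, ordered along the contour (either orientation accepted).

#' Signed area of a polygon
#'
#' Shoelace formula; positive for counterclockwise vertex order.
#'
#' @param xy numeric matrix with two columns (x, y), one row per vertex.
#' @return Signed area in squared input units.
#' @keywords internal
polygonSignedArea <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (absolute)
#' @inheritParams polygonSignedArea
#' @return Area, a positive number.
#' @export
polygonArea <- function(xy) abs(polygonSignedArea(xy))

#' Polygon perimeter
#' @inheritParams polygonSignedArea
#' @return Total edge length.
#' @export
polygonPerimeter <- function(xy) {
  d <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE]) - xy
  sum(sqrt(rowSums(d^2)))
}

#' Polygon centroid
#'
#' Either the area centroid (center of mass of the uniform lamina) or the
#' arithmetic mean of the vertices. The two differ for irregular polygons;
#' both are supported as reference points for the shape function.
#'
#' @inheritParams polygonSignedArea
#' @param method `"area"` for the area centroid, `"vertex-mean"` for the
#'   plain vertex average.
#' @return Numeric length-2 vector (x, y).
#' @export
polygonCentroid <- function(xy, method = c("area", "vertex-mean")) {
  method <- match.arg(method)
  if (method == "vertex-mean") return(colMeans(xy))
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * max(1, sum(abs(xy)))) {
    ## degenerate (zero-area) polygon: fall back to the vertex mean
    return(colMeans(xy))
  }
  c(sum((x + xn) * cross), sum((y + yn) * cross)) / (6 * a)
}

#' Enforce counterclockwise vertex order
#' @inheritParams polygonSignedArea
#' @return The same matrix, reversed if the input was clockwise.
#' @keywords internal
ensureCCW <- function(xy) {
  if (polygonSignedArea(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

#' Test whether a polygon is simple (non-self-intersecting)
#'
#' Brute-force pairwise segment intersection test; adequate for cell-sized
#' polygons (tens of vertices).
#'
#' @inheritParams polygonSignedArea
#' @return Logical scalar.
#' @keywords internal
isSimplePolygon <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  seg <- function(i) list(a = xy[i, ], b = xy[if (i == n) 1L else i + 1L, ])
  crossz <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(p, q) {
    d1 <- crossz(q$a, q$b, p$a); d2 <- crossz(q$a, q$b, p$b)
    d3 <- crossz(p$a, p$b, q$a); d4 <- crossz(p$a, p$b, q$b)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ## skip adjacent edges (they share an endpoint)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (intersects(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

#' Construct the vertices of a regular polygon
#'
#' @param n number of vertices (>= 3).
#' @param circumradius distance from center to each vertex.
#' @param center numeric length-2 center.
#' @param rotation rotation of the first vertex, radians.
#' @return An n x 2 vertex matrix in counterclockwise order.
#' @export
regularPolygon <- function(n, circumradius = 1, center = c(0, 0), rotation = 0) {
  stopifnot(n >= 3L, circumradius > 0)
  ang <- rotation + 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = center[1] + circumradius * cos(ang),
        y = center[2] + circumradius * sin(ang))
}
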