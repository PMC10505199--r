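## Accessors and show() methods. Slot access stays inside the package;
## users go through these.

#' @describeIn Monolayer number of cells (all, or interior only).
#' @param object,interior see individual methods.
#' @export
setMethod("nCells", "Monolayer", function(object, interior = FALSE) {
  if (interior) sum(!isBorder(object)) else length(object@cells)
})

#' @describeIn Monolayer integer ids of the cells.
#' @export
setMethod("cellIds", "Monolayer", function(object) {
  vapply(object@cells, function(cp) cp@cellId, integer(1))
})

#' @describeIn Monolayer list of [CellPolygon-class] objects.
#' @export
setMethod("cellPolygons", "Monolayer", function(object) object@cells)

#' @describeIn Monolayer n x 2 matrix of area centroids (um).
#' @export
setMethod("centroids", "Monolayer", function(object) {
  m <- t(vapply(object@cells, function(cp) cp@centroid, numeric(2)))
  colnames(m) <- c("x", "y")
  m
})

#' @describeIn Monolayer vector of cell areas (um^2).
#' @export
setMethod("cellAreas", "Monolayer", function(object) {
  vapply(object@cells, function(cp) cp@area, numeric(1))
})

#' @describeIn Monolayer vector of cell perimeters (um).
#' @export
setMethod("cellPerimeters", "Monolayer", function(object) {
  vapply(object@cells, function(cp) cp@perimeter, numeric(1))
})

#' @describeIn Monolayer logical vector flagging border cells.
#' @export
setMethod("isBorder", "Monolayer", function(object) {
  vapply(object@cells, function(cp) cp@isBorder, logical(1))
})

#' @describeIn Monolayer adjacency as a list of neighbor id vectors, named
#'   by cell id.
#' @export
setMethod("adjacencyList", "Monolayer", function(object) {
  out <- lapply(object@cells, function(cp) cp@neighborIds)
  names(out) <- as.character(cellIds(object))
  out
})

#' @describeIn Monolayer unordered neighbor pairs as a 2-column matrix of
#'   cell ids (each pair once); `interiorOnly` restricts to pairs of two
#'   interior cells.
#' @param interiorOnly logical.
#' @export
setMethod("neighborPairs", "Monolayer", function(object, interiorOnly = FALSE) {
  ids <- cellIds(object)
  keep <- if (interiorOnly) !isBorder(object) else rep(TRUE, length(ids))
  okId <- ids[keep]
  pairs <- do.call(rbind, lapply(object@cells[keep], function(cp) {
    nb <- cp@neighborIds
    nb <- nb[nb > cp@cellId & nb %in% okId]
    if (length(nb)) cbind(a = rep(cp@cellId, length(nb)), b = nb) else NULL
  }))
  if (is.null(pairs)) pairs <- matrix(integer(), 0L, 2L, dimnames = list(NULL, c("a", "b")))
  pairs
})

#' @describeIn Monolayer mean cell-cell distance R_cc (um).
#' @export
setMethod("rcc", "Monolayer", function(object) object@rcc)

#' @describeIn Monolayer field-of-view size c(width, height) in um.
#' @export
setMethod("boxSize", "Monolayer", function(object) object@box)

#' @describeIn Monolayer um/px of the source image (NA for ground truth).
#' @export
setMethod("pixelSize", "Monolayer", function(object) object@pixelSize)

setMethod("show", "Monolayer", function(object) {
  nb <- sum(isBorder(object))
  cat(sprintf("Monolayer: %d cells (%d interior, %d border)\n",
              nCells(object), nCells(object) - nb, nb))
  cat(sprintf("  box: %.1f x %.1f um; pixel size: %s um/px; R_cc: %s um\n",
              object@box[1], object@box[2],
              format(object@pixelSize, digits = 4),
              format(object@rcc, digits = 4)))
})

setMethod("show", "CellPolygon", function(object) {
  cat(sprintf("CellPolygon %d: %d vertices, area %.2f um^2, perimeter %.2f um%s\n",
              object@cellId, nrow(object@vertices), object@area,
              object@perimeter, if (object@isBorder) " (border)" else ""))
})

#' @describeIn CoarseField radius ladder (um).
#' @param object a CoarseField.
#' @export
setMethod("radii", "CoarseField", function(object) object@radii)

#' @describeIn CoarseField grid node positions (um).
#' @export
setMethod("gridPositions", "CoarseField", function(object) object@grid)

#' @describeIn CoarseField complex Gamma_p values, N_grid x N_radii.
#' @export
setMethod("fieldValues", "CoarseField", function(object) object@values)

#' @describeIn CoarseField disk occupancy N_disk per node and radius.
#' @export
setMethod("diskCounts", "CoarseField", function(object) object@counts)

#' @describeIn CoarseField the symmetry order p.
#' @export
setMethod("symmetryOrder", "CoarseField", function(object) object@p)

setMethod("show", "CoarseField", function(object) {
  cat(sprintf("CoarseField (p = %d): %d grid nodes (%d x %d), %d radii [%.2f .. %.2f um]\n",
              object@p, nrow(object@grid), object@gridDim[1], object@gridDim[2],
              length(object@radii), min(object@radii), max(object@radii)))
})

#' @describeIn CrossoverProfile normalized crossover scale R_x / R_cc (NA
#'   when the profile never changes sign).
#' @param object a CrossoverProfile.
#' @export
setMethod("crossoverScale", "CrossoverProfile", function(object) object@rCrossNorm)

setMethod("show", "CrossoverProfile", function(object) {
  cat(sprintf("CrossoverProfile: %d radii, R_cc = %.2f um, status: %s\n",
              length(object@radii), object@rcc, object@status))
  if (!is.na(object@rCrossNorm)) {
    cat(sprintf("  R_x / R_cc = %.3f (R_x = %.2f um)\n",
                object@rCrossNorm, object@rCrossNorm * object@rcc))
  }
})

#' @describeIn DefectSet signed charges (multiples of 1/p).
#' @param object a DefectSet.
#' @export
setMethod("defectCharges", "DefectSet", function(object) object@charges)

#' @describeIn DefectSet defect positions (plaquette centers, um).
#' @export
setMethod("defectPositions", "DefectSet", function(object) object@positions)

#' @describeIn DefectSet defects per 100 interior cells.
#' @export
setMethod("defectDensity", "DefectSet", function(object) object@densityPer100)

#' @describeIn DefectSet the symmetry order p.
#' @export
setMethod("symmetryOrder", "DefectSet", function(object) object@p)

setMethod("show", "DefectSet", function(object) {
  cat(sprintf("DefectSet (p = %d, R = %.2f um): %d defects (%d positive, %d negative), %.2f per 100 cells\n",
              object@p, object@radius, length(object@charges),
              sum(object@charges > 0), sum(object@charges < 0),
              object@densityPer100))
})
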