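#' CellPolygon: one segmented cell
#'
#' The straight-line polygon of a single cell, in micrometres, together with
#' derived geometry and its adjacency in the monolayer. Vertices are stored
#' in counterclockwise order; the neighbor relation is kept symmetric by the
#' containing [Monolayer-class].
#'
#' @slot cellId integer cell identifier, unique within a monolayer.
#' @slot vertices V x 2 matrix of (x, y) vertex positions in um,
#'   counterclockwise.
#' @slot centroid length-2 area centroid (um).
#' @slot area polygon area (um^2).
#' @slot perimeter polygon perimeter (um).
#' @slot neighborIds integer ids of cells sharing an edge with this one.
#' @slot isBorder TRUE when the cell touches the field-of-view boundary;
#'   border cells are kept but excluded from ensemble statistics.
#'
#' @exportClass CellPolygon
setClass("CellPolygon",
  representation(
    cellId      = "integer",
    vertices    = "matrix",
    centroid    = "numeric",
    area        = "numeric",
    perimeter   = "numeric",
    neighborIds = "integer",
    isBorder    = "logical"
  )
)

setValidity("CellPolygon", function(object) {
  v <- object@vertices
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 2L) msg <- c(msg, "vertices must be an n x 2 numeric matrix")
  else {
    if (nrow(v) < 3L) msg <- c(msg, "polygon needs at least 3 vertices")
    else {
      if (polygonSignedArea(v) <= 0) msg <- c(msg, "vertices must be in counterclockwise order with positive area")
      if (!isSimplePolygon(v)) msg <- c(msg, "polygon is self-intersecting")
    }
  }
  if (length(object@cellId) != 1L) msg <- c(msg, "cellId must be a single integer")
  if (length(object@isBorder) != 1L) msg <- c(msg, "isBorder must be a single flag")
  if (length(msg)) msg else TRUE
})

#' Construct a CellPolygon
#'
#' Geometry (centroid, area, perimeter) is derived from the vertices, which
#' are re-ordered counterclockwise if needed.
#'
#' @param cellId integer id.
#' @param vertices n x 2 vertex matrix (um), either orientation.
#' @param neighborIds integer vector of adjacent cell ids.
#' @param isBorder logical flag.
#' @return A [CellPolygon-class] object.
#' @export
CellPolygon <- function(cellId, vertices, neighborIds = integer(), isBorder = FALSE) {
  vertices <- ensureCCW(as.matrix(vertices))
  colnames(vertices) <- c("x", "y")
  new("CellPolygon",
      cellId = as.integer(cellId),
      vertices = vertices,
      centroid = as.numeric(polygonCentroid(vertices)),
      area = polygonArea(vertices),
      perimeter = polygonPerimeter(vertices),
      neighborIds = as.integer(neighborIds),
      isBorder = isTRUE(isBorder))
}

#' Monolayer: a confluent tiling of cell polygons
#'
#' A set of [CellPolygon-class] objects with their adjacency, the bounding
#' box of the field of view, the pixel size of the source image (NA for
#' ground-truth polygons) and the mean cell-cell distance R_cc.
#'
#' @slot cells list of [CellPolygon-class] objects.
#' @slot box length-2 numeric, field-of-view width and height in um.
#' @slot pixelSize um per pixel of the source image; NA when the monolayer
#'   did not come from an image.
#' @slot rcc mean centroid distance between neighboring interior cells (um);
#'   NA until computed.
#'
#' @seealso [generateMonolayer()], [segmentMonolayer()],
#'   [meanCellCellDistance()]
#' @exportClass Monolayer
setClass("Monolayer",
  representation(
    cells     = "list",
    box       = "numeric",
    pixelSize = "numeric",
    rcc       = "numeric"
  ),
  prototype(pixelSize = NA_real_, rcc = NA_real_)
)

setValidity("Monolayer", function(object) {
  msg <- character()
  if (length(object@box) != 2L || any(object@box <= 0)) {
    msg <- c(msg, "box must be two positive lengths (width, height)")
  }
  ids <- vapply(object@cells, function(cp) cp@cellId, integer(1))
  if (anyDuplicated(ids)) msg <- c(msg, "cell ids must be unique")
  nb <- lapply(object@cells, function(cp) cp@neighborIds)
  if (length(ids) && !all(unlist(nb) %in% ids)) {
    msg <- c(msg, "every neighborId must resolve to a cell in the monolayer")
  }
  ## symmetry of the neighbor relation
  if (length(ids)) {
    idx <- match(seq_len(max(ids, 0L)), ids)
    for (k in seq_along(ids)) {
      for (j in nb[[k]]) {
        back <- nb[[idx[j]]]
        if (!(ids[k] %in% back)) {
          msg <- c(msg, sprintf("neighbor relation not symmetric between cells %d and %d", ids[k], j))
          break
        }
      }
      if (length(msg)) break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Monolayer
#'
#' @param cells list of [CellPolygon-class] objects.
#' @param box length-2 field-of-view size (um).
#' @param pixelSize um/px of the source image, or NA.
#' @param rcc mean cell-cell distance; computed from the adjacency when NA
#'   and at least one interior neighbor pair exists.
#' @return A [Monolayer-class] object.
#' @export
Monolayer <- function(cells, box, pixelSize = NA_real_, rcc = NA_real_) {
  ml <- new("Monolayer", cells = cells, box = as.numeric(box),
            pixelSize = as.numeric(pixelSize), rcc = as.numeric(rcc))
  if (is.na(rcc)) {
    rcc.try <- tryCatch(meanCellCellDistance(ml), error = function(e) NA_real_)
    ml@rcc <- rcc.try
  }
  ml
}

#' CoarseField: the scale-dependent shape parameter on a grid
#'
#' Complex coarse-grained shape parameter Gamma_p(r_n, R): for each node r_n
#' of a square grid (spacing R_cc/2) and each radius R of a ladder in steps
#' of R_cc/2, the mean of the per-cell shape function gamma_p over interior
#' cells whose centroid lies strictly within the disk of radius R around
#' r_n. Nodes whose disk holds no cell are NA.
#'
#' @slot p integer symmetry order (2 = nematic, 6 = hexatic).
#' @slot radii radius ladder (um).
#' @slot rcc mean cell-cell distance used for grid spacing and normalization.
#' @slot grid N_grid x 2 matrix of node positions (um).
#' @slot gridDim integer (nx, ny): nodes per axis; grid is stored x-fastest.
#' @slot values complex N_grid x N_radii matrix of Gamma_p.
#' @slot counts integer N_grid x N_radii matrix of disk occupancies N_disk.
#'
#' @exportClass CoarseField
setClass("CoarseField",
  representation(
    p       = "integer",
    radii   = "numeric",
    rcc     = "numeric",
    grid    = "matrix",
    gridDim = "integer",
    values  = "matrix",
    counts  = "matrix"
  )
)

setValidity("CoarseField", function(object) {
  msg <- character()
  if (!is.complex(object@values)) msg <- c(msg, "values must be complex")
  if (nrow(object@values) != nrow(object@grid)) msg <- c(msg, "values rows must match grid nodes")
  if (ncol(object@values) != length(object@radii)) msg <- c(msg, "values columns must match radii")
  if (prod(object@gridDim) != nrow(object@grid)) msg <- c(msg, "gridDim inconsistent with grid")
  a <- abs(object@values)
  if (any(a > 1 + 1e-9, na.rm = TRUE)) msg <- c(msg, "|Gamma_p| must not exceed 1")
  if (length(msg)) msg else TRUE
})

#' CrossoverProfile: hexanematic difference profile and crossover scale
#'
#' Grid-averaged magnitudes of the hexatic and nematic shape parameters on a
#' shared radius ladder, their difference Delta(R) = |Gamma_6| - |Gamma_2|,
#' and the crossover scale R_x (first downward zero crossing of Delta,
#' linearly interpolated), normalized by R_cc.
#'
#' @slot radii radius ladder (um).
#' @slot radiiNorm ladder normalized by R_cc.
#' @slot meanAbs6,meanAbs2 grid-mean |Gamma_p| per radius.
#' @slot delta meanAbs6 - meanAbs2.
#' @slot rCrossNorm R_x / R_cc, or NA when Delta never changes sign.
#' @slot status `"crossover"`, `"hexatic-dominated"` or `"nematic-dominated"`.
#' @slot rcc mean cell-cell distance (um).
#'
#' @exportClass CrossoverProfile
setClass("CrossoverProfile",
  representation(
    radii      = "numeric",
    radiiNorm  = "numeric",
    meanAbs6   = "numeric",
    meanAbs2   = "numeric",
    delta      = "numeric",
    rCrossNorm = "numeric",
    status     = "character",
    rcc        = "numeric"
  )
)

#' DefectSet: topological defects of one orientation field
#'
#' Positions and signed charges (multiples of 1/p) of the singularities of
#' the coarse-grained p-fold orientation field at one coarse-graining
#' radius, with the defect density per 100 interior cells.
#'
#' @slot p integer symmetry order.
#' @slot radius coarse-graining radius (um).
#' @slot positions n x 2 matrix of plaquette centers (um).
#' @slot charges numeric vector of winding numbers (multiples of 1/p).
#' @slot nCells number of interior cells the density refers to.
#' @slot densityPer100 100 * number of defects / nCells.
#'
#' @exportClass DefectSet
setClass("DefectSet",
  representation(
    p             = "integer",
    radius        = "numeric",
    positions     = "matrix",
    charges       = "numeric",
    nCells        = "integer",
    densityPer100 = "numeric"
  )
)

setValidity("DefectSet", function(object) {
  msg <- character()
  if (nrow(object@positions) != length(object@charges)) {
    msg <- c(msg, "positions and charges must have equal length")
  }
  if (length(object@charges)) {
    mult <- object@charges * object@p
    if (any(abs(mult - round(mult)) > 1e-6) || any(round(mult) == 0)) {
      msg <- c(msg, "charges must be nonzero multiples of 1/p")
    }
  }
  if (length(msg)) msg else TRUE
})
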