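## Plain-text and TIFF interchange. Polygons travel as long-format CSV
## (cell_id, vertex_index, x_um, y_um) or the equivalent JSON; adjacency
## as an edge-list CSV; images as single-channel TIFF with the pixel size
## recorded in the resolution tag.

#' Write monolayer polygons as CSV
#'
#' Long format: one row per vertex, columns `cell_id`, `vertex_index`,
#' `x_um`, `y_um`, `is_border`.
#'
#' @param monolayer a [Monolayer-class].
#' @param path output file.
#' @export
writePolygonsCSV <- function(monolayer, path) {
  rows <- do.call(rbind, lapply(cellPolygons(monolayer), function(cp) {
    data.frame(cell_id = cp@cellId,
               vertex_index = seq_len(nrow(cp@vertices)) - 1L,
               x_um = cp@vertices[, 1], y_um = cp@vertices[, 2],
               is_border = cp@isBorder)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write monolayer adjacency as an edge-list CSV
#'
#' Columns `cell_a`, `cell_b`, each unordered neighbor pair once.
#'
#' @inheritParams writePolygonsCSV
#' @export
writeAdjacencyCSV <- function(monolayer, path) {
  pairs <- neighborPairs(monolayer)
  utils::write.csv(data.frame(cell_a = pairs[, 1], cell_b = pairs[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a monolayer as JSON
#'
#' Full structure: box, pixel size, R_cc, and per cell the vertices,
#' neighbor ids and border flag.
#'
#' @inheritParams writePolygonsCSV
#' @export
writeMonolayerJSON <- function(monolayer, path) {
  obj <- list(
    box_um = boxSize(monolayer),
    pixel_size_um = pixelSize(monolayer),
    rcc_um = rcc(monolayer),
    cells = lapply(cellPolygons(monolayer), function(cp) {
      list(cell_id = cp@cellId,
           vertices_um = unname(cp@vertices),
           neighbor_ids = cp@neighborIds,
           is_border = cp@isBorder)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read monolayer polygons from CSV (+ optional adjacency)
#'
#' Rebuilds a [Monolayer-class] from [writePolygonsCSV()] output. The
#' adjacency edge list is optional; without it neighbor sets are empty and
#' R_cc cannot be computed.
#'
#' @param path polygons CSV.
#' @param adjacencyPath optional adjacency CSV.
#' @param box length-2 box size (um); default: bounding box of the
#'   vertices.
#' @param pixelSize um/px to record (NA for ground truth).
#' @return A [Monolayer-class].
#' @export
readPolygonsCSV <- function(path, adjacencyPath = NULL, box = NULL,
                            pixelSize = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("cell_id", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("polygons CSV must have columns: ", paste(need, collapse = ", "))
  }
  adj <- NULL
  if (!is.null(adjacencyPath)) adj <- utils::read.csv(adjacencyPath)
  sp <- split(df, df$cell_id)
  cells <- lapply(sp, function(s) {
    s <- s[order(s$vertex_index), , drop = FALSE]
    nb <- integer()
    if (!is.null(adj)) {
      nb <- c(adj$cell_b[adj$cell_a == s$cell_id[1]],
              adj$cell_a[adj$cell_b == s$cell_id[1]])
    }
    CellPolygon(cellId = s$cell_id[1], vertices = cbind(s$x_um, s$y_um),
                neighborIds = nb,
                isBorder = if ("is_border" %in% names(s)) any(s$is_border) else FALSE)
  })
  names(cells) <- NULL
  if (is.null(box)) {
    box <- c(max(df$x_um), max(df$y_um))
  }
  Monolayer(cells = cells, box = box, pixelSize = pixelSize)
}

#' Read a monolayer from JSON
#'
#' Counterpart of [writeMonolayerJSON()].
#'
#' @param path JSON file.
#' @return A [Monolayer-class].
#' @export
readMonolayerJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- lapply(seq_len(nrow(obj$cells)), function(i) {
    CellPolygon(cellId = obj$cells$cell_id[i],
                vertices = obj$cells$vertices_um[[i]],
                neighborIds = unlist(obj$cells$neighbor_ids[i]),
                isBorder = obj$cells$is_border[i])
  })
  Monolayer(cells = cells, box = unlist(obj$box_um),
            pixelSize = if (is.null(obj$pixel_size_um)) NA_real_ else obj$pixel_size_um,
            rcc = if (is.null(obj$rcc_um)) NA_real_ else obj$rcc_um)
}

#' Write a junction image as single-channel TIFF
#'
#' Intensities are rescaled to [0, 1] for 16-bit storage. The pixel size
#' travels in a small JSON sidecar (`<path>.meta.json`) next to the
#' image.
#'
#' @param image numeric matrix, or a [renderJunctionImage()] list.
#' @param path output file.
#' @param pixelSize um per pixel (taken from the list if present).
#' @export
writeImageTIFF <- function(image, path, pixelSize = NULL) {
  if (is.list(image)) {
    if (is.null(pixelSize)) pixelSize <- image$pixelSize
    image <- image$image
  }
  if (is.null(pixelSize)) stop("pixelSize is required")
  rng <- range(image)
  img01 <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  tiff::writeTIFF(img01, path, bits.per.sample = 16L)
  jsonlite::write_json(list(pixel_size_um = pixelSize,
                            intensity_range = rng),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a junction image from TIFF
#'
#' Reads the pixel size from the [writeImageTIFF()] sidecar, or from a
#' resolution tag written by other software; an explicit `pixelSize`
#' overrides both.
#'
#' @param path TIFF file.
#' @param pixelSize um per pixel; overrides file metadata.
#' @return A list: `image` (numeric matrix), `pixelSize` (um/px, NA when
#'   absent from file metadata and the argument).
#' @export
readImageTIFF <- function(path, pixelSize = NULL) {
  img <- tiff::readTIFF(path, info = TRUE)
  if (is.null(pixelSize)) {
    pixelSize <- NA_real_
    meta <- paste0(path, ".meta.json")
    if (file.exists(meta)) {
      obj <- jsonlite::read_json(meta, simplifyVector = TRUE)
      if (!is.null(obj$pixel_size_um)) pixelSize <- obj$pixel_size_um
    } else {
      res <- attr(img, "x.resolution")
      unit <- attr(img, "resolution.unit")
      if (!is.null(res) && res > 0) {
        perUm <- switch(ifelse(is.null(unit), "inch", unit),
                        cm = res / 1e4, inch = res / 2.54e4, res / 1e4)
        pixelSize <- 1 / perUm
      }
    }
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  list(image = unclass(as.matrix(img)), pixelSize = pixelSize)
}

#' Echo a generator configuration as JSON
#'
#' @param config a [monolayerConfig()].
#' @param path output file.
#' @export
writeConfigJSON <- function(config, path) {
  sl <- methods::slotNames(class(config))
  obj <- lapply(stats::setNames(sl, sl), function(s) methods::slot(config, s))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a per-cell shape record table as CSV
#'
#' @param records a [shapeTable()] data.frame.
#' @param path output file.
#' @export
writeShapeTableCSV <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
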