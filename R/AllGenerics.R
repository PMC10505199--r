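#' @name hexanematic-generics
#' @title Generics for monolayer containers
#' @description Accessor generics for the S4 containers of the package.
#' @param object a package object.
#' @param ... passed to methods.
NULL

#' @rdname hexanematic-generics
#' @export
setGeneric("nCells", function(object, ...) standardGeneric("nCells"))

#' @rdname hexanematic-generics
#' @export
setGeneric("cellIds", function(object, ...) standardGeneric("cellIds"))

#' @rdname hexanematic-generics
#' @export
setGeneric("cellPolygons", function(object, ...) standardGeneric("cellPolygons"))

#' @rdname hexanematic-generics
#' @export
setGeneric("centroids", function(object, ...) standardGeneric("centroids"))

#' @rdname hexanematic-generics
#' @export
setGeneric("cellAreas", function(object, ...) standardGeneric("cellAreas"))

#' @rdname hexanematic-generics
#' @export
setGeneric("cellPerimeters", function(object, ...) standardGeneric("cellPerimeters"))

#' @rdname hexanematic-generics
#' @export
setGeneric("isBorder", function(object, ...) standardGeneric("isBorder"))

#' @rdname hexanematic-generics
#' @export
setGeneric("adjacencyList", function(object, ...) standardGeneric("adjacencyList"))

#' @rdname hexanematic-generics
#' @export
setGeneric("neighborPairs", function(object, ...) standardGeneric("neighborPairs"))

#' @rdname hexanematic-generics
#' @export
setGeneric("rcc", function(object, ...) standardGeneric("rcc"))

#' @rdname hexanematic-generics
#' @export
setGeneric("boxSize", function(object, ...) standardGeneric("boxSize"))

#' @rdname hexanematic-generics
#' @export
setGeneric("pixelSize", function(object, ...) standardGeneric("pixelSize"))

#' @rdname hexanematic-generics
#' @export
setGeneric("radii", function(object, ...) standardGeneric("radii"))

#' @rdname hexanematic-generics
#' @export
setGeneric("gridPositions", function(object, ...) standardGeneric("gridPositions"))

#' @rdname hexanematic-generics
#' @export
setGeneric("fieldValues", function(object, ...) standardGeneric("fieldValues"))

#' @rdname hexanematic-generics
#' @export
setGeneric("diskCounts", function(object, ...) standardGeneric("diskCounts"))

#' @rdname hexanematic-generics
#' @export
setGeneric("symmetryOrder", function(object, ...) standardGeneric("symmetryOrder"))

#' @rdname hexanematic-generics
#' @export
setGeneric("crossoverScale", function(object, ...) standardGeneric("crossoverScale"))

#' @rdname hexanematic-generics
#' @export
setGeneric("defectCharges", function(object, ...) standardGeneric("defectCharges"))

#' @rdname hexanematic-generics
#' @export
setGeneric("defectPositions", function(object, ...) standardGeneric("defectPositions"))

#' @rdname hexanematic-generics
#' @export
setGeneric("defectDensity", function(object, ...) standardGeneric("defectDensity"))
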