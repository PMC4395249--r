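#' @name netscale-accessors
#' @title Accessors for netscale S4 containers
#' @description Accessor generics for the core containers. Slot access via
#'   `@` is internal; user code should go through these.
#' @param x an object.
#' @param ... further arguments for methods.
NULL

#' @rdname netscale-accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname netscale-accessors
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))
#' @rdname netscale-accessors
#' @export
setGeneric("landmarkIds", function(x) standardGeneric("landmarkIds"))
#' @rdname netscale-accessors
#' @export
setGeneric("centerVertices", function(x) standardGeneric("centerVertices"))
#' @rdname netscale-accessors
#' @export
setGeneric("patchRadius", function(x) standardGeneric("patchRadius"))
#' @rdname netscale-accessors
#' @export
setGeneric("nFibers", function(x) standardGeneric("nFibers"))
#' @rdname netscale-accessors
#' @export
setGeneric("fiberPoints", function(x, i) standardGeneric("fiberPoints"))
#' @rdname netscale-accessors
#' @export
setGeneric("fiberScalar", function(x, name) standardGeneric("fiberScalar"))
#' @rdname netscale-accessors
#' @export
setGeneric("connectionValues",
           function(x) standardGeneric("connectionValues"))
#' @rdname netscale-accessors
#' @export
setGeneric("fiberCounts", function(x) standardGeneric("fiberCounts"))
#' @rdname netscale-accessors
#' @export
setGeneric("combinedDistance",
           function(x) standardGeneric("combinedDistance"))
#' @rdname netscale-accessors
#' @export
setGeneric("featureG", function(x) standardGeneric("featureG"))
#' @rdname netscale-accessors
#' @export
setGeneric("featureP", function(x) standardGeneric("featureP"))

#' @rdname netscale-accessors
#' @export
setGeneric("nScales", function(x) standardGeneric("nScales"))

#' Per-scale label vector from a multi-scale partition
#'
#' @param x a [NetworkTree-class].
#' @param scale integer scale index; scale 1 is the root (one block), scale
#'   s cuts the tree at depth s - 1 with non-split nodes persisting.
#' @return named integer vector of block labels over landmark ids.
#' @export
setGeneric("scaleLabels", function(x, scale) standardGeneric("scaleLabels"))

#' @rdname netscale-accessors
#' @export
setGeneric("bundleAssignments",
           function(x) standardGeneric("bundleAssignments"))
#' @rdname netscale-accessors
#' @export
setGeneric("sceneSubject", function(x, i) standardGeneric("sceneSubject"))
#' @rdname netscale-accessors
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))
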