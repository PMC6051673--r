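#' Accessors for ecmap classes
#'
#' Small accessor layer so user code never reaches into slots directly.
#'
#' @param x an ecmap object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname accessors
#' @export
setMethod("mapValues", "ECMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("mapValues", "CorrelationMap", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("mapValues", "TimeSeriesMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("voxelCoords", "ECMap", function(x) x@voxelIndex)

#' @rdname accessors
#' @export
setMethod("voxelCoords", "TimeSeriesMatrix", function(x) x@voxelIndex)

#' @rdname accessors
#' @export
setMethod("voxelCoords", "StatMap", function(x) x@voxelIndex)

#' @rdname accessors
#' @export
setMethod("voxelCoords", "CorrelationMap", function(x) x@voxelIndex)

#' @rdname accessors
#' @export
setMethod("gridDim", "TimeSeriesMatrix", function(x) x@gridDim)

#' @rdname accessors
#' @export
setMethod("gridDim", "ECMap", function(x) x@gridDim)

#' @rdname accessors
#' @export
setMethod("gridDim", "StatMap", function(x) x@gridDim)

#' @rdname accessors
#' @export
setMethod("affineMatrix", "BOLDRun", function(x) x@affine)

#' @rdname accessors
#' @export
setMethod("affineMatrix", "VoxelMask", function(x) x@affine)

#' @rdname accessors
#' @export
setMethod("affineMatrix", "TimeSeriesMatrix", function(x) x@affine)

#' @rdname accessors
#' @export
setMethod("designMatrix", "StudyDesign", function(x) x@design)
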