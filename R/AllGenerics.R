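#' @rdname CTVolume-class
#' @param object,x a `CTVolume` (or subclass).
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname CTVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname CTVolume-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname CTVolume-class
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname CombinedVolume-class
#' @param x a `CombinedVolume`.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname CombinedVolume-class
#' @export
setGeneric("combineMethod", function(x) standardGeneric("combineMethod"))

#' Rigidly resample a volume onto a target grid
#'
#' @param x object to resample.
#' @param ... method arguments.
#' @export
setGeneric("resample", function(x, ...) standardGeneric("resample"))

#' @rdname RigidTransform-class
#' @param x a `RigidTransform`.
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname RigidTransform-class
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' @rdname Sinogram-class
#' @param x a `Sinogram`.
#' @export
setGeneric("sinogramData", function(x) standardGeneric("sinogramData"))

#' @rdname Sinogram-class
#' @export
setGeneric("projectionAngles", function(x) standardGeneric("projectionAngles"))
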