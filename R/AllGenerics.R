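#' Bottleneck shape of a segmentation network
#'
#' Spatial extent and channel count of the central latent tensor:
#' input_shape / 16 per axis (four 2x2x2 poolings) by the last encoder
#' channel count.
#'
#' @param object a [SegNetModel-class] or [UNetConfig-class].
#' @return integer 4-vector (x, y, z, channels).
#' @export
setGeneric("bottleneckShape", function(object) standardGeneric("bottleneckShape"))

#' Length of the flattened central latent vector
#' @param object a [SegNetModel-class] or [UNetConfig-class].
#' @return integer, the product of [bottleneckShape()].
#' @export
setGeneric("latentLength", function(object) standardGeneric("latentLength"))

#' Clinical long table of a cohort
#' @param object a [PhantomCohort-class].
#' @return data.frame, one row per scan.
#' @export
setGeneric("clinicalTable", function(object) standardGeneric("clinicalTable"))

#' Patients x features activation matrix of a panel
#' @param object a [FeaturePanel-class].
#' @return numeric matrix, patients in rows, latent features in columns.
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

setMethod("bottleneckShape", "UNetConfig", function(object)
  c(object@input_shape %/% 16L, object@encoder_channels[4L]))

setMethod("bottleneckShape", "SegNetModel", function(object)
  bottleneckShape(object@config))

setMethod("latentLength", "UNetConfig", function(object)
  prod(bottleneckShape(object)))

setMethod("latentLength", "SegNetModel", function(object)
  latentLength(object@config))

setMethod("clinicalTable", "PhantomCohort", function(object) object@clinical)
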