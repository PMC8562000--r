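#' Access the pixel grid of an image-like object
#' @param x an object with a pixel grid slot.
#' @return numeric matrix of pixels.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' Physical scan width in mm
#' @param x an object carrying scan geometry.
#' @export
setGeneric("scanWidthMm", function(x) standardGeneric("scanWidthMm"))

#' Plexus label of an angiogram ("SCP" or "DCP")
#' @param x an [EnFaceAngiogram-class].
#' @export
setGeneric("plexusLabel", function(x) standardGeneric("plexusLabel"))

#' Eye identifier of an angiogram
#' @param x an [EnFaceAngiogram-class].
#' @export
setGeneric("eyeId", function(x) standardGeneric("eyeId"))

#' Area of an extracted FAZ in mm^2
#' @param x a [FAZResult-class].
#' @export
setGeneric("fazAreaMm2", function(x) standardGeneric("fazAreaMm2"))

#' @describeIn EnFaceAngiogram pixel grid accessor
#' @param x object
#' @export
setMethod("pixels", "EnFaceAngiogram", function(x) x@pixels)
#' @export
setMethod("pixels", "BinaryMap", function(x) x@pixels)
#' @export
setMethod("pixels", "RegionMask", function(x) x@pixels)
#' @export
setMethod("pixels", "FAZResult", function(x) x@componentMask)
#' @export
setMethod("pixels", "PhantomTruth", function(x) x@vesselMask)

#' @export
setMethod("scanWidthMm", "EnFaceAngiogram", function(x) x@scanWidthMm)
#' @export
setMethod("scanWidthMm", "BinaryMap", function(x) x@scanWidthMm)
#' @export
setMethod("scanWidthMm", "RegionMask", function(x) x@scanWidthMm)
#' @export
setMethod("scanWidthMm", "FAZResult", function(x) x@scanWidthMm)
#' @export
setMethod("scanWidthMm", "PhantomTruth", function(x) x@scanWidthMm)

#' @export
setMethod("plexusLabel", "EnFaceAngiogram", function(x) x@plexus)
#' @export
setMethod("eyeId", "EnFaceAngiogram", function(x) x@eyeId)
#' @export
setMethod("fazAreaMm2", "FAZResult", function(x) x@areaMm2)

setMethod("show", "EnFaceAngiogram", function(object) {
  cat(sprintf("EnFaceAngiogram %s [%s], %d x %d px, %.1f mm scan, range [%g, %g]\n",
              object@eyeId, object@plexus, nrow(object@pixels),
              ncol(object@pixels), object@scanWidthMm,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "VesselMap", function(object) {
  cat(sprintf("VesselMap %d x %d px, %.1f mm scan, %d vessel px (%.1f%%)\n",
              nrow(object@pixels), ncol(object@pixels), object@scanWidthMm,
              sum(object@pixels), 100 * mean(object@pixels)))
})

setMethod("show", "SkeletonMap", function(object) {
  cat(sprintf("SkeletonMap %d x %d px, %.1f mm scan, %d centerline px\n",
              nrow(object@pixels), ncol(object@pixels), object@scanWidthMm,
              sum(object@pixels)))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask '%s': %g-%g mm diameter, center (%.1f, %.1f), %d px\n",
              object@label, object@innerDiameterMm, object@outerDiameterMm,
              object@centerPx[1], object@centerPx[2], sum(object@pixels)))
})

setMethod("show", "FAZResult", function(object) {
  cat(sprintf("FAZResult: %.4f mm^2 (%d px), centroid (%.1f, %.1f)\n",
              object@areaMm2, sum(object@componentMask),
              object@centroidPx[1], object@centroidPx[2]))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(paste0("PhantomTruth: FAZ %.3f mm^2; VAD fov/para %.3f/%.3f; ",
                     "VSD fov/para %.3f/%.3f\n"),
              object@trueFazAreaMm2, object@trueVadFoveal,
              object@trueVadParafoveal, object@trueVsdFoveal,
              object@trueVsdParafoveal))
})
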