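#' EnFaceAngiogram: a single-plexus en-face OCTA image
#'
#' Holds the pixel grid of one en-face angiogram together with its physical
#' scan geometry and plexus label. Raw instrument exports are 8-bit (values
#' 0..255); after [grayscaleAndCrop()] pixels are real-valued in [0, 1].
#'
#' @slot pixels numeric matrix (square) of pixel intensities.
#' @slot scanWidthMm physical width of the scanned field in mm (3.0 for a
#'   3x3 mm macular scan).
#' @slot plexus `"SCP"` (superficial) or `"DCP"` (deep capillary plexus).
#' @slot eyeId free-form eye identifier.
#' @export
setClass("EnFaceAngiogram",
  representation(pixels = "matrix", scanWidthMm = "numeric",
                 plexus = "character", eyeId = "character"),
  prototype(scanWidthMm = 3, plexus = "SCP", eyeId = ""))

setValidity("EnFaceAngiogram", function(object) {
  p <- object@pixels
  if (nrow(p) != ncol(p)) return("pixel grid must be square")
  if (length(object@scanWidthMm) != 1L || object@scanWidthMm <= 0)
    return("scanWidthMm must be a single positive number")
  if (!object@plexus %in% c("SCP", "DCP"))
    return("plexus must be 'SCP' or 'DCP'")
  TRUE
})

#' BinaryMap: base class for binary pixel grids with scan geometry
#'
#' @slot pixels integer/numeric matrix with values in {0, 1}.
#' @slot scanWidthMm physical scan width in mm.
#' @export
setClass("BinaryMap",
  representation(pixels = "matrix", scanWidthMm = "numeric", "VIRTUAL"))

validBinary <- function(object) {
  p <- object@pixels
  if (!all(p %in% c(0, 1))) return("pixels must be binary (0/1)")
  if (length(object@scanWidthMm) != 1L || object@scanWidthMm <= 0)
    return("scanWidthMm must be a single positive number")
  TRUE
}

#' VesselMap: binary segmentation of the vasculature
#' @export
setClass("VesselMap", contains = "BinaryMap")
setValidity("VesselMap", validBinary)

#' SkeletonMap: one-pixel-wide vessel centerlines
#'
#' Subset of its parent [VesselMap-class]; maximum local thickness is one
#' pixel (no 2x2 block of the grid is fully set).
#' @export
setClass("SkeletonMap", contains = "BinaryMap")
setValidity("SkeletonMap", function(object) {
  ok <- validBinary(object)
  if (!isTRUE(ok)) return(ok)
  p <- object@pixels
  blocks <- p[-nrow(p), -ncol(p)] * p[-1, -ncol(p)] *
            p[-nrow(p), -1] * p[-1, -1]
  if (any(blocks > 0)) return("skeleton thicker than 1 px (full 2x2 block)")
  TRUE
})

#' RegionMask: ETDRS-style sampling region (foveal disc or parafoveal ring)
#'
#' @slot pixels binary matrix marking the region.
#' @slot label `"foveal"` (1-mm-diameter central disc) or `"parafoveal"`
#'   (annulus between the 1-mm and 3-mm circles).
#' @slot centerPx (row, col) of the fovea center in pixel coordinates.
#' @slot innerDiameterMm,outerDiameterMm bounding circle diameters in mm.
#' @slot scanWidthMm physical scan width in mm.
#' @export
setClass("RegionMask",
  representation(pixels = "matrix", label = "character",
                 centerPx = "numeric", innerDiameterMm = "numeric",
                 outerDiameterMm = "numeric", scanWidthMm = "numeric"))

setValidity("RegionMask", function(object) {
  if (!object@label %in% c("foveal", "parafoveal"))
    return("label must be 'foveal' or 'parafoveal'")
  if (!all(object@pixels %in% c(0, 1))) return("pixels must be binary")
  if (object@innerDiameterMm < 0 ||
      object@outerDiameterMm <= object@innerDiameterMm)
    return("need 0 <= innerDiameterMm < outerDiameterMm")
  TRUE
})

#' FAZResult: an extracted foveal avascular zone
#'
#' @slot componentMask binary matrix of the selected avascular component
#'   (a single 8-connected component).
#' @slot areaMm2 component area in mm^2.
#' @slot centroidPx (row, col) centroid in pixel coordinates.
#' @slot boundary n x 2 matrix of (row, col) contour pixels.
#' @slot scanWidthMm physical scan width in mm.
#' @export
setClass("FAZResult",
  representation(componentMask = "matrix", areaMm2 = "numeric",
                 centroidPx = "numeric", boundary = "matrix",
                 scanWidthMm = "numeric"))

setValidity("FAZResult", function(object) {
  if (!all(object@componentMask %in% c(0, 1)))
    return("componentMask must be binary")
  if (object@areaMm2 < 0) return("areaMm2 must be >= 0")
  TRUE
})

#' PhantomTruth: exact ground truth of a synthetic angiogram
#'
#' @slot vesselMask,fazMask binary matrices (disjoint).
#' @slot trueVadFoveal,trueVadParafoveal,trueVsdFoveal,trueVsdParafoveal
#'   pixel-counted vessel area / skeleton densities within the region masks.
#' @slot trueFazAreaMm2 rasterized FAZ area in mm^2.
#' @slot foveaCenterPx (row, col) of the fovea center.
#' @slot scanWidthMm physical scan width in mm.
#' @export
setClass("PhantomTruth",
  representation(vesselMask = "matrix", fazMask = "matrix",
                 trueVadFoveal = "numeric", trueVadParafoveal = "numeric",
                 trueVsdFoveal = "numeric", trueVsdParafoveal = "numeric",
                 trueFazAreaMm2 = "numeric", foveaCenterPx = "numeric",
                 scanWidthMm = "numeric"))

setValidity("PhantomTruth", function(object) {
  if (any(object@vesselMask * object@fazMask > 0))
    return("vesselMask and fazMask must be disjoint")
  dens <- c(object@trueVadFoveal, object@trueVadParafoveal,
            object@trueVsdFoveal, object@trueVsdParafoveal)
  if (any(dens < 0 | dens > 1)) return("densities must lie in [0, 1]")
  TRUE
})
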