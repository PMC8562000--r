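## Reading raw exports and writing masks. PNG/TIFF handling goes through
## EBImage (which wraps the png/tiff readers); pixel data are kept as plain
## matrices inside the package classes.

#' Read an en-face angiogram from a PNG or TIFF file
#'
#' Grayscale images load directly; RGB images are kept as 3-channel arrays
#' so [grayscaleAndCrop()] can collapse them by luminance. Values are
#' returned on the 8-bit 0..255 scale.
#'
#' @param path image file path.
#' @param scanWidthMm physical scan width of the export.
#' @param plexus plexus label ("SCP" or "DCP").
#' @param eyeId eye identifier.
#' @return an [EnFaceAngiogram-class] (RGB input is collapsed by luminance).
#' @export
readAngiogram <- function(path, scanWidthMm = 3.0, plexus = "SCP",
                          eyeId = basename(path)) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  m <- EBImage::imageData(img)
  if (length(d) == 3) {
    if (d[3] < 3) m <- m[, , 1]
    else m <- 0.299 * m[, , 1] + 0.587 * m[, , 2] + 0.114 * m[, , 3]
  }
  new("EnFaceAngiogram", pixels = as.matrix(m) * 255,
      scanWidthMm = scanWidthMm, plexus = plexus, eyeId = eyeId)
}

#' Write a binary mask or 8-bit image as PNG
#'
#' @param x a [BinaryMap-class], [FAZResult-class], [EnFaceAngiogram-class]
#'   or matrix; values are rescaled to [0, 1] for writing.
#' @param path output file path (extension selects the format).
#' @return the path, invisibly.
#' @export
writeImageFile <- function(x, path) {
  m <- pixelsOf(x)
  if (max(m) > 1) m <- m / 255
  EBImage::writeImage(asImage(m), path)
  invisible(path)
}

pixelsOf <- function(x) {
  if (is(x, "EnFaceAngiogram")) return(x@pixels)
  if (is(x, "BinaryMap")) return(x@pixels)
  if (is(x, "FAZResult")) return(x@componentMask)
  asMatrix(x)
}
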