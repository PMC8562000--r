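## Foveal avascular zone extraction from the raw angiogram: adaptive
## ("variable") thresholding that marks only clear vessel margins, removal
## of small speckle components, morphological linking of the capillary ring,
## then selection of the largest background component near the image center.

#' FAZ extraction configuration
#'
#' @param windowPx side of the moving window of the adaptive threshold
#'   (odd; default 25 px).
#' @param offset intensity offset above the local mean required to call a
#'   pixel vessel foreground; excludes speckle inside avascular zones.
#' @param maxHolePx foreground specks of at most this many pixels are
#'   removed (~1.4e3 um^2 at 8.24 um/px).
#' @param linkElements list of structuring-element sizes (rows x cols) used
#'   to close inter-capillary gaps at the FAZ rim.
#' @param centerCapMm candidate components must have their centroid within
#'   this distance (mm) of the image center (scans are fovea-centered).
#' @param minAreaMm2 candidates smaller than this are rasterization-scale
#'   inter-capillary gaps, not a FAZ, and are ignored.
#' @param excludeBorder drop candidate components touching the image border
#'   (the FAZ never does; peripheral avascular background always does).
#' @param dilateSelected dilate the selected component once with a 3x3
#'   element to compensate the rim erosion introduced by the linking step.
#' @return validated list of class \code{FazConfig}.
#' @export
fazConfig <- function(windowPx = 25L, offset = 0.10, maxHolePx = 20L,
                      linkElements = list(c(5L, 5L), c(9L, 1L), c(1L, 9L)),
                      centerCapMm = 0.75, minAreaMm2 = 0.05,
                      excludeBorder = TRUE, dilateSelected = FALSE) {
  cfg <- list(windowPx = as.integer(windowPx), offset = offset,
              maxHolePx = as.integer(maxHolePx), linkElements = linkElements,
              centerCapMm = centerCapMm, minAreaMm2 = minAreaMm2,
              excludeBorder = excludeBorder, dilateSelected = dilateSelected)
  if (cfg$windowPx < 3L) stop("windowPx must be >= 3")
  if (cfg$maxHolePx < 0L) stop("maxHolePx must be >= 0")
  class(cfg) <- "FazConfig"
  cfg
}

#' Variable-threshold binarization of a raw angiogram
#'
#' Mean-based adaptive thresholding: a pixel is vessel foreground when its
#' intensity exceeds the local window mean by \code{offset}. Because the
#' threshold tracks the local background, only clear vessel margins are
#' marked, and speckle or motion noise inside avascular zones — which stays
#' near the local mean — is excluded.
#'
#' @param angiogram an [EnFaceAngiogram-class] or numeric matrix; 8-bit
#'   values are rescaled to [0, 1].
#' @param windowPx moving-window side in px.
#' @param offset required excess over the local mean.
#' @return binary matrix (1 = vessel foreground).
#' @export
binarizeVariableThreshold <- function(angiogram, windowPx = 25L,
                                      offset = 0.10) {
  m <- if (is(angiogram, "EnFaceAngiogram")) angiogram@pixels
       else asMatrix(angiogram)
  if (max(m) > 1) m <- m / 255
  half <- max(1L, as.integer(windowPx) %/% 2L)
  fg <- EBImage::thresh(asImage(m), w = half, h = half, offset = offset)
  asMatrix(fg) + 0
}

#' Remove small foreground specks
#'
#' Deletes 8-connected foreground components of at most \code{maxHolePx}
#' pixels (isolated speckle dots inside avascular regions); larger
#' structures are untouched.
#'
#' @param binary binary matrix.
#' @param maxHolePx maximum component size to remove.
#' @return cleaned binary matrix.
#' @export
removeSmallSpecks <- function(binary, maxHolePx = 20L) {
  m <- asMatrix(binary)
  if (maxHolePx < 1L || !any(m > 0)) return((m > 0) + 0)
  lab <- labelComponents(m, connectivity = 8)
  sizes <- componentSizes(lab)
  small <- which(sizes <= maxHolePx)
  out <- (m > 0) + 0
  if (length(small)) out[lab %in% small] <- 0
  out
}

#' Morphologically link vessel edges around the FAZ
#'
#' Applies a sequence of morphological closings with square and rectangular
#' structuring elements so that small inter-capillary gaps at the FAZ rim
#' are bridged and the avascular background becomes one enclosed region.
#'
#' @param binary binary matrix of vessel foreground.
#' @param elements list of (rows, cols) element sizes.
#' @return linked binary matrix.
#' @export
morphologicalOpenLink <- function(binary,
                                  elements = list(c(3L, 3L), c(5L, 1L),
                                                  c(1L, 5L))) {
  m <- (asMatrix(binary) > 0) + 0
  if (!any(m > 0)) return(m)
  img <- asImage(m)
  for (el in elements) {
    kern <- matrix(1, el[1], el[2])
    img <- EBImage::closing(img, kern)
  }
  (asMatrix(img) > 0) + 0
}

#' Extract the foveal avascular zone
#'
#' Runs [binarizeVariableThreshold()], [removeSmallSpecks()] and
#' [morphologicalOpenLink()] on the raw angiogram, then inverts the
#' foreground: avascular candidates are the 8-connected background
#' components. Among candidates whose centroid lies within
#' \code{centerCapMm} of the image center, the largest is selected as the
#' FAZ; its area is the pixel count times the pixel area.
#'
#' @param angiogram an [EnFaceAngiogram-class] (raw image; a 365 x 365
#'   export is cropped first).
#' @param config a [fazConfig()] list.
#' @return a [FAZResult-class].
#' @examples
#' ph <- generatePhantom(phantomParams(noiseSigma = 0, rngSeed = 3))
#' faz <- extractFaz(ph$angiogram)
#' fazAreaMm2(faz)
#' @export
extractFaz <- function(angiogram, config = fazConfig()) {
  stopifnot(is(angiogram, "EnFaceAngiogram"), inherits(config, "FazConfig"))
  a <- if (nrow(angiogram@pixels) %% 2 == 1) grayscaleAndCrop(angiogram)
       else angiogram
  m <- a@pixels
  if (max(m) > 1) m <- m / 255
  n <- nrow(m)
  mmPerPx <- a@scanWidthMm / n
  fg <- binarizeVariableThreshold(m, windowPx = config$windowPx,
                                  offset = config$offset)
  fg <- removeSmallSpecks(fg, maxHolePx = config$maxHolePx)
  fg <- morphologicalOpenLink(fg, elements = config$linkElements)
  bg <- (fg == 0) + 0
  lab <- labelComponents(bg, connectivity = 8)
  nComp <- max(lab)
  if (nComp == 0)
    stop("FAZ not found: no avascular candidate component")
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  sizes <- componentSizes(lab)
  rows <- ((which(lab > 0) - 1) %% n) + 1
  cols <- ((which(lab > 0) - 1) %/% n) + 1
  labs <- lab[lab > 0]
  cenR <- tapply(rows, labs, mean)
  cenC <- tapply(cols, labs, mean)
  dMm <- sqrt((cenR - ctr[1])^2 + (cenC - ctr[2])^2) * mmPerPx
  central <- which(dMm <= config$centerCapMm &
                   sizes * mmPerPx^2 >= config$minAreaMm2)
  if (isTRUE(config$excludeBorder)) {
    onBorder <- tapply(rows == 1 | rows == n | cols == 1 | cols == n,
                       labs, any)
    central <- central[!onBorder[central]]
  }
  if (!length(central))
    stop("FAZ not found: no candidate component within ", config$centerCapMm,
         " mm of the image center (expected for burnout eyes)")
  sel <- central[which.max(sizes[central])]
  mask <- (lab == sel) + 0
  if (isTRUE(config$dilateSelected)) {
    mask <- asMatrix(EBImage::dilate(asImage(mask), matrix(1, 3, 3)))
    mask <- (mask > 0) + 0
    ## dilation may touch neighboring background; keep a single component
    lab2 <- labelComponents(mask, connectivity = 8)
    keep <- lab2[round(cenR[sel]), round(cenC[sel])]
    if (keep == 0) keep <- which.max(componentSizes(lab2))
    mask <- (lab2 == keep) + 0
  }
  idx <- which(mask > 0)
  centroid <- c(mean(((idx - 1) %% n) + 1), mean(((idx - 1) %/% n) + 1))
  contour <- EBImage::ocontour(asImage(mask))
  boundary <- if (length(contour)) contour[[1]] + 1  # (row, col), 1-based
              else matrix(numeric(0), 0, 2)
  new("FAZResult", componentMask = mask, areaMm2 = sum(mask) * mmPerPx^2,
      centroidPx = centroid, boundary = boundary, scanWidthMm = a@scanWidthMm)
}
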