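## Binarization, skeletonization and regional density measurement. Densities
## follow the en-face OCTA conventions: VAD (vessel area density) is the
## fraction of region area covered by binarized vessels; VSD (vessel
## skeleton density) is the fraction covered by 1-px-wide centerlines.

#' Otsu binarization of a vesselness map
#'
#' The threshold maximizes the between-class variance of a 256-bin histogram
#' over [0, 1]; pixels strictly above the threshold form the (bright) vessel
#' class. A constant map yields an all-background result with a warning.
#'
#' @param map numeric matrix in [0, 1] (a vesselness map), optionally with a
#'   \code{"scanWidthMm"} attribute.
#' @param scanWidthMm scan width; defaults to the map attribute or 3 mm.
#' @return a [VesselMap-class]; attribute \code{"threshold"} carries the
#'   upper edge of the selected background bin (vessels are the pixels at
#'   or above it) and \code{"thresholdBin"} the 0-based 256-bin index.
#' @export
binarizeOtsu <- function(map, scanWidthMm = NULL) {
  m <- asMatrix(map)
  if (any(m < 0 | m > 1)) stop("binarizeOtsu: map values must lie in [0, 1]")
  sw <- scanWidthMm
  if (is.null(sw)) sw <- attr(map, "scanWidthMm")
  if (is.null(sw)) sw <- 3
  if (diff(range(m)) == 0) {
    warning("binarizeOtsu: constant map, returning all-background")
    out <- new("VesselMap", pixels = matrix(0, nrow(m), ncol(m)),
               scanWidthMm = sw)
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  b <- pmin(floor(m * 256), 255)          # 0-based bin index
  h <- as.double(tabulate(b + 1L, 256L))
  lv <- 0:255
  w1 <- cumsum(h)
  s1 <- cumsum(h * lv)
  tot <- w1[256L]; stot <- s1[256L]
  w2 <- tot - w1
  bcv <- w1 * w2 * (s1 / w1 - (stot - s1) / w2)^2
  bcv[!is.finite(bcv)] <- -Inf
  t <- which.max(bcv[1:255]) - 1L         # background class = bins 0..t
  out <- new("VesselMap", pixels = (b > t) + 0, scanWidthMm = sw)
  attr(out, "threshold") <- (t + 1) / 256
  attr(out, "thresholdBin") <- t
  out
}

#' Foveal and parafoveal sampling masks
#'
#' Rasterizes the ETDRS-style sampling geometry: a foveal disc of 1 mm
#' diameter and a parafoveal annulus between the 1 mm and 3 mm circles, both
#' centered on the fovea, at scale \code{scanWidthMm / sidePx} mm/px.
#'
#' @param sidePx image side in px.
#' @param scanWidthMm physical scan width in mm.
#' @param centerPx fovea center (row, col); defaults to the image center.
#' @param innerDiameterMm,outerDiameterMm circle diameters (1 and 3 mm).
#' @return list with [RegionMask-class] elements \code{foveal} and
#'   \code{parafoveal} (disjoint; union = the 3-mm disc).
#' @export
makeRegionMasks <- function(sidePx, scanWidthMm,
                            centerPx = c((sidePx + 1) / 2, (sidePx + 1) / 2),
                            innerDiameterMm = 1, outerDiameterMm = 3) {
  mmPerPx <- scanWidthMm / sidePx
  rowG <- matrix(seq_len(sidePx), sidePx, sidePx)
  colG <- matrix(seq_len(sidePx), sidePx, sidePx, byrow = TRUE)
  dMm <- sqrt((rowG - centerPx[1])^2 + (colG - centerPx[2])^2) * mmPerPx
  rOut <- outerDiameterMm / 2
  lim <- c(centerPx[1], sidePx - centerPx[1] + 1,
           centerPx[2], sidePx - centerPx[2] + 1) * mmPerPx
  if (any(lim < rOut - mmPerPx / 2))
    stop("makeRegionMasks: the ", outerDiameterMm,
         "-mm circle does not fit inside the image at this center")
  rIn <- innerDiameterMm / 2
  fov <- (dMm <= rIn) + 0
  para <- (dMm > rIn & dMm <= rOut) + 0
  list(foveal = new("RegionMask", pixels = fov, label = "foveal",
                    centerPx = centerPx, innerDiameterMm = 0,
                    outerDiameterMm = innerDiameterMm,
                    scanWidthMm = scanWidthMm),
       parafoveal = new("RegionMask", pixels = para, label = "parafoveal",
                        centerPx = centerPx, innerDiameterMm = innerDiameterMm,
                        outerDiameterMm = outerDiameterMm,
                        scanWidthMm = scanWidthMm))
}

#' Vessel area density within a region
#'
#' Fraction of the region's pixels occupied by binarized vessels.
#'
#' @param vesselMap a [VesselMap-class] or binary matrix.
#' @param region a [RegionMask-class] or binary matrix.
#' @return fraction in [0, 1].
#' @export
vad <- function(vesselMap, region) {
  vm <- if (is(vesselMap, "BinaryMap")) vesselMap@pixels else asMatrix(vesselMap)
  rg <- if (is(region, "RegionMask")) region@pixels else asMatrix(region)
  if (!all(dim(vm) == dim(rg)))
    stop("vad: vessel map and region geometry differ")
  npx <- sum(rg > 0)
  if (npx == 0) stop("vad: empty region")
  sum(vm[rg > 0] > 0) / npx
}

#' Vessel skeleton density within a region
#'
#' Fraction of the region's pixels occupied by the 1-px-wide vessel
#' centerlines (each skeleton pixel counts 1, including diagonal steps).
#'
#' @param skeletonMap a [SkeletonMap-class] or binary matrix.
#' @param region a [RegionMask-class] or binary matrix.
#' @return fraction in [0, 1].
#' @export
vsd <- function(skeletonMap, region) {
  sk <- if (is(skeletonMap, "BinaryMap")) skeletonMap@pixels
        else asMatrix(skeletonMap)
  rg <- if (is(region, "RegionMask")) region@pixels else asMatrix(region)
  if (!all(dim(sk) == dim(rg)))
    stop("vsd: skeleton map and region geometry differ")
  npx <- sum(rg > 0)
  if (npx == 0) stop("vsd: empty region")
  sum(sk[rg > 0] > 0) / npx
}

#' Quantify one eye: densities per plexus and region
#'
#' Runs Otsu binarization, skeletonization, region-mask construction and
#' VAD/VSD measurement for the superficial and deep plexus vesselness maps
#' of one eye. Otsu is computed globally on each full map (a single
#' binarization precedes the regional measurement).
#'
#' @param scpMap,dcpMap vesselness matrices in [0, 1] (e.g. from
#'   [runPreprocess()]).
#' @param scanWidthMm physical scan width in mm.
#' @param centerPx fovea center; defaults to the image center (scans are
#'   fovea-centered by protocol). The FAZ centroid from [extractFaz()] may
#'   be passed instead.
#' @param pruneSpurLen skeleton spur-pruning length (0 disables).
#' @param eyeId identifier copied into the output.
#' @return data.frame with one row per plexus x region: \code{eyeId},
#'   \code{plexus}, \code{region}, \code{vad}, \code{vsd},
#'   \code{otsuThreshold} (densities as fractions; multiply by 100 for the
#'   conventional percent scale).
#' @export
quantifyEye <- function(scpMap, dcpMap, scanWidthMm = 3,
                        centerPx = NULL, pruneSpurLen = 3L, eyeId = "") {
  maps <- list(SCP = scpMap, DCP = dcpMap)
  rows <- list()
  for (plexus in names(maps)) {
    m <- asMatrix(maps[[plexus]])
    if (!all(dim(m) == dim(asMatrix(maps[[1]]))))
      stop("quantifyEye: SCP and DCP maps must share geometry")
    ctr <- if (is.null(centerPx)) c((nrow(m) + 1) / 2, (ncol(m) + 1) / 2)
           else centerPx
    vmap <- binarizeOtsu(m, scanWidthMm = scanWidthMm)
    skel <- skeletonizeMap(vmap, pruneSpurLen = pruneSpurLen)
    regs <- makeRegionMasks(nrow(m), scanWidthMm, ctr)
    for (rg in names(regs)) {
      rows[[length(rows) + 1]] <- data.frame(
        eyeId = eyeId, plexus = plexus, region = rg,
        vad = vad(vmap, regs[[rg]]), vsd = vsd(skel, regs[[rg]]),
        otsuThreshold = as.numeric(attr(vmap, "threshold")),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
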