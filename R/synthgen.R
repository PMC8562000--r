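## Synthetic en-face OCTA phantoms with exact ground truth. The scene is the
## one the measurement chain assumes: bright curvilinear vessels on a dark
## background, converging on an avascular foveal zone ringed by capillaries,
## with optional speckle inside the FAZ, a low-frequency illumination
## gradient, and burnout-pattern attenuation.

#' Parameters of a synthetic en-face angiogram
#'
#' @param imageSidePx side of the raw exported image in px (365 = 364 px
#'   scene plus the 1-px border removed by [grayscaleAndCrop()]).
#' @param scanWidthMm physical scan width (3.0 mm macular scan).
#' @param fazAreaMm2 target foveal avascular zone area in mm^2.
#' @param nSeedVessels number of vessel trees seeded at the image edge.
#' @param branchProbability per-step probability that a growing vessel
#'   spawns a daughter branch.
#' @param vesselWidthPxRange (min, max) stroke widths in px.
#' @param targetVad target vessel area density (fraction of the 3-mm disc).
#' @param noiseSigma additive Gaussian noise sd, normalized intensity units.
#' @param fazNoiseLevel extra Gaussian noise sd inside the FAZ, emulating
#'   speckle that instruments misread as flow signal.
#' @param illuminationGradientAmp amplitude of the multiplicative
#'   low-frequency illumination gradient (fraction).
#' @param burnoutAttenuation fraction of vessel area removed by
#'   [applyBurnout()] at generation time (0 = none).
#' @param rngSeed integer random seed; identical seeds give bit-identical
#'   phantoms.
#' @return validated parameter list of class \code{PhantomParams}.
#' @export
phantomParams <- function(imageSidePx = 365L, scanWidthMm = 3.0,
                          fazAreaMm2 = 0.30, nSeedVessels = 24L,
                          branchProbability = 0.12,
                          vesselWidthPxRange = c(2, 5), targetVad = 0.32,
                          noiseSigma = 0.05, fazNoiseLevel = 0,
                          illuminationGradientAmp = 0.15,
                          burnoutAttenuation = 0, rngSeed = 1L) {
  p <- list(imageSidePx = as.integer(imageSidePx), scanWidthMm = scanWidthMm,
            fazAreaMm2 = fazAreaMm2, nSeedVessels = as.integer(nSeedVessels),
            branchProbability = branchProbability,
            vesselWidthPxRange = vesselWidthPxRange, targetVad = targetVad,
            noiseSigma = noiseSigma, fazNoiseLevel = fazNoiseLevel,
            illuminationGradientAmp = illuminationGradientAmp,
            burnoutAttenuation = burnoutAttenuation,
            rngSeed = as.integer(rngSeed))
  if (p$imageSidePx < 64L) stop("imageSidePx must be >= 64")
  if (p$fazAreaMm2 < 0 || p$fazAreaMm2 >= p$scanWidthMm^2)
    stop("fazAreaMm2 must lie in [0, scanWidthMm^2)")
  fr <- c(p$branchProbability, p$targetVad, p$illuminationGradientAmp,
          p$burnoutAttenuation)
  if (any(fr < 0 | fr > 1))
    stop("branchProbability, targetVad, illuminationGradientAmp and ",
         "burnoutAttenuation must lie in [0, 1]")
  if (length(p$vesselWidthPxRange) != 2 || p$vesselWidthPxRange[1] < 1 ||
      diff(p$vesselWidthPxRange) < 0)
    stop("vesselWidthPxRange must be (min, max) with min >= 1")
  if (p$targetVad > 0.85)
    stop("targetVad = ", p$targetVad, " is not reachable by a curvilinear ",
         "network with the given width range; use targetVad <= 0.85")
  class(p) <- "PhantomParams"
  p
}

## pixel offsets of a stamped disc of the given stroke width
discOffsets <- function(width) {
  r <- max(0, width / 2 - 0.25)
  ri <- ceiling(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g <- g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

## polar radius (px) of the perturbed-ellipse FAZ boundary
fazRadiusFun <- function(areaPx, seedDraws) {
  q <- seedDraws$q; th0 <- seedDraws$th0
  a <- sqrt(areaPx / (pi * q)); b <- q * a
  function(phi) {
    re <- a * b / sqrt((b * cos(phi - th0))^2 + (a * sin(phi - th0))^2)
    re * (1 + seedDraws$p1 * sin(2 * phi + seedDraws$ps1) +
              seedDraws$p2 * sin(3 * phi + seedDraws$ps2))
  }
}

#' Generate a synthetic en-face OCTA angiogram with exact ground truth
#'
#' Grows stochastic branching vessel trees from the image edge toward the rim
#' of a perturbed-elliptical foveal avascular zone, stamps them as bright
#' strokes, adds a capillary ring around the FAZ, applies a multiplicative
#' illumination gradient and additive noise (extra speckle inside the FAZ),
#' and quantizes to 8 bits. The raw image is \code{imageSidePx} square with a
#' 1-px dark border, matching instrument exports; all ground-truth masks live
#' on the cropped \code{imageSidePx - 1} grid.
#'
#' Vessel trees are added until the pixel-counted vessel area density inside
#' the 3-mm disc reaches \code{targetVad}; ground-truth densities are exact
#' pixel counts on the final masks (the generator reports what it drew, not
#' what was requested).
#'
#' @param params a [phantomParams()] list.
#' @param plexus plexus label stored on the angiogram.
#' @param eyeId identifier stored on the angiogram.
#' @return list with elements \code{angiogram} ([EnFaceAngiogram-class],
#'   8-bit values 0..255) and \code{truth} ([PhantomTruth-class]).
#' @examples
#' ph <- generatePhantom(phantomParams(targetVad = 0.3, noiseSigma = 0,
#'                                     rngSeed = 7))
#' ph$truth
#' @export
generatePhantom <- function(params = phantomParams(), plexus = "SCP",
                            eyeId = "phantom") {
  stopifnot(inherits(params, "PhantomParams"))
  withLocalSeed(params$rngSeed, {
    n <- params$imageSidePx - 1L
    mmPerPx <- params$scanWidthMm / n
    pxArea <- mmPerPx^2
    ctr <- c((n + 1) / 2, (n + 1) / 2)
    rowG <- matrix(seq_len(n), n, n)
    colG <- matrix(seq_len(n), n, n, byrow = TRUE)
    dr <- rowG - ctr[1]; dc <- colG - ctr[2]
    dist <- sqrt(dr^2 + dc^2)
    phi <- atan2(dr, dc)

    ## ---- FAZ mask: perturbed ellipse, renormalized to the target area ----
    fazMask <- matrix(0, n, n)
    fazR <- function(p) rep(0, length(p))
    if (params$fazAreaMm2 > 0) {
      draws <- list(q = runif(1, 0.78, 1), th0 = runif(1, 0, pi),
                    p1 = runif(1, 0, 0.06), p2 = runif(1, 0, 0.05),
                    ps1 = runif(1, 0, 2 * pi), ps2 = runif(1, 0, 2 * pi))
      targetPx <- params$fazAreaMm2 / pxArea
      fazR <- fazRadiusFun(targetPx, draws)
      ## one renormalization pass: rasterized area scales linearly with the
      ## area argument, so rescale it by target/actual
      m0 <- (dist < fazR(phi)) + 0
      fazR <- fazRadiusFun(targetPx^2 / max(sum(m0), 1), draws)
      fazMask <- (dist < fazR(phi)) + 0
    }

    ## ---- vessel network ----
    vm <- matrix(0, n, n)
    intens <- matrix(0, n, n)
    disc3 <- dist <= (1.5 / mmPerPx)
    targetCount <- params$targetVad * sum(disc3)

    stamp <- function(ptsR, ptsC, width, bright) {
      off <- discOffsets(width)
      rr <- rep(round(ptsR), each = nrow(off)) + off[, 1]
      cc <- rep(round(ptsC), each = nrow(off)) + off[, 2]
      ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      idx <- (cc[ok] - 1) * n + rr[ok]
      vm[idx] <<- 1
      intens[idx] <<- pmax(intens[idx], bright)
    }

    fazR0 <- if (params$fazAreaMm2 > 0)
               sqrt(params$fazAreaMm2 / pxArea / pi) else 0
    newWaypoint <- function() {
      ang <- runif(1, -pi, pi)
      rad <- sqrt(runif(1, (fazR0 + 8)^2, (0.48 * n)^2))
      ctr + rad * c(sin(ang), cos(ang))
    }

    ## Vessel paths are angle random walks pulled toward a wandering
    ## waypoint (AR(1) on the heading), simulated in vectorized chunks;
    ## branches spawn daughters with deflected headings and tapered width.
    growTree <- function(seedPos, seedTheta, width) {
      stack <- list(list(pos = seedPos, th = seedTheta, w = width, depth = 0))
      nBranches <- 0L
      while (length(stack)) {
        st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        pos <- st$pos; th <- st$th; w <- st$w
        bright <- runif(1, 0.45, 0.85)
        way <- newWaypoint()
        step <- max(1.0, 0.6 * w)
        ptsR <- numeric(0); ptsC <- numeric(0)
        alive <- TRUE; chunks <- 0L
        while (alive && chunks < 10L) {
          chunks <- chunks + 1L
          L <- 40L
          phiW <- atan2(way[1] - pos[1], way[2] - pos[2])
          d0 <- atan2(sin(th - phiW), cos(th - phiW))
          k <- 0.10
          dec <- (1 - k)^seq_len(L)
          thv <- phiW + dec * (d0 + cumsum(rnorm(L, 0, 0.28) / dec))
          rr <- pos[1] + step * cumsum(sin(thv))
          cc <- pos[2] + step * cumsum(cos(thv))
          dctr <- sqrt((rr - ctr[1])^2 + (cc - ctr[2])^2)
          bad <- rr < 2 | rr > n - 1 | cc < 2 | cc > n - 1 |
                 dctr < fazR(atan2(rr - ctr[1], cc - ctr[2])) + 1 + w / 2
          stopAt <- if (any(bad)) which(bad)[1] - 1L else L
          if (stopAt > 0L) {
            ## capillaries keep spacing: a path running along existing
            ## vessel mass for more than a crossing's length is redundant
            ## and terminates (prevents solid merged clumps at high VAD)
            idx <- (round(cc[seq_len(stopAt)]) - 1) * n +
                   round(rr[seq_len(stopAt)])
            runs <- rle(vm[idx] > 0)
            ends <- cumsum(runs$lengths)
            j <- which(runs$values & runs$lengths > 5L)
            if (length(j)) {
              stopAt <- ends[j[1]] - runs$lengths[j[1]]
              alive <- FALSE
            }
          }
          if (stopAt > 0L) {
            ptsR <- c(ptsR, rr[seq_len(stopAt)])
            ptsC <- c(ptsC, cc[seq_len(stopAt)])
            pos <- c(rr[stopAt], cc[stopAt]); th <- thv[stopAt]
          }
          if (any(bad)) alive <- FALSE
          if (alive && sqrt(sum((pos - way)^2)) < 15) way <- newWaypoint()
          if (st$depth < 3 && nBranches < 40L && stopAt > 0L) {
            ns <- min(rbinom(1, stopAt, params$branchProbability), 2L)
            if (ns > 0L) for (j in sample.int(stopAt, ns)) {
              stack[[length(stack) + 1L]] <-
                list(pos = c(rr[j], cc[j]),
                     th = thv[j] + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1),
                     w = max(1.2, w * 0.75), depth = st$depth + 1L)
              nBranches <- nBranches + 1L
            }
          }
        }
        if (length(ptsR)) stamp(ptsR, ptsC, w, bright)
      }
    }

    if (params$targetVad > 0) {
      ## capillary ring hugging the FAZ rim
      if (params$fazAreaMm2 > 0) {
        rimBand <- dist >= fazR(phi) + 0.5 & dist <= fazR(phi) + 2.2
        vm[rimBand] <- 1
        intens[rimBand] <- pmax(intens[rimBand], 0.62)
      }
      maxTrees <- max(400L, params$nSeedVessels * 30L)
      grown <- 0L
      while (sum(vm[disc3]) < targetCount) {
        if (grown >= maxTrees)
          stop("target VAD ", params$targetVad, " not reached after ",
               maxTrees, " vessel trees; lower targetVad or widen ",
               "vesselWidthPxRange")
        grown <- grown + 1L
        if (grown <= params$nSeedVessels || sum(vm) < 50) {
          ## arteriole/venule entering from the image edge
          side <- sample(4, 1)
          t0 <- runif(1, 2, n - 1)
          seedPos <- switch(side, c(2, t0), c(n - 1, t0), c(t0, 2),
                            c(t0, n - 1))
          seedTheta <- atan2(ctr[1] - seedPos[1], ctr[2] - seedPos[2]) +
                       rnorm(1, 0, 0.35)
          w <- runif(1, params$vesselWidthPxRange[1],
                     params$vesselWidthPxRange[2])
        } else {
          ## capillary sprouting from the existing network
          i <- sample(which(vm > 0), 1)
          seedPos <- c(((i - 1) %% n) + 1, ((i - 1) %/% n) + 1)
          seedTheta <- runif(1, -pi, pi)
          w <- runif(1, max(1.2, params$vesselWidthPxRange[1] * 0.6),
                     max(1.6, params$vesselWidthPxRange[1]))
        }
        growTree(seedPos, seedTheta, w)
      }
      vm[fazMask > 0] <- 0
      intens[fazMask > 0] <- 0
    }

    truth <- phantomTruthFromMasks(vm, fazMask, ctr, params$scanWidthMm)

    ## ---- render ----
    img <- matrix(0.18, n, n)
    img[vm > 0] <- intens[vm > 0]
    img <- asMatrix(EBImage::gblur(asImage(img), sigma = 0.6))
    if (params$illuminationGradientAmp > 0) {
      theta <- runif(1, 0, 2 * pi); phase <- runif(1, 0, 2 * pi)
      field <- cos(2 * pi * (rowG * sin(theta) + colG * cos(theta)) / n + phase)
      img <- img * (1 + params$illuminationGradientAmp * field)
    }
    if (params$noiseSigma > 0) {
      ## OCTA-like degradation, all scaled by noiseSigma: low-frequency
      ## background haze (deep-signal texture), multiplicative speckle on
      ## the decorrelation signal, and an additive sensor floor
      tex <- matrix(rnorm(n * n), n, n)
      tex <- asMatrix(EBImage::gblur(asImage(tex), sigma = 8))
      img <- img + params$noiseSigma * tex / sd(tex)
      img <- img * (1 + rnorm(n * n, 0, params$noiseSigma))
      img <- img + rnorm(n * n, 0, 0.5 * params$noiseSigma)
    }
    if (params$fazNoiseLevel > 0 && sum(fazMask) > 0)
      img[fazMask > 0] <- img[fazMask > 0] +
        rnorm(sum(fazMask), 0, params$fazNoiseLevel)
    raw <- round(clip01(img) * 255)
    full <- matrix(0, n + 1L, n + 1L)
    full[-1, -1] <- raw

    out <- list(angiogram = new("EnFaceAngiogram", pixels = full,
                                scanWidthMm = params$scanWidthMm,
                                plexus = plexus, eyeId = eyeId),
                truth = truth)
    if (params$burnoutAttenuation > 0)
      out <- applyBurnout(out$angiogram, out$truth,
                          attenuation = params$burnoutAttenuation,
                          seed = params$rngSeed + 104729L)
    out
  })
}

## recompute exact pixel-counted densities for a vessel/FAZ mask pair
phantomTruthFromMasks <- function(vm, fazMask, ctr, scanWidthMm) {
  n <- nrow(vm)
  pxArea <- (scanWidthMm / n)^2
  ## foveal/parafoveal geometry scales with the scan: 1 and 3 mm diameters
  ## at the instrument's 3-mm field
  regions <- makeRegionMasks(n, scanWidthMm, ctr,
                             innerDiameterMm = scanWidthMm / 3,
                             outerDiameterMm = scanWidthMm)
  fov <- regions$foveal@pixels; para <- regions$parafoveal@pixels
  sk <- if (sum(vm) > 0) pixels(skeletonizeMap(vm, scanWidthMm = scanWidthMm))
        else vm
  new("PhantomTruth", vesselMask = vm, fazMask = fazMask,
      trueVadFoveal = sum(vm * fov) / sum(fov),
      trueVadParafoveal = sum(vm * para) / sum(para),
      trueVsdFoveal = sum(sk * fov) / sum(fov),
      trueVsdParafoveal = sum(sk * para) / sum(para),
      trueFazAreaMm2 = sum(fazMask) * pxArea,
      foveaCenterPx = ctr, scanWidthMm = scanWidthMm)
}

#' Apply burnout-pattern attenuation to a phantom
#'
#' Emulates end-stage radiation maculopathy: focal capillary dropout patches
#' are removed at random until the surviving vessel-mask area equals
#' \code{(1 - attenuation)} times the original, surviving vessels are dimmed,
#' and the ground truth is recomputed from the surviving mask.
#'
#' @param angiogram the phantom [EnFaceAngiogram-class] (raw 8-bit image).
#' @param truth its [PhantomTruth-class].
#' @param attenuation fraction of vessel area to remove, in [0, 1].
#' @param seed integer seed for the dropout pattern.
#' @return list(angiogram, truth) with updated image and ground truth.
#' @export
applyBurnout <- function(angiogram, truth, attenuation, seed = 1L) {
  stopifnot(attenuation >= 0, attenuation <= 1)
  if (attenuation == 0) return(list(angiogram = angiogram, truth = truth))
  withLocalSeed(seed, {
    full <- pixels(angiogram)
    img <- full[-1, -1] / 255
    vm <- truth@vesselMask
    n <- nrow(vm)
    orig <- sum(vm)
    target <- round((1 - attenuation) * orig)
    removed <- matrix(FALSE, n, n)
    if (target == 0) {
      removed <- vm > 0
      vm <- matrix(0, n, n)
    } else {
      while (sum(vm) > target) {
        i <- sample(which(vm > 0), 1)
        excess <- sum(vm) - target
        rad <- if (excess > 600) sample(4:9, 1) else 2
        off <- discOffsets(2 * rad)
        rr <- ((i - 1) %% n) + 1 + off[, 1]
        cc <- ((i - 1) %/% n) + 1 + off[, 2]
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
        idx <- (cc[ok] - 1) * n + rr[ok]
        removed[idx[vm[idx] > 0]] <- TRUE
        vm[idx] <- 0
      }
    }
    ## fill a dilated neighborhood of the dropout so the halo left by the
    ## render-time blur of removed vessels disappears too
    fillMask <- asMatrix(EBImage::dilate(asImage(removed + 0),
                                         EBImage::makeBrush(5, "disc"))) > 0
    fillMask <- fillMask & vm == 0
    bg <- mean(img[truth@vesselMask == 0])
    img[fillMask] <- clip01(bg + rnorm(sum(fillMask), 0, 0.02))
    surv <- vm > 0
    img[surv] <- img[surv] * (1 - 0.5 * attenuation)
    newTruth <- phantomTruthFromMasks(vm, truth@fazMask, truth@foveaCenterPx,
                                      truth@scanWidthMm)
    fullOut <- matrix(0, n + 1L, n + 1L)
    fullOut[-1, -1] <- round(clip01(img) * 255)
    list(angiogram = new("EnFaceAngiogram", pixels = fullOut,
                         scanWidthMm = angiogram@scanWidthMm,
                         plexus = angiogram@plexus, eyeId = angiogram@eyeId),
         truth = newTruth)
  })
}

#' Parameters of a synthetic paired-eye cohort
#'
#' Defaults emulate the structure of a brachytherapy maculopathy cohort:
#' per-patient baseline densities shared by both eyes (inducing inter-eye
#' correlation), programmed treated-eye deficits larger in the deep than the
#' superficial plexus, FAZ enlargement, dose draws linked to deficit
#' magnitude, and a burnout subgroup.
#'
#' @param nPatients number of patients (two eyes each: one treated, one
#'   fellow control).
#' @param effectVadScp,effectVadDcp mean treated-eye vessel area density
#'   deficit in percentage points, superficial / deep plexus.
#' @param effectFaz multiplicative FAZ enlargement factor for treated eyes.
#' @param fractionBurnout probability that a treated eye shows the burnout
#'   pattern.
#' @param doseModel list with \code{fovealMeanGy}, \code{fovealSdGy},
#'   \code{discMeanGy}, \code{discSdGy} and \code{slopePpPerGy}, the link
#'   slope from (foveal dose - mean) to extra density deficit in
#'   percentage points per Gy.
#' @param rngSeed integer seed.
#' @return validated parameter list of class \code{CohortParams}.
#' @export
cohortParams <- function(nPatients = 31L, effectVadScp = 7, effectVadDcp = 12,
                         effectFaz = 4, fractionBurnout = 9 / 31,
                         doseModel = list(fovealMeanGy = 30, fovealSdGy = 30,
                                          discMeanGy = 85, discSdGy = 10,
                                          slopePpPerGy = 0.05),
                         rngSeed = 1L) {
  p <- list(nPatients = as.integer(nPatients), effectVadScp = effectVadScp,
            effectVadDcp = effectVadDcp, effectFaz = effectFaz,
            fractionBurnout = fractionBurnout, doseModel = doseModel,
            rngSeed = as.integer(rngSeed))
  if (p$nPatients < 2L) stop("nPatients must be >= 2")
  if (p$fractionBurnout < 0 || p$fractionBurnout > 1)
    stop("fractionBurnout must lie in [0, 1]")
  if (p$effectFaz <= 0) stop("effectFaz must be > 0")
  need <- c("fovealMeanGy", "fovealSdGy", "discMeanGy", "discSdGy",
            "slopePpPerGy")
  if (!all(need %in% names(doseModel)))
    stop("doseModel must contain: ", paste(need, collapse = ", "))
  class(p) <- "CohortParams"
  p
}

## control-arm baseline (mean, sd) of each density metric, as fractions
cohortBaselines <- function() {
  list(vadScpFoveal     = c(0.294, 0.038),
       vadScpParafoveal = c(0.321, 0.041),
       vadDcpFoveal     = c(0.347, 0.036),
       vadDcpParafoveal = c(0.366, 0.035),
       vsdScpFoveal     = c(0.115, 0.015),
       vsdScpParafoveal = c(0.125, 0.017),
       vsdDcpFoveal     = c(0.152, 0.016),
       vsdDcpParafoveal = c(0.159, 0.015))
}

#' Generate a synthetic paired-eye cohort with ground-truth table
#'
#' Each patient contributes a treated and a fellow (control) eye sharing a
#' patient-level baseline, so outcomes are correlated within patient. The
#' treated eye receives the programmed density deficits (scaled with the
#' drawn foveal dose through \code{doseModel$slopePpPerGy}), multiplicative
#' FAZ enlargement, and — with probability \code{fractionBurnout} — a
#' burnout attenuation of 80-95% of the vasculature.
#'
#' @param params a [cohortParams()] list.
#' @param render if \code{TRUE}, also generate the SCP and DCP phantom images
#'   for every eye via [generatePhantom()] (slow); the ground-truth table is
#'   always returned.
#' @param renderNoiseSigma,renderFazNoise noise settings passed to the
#'   rendered phantoms.
#' @return list with \code{table} (one row per eye) and \code{phantoms}
#'   (nested list \code{[[eyeId]][[plexus]]} of phantom/truth pairs, or
#'   \code{NULL} when \code{render = FALSE}).
#' @export
generateCohort <- function(params = cohortParams(), render = FALSE,
                           renderNoiseSigma = 0.05, renderFazNoise = 0.05) {
  stopifnot(inherits(params, "CohortParams"))
  withLocalSeed(params$rngSeed, {
    bl <- cohortBaselines()
    dm <- params$doseModel
    rows <- list()
    eyeSpecs <- list()
    for (p in seq_len(params$nPatients)) {
      patBase <- lapply(bl, function(ms) rnorm(1, ms[1], ms[2]))
      fazBase <- rlnorm(1, log(0.30), 0.35)
      interval <- max(6, rnorm(1, 25, 13))
      fovealDose <- max(0, rnorm(1, dm$fovealMeanGy, dm$fovealSdGy))
      discDose <- max(0, rnorm(1, dm$discMeanGy, dm$discSdGy))
      extraPp <- dm$slopePpPerGy * (fovealDose - dm$fovealMeanGy)
      defScp <- max(0, params$effectVadScp + extraPp)
      defDcp <- max(0, params$effectVadDcp + extraPp)
      burnout <- runif(1) < params$fractionBurnout
      attn <- if (burnout) runif(1, 0.80, 0.95) else 0
      hasRM <- burnout || runif(1) < stats::plogis(-0.6 + 0.07 * (interval - 15))
      bcvaFellow <- abs(rnorm(1, 0.05, 0.08))
      for (eye in c("treated", "fellow")) {
        met <- lapply(names(bl), function(nm) {
          v <- patBase[[nm]] + rnorm(1, 0, 0.008)
          if (eye == "treated") {
            def <- if (grepl("Scp", nm)) defScp else defDcp
            if (grepl("^vsd", nm)) def <- def * 0.42
            v <- v - def / 100
          }
          min(max(v, 0.002), 0.98)
        })
        names(met) <- names(bl)
        if (eye == "treated" && burnout)
          met <- lapply(met, function(v) max(v * (1 - attn), 0.002))
        fazS <- fazBase * rlnorm(1, 0, 0.10)
        fazD <- fazBase * rlnorm(1, 0.05, 0.10)
        if (eye == "treated") {
          fazS <- fazS * params$effectFaz * rlnorm(1, 0, 0.15)
          fazD <- fazD * params$effectFaz * rlnorm(1, 0, 0.15)
        }
        grp <- if (eye == "fellow") "fellow_control"
               else if (hasRM) "treated_RM" else "treated_noRM"
        bcva <- if (eye == "fellow") bcvaFellow
                else bcvaFellow + 0.15 + 0.4 * max(0, fazS - 0.6) +
                     abs(rnorm(1, 0, 0.1))
        eid <- sprintf("P%03d_%s", p, if (eye == "treated") "T" else "F")
        rows[[length(rows) + 1]] <- data.frame(
          patientId = sprintf("P%03d", p), eyeId = eid, group = grp,
          treated = eye == "treated", burnout = eye == "treated" && burnout,
          fovealDoseGy = if (eye == "treated") fovealDose else 0,
          discDoseGy = if (eye == "treated") discDose else 0,
          intervalMonths = interval, bcvaLogmar = bcva,
          as.data.frame(met),
          fazScpMm2 = fazS, fazDcpMm2 = fazD,
          stringsAsFactors = FALSE)
        eyeSpecs[[eid]] <- list(met = met, fazS = fazS, fazD = fazD,
                                attn = attn,
                                burnout = eye == "treated" && burnout)
      }
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL

    phantoms <- NULL
    if (render) {
      phantoms <- list()
      k <- 0L
      for (eid in tab$eyeId) {
        sp <- eyeSpecs[[eid]]
        phantoms[[eid]] <- list()
        for (plexus in c("SCP", "DCP")) {
          k <- k + 1L
          child <- (params$rngSeed %% 100000L) * 10000L + k
          tv <- if (plexus == "SCP")
                  mean(c(sp$met$vadScpFoveal, sp$met$vadScpParafoveal))
                else mean(c(sp$met$vadDcpFoveal, sp$met$vadDcpParafoveal))
          ## render the pre-burnout network, then attenuate it
          tvRender <- if (sp$burnout) min(tv / max(1 - sp$attn, 0.05), 0.6)
                      else tv
          pp <- phantomParams(
            fazAreaMm2 = min(if (plexus == "SCP") sp$fazS else sp$fazD, 2.5),
            nSeedVessels = if (plexus == "SCP") 22L else 30L,
            vesselWidthPxRange = if (plexus == "SCP") c(2, 5) else c(1.5, 3),
            targetVad = max(tvRender, 0.02),
            noiseSigma = renderNoiseSigma, fazNoiseLevel = renderFazNoise,
            burnoutAttenuation = if (sp$burnout) sp$attn else 0,
            rngSeed = child)
          phantoms[[eid]][[plexus]] <-
            generatePhantom(pp, plexus = plexus, eyeId = eid)
        }
      }
    }
    list(table = tab, phantoms = phantoms, params = params)
  })
}
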