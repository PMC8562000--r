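test_that("Otsu threshold matches the exhaustive variance search", {
  set.seed(31)
  for (i in 1:6) {
    m <- matrix(runif(80 * 80)^sample(c(0.5, 1, 2), 1), 80)
    vm <- binarizeOtsu(m)
    expect_equal(attr(vm, "thresholdBin"), otsuExhaustiveBin(m))
  }
})

test_that("Otsu separates a two-level map at the exact class fraction", {
  set.seed(5)
  m <- matrix(sample(c(0.1, 0.8), 100 * 100, replace = TRUE,
                     prob = c(0.6, 0.4)), 100)
  vm <- binarizeOtsu(m)
  thr <- attr(vm, "threshold")
  expect_gt(thr, 0.1); expect_lt(thr, 0.8)
  expect_equal(mean(pixels(vm)), mean(m == 0.8))

  expect_warning(z <- binarizeOtsu(matrix(0, 20, 20)), "constant")
  expect_equal(sum(pixels(z)), 0)

  ## inverting the map complements the classes (away from the bin edges)
  inv <- binarizeOtsu(1 - m)
  expect_equal(pixels(inv), 1 - pixels(vm))
})

test_that("skeletonization thins a bar to its centerline", {
  expect_equal(sum(pixels(skeletonizeMap(matrix(0, 30, 30),
                                         scanWidthMm = 3))), 0)

  bar <- matrix(0, 20, 110); bar[8:12, 6:105] <- 1
  sk <- skeletonizeMap(bar, scanWidthMm = 3)
  p <- pixels(sk)
  expect_true(all(bar[p > 0] == 1))             # subset of the input
  ## length close to the bar length (thinning rounds the two ends;
  ## reference implementations give 96-97 px for a 5 x 100 bar)
  expect_gte(sum(p), 92)
  expect_lte(sum(p), 102)
  expect_equal(max(labelComponents(p)), 1)
})

test_that("a plus-shaped cross keeps one component and one 4-way junction", {
  plus <- matrix(0, 30, 30); plus[14:18, 6:25] <- 1; plus[6:25, 14:18] <- 1
  p <- pixels(skeletonizeMap(plus, scanWidthMm = 3))
  expect_equal(max(labelComponents(p)), 1)
  ## exactly one pixel with all four 4-connected neighbors set
  nb4 <- (rbind(p[-1, ], 0) + rbind(0, p[-nrow(p), ]) +
          cbind(p[, -1], 0) + cbind(0, p[, -ncol(p)]))
  expect_equal(sum(p > 0 & nb4 == 4), 1)
})

test_that("skeletons are at most one pixel thick and preserve topology", {
  for (seed in c(3, 4)) {
    ph <- smallPhantom(seed)
    vmask <- ph$truth@vesselMask
    p <- pixels(skeletonizeMap(vmask, scanWidthMm = 1))
    blocks <- p[-nrow(p), -ncol(p)] * p[-1, -ncol(p)] *
              p[-nrow(p), -1] * p[-1, -1]
    expect_equal(sum(blocks), 0)
    ## unpruned thinning keeps the component count
    p0 <- pixels(skeletonizeMap(vmask, pruneSpurLen = 0, scanWidthMm = 1))
    expect_equal(max(labelComponents(p0)), max(labelComponents(vmask)))
  }
})

test_that("region masks rasterize the 1/3-mm circles accurately", {
  regs <- makeRegionMasks(364, 3)
  pxArea <- (3 / 364)^2
  areaFov <- sum(pixels(regs$foveal)) * pxArea
  areaPara <- sum(pixels(regs$parafoveal)) * pxArea
  expect_lt(abs(areaFov - pi * 0.5^2) / (pi * 0.5^2), 0.01)
  expect_lt(abs(areaPara - 2 * pi) / (2 * pi), 0.01)
  expect_equal(sum(pixels(regs$foveal) * pixels(regs$parafoveal)), 0)
  expect_error(makeRegionMasks(364, 3, centerPx = c(10, 10)),
               "does not fit")
})

test_that("densities are pixel-count ratios", {
  regs <- makeRegionMasks(120, 1, innerDiameterMm = 1 / 3,
                          outerDiameterMm = 1)
  fov <- regs$foveal
  expect_equal(vad(matrix(1, 120, 120), fov), 1)
  expect_equal(vad(matrix(0, 120, 120), fov), 0)

  set.seed(9)
  m <- matrix(rbinom(120^2, 1, 0.3), 120)
  expect_lt(abs(vad(m, pixels(regs$parafoveal)) - 0.3), 0.015)

  onerow <- matrix(0, 50, 50); onerow[25, ] <- 1
  expect_equal(vsd(onerow, matrix(1, 50, 50)), 1 / 50)
  expect_error(vad(m, matrix(0, 120, 120)), "empty region")
  expect_error(vsd(onerow, matrix(1, 10, 10)), "geometry")
})

test_that("skeleton density is about area density over the bar width", {
  bar <- matrix(0, 60, 60); bar[28:32, 6:55] <- 1
  region <- matrix(1, 60, 60)
  v <- vad(bar, region)
  s <- vsd(pixels(skeletonizeMap(bar, scanWidthMm = 3)), region)
  expect_lt(abs(s - v / 5) / (v / 5), 0.15)
})

test_that("quantifyEye recovers phantom densities and is monotone", {
  ph <- fullPhantom(42, noiseSigma = 0, fazNoiseLevel = 0)
  maps <- runPreprocess(ph$angiogram)
  met <- quantifyEye(maps, maps, scanWidthMm = 3, eyeId = "e1")
  expect_equal(nrow(met), 4)
  expect_true(all(met$vsd <= met$vad))
  fovRow <- met[met$plexus == "SCP" & met$region == "foveal", ]
  expect_lt(abs(fovRow$vad - ph$truth@trueVadFoveal), 0.07)
  expect_lt(mean(abs(met$vad - c(ph$truth@trueVadFoveal,
                                 ph$truth@trueVadParafoveal))), 0.06)

  ## identical rerun
  expect_identical(met, quantifyEye(maps, maps, scanWidthMm = 3,
                                    eyeId = "e1"))

  ## attenuation strictly reduces every measured density
  bo <- applyBurnout(ph$angiogram, ph$truth, 0.9, seed = 2)
  mb <- runPreprocess(bo$angiogram)
  metB <- quantifyEye(mb, mb, scanWidthMm = 3)
  expect_true(all(metB$vad < met$vad))
})

test_that("removing vessel pixels never increases densities", {
  ph <- smallPhantom(3)
  vmask <- ph$truth@vesselMask
  regs <- makeRegionMasks(nrow(vmask), 1, innerDiameterMm = 1 / 3,
                          outerDiameterMm = 1)
  set.seed(10)
  eroded <- vmask
  eroded[sample(which(eroded > 0), round(0.3 * sum(eroded)))] <- 0
  for (rg in regs) {
    expect_lte(vad(eroded, rg), vad(vmask, rg))
    expect_lte(vsd(pixels(skeletonizeMap(eroded, scanWidthMm = 1)), rg),
               vsd(pixels(skeletonizeMap(vmask, scanWidthMm = 1)), rg) +
                 0.01)
  }
})

test_that("densities are exactly invariant under 90-degree rotation", {
  ph <- smallPhantom(4)
  vmask <- ph$truth@vesselMask
  regs <- makeRegionMasks(nrow(vmask), 1, innerDiameterMm = 1 / 3,
                          outerDiameterMm = 1)
  for (rg in regs) {
    expect_identical(vad(rotate90(vmask), rotate90(pixels(rg))),
                     vad(vmask, rg))
  }
})
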