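test_that("crop removes the border row/column and collapses RGB", {
  m <- matrix(runif(365 * 365), 365)
  a <- grayscaleAndCrop(m)
  expect_s4_class(a, "EnFaceAngiogram")
  expect_equal(dim(pixels(a)), c(364, 364))
  expect_equal(pixels(a), m[-1, -1])

  rgb <- array(runif(365 * 365 * 3), c(365, 365, 3))
  g <- grayscaleAndCrop(rgb)
  lum <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  expect_equal(pixels(g), lum[-1, -1])

  const <- matrix(0.4, 365, 365)
  expect_true(all(pixels(grayscaleAndCrop(const)) == 0.4))

  expect_error(grayscaleAndCrop(matrix(0, 364, 364)), "expected a 365 x 365")
})

test_that("homomorphic filter compresses illumination, is log-linear", {
  ## constant image: only the DC component, scaled by lowGain in log domain
  const <- matrix(0.5, 64, 64)
  out <- homomorphicFilter(const, cutoff = 8, lowGain = 0.5, highGain = 1.5)
  expect_equal(max(abs(out - expm1(0.5 * log1p(0.5)))), 0, tolerance = 1e-10)

  ## ridge pattern under a 2:1 illumination ramp: left/right contrast ratio
  ## moves toward 1 after filtering
  n <- 128
  ridges <- 0.2 + 0.6 * (sin(2 * pi * row(matrix(0, n, n)) / 8) > 0)
  ramp <- matrix(seq(1, 2, length.out = n), n, n, byrow = TRUE)
  img <- ridges * ramp / 2
  contrastRatio <- function(m) sd(m[11:118, 1:32]) / sd(m[11:118, 97:128])
  before <- contrastRatio(img)
  after <- contrastRatio(homomorphicFilter(img, cutoff = 4))
  expect_lt(abs(log(after)), abs(log(before)))

  ## two applications equal one application of the squared transfer
  m <- matrix(runif(64 * 64), 64)
  expect_equal(homomorphicFilter(homomorphicFilter(m)),
               homomorphicFilter(m, passes = 2), tolerance = 1e-10)
})

test_that("normalization maps min/max to 0/1 and handles constants", {
  expect_equal(normalizeImage(matrix(c(5, 10, 15, 10), 2)),
               matrix(c(0, 0.5, 1, 0.5), 2))
  m <- matrix(runif(100), 10); m[1] <- 0; m[100] <- 1
  expect_equal(normalizeImage(m), m)
  expect_equal(normalizeImage(matrix(7, 5, 5)), matrix(0, 5, 5))
})

test_that("FAZ background subtraction is an elementwise clipped shift", {
  m <- matrix(runif(50 * 50), 50)
  region <- matrix(FALSE, 50, 50); region[21:30, 21:30] <- TRUE
  out <- subtractFazBackground(m, region)
  expect_equal(out, pmax(m - mean(m[region]), 0))
  expect_lte(max(out - m), 0)                  # never exceeds the input
  expect_gte(min(out), 0)

  zero <- m; zero[region] <- 0
  expect_equal(subtractFazBackground(zero, region), zero)
  expect_equal(subtractFazBackground(matrix(0.3, 50, 50), region),
               matrix(0, 50, 50))
  expect_error(subtractFazBackground(m, matrix(FALSE, 50, 50)), "empty")
})

test_that("top-hat/bottom-hat enhancement raises small bright structures", {
  expect_equal(tophatBottomhatEnhance(matrix(0.5, 40, 40)),
               matrix(0.5, 40, 40))

  ## independent brute-force grayscale morphology oracle (disc radius 4)
  off <- which(outer((-4:4)^2, (-4:4)^2, "+") <= 16, arr.ind = TRUE) - 5
  minFilt <- function(m) {
    out <- m
    for (r in 1:nrow(m)) for (c in 1:ncol(m)) {
      rr <- r + off[, 1]; cc <- c + off[, 2]
      ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
      out[r, c] <- min(m[cbind(rr[ok], cc[ok])])
    }
    out
  }
  maxFilt <- function(m) {
    out <- m
    for (r in 1:nrow(m)) for (c in 1:ncol(m)) {
      rr <- r + off[, 1]; cc <- c + off[, 2]
      ok <- rr >= 1 & rr <= nrow(m) & cc >= 1 & cc <= ncol(m)
      out[r, c] <- max(m[cbind(rr[ok], cc[ok])])
    }
    out
  }
  dot <- matrix(0.1, 31, 31); dot[16, 16] <- 0.6
  oracle <- pmin(pmax(dot + (dot - maxFilt(minFilt(dot))) -
                        (minFilt(maxFilt(dot)) - dot), 0), 1)
  got <- tophatBottomhatEnhance(dot)
  expect_gt(got[16, 16] - got[1, 1], dot[16, 16] - dot[1, 1])
  expect_equal(got[16, 16], oracle[16, 16], tolerance = 1e-8)

  bar <- matrix(0.1, 41, 41); bar[20:22, 6:36] <- 0.7
  enhanced <- tophatBottomhatEnhance(bar)
  expect_gt(mean(enhanced[20:22, 6:36]), mean(bar[20:22, 6:36]))
})

test_that("bilateral filter denoises flat regions and keeps step edges", {
  const <- matrix(0.4, 40, 40)
  expect_equal(bilateralDenoise(const, 3, 0.1), const, tolerance = 1e-12)

  set.seed(8)
  noisy <- matrix(0.5 + rnorm(60 * 60, 0, 0.05), 60)
  out <- bilateralDenoise(noisy, 3, 0.1)
  expect_lt(sd(out[11:50, 11:50]), 0.05)

  step <- matrix(0, 40, 40); step[, 21:40] <- 1
  filt <- bilateralDenoise(step, 3, 0.1)
  expect_gte(mean(filt[, 30]) - mean(filt[, 10]), 0.9)
})

test_that("vesselness is zero on constants, peaks on ridge centerlines", {
  expect_equal(jermanVesselness(matrix(0.7, 50, 50)), matrix(0, 50, 50))

  ## Gaussian ridge along columns, sd 2 px, centered at row 25
  n <- 51
  ridge <- exp(-(row(matrix(0, n, n)) - 26)^2 / (2 * 2^2))
  v <- jermanVesselness(ridge, scalesPx = c(1, 2, 3), tau = 0.75)
  expect_true(all(v >= 0 & v <= 1))
  ## the centerline attains the columnwise maximum (the saturated response
  ## forms a plateau, so a bare argmax is ambiguous within it)
  for (cc in seq(11, 40, by = 3))
    expect_equal(v[26, cc], max(v[, cc]))

  ## an elongated ridge excites far more integrated response than an
  ## isotropic blob of equal peak intensity
  blob <- exp(-((row(matrix(0, n, n)) - 26)^2 +
                (col(matrix(0, n, n)) - 26)^2) / (2 * 2^2))
  vb <- jermanVesselness(blob, scalesPx = c(1, 2, 3), tau = 0.75)
  expect_gt(sum(v), 3 * sum(vb))
})

test_that("the preprocessing chain is deterministic and null-safe", {
  ph <- fullPhantom(41)
  v1 <- runPreprocess(ph$angiogram)
  v2 <- runPreprocess(ph$angiogram)
  expect_identical(v1, v2)

  black <- new("EnFaceAngiogram", pixels = matrix(0, 365, 365),
               scanWidthMm = 3, plexus = "SCP", eyeId = "k")
  expect_true(all(runPreprocess(black) == 0))
})

test_that("segmentation of a noise-free phantom overlaps the truth well", {
  ph <- fullPhantom(42, noiseSigma = 0, fazNoiseLevel = 0)
  vm <- binarizeOtsu(runPreprocess(ph$angiogram))
  expect_gte(diceCoef(pixels(vm), ph$truth@vesselMask), 0.75)
})

test_that("segmentation quality degrades gracefully with noise", {
  ph <- fullPhantom(43, noiseSigma = 0.1)
  dicePre <- diceCoef(pixels(binarizeOtsu(runPreprocess(ph$angiogram))),
                      ph$truth@vesselMask)
  expect_gte(dicePre, 0.65)
})

test_that("the chain commutes with 90-degree rotation", {
  ph <- fullPhantom(41)
  a <- grayscaleAndCrop(ph$angiogram)
  a90 <- new("EnFaceAngiogram", pixels = rotate90(pixels(a)),
             scanWidthMm = 3, plexus = "SCP", eyeId = "r")
  v <- runPreprocess(a)
  v90 <- runPreprocess(a90)
  expect_equal(rotate90(matrix(v, 364)), matrix(v90, 364),
               tolerance = 1e-9)
})
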