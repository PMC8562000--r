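test_that("phantom parameters are validated", {
  expect_error(phantomParams(imageSidePx = 32), "imageSidePx")
  expect_error(phantomParams(fazAreaMm2 = 9.5), "fazAreaMm2")
  expect_error(phantomParams(targetVad = 1.2), "\\[0, 1\\]")
  expect_error(phantomParams(targetVad = 0.95), "reachable")
  expect_error(phantomParams(vesselWidthPxRange = c(0.5, 2)), "min >= 1")
  expect_s3_class(phantomParams(), "PhantomParams")
})

test_that("zero target density yields an empty network over background", {
  ph <- generatePhantom(phantomParams(imageSidePx = 122L, scanWidthMm = 1,
                                      fazAreaMm2 = 0.06, targetVad = 0,
                                      noiseSigma = 0.02, rngSeed = 4))
  expect_equal(sum(ph$truth@vesselMask), 0)
  expect_equal(ph$truth@trueVadFoveal, 0)
  expect_equal(ph$truth@trueVsdParafoveal, 0)
  ## background + noise only: dim and unstructured
  inner <- pixels(ph$angiogram)[-1, -1]
  expect_lt(mean(inner) / 255, 0.2)
})

test_that("identical seeds give bit-identical phantoms", {
  p <- phantomParams(imageSidePx = 122L, scanWidthMm = 1, fazAreaMm2 = 0.07,
                     targetVad = 0.3, noiseSigma = 0.05, rngSeed = 7)
  a <- generatePhantom(p)
  b <- generatePhantom(p)
  expect_identical(pixels(a$angiogram), pixels(b$angiogram))
  expect_identical(a$truth@vesselMask, b$truth@vesselMask)
})

test_that("rasterized FAZ area hits the requested area within 5%", {
  ph <- fullPhantom(31, fazAreaMm2 = 0.3)
  pxArea <- (3 / 364)^2
  counted <- sum(ph$truth@fazMask) * pxArea
  expect_equal(ph$truth@trueFazAreaMm2, counted)
  expect_gte(counted, 0.285)
  expect_lte(counted, 0.315)
})

test_that("ground-truth densities equal brute-force pixel counts", {
  for (seed in c(1, 2)) {
    ph <- smallPhantom(seed)
    tr <- ph$truth
    n <- nrow(tr@vesselMask)
    regs <- makeRegionMasks(n, tr@scanWidthMm, tr@foveaCenterPx,
                            innerDiameterMm = tr@scanWidthMm / 3,
                            outerDiameterMm = tr@scanWidthMm)
    fov <- pixels(regs$foveal); para <- pixels(regs$parafoveal)
    expect_identical(tr@trueVadFoveal, sum(tr@vesselMask * fov) / sum(fov))
    expect_identical(tr@trueVadParafoveal,
                     sum(tr@vesselMask * para) / sum(para))
    ## FAZ and vessels never overlap
    expect_equal(sum(tr@vesselMask * tr@fazMask), 0)
    ## skeleton truth is a subset of the vessel truth
    sk <- pixels(skeletonizeMap(tr@vesselMask,
                                scanWidthMm = tr@scanWidthMm))
    expect_true(all(tr@vesselMask[sk > 0] == 1))
    expect_identical(tr@trueVsdFoveal, sum(sk * fov) / sum(fov))
  }
})

test_that("burnout attenuation removes the programmed vessel fraction", {
  ph <- smallPhantom(5, noiseSigma = 0)
  orig <- sum(ph$truth@vesselMask)

  un <- applyBurnout(ph$angiogram, ph$truth, 0, seed = 1)
  expect_identical(pixels(un$angiogram), pixels(ph$angiogram))
  expect_identical(un$truth@vesselMask, ph$truth@vesselMask)

  half <- applyBurnout(ph$angiogram, ph$truth, 0.5, seed = 1)
  expect_lt(abs(sum(half$truth@vesselMask) / orig - 0.5), 0.02)

  gone <- applyBurnout(ph$angiogram, ph$truth, 1, seed = 1)
  expect_equal(sum(gone$truth@vesselMask), 0)
  expect_equal(gone$truth@trueVadFoveal, 0)
  expect_equal(gone$truth@trueVadParafoveal, 0)
})

test_that("cohort with null effects shows no treated-fellow difference", {
  co <- generateCohort(cohortParams(
    nPatients = 50, effectVadScp = 0, effectVadDcp = 0, effectFaz = 1,
    fractionBurnout = 0,
    doseModel = list(fovealMeanGy = 30, fovealSdGy = 30, discMeanGy = 85,
                     discSdGy = 10, slopePpPerGy = 0), rngSeed = 12))
  tab <- co$table
  d <- tab$vadDcpFoveal[tab$treated] - tab$vadDcpFoveal[!tab$treated]
  expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)) + 1e-9)
})

test_that("a programmed 12-point deep-plexus deficit is recoverable at n=50", {
  co <- generateCohort(cohortParams(nPatients = 50, fractionBurnout = 0,
                                    rngSeed = 21))
  tab <- co$table
  d <- 100 * (tab$vadDcpParafoveal[!tab$treated] -
              tab$vadDcpParafoveal[tab$treated])
  expect_gt(mean(d), 10)
  expect_lt(mean(d), 14)
})

test_that("burnout count is binomially consistent", {
  co <- generateCohort(cohortParams(nPatients = 100, fractionBurnout = 0.36,
                                    rngSeed = 77))
  k <- sum(co$table$burnout)
  ci <- stats::binom.test(round(0.36 * 100), 100)$conf.int
  expect_gte(k / 100, ci[1])
  expect_lte(k / 100, ci[2])
})

test_that("cohort tables are deterministic given the seed", {
  a <- generateCohort(cohortParams(nPatients = 6, rngSeed = 3))
  b <- generateCohort(cohortParams(nPatients = 6, rngSeed = 3))
  expect_identical(a$table, b$table)
})
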