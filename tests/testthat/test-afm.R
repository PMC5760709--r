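test_that("the contact point is found to sample precision on noiseless curves", {
  p <- makePreset("control")
  for (seed in 1:5) {
    fc <- simulateForceCurve(p, seed = seed, noiseSd = 0)
    spacing <- abs(diff(fc@sepExt[1:2]))
    expect_lt(abs(findContactPoint(fc) - groundTruth(fc)$contactPoint),
              spacing)
  }
})

test_that("curves without deflection raise a no-contact error", {
  flat <- new("ForceCurve", sepExt = seq(6000, 1000, length.out = 500),
              forceExt = rep(0, 500), sepRet = numeric(0),
              forceRet = numeric(0), springConstant = 0.03, velocity = 2,
              truth = list())
  expect_error(findContactPoint(flat), "no contact")
})

test_that("a constant force offset moves neither contact point nor modulus", {
  set.seed(1)  # helper noise uses the ambient RNG
  fc <- syntheticExtension(E = 800, cp = 2200, noiseSd = 2)
  fcOff <- new("ForceCurve", sepExt = fc@sepExt,
               forceExt = fc@forceExt + 57, sepRet = numeric(0),
               forceRet = numeric(0), springConstant = 0.03, velocity = 2,
               truth = fc@truth)
  expect_equal(findContactPoint(fcOff), findContactPoint(fc),
               tolerance = 1e-6)
  expect_equal(youngsModulus(fitHertz(fcOff)), youngsModulus(fitHertz(fc)),
               tolerance = 1e-9)
})

test_that("the pyramidal Hertz fit recovers a known modulus", {
  fc <- syntheticExtension(E = 1000, cp = 2000, nu = 0.5, halfAngle = 35)
  hf <- fitHertz(fc)
  expect_equal(youngsModulus(hf), 1000, tolerance = 1e-3)  # 0.1%
  expect_equal(contactPoint(hf), 2000, tolerance = 1)
  ## simulator inversion at preset geometry
  fcSim <- simulateForceCurve(makePreset("gaucher"), seed = 9, noiseSd = 0)
  expect_equal(youngsModulus(fitHertz(fcSim)), groundTruth(fcSim)$E,
               tolerance = 1e-3)
})

test_that("a negative fitted modulus is clamped to zero and flagged", {
  s <- seq(6000, 500, length.out = 600)
  f <- -1e-4 * pmax(2000 - s, 0)^2   # pulled down, not pushed up
  fc <- new("ForceCurve", sepExt = s, forceExt = f, sepRet = numeric(0),
            forceRet = numeric(0), springConstant = 0.03, velocity = 2,
            truth = list())
  hf <- fitHertz(fc, contactPoint = 2000)
  expect_equal(youngsModulus(hf), 0)
  expect_true(any(grepl("clamped", hf@flags)))
})

test_that("the Hertz fit is stable under re-sampling density", {
  p <- makePreset("control")
  e1 <- youngsModulus(fitHertz(simulateForceCurve(p, 11, nPoints = 800,
                                                  noiseSd = 0)))
  e2 <- youngsModulus(fitHertz(simulateForceCurve(p, 11, nPoints = 1600,
                                                  noiseSd = 0)))
  expect_equal(e1, e2, tolerance = 0.01)
})

test_that("noiseless step curves are recovered exactly by both detectors", {
  fc <- syntheticRetraction(positions = c(1000, 2500, 4000),
                            heights = c(30, 30, 30))
  ev <- detectSteps(fc)
  expect_equal(nSteps(ev), 3L)
  expect_equal(stepHeights(ev), rep(30, 3), tolerance = 1e-6)
  spacing <- diff(fc@sepRet[1:2])
  expect_true(all(abs(stepPositions(ev) - c(1000, 2500, 4000)) <= spacing))
  expect_equal(length(ev@algB$positions), 3L)
})

test_that("step fitting matches the brute-force breakpoint oracle", {
  p <- makePreset("control")
  checked <- 0
  for (seed in 1:30) {
    fc <- simulateForceCurve(p, seed = seed, noiseSd = 0)
    tr <- groundTruth(fc)
    if (tr$nTethers < 1 || tr$nTethers > 5) next
    oracle <- bruteForceSteps(fc@sepRet, fc@forceRet)
    ev <- detectSteps(fc)
    expect_equal(ev@algA$positions, oracle$positions, tolerance = 1e-9)
    expect_equal(ev@algA$heights, oracle$heights, tolerance = 1e-9)
    checked <- checked + 1
    if (checked >= 10) break
  }
  expect_gte(checked, 5)
})

test_that("flat noisy baselines yield almost no false steps", {
  set.seed(42)
  fp <- vapply(1:100, function(i) {
    s <- seq(0, 6000, length.out = 1200)
    fc <- new("ForceCurve", sepExt = numeric(0), forceExt = numeric(0),
              sepRet = s, forceRet = rnorm(1200, sd = 2),
              springConstant = 0.03, velocity = 2, truth = list())
    nSteps(detectSteps(fc))
  }, integer(1))
  expect_lte(mean(fp), 0.05)
})

test_that("30 pN steps in 2 pN noise are detected with high recall", {
  set.seed(7)
  hits <- vapply(1:100, function(i) {
    pos <- sort(runif(3, 500, 5500))
    fc <- syntheticRetraction(pos, rep(30, 3), noiseSd = 2)
    ev <- detectSteps(fc)
    sum(vapply(pos, function(pz)
      any(abs(stepPositions(ev) - pz) < 50), logical(1)))
  }, numeric(1))
  expect_gte(sum(hits) / 300, 0.95)
})

test_that("tether statistics pool heights and counts", {
  ev <- function(h) new("StepEvents", positions = seq_along(h) * 100,
                        heights = h, detector = "consensus",
                        algA = list(), algB = list())
  st <- tetherStatistics(list(ev(c(10, 20)), ev(30)))
  expect_equal(st$medianForce, 20)
  expect_equal(st$meanCount, 1.5)
  expect_equal(st$nCurves, 2)
  expect_equal(sum(st$forceHist$count), 3)
  ## empty events give zero counts, not an error
  st0 <- tetherStatistics(list(ev(numeric(0))))
  expect_equal(st0$meanCount, 0)
  expect_true(is.na(st0$medianForce))
  expect_error(tetherStatistics(list()), "curve")
})

test_that("modulus-height profiles bin correctly", {
  h <- seq(0, 2400, length.out = 120)
  prof <- modulusHeightProfile(rep(500, 120), h)
  expect_equal(length(prof@binEdges), 26L)      # default 25 bins
  expect_equal(prof@meanE, rep(500, 25))
  expect_equal(sum(prof@counts), 120L)
  ## a two-level modulus landscape reproduces the step
  E2 <- ifelse(h < median(h), 1000, 500)
  prof2 <- modulusHeightProfile(E2, h, nBins = 10)
  expect_equal(prof2@meanE[1:4], rep(1000, 4))
  expect_equal(prof2@meanE[7:10], rep(500, 4))
  expect_error(modulusHeightProfile(rep(1, 5), rep(3, 5)), "identical")
  expect_error(modulusHeightProfile(1:4, 1:5), "equal lengths")
})
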