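makeRecord <- function(t, I, T, bg, bleachIndex) {
  new("FrapRecord", t = t, I = I, T = T, bg = bg,
      bleachIndex = as.integer(bleachIndex), truth = list())
}

test_that("double normalization cancels matching numerator and denominator", {
  t <- 0:19
  Tser <- 1000 - 10 * t
  ## I identical to T, zero background: ratios cancel, R == 1
  r <- doubleNormalize(makeRecord(t, Tser, Tser, rep(0, 20), 6))
  expect_equal(recovery(r), rep(1, 20))
  ## proportional ROI with constant background: still R == 1
  bg <- rep(30, 20)
  r2 <- doubleNormalize(makeRecord(t, 0.4 * (Tser - 30) + 30, Tser, bg, 6))
  expect_equal(recovery(r2), rep(1, 20))
})

test_that("double normalization is invariant to intensity scale and shared bleaching", {
  p <- makePreset("control")
  for (seed in 1:5) {
    rec <- simulateFrapRecord(p, seed = seed)
    base <- recovery(doubleNormalize(rec))
    ## global positive rescaling of I and T about the background
    sc <- new("FrapRecord", t = rec@t, I = (rec@I - rec@bg) * 3.7 + rec@bg,
              T = (rec@T - rec@bg) * 3.7 + rec@bg, bg = rec@bg,
              bleachIndex = rec@bleachIndex, truth = list())
    expect_equal(recovery(doubleNormalize(sc)), base, tolerance = 1e-12)
  }
  ## extra per-frame photobleaching on both signals cancels; exact on
  ## noiseless records (noisy pre-bleach means re-weight it at O(noise^2))
  rec0 <- simulateFrapRecord(p, seed = 1, noiseSd = 0)
  base0 <- recovery(doubleNormalize(rec0))
  decay <- 0.99^(seq_along(rec0@t) - 1)
  bl <- new("FrapRecord", t = rec0@t,
            I = (rec0@I - rec0@bg) * decay + rec0@bg,
            T = (rec0@T - rec0@bg) * decay + rec0@bg, bg = rec0@bg,
            bleachIndex = rec0@bleachIndex, truth = list())
  expect_equal(recovery(doubleNormalize(bl)), base0, tolerance = 1e-12)
  recN <- simulateFrapRecord(p, seed = 2)
  blN <- new("FrapRecord", t = recN@t,
             I = (recN@I - recN@bg) * decay + recN@bg,
             T = (recN@T - recN@bg) * decay + recN@bg, bg = recN@bg,
             bleachIndex = recN@bleachIndex, truth = list())
  expect_equal(recovery(doubleNormalize(blN)),
               recovery(doubleNormalize(recN)), tolerance = 2e-3)
})

test_that("noiseless simulated records invert to the recovery model exactly", {
  cases <- list(c(0.5, 0.2, 5), c(0.6, 0.15, 10), c(0.8, 0.45, 25),
                c(0.3, 0.9, 2))
  for (cs in cases) {
    p <- presetWith(frap = list(a = cs[1], b = cs[2], tau = cs[3]))
    rec <- simulateFrapRecord(p, seed = 1, noiseSd = 0)
    expect_lt(max(abs(recovery(doubleNormalize(rec)) -
                      groundTruth(rec)$R)), 1e-10)
  }
})

test_that("a fully immobile pool gives a flat post-bleach curve", {
  p <- presetWith(frap = list(b = 1))
  rec <- simulateFrapRecord(p, seed = 1, noiseSd = 0)
  R <- recovery(doubleNormalize(rec))
  post <- R[rec@bleachIndex:length(R)]
  expect_equal(post, rep(1 - p@frap$a, length(post)), tolerance = 1e-12)
  fit <- fitRecovery(doubleNormalize(rec))
  expect_equal(unname(coef(fit)["a"]), p@frap$a, tolerance = 1e-6)
  expect_true(any(grepl("b pinned", fit@flags)))
})

test_that("errors name the offending frame or condition", {
  t <- 0:19
  I <- rep(100, 20); T <- rep(500, 20); bg <- rep(10, 20)
  T[8] <- 5  # below background
  expect_error(doubleNormalize(makeRecord(t, I, T, bg, 6)), "frame 8")
  expect_error(makeRecord(t, I[-1], T, bg, 6), "equal lengths")
})

test_that("curve averaging is a pointwise mean with SEM", {
  p <- makePreset("control")
  cv <- doubleNormalize(simulateFrapRecord(p, seed = 1))
  same <- averageCurves(list(cv, cv, cv))
  expect_equal(recovery(same), recovery(cv))
  expect_equal(same@nAveraged, 3L)
  ## constant curves 0.8 and 1.2 average to 1.0
  flat <- function(v) new("NormalizedCurve", t = cv@t,
                          R = rep(v, length(cv@t)),
                          sem = rep(NA_real_, length(cv@t)),
                          bleachIndex = cv@bleachIndex, nAveraged = 1L)
  expect_equal(recovery(averageCurves(list(flat(0.8), flat(1.2)))),
               rep(1.0, length(cv@t)))
  expect_error(averageCurves(list()), "empty")
  shifted <- new("NormalizedCurve", t = cv@t + 0.5, R = recovery(cv),
                 sem = cv@sem, bleachIndex = cv@bleachIndex, nAveraged = 1L)
  expect_error(averageCurves(list(cv, shifted)), "resample")
  expect_silent(averageCurves(list(cv, shifted), resample = TRUE))
})

test_that("averaging reduces noise like one over the square root of n", {
  p <- makePreset("control")
  curves <- lapply(1:10, function(s)
    doubleNormalize(simulateFrapRecord(p, seed = s)))
  truthR <- groundTruth(simulateFrapRecord(p, seed = 1, noiseSd = 0))$R
  rmsSingle <- mean(vapply(curves, function(cv)
    sqrt(mean((recovery(cv) - truthR)^2)), numeric(1)))
  rmsAvg <- sqrt(mean((recovery(averageCurves(curves)) - truthR)^2))
  expect_gt(rmsSingle / rmsAvg, 2)    # ~ sqrt(10) = 3.2
  expect_lt(rmsSingle / rmsAvg, 4.5)
})

test_that("noiseless fits recover the generating parameters exactly", {
  p <- presetWith(frap = list(a = 0.5, b = 0.2, tau = 5))
  fit <- fitRecovery(doubleNormalize(simulateFrapRecord(p, 1, noiseSd = 0)))
  expect_equal(unname(coef(fit)[c("a", "b", "tau")]), c(0.5, 0.2, 5),
               tolerance = 1e-6)
  ## asymptote identity: R(inf) = R0 - a b
  e <- coef(fit)
  expect_equal(unname(e["R0"] - e["a"] + e["a"] * (1 - e["b"])),
               unname(e["R0"] - e["a"] * e["b"]), tolerance = 1e-12)
  ## confidence bounds bracket the estimates
  ci <- confint(fit)
  expect_true(all(ci[, "lower"] <= e[rownames(ci)] + 1e-12))
  expect_true(all(ci[, "upper"] >= e[rownames(ci)] - 1e-12))
})

test_that("the fit is invariant to rescaling the raw record", {
  p <- makePreset("control")
  rec <- simulateFrapRecord(p, seed = 3)
  f1 <- coef(fitRecovery(doubleNormalize(rec)))
  sc <- new("FrapRecord", t = rec@t, I = rec@I * 2.5, T = rec@T * 2.5,
            bg = rec@bg * 2.5, bleachIndex = rec@bleachIndex, truth = list())
  f2 <- coef(fitRecovery(doubleNormalize(sc)))
  expect_equal(f1, f2, tolerance = 1e-6)
})

test_that("condition differences are read off confidence-interval overlap", {
  fits <- lapply(c("control", "gaucher"), function(nm) {
    curves <- lapply(1:10, function(s)
      doubleNormalize(simulateFrapRecord(makePreset(nm), seed = s)))
    fitRecovery(averageCurves(curves))
  })
  ## a 3-fold immobile-fraction difference at this noise is significant
  expect_false(ciOverlaps(fits[[1]], fits[[2]], "b"))
})
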