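#' Simulate a raw FRAP intensity record
#'
#' Constructs bleached-ROI (\code{I}), whole-membrane (\code{T}) and
#' background (\code{bg}) intensity series such that exact double
#' normalization of the noiseless record reproduces the empirical recovery
#' model R(t) = R(0) - a + a (1 - b) (1 - exp(-t / tau)) with the preset
#' parameters. Acquisition bleaching is applied as a multiplicative
#' per-frame decay to both I and T (double normalization cancels it), the
#' bleach pulse additionally reduces whole-membrane intensity by
#' \code{bleachDrop}, and relative Gaussian noise is applied last.
#'
#' @param params a \linkS4class{MemPreset}.
#' @param seed integer seed; identical (preset, seed) pairs give
#'   bit-identical records.
#' @param nPre,nPost number of pre- and post-bleach frames.
#' @param dt frame interval (s); must be positive.
#' @param I0,T0,bg0 noiseless pre-bleach ROI, membrane and background
#'   levels (a.u.).
#' @param bleachDrop fraction of whole-membrane signal surviving the bleach
#'   pulse.
#' @param noiseSd relative intensity noise; defaults to the preset value.
#' @return a \linkS4class{FrapRecord} whose \code{truth} holds
#'   \code{a}, \code{b}, \code{tau} and the noiseless recovery curve.
#' @examples
#' rec <- simulateFrapRecord(makePreset("control"), seed = 1)
#' fit <- fitRecovery(doubleNormalize(rec))
#' coef(fit)
#' @export
simulateFrapRecord <- function(params, seed, nPre = 10L, nPost = 100L,
                               dt = 1, I0 = 1000, T0 = 5000, bg0 = 50,
                               bleachDrop = 0.9,
                               noiseSd = params@frap$noise_sd) {
  stopifnot(is(params, "MemPreset"))
  if (dt <= 0) stop("dt must be positive")
  if (nPre < 1L || nPost < 10L)
    stop("need nPre >= 1 and nPost >= 10")
  fr <- params@frap
  n <- nPre + nPost
  t <- (seq_len(n) - 1) * dt
  post <- seq_len(n) > nPre
  tp <- t - t[nPre + 1L]          # 0 at first post-bleach frame

  ## Target recovery curve (pre-bleach R = 1, i.e. R(0) = 1)
  R <- rep(1, n)
  R[post] <- 1 - fr$a + fr$a * (1 - fr$b) * (1 - exp(-tp[post] / fr$tau))

  decay <- (1 - fr$acq_bleach_rate)^(seq_len(n) - 1)
  Tsig <- (T0 - bg0) * decay * ifelse(post, bleachDrop, 1)
  Tser <- bg0 + Tsig
  ## Invert double normalization: pre-bleach I carries the same decay (so
  ## its ratio to T is constant and pre-bleach R is exactly 1); post-bleach
  ## I is chosen so Eq. 1 applied with pre-bleach means returns R exactly.
  Iser <- numeric(n)
  Iser[!post] <- bg0 + (I0 - bg0) * decay[!post]
  T0sig <- T0 - bg0
  Iser[post] <- bg0 + R[post] * (I0 - bg0) * Tsig[post] / T0sig
  bgser <- rep(bg0, n)

  withSeed(seed, {
    if (noiseSd > 0) {
      Iser <- Iser * (1 + rnorm(n, sd = noiseSd))
      Tser <- Tser * (1 + rnorm(n, sd = noiseSd))
      bgser <- bgser * (1 + rnorm(n, sd = noiseSd))
    }
  })

  new("FrapRecord", t = t, I = pmax(Iser, 0), T = pmax(Tser, 0),
      bg = bgser, bleachIndex = nPre + 1L,
      truth = list(a = fr$a, b = fr$b, tau = fr$tau, R = R,
                   preset = params@name, seed = seed))
}
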