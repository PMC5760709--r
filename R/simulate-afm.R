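# pN per (Pa * nm^2): four-sided pyramidal indenter geometry factor.
hertzFactor <- function(nu, halfAngle) {
  tan(halfAngle * pi / 180) / sqrt(2) / (1 - nu^2) * 1e-6
}

#' Simulate an AFM force-vs-separation curve
#'
#' Extension segment: zero-force baseline above the contact point, then
#' Hertzian indentation F = E / (1 - nu^2) * tan(alpha) / sqrt(2) * delta^2
#' for a four-sided pyramidal tip, truncated at the load cap (1 nN, the
#' acquisition protocol's trigger force). Retraction segment: the tether
#' count is drawn from a rounded truncated normal (minimum 0) with the
#' preset mean/SD, step heights from a lognormal about the preset median
#' (sigma_log 0.3), and rupture separations uniformly over the tether-length
#' range; the force at each separation is minus the running sum of
#' unruptured tether forces (adhesive forces are negative), so each rupture
#' is an abrupt upward step. Gaussian force noise is added to both
#' segments. Young's modulus is drawn per curve from a lognormal whose
#' log-scale spread is fixed by the preset median/mean pair.
#'
#' @param params a \linkS4class{MemPreset}.
#' @param seed integer seed.
#' @param nPoints samples per segment (>= 200).
#' @param noiseSd force noise SD in pN; defaults to the preset value.
#' @return a \linkS4class{ForceCurve}; \code{truth} holds the contact point
#'   (nm), Young's modulus (Pa), and tether step positions (nm) and heights
#'   (pN).
#' @examples
#' fc <- simulateForceCurve(makePreset("control"), seed = 1)
#' groundTruth(fc)$E
#' @export
simulateForceCurve <- function(params, seed, nPoints = 1500L,
                               noiseSd = params@afm$force_noise_sd) {
  stopifnot(is(params, "MemPreset"))
  if (nPoints < 200L) stop("need nPoints >= 200 per segment")
  af <- params@afm
  K <- hertzFactor(af$nu, af$half_angle)

  withSeed(seed, {
    cp <- runif(1, af$contact_point_range[1], af$contact_point_range[2])
    E <- rlnorm(1, meanlog = log(af$E_median), sdlog = af$E_sdlog)
    dmax <- sqrt(af$max_load / (K * E))
    sepExt <- seq(af$approach_start, cp - dmax, length.out = nPoints)
    delta <- pmax(cp - sepExt, 0)
    forceExt <- K * E * delta^2

    nTeth <- as.integer(round(pmax(0,
      rnorm(1, af$tether_count_mean, af$tether_count_sd))))
    sepRet <- seq(0, af$approach_start, length.out = nPoints)
    if (nTeth > 0) {
      rupture <- sort(runif(nTeth, af$tether_rupture_range[1],
                            af$tether_rupture_range[2]))
      heights <- rlnorm(nTeth, meanlog = log(af$tether_force_median),
                        sdlog = af$tether_force_sdlog)
      nRuptured <- findInterval(sepRet, rupture)
      remaining <- sum(heights) - c(0, cumsum(heights))[nRuptured + 1L]
      forceRet <- -remaining
    } else {
      rupture <- numeric(0); heights <- numeric(0)
      forceRet <- rep(0, nPoints)
    }
    if (noiseSd > 0) {
      forceExt <- forceExt + rnorm(nPoints, sd = noiseSd)
      forceRet <- forceRet + rnorm(nPoints, sd = noiseSd)
    }
    new("ForceCurve",
        sepExt = sepExt, forceExt = forceExt,
        sepRet = sepRet, forceRet = forceRet,
        springConstant = af$spring_constant, velocity = af$velocity,
        truth = list(contactPoint = cp, E = E, nTethers = nTeth,
                     stepPositions = rupture, stepHeights = heights,
                     preset = params@name, seed = seed,
                     grid = "16x16 force-volume"))
  })
}

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf(
    "ForceCurve: %d extension + %d retraction samples, k = %.3f N/m\n",
    length(object@sepExt), length(object@sepRet), object@springConstant))
  if (length(object@truth))
    cat(sprintf("  truth: E = %.0f Pa, contact %.0f nm, %d tethers\n",
                object@truth$E, object@truth$contactPoint,
                object@truth$nTethers))
})
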