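# Shared fixtures and independent oracles.

# Preset with one or more frap/afm/gp/endo fields overridden (for
# controlled-parameter fixtures).
presetWith <- function(name = "control", frap = list(), afm = list(),
                       gp = list(), endo = list()) {
  p <- makePreset(name)
  for (k in names(frap)) p@frap[[k]] <- frap[[k]]
  for (k in names(afm)) p@afm[[k]] <- afm[[k]]
  for (k in names(gp)) p@gp[[k]] <- gp[[k]]
  for (k in names(endo)) p@endo[[k]] <- endo[[k]]
  validObject(p)
  p
}

# Brute-force step oracle for noiseless piecewise-constant traces:
# enumerate every sample boundary and keep those with a non-zero jump.
bruteForceSteps <- function(sep, force, tol = 1e-9) {
  d <- diff(force)
  idx <- which(abs(d) > tol)
  list(positions = (sep[idx] + sep[idx + 1]) / 2, heights = abs(d[idx]))
}

# Noiseless retraction-only force curve with given step positions/heights
# (adhesive convention: force = minus the sum of unruptured tether forces).
syntheticRetraction <- function(positions, heights, n = 1200,
                                sMax = 6000, noiseSd = 0) {
  s <- seq(0, sMax, length.out = n)
  ord <- order(positions)
  positions <- positions[ord]; heights <- heights[ord]
  nRuptured <- findInterval(s, positions)
  f <- -(sum(heights) - c(0, cumsum(heights))[nRuptured + 1])
  if (noiseSd > 0) f <- f + rnorm(n, sd = noiseSd)
  new("ForceCurve", sepExt = numeric(0), forceExt = numeric(0),
      sepRet = s, forceRet = f, springConstant = 0.03, velocity = 2,
      truth = list(stepPositions = positions, stepHeights = heights))
}

# Noiseless extension-only curve following the pyramidal Hertz model.
syntheticExtension <- function(E = 1000, cp = 2000, nu = 0.5,
                               halfAngle = 35, n = 1000, sMax = 6000,
                               maxLoad = 1000, offset = 0, noiseSd = 0) {
  K <- tan(halfAngle * pi / 180) / sqrt(2) / (1 - nu^2) * 1e-6
  dmax <- sqrt(maxLoad / (K * E))
  s <- seq(sMax, cp - dmax, length.out = n)
  f <- K * E * pmax(cp - s, 0)^2 + offset
  if (noiseSd > 0) f <- f + rnorm(n, sd = noiseSd)
  new("ForceCurve", sepExt = s, forceExt = f,
      sepRet = numeric(0), forceRet = numeric(0),
      springConstant = 0.03, velocity = 2,
      truth = list(contactPoint = cp, E = E))
}

# Disk painter for hand-built images.
paintDisk <- function(img, center, r, value, rInner = 0) {
  d2 <- outer((seq_len(nrow(img)) - center[1])^2,
              (seq_len(ncol(img)) - center[2])^2, "+")
  img[d2 <= r^2 & d2 > rInner^2] <- value
  img
}
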