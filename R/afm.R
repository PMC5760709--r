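#' Detect the tip-sample contact point on an extension curve
#'
#' Fits a piecewise model - flat baseline at large separation, quadratic
#' (Hertzian) contact region below the breakpoint - at candidate
#' breakpoints and returns the separation minimizing the total squared
#' error. A coarse grid over all samples is refined to single-sample
#' resolution around the coarse optimum. A constant force offset is
#' absorbed by the baseline term and leaves the detected contact point
#' unchanged.
#'
#' @param curve a \linkS4class{ForceCurve}; its extension segment is used.
#' @param minBaseline minimum number of pre-contact baseline samples.
#' @param minDeflection detection threshold in baseline noise SDs: if no
#'   force anywhere exceeds the baseline by this many SDs (with an absolute
#'   floor of 1e-6 pN), a "no contact" error is raised.
#' @return the contact point (nm, separation units).
#' @export
findContactPoint <- function(curve, minBaseline = 20L, minDeflection = 5) {
  stopifnot(is(curve, "ForceCurve"))
  s <- curve@sepExt; f <- curve@forceExt
  n <- length(s)
  if (n < 2L * minBaseline) stop("extension segment too short")
  ## baseline = far-separation end (start of the approach)
  base <- f[seq_len(minBaseline)]
  sdb <- sd(base)
  if (max(f) - mean(base) < max(minDeflection * sdb, 1e-6))
    stop("no contact: no super-threshold deflection on the extension segment")

  sse <- function(cp) {
    # model f = b0 + beta * max(cp - s, 0)^2
    z <- pmax(cp - s, 0)^2
    zm <- mean(z); fm <- mean(f)
    vz <- sum((z - zm)^2)
    beta <- if (vz > 0) sum((z - zm) * (f - fm)) / vz else 0
    beta <- max(beta, 0)             # indentation force can only push up
    r <- f - (fm - beta * zm) - beta * z
    sum(r^2)
  }
  cand <- unique(round(seq(minBaseline, n, length.out = 128L)))
  err <- vapply(s[cand], sse, numeric(1))
  bestC <- cand[which.min(err)]
  step <- max(1L, diff(cand[1:2]))
  fine <- max(minBaseline, bestC - step):min(n, bestC + step)
  errF <- vapply(s[fine], sse, numeric(1))
  bestF <- fine[which.min(errF)]
  ## continuous refinement between neighbouring samples
  lo <- s[min(bestF + 1L, n)]; hi <- s[max(bestF - 1L, 1L)]
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  if (hi > lo) optimize(sse, c(lo, hi), tol = 1e-4)$minimum else s[bestF]
}

#' Fit the pyramidal-tip Hertz model to an extension curve
#'
#' Least-squares fit of F = E / (1 - nu^2) * tan(alpha) / sqrt(2) * delta^2
#' with delta the indentation beyond the contact point, over the range from
#' the contact point to the load cap (the acquisition trigger). The model
#' is linear in E given the contact point, so the fit is a closed-form
#' linear least squares with a free baseline offset; the offset makes the
#' fit invariant to constant force shifts.
#'
#' @param curve a \linkS4class{ForceCurve}.
#' @param nu Poisson ratio (default 0.5, incompressible cell).
#' @param halfAngle pyramid face half-angle in degrees (default 35).
#' @param contactPoint contact point (nm); detected with
#'   [findContactPoint()] when NULL.
#' @return a \linkS4class{HertzFit}. A negative fitted modulus is clamped
#'   to 0 and flagged.
#' @examples
#' fc <- simulateForceCurve(makePreset("control"), seed = 1, noiseSd = 0)
#' youngsModulus(fitHertz(fc))  # recovers the true modulus
#' @export
fitHertz <- function(curve, nu = 0.5, halfAngle = 35, contactPoint = NULL) {
  stopifnot(is(curve, "ForceCurve"))
  if (is.null(contactPoint)) contactPoint <- findContactPoint(curve)
  s <- curve@sepExt; f <- curve@forceExt
  z <- pmax(contactPoint - s, 0)^2
  if (!any(z > 0)) stop("empty indentation range beyond the contact point")
  zm <- mean(z); fm <- mean(f)
  vz <- sum((z - zm)^2)
  if (vz == 0) stop("degenerate indentation regressor")
  beta <- sum((z - zm) * (f - fm)) / vz
  b0 <- fm - beta * zm
  resid <- f - b0 - beta * z
  flags <- character()
  if (beta < 0) {
    beta <- 0
    flags <- "E clamped to 0 (negative fitted modulus)"
  }
  E <- beta / hertzFactor(nu, halfAngle)
  new("HertzFit", E = E, contactPoint = contactPoint, nu = nu,
      halfAngle = halfAngle, fitRange = range(s),
      residual = sqrt(mean(resid^2)), flags = flags)
}

## --- step detection -------------------------------------------------------

# Binary segmentation of a series into piecewise-constant segments:
# repeatedly add the breakpoint with the largest variance reduction while
# the implied jump exceeds thr; returns sorted breakpoint indices (last
# index of the left segment).
.binsegBreaks <- function(f, thr, minSegLen) {
  n <- length(f)
  bps <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    l <- seg[1]; r <- seg[2]; len <- r - l + 1L
    if (len < 2L * minSegLen) next
    y <- f[l:r]
    cs <- cumsum(y)
    i <- minSegLen:(len - minSegLen)
    mL <- cs[i] / i
    mR <- (cs[len] - cs[i]) / (len - i)
    red <- i * (len - i) / len * (mL - mR)^2
    k <- which.max(red)
    if (abs(mL[k] - mR[k]) > thr) {
      bp <- l + i[k] - 1L
      bps <- c(bps, bp)
      stack <- c(stack, list(c(l, bp)), list(c(bp + 1L, r)))
    }
  }
  sort(bps)
}

# Merge adjacent piecewise-constant segments whose mean difference is
# below thr; returns list(breaks, jumps) with signed jumps (right - left).
.mergeSegments <- function(f, bps, thr) {
  repeat {
    bounds <- c(0L, bps, length(f))
    means <- vapply(seq_len(length(bounds) - 1L), function(j)
      mean(f[(bounds[j] + 1L):bounds[j + 1L]]), numeric(1))
    jumps <- diff(means)
    if (!length(jumps) || all(abs(jumps) > thr))
      return(list(breaks = bps, jumps = jumps))
    drop <- which.min(abs(jumps))
    bps <- bps[-drop]
  }
}

# Smoothed-derivative detector: difference of w-sample means after/before
# each candidate boundary, thresholded with non-maximum suppression.
.derivSteps <- function(f, thr, w, minSep) {
  n <- length(f)
  if (n < 2L * w + 1L) return(list(breaks = integer(0), jumps = numeric(0)))
  cs <- c(0, cumsum(f))
  i <- w:(n - w)                       # boundary after sample i
  g <- (cs[i + w + 1L] - cs[i + 1L]) / w - (cs[i + 1L] - cs[i - w + 1L]) / w
  cand <- which(abs(g) > thr)
  if (!length(cand)) return(list(breaks = integer(0), jumps = numeric(0)))
  ord <- cand[order(-abs(g[cand]))]
  keep <- integer(0)
  for (j in ord)
    if (!length(keep) || all(abs(keep - j) >= minSep)) keep <- c(keep, j)
  keep <- sort(keep)
  list(breaks = i[keep], jumps = g[keep])
}

#' Detect tether rupture steps on a retraction curve
#'
#' Runs two independent detectors on the retraction force series and
#' reports their consensus. Algorithm A is iterative step-function fitting
#' (binary segmentation): the breakpoint maximizing the variance reduction
#' is added greedily while the implied step height exceeds k sigma, where
#' sigma is the robust noise estimated from the median absolute deviation
#' of first differences; adjacent segments closer than k sigma are then
#' re-merged. Algorithm B thresholds a smoothed derivative (difference of
#' w-sample means) at k sigma of its own noise scale, with non-maximum
#' suppression at a minimum separation. Consensus events are A events with
#' a B event within the matching window, and are reported by default; both
#' full sets are retained in the result.
#'
#' @param curve a \linkS4class{ForceCurve}; its retraction segment is used.
#' @param noiseSd force noise SD (pN) or "auto" for the robust estimate.
#' @param k step acceptance threshold in noise SD units.
#' @param minSegLen minimum piecewise segment length (samples), algorithm A.
#' @param smoothWidth half-window of the derivative smoother (samples).
#' @param minSep non-maximum suppression distance (samples), algorithm B.
#' @param matchWindow consensus matching window (samples).
#' @return a \linkS4class{StepEvents} with \code{detector = "consensus"}.
#' @examples
#' fc <- simulateForceCurve(makePreset("control"), seed = 2)
#' ev <- detectSteps(fc)
#' nSteps(ev); stepHeights(ev)
#' @export
detectSteps <- function(curve, noiseSd = "auto", k = 3, minSegLen = 3L,
                        smoothWidth = 3L, minSep = 3L, matchWindow = 10L) {
  stopifnot(is(curve, "ForceCurve"))
  s <- curve@sepRet; f <- curve@forceRet
  n <- length(f)
  if (n < 2L * smoothWidth + 1L)
    stop("retraction segment shorter than twice the smoothing window")
  sigma <- if (identical(noiseSd, "auto")) robustNoiseSd(f) else noiseSd
  rngF <- diff(range(f))
  eps <- if (rngF > 0) 1e-8 * rngF else Inf  # constant trace: no steps
  thrA <- max(k * sigma, eps)

  bpsA <- .binsegBreaks(f, thrA, minSegLen)
  A <- .mergeSegments(f, bpsA, thrA)
  posIdxA <- A$breaks; hA <- abs(A$jumps)

  thrB <- max(k * sigma * sqrt(2 / smoothWidth), eps)
  B <- .derivSteps(f, thrB, smoothWidth, minSep)
  posIdxB <- B$breaks; hB <- abs(B$jumps)

  ## consensus: greedy nearest matching of A events to B events
  consensus <- logical(length(posIdxA))
  if (length(posIdxA) && length(posIdxB)) {
    usedB <- logical(length(posIdxB))
    for (j in seq_along(posIdxA)) {
      d <- abs(posIdxB - posIdxA[j])
      d[usedB] <- Inf
      m <- which.min(d)
      if (length(m) && d[m] <= matchWindow) {
        consensus[j] <- TRUE; usedB[m] <- TRUE
      }
    }
  }

  midpos <- function(idx) (s[idx] + s[pmin(idx + 1L, n)]) / 2
  new("StepEvents",
      positions = midpos(posIdxA[consensus]),
      heights = hA[consensus],
      detector = "consensus",
      algA = list(positions = midpos(posIdxA), heights = hA),
      algB = list(positions = midpos(posIdxB), heights = hB))
}

setMethod("show", "StepEvents", function(object) {
  cat(sprintf("StepEvents (%s): %d steps", object@detector,
              length(object@positions)))
  if (length(object@heights))
    cat(sprintf(", heights %.1f-%.1f pN (median %.1f)",
                min(object@heights), max(object@heights),
                median(object@heights)))
  cat(sprintf("  [algA: %d, algB: %d]\n",
              length(object@algA$positions), length(object@algB$positions)))
})

#' Pooled tether statistics over many curves
#'
#' Pools the detected step heights of a set of retraction curves and
#' summarizes the tether-force distribution (median) and the per-curve
#' tether count distribution (mean, SD), with histogram tables.
#'
#' @param events list of \linkS4class{StepEvents}.
#' @param forceBinWidth histogram bin width for step heights (pN).
#' @return a list with \code{medianForce}, \code{forces}, \code{counts},
#'   \code{meanCount}, \code{sdCount}, \code{nCurves}, \code{forceHist}
#'   (data.frame mid/count) and \code{countHist} (table).
#' @export
tetherStatistics <- function(events, forceBinWidth = 5) {
  if (!length(events)) stop("need >= 1 curve")
  stopifnot(all(vapply(events, is, logical(1), "StepEvents")))
  forces <- unlist(lapply(events, stepHeights))
  counts <- vapply(events, nSteps, integer(1))
  forceHist <- if (length(forces)) {
    brk <- seq(0, max(forces) + forceBinWidth, by = forceBinWidth)
    h <- hist(forces, breaks = brk, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  } else data.frame(mid = numeric(0), count = integer(0))
  list(medianForce = if (length(forces)) median(forces) else NA_real_,
       forces = forces, counts = counts,
       meanCount = mean(counts), sdCount = sd(counts),
       nCurves = length(events),
       forceHist = forceHist,
       countHist = table(factor(counts, levels = 0:max(counts))))
}

#' Height-binned mean Young's modulus profile
#'
#' Divides the observed height range into equal-width bins (25 by default,
#' matching the published profile) and reports the mean fitted modulus and
#' curve count per bin; empty bins are NA.
#'
#' @param fits list of \linkS4class{HertzFit} objects, or a numeric vector
#'   of moduli (Pa).
#' @param heights per-curve heights (nm), same length.
#' @param nBins number of bins (>= 2).
#' @return a \linkS4class{ModulusProfile}.
#' @export
modulusHeightProfile <- function(fits, heights, nBins = 25L) {
  E <- if (is.numeric(fits)) fits
       else vapply(fits, youngsModulus, numeric(1))
  if (length(E) != length(heights))
    stop("fits and heights must have equal lengths")
  if (nBins < 2L) stop("need nBins >= 2")
  rng <- range(heights)
  if (rng[1] == rng[2]) stop("all heights identical; cannot bin")
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bin <- findInterval(heights, edges, rightmost.closed = TRUE)
  fb <- factor(bin, levels = seq_len(nBins))
  meanE <- as.numeric(tapply(E, fb, mean))
  counts <- as.integer(table(fb))
  new("ModulusProfile", binEdges = edges, meanE = meanE, counts = counts)
}

setMethod("show", "ModulusProfile", function(object) {
  nb <- length(object@meanE)
  cat(sprintf("ModulusProfile: %d bins over [%.0f, %.0f] nm, %d curves\n",
              nb, object@binEdges[1], object@binEdges[nb + 1L],
              sum(object@counts)))
})
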