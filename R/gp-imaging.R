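#' Simulate a two-channel Laurdan image with known domain structure
#'
#' A binary ordered-domain mask is generated by thresholding a
#' Gaussian-smoothed random field at the quantile that yields exactly the
#' preset high-GP area fraction. Blue and red channel intensities are then
#' chosen so the generalized polarization equals \code{gp_high} inside
#' domains and \code{gp_low} outside, multiplicative photon noise is
#' applied per channel, and the additive channel background (recorded in
#' the object) is added last.
#'
#' @param params a \linkS4class{MemPreset}.
#' @param seed integer seed.
#' @param shape image size in pixels (rows, cols), each >= 64.
#' @param photonNoise relative multiplicative noise; defaults to the preset.
#' @return a \linkS4class{SimulatedGpImage}; \code{truth} holds the domain
#'   mask and the exact pixel area fraction.
#' @examples
#' sim <- simulateGpImage(makePreset("gaucher"), seed = 1, shape = c(128, 128))
#' groundTruth(sim)$fraction
#' @export
simulateGpImage <- function(params, seed, shape = c(256L, 256L),
                            photonNoise = params@gp$photon_noise) {
  stopifnot(is(params, "MemPreset"))
  if (any(shape < 64)) stop("shape must be at least 64 x 64")
  gp <- params@gp
  if (abs(gp$gp_high) >= 1 || abs(gp$gp_low) >= 1)
    stop("gp levels must lie strictly inside (-1, 1)")
  frac <- gp$high_area_fraction
  withSeed(seed, {
    field <- gaussianBlur(matrix(rnorm(prod(shape)), shape[1], shape[2]),
                          sigma = gp$domain_length_scale)
    mask <- if (frac <= 0) {
      matrix(FALSE, shape[1], shape[2])
    } else if (frac >= 1) {
      matrix(TRUE, shape[1], shape[2])
    } else {
      field >= quantile(field, 1 - frac, names = FALSE)
    }
    g <- ifelse(mask, gp$gp_high, gp$gp_low)
    S <- gp$total_intensity
    blue <- S * (1 + g) / 2
    red <- S * (1 - g) / 2
    if (photonNoise > 0) {
      blue <- blue * (1 + rnorm(length(blue), sd = photonNoise))
      red <- red * (1 + rnorm(length(red), sd = photonNoise))
    }
    blue <- pmax(matrix(blue, shape[1], shape[2]), 0) + gp$background
    red <- pmax(matrix(red, shape[1], shape[2]), 0) + gp$background
    new("SimulatedGpImage", blue = blue, red = red,
        backgrounds = c(blue = gp$background, red = gp$background),
        truth = list(mask = mask, fraction = mean(mask),
                     gpHigh = gp$gp_high, gpLow = gp$gp_low,
                     preset = params@name, seed = seed))
  })
}

#' Build a per-pixel generalized polarization map
#'
#' Subtracts the channel backgrounds, clips negative corrected intensities
#' to zero, marks pixels whose corrected channel sum is not positive as
#' invalid, and computes GP = (Iblue - Ired) / (Iblue + Ired) elsewhere.
#'
#' @param imgBlue,imgRed channel images (matrices of equal shape).
#' @param bgBlue,bgRed non-negative scalar backgrounds (a.u.).
#' @return a \linkS4class{GPMap}.
#' @examples
#' m <- gpMap(matrix(300, 8, 8), matrix(200, 8, 8), 100, 100)
#' gpValues(m)[1, 1]  # 1/3
#' @export
gpMap <- function(imgBlue, imgRed, bgBlue = 0, bgRed = 0) {
  if (!all(dim(imgBlue) == dim(imgRed)))
    stop("channel image shapes differ")
  if (bgBlue < 0 || bgRed < 0) stop("backgrounds must be non-negative")
  cb <- pmax(imgBlue - bgBlue, 0)
  cr <- pmax(imgRed - bgRed, 0)
  den <- cb + cr
  valid <- den > 0
  gp <- matrix(NA_real_, nrow(imgBlue), ncol(imgBlue))
  gp[valid] <- (cb[valid] - cr[valid]) / den[valid]
  new("GPMap", gp = gp, validMask = valid,
      backgrounds = c(blue = bgBlue, red = bgRed))
}

#' GP map of a simulated Laurdan image
#'
#' Convenience wrapper applying [gpMap()] with the backgrounds recorded in
#' the simulated object.
#'
#' @param sim a \linkS4class{SimulatedGpImage}.
#' @return a \linkS4class{GPMap}.
#' @export
gpMapOf <- function(sim) {
  stopifnot(is(sim, "SimulatedGpImage"))
  gpMap(sim@blue, sim@red, sim@backgrounds["blue"], sim@backgrounds["red"])
}

#' Shared GP threshold from a pooled comparison set
#'
#' Otsu threshold computed on the pooled GP histogram of all maps in a
#' comparison set. Applying this single value to every image honours the
#' shared-threshold contract: images compared against each other must be
#' segmented with the same cutoff.
#'
#' @param maps list of \linkS4class{GPMap} objects.
#' @return a GP threshold (numeric scalar).
#' @export
pooledGpThreshold <- function(maps) {
  if (is(maps, "GPMap")) maps <- list(maps)
  stopifnot(length(maps) > 0,
            all(vapply(maps, is, logical(1), "GPMap")))
  vals <- unlist(lapply(maps, function(m) m@gp[m@validMask]))
  otsuThreshold(vals)
}

#' @describeIn segmentGpDomains segment one GP map. \code{threshold} is a
#'   numeric GP cutoff or \code{"auto"} (Otsu on this map's own valid
#'   pixels; for comparisons across images compute one shared value with
#'   [pooledGpThreshold()]). \code{region} restricts the analysis region
#'   (logical matrix, subset of the valid mask); high = gp >= threshold.
#' @param threshold numeric GP cutoff or \code{"auto"}.
#' @param region logical matrix; defaults to the valid mask.
#' @export
setMethod("segmentGpDomains", "GPMap",
  function(object, threshold = "auto", region = NULL) {
    if (is.null(region)) region <- object@validMask
    if (!all(dim(region) == dim(object@gp)))
      stop("region shape differs from the map")
    region <- region & object@validMask
    if (!any(region)) stop("empty analysis region")
    if (identical(threshold, "auto"))
      threshold <- otsuThreshold(object@gp[region])
    high <- region & !is.na(object@gp) & object@gp >= threshold
    low <- region & !high
    new("DomainMasks", highMask = high, lowMask = low,
        threshold = as.numeric(threshold),
        fractionHigh = sum(high) / sum(region))
  })

#' @describeIn segmentGpDomains segment a list of maps with one shared
#'   threshold (pooled Otsu when \code{threshold = "auto"}); returns a list
#'   of \linkS4class{DomainMasks}.
#' @export
setMethod("segmentGpDomains", "list",
  function(object, threshold = "auto", region = NULL) {
    if (identical(threshold, "auto"))
      threshold <- pooledGpThreshold(object)
    lapply(object, segmentGpDomains, threshold = threshold, region = region)
  })

setMethod("show", "GPMap", function(object) {
  v <- object@gp[object@validMask]
  cat(sprintf("GPMap %dx%d: %.1f%% valid pixels, GP range [%.3f, %.3f]\n",
              nrow(object@gp), ncol(object@gp),
              100 * mean(object@validMask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

setMethod("show", "DomainMasks", function(object) {
  cat(sprintf(
    "DomainMasks: threshold GP = %.3f, high-GP fraction = %.1f%%\n",
    object@threshold, 100 * object@fractionHigh))
})
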