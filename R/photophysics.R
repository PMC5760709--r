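#' Steady-state fluorescence anisotropy (L-format)
#'
#' r = (Ivv - G Ivh) / (Ivv + 2 G Ivh), where Ivv and Ivh are the vertical
#' and horizontal emission components under vertically polarized excitation
#' and G is the instrument-specific correction factor for the different
#' detection sensitivity of the two polarizations. G is always supplied, it
#' is never estimated here. Vectorized over readings.
#'
#' @param Ivv,Ivh non-negative intensities (a.u.).
#' @param G instrument G factor (> 0).
#' @return anisotropy value(s); in [-0.5, 1] for physical inputs.
#' @examples
#' anisotropy(1, 0, 1)    # 1, fully polarized limit
#' anisotropy(1, 1, 1)    # 0, isotropic limit
#' anisotropy(2, 1, 0.5)  # 0.5
#' @export
anisotropy <- function(Ivv, Ivh, G = 1) {
  if (any(G <= 0)) stop("G must be positive")
  if (any(Ivv < 0) || any(Ivh < 0)) stop("intensities must be non-negative")
  den <- Ivv + 2 * G * Ivh
  if (any(den == 0)) stop("zero denominator Ivv + 2 G Ivh")
  (Ivv - G * Ivh) / den
}

#' Laurdan generalized polarization
#'
#' GP = (Iblue - Ired) / (Iblue + Ired), the normalized difference of
#' blue-edge (ordered, dehydrated membrane) and red-edge (disordered,
#' hydrated membrane) Laurdan emission; range [-1, 1]. Elementwise over
#' vectors or matrices. Scalar zero-sum input is an error; in array input,
#' zero-sum pixels are returned as NA (an invalid-pixel mask) so isolated
#' empty pixels do not abort image processing.
#'
#' @param Iblue,Ired non-negative intensities (a.u.), same shape.
#' @return GP value(s), NA where the channel sum is not positive (arrays).
#' @examples
#' generalizedPolarization(1, 1)      # 0
#' generalizedPolarization(1, 0)      # 1
#' generalizedPolarization(200, 100)  # 1/3
#' @export
generalizedPolarization <- function(Iblue, Ired) {
  if (length(Iblue) != length(Ired))
    stop("Iblue and Ired must have the same length")
  if (any(Iblue < 0, na.rm = TRUE) || any(Ired < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  den <- Iblue + Ired
  if (length(den) == 1 && (!is.finite(den) || den <= 0))
    stop("zero channel sum Iblue + Ired")
  gp <- (Iblue - Ired) / den
  gp[!is.finite(den) | den <= 0] <- NA_real_
  gp
}
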