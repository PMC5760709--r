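#' @import methods
#' @importFrom stats coef confint mad median quantile rnorm runif rlnorm sd
#'   vcov qt approx optimize
#' @importFrom graphics hist
NULL

## Central data containers. Images are stored as plain numeric matrices
## (row, column); label images as integer matrices with 0 = background.

#' Named simulation parameter set
#'
#' Holds the per-modality parameters of the synthetic-data generator:
#' FRAP recovery parameters, AFM elasticity and tether statistics, Laurdan
#' generalized-polarization image structure and endocytosis field geometry.
#' Create with [makePreset()].
#'
#' @slot name preset name, e.g. \code{"control"} or \code{"gaucher"}.
#' @slot frap list with \code{a} (extent of bleaching), \code{b} (immobile
#'   fraction), \code{tau} (empirical recovery time constant, s),
#'   \code{noise_sd} (relative intensity noise) and \code{acq_bleach_rate}
#'   (per-frame fractional acquisition bleaching).
#' @slot afm list with lognormal Young's modulus parameters
#'   (\code{E_median}, \code{E_mean}, Pa), tether count moments
#'   (\code{tether_count_mean}, \code{tether_count_sd}), tether force
#'   parameters (\code{tether_force_median} pN, \code{tether_force_sdlog}),
#'   \code{force_noise_sd} (pN), \code{spring_constant} (N/m) and curve
#'   geometry (contact-point range, rupture range, load cap, tip geometry).
#' @slot gp list with \code{high_area_fraction}, \code{gp_high},
#'   \code{gp_low}, \code{domain_length_scale} (px), \code{photon_noise},
#'   \code{total_intensity} and \code{background}.
#' @slot endo list with \code{f_endo}, \code{ligand}, \code{n_cells},
#'   \code{nucleus_radius}, \code{cell_radius}, \code{membrane_thickness}
#'   (all lengths in px).
#' @seealso [makePreset()]
#' @exportClass MemPreset
setClass("MemPreset",
  representation(name = "character", frap = "list", afm = "list",
                 gp = "list", endo = "list"))

setValidity("MemPreset", function(object) {
  msg <- character()
  fr <- object@frap; af <- object@afm; gp <- object@gp; en <- object@endo
  inunit <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!inunit(fr$a)) msg <- c(msg, "frap$a must be a fraction in [0,1]")
  if (!inunit(fr$b)) msg <- c(msg, "frap$b must be a fraction in [0,1]")
  if (!is.numeric(fr$tau) || fr$tau <= 0) msg <- c(msg, "frap$tau must be > 0")
  if (!is.numeric(af$E_median) || af$E_median <= 0)
    msg <- c(msg, "afm$E_median must be > 0")
  if (!is.numeric(af$spring_constant) || af$spring_constant <= 0)
    msg <- c(msg, "afm$spring_constant must be > 0")
  if (!inunit(gp$high_area_fraction))
    msg <- c(msg, "gp$high_area_fraction must be in [0,1]")
  if (any(abs(c(gp$gp_high, gp$gp_low)) >= 1))
    msg <- c(msg, "gp levels must lie strictly inside (-1, 1)")
  if (!inunit(en$f_endo)) msg <- c(msg, "endo$f_endo must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Raw FRAP intensity record
#'
#' Time series of mean intensities of the bleached ROI (\code{I}), the whole
#' membrane mask (\code{T}) and a background ROI (\code{bg}), with the index
#' of the first post-bleach frame. Simulated records carry their generating
#' truth in \code{truth}.
#'
#' @slot t frame times (s).
#' @slot I bleached-ROI mean intensity (a.u.).
#' @slot T whole-membrane mean intensity (a.u.).
#' @slot bg background mean intensity (a.u.).
#' @slot bleachIndex 1-based index of the first post-bleach frame.
#' @slot truth list of ground-truth parameters (simulated data) or empty.
#' @seealso [doubleNormalize()], [simulateFrapRecord()]
#' @exportClass FrapRecord
setClass("FrapRecord",
  representation(t = "numeric", I = "numeric", T = "numeric",
                 bg = "numeric", bleachIndex = "integer", truth = "list"))

setValidity("FrapRecord", function(object) {
  n <- length(object@t)
  if (length(object@I) != n || length(object@T) != n || length(object@bg) != n)
    return("t, I, T and bg must have equal lengths")
  if (object@bleachIndex < 2L || object@bleachIndex > n)
    return("bleachIndex must lie inside the record and leave >= 1 pre-bleach frame")
  if (any(object@I < 0) || any(object@T < 0))
    return("intensities must be non-negative")
  TRUE
})

#' Double-normalized FRAP recovery curve
#'
#' @slot t frame times (s), same grid as the parent record(s).
#' @slot R unitless double-normalized recovery.
#' @slot sem pointwise standard error of the mean (NA for single curves).
#' @slot bleachIndex index of the first post-bleach frame.
#' @slot nAveraged number of curves averaged into this one.
#' @seealso [doubleNormalize()], [averageCurves()], [fitRecovery()]
#' @exportClass NormalizedCurve
setClass("NormalizedCurve",
  representation(t = "numeric", R = "numeric", sem = "numeric",
                 bleachIndex = "integer", nAveraged = "integer"))

setValidity("NormalizedCurve", function(object) {
  if (length(object@R) != length(object@t))
    return("t and R must have equal lengths")
  if (any(!is.finite(object@R))) return("R must be finite everywhere")
  TRUE
})

#' Fitted FRAP recovery model
#'
#' Result of fitting R(t) = R(0) - a + a (1 - b) (1 - exp(-t / tau)) to the
#' post-bleach part of a recovery curve: \code{a} is the extent of bleaching,
#' \code{b} the immobile fraction and \code{tau} the empirical recovery time
#' constant. \code{ci95} holds per-parameter 95% confidence bounds from the
#' fit covariance; R(0) is fixed to the pre-bleach mean.
#'
#' @slot estimates named numeric: R0, a, b, tau.
#' @slot ci95 matrix with rows a, b, tau and columns lower, upper.
#' @slot flags character vector of fit warnings (e.g. parameter at bound).
#' @slot fit the underlying \code{nls}-like fit object.
#' @slot nPost number of post-bleach points used.
#' @seealso [fitRecovery()]
#' @exportClass FrapFit
setClass("FrapFit",
  representation(estimates = "numeric", ci95 = "matrix",
                 flags = "character", fit = "ANY", nPost = "integer"))

#' AFM force-vs-separation curve
#'
#' Extension (approach) and retraction segments of a single force curve.
#' Separation is tip-sample distance in nm; force in pN, with adhesive
#' (tether) forces negative on retraction. Simulated curves carry their
#' ground truth (contact point, Young's modulus, tether step positions and
#' heights) in \code{truth}.
#'
#' @slot sepExt,forceExt extension segment (separation decreasing).
#' @slot sepRet,forceRet retraction segment (separation increasing).
#' @slot springConstant cantilever spring constant (N/m).
#' @slot velocity tip velocity (um/s).
#' @slot truth ground-truth list for simulated curves.
#' @seealso [simulateForceCurve()], [findContactPoint()], [fitHertz()],
#'   [detectSteps()]
#' @exportClass ForceCurve
setClass("ForceCurve",
  representation(sepExt = "numeric", forceExt = "numeric",
                 sepRet = "numeric", forceRet = "numeric",
                 springConstant = "numeric", velocity = "numeric",
                 truth = "list"))

setValidity("ForceCurve", function(object) {
  if (length(object@sepExt) != length(object@forceExt))
    return("extension separation/force length mismatch")
  if (length(object@sepRet) != length(object@forceRet))
    return("retraction separation/force length mismatch")
  if (length(object@sepExt) > 1 && any(diff(object@sepExt) > 0))
    return("extension separation must be monotone decreasing")
  if (length(object@sepRet) > 1 && any(diff(object@sepRet) < 0))
    return("retraction separation must be monotone increasing")
  if (any(!is.finite(c(object@forceExt, object@forceRet))))
    return("forces must be finite")
  TRUE
})

#' Detected tether rupture steps
#'
#' Step-like force changes on a retraction segment found by the iterative
#' step-fitting detector (algorithm A), the smoothed-derivative detector
#' (algorithm B), and their consensus. Heights are magnitudes in pN.
#'
#' @slot positions step positions (nm), ascending.
#' @slot heights step heights (pN, magnitudes), parallel to positions.
#' @slot detector which set this object reports: "algA", "algB" or
#'   "consensus".
#' @slot algA,algB full per-detector event lists (positions, heights).
#' @seealso [detectSteps()], [tetherStatistics()]
#' @exportClass StepEvents
setClass("StepEvents",
  representation(positions = "numeric", heights = "numeric",
                 detector = "character", algA = "list", algB = "list"))

setValidity("StepEvents", function(object) {
  if (length(object@positions) != length(object@heights))
    return("positions and heights must have equal lengths")
  if (is.unsorted(object@positions)) return("positions must be ascending")
  TRUE
})

#' Hertzian contact fit of an extension curve
#'
#' Young's modulus from a least-squares fit of the four-sided pyramidal-tip
#' Hertz model F = E / (1 - nu^2) * tan(alpha) / sqrt(2) * delta^2 over the
#' indentation range from the contact point to the load cap.
#'
#' @slot E Young's modulus (Pa).
#' @slot contactPoint detected contact point (nm separation).
#' @slot nu Poisson ratio used.
#' @slot halfAngle pyramid face half-angle (degrees).
#' @slot fitRange separation interval used for the fit (nm).
#' @slot residual root-mean-square force residual (pN).
#' @slot flags character fit warnings ("E clamped to 0", ...).
#' @seealso [fitHertz()]
#' @exportClass HertzFit
setClass("HertzFit",
  representation(E = "numeric", contactPoint = "numeric", nu = "numeric",
                 halfAngle = "numeric", fitRange = "numeric",
                 residual = "numeric", flags = "character"))

#' Height-binned Young's modulus profile
#'
#' @slot binEdges bin edges (nm), length \code{nBins + 1}.
#' @slot meanE per-bin mean Young's modulus (Pa), NA for empty bins.
#' @slot counts per-bin curve counts.
#' @seealso [modulusHeightProfile()]
#' @exportClass ModulusProfile
setClass("ModulusProfile",
  representation(binEdges = "numeric", meanE = "numeric",
                 counts = "integer"))

#' Per-pixel generalized polarization map
#'
#' GP computed pixelwise from background-corrected blue and red channel
#' images; pixels whose corrected channel sum is not positive are invalid.
#'
#' @slot gp GP image (matrix, NA where invalid), values in [-1, 1].
#' @slot validMask logical matrix of valid pixels.
#' @slot backgrounds numeric: background subtracted from blue and red.
#' @seealso [gpMap()], [segmentGpDomains()]
#' @exportClass GPMap
setClass("GPMap",
  representation(gp = "matrix", validMask = "matrix",
                 backgrounds = "numeric"))

setValidity("GPMap", function(object) {
  if (!all(dim(object@gp) == dim(object@validMask)))
    return("gp and validMask dimensions differ")
  v <- object@gp[object@validMask]
  if (any(!is.finite(v))) return("gp must be finite on valid pixels")
  if (length(v) && max(abs(v)) > 1 + 1e-12)
    return("|gp| must be <= 1 on valid pixels")
  TRUE
})

#' High/low generalized-polarization domain masks
#'
#' Binary segmentation of a GP map into an ordered (high-GP, raft-like)
#' phase and a disordered (low-GP) phase at a shared threshold.
#'
#' @slot highMask,lowMask disjoint logical matrices covering the analysis
#'   region.
#' @slot threshold GP threshold used.
#' @slot fractionHigh high-GP area / (high + low area).
#' @seealso [segmentGpDomains()], [pooledGpThreshold()]
#' @exportClass DomainMasks
setClass("DomainMasks",
  representation(highMask = "matrix", lowMask = "matrix",
                 threshold = "numeric", fractionHigh = "numeric"))

setValidity("DomainMasks", function(object) {
  if (any(object@highMask & object@lowMask))
    return("high and low masks must be disjoint")
  nh <- sum(object@highMask); nl <- sum(object@lowMask)
  if (nh + nl > 0 &&
      abs(object@fractionHigh - nh / (nh + nl)) > 1e-12)
    return("fractionHigh inconsistent with masks")
  TRUE
})

#' Cell segmentation into nuclei, membrane rings and interiors
#'
#' Label images produced by nucleus detection plus seeded-watershed cell
#' segmentation; each cell's boundary is thickened inward to form the
#' membrane mask, the remainder of the cell being the intracellular mask.
#'
#' @slot nucleusLabels integer label image of nuclei.
#' @slot cellLabels integer label image of whole cells.
#' @slot membraneLabels integer label image of per-cell membrane rings.
#' @slot intracellularLabels integer label image of per-cell interiors.
#' @slot cellIds integer vector of cell labels present.
#' @slot edgeCells integer vector of labels touching the image border.
#' @seealso [detectNuclei()], [segmentCells()], [endocytosedFraction()],
#'   [nuclearFraction()]
#' @exportClass CellSegmentation
setClass("CellSegmentation",
  representation(nucleusLabels = "matrix", cellLabels = "matrix",
                 membraneLabels = "matrix", intracellularLabels = "matrix",
                 cellIds = "integer", edgeCells = "integer"))

setValidity("CellSegmentation", function(object) {
  if (any(object@membraneLabels > 0 & object@intracellularLabels > 0))
    return("membrane and intracellular masks must be disjoint")
  TRUE
})

#' Simulated two-channel Laurdan image
#'
#' @slot blue,red channel images (a.u.).
#' @slot backgrounds additive background of each channel (blue, red).
#' @slot truth list: domain mask, true high-GP fraction, gp levels.
#' @seealso [simulateGpImage()]
#' @exportClass SimulatedGpImage
setClass("SimulatedGpImage",
  representation(blue = "matrix", red = "matrix", backgrounds = "numeric",
                 truth = "list"))

#' Simulated three-channel cell field
#'
#' @slot dapi,membrane,ligand channel images (a.u.).
#' @slot truth list: per-cell centers and intracellular fractions, nucleus /
#'   membrane / interior label images, channel backgrounds.
#' @seealso [simulateCellField()]
#' @exportClass SimulatedCellField
setClass("SimulatedCellField",
  representation(dapi = "matrix", membrane = "matrix", ligand = "matrix",
                 truth = "list"))
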