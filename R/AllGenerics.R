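#' Ground truth of a simulated object
#'
#' Every simulator emits the parameters and masks its record was built from;
#' this accessor returns them as a list.
#'
#' @param object a simulated object (\linkS4class{FrapRecord},
#'   \linkS4class{ForceCurve}, \linkS4class{SimulatedGpImage},
#'   \linkS4class{SimulatedCellField}).
#' @return a list of ground-truth values.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

setMethod("groundTruth", "FrapRecord", function(object) object@truth)
setMethod("groundTruth", "ForceCurve", function(object) object@truth)
setMethod("groundTruth", "SimulatedGpImage", function(object) object@truth)
setMethod("groundTruth", "SimulatedCellField", function(object) object@truth)

#' Segment high- and low-GP domains
#'
#' @param object a \linkS4class{GPMap}, or a list of GP maps segmented with
#'   one shared pooled threshold.
#' @param ... passed to methods; see [segmentGpDomains,GPMap-method].
#' @export
setGeneric("segmentGpDomains",
           function(object, ...) standardGeneric("segmentGpDomains"))

#' Number of detected steps
#' @param object a \linkS4class{StepEvents} object.
#' @return integer count of steps in the reported detector set.
#' @export
setGeneric("nSteps", function(object) standardGeneric("nSteps"))
setMethod("nSteps", "StepEvents", function(object) length(object@positions))

#' Step positions (nm)
#' @param object a \linkS4class{StepEvents} object.
#' @export
setGeneric("stepPositions", function(object) standardGeneric("stepPositions"))
setMethod("stepPositions", "StepEvents", function(object) object@positions)

#' Step heights (pN, magnitudes)
#' @param object a \linkS4class{StepEvents} object.
#' @export
setGeneric("stepHeights", function(object) standardGeneric("stepHeights"))
setMethod("stepHeights", "StepEvents", function(object) object@heights)

#' Young's modulus of a Hertz fit (Pa)
#' @param object a \linkS4class{HertzFit} object.
#' @export
setGeneric("youngsModulus", function(object) standardGeneric("youngsModulus"))
setMethod("youngsModulus", "HertzFit", function(object) object@E)

#' Fitted or detected contact point (nm)
#' @param object a \linkS4class{HertzFit} object.
#' @export
setGeneric("contactPoint", function(object) standardGeneric("contactPoint"))
setMethod("contactPoint", "HertzFit", function(object) object@contactPoint)

#' High-GP area fraction of a domain segmentation
#' @param object a \linkS4class{DomainMasks} object.
#' @export
setGeneric("fractionHigh", function(object) standardGeneric("fractionHigh"))
setMethod("fractionHigh", "DomainMasks", function(object) object@fractionHigh)

#' GP values of a map
#' @param object a \linkS4class{GPMap} object.
#' @return numeric matrix of GP values (NA where invalid).
#' @export
setGeneric("gpValues", function(object) standardGeneric("gpValues"))
setMethod("gpValues", "GPMap", function(object) object@gp)

#' Recovery values of a normalized FRAP curve
#' @param object a \linkS4class{NormalizedCurve} object.
#' @export
setGeneric("recovery", function(object) standardGeneric("recovery"))
setMethod("recovery", "NormalizedCurve", function(object) object@R)

#' Frame times of a normalized FRAP curve
#' @param object a \linkS4class{NormalizedCurve} object.
#' @export
setGeneric("curveTimes", function(object) standardGeneric("curveTimes"))
setMethod("curveTimes", "NormalizedCurve", function(object) object@t)

#' @describeIn FrapFit point estimates (R0, a, b, tau).
#' @param object a \linkS4class{FrapFit} object.
#' @export
setMethod("coef", "FrapFit", function(object) object@estimates)

#' @describeIn FrapFit 95% confidence bounds for a, b and tau.
#' @param parm,level ignored; bounds are the stored 95% intervals.
#' @export
setMethod("confint", "FrapFit",
          function(object, parm, level = 0.95) object@ci95)
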