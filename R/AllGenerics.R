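#' Compute the fibular-head/tibia overlap ratio
#'
#' @param x a \code{\link{KeypointSet}} with visible keypoints A-E.
#' @param ... further arguments passed to methods.
#' @return numeric scalar in [0, 1] with attribute \code{clamped}.
#' @seealso \code{\link{computeQC}}
#' @export
setGeneric("overlapRatio", function(x, ...) standardGeneric("overlapRatio"))

#' Compute the lateral knee flexion angle
#'
#' @param x a \code{\link{KeypointSet}} with visible keypoints F-I.
#' @param ... further arguments passed to methods.
#' @return angle in degrees in [0, 180]; 180 for a fully extended limb.
#' @seealso \code{\link{computeQC}}
#' @export
setGeneric("flexionAngle", function(x, ...) standardGeneric("flexionAngle"))

#' Compute all positioning QC criteria for one radiograph
#'
#' @param x a complete \code{\link{KeypointSet}} (A-E visible for AP,
#'   A-I for LAT) or a \code{\link{DecodedKeypoints}} object.
#' @param ... further arguments passed to methods.
#' @return a \code{\link{QCResult}}.
#' @export
setGeneric("computeQC", function(x, ...) standardGeneric("computeQC"))

#' Decode a heatmap stack to keypoints
#'
#' @param x a \code{\link{HeatmapStack}}.
#' @param ... further arguments passed to methods (see the
#'   \code{HeatmapStack} method).
#' @return a \code{\link{DecodedKeypoints}}.
#' @export
setGeneric("decodeHeatmaps", function(x, ...)
    standardGeneric("decodeHeatmaps"))

#' Classify the radiographic projection from detected keypoints
#'
#' The projection is identified from the detected-keypoint count: a
#' radiograph is called LAT when at least 3 of the 4 LAT-only landmarks
#' (F, G, H, I) are detected, and AP otherwise.
#'
#' @param x a \code{\link{DecodedKeypoints}} or \code{\link{KeypointSet}}.
#' @return \code{"AP"} or \code{"LAT"}.
#' @export
setGeneric("classifyView", function(x) standardGeneric("classifyView"))

#' Predict keypoint heatmaps for an image
#'
#' @param model a \code{\link{KneeNet}}.
#' @param image numeric grayscale matrix with values in [0, 1].
#' @param ... further arguments passed to methods.
#' @return a \code{\link{HeatmapStack}} with the model's output stride.
#' @export
setGeneric("predictHeatmaps", function(model, image, ...)
    standardGeneric("predictHeatmaps"))

## ---- accessors ------------------------------------------------------------

#' @describeIn KeypointSet-accessors coordinates (9 x 2 matrix, x/y columns)
#' @export
setGeneric("kpCoords", function(x) standardGeneric("kpCoords"))

#' @describeIn KeypointSet-accessors named logical visibility vector
#' @export
setGeneric("kpVisible", function(x) standardGeneric("kpVisible"))

#' @describeIn KeypointSet-accessors the projection view ("AP"/"LAT")
#' @export
setGeneric("kpView", function(x) standardGeneric("kpView"))

#' @describeIn KeypointSet-accessors the image identifier
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' Accessors for KeypointSet and related classes
#'
#' @param x the object.
#' @name KeypointSet-accessors
NULL

setMethod("kpCoords", "KeypointSet", function(x) x@coords)
setMethod("kpVisible", "KeypointSet", function(x) x@visible)
setMethod("kpView", "KeypointSet", function(x) x@view)
setMethod("imageId", "KeypointSet", function(x) x@imageId)
setMethod("kpCoords", "DecodedKeypoints", function(x) x@keypoints@coords)
setMethod("kpVisible", "DecodedKeypoints", function(x) x@keypoints@visible)
setMethod("kpView", "DecodedKeypoints", function(x) x@viewCall)

#' @describeIn HeatmapStack-accessors the h x w x 9 heatmap array
#' @export
setGeneric("heatmapArray", function(x) standardGeneric("heatmapArray"))

#' @describeIn HeatmapStack-accessors input pixels per heatmap pixel
#' @export
setGeneric("stride", function(x) standardGeneric("stride"))

#' Accessors for HeatmapStack
#'
#' @param x a \code{\link{HeatmapStack}}.
#' @name HeatmapStack-accessors
NULL

setMethod("heatmapArray", "HeatmapStack", function(x) x@maps)
setMethod("stride", "HeatmapStack", function(x) x@stride)

#' @describeIn SyntheticCase-accessors the rendered image matrix
#' @export
setGeneric("caseImage", function(x) standardGeneric("caseImage"))

#' @describeIn SyntheticCase-accessors the ground-truth KeypointSet
#' @export
setGeneric("caseKeypoints", function(x) standardGeneric("caseKeypoints"))

#' @describeIn SyntheticCase-accessors the generative QCResult
#' @export
setGeneric("caseTruth", function(x) standardGeneric("caseTruth"))

#' @describeIn SyntheticCase-accessors the generating PhantomSpec
#' @export
setGeneric("caseSpec", function(x) standardGeneric("caseSpec"))

#' Accessors for SyntheticCase
#'
#' @param x a \code{\link{SyntheticCase}}.
#' @name SyntheticCase-accessors
NULL

setMethod("caseImage", "SyntheticCase", function(x) x@image)
setMethod("caseKeypoints", "SyntheticCase", function(x) x@keypoints)
setMethod("caseTruth", "SyntheticCase", function(x) x@truth)
setMethod("caseSpec", "SyntheticCase", function(x) x@spec)

#' @describeIn QCResult-accessors the overlap ratio
#' @export
setGeneric("qcOverlap", function(x) standardGeneric("qcOverlap"))

#' @describeIn QCResult-accessors the flexion angle in degrees (NA for AP)
#' @export
setGeneric("qcFlexion", function(x) standardGeneric("qcFlexion"))

#' Accessors for QCResult
#'
#' @param x a \code{\link{QCResult}}.
#' @name QCResult-accessors
NULL

setMethod("qcOverlap", "QCResult", function(x) x@overlapRatio)
setMethod("qcFlexion", "QCResult", function(x) x@flexionAngleDeg)

#' @describeIn KneeNet-accessors per-epoch training log
#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))

#' @describeIn KneeNet-accessors the network configuration list
#' @export
setGeneric("netConfig", function(x) standardGeneric("netConfig"))

#' Accessors for KneeNet
#'
#' @param x a \code{\link{KneeNet}}.
#' @name KneeNet-accessors
NULL

setMethod("trainLog", "KneeNet", function(x) x@trainLog)
setMethod("netConfig", "KneeNet", function(x) x@config)

#' @describeIn DecodedKeypoints-accessors per-label peak scores
#' @export
setGeneric("kpScores", function(x) standardGeneric("kpScores"))

#' Accessors for DecodedKeypoints
#'
#' @param x a \code{\link{DecodedKeypoints}}.
#' @name DecodedKeypoints-accessors
NULL

setMethod("kpScores", "DecodedKeypoints", function(x) x@scores)
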