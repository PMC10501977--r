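#' @import methods
NULL

#' Canonical key-point labels
#'
#' The nine anatomical landmarks used for knee-radiograph positioning QC, in
#' their fixed channel order: A/B on the fibular diaphysis axis, C/D at the
#' transverse extremes of the fibular head (closest to / furthest from the
#' tibia), E where the tibia edge crosses the fibular head outline, F/G on the
#' femoral diaphysis axis and H/I on the tibial diaphysis axis.  AP
#' radiographs use A-E only; LAT radiographs use all nine.
#'
#' @format A character vector of length 9.
#' @export
KP_LABELS <- c("A", "B", "C", "D", "E", "F", "G", "H", "I")

.AP_LABELS  <- c("A", "B", "C", "D", "E")
.LAT_ONLY   <- c("F", "G", "H", "I")

#' KeypointSet: labeled 2-D landmarks on one radiograph
#'
#' Holds the nine labeled landmarks (A-I) for a single AP or LAT knee
#' radiograph.  Coordinates are 0-based pixel centers with \code{x} the image
#' column and \code{y} the image row.  Landmarks that are absent (e.g. F-I on
#' an AP radiograph) or not trusted are marked invisible; their coordinates
#' are not used by any computation.
#'
#' Structural validity requires the full 9 x 2 coordinate matrix, finite
#' coordinates wherever a point is visible, and no visible F-I landmarks on an
#' AP set.  Completeness of the view (all A-E visible for AP, all A-I for LAT)
#' is a precondition of \code{\link{computeQC}}, not of the class, so that
#' partially decoded detections remain representable.
#'
#' @slot view \code{"AP"} or \code{"LAT"}.
#' @slot coords numeric 9 x 2 matrix, rows named A-I, columns \code{x},
#'   \code{y}; \code{NA} allowed for invisible points.
#' @slot visible named logical vector of length 9.
#' @slot imageId character scalar identifier.
#' @export
setClass("KeypointSet",
    representation(view = "character", coords = "matrix",
                   visible = "logical", imageId = "character"))

setValidity("KeypointSet", function(object) {
    msg <- character()
    if (length(object@view) != 1L || !object@view %in% c("AP", "LAT"))
        msg <- c(msg, "view must be \"AP\" or \"LAT\"")
    if (!is.numeric(object@coords) || !identical(dim(object@coords), c(9L, 2L)))
        msg <- c(msg, "coords must be a numeric 9 x 2 matrix")
    else if (!identical(rownames(object@coords), KP_LABELS))
        msg <- c(msg, "coords rows must be named A-I in order")
    if (length(object@visible) != 9L || anyNA(object@visible))
        msg <- c(msg, "visible must be a logical vector of length 9 without NA")
    if (!length(msg)) {
        vis <- object@visible
        if (any(!is.finite(object@coords[vis, , drop = FALSE])))
            msg <- c(msg, "visible keypoints must have finite coordinates")
        if (object@view == "AP" && any(vis[.LAT_ONLY]))
            msg <- c(msg, "AP sets cannot have visible F-I keypoints")
    }
    if (length(msg)) msg else TRUE
})

#' QCResult: the three positioning quality-control criteria
#'
#' @slot view \code{"AP"} or \code{"LAT"}.
#' @slot overlapRatio fibular-head/tibia overlap ratio in [0, 1].
#' @slot flexionAngleDeg knee flexion angle in degrees in [0, 180]
#'   (\code{NA} for AP, where the angle is undefined).
#' @slot normalizedFlexion flexion angle divided by 180 (\code{NA} for AP).
#' @slot clamped logical; \code{TRUE} when the raw overlap ratio fell outside
#'   [0, 1] and was clamped.
#' @export
setClass("QCResult",
    representation(view = "character", overlapRatio = "numeric",
                   flexionAngleDeg = "numeric", normalizedFlexion = "numeric",
                   clamped = "logical"))

setValidity("QCResult", function(object) {
    msg <- character()
    if (!object@view %in% c("AP", "LAT"))
        msg <- c(msg, "view must be \"AP\" or \"LAT\"")
    r <- object@overlapRatio
    if (length(r) != 1L || !is.finite(r) || r < -1e-9 || r > 1 + 1e-9)
        msg <- c(msg, "overlapRatio must be a scalar in [0, 1]")
    a <- object@flexionAngleDeg
    if (length(a) != 1L)
        msg <- c(msg, "flexionAngleDeg must be a scalar (NA for AP)")
    else if (object@view == "AP" && !is.na(a))
        msg <- c(msg, "AP results carry no flexion angle")
    else if (object@view == "LAT" && (!is.finite(a) || a < 0 || a > 180))
        msg <- c(msg, "LAT flexion angle must lie in [0, 180] degrees")
    if (length(msg)) msg else TRUE
})

#' HeatmapStack: 9-channel keypoint probability maps
#'
#' One channel per landmark in the fixed order A-I, at a stated stride
#' relative to the input image (input pixels per heatmap pixel).  Encoded
#' targets lie in [0, 1]; network predictions may slightly overshoot but must
#' be finite.
#'
#' @slot maps numeric array h x w x 9.
#' @slot stride integer scalar >= 1.
#' @export
setClass("HeatmapStack",
    representation(maps = "array", stride = "integer"))

setValidity("HeatmapStack", function(object) {
    msg <- character()
    d <- dim(object@maps)
    if (length(d) != 3L || d[3] != 9L)
        msg <- c(msg, "maps must be an h x w x 9 array")
    else if (!all(is.finite(object@maps)))
        msg <- c(msg, "heatmap values must be finite")
    if (length(object@stride) != 1L || is.na(object@stride) ||
        object@stride < 1L)
        msg <- c(msg, "stride must be an integer >= 1")
    if (length(msg)) msg else TRUE
})

#' DecodedKeypoints: keypoints decoded from a heatmap stack
#'
#' @slot keypoints a \code{\link{KeypointSet}} with positions in input-image
#'   pixels; visibility reflects the detection threshold.
#' @slot scores named numeric vector of per-label peak activations in [0, 1].
#' @slot viewCall \code{"AP"} or \code{"LAT"}, from the detected-keypoint
#'   count rule (see \code{\link{classifyView}}).
#' @slot tau the detection threshold used.
#' @export
setClass("DecodedKeypoints",
    representation(keypoints = "KeypointSet", scores = "numeric",
                   viewCall = "character", tau = "numeric"))

setValidity("DecodedKeypoints", function(object) {
    msg <- character()
    if (length(object@scores) != 9L ||
        !identical(names(object@scores), KP_LABELS))
        msg <- c(msg, "scores must be a length-9 vector named A-I")
    else if (any(object@scores < 0 | object@scores > 1))
        msg <- c(msg, "scores must lie in [0, 1]")
    if (!object@viewCall %in% c("AP", "LAT"))
        msg <- c(msg, "viewCall must be \"AP\" or \"LAT\"")
    if (length(msg)) msg else TRUE
})

#' PhantomSpec: parameters of one synthetic knee phantom
#'
#' Describes a stylized AP or LAT knee phantom: bone shafts rendered as
#' bright capsules, a fibula with an elliptical head partially overlapped by
#' the tibia edge at a controllable true overlap ratio, and (for LAT) femoral
#' and tibial shafts meeting at a controllable flexion angle.  Corruption
#' parameters (noise, blur, occlusion band) are applied after landmark
#' placement and never move the ground truth.
#'
#' @slot view \code{"AP"} or \code{"LAT"}.
#' @slot imageSize integer (rows, cols) in pixels.
#' @slot trueOverlap generative overlap ratio in [0, 1].
#' @slot trueFlexion generative flexion angle in degrees (LAT; \code{NA} for
#'   AP), intended range [90, 180].
#' @slot fibulaHeadRadius transverse semi-axis of the fibular head, pixels.
#' @slot shaftWidth full width of the fibular shaft, pixels.
#' @slot noiseSd additive Gaussian noise standard deviation, intensity units.
#' @slot blurSigma Gaussian blur sigma in pixels (0 = none).
#' @slot occlusion empty list, or \code{list(pos=, width=, opacity=)} for a
#'   horizontal occlusion band (rows, pixels, [0,1]).
#' @slot seed integer random seed for the per-case stream.
#' @export
setClass("PhantomSpec",
    representation(view = "character", imageSize = "integer",
                   trueOverlap = "numeric", trueFlexion = "numeric",
                   fibulaHeadRadius = "numeric", shaftWidth = "numeric",
                   noiseSd = "numeric", blurSigma = "numeric",
                   occlusion = "list", seed = "integer"))

setValidity("PhantomSpec", function(object) {
    msg <- character()
    if (!object@view %in% c("AP", "LAT"))
        msg <- c(msg, "view must be \"AP\" or \"LAT\"")
    if (length(object@imageSize) != 2L || any(object@imageSize < 32L))
        msg <- c(msg, "imageSize must be two integers >= 32")
    r <- object@trueOverlap
    if (!is.finite(r) || r < 0 || r > 1)
        msg <- c(msg, "trueOverlap must lie in [0, 1]")
    if (object@view == "LAT" &&
        (!is.finite(object@trueFlexion) || object@trueFlexion <= 0 ||
         object@trueFlexion > 180))
        msg <- c(msg, "LAT trueFlexion must lie in (0, 180] degrees")
    if (object@fibulaHeadRadius < 2)
        msg <- c(msg, "fibulaHeadRadius must be at least 2 pixels")
    if (object@shaftWidth < 1)
        msg <- c(msg, "shaftWidth must be at least 1 pixel")
    if (object@noiseSd < 0 || object@blurSigma < 0)
        msg <- c(msg, "noiseSd and blurSigma must be nonnegative")
    if (length(object@occlusion) &&
        !all(c("pos", "width", "opacity") %in% names(object@occlusion)))
        msg <- c(msg, "occlusion must be empty or give pos, width, opacity")
    if (length(msg)) msg else TRUE
})

#' SyntheticCase: a rendered phantom with exact ground truth
#'
#' @slot image numeric matrix (rows x cols), intensities in [0, 1], bone
#'   bright on dark background.
#' @slot keypoints ground-truth \code{\link{KeypointSet}} (exact, sub-pixel).
#' @slot truth the generative \code{\link{QCResult}}; by construction
#'   \code{computeQC(keypoints)} reproduces it to numerical precision.
#' @slot spec the generating \code{\link{PhantomSpec}}.
#' @export
setClass("SyntheticCase",
    representation(image = "matrix", keypoints = "KeypointSet",
                   truth = "QCResult", spec = "PhantomSpec"))

setValidity("SyntheticCase", function(object) {
    msg <- character()
    if (!is.numeric(object@image) ||
        min(object@image) < 0 || max(object@image) > 1)
        msg <- c(msg, "image must be numeric with values in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' KneeNet: a multiresolution heatmap-regression keypoint detector
#'
#' A high-resolution multibranch convolutional network that regresses the
#' nine landmark heatmaps from a grayscale radiograph.  The network keeps a
#' high-resolution branch throughout while adding parallel lower-resolution
#' branches stage by stage, with repeated cross-resolution exchange (fusion)
#' blocks; the head fuses all branches at 1/4 input resolution into a
#' 9-channel output.  See \code{\link{networkConfig}},
#' \code{\link{buildNetwork}}, \code{\link{trainDetector}} and
#' \code{\link{predictHeatmaps}}.
#'
#' @slot config the network configuration list (see
#'   \code{\link{networkConfig}}).
#' @slot nodes internal computation-graph node list holding the weights.
#' @slot trainLog data.frame with one row per completed training epoch
#'   (columns \code{epoch}, \code{loss}, \code{lr}).
#' @export
setClass("KneeNet",
    representation(config = "list", nodes = "list", trainLog = "data.frame"))

## ---- show methods ---------------------------------------------------------

setMethod("show", "KeypointSet", function(object) {
    vis <- names(which(object@visible))
    cat(sprintf("KeypointSet (%s) image '%s': %d visible [%s]\n",
                object@view, object@imageId, length(vis),
                paste(vis, collapse = "")))
})

setMethod("show", "QCResult", function(object) {
    if (object@view == "AP")
        cat(sprintf("QCResult (AP): overlap ratio %.4f%s\n",
                    object@overlapRatio,
                    if (object@clamped) " [clamped]" else ""))
    else
        cat(sprintf(
            "QCResult (LAT): overlap ratio %.4f, flexion %.2f deg (norm %.4f)%s\n",
            object@overlapRatio, object@flexionAngleDeg,
            object@normalizedFlexion,
            if (object@clamped) " [clamped]" else ""))
})

setMethod("show", "HeatmapStack", function(object) {
    d <- dim(object@maps)
    cat(sprintf("HeatmapStack: %d x %d x 9, stride %d, range [%.3g, %.3g]\n",
                d[1], d[2], object@stride, min(object@maps),
                max(object@maps)))
})

setMethod("show", "DecodedKeypoints", function(object) {
    cat(sprintf("DecodedKeypoints: view call %s, %d/9 above tau=%.2f\n",
                object@viewCall, sum(object@keypoints@visible), object@tau))
})

setMethod("show", "PhantomSpec", function(object) {
    cat(sprintf(
        "PhantomSpec (%s) %dx%d: overlap %.3f%s, noise %.3f, seed %d\n",
        object@view, object@imageSize[1], object@imageSize[2],
        object@trueOverlap,
        if (object@view == "LAT")
            sprintf(", flexion %.1f deg", object@trueFlexion) else "",
        object@noiseSd, object@seed))
})

setMethod("show", "SyntheticCase", function(object) {
    cat("SyntheticCase:\n  ")
    show(object@spec)
    cat("  ")
    show(object@truth)
})

setMethod("show", "KneeNet", function(object) {
    np <- sum(vapply(object@nodes, function(n)
        length(n$W) + length(n$b), numeric(1)))
    cat(sprintf(
        "KneeNet: C=%d, exchanges (%s), %d parameters, %d epochs trained\n",
        object@config$baseChannels,
        paste(object@config$stageExchange, collapse = ","),
        as.integer(np), nrow(object@trainLog)))
})
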