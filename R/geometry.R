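## Planar geometry turning labeled key points into the three QC criteria.
## Coordinates are 0-based pixel centers, x = image column, y = image row.

.COINCIDENT_TOL <- 1e-9  # pixels; far below annotation precision

#' Construct a KeypointSet
#'
#' @param coords numeric matrix with columns \code{x}, \code{y} and row names
#'   drawn from A-I (missing labels are filled as invisible), or a full
#'   9 x 2 matrix in label order.
#' @param view \code{"AP"} or \code{"LAT"}.
#' @param visible logical vector (recycled/named like \code{coords} rows);
#'   defaults to visibility of every supplied row with finite coordinates.
#' @param imageId character identifier.
#' @return a \code{\link{KeypointSet}}.
#' @examples
#' kps <- keypointSet(rbind(A = c(0, 0), B = c(0, 100), C = c(10, 50),
#'                          D = c(-6, 50), E = c(2, 50)), view = "AP")
#' overlapRatio(kps)
#' @export
keypointSet <- function(coords, view = c("AP", "LAT"), visible = NULL,
                        imageId = "image") {
    view <- match.arg(view)
    full <- matrix(NA_real_, 9L, 2L, dimnames = list(KP_LABELS, c("x", "y")))
    coords <- as.matrix(coords)
    if (is.null(rownames(coords))) {
        stopifnot(nrow(coords) == 9L)
        rownames(coords) <- KP_LABELS
    }
    bad <- setdiff(rownames(coords), KP_LABELS)
    if (length(bad))
        stop("unknown keypoint label(s): ", paste(bad, collapse = ", "))
    full[rownames(coords), ] <- coords
    if (is.null(visible)) {
        vis <- stats::setNames(rowSums(is.finite(full)) == 2L, KP_LABELS)
    } else {
        vis <- stats::setNames(rep(FALSE, 9L), KP_LABELS)
        if (!is.null(names(visible))) vis[names(visible)] <- visible
        else vis[rownames(coords)] <- visible
    }
    methods::new("KeypointSet", view = view, coords = full,
                 visible = vis, imageId = as.character(imageId))
}

#' Fit the line through two points
#'
#' Returns the auxiliary line through \code{p} and \code{q} (e.g. L1 through
#' A and B for the fibular diaphysis axis) as an anchor plus a unit
#' direction vector.
#'
#' @param p,q numeric length-2 points \code{c(x, y)}.
#' @return a list with elements \code{anchor} and \code{direction} (unit
#'   norm), of class \code{"Line2D"}.
#' @examples
#' fitLine(c(1, 1), c(3, 3))$direction  # c(1, 1)/sqrt(2)
#' @export
fitLine <- function(p, q) {
    p <- as.numeric(p); q <- as.numeric(q)
    stopifnot(length(p) == 2L, length(q) == 2L,
              all(is.finite(p)), all(is.finite(q)))
    d <- q - p
    len <- sqrt(sum(d^2))
    if (len <= .COINCIDENT_TOL)
        stop("coincident points: cannot fit a line through points closer ",
             "than ", .COINCIDENT_TOL, " pixels")
    structure(list(anchor = p, direction = d / len), class = "Line2D")
}

#' Signed perpendicular distance from a point to a line
#'
#' The magnitude is the perpendicular Euclidean distance; the sign is
#' positive when \code{p} lies on the same side of the line as
#' \code{reference}.  Used with key point C as the reference so that the
#' transverse distances Sc, Sd, Se share one sign convention, which folds the
#' same-side / opposite-side case split of the overlap-ratio definition into
#' a single formula.
#'
#' @param p numeric length-2 point.
#' @param line a \code{"Line2D"} from \code{\link{fitLine}}.
#' @param reference numeric length-2 point off the line fixing the positive
#'   half-plane.
#' @return signed distance in pixels.
#' @examples
#' L <- fitLine(c(0, 0), c(0, 100))           # the y axis
#' signedDistance(c(10, 50), L, c(1, 0))      # +10
#' signedDistance(c(-6, 50), L, c(1, 0))      # -6
#' @export
signedDistance <- function(p, line, reference) {
    stopifnot(inherits(line, "Line2D"))
    p <- as.numeric(p); reference <- as.numeric(reference)
    n <- c(-line$direction[2], line$direction[1])  # unit normal
    dp <- sum((p - line$anchor) * n)
    dr <- sum((reference - line$anchor) * n)
    if (abs(dr) <= .COINCIDENT_TOL)
        stop("reference point lies on the line; positive side undefined")
    dp * sign(dr)
}

.needVisible <- function(kps, labels) {
    vis <- kps@visible[labels]
    if (!all(vis))
        stop("required keypoint(s) not visible: ",
             paste(labels[!vis], collapse = ", "))
    kps@coords[labels, , drop = FALSE]
}

#' @describeIn overlapRatio overlap ratio from keypoints A-E.
#'
#' With L1 the A-B fibular axis and Sc, Sd, Se the signed transverse
#' distances of C, D, E from L1 (C's side positive), the ratio is
#' \code{(Sc - Se) / (Sc - Sd)}, clamped to [0, 1].  It is 0 when the tibia
#' edge just reaches the fibular-head point nearest the tibia (E = C) and 1
#' at full overlap (E = D).
#' @export
setMethod("overlapRatio", "KeypointSet", function(x, ...) {
    P <- .needVisible(x, c("A", "B", "C", "D", "E"))
    L1 <- fitLine(P["A", ], P["B", ])
    C <- P["C", ]
    Sc <- signedDistance(C, L1, C)
    Sd <- signedDistance(P["D", ], L1, C)
    Se <- signedDistance(P["E", ], L1, C)
    if (abs(Sc - Sd) < .COINCIDENT_TOL)
        stop("degenerate geometry: fibular head has no transverse width ",
             "(|Sc - Sd| < ", .COINCIDENT_TOL, ")")
    raw <- (Sc - Se) / (Sc - Sd)
    r <- min(max(raw, 0), 1)
    attr(r, "clamped") <- (raw < 0 || raw > 1)
    r
})

#' @describeIn flexionAngle flexion angle from keypoints F-I.
#'
#' The angle between the femoral shaft vector F - G (pointing proximally)
#' and the tibial shaft vector I - H (pointing distally): 180 degrees for a
#' fully extended (collinear) limb, smaller when flexed.
#' @export
setMethod("flexionAngle", "KeypointSet", function(x, ...) {
    P <- .needVisible(x, c("F", "G", "H", "I"))
    u <- P["F", ] - P["G", ]
    v <- P["I", ] - P["H", ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu <= .COINCIDENT_TOL || nv <= .COINCIDENT_TOL)
        stop("degenerate line: shaft keypoints coincide")
    ct <- sum(u * v) / (nu * nv)
    acos(min(max(ct, -1), 1)) * 180 / pi
})

#' @describeIn computeQC QC criteria from a labeled KeypointSet.
#' @export
setMethod("computeQC", "KeypointSet", function(x, ...) {
    need <- if (x@view == "AP") .AP_LABELS else KP_LABELS
    if (!all(x@visible[need]))
        stop("invalid ", x@view, " keypoint set: keypoint(s) ",
             paste(need[!x@visible[need]], collapse = ", "), " not visible")
    r <- overlapRatio(x)
    clamped <- isTRUE(attr(r, "clamped"))
    if (clamped)
        message("overlap ratio outside [0, 1]; clamped")
    if (x@view == "AP") {
        methods::new("QCResult", view = "AP", overlapRatio = as.numeric(r),
                     flexionAngleDeg = NA_real_,
                     normalizedFlexion = NA_real_, clamped = clamped)
    } else {
        a <- flexionAngle(x)
        methods::new("QCResult", view = "LAT", overlapRatio = as.numeric(r),
                     flexionAngleDeg = a, normalizedFlexion = a / 180,
                     clamped = clamped)
    }
})

#' @describeIn computeQC QC criteria from decoded detections (uses the
#'   automatic view call).
#' @export
setMethod("computeQC", "DecodedKeypoints", function(x, ...) {
    kps <- x@keypoints
    kps@view <- x@viewCall
    if (kps@view == "AP")  # drop any stray LAT-only detections
        kps@visible[.LAT_ONLY] <- FALSE
    methods::validObject(kps)
    computeQC(kps)
})
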