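## Gaussian heatmap encoding / argmax decoding and view identification.

#' Encode keypoints as Gaussian target heatmaps
#'
#' Each visible keypoint contributes an amplitude-1 isotropic Gaussian
#' (standard deviation \code{sigma}, in heatmap pixels) centered at its
#' strided (possibly fractional) position on a h x w grid; channels of
#' absent or invisible keypoints are identically zero.  On AP radiographs the
#' four LAT-only channels F-I are therefore all-zero regression targets,
#' which is what lets a single network serve both views and lets the view be
#' identified from the detected-keypoint count.
#'
#' @param kps a \code{\link{KeypointSet}}.
#' @param shape integer (h, w) of the heatmap grid.
#' @param stride input pixels per heatmap pixel (>= 1).
#' @param sigma Gaussian standard deviation in heatmap pixels (default 2).
#' @return a \code{\link{HeatmapStack}}.
#' @examples
#' kps <- keypointSet(rbind(A = c(12, 8)), view = "AP")
#' hm <- encodeHeatmaps(kps, shape = c(16, 16), stride = 1)
#' heatmapArray(hm)[9, 13, 1]  # 1 at the keypoint (0-based (12, 8))
#' @export
encodeHeatmaps <- function(kps, shape, stride = 1L, sigma = 2) {
    stopifnot(methods::is(kps, "KeypointSet"), length(shape) == 2L,
              stride >= 1L, sigma > 0)
    h <- as.integer(shape[1]); w <- as.integer(shape[2])
    maps <- array(0, dim = c(h, w, 9L))
    gx <- 0:(w - 1L); gy <- 0:(h - 1L)
    for (i in seq_len(9L)) {
        if (!kps@visible[i]) next
        cx <- kps@coords[i, "x"] / stride
        cy <- kps@coords[i, "y"] / stride
        if (cx < 0 || cx > w - 1L || cy < 0 || cy > h - 1L)
            stop("keypoint ", KP_LABELS[i],
                 " falls outside the heatmap grid after striding")
        maps[, , i] <- exp(-(outer((gy - cy)^2, (gx - cx)^2, "+")) /
                               (2 * sigma^2))
    }
    methods::new("HeatmapStack", maps = maps, stride = as.integer(stride))
}

## argmax with deterministic lexicographic (row, col) tie-break
.argmaxRC <- function(m) {
    mx <- max(m)
    idx <- which(m == mx)
    r <- (idx - 1L) %% nrow(m)         # 0-based row
    c0 <- (idx - 1L) %/% nrow(m)       # 0-based col
    o <- order(r, c0)[1L]
    c(row = r[o], col = c0[o], value = mx)
}

## Sub-pixel peak localization: weighted least-squares fit of a known-sigma
## Gaussian on log-activations over a window around the argmax.  For an
## amplitude-A sigma-s Gaussian, log v + p^2/(2 s^2) is linear in the pixel
## coordinate p with slope mu/s^2, so a per-axis weighted regression (weights
## v^2, which are separable for a true Gaussian) recovers the center exactly,
## including at clipped windows.  Returns c(row, col), 0-based, or NULL when
## the window is degenerate.
.gaussianPeakFit <- function(m, r0, c0, window = 3L, sigma = 2) {
    rs <- max(1L, r0 + 1L - window):min(nrow(m), r0 + 1L + window)
    cs <- max(1L, c0 + 1L - window):min(ncol(m), c0 + 1L + window)
    win <- m[rs, cs, drop = FALSE]
    if (max(win) <= 0) return(NULL)
    win <- pmax(win, 1e-9 * max(win))
    lv <- log(win)
    wt <- win^2
    slope <- function(p, y) {
        pm <- sum(wt * p) / sum(wt)
        ym <- sum(wt * y) / sum(wt)
        den <- sum(wt * (p - pm)^2)
        if (den <= 0) return(NA_real_)
        sum(wt * (p - pm) * (y - ym)) / den
    }
    P <- matrix(rs, length(rs), length(cs))
    Q <- matrix(cs, length(rs), length(cs), byrow = TRUE)
    muR <- slope(P, lv + P^2 / (2 * sigma^2)) * sigma^2
    muC <- slope(Q, lv + Q^2 / (2 * sigma^2)) * sigma^2
    if (!is.finite(muR) || !is.finite(muC) ||
        abs(muR - 1 - r0) > window || abs(muC - 1 - c0) > window)
        return(NULL)
    c(muR - 1, muC - 1)
}

#' @describeIn decodeHeatmaps maximum-activation decoding.
#'
#' Per channel the detected position is the argmax scaled by the stride
#' (ties broken by smallest (row, col) lexicographically) and the score is
#' the peak value; a keypoint is visible iff its score reaches \code{tau}.
#' With \code{refine = TRUE} the argmax is refined to sub-pixel precision by
#' a weighted least-squares Gaussian fit (known \code{sigma}) on
#' log-activations over a window around the peak — exact on encoded Gaussian
#' targets and robust on predicted maps; the default is plain argmax
#' resolution, matching the maximum-activation definition.
#'
#' @param tau detection threshold in [0, 1] (default 0.1).
#' @param refine logical; sub-pixel peak refinement (default \code{FALSE}).
#' @param window half-width (heatmap pixels) of the refinement window.
#' @param sigma assumed Gaussian peak width for refinement (heatmap pixels).
#' @param imageId identifier stored in the resulting KeypointSet.
#' @export
setMethod("decodeHeatmaps", "HeatmapStack",
          function(x, tau = 0.1, refine = FALSE, window = 3L, sigma = 2,
                   imageId = "image", ...) {
    maps <- x@maps
    coords <- matrix(NA_real_, 9L, 2L,
                     dimnames = list(KP_LABELS, c("x", "y")))
    scores <- stats::setNames(numeric(9L), KP_LABELS)
    for (i in seq_len(9L)) {
        m <- maps[, , i]
        p <- .argmaxRC(m)
        rc <- c(p[["row"]], p[["col"]])
        if (refine) {
            fit <- .gaussianPeakFit(m, p[["row"]], p[["col"]],
                                    window = window, sigma = sigma)
            if (!is.null(fit)) rc <- fit
        }
        coords[i, ] <- c(rc[2], rc[1]) * x@stride
        scores[i] <- min(max(p[["value"]], 0), 1)
    }
    vis <- scores >= tau
    kps <- methods::new("KeypointSet", view = "LAT", coords = coords,
                        visible = vis, imageId = as.character(imageId))
    view <- if (sum(vis[.LAT_ONLY]) >= 3L) "LAT" else "AP"
    if (view == "AP") {
        kps@view <- "AP"
        kps@visible[.LAT_ONLY] <- FALSE
    }
    methods::new("DecodedKeypoints", keypoints = kps, scores = scores,
                 viewCall = view, tau = as.numeric(tau))
})

#' @describeIn classifyView from decoded detections.
#' @export
setMethod("classifyView", "DecodedKeypoints", function(x) x@viewCall)

#' @describeIn classifyView from a keypoint set's visibility pattern.
#' @export
setMethod("classifyView", "KeypointSet", function(x)
    if (sum(x@visible[.LAT_ONLY]) >= 3L) "LAT" else "AP")
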