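## Evaluation stack: object keypoint similarity (OKS) with per-label
## tolerance constants, detection AP/AR over OKS thresholds, ICC(2,1)
## agreement analysis, deviation statistics with range normalization, and
## pooled-variance two-sample t tests.

#' OKS configuration
#'
#' Per-label tolerance standard deviations for landmarks A-I; the OKS
#' constant for each label is \code{k_i = 2 * sigma_i}.  The defaults use
#' 0.083 for the diaphyseal landmarks (A, B, F, G, H, I), whose position
#' along the shaft axis is not unique, and 0.029 for the tightly defined
#' fibular-head landmarks (C, D, E).  The object scale s^2 is the area of
#' the smallest axis-aligned bounding box containing all visible
#' ground-truth keypoints.
#'
#' @param sigma numeric length-9 vector of per-label sigmas.
#' @return list with elements \code{sigma} and \code{k}.
#' @export
oksConfig <- function(sigma = c(0.083, 0.083, 0.029, 0.029, 0.029,
                                0.083, 0.083, 0.083, 0.083)) {
    stopifnot(length(sigma) == 9L, all(sigma > 0))
    list(sigma = stats::setNames(sigma, KP_LABELS),
         k = stats::setNames(2 * sigma, KP_LABELS))
}

#' Object keypoint similarity between a prediction and ground truth
#'
#' \code{OKS = sum_i exp(-d_i^2 / (2 s^2 k_i^2)) [v_i > 0] / sum_i [v_i > 0]}
#' where \code{d_i} is the Euclidean distance between the detected and true
#' keypoint, \code{v_i} the ground-truth visibility and \code{s^2} the
#' bounding-box area of the visible ground-truth keypoints.  A visible
#' ground-truth keypoint with no corresponding detection contributes 0
#' (the \code{d_i = Inf} convention).
#'
#' @param pred a \code{\link{KeypointSet}} or \code{\link{DecodedKeypoints}}.
#' @param gt the ground-truth \code{\link{KeypointSet}}.
#' @param cfg an \code{\link{oksConfig}}.
#' @return OKS in [0, 1].
#' @export
oks <- function(pred, gt, cfg = oksConfig()) {
    if (methods::is(pred, "DecodedKeypoints")) pred <- pred@keypoints
    stopifnot(methods::is(pred, "KeypointSet"), methods::is(gt, "KeypointSet"))
    vis <- gt@visible
    if (!any(vis)) stop("ground truth has no visible keypoints")
    P <- gt@coords[vis, , drop = FALSE]
    s2 <- diff(range(P[, "x"])) * diff(range(P[, "y"]))
    if (s2 <= 0)
        stop("degenerate scale: ground-truth bounding box has zero area")
    tot <- 0
    for (i in which(vis)) {
        if (pred@visible[i]) {
            d2 <- sum((pred@coords[i, ] - gt@coords[i, ])^2)
            tot <- tot + exp(-d2 / (2 * s2 * cfg$k[i]^2))
        }                               # else contributes 0
    }
    unname(tot / sum(vis))
}

#' Detection AP/AR metrics over OKS thresholds
#'
#' One ground-truth instance and at most one detection per image.
#' Detections are ranked by confidence; at each OKS threshold a detection
#' is a true positive iff its OKS reaches the threshold.  AP is the area
#' under the 101-point interpolated precision-recall curve; AP50/AP75 are
#' taken at thresholds 0.50/0.75 and mAP/mAR average over thresholds
#' 0.50, 0.55, ..., 0.95.
#'
#' @param oksValues numeric vector: OKS of each image's detection
#'   (\code{NA} for images with no detection).
#' @param confidences numeric vector of detection confidences (the mean
#'   decoded peak score), same length.
#' @param nCases number of ground-truth images (default
#'   \code{length(oksValues)}).
#' @param thresholds OKS thresholds (default \code{seq(0.5, 0.95, 0.05)}).
#' @return list with \code{mAP}, \code{AP50}, \code{AP75}, \code{mAR},
#'   \code{perThreshold} data.frame and the input OKS values.
#' @export
detectionMetrics <- function(oksValues, confidences,
                             nCases = length(oksValues),
                             thresholds = seq(0.5, 0.95, by = 0.05)) {
    if (length(oksValues) == 0L || nCases == 0L)
        stop("empty case list")
    stopifnot(length(confidences) == length(oksValues))
    det <- which(!is.na(oksValues))
    ord <- det[order(-confidences[det])]
    recGrid <- seq(0, 1, by = 0.01)
    apAt <- function(t) {
        if (!length(ord)) return(c(ap = 0, ar = 0))
        tp <- cumsum(oksValues[ord] >= t)
        prec <- tp / seq_along(ord)
        rec <- tp / nCases
        ## 101-point interpolation: max precision at recall >= r
        ap <- mean(vapply(recGrid, function(r) {
            ok <- rec >= r
            if (any(ok)) max(prec[ok]) else 0
        }, numeric(1)))
        c(ap = ap, ar = max(rec))
    }
    per <- t(vapply(thresholds, apAt, numeric(2)))
    perDf <- data.frame(threshold = thresholds, AP = per[, "ap"],
                        AR = per[, "ar"])
    list(mAP = mean(per[, "ap"]),
         AP50 = perDf$AP[match(0.50, thresholds)],
         AP75 = perDf$AP[match(0.75, thresholds)],
         mAR = mean(per[, "ar"]),
         perThreshold = perDf, oks = oksValues)
}

#' Keypoint detection AP/AR from prediction/ground-truth pairs
#'
#' Convenience wrapper computing per-case OKS and confidences (mean decoded
#' peak score) and passing them to \code{\link{detectionMetrics}}.
#'
#' @param preds list of \code{\link{DecodedKeypoints}} (or
#'   \code{\link{KeypointSet}}) predictions; \code{NULL} entries mean no
#'   detection.
#' @param gts list of ground-truth \code{\link{KeypointSet}} objects.
#' @param cfg an \code{\link{oksConfig}}.
#' @param thresholds OKS thresholds.
#' @return see \code{\link{detectionMetrics}}.
#' @export
keypointAPAR <- function(preds, gts, cfg = oksConfig(),
                         thresholds = seq(0.5, 0.95, by = 0.05)) {
    stopifnot(length(preds) == length(gts), length(gts) >= 1L)
    oksv <- rep(NA_real_, length(gts))
    conf <- rep(NA_real_, length(gts))
    for (i in seq_along(gts)) {
        p <- preds[[i]]
        if (is.null(p)) next
        oksv[i] <- oks(p, gts[[i]], cfg)
        conf[i] <- if (methods::is(p, "DecodedKeypoints"))
            mean(p@scores) else 1
    }
    detectionMetrics(oksv, conf, nCases = length(gts),
                     thresholds = thresholds)
}

#' Intraclass correlation ICC(2,1) with 95\% confidence interval
#'
#' Two-way random effects, absolute agreement, single rater:
#' \code{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))}
#' with MSR, MSC, MSE the two-way ANOVA mean squares for subjects (rows),
#' raters (columns) and error.  The confidence interval is the F-based
#' interval of McGraw & Wong (1996) with Satterthwaite degrees of freedom.
#'
#' @param ratings numeric n x k matrix (n subjects, k raters; typically
#'   k = 2), no missing cells.
#' @param conf confidence level (default 0.95).
#' @return list with \code{estimate}, \code{ci} (lower, upper), \code{n},
#'   \code{k} and the mean squares.
#' @export
icc21 <- function(ratings, conf = 0.95) {
    ratings <- as.matrix(ratings)
    if (anyNA(ratings)) stop("missing cells are not supported")
    n <- nrow(ratings); k <- ncol(ratings)
    if (n < 5L) stop("insufficient data: need at least 5 subjects")
    if (k < 2L) stop("need at least 2 raters")
    if (stats::var(as.vector(ratings)) < 1e-300)
        stop("constant ratings: ICC undefined with zero variance")
    m <- mean(ratings)
    rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
    SSR <- k * sum((rm_ - m)^2)
    SSC <- n * sum((cm - m)^2)
    SST <- sum((ratings - m)^2)
    SSE <- SST - SSR - SSC
    MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
    MSE <- SSE / ((n - 1) * (k - 1))
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
    alpha <- 1 - conf
    if (MSE <= 1e-300 && MSC <= 1e-300) {
        ci <- c(1, 1)                  # perfect agreement
    } else {
        a <- (k * est) / (n * (1 - est))
        b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
        v <- (a * MSC + b * MSE)^2 /
            ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
        FL <- stats::qf(1 - alpha / 2, n - 1, v)
        FU <- stats::qf(1 - alpha / 2, v, n - 1)
        lower <- n * (MSR - FL * MSE) /
            (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
        upper <- n * (FU * MSR - MSE) /
            (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
        ci <- c(lower, upper)
    }
    list(estimate = est, ci = ci, n = n, k = k,
         MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Deviation statistics between two raters
#'
#' Mean, sample standard deviation and maximum of the absolute deviations
#' \code{|r1 - r2|}.  When a normalization range is given (180 for angles),
#' each statistic is additionally reported divided by that width and rounded
#' to 3 decimals for display, so that criteria on different scales are
#' comparable.
#'
#' @param r1,r2 numeric vectors of paired measurements.
#' @param normalizationRange optional range width (e.g. 180).
#' @return list with \code{mean}, \code{sd}, \code{max} and (if requested)
#'   \code{normalized} (named vector, rounded to 3 decimals).
#' @export
deviationStats <- function(r1, r2, normalizationRange = NULL) {
    stopifnot(length(r1) == length(r2), length(r1) >= 1L)
    dev <- abs(r1 - r2)
    out <- list(mean = mean(dev),
                sd = if (length(dev) > 1L) stats::sd(dev) else 0,
                max = max(dev))
    if (!is.null(normalizationRange)) {
        stopifnot(normalizationRange > 0)
        out$normalized <- round(c(mean = out$mean, sd = out$sd,
                                  max = out$max) / normalizationRange, 3)
    }
    out
}

#' Pooled-variance two-sample t test
#'
#' Equal-variance (Student) independent two-sample t statistic with
#' two-sided p-value.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @return list with \code{t} and \code{p}.
#' @export
twoSampleT <- function(x, y) {
    stopifnot(length(x) >= 2L, length(y) >= 2L)
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) *
                stats::var(y)) / (length(x) + length(y) - 2)
    if (sp2 <= 1e-300) {
        if (mean(x) == mean(y))
            stop("degenerate variance: both samples constant and equal")
        return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
    }
    ht <- stats::t.test(x, y, var.equal = TRUE)
    list(t = unname(ht$statistic), p = ht$p.value)
}
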