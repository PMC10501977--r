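## Fixtures and independent oracles shared across test files.

apKps <- function(A = c(0, 0), B = c(0, 100), C = c(10, 50),
                  D = c(-6, 50), E = c(2, 50), id = "ap1") {
    keypointSet(rbind(A = A, B = B, C = C, D = D, E = E),
                view = "AP", imageId = id)
}

latKps <- function(flexDeg = 180, id = "lat1") {
    ## A-E as in the AP fixture; tibial shaft vertical below the knee,
    ## femoral shaft rotated so the F-G / I-H angle equals flexDeg
    v <- c(0, 1)                              # tibial distal direction
    a <- (180 - flexDeg) * pi / 180
    u <- c(-(sin(a) * v[1]) - 0 , 0)          # placeholder, built below
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    u <- as.vector(R %*% (-v))                # femoral proximal direction
    J <- c(20, 110)
    keypointSet(rbind(A = c(0, 0), B = c(0, 100), C = c(10, 50),
                      D = c(-6, 50), E = c(2, 50),
                      F = J + 80 * u, G = J + 20 * u,
                      H = J + 10 * v, I = J + 90 * v),
                view = "LAT", imageId = id)
}

## random similarity transform applied to a KeypointSet
similarityTransform <- function(kps, angleDeg, scale, shift) {
    a <- angleDeg * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    co <- kps@coords
    ok <- rowSums(is.finite(co)) == 2L
    co[ok, ] <- t(scale * (R %*% t(co[ok, , drop = FALSE])) + shift)
    kps@coords <- co
    kps
}

## brute-force nearest-point distance to a line sampled densely
bruteLineDistance <- function(p, anchor, direction, nSample = 1e5,
                              halfSpan = 1000) {
    t <- seq(-halfSpan, halfSpan, length.out = nSample)
    pts <- cbind(anchor[1] + t * direction[1], anchor[2] + t * direction[2])
    sqrt(min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
}

## naive PR-curve enumeration oracle for detection AP/AR (independent of
## detectionMetrics): plain loops, 101-point interpolation by scanning
naiveDetectionMetrics <- function(oksValues, confidences, nCases,
                                  thresholds = seq(0.5, 0.95, 0.05)) {
    det <- which(!is.na(oksValues))
    det <- det[order(-confidences[det])]
    aps <- ars <- numeric(length(thresholds))
    for (ti in seq_along(thresholds)) {
        tp <- 0
        prec <- rec <- numeric(0)
        for (j in seq_along(det)) {
            if (oksValues[det[j]] >= thresholds[ti]) tp <- tp + 1
            prec <- c(prec, tp / j)
            rec <- c(rec, tp / nCases)
        }
        ap <- 0
        for (r in seq(0, 1, 0.01)) {
            best <- 0
            for (j in seq_along(det))
                if (rec[j] >= r && prec[j] > best) best <- prec[j]
            ap <- ap + best / 101
        }
        aps[ti] <- ap
        ars[ti] <- if (length(det)) tp / nCases else 0
    }
    list(mAP = mean(aps), mAR = mean(ars),
         AP50 = aps[thresholds == 0.5], AP75 = aps[thresholds == 0.75])
}

## two-way ANOVA mean squares via stats::aov (oracle for icc21)
aovMeanSquares <- function(ratings) {
    n <- nrow(ratings); k <- ncol(ratings)
    df <- data.frame(y = as.vector(ratings),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
    tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
    list(MSR = tab["subj", "Mean Sq"], MSC = tab["rater", "Mean Sq"],
         MSE = tab["Residuals", "Mean Sq"])
}

## deterministic deviation vector with prescribed mean, sample sd and max
## (n = 20; used to exercise range normalization at realistic magnitudes)
deviationVector <- function(m, s, mx, n = 20L) {
    restMean <- (n * m - mx) / (n - 1)
    ssRest <- (n - 1) * s^2 - (mx - m)^2
    ssCentered <- ssRest - (n - 1) * (restMean - m)^2
    stopifnot(ssCentered > 0)
    t <- sqrt(ssCentered / (n - 2))
    v <- c(mx, restMean + t * rep(c(1, -1), (n - 2) / 2), restMean)
    stopifnot(abs(mean(v) - m) < 1e-12, abs(stats::sd(v) - s) < 1e-9,
              max(v) == mx, all(v >= 0))
    v
}

## easy-regime synthetic dataset shared by learning tests
easyRanges <- function() list(overlap = c(0.2, 0.8), flexion = c(120, 175),
                              noiseSd = c(0.005, 0.015),
                              blurSigma = c(0, 0))

## configuration of the scaled-down capability experiment: 64 easy
## phantoms, tiny preset, 30 epochs; no augmentation (the phantom set
## already spans the generative variation) and a learning-rate schedule
## sized for from-scratch training of this configuration
tinyExperimentConfig <- function(seed = 11L) {
    trainConfig(lr = 0.4, epochs = 30L, decayEpochs = c(26L, 29L),
                batchSize = 1L, flipProb = 0, inversionProb = 0,
                seed = seed)
}

## shared trained detectors (each trained once per test run):
## demoModel  — the full 30-epoch capability experiment on 64 LAT phantoms
##              (the view where all nine landmarks exist)
## viewModel  — a short 10-epoch run on a mixed AP/LAT set, enough for the
##              zero-target view-identification mechanism to separate
.modelCache <- new.env(parent = emptyenv())
demoModel <- function() {
    if (!is.null(.modelCache$model)) return(.modelCache$model)
    tr <- generateDataset(64, easyRanges(), seed = 101, apFraction = 0)
    net <- buildNetwork(networkConfig("tiny"), seed = 11)
    net <- trainDetector(net, tr$cases, tinyExperimentConfig())
    .modelCache$model <- net
    net
}

viewModel <- function() {
    if (!is.null(.modelCache$view)) return(.modelCache$view)
    tr <- generateDataset(64, easyRanges(), seed = 101, apFraction = 0.5)
    cfg <- tinyExperimentConfig()
    cfg$epochs <- 10L
    net <- buildNetwork(networkConfig("tiny"), seed = 11)
    net <- trainDetector(net, tr$cases, cfg)
    .modelCache$view <- net
    net
}
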