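test_that("network presets match the stated architecture", {
    ref <- networkConfig("reference")
    expect_equal(ref$branchChannels, c(32L, 64L, 128L, 256L))
    expect_equal(ref$stageExchange, c(1L, 4L, 3L))
    expect_equal(ref$stride, 4L)
    expect_equal(ref$outChannels, 9L)
    expect_equal(ref$inputShortSide, 288L)
    tiny <- networkConfig("tiny")
    expect_equal(tiny$branchChannels, c(8L, 16L, 32L, 64L))
    expect_equal(tiny$inputShortSide, 64L)
})

test_that("stem and head parameter counts match the hand formula", {
    for (preset in c("tiny", "reference")) {
        cfg <- networkConfig(preset)
        net <- buildNetwork(cfg, seed = 1)
        C <- cfg$baseChannels
        ch <- cfg$branchChannels
        ## stem: two 3x3 convs (1->C, C->C) each followed by a norm (2C)
        stemWant <- (9 * 1 * C + C) + 2 * C + (9 * C * C + C) + 2 * C
        ## head: per branch 1x1 conv ch[r]->C + bias + norm, then 4C->9
        headWant <- sum(ch * C + C + 2 * C) + (4 * C * 9 + 9)
        expect_equal(paramCount(net, "stem"), stemWant)
        expect_equal(paramCount(net, "head"), headWant)
    }
})

test_that("forward pass yields well-formed stride-4 stacks on any size", {
    net <- buildNetwork(networkConfig("tiny"), seed = 1)
    hm <- predictHeatmaps(net, matrix(runif(64 * 64), 64, 64))
    expect_s4_class(hm, "HeatmapStack")
    expect_equal(dim(heatmapArray(hm)), c(16L, 16L, 9L))
    expect_equal(stride(hm), 4L)
    expect_true(all(is.finite(heatmapArray(hm))))
    ## non-multiple-of-32 input is padded and cropped
    hm2 <- predictHeatmaps(net, matrix(0.3, 70, 90))
    expect_equal(dim(heatmapArray(hm2))[1:2], c(18L, 23L))
    expect_error(predictHeatmaps(net, matrix(0, 16, 16)), "small")
})

test_that("prediction is deterministic", {
    net <- buildNetwork(networkConfig("tiny"), seed = 3)
    img <- matrix(runif(64 * 64), 64, 64)
    expect_identical(heatmapArray(predictHeatmaps(net, img)),
                     heatmapArray(predictHeatmaps(net, img)))
})

test_that("zero-epoch training is a no-op and training is seeded-deterministic", {
    cs <- generateCase(phantomSpec("AP", seed = 4, noiseSd = 0.01))
    net <- buildNetwork(networkConfig("tiny"), seed = 2)
    same <- trainDetector(net, list(cs), trainConfig(epochs = 0L))
    expect_identical(same@nodes, net@nodes)
    ds <- lapply(1:4, function(i)
        generateCase(phantomSpec("AP", trueOverlap = i / 5, seed = i,
                                 noiseSd = 0.01)))
    tc <- trainConfig(lr = 0.2, epochs = 2, decayEpochs = 99L,
                      batchSize = 2L, seed = 7)
    a <- trainDetector(net, ds, tc)
    b <- trainDetector(net, ds, tc)
    expect_identical(trainLog(a)$loss, trainLog(b)$loss)
    expect_identical(a@nodes, b@nodes)
})

test_that("training loss decreases when overfitting a repeated sample", {
    cs <- generateCase(phantomSpec("LAT", trueFlexion = 150, seed = 3,
                                   noiseSd = 0.01, blurSigma = 0))
    net <- buildNetwork(networkConfig("tiny"), seed = 1)
    r <- trainDetector(net, rep(list(cs), 4),
                       trainConfig(lr = 0.2, epochs = 10, decayEpochs = 99L,
                                   batchSize = 4L, flipProb = 0,
                                   inversionProb = 0, seed = 1))
    l <- trainLog(r)$loss
    expect_lt(tail(l, 1), 0.5 * l[1])
})

test_that("convolution and normalization gradients match finite differences", {
    set.seed(9)
    x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
    W <- matrix(rnorm(3 * 3 * 2 * 3, sd = 0.2), 18, 3)
    b <- rnorm(3)
    f <- kneeqc:::convForward(x, W, b, 3L, 2L, 1L)
    dY <- array(rnorm(length(f$out)), dim(f$out))
    bk <- kneeqc:::convBackward(dY, W, f$cache)
    eps <- 1e-6
    for (i in sample(length(W), 10)) {
        Wp <- W; Wp[i] <- W[i] + eps
        Wm <- W; Wm[i] <- W[i] - eps
        num <- (sum(kneeqc:::convForward(x, Wp, b, 3L, 2L, 1L)$out * dY) -
                sum(kneeqc:::convForward(x, Wm, b, 3L, 2L, 1L)$out * dY)) /
            (2 * eps)
        expect_equal(bk$dW[i], num, tolerance = 1e-5)
    }
    for (i in sample(length(x), 10)) {
        xp <- x; xp[i] <- x[i] + eps
        xm <- x; xm[i] <- x[i] - eps
        num <- (sum(kneeqc:::convForward(xp, W, b, 3L, 2L, 1L)$out * dY) -
                sum(kneeqc:::convForward(xm, W, b, 3L, 2L, 1L)$out * dY)) /
            (2 * eps)
        expect_equal(bk$dX[i], num, tolerance = 1e-5)
    }
    g <- runif(2, 0.5, 1.5); bb <- rnorm(2)
    fn <- kneeqc:::inormForward(x, g, bb)
    dN <- array(rnorm(length(fn$out)), dim(fn$out))
    bn <- kneeqc:::inormBackward(dN, g, fn$cache)
    for (i in sample(length(x), 10)) {
        xp <- x; xp[i] <- x[i] + eps
        xm <- x; xm[i] <- x[i] - eps
        num <- (sum(kneeqc:::inormForward(xp, g, bb)$out * dN) -
                sum(kneeqc:::inormForward(xm, g, bb)$out * dN)) / (2 * eps)
        expect_equal(bn$dX[i], num, tolerance = 1e-5)
    }
})

test_that("checkpoints round-trip through save/load", {
    net <- buildNetwork(networkConfig("tiny"), seed = 5)
    f <- withr::local_tempfile(fileext = ".rds")
    saveKneeNet(net, f)
    back <- loadKneeNet(f)
    img <- matrix(runif(64 * 64), 64, 64)
    expect_identical(heatmapArray(predictHeatmaps(net, img)),
                     heatmapArray(predictHeatmaps(back, img)))
    expect_equal(netConfig(back), netConfig(net))
})

test_that("augmentation helpers preserve keypoint geometry", {
    cs <- generateCase(phantomSpec("LAT", trueFlexion = 140, seed = 6))
    smp <- list(image = caseImage(cs), keypoints = caseKeypoints(cs))
    fl <- kneeqc:::.flipSample(smp)
    ## flip twice restores the original
    fl2 <- kneeqc:::.flipSample(fl)
    expect_equal(fl2$image, smp$image)
    expect_equal(kpCoords(fl2$keypoints), kpCoords(smp$keypoints))
    ## QC criteria are invariant under the mirror flip
    q0 <- computeQC(smp$keypoints)
    q1 <- computeQC(fl$keypoints)
    expect_equal(qcOverlap(q1), qcOverlap(q0), tolerance = 1e-9)
    expect_equal(qcFlexion(q1), qcFlexion(q0), tolerance = 1e-9)
})
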