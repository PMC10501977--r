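test_that("OKS closed forms: exact match, characteristic distance, constants", {
    cfg <- oksConfig()
    expect_equal(unname(cfg$k["C"]), 0.058)
    gt <- latKps(160)
    expect_equal(oks(gt, gt, cfg), 1)
    ## single visible keypoint C at the characteristic distance d^2 = 2 s^2 k^2
    co <- rbind(A = c(0, 0), B = c(30, 40), C = c(10, 20))
    gt1 <- keypointSet(co, view = "AP",
                       visible = c(A = TRUE, B = TRUE, C = TRUE))
    s2 <- 30 * 40
    d <- sqrt(2 * s2 * cfg$k["C"]^2)
    pr <- co
    pr["C", ] <- pr["C", ] + c(d, 0)
    pred <- keypointSet(pr, view = "AP")
    ## A and B predicted perfectly, C at the characteristic distance
    got <- oks(pred, gt1, cfg)
    expect_equal(got, (1 + 1 + exp(-1)) / 3)
})

test_that("OKS is invariant to joint translation and scaling, monotone in error", {
    cfg <- oksConfig()
    gt <- latKps(150)
    pr <- gt
    set.seed(5)
    pr@coords <- pr@coords + matrix(rnorm(18, 0, 2), 9, 2)
    base <- oks(pr, gt, cfg)
    for (i in 1:20) {
        sc <- exp(runif(1, -2, 2)); sh <- runif(2, -300, 300)
        gt2 <- gt; gt2@coords <- gt2@coords * sc +
            matrix(sh, 9, 2, byrow = TRUE)
        pr2 <- pr; pr2@coords <- pr2@coords * sc +
            matrix(sh, 9, 2, byrow = TRUE)
        expect_equal(oks(pr2, gt2, cfg), base, tolerance = 1e-9)
    }
    ## growing one keypoint's error strictly decreases OKS
    worse <- pr
    worse@coords["E", ] <- worse@coords["E", ] + c(5, 0)
    expect_lt(oks(worse, gt, cfg), base)
    ## a visible gt keypoint with no prediction contributes 0
    miss <- gt
    miss@visible["C"] <- FALSE
    expect_equal(oks(miss, gt, cfg), 8 / 9)
})

test_that("detection metrics match hand constructions", {
    ## perfect detector
    m <- detectionMetrics(rep(1, 10), rep(0.9, 10))
    expect_equal(m$mAP, 1); expect_equal(m$AP50, 1)
    expect_equal(m$AP75, 1); expect_equal(m$mAR, 1)
    ## all OKS at 0.6: TP below 0.6 thresholds only
    m2 <- detectionMetrics(rep(0.6, 8), rep(0.5, 8))
    expect_equal(m2$AP50, 1)
    expect_equal(m2$AP75, 0)
    expect_equal(m2$mAP, 3 / 10)  # thresholds 0.50, 0.55, 0.60 pass
    expect_error(detectionMetrics(numeric(0), numeric(0)), "empty")
})

test_that("detection metrics equal brute-force PR enumeration", {
    set.seed(11)
    pool_oks <- c(0.97, 0.93, 0.81, 0.74, 0.52, 0.31)
    pool_conf <- c(0.9, 0.4, 0.95, 0.6, 0.99, 0.2)
    ## exhaustive: every nonempty subset of the 6-case pool
    for (mask in 1:63) {
        keep <- which(bitwAnd(mask, 2^(0:5)) > 0)
        o <- pool_oks[keep]; cf <- pool_conf[keep]
        got <- detectionMetrics(o, cf)
        want <- naiveDetectionMetrics(o, cf, length(o))
        expect_equal(got$mAP, want$mAP, tolerance = 1e-12)
        expect_equal(got$mAR, want$mAR, tolerance = 1e-12)
        expect_equal(got$AP50, want$AP50, tolerance = 1e-12)
        expect_equal(got$AP75, want$AP75, tolerance = 1e-12)
    }
    ## with missed detections (NA) counting as false negatives
    o <- c(0.9, NA, 0.7, NA, 0.55)
    cf <- c(0.8, NA, 0.9, NA, 0.3)
    got <- detectionMetrics(o, cf)
    want <- naiveDetectionMetrics(o, cf, 5)
    expect_equal(got$mAP, want$mAP, tolerance = 1e-12)
    expect_equal(got$mAR, want$mAR, tolerance = 1e-12)
})

test_that("icc21 matches the ANOVA mean-squares oracle to 1e-10", {
    set.seed(21)
    for (rep in 1:5) {
        n <- sample(6:30, 1)
        r1 <- rnorm(n, 10, 3)
        ratings <- cbind(r1, r1 + rnorm(n, 0.5, 1))
        got <- icc21(ratings)
        ms <- aovMeanSquares(ratings)
        expect_equal(got$MSR, ms$MSR, tolerance = 1e-10)
        expect_equal(got$MSC, ms$MSC, tolerance = 1e-10)
        expect_equal(got$MSE, ms$MSE, tolerance = 1e-10)
        k <- 2
        want <- (ms$MSR - ms$MSE) /
            (ms$MSR + (k - 1) * ms$MSE + (k / n) * (ms$MSC - ms$MSE))
        expect_equal(got$estimate, want, tolerance = 1e-10)
        expect_true(got$ci[1] <= got$estimate && got$estimate <= got$ci[2])
    }
})

test_that("icc21 confidence interval reproduces a reference computation", {
    ## fixed 6x2 fixture; expected values frozen from an independent
    ## implementation of the two-way random effects / absolute agreement
    ## model (cross-checked against pingouin's ICC(A,1) row)
    ratings <- cbind(c(9, 2, 5, 8, 6, 7), c(2, 1, 8, 6, 1, 2))
    got <- icc21(ratings)
    expect_equal(got$estimate, 0.09017713365539, tolerance = 1e-10)
    expect_equal(got$ci[1], -0.3746659566075, tolerance = 1e-8)
    expect_equal(got$ci[2], 0.7342786161104, tolerance = 1e-8)
})

test_that("icc21 properties: perfect agreement, bias penalty, errors", {
    x <- c(3, 7, 1, 9, 4, 6)
    expect_equal(icc21(cbind(x, x))$estimate, 1)
    expect_equal(icc21(cbind(x, x))$ci, c(1, 1))
    ## absolute agreement penalizes a constant shift
    noisy <- cbind(x, x + rnorm(6, 0, 0.1))
    shifted <- noisy; shifted[, 2] <- shifted[, 2] + 10
    expect_lt(icc21(shifted)$estimate, icc21(noisy)$estimate)
    expect_error(icc21(cbind(x[1:4], x[1:4])), "at least 5")
    expect_error(icc21(matrix(5, 6, 2)), "constant")
    expect_error(icc21(cbind(x, c(NA, x[-1]))), "missing")
})

test_that("icc21 recovers the population ICC on simulated two-rater data", {
    ## subjects + rater bias + noise: population ICC(2,1) =
    ## va / (va + vb + ve)
    va <- 4; vb <- 0.25; ve <- 1
    popICC <- va / (va + vb + ve)
    set.seed(31)
    ests <- replicate(20, {
        subj <- rnorm(500, 0, sqrt(va))
        rater <- rnorm(2, 0, sqrt(vb))
        y <- outer(subj, rater, "+") + matrix(rnorm(1000, 0, sqrt(ve)),
                                              500, 2)
        icc21(y)$estimate
    })
    ## with k = 2 raters the rater-variance component is estimated from 2
    ## draws, so replicate scatter is dominated by it; compare the mean at
    ## a Monte-Carlo tolerance of 3 SE
    expect_lt(abs(mean(ests) - popICC), 3 * sd(ests) / sqrt(20) + 0.02)
})

test_that("deviation statistics and range normalization match hand values", {
    d <- deviationStats(c(1, 2, 3), c(1, 2, 3))
    expect_equal(c(d$mean, d$sd, d$max), c(0, 0, 0))
    v <- deviationVector(1.049, 0.748, 3.730)
    s <- deviationStats(rep(0, 20), v, normalizationRange = 180)
    expect_equal(s$mean, 1.049, tolerance = 1e-9)
    expect_equal(s$sd, 0.748, tolerance = 1e-9)
    expect_equal(s$max, 3.730)
    expect_equal(unname(s$normalized), c(0.006, 0.004, 0.021))
    expect_error(deviationStats(numeric(0), numeric(0)), "length")
})

test_that("twoSampleT matches the closed-form pooled-variance formula", {
    x <- c(1, 2, 3); y <- c(4, 5, 6)
    got <- twoSampleT(x, y)
    sp <- sqrt(((2) * var(x) + (2) * var(y)) / 4)
    tHand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 3 + 1 / 3))
    expect_equal(got$t, tHand)
    expect_equal(got$p, 2 * pt(-abs(tHand), df = 4))
    ## identical samples
    same <- twoSampleT(c(1, 2, 5), c(1, 2, 5))
    expect_equal(same$t, 0)
    expect_equal(same$p, 1)
    ## antisymmetry
    swap <- twoSampleT(y, x)
    expect_equal(swap$t, -got$t)
    expect_equal(swap$p, got$p)
    expect_error(twoSampleT(c(2, 2), c(2, 2)), "degenerate")
})
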