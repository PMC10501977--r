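test_that("fitLine passes through its points and rejects coincident input", {
    L <- fitLine(c(0, 0), c(0, 100))
    expect_equal(abs(L$direction), c(0, 1))
    L2 <- fitLine(c(1, 1), c(3, 3))
    expect_equal(L2$direction, c(sqrt(2) / 2, sqrt(2) / 2))
    expect_equal(sum(L2$direction^2), 1)
    expect_error(fitLine(c(2, 5), c(2, 5)), "coincident")
})

test_that("signedDistance has the reference-side sign convention", {
    L <- fitLine(c(0, 0), c(0, 100))
    expect_equal(signedDistance(c(10, 50), L, c(1, 0)), 10)
    expect_equal(signedDistance(c(-6, 50), L, c(1, 0)), -6)
    expect_equal(signedDistance(c(0, 33), L, c(1, 0)), 0)
    ## swapping the reference side flips the sign
    expect_equal(signedDistance(c(10, 50), L, c(-1, 0)), -10)
    expect_error(signedDistance(c(1, 1), L, c(0, 50)), "on the line")
})

test_that("signedDistance magnitude matches a brute-force nearest-point search", {
    L <- fitLine(c(0, 0), c(0.6, 0.8))
    p <- c(4, 3)                      # off the line through (0.6, 0.8)
    d <- signedDistance(p, L, c(-4, 3))
    expect_equal(abs(d), 1.4, tolerance = 1e-12)
    expect_equal(abs(d), bruteLineDistance(p, c(0, 0), c(0.6, 0.8)),
                 tolerance = 1e-3)
    set.seed(42)
    for (i in 1:10) {
        a <- runif(2, -50, 50); b <- runif(2, -50, 50)
        if (sum((a - b)^2) < 1) next
        L <- fitLine(a, b)
        p <- runif(2, -100, 100)
        ref <- a + c(-L$direction[2], L$direction[1]) * 5
        expect_equal(abs(signedDistance(p, L, ref)),
                     bruteLineDistance(p, a, (b - a) / sqrt(sum((b - a)^2)),
                                       halfSpan = 2000),
                     tolerance = 1e-3)
    }
})

test_that("overlapRatio reproduces hand-computed values and boundaries", {
    expect_equal(as.numeric(overlapRatio(apKps())), 0.5)  # (10-2)/(10+6)
    ## E at C: tibia edge just reaches the near extreme -> no overlap
    expect_equal(as.numeric(overlapRatio(apKps(E = c(10, 50)))), 0)
    ## E at D: full overlap
    expect_equal(as.numeric(overlapRatio(apKps(E = c(-6, 50)))), 1)
    ## E on the far side of L1 (negative Se) raises the ratio beyond the
    ## same-side case: one signed formula covers both printed branches
    expect_equal(as.numeric(overlapRatio(apKps(E = c(-2, 50)))), 0.75)
})

test_that("overlapRatio clamps and flags out-of-range geometry", {
    r <- overlapRatio(apKps(E = c(14, 50)))   # Se > Sc -> raw < 0
    expect_equal(as.numeric(r), 0)
    expect_true(attr(r, "clamped"))
    r2 <- overlapRatio(apKps())
    expect_false(attr(r2, "clamped"))
    ## C and D coincide transversely: no head width
    expect_error(overlapRatio(apKps(D = c(10, 60))), "degenerate")
})

test_that("flexionAngle matches analytic vector angles", {
    expect_equal(flexionAngle(latKps(180)), 180)
    k90 <- keypointSet(rbind(A = c(0, 0), B = c(0, 100), C = c(10, 50),
                             D = c(-6, 50), E = c(2, 50),
                             F = c(0, 0), G = c(0, 100), H = c(0, 120),
                             I = c(100, 120)), view = "LAT")
    expect_equal(flexionAngle(k90), 90)
    k150 <- keypointSet(rbind(A = c(0, 0), B = c(0, 100), C = c(10, 50),
                              D = c(-6, 50), E = c(2, 50),
                              F = c(0, 0), G = c(0, 100), H = c(0, 120),
                              I = c(50, 120 + 50 * sqrt(3))), view = "LAT")
    expect_equal(flexionAngle(k150), 150, tolerance = 1e-8)
    for (a in c(95, 120, 144.5, 170))
        expect_equal(flexionAngle(latKps(a)), a, tolerance = 1e-8)
})

test_that("overlap ratio and flexion angle are similarity invariant", {
    set.seed(7)
    ap <- apKps(); lat <- latKps(143)
    r0 <- as.numeric(overlapRatio(ap))
    f0 <- flexionAngle(lat)
    for (i in 1:100) {
        ang <- runif(1, 0, 360); sc <- exp(runif(1, -2, 2))
        sh <- runif(2, -500, 500)
        expect_equal(as.numeric(overlapRatio(
            similarityTransform(ap, ang, sc, sh))), r0, tolerance = 1e-9)
        expect_equal(flexionAngle(similarityTransform(lat, ang, sc, sh)),
                     f0, tolerance = 1e-9)
    }
    ## mirror reflection preserves the angle
    m <- latKps(143)
    m@coords[, "x"] <- -m@coords[, "x"]
    expect_equal(flexionAngle(m), f0, tolerance = 1e-9)
})

test_that("overlapRatio is monotone as E sweeps from C to D", {
    es <- seq(10, -6, length.out = 33)      # C side -> D side
    rs <- vapply(es, function(ex)
        as.numeric(overlapRatio(apKps(E = c(ex, 50)))), numeric(1))
    expect_true(all(diff(rs) >= -1e-12))
    expect_equal(rs[1], 0)
    expect_equal(rs[33], 1)
})

test_that("computeQC composes the criteria per view and checks completeness", {
    q <- computeQC(apKps())
    expect_s4_class(q, "QCResult")
    expect_equal(qcOverlap(q), 0.5)
    expect_true(is.na(qcFlexion(q)))
    ql <- computeQC(latKps(180))
    expect_equal(qcOverlap(ql), 0.5)
    expect_equal(qcFlexion(ql), 180)
    expect_equal(ql@normalizedFlexion, 1)
    ## missing required keypoint
    broken <- apKps()
    broken@visible["C"] <- FALSE
    expect_error(computeQC(broken), "C")
})

test_that("KeypointSet validity rejects malformed objects", {
    expect_error(keypointSet(rbind(Z = c(0, 0)), view = "AP"), "unknown")
    bad <- apKps()
    expect_error({bad@visible["F"] <- TRUE; validObject(bad)}, "AP")
    bad2 <- apKps()
    expect_error({bad2@coords["A", 1] <- NaN; validObject(bad2)}, "finite")
})
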