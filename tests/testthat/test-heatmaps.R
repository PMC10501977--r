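test_that("encodeHeatmaps places unit Gaussians and zero channels", {
    kps <- keypointSet(rbind(A = c(60, 40)), view = "AP")  # x=60 -> col 61
    hm <- encodeHeatmaps(kps, shape = c(80, 80), stride = 1, sigma = 2)
    m <- heatmapArray(hm)
    expect_equal(m[41, 61, 1], 1)
    expect_equal(m[41, 63, 1], exp(-0.5))    # offset 2 at sigma 2
    expect_equal(m[43, 61, 1], exp(-0.5))
    ## all other channels identically zero
    expect_equal(sum(m[, , 2:9]), 0)
})

test_that("AP sets give exactly-zero LAT-only channels", {
    cs <- generateCase(phantomSpec("AP", seed = 2))
    hm <- encodeHeatmaps(caseKeypoints(cs), shape = c(64, 64), stride = 1)
    m <- heatmapArray(hm)
    expect_identical(sum(m[, , 6:9]), 0)     # F, G, H, I
    expect_true(all(apply(m[, , 1:5], 3, max) == 1 |
                    abs(apply(m[, , 1:5], 3, max) - 1) < 0.07))
})

test_that("empty keypoint set encodes to an all-zero stack", {
    empty <- keypointSet(matrix(NA_real_, 9, 2,
                                dimnames = list(KP_LABELS, c("x", "y"))),
                         view = "AP",
                         visible = stats::setNames(rep(FALSE, 9), KP_LABELS))
    hm <- encodeHeatmaps(empty, shape = c(16, 16), stride = 4)
    expect_equal(sum(heatmapArray(hm)), 0)
    dec <- decodeHeatmaps(hm, tau = 0.1)
    expect_equal(sum(kpVisible(dec)), 0)
})

test_that("encode then decode is the identity at stride 1 on integer grids", {
    set.seed(3)
    for (rep in 1:5) {
        co <- cbind(x = sample(0:63, 9), y = sample(0:63, 9))
        rownames(co) <- KP_LABELS
        kps <- keypointSet(co, view = "LAT")
        for (sigma in c(0.5, 2, 4)) {
            dec <- decodeHeatmaps(encodeHeatmaps(kps, c(64, 64), 1, sigma),
                                  tau = 0.5)
            expect_identical(kpCoords(dec), kpCoords(kps))
            expect_equal(unname(kpScores(dec)), rep(1, 9))
        }
    }
})

test_that("decoding respects stride and is equivariant to translation", {
    kps <- keypointSet(rbind(A = c(40, 60)), view = "AP")
    hm <- encodeHeatmaps(kps, shape = c(32, 32), stride = 4)
    dec <- decodeHeatmaps(hm, tau = 0.5)
    expect_equal(kpCoords(dec)["A", ], c(x = 40, y = 60))
    ## integer translation of the stack shifts decoded positions accordingly
    m <- heatmapArray(hm)
    shifted <- array(0, dim(m))
    shifted[4:32, 3:32, ] <- m[1:29, 1:30, ]
    hm2 <- new("HeatmapStack", maps = shifted, stride = 4L)
    dec2 <- decodeHeatmaps(hm2, tau = 0.5)
    expect_equal(kpCoords(dec2)["A", ],
                 c(x = 40 + 2 * 4, y = 60 + 3 * 4))
})

test_that("ties break to the lexicographically smallest (row, col)", {
    m <- array(0, c(8, 8, 9))
    m[5, 2, 1] <- 0.9; m[3, 6, 1] <- 0.9; m[3, 7, 1] <- 0.9
    hm <- new("HeatmapStack", maps = m, stride = 1L)
    dec <- decodeHeatmaps(hm, tau = 0.5)
    expect_equal(kpCoords(dec)["A", ], c(x = 5, y = 2))  # row 2, col 5
})

test_that("sub-pixel refinement recovers fractional Gaussian centers", {
    kps <- keypointSet(rbind(A = c(41.7, 58.2)), view = "AP")
    hm <- encodeHeatmaps(kps, shape = c(32, 32), stride = 4)
    plain <- decodeHeatmaps(hm, tau = 0.2)
    fine <- decodeHeatmaps(hm, tau = 0.2, refine = TRUE)
    errPlain <- max(abs(kpCoords(plain)["A", ] - c(41.7, 58.2)))
    errFine <- max(abs(kpCoords(fine)["A", ] - c(41.7, 58.2)))
    expect_lt(errFine, 1e-6)      # the Gaussian LSQ fit is exact here
    expect_gt(errPlain, 1)        # argmax quantizes to the stride-4 grid
})

test_that("heatmap stacks export as valid NPY files", {
    kps <- keypointSet(rbind(A = c(12, 8)), view = "AP")
    hm <- encodeHeatmaps(kps, shape = c(16, 20), stride = 4)
    f <- withr::local_tempfile(fileext = ".npy")
    writeHeatmapsNPY(hm, f)
    con <- file(f, "rb")
    withr::defer(close(con))
    magic <- readBin(con, "raw", 8)
    expect_identical(magic[1], as.raw(0x93))
    expect_identical(rawToChar(magic[2:6]), "NUMPY")
    hlen <- readBin(con, "integer", 1, size = 2, endian = "little")
    hdr <- rawToChar(readBin(con, "raw", hlen))
    expect_match(hdr, "'<f8'")
    expect_match(hdr, "16, 20, 9")
    expect_match(hdr, "'fortran_order': True")
    vals <- readBin(con, "double", 16 * 20 * 9, endian = "little")
    expect_equal(vals, as.vector(heatmapArray(hm)))
})

test_that("classifyView follows the >=3-of-4 LAT-only rule", {
    lat <- latKps(160)
    expect_equal(classifyView(lat), "LAT")
    expect_equal(classifyView(apKps()), "AP")
    ## encode -> decode reproduces the generating view
    for (mk in list(apKps(), latKps(135))) {
        mk <- similarityTransform(mk, 0, 1, c(20, 20))  # keep on the grid
        big <- encodeHeatmaps(mk, c(256, 256), 1)
        expect_equal(classifyView(decodeHeatmaps(big, tau = 0.1)),
                     kpView(mk))
    }
    ## only 2 of the 4 LAT-only labels visible -> AP
    part <- latKps(160)
    part@visible[c("H", "I")] <- FALSE
    expect_equal(classifyView(part), "AP")
    ## 3 of 4 -> LAT
    part2 <- latKps(160)
    part2@visible["I"] <- FALSE
    expect_equal(classifyView(part2), "LAT")
})
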