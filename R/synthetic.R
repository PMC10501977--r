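## Seeded synthetic knee-phantom generator with exact ground truth.
##
## Phantoms are stylized, not anatomically realistic: bones are bright
## capsules on a dark background and the fibular head is an ellipse.  The
## point of the generator is that every landmark is placed analytically, so
## the generative overlap ratio and flexion angle are recovered exactly by
## the geometry module, and corruptions (noise, blur, occlusion) are applied
## after landmark placement and cannot move the truth.

.rot <- function(v, deg) {
    a <- deg * pi / 180
    c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2])
}

#' Construct a PhantomSpec
#'
#' Defaults describe the standard study condition for CPU-scale
#' experiments: a 64 x 64 pixel phantom (matching the tiny detector
#' preset's input size), a 5-pixel fibular-head transverse semi-axis, a
#' 3-pixel fibular shaft, mild additive noise and slight blur.
#'
#' @param view \code{"AP"} or \code{"LAT"}.
#' @param imageSize integer (rows, cols).
#' @param trueOverlap generative overlap ratio in [0, 1].
#' @param trueFlexion generative flexion angle in degrees (LAT only).
#' @param fibulaHeadRadius,shaftWidth bone dimensions in pixels.
#' @param noiseSd additive Gaussian noise sd (intensity units).
#' @param blurSigma Gaussian blur sigma in pixels (0 disables).
#' @param occlusion empty list or \code{list(pos=, width=, opacity=)}.
#' @param seed integer seed of the per-case random stream.
#' @return a \code{\link{PhantomSpec}}.
#' @export
phantomSpec <- function(view = c("AP", "LAT"), imageSize = c(64L, 64L),
                        trueOverlap = 0.5, trueFlexion = 160,
                        fibulaHeadRadius = 5, shaftWidth = 3,
                        noiseSd = 0.02, blurSigma = 0.6,
                        occlusion = list(), seed = 1L) {
    view <- match.arg(view)
    methods::new("PhantomSpec", view = view,
                 imageSize = as.integer(imageSize),
                 trueOverlap = as.numeric(trueOverlap),
                 trueFlexion = if (view == "LAT") as.numeric(trueFlexion)
                               else NA_real_,
                 fibulaHeadRadius = as.numeric(fibulaHeadRadius),
                 shaftWidth = as.numeric(shaftWidth),
                 noiseSd = as.numeric(noiseSd),
                 blurSigma = as.numeric(blurSigma),
                 occlusion = occlusion, seed = as.integer(seed))
}

## ---- rendering primitives (0-based pixel-center coordinates) --------------

.pixelGrid <- function(H, W) {
    list(X = matrix(0:(W - 1L), H, W, byrow = TRUE),
         Y = matrix(0:(H - 1L), H, W))
}

## anti-aliased capsule (segment p1-p2 dilated by halfw)
.capsuleMask <- function(g, p1, p2, halfw) {
    dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
    len2 <- dx^2 + dy^2
    t <- ((g$X - p1[1]) * dx + (g$Y - p1[2]) * dy) / max(len2, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    dist <- sqrt((g$X - (p1[1] + t * dx))^2 + (g$Y - (p1[2] + t * dy))^2)
    pmin(pmax(halfw + 0.5 - dist, 0), 1)
}

## anti-aliased ellipse centered at ctr, semi-axis al along unit axu,
## semi-axis at along the perpendicular
.ellipseMask <- function(g, ctr, axu, al, at) {
    u <- (g$X - ctr[1]) * axu[1] + (g$Y - ctr[2]) * axu[2]
    v <- -(g$X - ctr[1]) * axu[2] + (g$Y - ctr[2]) * axu[1]
    rho <- sqrt((u / al)^2 + (v / at)^2)
    pmin(pmax((1 - rho) * min(al, at) + 0.5, 0), 1)
}

## ---- layouts --------------------------------------------------------------

## Shared fibula/tibia overlap assembly, in coordinates relative to the head
## center O with vhat the distal shaft direction and that the unit vector
## from the fibular axis toward the tibia.  Returns keypoints A-E and the
## render pieces; the tibia's near edge runs at signed transverse distance
## Se = at*(1-2r) from the fibular axis, so the analytic overlap ratio is
## exactly r.
.fibulaAssembly <- function(vhat, that, at, al, r, dA, dB, wTib,
                            tibUp, tibDown) {
    Se <- at * (1 - 2 * r)
    E <- Se * that - al * sqrt(max(1 - (Se / at)^2, 0)) * vhat
    tibAxis <- (Se + wTib / 2) * that
    list(kp = rbind(A = dA * vhat, B = dB * vhat,
                    C = at * that, D = -at * that, E = E),
         tibP1 = tibAxis - tibUp * vhat, tibP2 = tibAxis + tibDown * vhat,
         wTib = wTib)
}

.layoutAP <- function(spec) {
    H <- spec@imageSize[1]; W <- spec@imageSize[2]
    at <- spec@fibulaHeadRadius; al <- 1.35 * at
    wf <- spec@shaftWidth; wTib <- 3.5 * spec@shaftWidth
    margin <- 8
    theta <- stats::runif(1, -6, 6)
    vhat <- .rot(c(0, 1), theta)              # distal (down) along the shaft
    that <- c(vhat[2], -vhat[1])              # toward the tibia
    Lw <- 0.68 * (min(H, W) - 2 * margin)     # shaft working length
    asm <- .fibulaAssembly(vhat, that, at, al, spec@trueOverlap,
                           dA = stats::runif(1, 0.40, 0.48) * Lw,
                           dB = stats::runif(1, 0.75, 0.88) * Lw,
                           wTib = wTib,
                           tibUp = al + stats::runif(1, 2, 4),
                           tibDown = 0.92 * Lw)
    kp <- asm$kp
    ## extent of everything drawn, for centering and feasibility
    ext <- rbind(kp,
                 t(sapply(c(-1, 1), function(s) s * (al * vhat + at * that))),
                 t(sapply(c(-1, 1), function(s) s * (al * vhat - at * that))),
                 asm$tibP1 + (wTib / 2) * that, asm$tibP1 - (wTib / 2) * that,
                 asm$tibP2 + (wTib / 2) * that, asm$tibP2 - (wTib / 2) * that,
                 kp["B", ] + wf * vhat)
    list(kp = kp, asm = asm, ext = ext, vhat = vhat, wf = wf,
         labels = c("A", "B", "C", "D", "E"), view = "AP")
}

.layoutLAT <- function(spec) {
    H <- spec@imageSize[1]; W <- spec@imageSize[2]
    S <- min(H, W)
    at <- spec@fibulaHeadRadius; al <- 1.35 * at
    wf <- spec@shaftWidth; wTib <- 3.5 * spec@shaftWidth
    wFem <- 2.2 * spec@shaftWidth
    theta <- stats::runif(1, -4, 4)
    vhat <- .rot(c(0, 1), theta)              # tibial distal direction
    delta <- 180 - spec@trueFlexion
    uhat <- .rot(-vhat, delta)                # femoral proximal direction
    nhat <- c(vhat[2], -vhat[1])              # perpendicular to the tibia
    ## femur tilts to one side; put the fibula on the other (posterior)
    side <- if (sum(uhat * nhat) >= 0) -1 else 1
    that <- side * nhat                       # fibula -> tibia direction
    J <- c(0, 0)                              # knee joint center
    mf <- stats::runif(1, 0.07, 0.09) * S; Lf <- 0.17 * S
    G <- J + mf * uhat; Fp <- J + (mf + Lf) * uhat
    mt <- stats::runif(1, 0.06, 0.08) * S; Lt <- 0.17 * S
    Hp <- J + mt * vhat; Ip <- J + (mt + Lt) * vhat
    hoff <- stats::runif(1, 0.08, 0.11) * S
    Se <- at * (1 - 2 * spec@trueOverlap)
    Dlt <- Se + wTib / 2                      # fibular axis to tibial axis
    O <- J + hoff * vhat - Dlt * that
    asm <- .fibulaAssembly(vhat, that, at, al, spec@trueOverlap,
                           dA = stats::runif(1, 0.06, 0.09) * S,
                           dB = stats::runif(1, 0.15, 0.18) * S,
                           wTib = wTib,
                           tibUp = hoff - mt + at,   # relative to O
                           tibDown = (mt + Lt + 0.04 * S) - hoff)
    kp <- rbind(sweep(asm$kp, 2L, O, "+"),
                F = Fp, G = G, H = Hp, I = Ip)
    ext <- rbind(kp,
                 Fp + (wFem / 2 + 1) * uhat, J - 0.02 * S * vhat,
                 Ip + (wTib / 2 + 1) * vhat,
                 O + al * vhat + at * that, O - al * vhat - at * that,
                 O + al * vhat - at * that, O - al * vhat + at * that,
                 kp["B", ] + wf * vhat)
    list(kp = kp, asm = asm, O = O, ext = ext, vhat = vhat, uhat = uhat,
         J = J, Fp = Fp, Ip = Ip, wf = wf, wFem = wFem,
         labels = KP_LABELS, view = "LAT")
}

#' Generate one synthetic phantom
#'
#' Deterministic for a given spec (including its seed).  Bones are rendered
#' as bright capsules and an elliptical fibular head on a dark background;
#' landmarks are placed analytically so that \code{\link{computeQC}} on the
#' ground-truth keypoints reproduces the generative parameters to numerical
#' precision.  Additive Gaussian noise, optional Gaussian blur and an
#' optional occlusion band are applied after landmark placement.
#'
#' @param spec a \code{\link{PhantomSpec}}.
#' @return a \code{\link{SyntheticCase}}.
#' @examples
#' cs <- generateCase(phantomSpec("LAT", trueFlexion = 150, seed = 3))
#' qcFlexion(computeQC(caseKeypoints(cs)))  # 150
#' @export
generateCase <- function(spec) {
    methods::validObject(spec)
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec@seed)
    H <- spec@imageSize[1]; W <- spec@imageSize[2]
    margin <- 8
    lay <- if (spec@view == "AP") .layoutAP(spec) else .layoutLAT(spec)
    ## translate so the drawn extent is centered (plus a small jitter)
    lo <- apply(lay$ext, 2L, min); hi <- apply(lay$ext, 2L, max)
    ctr <- c((W - 1) / 2, (H - 1) / 2) +
        stats::runif(2, -1.5, 1.5)
    shift <- ctr - (lo + hi) / 2
    lo <- lo + shift; hi <- hi + shift
    if (any(lo < margin) || hi[1] > W - 1 - margin || hi[2] > H - 1 - margin)
        stop("infeasible layout: bones cannot fit the canvas with an ",
             "8-pixel margin; enlarge imageSize or shrink the bones")
    kp <- sweep(lay$kp, 2L, shift, "+")
    g <- .pixelGrid(H, W)
    img <- matrix(0.08, H, W)
    addPiece <- function(mask, amp) img <<- img + amp * mask
    if (spec@view == "AP") {
        O <- shift                       # head center was at the origin
        tibP1 <- lay$asm$tibP1 + shift; tibP2 <- lay$asm$tibP2 + shift
        addPiece(.capsuleMask(g, tibP1, tibP2, lay$asm$wTib / 2), 0.45)
        addPiece(.capsuleMask(g, O, kp["B", ] + lay$wf * lay$vhat,
                              lay$wf / 2), 0.55)
        addPiece(.ellipseMask(g, O, lay$vhat, 1.35 * spec@fibulaHeadRadius,
                              spec@fibulaHeadRadius), 0.60)
    } else {
        O <- lay$O + shift
        J <- lay$J + shift
        addPiece(.capsuleMask(g, J + 0.02 * min(H, W) * lay$uhat,
                              lay$Fp + shift, lay$wFem / 2), 0.45)
        addPiece(.capsuleMask(g, J + 0.02 * min(H, W) * lay$vhat,
                              lay$Ip + shift, lay$asm$wTib / 2), 0.45)
        addPiece(.capsuleMask(g, O, kp["B", ] + lay$wf * lay$vhat,
                              lay$wf / 2), 0.55)
        addPiece(.ellipseMask(g, O, lay$vhat, 1.35 * spec@fibulaHeadRadius,
                              spec@fibulaHeadRadius), 0.60)
    }
    img <- pmin(img, 0.95)
    ## corruption modes: applied after landmark placement
    if (spec@blurSigma > 0)
        img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                                   sigma = spec@blurSigma)))
    if (spec@noiseSd > 0)
        img <- img + matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W)
    if (length(spec@occlusion)) {
        occ <- spec@occlusion
        rows <- seq(max(1L, as.integer(occ$pos) + 1L),
                    min(H, as.integer(occ$pos + occ$width)))
        img[rows, ] <- img[rows, ] * (1 - occ$opacity)
    }
    img <- pmin(pmax(img, 0), 1)
    kps <- keypointSet(kp[lay$labels, , drop = FALSE], view = spec@view,
                       imageId = sprintf("phantom_%s_%d", spec@view,
                                         spec@seed))
    truth <- if (spec@view == "AP")
        methods::new("QCResult", view = "AP",
                     overlapRatio = spec@trueOverlap,
                     flexionAngleDeg = NA_real_,
                     normalizedFlexion = NA_real_, clamped = FALSE)
    else
        methods::new("QCResult", view = "LAT",
                     overlapRatio = spec@trueOverlap,
                     flexionAngleDeg = spec@trueFlexion,
                     normalizedFlexion = spec@trueFlexion / 180,
                     clamped = FALSE)
    methods::new("SyntheticCase", image = img, keypoints = kps,
                 truth = truth, spec = spec)
}

#' Generate a dataset of phantoms with a manifest
#'
#' Parameters are drawn uniformly from the supplied ranges with one random
#' stream per case derived from \code{(seed, case index)}, so the dataset is
#' reproducible case-by-case.
#'
#' @param n number of cases (>= 1).
#' @param ranges named list of sampling ranges, each \code{c(lo, hi)}:
#'   \code{overlap}, \code{flexion}, \code{noiseSd}, \code{blurSigma},
#'   \code{headRadius}, \code{shaftWidth}; plus scalars
#'   \code{occlusionProb} (probability of a random occlusion band) and
#'   \code{imageSize}.  Missing entries fall back to the
#'   \code{\link{phantomSpec}} defaults.
#' @param seed integer dataset seed.
#' @param apFraction fraction of AP cases (default 0.5).
#' @param dir optional output directory: images are written as 16-bit
#'   grayscale PNG, ground-truth keypoints as JSON and the manifest as CSV.
#' @return list with elements \code{cases} (list of
#'   \code{\link{SyntheticCase}}) and \code{manifest} (data.frame).
#' @export
generateDataset <- function(n, ranges = list(), seed = 1L,
                            apFraction = 0.5, dir = NULL) {
    stopifnot(n >= 1L)
    dflt <- list(overlap = c(0, 1), flexion = c(90, 180),
                 noiseSd = c(0.02, 0.02), blurSigma = c(0.6, 0.6),
                 headRadius = c(5, 5), shaftWidth = c(3, 3),
                 occlusionProb = 0, imageSize = c(64L, 64L))
    rg <- utils::modifyList(dflt, ranges)
    u <- function(r) if (length(r) == 1L) r else stats::runif(1, r[1], r[2])
    cases <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        caseSeed <- (seed + 1000003 * i) %% .Machine$integer.max
        set.seed(caseSeed)
        view <- if (stats::runif(1) < apFraction) "AP" else "LAT"
        occ <- list()
        if (stats::runif(1) < rg$occlusionProb) {
            Hn <- rg$imageSize[1]
            occ <- list(pos = stats::runif(1, 0.2, 0.7) * Hn,
                        width = stats::runif(1, 0.05, 0.15) * Hn,
                        opacity = stats::runif(1, 0.3, 0.8))
        }
        sp <- phantomSpec(view = view, imageSize = rg$imageSize,
                          trueOverlap = u(rg$overlap),
                          trueFlexion = u(rg$flexion),
                          fibulaHeadRadius = u(rg$headRadius),
                          shaftWidth = u(rg$shaftWidth),
                          noiseSd = u(rg$noiseSd),
                          blurSigma = u(rg$blurSigma),
                          occlusion = occ, seed = as.integer(caseSeed))
        cases[[i]] <- generateCase(sp)
        rows[[i]] <- data.frame(
            case = i, image_id = imageId(cases[[i]]@keypoints), view = view,
            seed = as.integer(caseSeed), true_overlap = sp@trueOverlap,
            true_flexion = sp@trueFlexion,
            head_radius = sp@fibulaHeadRadius, shaft_width = sp@shaftWidth,
            noise_sd = sp@noiseSd, blur_sigma = sp@blurSigma,
            occluded = length(occ) > 0L)
    }
    manifest <- do.call(rbind, rows)
    if (!is.null(dir)) {
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        for (i in seq_len(n)) {
            id <- manifest$image_id[i]
            writePNG16(cases[[i]]@image, file.path(dir, paste0(id, ".png")))
            writeKeypointsJSON(list(cases[[i]]@keypoints),
                               file.path(dir, paste0(id, ".json")))
        }
        utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                         row.names = FALSE)
    }
    list(cases = cases, manifest = manifest)
}
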