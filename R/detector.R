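## The multiresolution heatmap-regression keypoint detector.
##
## Architecture: a stem of two stride-2 3x3 convolutions brings the input to
## 1/4 resolution; four stages maintain parallel branches at 1/4, 1/8, 1/16
## and 1/32 resolution with channel counts C, 2C, 4C, 8C; each exchange
## block runs residual units on every branch and then fuses all branches
## (stride-2 3x3 convolution chains downward, 1x1 convolution plus
## nearest-neighbour upsampling upward, contributions summed); the head maps
## every branch to C channels with 1x1 convolutions, upsamples branches 2-4
## to 1/4 resolution, concatenates, and applies a final 1x1 convolution to
## the 9 output channels.  The network is built as an explicit computation
## graph (topologically ordered node list) with hand-written backprop.

#' Detector network configuration
#'
#' @param preset \code{"reference"} (C = 32, input short side 288, exchange
#'   counts 1/4/3 in stages 2-4, 4 residual units per block) or
#'   \code{"tiny"}, a scaled-down configuration for CPU-scale experiments
#'   (C = 8, input short side 64, exchange counts 1/2/2, 2 residual units
#'   per block).  Both output 9 channels at stride 4.
#' @param baseChannels,inputShortSide,stageExchange,unitsPerBlock,stage1Units
#'   overrides of individual preset fields.
#' @param upsampleMode \code{"nearest"} (default) or \code{"bilinear"}
#'   (reserved; fusion currently uses nearest-neighbour upsampling).
#' @return a configuration list.
#' @examples
#' cfg <- networkConfig("tiny")
#' cfg$branchChannels   # 8 16 32 64
#' @export
networkConfig <- function(preset = c("tiny", "reference"), baseChannels = NULL,
                          inputShortSide = NULL, stageExchange = NULL,
                          unitsPerBlock = NULL, stage1Units = NULL,
                          upsampleMode = "nearest") {
    preset <- match.arg(preset)
    cfg <- if (preset == "reference")
        list(baseChannels = 32L, inputShortSide = 288L,
             stageExchange = c(1L, 4L, 3L), unitsPerBlock = 4L,
             stage1Units = 4L)
    else
        list(baseChannels = 8L, inputShortSide = 64L,
             stageExchange = c(1L, 2L, 2L), unitsPerBlock = 2L,
             stage1Units = 2L)
    if (!is.null(baseChannels))  cfg$baseChannels  <- as.integer(baseChannels)
    if (!is.null(inputShortSide))
        cfg$inputShortSide <- as.integer(inputShortSide)
    if (!is.null(stageExchange))
        cfg$stageExchange <- as.integer(stageExchange)
    if (!is.null(unitsPerBlock)) cfg$unitsPerBlock <- as.integer(unitsPerBlock)
    if (!is.null(stage1Units))   cfg$stage1Units   <- as.integer(stage1Units)
    stopifnot(cfg$baseChannels >= 1L, length(cfg$stageExchange) == 3L,
              all(cfg$stageExchange >= 1L), cfg$unitsPerBlock >= 1L)
    cfg$preset <- preset
    cfg$outChannels <- 9L
    cfg$stride <- 4L
    cfg$branchChannels <- cfg$baseChannels * c(1L, 2L, 4L, 8L)
    cfg$upsampleMode <- upsampleMode
    cfg
}

#' Training configuration
#'
#' Defaults follow the reference schedule: SGD with momentum 0.9, weight
#' decay 1e-4, initial learning rate 0.002 decayed by 10 at epochs 50 and
#' 56 of 60, mini-batches of 4, horizontal flips and intensity inversions
#' each with probability 0.5, and sigma-2 Gaussian target heatmaps.  For the
#' scaled-down (tiny-preset) experiments a larger learning rate and a
#' proportionally shortened schedule are appropriate; see
#' \code{\link{trainDetector}}.
#'
#' @param lr initial learning rate.
#' @param lrDecayFactor multiplicative decay applied at \code{decayEpochs}.
#' @param decayEpochs epochs after which the decay applies.
#' @param momentum,weightDecay,batchSize,epochs SGD hyperparameters.
#' @param flipProb,inversionProb augmentation probabilities.
#' @param sigma Gaussian target standard deviation (heatmap pixels).
#' @param nesterov use Nesterov (lookahead) momentum (default plain).
#' @param seed integer seed controlling shuffling, augmentation draws and
#'   (via \code{\link{buildNetwork}}) initialization.
#' @return a configuration list.
#' @export
trainConfig <- function(lr = 0.002, lrDecayFactor = 0.1,
                        decayEpochs = c(50L, 56L), momentum = 0.9,
                        weightDecay = 1e-4, batchSize = 4L, epochs = 60L,
                        flipProb = 0.5, inversionProb = 0.5, sigma = 2,
                        nesterov = FALSE, seed = 1L) {
    stopifnot(lr > 0, momentum >= 0, weightDecay >= 0, batchSize >= 1L,
              epochs >= 0L, all(decayEpochs >= 1L))
    list(lr = lr, lrDecayFactor = lrDecayFactor,
         decayEpochs = as.integer(decayEpochs), momentum = momentum,
         weightDecay = weightDecay, batchSize = as.integer(batchSize),
         epochs = as.integer(epochs), flipProb = flipProb,
         inversionProb = inversionProb, sigma = sigma,
         nesterov = isTRUE(nesterov), seed = as.integer(seed))
}

## ---- graph construction ---------------------------------------------------

.newBuilder <- function() {
    env <- new.env(parent = emptyenv())
    env$nodes <- list()
    env$add <- function(node) {
        env$nodes[[length(env$nodes) + 1L]] <- node
        length(env$nodes)
    }
    env
}

.addConv <- function(b, input, kh, stride, pad, cin, cout, group,
                     gain = 1) {
    b$add(list(op = "conv", inputs = input, kh = kh, stride = stride,
               pad = pad, W = heInit(kh, cin, cout, gain),
               b = numeric(cout), group = group))
}

.addRelu <- function(b, input) b$add(list(op = "relu", inputs = input))

## Instance normalization (learned per-channel scale/shift); gamma starts
## at `gain` so residual branches can open gently.
.addNorm <- function(b, input, ch, group, gain = 1) {
    b$add(list(op = "inorm", inputs = input, W = rep(gain, ch),
               b = numeric(ch), group = group))
}

## Residual unit: conv-norm-relu-conv-norm + skip, relu.  The second norm's
## scale starts small so the identity path dominates at initialization.
.addResUnit <- function(b, input, ch, group) {
    c1 <- .addConv(b, input, 3L, 1L, 1L, ch, ch, group)
    n1 <- .addNorm(b, c1, ch, group)
    r1 <- .addRelu(b, n1)
    c2 <- .addConv(b, r1, 3L, 1L, 1L, ch, ch, group)
    n2 <- .addNorm(b, c2, ch, group, gain = 0.1)
    s  <- b$add(list(op = "add", inputs = c(n2, input)))
    .addRelu(b, s)
}

## branch-to-branch fusion transform: src resolution index -> dst index.
## Cross-branch contributions are normalized with a small initial scale so
## the fused sums do not blow up the identity-resolution path.
.addFuse <- function(b, input, src, dst, ch, group) {
    if (src == dst) return(input)
    if (src < dst) {                       # downsample (dst - src) times
        cur <- input
        for (s in src:(dst - 1L)) {
            cin <- ch[src]
            cout <- if (s == dst - 1L) ch[dst] else ch[src]
            cur <- .addConv(b, cur, 3L, 2L, 1L, cin, cout, group)
            cur <- .addNorm(b, cur, cout, group,
                            gain = if (s == dst - 1L) 0.5 else 1)
            if (s < dst - 1L) cur <- .addRelu(b, cur)
        }
        cur
    } else {                               # 1x1 conv then upsample
        cv <- .addConv(b, input, 1L, 1L, 0L, ch[src], ch[dst], group)
        nm <- .addNorm(b, cv, ch[dst], group, gain = 0.5)
        b$add(list(op = "up", inputs = nm, f = 2L^(src - dst)))
    }
}

.addExchange <- function(b, branches, ch, group) {
    nb <- length(branches)
    units <- b$cfg$unitsPerBlock
    for (r in seq_len(nb))
        for (u in seq_len(units))
            branches[r] <- .addResUnit(b, branches[r], ch[r], group)
    out <- integer(nb)
    for (r in seq_len(nb)) {
        parts <- vapply(seq_len(nb), function(s)
            .addFuse(b, branches[s], s, r, ch, group), integer(1))
        s <- if (nb > 1L) b$add(list(op = "add", inputs = parts))
             else parts[1L]
        out[r] <- .addRelu(b, s)
    }
    out
}

#' Build an (untrained) detector network
#'
#' @param cfg a configuration from \code{\link{networkConfig}}.
#' @param seed integer seed for weight initialization (He-style random
#'   init; no pretraining).
#' @return a \code{\link{KneeNet}}.
#' @examples
#' net <- buildNetwork(networkConfig("tiny"), seed = 1)
#' hm <- predictHeatmaps(net, matrix(0.5, 64, 64))
#' dim(heatmapArray(hm))  # 16 16 9
#' @export
buildNetwork <- function(cfg, seed = 1L) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", .GlobalEnv))
            get(".Random.seed", .GlobalEnv) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
        set.seed(seed)
    }
    ch <- cfg$branchChannels
    b <- .newBuilder()
    b$cfg <- cfg
    inp <- b$add(list(op = "input"))
    ## stem: two stride-2 3x3 convolutions -> 1/4 resolution
    s1 <- .addRelu(b, .addNorm(b, .addConv(b, inp, 3L, 2L, 1L, 1L, ch[1],
                                           "stem"), ch[1], "stem"))
    b1 <- .addRelu(b, .addNorm(b, .addConv(b, s1, 3L, 2L, 1L, ch[1], ch[1],
                                           "stem"), ch[1], "stem"))
    branches <- b1
    ## stage 1: high-resolution subnetwork only
    for (u in seq_len(cfg$stage1Units))
        branches[1] <- .addResUnit(b, branches[1], ch[1], "stage1")
    ## stages 2-4: add a lower-resolution branch, then exchange blocks
    for (stage in 2:4) {
        grp <- paste0("stage", stage)
        nb <- stage
        branches[nb] <- .addRelu(b, .addNorm(b,
            .addConv(b, branches[nb - 1L], 3L, 2L, 1L, ch[nb - 1L], ch[nb],
                     grp), ch[nb], grp))
        for (e in seq_len(cfg$stageExchange[stage - 1L]))
            branches <- .addExchange(b, branches, ch[seq_len(nb)], grp)
    }
    ## head: per-branch 1x1 conv to C channels, upsample, concat, 1x1 to 9
    parts <- integer(4L)
    for (r in 1:4) {
        cv <- .addRelu(b, .addNorm(b, .addConv(b, branches[r], 1L, 1L, 0L,
                                               ch[r], ch[1], "head"),
                                   ch[1], "head"))
        parts[r] <- if (r == 1L) cv
                    else b$add(list(op = "up", inputs = cv, f = 2L^(r - 1L)))
    }
    cat_ <- b$add(list(op = "concat", inputs = parts))
    out <- .addConv(b, cat_, 1L, 1L, 0L, 4L * ch[1], cfg$outChannels,
                    "head", gain = 0.1)
    nodes <- b$nodes
    attr(nodes, "output") <- out
    methods::new("KneeNet", config = cfg, nodes = nodes,
                 trainLog = data.frame(epoch = integer(), loss = numeric(),
                                       lr = numeric()))
}

## ---- graph execution ------------------------------------------------------

.netForward <- function(nodes, x, keepCache = FALSE) {
    n <- length(nodes)
    vals <- vector("list", n)
    caches <- if (keepCache) vector("list", n) else NULL
    for (i in seq_len(n)) {
        nd <- nodes[[i]]
        vals[[i]] <- switch(nd$op,
            input = x,
            conv = {
                f <- convForward(vals[[nd$inputs]], nd$W, nd$b, nd$kh,
                                 nd$stride, nd$pad)
                if (keepCache) caches[[i]] <- f$cache
                f$out
            },
            relu = reluForward(vals[[nd$inputs]]),
            inorm = {
                f <- inormForward(vals[[nd$inputs]], nd$W, nd$b)
                if (keepCache) caches[[i]] <- f$cache
                f$out
            },
            add = {
                a <- vals[[nd$inputs[1]]]
                for (j in nd$inputs[-1]) a <- a + vals[[j]]
                a
            },
            up = upForward(vals[[nd$inputs]], nd$f),
            concat = {
                xs <- lapply(nd$inputs, function(j) vals[[j]])
                d <- dim(xs[[1]])
                array(unlist(xs, use.names = FALSE),
                      c(d[1], d[2], sum(vapply(xs, function(z) dim(z)[3],
                                               numeric(1)))))
            },
            stop("unknown op ", nd$op))
    }
    list(vals = vals, caches = caches)
}

## Backward pass; returns per-node dW/db gradients.
.netBackward <- function(nodes, fw, dOut) {
    n <- length(nodes)
    grads <- vector("list", n)      # upstream gradients per node output
    pgrads <- vector("list", n)     # parameter gradients for conv nodes
    grads[[n]] <- dOut
    for (i in n:1) {
        g <- grads[[i]]
        if (is.null(g)) next
        nd <- nodes[[i]]
        addg <- function(j, gj) {
            grads[[j]] <<- if (is.null(grads[[j]])) gj else grads[[j]] + gj
        }
        switch(nd$op,
            input = NULL,
            conv = {
                bk <- convBackward(g, nd$W, fw$caches[[i]])
                pgrads[[i]] <- list(dW = bk$dW, db = bk$db)
                addg(nd$inputs, bk$dX)
            },
            relu = addg(nd$inputs, reluBackward(g, fw$vals[[nd$inputs]])),
            inorm = {
                bk <- inormBackward(g, nd$W, fw$caches[[i]])
                pgrads[[i]] <- list(dW = bk$dW, db = bk$db)
                addg(nd$inputs, bk$dX)
            },
            add = for (j in nd$inputs) addg(j, g),
            up = addg(nd$inputs, upBackward(g, nd$f)),
            concat = {
                off <- 0L
                for (j in nd$inputs) {
                    cj <- dim(fw$vals[[j]])[3]
                    addg(j, g[, , off + seq_len(cj), drop = FALSE])
                    off <- off + cj
                }
            })
        grads[i] <- list(NULL)      # release memory early
    }
    pgrads
}

#' Count parameters of network components
#'
#' @param model a \code{\link{KneeNet}}.
#' @param groups optional character vector of component groups
#'   (\code{"stem"}, \code{"stage1"}..\code{"stage4"}, \code{"head"});
#'   default all.
#' @return total number of weights and biases in the selected groups.
#' @export
paramCount <- function(model, groups = NULL) {
    sum(vapply(model@nodes, function(nd) {
        if (is.null(nd$W)) return(0)
        if (!is.null(groups) && !(nd$group %in% groups)) return(0)
        length(nd$W) + length(nd$b)
    }, numeric(1)))
}

## ---- inference ------------------------------------------------------------

#' @describeIn predictHeatmaps forward pass of the detector.
#'
#' The image is zero-padded on the right/bottom to a multiple of 32 (the
#' deepest branch stride) before the forward pass and the heatmaps are
#' cropped back, so any image with both sides >= 32 is accepted.
#' @export
setMethod("predictHeatmaps", "KneeNet", function(model, image, ...) {
    stopifnot(is.matrix(image), all(is.finite(image)))
    d <- dim(image)
    if (any(d < 32L))
        stop("image too small for the stem/branch strides: both sides must ",
             "be >= 32 pixels")
    d32 <- as.integer(ceiling(d / 32) * 32)
    x <- array(0, c(d32[1], d32[2], 1L))
    x[seq_len(d[1]), seq_len(d[2]), 1L] <- image
    fw <- .netForward(model@nodes, x)
    out <- fw$vals[[attr(model@nodes, "output")]]
    s <- model@config$stride
    out <- out[seq_len(ceiling(d[1] / s)), seq_len(ceiling(d[2] / s)), ,
               drop = FALSE]
    methods::new("HeatmapStack", maps = out, stride = s)
})

## ---- training -------------------------------------------------------------

.asTrainSample <- function(item) {
    if (methods::is(item, "SyntheticCase"))
        list(image = item@image, keypoints = item@keypoints)
    else {
        stopifnot(is.matrix(item$image),
                  methods::is(item$keypoints, "KeypointSet"))
        item
    }
}

## resize an image (short side -> target) and scale keypoints accordingly
.resizeSample <- function(smp, shortSide) {
    d <- dim(smp$image)
    if (min(d) == shortSide) return(smp)
    f <- shortSide / min(d)
    nh <- as.integer(round(d[1] * f)); nw <- as.integer(round(d[2] * f))
    img <- EBImage::resize(EBImage::Image(t(smp$image)), w = nw, h = nh)
    img <- t(EBImage::imageData(img))
    kp <- smp$keypoints
    kp@coords <- kp@coords * f
    list(image = pmin(pmax(img, 0), 1), keypoints = kp)
}

.flipSample <- function(smp) {
    W <- ncol(smp$image)
    kp <- smp$keypoints
    kp@coords[, "x"] <- (W - 1) - kp@coords[, "x"]
    list(image = smp$image[, W:1, drop = FALSE], keypoints = kp)
}

#' Train the detector by heatmap regression
#'
#' Minimizes the mean per-pixel squared error between predicted and target
#' heatmaps over all 9 channels; channels of absent keypoints (F-I on AP
#' images) regress to zero rather than being masked, which is what enables
#' automatic view identification at inference time.  Augmentation applies a
#' horizontal flip (x coordinates remapped; the nine labels have no
#' left/right pairs, so none are swapped) and an intensity inversion
#' (value -> 1 - value, keypoints unchanged), each with the configured
#' probability.  Images whose short side differs from the configured input
#' size are resized (aspect preserved).  Optimization is plain SGD with
#' momentum, weight decay and a step learning-rate schedule; the whole run
#' is driven by \code{cfg$seed} and is deterministic on a single CPU.
#'
#' @param model a \code{\link{KneeNet}} (untrained or to continue training).
#' @param dataset list of \code{\link{SyntheticCase}} objects or of
#'   \code{list(image=, keypoints=)} pairs.
#' @param cfg a \code{\link{trainConfig}}.
#' @param verbose print per-epoch loss.
#' @return the trained \code{\link{KneeNet}} with an appended
#'   \code{trainLog}.
#' @export
trainDetector <- function(model, dataset, cfg = trainConfig(),
                          verbose = FALSE) {
    stopifnot(length(dataset) >= 1L)
    if (cfg$epochs == 0L) return(model)
    samples <- lapply(dataset, .asTrainSample)
    samples <- lapply(samples, .resizeSample,
                      shortSide = model@config$inputShortSide)
    nodes <- model@nodes
    outId <- attr(nodes, "output")
    stride <- model@config$stride
    vel <- vector("list", length(nodes))
    old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(cfg$seed)
    log <- model@trainLog
    for (epoch in seq_len(cfg$epochs)) {
        lr <- cfg$lr * cfg$lrDecayFactor^sum(epoch > cfg$decayEpochs)
        ord <- sample.int(length(samples))
        epochLoss <- 0; nb <- 0L
        for (start in seq(1L, length(ord), by = cfg$batchSize)) {
            batch <- ord[start:min(start + cfg$batchSize - 1L, length(ord))]
            acc <- vector("list", length(nodes))
            batchLoss <- 0
            for (si in batch) {
                smp <- samples[[si]]
                if (stats::runif(1) < cfg$flipProb) smp <- .flipSample(smp)
                img <- smp$image
                if (stats::runif(1) < cfg$inversionProb) img <- 1 - img
                d <- dim(img)
                tgt <- encodeHeatmaps(smp$keypoints,
                                      shape = c(d[1] %/% stride,
                                                d[2] %/% stride),
                                      stride = stride, sigma = cfg$sigma)
                x <- array(img, c(d[1], d[2], 1L))
                fw <- .netForward(nodes, x, keepCache = TRUE)
                Y <- fw$vals[[outId]]
                R <- Y - tgt@maps
                loss <- mean(R^2)
                if (!is.finite(loss))
                    stop("training diverged: non-finite loss at epoch ",
                         epoch)
                batchLoss <- batchLoss + loss
                pg <- .netBackward(nodes, fw, 2 * R / length(R))
                for (i in seq_along(pg)) {
                    if (is.null(pg[[i]])) next
                    if (is.null(acc[[i]])) acc[[i]] <- pg[[i]]
                    else {
                        acc[[i]]$dW <- acc[[i]]$dW + pg[[i]]$dW
                        acc[[i]]$db <- acc[[i]]$db + pg[[i]]$db
                    }
                }
            }
            nbatch <- length(batch)
            for (i in seq_along(acc)) {
                if (is.null(acc[[i]])) next
                wd <- if (nodes[[i]]$op == "conv") cfg$weightDecay else 0
                gW <- acc[[i]]$dW / nbatch + wd * nodes[[i]]$W
                gb <- acc[[i]]$db / nbatch
                if (is.null(vel[[i]]))
                    vel[[i]] <- list(W = gW * 0, b = gb * 0)
                vel[[i]]$W <- cfg$momentum * vel[[i]]$W - lr * gW
                vel[[i]]$b <- cfg$momentum * vel[[i]]$b - lr * gb
                if (isTRUE(cfg$nesterov)) {
                    nodes[[i]]$W <- nodes[[i]]$W +
                        cfg$momentum * vel[[i]]$W - lr * gW
                    nodes[[i]]$b <- nodes[[i]]$b +
                        cfg$momentum * vel[[i]]$b - lr * gb
                } else {
                    nodes[[i]]$W <- nodes[[i]]$W + vel[[i]]$W
                    nodes[[i]]$b <- nodes[[i]]$b + vel[[i]]$b
                }
            }
            epochLoss <- epochLoss + batchLoss / nbatch
            nb <- nb + 1L
        }
        log <- rbind(log, data.frame(epoch = nrow(log) + 1L,
                                     loss = epochLoss / nb, lr = lr))
        if (verbose)
            message(sprintf("epoch %3d  loss %.6f  lr %.4g",
                            nrow(log), epochLoss / nb, lr))
    }
    methods::new("KneeNet", config = model@config, nodes = nodes,
                 trainLog = log)
}

#' Save / load a detector checkpoint
#'
#' The checkpoint is a single RDS archive embedding the configuration,
#' weights and training log.
#'
#' @param model a \code{\link{KneeNet}}.
#' @param path file path.
#' @return \code{loadKneeNet} returns the \code{\link{KneeNet}}.
#' @export
saveKneeNet <- function(model, path) {
    saveRDS(list(config = model@config, nodes = model@nodes,
                 output = attr(model@nodes, "output"),
                 trainLog = model@trainLog), path)
    invisible(path)
}

#' @rdname saveKneeNet
#' @export
loadKneeNet <- function(path) {
    obj <- readRDS(path)
    nodes <- obj$nodes
    attr(nodes, "output") <- obj$output
    methods::new("KneeNet", config = obj$config, nodes = nodes,
                 trainLog = obj$trainLog)
}
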