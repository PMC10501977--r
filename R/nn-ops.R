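## Vectorized convolutional-network primitives with explicit backprop.
##
## Feature maps are H x W x C arrays (column-major, spatial indices fastest),
## convolutions use im2col with precomputed gather indices, and every op has
## a matching backward pass.  All arithmetic is plain double-precision base
## R, so results are deterministic for a given RNG seed.

.idxCache <- new.env(parent = emptyenv())

## Gather-index matrix for im2col: rows = output positions (column-major),
## cols = kernel taps; entries are flat spatial indices into the padded map.
.convIdx <- function(H, W, kh, kw, stride, pad) {
    key <- paste(H, W, kh, kw, stride, pad, sep = "_")
    got <- .idxCache[[key]]
    if (!is.null(got)) return(got)
    Hp <- H + 2L * pad; Wp <- W + 2L * pad
    Ho <- (Hp - kh) %/% stride + 1L
    Wo <- (Wp - kw) %/% stride + 1L
    r0 <- (seq_len(Ho) - 1L) * stride          # 0-based top row per output
    c0 <- (seq_len(Wo) - 1L) * stride          # 0-based left col per output
    base <- outer(r0 + 1L, c0 * Hp, "+")       # flat index of tap (1,1)
    idx <- matrix(0L, Ho * Wo, kh * kw)
    t <- 1L
    for (kj in 0:(kw - 1L)) for (ki in 0:(kh - 1L)) {
        idx[, t] <- as.vector(base) + ki + kj * Hp
        t <- t + 1L
    }
    out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
    assign(key, out, envir = .idxCache)
    out
}

.pad3 <- function(x, pad) {
    if (pad == 0L) return(x)
    d <- dim(x)
    xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
    xp
}

## Forward convolution.  W is a (kh*kw*Cin) x Cout matrix with kernel taps
## fastest then input channel (matching the im2col column order); b length
## Cout.  Returns list(out, cache) where cache feeds convBackward.
convForward <- function(x, W, b, kh, stride, pad) {
    d <- dim(x); Cin <- d[3]
    g <- .convIdx(d[1], d[2], kh, kh, stride, pad)
    xp <- .pad3(x, pad)
    dim(xp) <- c(g$Hp * g$Wp, Cin)
    Xcol <- xp[as.vector(g$idx), , drop = FALSE]
    dim(Xcol) <- c(nrow(g$idx), kh * kh * Cin)
    Y <- Xcol %*% W
    Y <- sweep(Y, 2L, b, "+")
    dim(Y) <- c(g$Ho, g$Wo, ncol(W))
    list(out = Y, cache = list(Xcol = Xcol, g = g, dimIn = d,
                               kh = kh, stride = stride, pad = pad))
}

convBackward <- function(dY, W, cache) {
    g <- cache$g; d <- cache$dimIn
    kk <- cache$kh * cache$kh
    Cin <- d[3]
    dim(dY) <- c(nrow(g$idx), ncol(W))
    dW <- crossprod(cache$Xcol, dY)
    db <- colSums(dY)
    dXcol <- tcrossprod(dY, W)                  # nout x (kk*Cin)
    dim(dXcol) <- c(nrow(g$idx), kk, Cin)
    dMp <- matrix(0, g$Hp * g$Wp, Cin)
    for (t in seq_len(kk)) {
        ii <- g$idx[, t]
        dMp[ii, ] <- dMp[ii, ] + dXcol[, t, ]   # taps hit distinct cells
    }
    dim(dMp) <- c(g$Hp, g$Wp, Cin)
    p <- cache$pad
    dX <- if (p > 0L) dMp[p + seq_len(d[1]), p + seq_len(d[2]), ,
                          drop = FALSE] else dMp
    list(dX = dX, dW = dW, db = db)
}

reluForward <- function(x) {
    y <- x
    y[y < 0] <- 0
    y
}

reluBackward <- function(dY, x) {
    dY[x <= 0] <- 0
    dY
}

## Nearest-neighbour upsampling by integer factor f.
upForward <- function(x, f) {
    d <- dim(x)
    x[rep(seq_len(d[1]), each = f), rep(seq_len(d[2]), each = f), ,
      drop = FALSE]
}

upBackward <- function(dY, f) {
    d <- dim(dY)
    H <- d[1] %/% f; W <- d[2] %/% f; C <- d[3]
    dim(dY) <- c(f, H, f, W, C)
    s1 <- colSums(dY)                # (H, f, W, C)
    dX <- colSums(aperm(s1, c(2, 1, 3, 4)))
    dim(dX) <- c(H, W, C)
    dX
}

## Instance normalization: per-channel spatial standardization with learned
## scale (g) and shift (b).  Statistics are per sample, so training and
## inference behave identically and no running averages are needed.
inormForward <- function(x, g, b, eps = 1e-5) {
    d <- dim(x)
    N <- d[1] * d[2]
    dim(x) <- c(N, d[3])
    mu <- colMeans(x)
    xc <- sweep(x, 2L, mu)
    v <- colSums(xc^2) / N
    istd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, istd, "*")
    y <- sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
    dim(y) <- d
    list(out = y, cache = list(xhat = xhat, istd = istd, d = d))
}

inormBackward <- function(dY, g, cache) {
    d <- cache$d
    N <- d[1] * d[2]
    dim(dY) <- c(N, d[3])
    xhat <- cache$xhat
    dg <- colSums(dY * xhat)
    db <- colSums(dY)
    dxhat <- sweep(dY, 2L, g, "*")
    ## dX = istd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
    dX <- sweep(t1 - t2, 2L, cache$istd, "*")
    dim(dX) <- d
    list(dX = dX, dW = dg, db = db)
}

## He-style initialization for a conv weight matrix.
heInit <- function(kh, cin, cout, gain = 1) {
    fanin <- kh * kh * cin
    matrix(stats::rnorm(fanin * cout, sd = gain * sqrt(2 / fanin)),
           fanin, cout)
}
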