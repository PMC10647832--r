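## Small internal numerics shared across modules.

## 1D convolution with edge replication; kernel length 2r+1.
convolve1Replicate <- function(v, k) {
    r <- (length(k) - 1L) %/% 2L
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(vp[i:(i + 2L * r)] * k)
    out
}

## Separable 3D Gaussian smoothing with replicated edges; sigma in voxels.
gaussianSmooth3d <- function(x, sigma) {
    if (sigma <= 0) return(x)
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    k <- dnorm(seq(-r, r), sd = sigma)
    k <- k / sum(k)
    d <- dim(x)
    for (ax in 1:3) {
        x <- apply(x, setdiff(1:3, ax), convolve1Replicate, k = k)
        ## apply() returns the convolved axis first; rotate back into place
        x <- aperm(array(x, c(d[ax], d[setdiff(1:3, ax)])),
                   order(c(ax, setdiff(1:3, ax))))
    }
    x
}

## Stratified fold assignment for cross-validation; deterministic given the
## RNG state. Each class is shuffled and dealt round-robin over folds.
stratifiedFolds <- function(y, nfolds) {
    foldid <- integer(length(y))
    for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    foldid
}

## Ellipsoid mask on an integer grid; center and radii in voxel units.
ellipsoidMask <- function(gridShape, center, radii) {
    ix <- seq_len(gridShape[1])
    iy <- seq_len(gridShape[2])
    iz <- seq_len(gridShape[3])
    dx2 <- ((ix - center[1]) / radii[1])^2
    dy2 <- ((iy - center[2]) / radii[2])^2
    dz2 <- ((iz - center[3]) / radii[3])^2
    outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

## Sample standard deviation guarded against length-1 input.
safeSd <- function(x) if (length(x) < 2L) 0 else sd(x)

stopIfNot01 <- function(x, what) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
        stop(sprintf("%s must lie in [0, 1]; offending value(s): %s", what,
                     paste(format(head(x[!is.finite(x) | x < 0 | x > 1], 3)),
                           collapse = ", ")))
    invisible(x)
}
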