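# Independent brute-force oracles for the texture stack. These deliberately
# re-derive everything from the definitions with naive loops, sharing no
# code with the package implementation.

oracleRescale <- function(w) {
    lo <- min(w); hi <- max(w)
    if (hi == lo) return(array(0L, dim(w)))
    array(as.integer(floor((w - lo) / (hi - lo) * 255 + 0.5)), dim(w))
}

oracleGlcm <- function(win, nBins = 128L, offsets = glcmOffsets3d(),
                       symmetric = TRUE) {
    d <- dim(win)
    bin <- floor(win * nBins / 256)
    P <- matrix(0, nBins, nBins)
    for (k in seq_len(nrow(offsets))) {
        o <- offsets[k, ]
        for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
            x2 <- x + o[1]; y2 <- y + o[2]; z2 <- z + o[3]
            if (x2 >= 1 && x2 <= d[1] && y2 >= 1 && y2 <= d[2] &&
                z2 >= 1 && z2 <= d[3]) {
                i <- bin[x, y, z] + 1L; j <- bin[x2, y2, z2] + 1L
                P[i, j] <- P[i, j] + 1
                if (symmetric) P[j, i] <- P[j, i] + 1
            }
        }
    }
    P / sum(P)
}

oracleHaralick <- function(P) {
    n <- nrow(P)
    ene <- 0; ent <- 0; con <- 0; hom <- 0
    mui <- 0; muj <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
        p <- P[i, j]
        ene <- ene + p^2
        if (p > 0) ent <- ent - p * log(p)
        con <- con + (i - j)^2 * p
        hom <- hom + p / (1 + (i - j)^2)
        mui <- mui + i * p
        muj <- muj + j * p
    }
    vi <- 0; vj <- 0; cij <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
        p <- P[i, j]
        vi <- vi + (i - mui)^2 * p
        vj <- vj + (j - muj)^2 * p
        cij <- cij + (i - mui) * (j - muj) * p
    }
    cor <- if (vi > 0 && vj > 0) cij / sqrt(vi * vj) else 0
    c(con = con, cor = cor, ene = ene, ent = ent, hom = hom)
}

# All-pairs concordance oracle for the AUC (ties counted 1/2).
oracleAuc <- function(scores, labels) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (a in pos) for (b in neg)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
}
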