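## First- and second-order radiomic features.
##
## The canonical feature set is 162 variables per ROI: 3 sequences (t2, adc,
## b) x 6 feature families (intensity plus the five Haralick textures
## contrast, correlation, energy, entropy, homogeneity) x 9 histogram
## descriptors, over the three ROI roles L, NAPZ and NATZ (486 total), plus
## the lesion-mask volume ("HRS6") that every radiomics model carries.
## Texture is computed voxel-wise: a 5x5x5 window centered at each ROI voxel
## is locally rescaled to 0-255, binned into a 128-level 3D GLCM over the 13
## unique unit-displacement directions, symmetrized, normalized, and reduced
## to the five Haralick scalars; the per-voxel texture values over the ROI
## are then summarized by the same nine descriptors.

.ROI_ROLES <- c("L", "NAPZ", "NATZ")
.FEATURE_FAMILIES <- c("int", "con", "cor", "ene", "ent", "hom")
.TEXTURE_FAMILIES <- c("con", "cor", "ene", "ent", "hom")
.DESCRIPTORS <- c("10", "25", "50", "75", "90", "mean", "SD", "Kur", "Ske")

#' Canonical radiomic feature names
#'
#' Names are the concatenation `ROI_sequence_family_descriptor`, e.g.
#' `L_adc_ene_90` or `NATZ_t2_cor_50`, enumerated in deterministic order
#' (ROI, sequence, family, descriptor): 162 names per ROI, 486 over the
#' three ROI roles.
#'
#' @param roi ROI role(s) to enumerate; default all of `L`, `NAPZ`, `NATZ`.
#' @param intensityOnly If `TRUE`, restrict to the first-order (`int`)
#'   family.
#' @return Character vector of feature names.
#' @examples
#' length(featureNames())        # 486
#' length(featureNames("L"))     # 162
#' @export
featureNames <- function(roi = .ROI_ROLES, intensityOnly = FALSE) {
    roi <- match.arg(roi, .ROI_ROLES, several.ok = TRUE)
    fams <- if (intensityOnly) "int" else .FEATURE_FAMILIES
    out <- character(0)
    for (r in roi)
        for (s in mriSequences())
            for (f in fams)
                out <- c(out, paste(r, s, f, .DESCRIPTORS, sep = "_"))
    out
}

#' Full model feature-vector names: tumor volume plus the 486 radiomics
#'
#' @param intensityOnly Restrict radiomics to the first-order family.
#' @return Character vector; `"HRS6"` followed by [featureNames()].
#' @export
allFeatureNames <- function(intensityOnly = FALSE)
    c("HRS6", featureNames(intensityOnly = intensityOnly))

#' Nine histogram descriptors of a sample
#'
#' 10/25/50/75/90th percentiles (linear interpolation between order
#' statistics), mean, sample standard deviation, excess kurtosis and
#' skewness (standardized third/fourth central moments). For a degenerate
#' sample (zero variance), skewness and kurtosis are reported as 0.
#'
#' @param values Non-empty numeric vector of finite values.
#' @return Named numeric vector with names
#'   `10, 25, 50, 75, 90, mean, SD, Kur, Ske`.
#' @export
histogramDescriptors <- function(values) {
    values <- as.numeric(values)
    if (length(values) == 0L || any(!is.finite(values)))
        stop("histogramDescriptors needs at least one finite value and no NA/Inf")
    q <- quantile(values, c(.10, .25, .50, .75, .90), names = FALSE, type = 7)
    m <- mean(values)
    s <- safeSd(values)
    if (s > 0) {
        z <- values - m
        m2 <- mean(z^2)
        ske <- mean(z^3) / m2^1.5
        kur <- mean(z^4) / m2^2 - 3
    } else {
        ske <- 0
        kur <- 0
    }
    setNames(c(q, m, s, kur, ske), .DESCRIPTORS)
}

#' Rescale a local window to integer grey levels 0-255
#'
#' Affine map sending the window minimum to 0 and maximum to 255, rounded
#' half-away-from-zero; a constant window maps to all zeros.
#'
#' @param window Numeric vector or array of window intensities.
#' @return Integer values in 0..255, same shape as the input.
#' @export
rescaleWindow <- function(window) {
    lo <- min(window)
    hi <- max(window)
    out <- window
    if (hi > lo) {
        out[] <- as.integer(floor((window - lo) / (hi - lo) * 255 + 0.5))
    } else {
        out[] <- 0L
    }
    out
}

#' Unit-displacement offsets for a 3D GLCM
#'
#' The 13 unique direction classes of the 26-neighborhood (one of each
#' antipodal pair); with symmetrization this covers all 26 neighbors.
#'
#' @return Integer matrix, 13 rows x 3 columns.
#' @export
glcmOffsets3d <- function() {
    m <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
               c(0, 1, 1), c(0, 1, -1),
               c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
    storage.mode(m) <- "integer"
    m
}

#' 3D grey-level co-occurrence matrix of a window
#'
#' Counts co-occurring grey-level bin pairs over all voxel pairs of the
#' window separated by each offset, optionally symmetrized, and normalizes
#' the counts to sum 1. Grey levels 0..255 are mapped to `nBins` bins as
#' `floor(level * nBins / 256)` (i.e. `floor(level / 2)` for the default
#' 128 bins).
#'
#' @param window 3D integer array of grey levels in 0..255 (see
#'   [rescaleWindow()]).
#' @param nBins Number of grey-level bins (default 128).
#' @param offsets Integer matrix of displacement vectors, one per row.
#' @param symmetric Count each pair in both orders (default `TRUE`).
#' @return `nBins x nBins` matrix of co-occurrence probabilities.
#' @export
glcm3d <- function(window, nBins = 128L, offsets = glcmOffsets3d(),
                   symmetric = TRUE) {
    if (is.null(dim(window)) || length(dim(window)) != 3L)
        stop("window must be a 3D array")
    if (nrow(offsets) == 0L) stop("offset set must not be empty")
    if (any(window < 0) || any(window > 255))
        stop("window grey levels must lie in 0..255")
    d <- dim(window)
    bins <- floor(window * nBins / 256)
    P <- matrix(0, nBins, nBins)
    for (k in seq_len(nrow(offsets))) {
        o <- offsets[k, ]
        xr <- seq(max(1, 1 - o[1]), min(d[1], d[1] - o[1]))
        yr <- seq(max(1, 1 - o[2]), min(d[2], d[2] - o[2]))
        zr <- seq(max(1, 1 - o[3]), min(d[3], d[3] - o[3]))
        if (!length(xr) || !length(yr) || !length(zr)) next
        a <- bins[xr, yr, zr, drop = FALSE]
        b <- bins[xr + o[1], yr + o[2], zr + o[3], drop = FALSE]
        for (i in seq_along(a)) {
            P[a[i] + 1L, b[i] + 1L] <- P[a[i] + 1L, b[i] + 1L] + 1
            if (symmetric) P[b[i] + 1L, a[i] + 1L] <- P[b[i] + 1L, a[i] + 1L] + 1
        }
    }
    tot <- sum(P)
    if (tot == 0) stop("no voxel pairs available for the given offsets")
    P / tot
}

#' Haralick texture scalars of a normalized GLCM
#'
#' Energy \eqn{\sum p^2}, entropy \eqn{-\sum p \log p} (natural log over
#' positive entries), contrast \eqn{\sum (i-j)^2 p}, homogeneity
#' \eqn{\sum p / (1 + (i-j)^2)} and correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j) p / (\sigma_i \sigma_j)}. When either
#' marginal has zero variance the correlation is defined as 0.
#'
#' @param glcm Square nonnegative matrix summing to 1.
#' @param entropyBase Base for the entropy logarithm (default `exp(1)`).
#' @return Named numeric vector `con, cor, ene, ent, hom`.
#' @export
haralickFeatures <- function(glcm, entropyBase = exp(1)) {
    if (abs(sum(glcm) - 1) > 1e-8)
        stop("GLCM must be normalized to sum 1")
    n <- nrow(glcm)
    i <- row(glcm)
    j <- col(glcm)
    ene <- sum(glcm^2)
    pos <- glcm > 0
    ent <- -sum(glcm[pos] * log(glcm[pos], base = entropyBase))
    con <- sum((i - j)^2 * glcm)
    hom <- sum(glcm / (1 + (i - j)^2))
    pi_ <- rowSums(glcm)
    pj_ <- colSums(glcm)
    mui <- sum(seq_len(n) * pi_)
    muj <- sum(seq_len(n) * pj_)
    vi <- sum((seq_len(n) - mui)^2 * pi_)
    vj <- sum((seq_len(n) - muj)^2 * pj_)
    cor <- if (vi > 0 && vj > 0)
        sum((i - mui) * (j - muj) * glcm) / sqrt(vi * vj) else 0
    c(con = con, cor = cor, ene = ene, ent = ent, hom = hom)
}

#' Voxel-wise Haralick texture maps over an ROI
#'
#' For every ROI voxel, a window centered at the voxel is taken from the
#' full image (context outside the ROI is used), locally rescaled to 0-255,
#' reduced to a symmetrized 3D GLCM and then to the five Haralick scalars.
#' Windows are clipped at the image boundary (partial windows are allowed;
#' the smallest, at a corner, holds 27 voxels for the default 5x5x5
#' window).
#'
#' @param volume A [VolumeGrid] (normalized where applicable).
#' @param roi A [RoiMask] on the same grid with at least one voxel.
#' @param windowSize Odd window edge length in voxels (default 5).
#' @param nBins GLCM grey-level bins (default 128).
#' @param offsets Displacement set (default [glcmOffsets3d()]).
#' @param symmetric Symmetrize the GLCM (default `TRUE`).
#' @return Numeric matrix, one row per ROI voxel (in array order of the
#'   mask), columns `con, cor, ene, ent, hom`.
#' @export
textureMaps <- function(volume, roi, windowSize = 5L, nBins = 128L,
                        offsets = glcmOffsets3d(), symmetric = TRUE) {
    stopifnot(is(volume, "VolumeGrid"), is(roi, "RoiMask"))
    vals <- gridValues(volume)
    m <- maskArray(roi)
    if (!identical(dim(m), dim(vals)))
        stop("ROI mask shape does not match the volume grid")
    if (!any(m)) stop("ROI mask is empty")
    if (windowSize %% 2L != 1L || windowSize < 3L)
        stop("windowSize must be an odd integer >= 3")
    if (any(dim(vals) < 3L)) stop("volume must be at least 3 voxels along each axis")
    if (nrow(offsets) == 0L) stop("offset set must not be empty")
    vox <- which(m, arr.ind = TRUE)
    storage.mode(vox) <- "integer"
    out <- texture_maps_cpp(as.numeric(vals), as.integer(dim(vals)), vox,
                            as.integer((windowSize - 1L) %/% 2L),
                            as.integer(nBins), offsets, isTRUE(symmetric))
    colnames(out) <- .TEXTURE_FAMILIES
    out
}

#' Lesion-mask ("HRS6") volume in cubic centimeters
#'
#' @param mask A [RoiMask].
#' @param spacing Voxel spacing in mm (length 3).
#' @return Volume of the set voxels in cc.
#' @export
hrs6Volume <- function(mask, spacing) {
    sum(maskArray(mask)) * prod(spacing) / 1000
}

#' Extract the 162 radiomic features of one ROI
#'
#' First-order (`int`) descriptors are computed from the in-ROI intensities
#' of each (normalized) sequence; each texture family's descriptors from
#' its voxel-wise texture map over the ROI.
#'
#' @param study A normalized [MpmriStudy].
#' @param roi A [RoiMask] with role `L`, `NAPZ` or `NATZ`.
#' @param minVoxels Smallest ROI accepted for extraction (default 10).
#' @param windowSize,nBins,offsets,symmetric Texture parameters, see
#'   [textureMaps()].
#' @return Named numeric vector of the 162 canonical features for the
#'   ROI's role.
#' @export
extractRoiFeatures <- function(study, roi, minVoxels = 10L, windowSize = 5L,
                               nBins = 128L, offsets = glcmOffsets3d(),
                               symmetric = TRUE) {
    role <- maskRole(roi)
    if (!role %in% .ROI_ROLES)
        stop(sprintf("features are extracted for roles %s, not '%s'",
                     paste(.ROI_ROLES, collapse = "/"), role))
    nvox <- sum(maskArray(roi))
    if (nvox < minVoxels)
        stop(sprintf("ROI '%s' has %d voxel(s); at least %d are required",
                     role, nvox, minVoxels))
    out <- numeric(0)
    for (s in mriSequences()) {
        vol <- studyVolumes(study)[[s]]
        tex <- textureMaps(vol, roi, windowSize, nBins, offsets, symmetric)
        for (f in .FEATURE_FAMILIES) {
            vals <- if (f == "int") gridValues(vol)[maskArray(roi)] else tex[, f]
            d <- histogramDescriptors(vals)
            names(d) <- paste(role, s, f, .DESCRIPTORS, sep = "_")
            out <- c(out, d)
        }
    }
    out
}

#' Extract the full 487-value feature vector for one lesion of an exam
#'
#' Combines the lesion ROI, NAPZ and NATZ radiomics (486 features) with the
#' lesion-mask volume (`HRS6`, in cc).
#'
#' @param study A normalized [MpmriStudy].
#' @param lesion Lesion id; may be omitted when the study has one lesion.
#' @param ... Passed to [extractRoiFeatures()].
#' @return Named numeric vector over [allFeatureNames()].
#' @export
extractFeatures <- function(study, lesion = NULL, ...) {
    L <- getMask(study, "L", lesion)
    out <- c(HRS6 = hrs6Volume(L, voxelSpacing(studyVolumes(study)$t2)),
             extractRoiFeatures(study, L, ...),
             extractRoiFeatures(study, getMask(study, "NAPZ"), ...),
             extractRoiFeatures(study, getMask(study, "NATZ"), ...))
    stopifnot(identical(names(out), allFeatureNames()))
    out
}
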