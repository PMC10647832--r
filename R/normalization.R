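## Reference-tissue intensity normalization.
##
## T2-weighted volumes are mapped through a monotone spline anchored at the
## origin and at (measured reference-tissue mean, fixed target) knots for
## gluteus maximus, femoral head and bladder. High b-value volumes are
## rescaled so the gluteus-maximus mean hits its target. ADC maps are used
## in native units and pass through untouched.

#' Reference targets for intensity normalization
#'
#' Fixed values that the mean intensity of each reference tissue is mapped
#' to. The scanner-arbitrary T2-weighted scale is anchored by three tissues
#' of increasing brightness; the high b-value scale by gluteus maximus
#' alone. The specific values are conventions: downstream features only
#' rely on all exams sharing one scale.
#'
#' @param t2 Named numeric vector of targets for `GM`, `femoral_head` and
#'   `bladder` on the T2-weighted scale; must be strictly increasing in
#'   brightness order and positive.
#' @param b Single positive target for the `GM` mean on the b-value scale.
#' @param method Interpolation family for the T2 map: `"monotone"`
#'   (monotone piecewise-cubic Hermite spline) or `"linear"` (piecewise
#'   linear), both through the origin with linear extrapolation above the
#'   largest knot.
#' @return A list of class `referenceTargets`.
#' @export
referenceTargets <- function(t2 = c(GM = 100, femoral_head = 300, bladder = 1000),
                             b = 100, method = c("monotone", "linear")) {
    method <- match.arg(method)
    need <- c("GM", "femoral_head", "bladder")
    if (!all(need %in% names(t2)))
        stop("t2 targets must name GM, femoral_head and bladder")
    t2 <- t2[need]
    if (any(t2 <= 0) || b <= 0) stop("all reference targets must be > 0")
    structure(list(t2 = t2, b = as.numeric(b), method = method),
              class = "referenceTargets")
}

## Monotone map through (0,0) and the supplied knots, linear above the last
## knot. Input below zero is clamped to the origin anchor.
.referenceMap <- function(knotX, knotY, method) {
    x <- c(0, knotX)
    y <- c(0, knotY)
    if (method == "monotone") {
        f <- splinefun(x, y, method = "hyman")
        xmax <- max(x)
        slope <- f(xmax, deriv = 1)
        ymax <- f(xmax)
        function(v) {
            v <- pmax(v, 0)
            out <- f(pmin(v, xmax))
            hi <- v > xmax
            if (any(hi)) out[hi] <- ymax + slope * (v[hi] - xmax)
            out
        }
    } else {
        n <- length(x)
        slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
        function(v) {
            v <- pmax(v, 0)
            out <- approx(x, y, xout = pmin(v, x[n]))$y
            hi <- v > x[n]
            if (any(hi)) out[hi] <- y[n] + slope * (v[hi] - x[n])
            out
        }
    }
}

.maskMean <- function(volume, mask, what) {
    m <- maskArray(mask)
    if (!identical(dim(m), dim(gridValues(volume))))
        stop(sprintf("%s mask shape does not match the volume grid", what))
    if (!any(m)) stop(sprintf("%s reference mask is empty", what))
    mean(gridValues(volume)[m])
}

#' Multireference spline normalization of a T2-weighted volume
#'
#' Measures the mean intensity inside the gluteus maximus, femoral head and
#' bladder masks and fits a monotone interpolating map through the origin
#' and the three (measured mean, target) pairs; the map is applied
#' voxel-wise. After normalization each reference-tissue mean equals its
#' target exactly, the map is order preserving, and re-normalizing is a
#' no-op (the knots become fixed points).
#'
#' @param volume A [VolumeGrid] with sequence `"t2"`.
#' @param masks Named list with [RoiMask] entries `GM`, `femoral_head`,
#'   `bladder`.
#' @param targets A [referenceTargets] object.
#' @return The normalized [VolumeGrid].
#' @seealso [normalizeB()], [normalizeStudy()]
#' @export
normalizeT2 <- function(volume, masks, targets = referenceTargets()) {
    stopifnot(is(volume, "VolumeGrid"))
    if (sequenceType(volume) != "t2")
        stop("normalizeT2 expects a t2 volume")
    roles <- names(targets$t2)
    measured <- vapply(roles, function(r) {
        if (is.null(masks[[r]])) stop(sprintf("missing reference mask '%s'", r))
        .maskMean(volume, masks[[r]], r)
    }, numeric(1))
    ord <- order(measured)
    mx <- measured[ord]
    ty <- targets$t2[ord]
    if (any(diff(mx) <= 0)) {
        dup <- roles[ord][c(FALSE, diff(mx) <= 0)]
        stop(sprintf("reference tissue means collide (%s); the intensity map would not be single-valued",
                     paste(dup, collapse = ", ")))
    }
    if (any(diff(ty) <= 0))
        stop(sprintf("reference targets are not monotone in the measured-intensity order (%s)",
                     paste(roles[ord], collapse = " < ")))
    f <- .referenceMap(mx, ty, targets$method)
    out <- gridValues(volume)
    out[] <- f(as.vector(out))
    VolumeGrid(out, voxelSpacing(volume), "t2")
}

#' Gluteus-maximus-referenced normalization of a high b-value volume
#'
#' Rescales the volume by `gmTarget / mean(volume[GM])`, so the
#' gluteus-maximus mean equals its target exactly.
#'
#' @param volume A [VolumeGrid] with sequence `"b"`.
#' @param gmMask Gluteus maximus [RoiMask].
#' @param gmTarget Positive target for the GM mean.
#' @return The normalized [VolumeGrid].
#' @export
normalizeB <- function(volume, gmMask, gmTarget = 100) {
    stopifnot(is(volume, "VolumeGrid"))
    if (sequenceType(volume) != "b")
        stop("normalizeB expects a high b-value volume")
    m <- .maskMean(volume, gmMask, "GM")
    if (m <= 0) stop("GM mean intensity must be positive for b-value normalization")
    VolumeGrid(gridValues(volume) * (gmTarget / m), voxelSpacing(volume), "b")
}

#' Normalize all sequences of an exam
#'
#' Applies [normalizeT2()] and [normalizeB()] using the study's own
#' reference masks; the ADC map is kept in native units.
#'
#' @param study An [MpmriStudy].
#' @param targets A [referenceTargets] object.
#' @return The study with normalized `t2` and `b` volumes.
#' @export
normalizeStudy <- function(study, targets = referenceTargets()) {
    refs <- list(GM = getMask(study, "GM"),
                 femoral_head = getMask(study, "femoral_head"),
                 bladder = getMask(study, "bladder"))
    vols <- studyVolumes(study)
    vols$t2 <- normalizeT2(vols$t2, refs, targets)
    vols$b <- normalizeB(vols$b, refs$GM, targets$b)
    MpmriStudy(patientId(study), examId(study), vols, studyMasks(study))
}
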