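## Synthetic phantom cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes: two
## lesion classes (low vs intermediate/high clinical-genomic risk) where
## non-low lesions have lower T2 and ADC intensity, higher b-value
## intensity, larger volume and shorter-range texture; class-correlated
## clinical variables (DRE positivity concentrated in non-low patients);
## and class-conditional Decipher scores. Geometry is deliberately
## schematic: piecewise-constant tissue zones (peripheral/transition zone,
## gluteus maximus, femoral head, bladder) with Gaussian noise, ellipsoidal
## lesions with jittered radii, and per-exam multiplicative intensity gains
## on the scanner-arbitrary T2W and BVAL scales that the normalization
## stage must undo.

#' Configuration of a synthetic phantom cohort
#'
#' Defaults are the package's reference study conditions. Mean-shift effect
#' sizes are expressed on the normalized intensity scale (the phantom's
#' pre-gain reference scale coincides with the normalization targets
#' GM = 100, femoral head = 300, bladder = 1000 for T2W and GM = 100 for
#' BVAL; ADC is native).
#'
#' @param nPatients Number of patients (>= 1).
#' @param lesionProbs Probabilities of 1..5 lesions per patient.
#' @param fracLowRisk Proportion of low-risk lesions.
#' @param gridShape Voxels per axis (length 3).
#' @param voxelSpacing mm per axis (length 3).
#' @param effectSizes Named mean shifts (`t2`, `adc`, `b`) added inside
#'   non-low lesion masks, in normalized units.
#' @param natEffectSizes Same, applied inside NAPZ/NATZ for non-low
#'   patients (the "lesion environment" signal).
#' @param betweenLesionSd Named per-sequence SD of the lesion-level random
#'   intensity shift shared by all voxels of a lesion; this is the
#'   biological between-lesion variability that makes the classes overlap
#'   (without it any nonzero mean shift would be perfectly separable after
#'   ROI averaging).
#' @param textureEffect Difference in Gaussian correlation length (voxels)
#'   of in-mask texture noise between classes: low-risk lesions are
#'   smoothed with `0.4 + textureEffect` on average, non-low with `0.4`.
#' @param textureJitterSd Between-lesion SD of the texture correlation
#'   length around its class mean.
#' @param volumeEffect Relative lesion radius increase for non-low lesions
#'   (0 = equal volumes).
#' @param noiseSd Named per-sequence Gaussian noise SD.
#' @param dreRates Named probabilities of a positive DRE for `low` and
#'   `nonlow` patients.
#' @param decipherParams List with `low` and `nonlow` Beta shape pairs for
#'   class-conditional Decipher scores.
#' @param clinicalEffects List with `psadShift` and `piradsShift` in
#'   \[0, 1\]: 0 makes the variable class-independent, 1 fully
#'   class-shifted.
#' @param duplicateExamRate Probability that a patient contributes a second
#'   exam of the same lesions (new noise and gains).
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   config.
#' @return A `CohortConfig` object.
#' @export
cohortConfig <- function(nPatients = 60L,
                         lesionProbs = c(.32, .13, .26, .12, .18),
                         fracLowRisk = 0.58,
                         gridShape = c(36L, 36L, 20L),
                         voxelSpacing = c(1.5, 1.5, 3),
                         effectSizes = c(t2 = -25, adc = -120, b = 15),
                         natEffectSizes = c(t2 = -8, adc = -40, b = 5),
                         betweenLesionSd = c(t2 = 25, adc = 140, b = 15),
                         textureEffect = 0.7,
                         textureJitterSd = 0.4,
                         volumeEffect = 0.25,
                         noiseSd = c(t2 = 18, adc = 60, b = 9),
                         dreRates = c(low = 0.02, nonlow = 0.70),
                         decipherParams = list(low = c(2, 4), nonlow = c(5, 3)),
                         clinicalEffects = list(psadShift = 1, piradsShift = 1),
                         duplicateExamRate = 0,
                         seed = 1L) {
    new("CohortConfig",
        nPatients = as.integer(nPatients),
        lesionProbs = lesionProbs / sum(lesionProbs),
        fracLowRisk = fracLowRisk,
        gridShape = as.integer(gridShape),
        voxelSpacing = as.numeric(voxelSpacing),
        effectSizes = effectSizes[c("t2", "adc", "b")],
        natEffectSizes = natEffectSizes[c("t2", "adc", "b")],
        betweenLesionSd = betweenLesionSd[c("t2", "adc", "b")],
        textureEffect = textureEffect,
        textureJitterSd = textureJitterSd,
        volumeEffect = volumeEffect,
        noiseSd = noiseSd[c("t2", "adc", "b")],
        dreRates = dreRates[c("low", "nonlow")],
        decipherParams = decipherParams,
        clinicalEffects = clinicalEffects,
        duplicateExamRate = duplicateExamRate,
        seed = as.integer(seed))
}

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (object@nPatients < 1L) msg <- c(msg, "nPatients must be >= 1")
    if (length(object@lesionProbs) != 5L || any(object@lesionProbs < 0))
        msg <- c(msg, "lesionProbs must be 5 nonnegative probabilities")
    if (!is.finite(object@fracLowRisk) || object@fracLowRisk < 0 ||
        object@fracLowRisk > 1)
        msg <- c(msg, "fracLowRisk must lie in [0, 1]")
    if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
        msg <- c(msg, "gridShape must be 3 axis sizes of at least 8 voxels")
    if (length(object@voxelSpacing) != 3L || any(object@voxelSpacing <= 0))
        msg <- c(msg, "voxelSpacing components must be > 0")
    if (anyNA(object@effectSizes) || anyNA(object@natEffectSizes))
        msg <- c(msg, "effect sizes must name t2, adc and b")
    if (any(object@dreRates < 0) || any(object@dreRates > 1) ||
        anyNA(object@dreRates))
        msg <- c(msg, "dreRates must be probabilities named low and nonlow")
    if (object@textureEffect < 0) msg <- c(msg, "textureEffect must be >= 0")
    if (anyNA(object@betweenLesionSd) || any(object@betweenLesionSd < 0))
        msg <- c(msg, "betweenLesionSd must be nonnegative and name t2, adc and b")
    if (object@textureJitterSd < 0) msg <- c(msg, "textureJitterSd must be >= 0")
    if (object@volumeEffect < 0) msg <- c(msg, "volumeEffect must be >= 0")
    if (object@duplicateExamRate < 0 || object@duplicateExamRate > 1)
        msg <- c(msg, "duplicateExamRate must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

## Pre-gain zone mean intensities per sequence. The T2W and BVAL reference
## tissues sit exactly at the default normalization targets so that the
## configured effect sizes read in normalized units.
.zoneMeans <- list(
    t2  = c(background = 60, TZ = 180, PZ = 240, GM = 100,
            femoral_head = 300, bladder = 1000),
    adc = c(background = 800, TZ = 1100, PZ = 1300, GM = 700,
            femoral_head = 600, bladder = 2800),
    b   = c(background = 30, TZ = 70, PZ = 90, GM = 100,
            femoral_head = 40, bladder = 20))

## Fixed structural geometry for a grid; all sites scale with the grid.
.cohortGeometry <- function(gridShape) {
    g <- gridShape
    sc <- function(f) f * g
    list(
        tz = list(center = sc(c(.50, .47, .50)), radii = pmax(sc(c(.19, .14, .25)), 1.2)),
        pz = list(center = sc(c(.50, .55, .50)), radii = pmax(sc(c(.28, .22, .35)), 1.6)),
        gm = list(center = sc(c(.10, .12, .50)), radii = pmax(sc(c(.07, .09, .18)), 1.2)),
        femoral_head = list(center = sc(c(.90, .14, .50)), radii = pmax(sc(c(.07, .07, .10)), 1.2)),
        bladder = list(center = sc(c(.50, .88, .72)), radii = pmax(sc(c(.14, .10, .15)), 1.2)),
        napz = list(center = sc(c(.50, .74, .50)), radii = pmax(sc(c(.07, .065, .08)), 1.2)),
        natz = list(center = sc(c(.50, .47, .50)), radii = pmax(sc(c(.07, .065, .08)), 1.2)))
}

#' Embed a lesion signal into a volume
#'
#' Adds, inside the mask only, a constant mean shift plus zero-mean texture
#' noise: white Gaussian noise smoothed with an isotropic Gaussian filter
#' of width `correlationLength` (in voxels), rescaled to standard deviation
#' `noiseSd` and centered so the in-mask mean shift equals `meanShift`
#' exactly. Voxels outside the mask are untouched; with zero shift and zero
#' noise the volume is returned unchanged.
#'
#' @param volume A [VolumeGrid].
#' @param mask A non-empty [RoiMask] aligned to the volume.
#' @param meanShift Constant added inside the mask.
#' @param noiseSd Standard deviation of the texture noise.
#' @param correlationLength Gaussian filter sigma of the texture noise, in
#'   voxels (0 = white noise).
#' @return The modified [VolumeGrid].
#' @export
embedLesion <- function(volume, mask, meanShift = 0, noiseSd = 0,
                        correlationLength = 0) {
    stopifnot(is(volume, "VolumeGrid"), is(mask, "RoiMask"))
    m <- maskArray(mask)
    if (!identical(dim(m), dim(gridValues(volume))))
        stop("mask is not aligned to the volume grid")
    if (!any(m)) stop("cannot embed a lesion with an empty mask")
    vals <- gridValues(volume)
    if (meanShift == 0 && noiseSd == 0) return(volume)
    add <- rep(meanShift, sum(m))
    if (noiseSd > 0) {
        idx <- which(m, arr.ind = TRUE)
        lo <- apply(idx, 2, min)
        hi <- apply(idx, 2, max)
        pad <- 3L
        bdim <- hi - lo + 1L + 2L * pad
        noise <- array(rnorm(prod(bdim)), bdim)
        noise <- gaussianSmooth3d(noise, correlationLength)
        s <- sd(noise)
        if (s > 0) noise <- noise / s * noiseSd
        sel <- noise[cbind(idx[, 1] - lo[1] + 1L + pad,
                           idx[, 2] - lo[2] + 1L + pad,
                           idx[, 3] - lo[3] + 1L + pad)]
        add <- add + (sel - mean(sel))
    }
    vals[m] <- vals[m] + add
    VolumeGrid(vals, voxelSpacing(volume), sequenceType(volume))
}

## Draw lesion grade group / Decipher / core percentage consistent with the
## intended class, given the patient's stage and PSA. Rejection sampling
## against the actual labeling rule guarantees ground truth == label.
.drawLesionPathology <- function(class, tStage, psa, decipherParams) {
    for (i in 1:500) {
        if (class == "low") {
            gg <- 1L
            cores <- runif(1, 0.05, 0.45)
            dec <- rbeta(1, decipherParams$low[1], decipherParams$low[2])
        } else {
            gg <- sample(c(2L, 3L, 4L, 5L), 1, prob = c(.40, .20, .22, .18))
            cores <- runif(1, 0.15, 0.9)
            dec <- rbeta(1, decipherParams$nonlow[1], decipherParams$nonlow[2])
        }
        lab <- sprattLabels(nccnGroup(tStage, gg, psa, cores),
                            decipherCategory(dec))
        if (lab$low_risk == (class == "low"))
            return(list(grade_group = gg, pct_positive_cores = cores,
                        decipher = dec, label = lab))
    }
    stop("could not draw pathology consistent with the intended class")
}

.buildBaseVolume <- function(seq, geom, gridShape, spacing, noiseSd, zoneMasks) {
    zm <- .zoneMeans[[seq]]
    vals <- array(zm["background"], gridShape)
    for (z in c("TZ", "PZ", "GM", "femoral_head", "bladder"))
        vals[zoneMasks[[z]]] <- zm[z]
    vals <- vals + rnorm(length(vals), sd = noiseSd)
    VolumeGrid(vals, spacing, seq)
}

#' Generate a synthetic phantom cohort
#'
#' Produces, deterministically from the config, a list of [MpmriStudy]
#' exams (raw, un-normalized intensities with per-exam T2W/BVAL gains) and
#' a per-lesion table of clinical variables, Decipher score and
#' ground-truth class. Clinical variables and Decipher scores are drawn
#' from class-conditional distributions that are consistent with the risk
#' labeling rule by construction, so `true_class` always equals the label
#' recomputed by [scoreCohort()].
#'
#' @param config A [cohortConfig()] object.
#' @param seed Optional integer overriding `config@seed`.
#' @return An `MpmriCohort`; see [cohortStudies()] and [cohortLesions()].
#' @examples
#' coh <- generateCohort(cohortConfig(nPatients = 2, seed = 7))
#' coh
#' @export
generateCohort <- function(config, seed = NULL) {
    validObject(config)
    set.seed(if (is.null(seed)) config@seed else as.integer(seed))
    g <- config@gridShape
    sp <- config@voxelSpacing
    geom <- .cohortGeometry(g)
    zoneMasks <- list(
        TZ = ellipsoidMask(g, geom$tz$center, geom$tz$radii),
        GM = ellipsoidMask(g, geom$gm$center, geom$gm$radii),
        femoral_head = ellipsoidMask(g, geom$femoral_head$center, geom$femoral_head$radii),
        bladder = ellipsoidMask(g, geom$bladder$center, geom$bladder$radii))
    zoneMasks$PZ <- ellipsoidMask(g, geom$pz$center, geom$pz$radii) & !zoneMasks$TZ
    napz <- ellipsoidMask(g, geom$napz$center, geom$napz$radii) & zoneMasks$PZ
    natz <- ellipsoidMask(g, geom$natz$center, geom$natz$radii) & zoneMasks$TZ
    for (nm in c("GM", "femoral_head", "bladder"))
        if (!any(zoneMasks[[nm]]))
            stop(sprintf("grid %s is too small to place the %s reference mask",
                         paste(g, collapse = "x"), nm))
    if (sum(napz) < 10L || sum(natz) < 10L)
        stop(sprintf("grid %s is too small to place NAPZ/NATZ masks of usable size",
                     paste(g, collapse = "x")))

    ## lesion centers must keep the lesion ellipsoid inside the grid and
    ## clear of the NAPZ/NATZ sites
    maxR <- 5.6 * (1 + config@volumeEffect) / min(sp) + 1
    pzIdx <- which(zoneMasks$PZ, arr.ind = TRUE)
    dNapz <- sqrt(rowSums(sweep(pzIdx, 2, geom$napz$center)^2))
    dNatz <- sqrt(rowSums(sweep(pzIdx, 2, geom$natz$center)^2))
    fits <- pzIdx[, 1] > maxR & pzIdx[, 1] <= g[1] - maxR &
        pzIdx[, 2] > maxR & pzIdx[, 2] <= g[2] - maxR &
        pzIdx[, 3] > 1.5 & pzIdx[, 3] <= g[3] - 0.5 &
        dNapz > maxR + max(geom$napz$radii) &
        dNatz > maxR + max(geom$natz$radii)
    centers <- pzIdx[fits, , drop = FALSE]
    if (nrow(centers) == 0L)
        stop(sprintf(
            "grid %s is too small to place lesion masks clear of the NAPZ/NATZ sites (max lesion radius %.1f voxels)",
            paste(g, collapse = "x"), maxR))

    studies <- list()
    rows <- list()
    for (p in seq_len(config@nPatients)) {
        pid <- sprintf("P%03d", p)
        nLes <- sample(1:5, 1, prob = config@lesionProbs)
        ## lesion classes are correlated within a patient: a latent patient
        ## type (all-low vs mixed) mirrors the low-risk / higher-risk trial
        ## arms of a real cohort and is what makes patient-level variables
        ## such as DRE informative for individual lesions
        targetNonlow <- 1 - config@fracLowRisk
        rLes <- 0.75
        if (targetNonlow <= rLes) {
            pType <- targetNonlow / rLes
        } else {
            pType <- 1
            rLes <- targetNonlow
        }
        classes <- if (runif(1) < pType)
            ifelse(runif(nLes) < rLes, "nonlow", "low")
        else rep("low", nLes)
        patientClass <- if (any(classes == "nonlow")) "nonlow" else "low"
        hasLow <- any(classes == "low")

        age <- round(min(max(rnorm(1, 65, 8), 44), 82))
        prostVol <- min(max(rnorm(1, 45, 12), 15), 120)
        wPsad <- config@clinicalEffects$psadShift
        if (hasLow || patientClass == "low") {
            tStage <- "T1c"
            psa <- runif(1, 3, 9)
        } else {
            tStage <- sample(c("T1c", "T2a", "T2b", "T2c", "T3a"), 1,
                             prob = c(.35, .15, .15, .15, .20))
            psa <- if (wPsad > 0)
                min(max(exp(rnorm(1, log(6 + 8 * wPsad), 0.45)), 1.5), 77)
            else runif(1, 3, 9)
        }
        psad <- psa / prostVol
        wPir <- config@clinicalEffects$piradsShift
        bp <- c(.15, .2, .2, .25, .2)
        cp <- if (patientClass == "low") c(.30, .25, .20, .15, .10)
              else c(.02, .08, .10, .35, .45)
        pirads <- sample(1:5, 1, prob = (1 - wPir) * bp + wPir * cp)
        dre <- if (rbinom(1, 1, config@dreRates[[patientClass]]) == 1L)
            sample(1:2, 1, prob = c(.78, .22)) else 0L

        ## lesion geometry, per-lesion biological jitters and pathology
        lesionInfo <- vector("list", nLes)
        for (l in seq_len(nLes)) {
            cls <- classes[l]
            rmm <- 4.0 * (1 + config@volumeEffect * (cls == "nonlow")) *
                exp(rnorm(1, 0, 0.18))
            radii <- pmax(rmm * runif(3, 0.85, 1.2) / sp, 1.05)
            ctr <- centers[sample(nrow(centers), 1), ]
            mask <- ellipsoidMask(g, ctr, radii)
            ## discretization can make a small ellipsoid unusable for
            ## extraction; grow it until it holds at least 10 voxels
            while (sum(mask) < 10L) {
                radii <- radii * 1.15
                mask <- ellipsoidMask(g, ctr, radii)
            }
            path <- .drawLesionPathology(cls, tStage, psa, config@decipherParams)
            shifts <- vapply(mriSequences(), function(s)
                config@effectSizes[[s]] * (cls == "nonlow") +
                    rnorm(1, 0, config@betweenLesionSd[[s]]), numeric(1))
            sigma <- max(0.05, 0.4 + config@textureEffect * (cls == "low") +
                         rnorm(1, 0, config@textureJitterSd))
            lesionInfo[[l]] <- list(class = cls, mask = mask, radius_mm = rmm,
                                    path = path, shifts = shifts, sigma = sigma)
        }
        ## per-patient NAT signal (environment of the worst lesion class)
        natShifts <- vapply(mriSequences(), function(s)
            config@natEffectSizes[[s]] * (patientClass == "nonlow") +
                rnorm(1, 0, 0.7 * config@betweenLesionSd[[s]]), numeric(1))
        natSigma <- max(0.05, 0.4 + config@textureEffect * (patientClass == "low") +
                        rnorm(1, 0, config@textureJitterSd))

        nExams <- 1L + (runif(1) < config@duplicateExamRate)
        for (e in seq_len(nExams)) {
            eid <- sprintf("%s_E%d", pid, e)
            gainT2 <- runif(1, 0.7, 1.4)
            gainB <- runif(1, 0.7, 1.4)
            vols <- list()
            for (s in mriSequences()) {
                v <- .buildBaseVolume(s, geom, g, sp, config@noiseSd[[s]], zoneMasks)
                for (l in seq_len(nLes))
                    v <- embedLesion(v, RoiMask(lesionInfo[[l]]$mask, "L"),
                                     meanShift = lesionInfo[[l]]$shifts[[s]],
                                     noiseSd = 1.5 * config@noiseSd[[s]],
                                     correlationLength = lesionInfo[[l]]$sigma)
                for (nm in list(napz, natz))
                    v <- embedLesion(v, RoiMask(nm, "NAPZ"),
                                     meanShift = natShifts[[s]],
                                     noiseSd = 1.5 * config@noiseSd[[s]],
                                     correlationLength = natSigma)
                gain <- switch(s, t2 = gainT2, b = gainB, 1)
                vols[[s]] <- VolumeGrid(gridValues(v) * gain, sp, s)
            }
            masks <- list(RoiMask(zoneMasks$GM, "GM"),
                          RoiMask(zoneMasks$femoral_head, "femoral_head"),
                          RoiMask(zoneMasks$bladder, "bladder"))
            lesAll <- Reduce(`|`, lapply(lesionInfo, `[[`, "mask"))
            masks <- c(masks, list(RoiMask(napz & !lesAll, "NAPZ"),
                                   RoiMask(natz & !lesAll, "NATZ")))
            for (l in seq_len(nLes))
                masks <- c(masks, list(RoiMask(lesionInfo[[l]]$mask, "L",
                                               sprintf("L%d", l))))
            studies[[eid]] <- MpmriStudy(pid, eid, vols, masks)
            for (l in seq_len(nLes)) {
                li <- lesionInfo[[l]]
                rows[[length(rows) + 1L]] <- data.frame(
                    patient_id = pid, exam_id = eid,
                    lesion_id = sprintf("L%d", l),
                    true_class = li$class,
                    age = age, psa = psa, prostate_volume = prostVol,
                    psad = psad, dre = dre, pirads = pirads,
                    t_stage = tStage,
                    grade_group = li$path$grade_group,
                    pct_positive_cores = li$path$pct_positive_cores,
                    decipher = li$path$decipher,
                    lesion_radius_mm = li$radius_mm,
                    lesion_voxels = sum(li$mask),
                    lesion_sigma = li$sigma,
                    shift_t2 = li$shifts[["t2"]],
                    shift_adc = li$shifts[["adc"]],
                    shift_b = li$shifts[["b"]])
            }
        }
    }
    new("MpmriCohort", studies = studies, lesions = do.call(rbind, rows),
        config = config)
}
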