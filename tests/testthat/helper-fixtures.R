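# Fixture builders shared across test files; everything is generated in
# code at test time.

# A small hand-built exam with block-shaped tissues. With homogeneous
# reference tissues (the default) the reference-tissue means are exact
# fixed points of the normalization map.
refStudy <- function(seed = 1, refNoiseSd = 0, gm = 120, fh = 350,
                     bl = 900, d = c(16L, 16L, 10L)) {
    set.seed(seed)
    mk <- function(base, noise = 5) array(rnorm(prod(d), base, noise), d)
    t2 <- mk(240); adc <- mk(1300, 40); b <- mk(90, 4)
    gmM <- fhM <- blM <- array(FALSE, d)
    gmM[2:4, 2:5, 3:7] <- TRUE
    fhM[12:14, 2:5, 3:7] <- TRUE
    blM[6:10, 12:15, 6:9] <- TRUE
    t2[gmM] <- gm + rnorm(sum(gmM), 0, refNoiseSd)
    t2[fhM] <- fh + rnorm(sum(fhM), 0, refNoiseSd)
    t2[blM] <- bl + rnorm(sum(blM), 0, refNoiseSd)
    b[gmM] <- 60 + rnorm(sum(gmM), 0, refNoiseSd)
    lesion <- array(FALSE, d)
    lesion[7:10, 5:8, 4:7] <- TRUE
    napz <- natz <- array(FALSE, d)
    napz[12:15, 12:15, 3:6] <- TRUE
    natz[2:5, 12:15, 3:6] <- TRUE
    MpmriStudy("PT", "PT_E1",
               list(t2 = VolumeGrid(t2, c(1, 1, 2), "t2"),
                    adc = VolumeGrid(adc, c(1, 1, 2), "adc"),
                    b = VolumeGrid(b, c(1, 1, 2), "b")),
               list(RoiMask(gmM, "GM"), RoiMask(fhM, "femoral_head"),
                    RoiMask(blM, "bladder"), RoiMask(napz, "NAPZ"),
                    RoiMask(natz, "NATZ"), RoiMask(lesion, "L", "L1")))
}

# Lesion-level modeling table with independent-noise radiomics; optionally
# plants a signal column. Used where the full image pipeline is overkill.
fakeModelData <- function(n = 80, seed = 1, planted = FALSE) {
    set.seed(seed)
    y <- rbinom(n, 1, 0.55)
    feats <- matrix(rnorm(n * 487), n,
                    dimnames = list(NULL, allFeatureNames()))
    feats[, "HRS6"] <- abs(feats[, "HRS6"])
    if (planted) feats[, "L_t2_int_10"] <- y * 2 + rnorm(n, 0, 0.7)
    tier <- ifelse(y == 1, "low", sample(c("intermediate", "high"), n, TRUE))
    df <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                     exam_id = sprintf("P%03d_E1", seq_len(n)),
                     lesion_id = "L1",
                     age = round(runif(n, 50, 75)),
                     psad = runif(n, 0.05, 0.4),
                     dre = sample(0:2, n, TRUE, prob = c(.7, .2, .1)),
                     pirads = sample(1:5, n, TRUE),
                     three_tier = factor(tier, c("low", "intermediate", "high"),
                                         ordered = TRUE),
                     spratt_numeric = ifelse(y == 1, 0L, 3L),
                     low_risk = y == 1,
                     patient_low_risk = y == 1,
                     feats, check.names = FALSE)
    df$dre_pos <- as.integer(df$dre > 0)
    df$pirads_high <- as.integer(df$pirads >= 3)
    df
}

# Full image-to-model path for a generated cohort.
cohortModelData <- function(config) {
    coh <- generateCohort(config)
    les <- cohortLesions(coh)
    feats <- extractCohortFeatures(cohortStudies(coh), les)
    assembleModelData(feats, scoreCohort(les))
}
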