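test_that("feature name grammar enumerates the canonical sets", {
    all <- featureNames()
    expect_length(all, 486)
    expect_length(featureNames("L"), 162)
    expect_length(featureNames("NAPZ"), 162)
    expect_true(all(c("L_adc_ene_90", "NATZ_t2_cor_50", "L_adc_int_50") %in% all))
    expect_false(anyDuplicated(all) > 0)
    # deterministic order: ROI, then sequence, then family, then descriptor
    expect_identical(all[1:9],
                     paste0("L_t2_int_",
                            c("10", "25", "50", "75", "90", "mean", "SD",
                              "Kur", "Ske")))
    expect_identical(allFeatureNames()[1], "HRS6")
    expect_length(allFeatureNames(), 487)
    # intensity-only restriction: one family x 9 descriptors x 3 sequences
    expect_length(featureNames("L", intensityOnly = TRUE), 27)
})

test_that("histogram descriptors match their definitions", {
    d <- histogramDescriptors(rep(3.5, 20))
    expect_equal(unname(d[c("10", "25", "50", "75", "90", "mean")]),
                 rep(3.5, 6))
    expect_equal(unname(d[c("SD", "Kur", "Ske")]), c(0, 0, 0))

    v <- sample(1:100)
    d <- histogramDescriptors(v)
    # independent order-statistic oracle for type-7 percentiles
    o7 <- function(p) { h <- (100 - 1) * p + 1
        sort(v)[floor(h)] + (h - floor(h)) * (sort(v)[ceiling(h)] - sort(v)[floor(h)]) }
    expect_equal(unname(d["50"]), o7(.5))
    expect_equal(unname(d["10"]), o7(.1))
    expect_equal(unname(d["90"]), o7(.9))
    expect_equal(unname(d["mean"]), 50.5)
    expect_equal(unname(d["SD"]), sd(1:100))

    expect_equal(unname(histogramDescriptors(c(-2, 0, 2))["Ske"]), 0)
    expect_error(histogramDescriptors(numeric(0)), "at least one")
    # percentile ordering holds on arbitrary samples
    for (s in 1:5) {
        set.seed(s)
        d <- histogramDescriptors(rexp(30))
        expect_true(all(diff(d[c("10", "25", "50", "75", "90")]) >= 0))
    }
})

test_that("window rescaling maps to 0-255 with half-away-from-zero rounding", {
    expect_true(all(rescaleWindow(array(4.2, c(3, 3, 3))) == 0L))
    expect_setequal(as.vector(rescaleWindow(c(10, 20, 10, 20))), c(0L, 255L))
    expect_equal(rescaleWindow(c(0, 1, 2))[2], 128L)   # 127.5 rounds away from zero
    expect_equal(rescaleWindow(c(0, 100))[2], 255L)
})

test_that("GLCM counting matches an exhaustive pair enumeration", {
    # constant window: single entry 1 at the (0,0) bin
    P <- glcm3d(array(0L, c(3, 3, 3)))
    expect_equal(P[1, 1], 1)
    expect_equal(sum(P), 1)

    # printed 2x2x2 toy, single offset (1,0,0): pairs are (w[1,y,z], w[2,y,z])
    w <- array(c(0L, 255L, 128L, 3L, 64L, 200L, 17L, 90L), c(2, 2, 2))
    off <- matrix(c(1L, 0L, 0L), 1)
    P <- glcm3d(w, nBins = 128L, offsets = off, symmetric = TRUE)
    expect_equal(P, oracleGlcm(w, 128L, off, TRUE))

    # symmetrized matrix equals its transpose; random windows match oracle
    for (s in 1:5) {
        set.seed(s)
        w <- array(sample(0:255, 27, TRUE), c(3, 3, 3))
        P <- glcm3d(w)
        expect_equal(P, t(P))
        expect_equal(P, oracleGlcm(w))
    }
    expect_error(glcm3d(array(0L, c(3, 3, 3)), offsets = matrix(integer(0), 0, 3)),
                 "offset")
})

test_that("Haralick scalars match closed forms and direct summation", {
    P <- matrix(0, 8, 8); P[3, 3] <- 1
    h <- haralickFeatures(P)
    expect_equal(unname(h), c(0, 0, 1, 0, 1))   # con, cor, ene, ent, hom

    k <- 4
    U <- matrix(1 / k^2, k, k)
    h <- haralickFeatures(U)
    expect_equal(unname(h["ene"]), 1 / k^2)
    expect_equal(unname(h["ent"]), log(k^2))

    set.seed(2)
    Q <- matrix(rexp(9), 3); Q <- Q / sum(Q)
    expect_equal(haralickFeatures(Q), oracleHaralick(Q), tolerance = 1e-12)
    expect_error(haralickFeatures(Q * 2), "normalized")
})

test_that("texture maps compose rescale -> GLCM -> Haralick with window clipping", {
    set.seed(9)
    vol <- array(rnorm(10 * 9 * 8, 100, 25), c(10, 9, 8))
    v <- VolumeGrid(vol, c(1, 1, 1), "adc")
    m <- array(FALSE, dim(vol))
    m[c(1, 40, 300, 500, 719)] <- TRUE   # includes corner/edge voxels
    tm <- textureMaps(v, RoiMask(m, "L"))
    vox <- which(m, arr.ind = TRUE)
    for (i in seq_len(nrow(vox))) {
        c0 <- vox[i, ]
        xr <- max(1, c0[1] - 2):min(10, c0[1] + 2)
        yr <- max(1, c0[2] - 2):min(9, c0[2] + 2)
        zr <- max(1, c0[3] - 2):min(8, c0[3] + 2)
        ref <- haralickFeatures(glcm3d(rescaleWindow(vol[xr, yr, zr])))
        expect_equal(tm[i, ], ref, tolerance = 1e-10)
    }
})

test_that("homogeneous volumes give degenerate texture and constants shift nothing", {
    v <- VolumeGrid(array(55, c(8, 8, 8)), c(1, 1, 1), "t2")
    m <- array(FALSE, c(8, 8, 8)); m[3:5, 3:5, 3:5] <- TRUE
    tm <- textureMaps(v, RoiMask(m, "L"))
    expect_true(all(tm[, "ene"] == 1))
    expect_true(all(tm[, "con"] == 0))

    # translation invariance of texture (local rescaling removes offsets)
    set.seed(4)
    vol <- array(rnorm(8^3, 50, 10), c(8, 8, 8))
    t1 <- textureMaps(VolumeGrid(vol, c(1, 1, 1), "t2"), RoiMask(m, "L"))
    t2 <- textureMaps(VolumeGrid(vol + 1000, c(1, 1, 1), "t2"), RoiMask(m, "L"))
    expect_equal(t1, t2, tolerance = 1e-9)
})

test_that("checkerboard texture shows more contrast than smooth texture", {
    d <- c(12, 12, 12)
    idx <- array(seq_len(prod(d)), d)
    pos <- which(idx > 0, arr.ind = TRUE)
    chk <- array(((pos[, 1] + pos[, 2] + pos[, 3]) %% 2) * 2 - 1, d)
    set.seed(8)
    smooth <- mpRadRisk:::gaussianSmooth3d(array(rnorm(prod(d)), d), 1.5)
    smooth <- smooth / sd(smooth)   # equal variance to the checkerboard
    m <- array(FALSE, d); m[4:9, 4:9, 4:9] <- TRUE
    conChk <- mean(textureMaps(VolumeGrid(chk, c(1, 1, 1), "t2"), RoiMask(m, "L"))[, "con"])
    conSm <- mean(textureMaps(VolumeGrid(smooth, c(1, 1, 1), "t2"), RoiMask(m, "L"))[, "con"])
    expect_gt(conChk, conSm)
})

test_that("mask volume arithmetic is exact", {
    d <- c(20, 10, 10)
    m <- array(FALSE, d); m[seq_len(1000)] <- TRUE
    expect_equal(hrs6Volume(RoiMask(m, "L"), c(1, 1, 1)), 1.0)
    expect_equal(hrs6Volume(RoiMask(array(FALSE, d), "L"), c(1, 1, 1)), 0.0)
    m2 <- array(FALSE, d); m2[seq_len(250)] <- TRUE
    expect_equal(hrs6Volume(RoiMask(m2, "L"), c(0.5, 0.5, 3)), 0.1875)
})

test_that("ROI extraction yields the canonical names and definitional values", {
    st <- refStudy(seed = 3)
    nst <- normalizeStudy(st)
    f <- extractRoiFeatures(nst, getMask(nst, "L", "L1"))
    expect_identical(names(f), featureNames("L"))
    expect_true(all(is.finite(f)))
    inRoi <- gridValues(studyVolumes(nst)$adc)[maskArray(getMask(nst, "L", "L1"))]
    expect_equal(unname(f["L_adc_int_50"]), unname(median(inRoi)))

    full <- extractFeatures(nst)
    expect_identical(names(full), allFeatureNames())
    expect_identical(full, extractFeatures(nst))   # bit-identical re-extraction

    tiny <- array(FALSE, dim(gridValues(studyVolumes(st)$t2)))
    tiny[1:3] <- TRUE
    expect_error(extractRoiFeatures(nst, RoiMask(tiny, "L")), "at least")
})
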