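targets <- referenceTargets()

test_that("reference tissues hit their targets exactly and the map is stable", {
    st <- refStudy(seed = 1)                  # homogeneous reference tissues
    refs <- list(GM = getMask(st, "GM"),
                 femoral_head = getMask(st, "femoral_head"),
                 bladder = getMask(st, "bladder"))
    t2n <- normalizeT2(studyVolumes(st)$t2, refs, targets)
    for (r in names(refs)) {
        m <- mean(gridValues(t2n)[maskArray(refs[[r]])])
        expect_equal(m, unname(targets$t2[r]), tolerance = 1e-9)
    }
    # idempotence: a second pass is the identity
    t2nn <- normalizeT2(t2n, refs, targets)
    expect_equal(gridValues(t2nn), gridValues(t2n), tolerance = 1e-9)

    # order preservation across random voxel pairs
    v0 <- as.vector(gridValues(studyVolumes(st)$t2))
    v1 <- as.vector(gridValues(t2n))
    set.seed(2); i <- sample(length(v0), 500); j <- sample(length(v0), 500)
    expect_true(all(sign(v1[i] - v1[j]) * sign(v0[i] - v0[j]) >= 0))
})

test_that("normalization undoes a global intensity scaling at the knots", {
    st <- refStudy(seed = 2)
    refs <- list(GM = getMask(st, "GM"),
                 femoral_head = getMask(st, "femoral_head"),
                 bladder = getMask(st, "bladder"))
    t2 <- studyVolumes(st)$t2
    t2x2 <- VolumeGrid(gridValues(t2) * 2, voxelSpacing(t2), "t2")
    n1 <- normalizeT2(t2, refs, targets)
    n2 <- normalizeT2(t2x2, refs, targets)
    for (r in names(refs)) {
        expect_equal(mean(gridValues(n2)[maskArray(refs[[r]])]),
                     unname(targets$t2[r]), tolerance = 1e-9)
    }
    expect_equal(gridValues(n1), gridValues(n2), tolerance = 1e-6)
})

test_that("piecewise-linear mode reproduces hand interpolation", {
    # knots (0,0), (100,80), (200,160), (400,300): f(150) = 120
    st <- refStudy(seed = 3, gm = 100, fh = 200, bl = 400)
    refs <- list(GM = getMask(st, "GM"),
                 femoral_head = getMask(st, "femoral_head"),
                 bladder = getMask(st, "bladder"))
    tgt <- referenceTargets(t2 = c(GM = 80, femoral_head = 160, bladder = 300),
                            method = "linear")
    vals <- gridValues(studyVolumes(st)$t2)
    vals[1, 1, 1] <- 150
    vals[1, 2, 1] <- 500    # above the last knot: linear extrapolation
    vn <- normalizeT2(VolumeGrid(vals, c(1, 1, 2), "t2"), refs, tgt)
    expect_equal(gridValues(vn)[1, 1, 1], 120)
    expect_equal(gridValues(vn)[1, 2, 1], 300 + (500 - 400) * (300 - 160) / (400 - 200))
})

test_that("degenerate reference configurations fail loudly", {
    st <- refStudy(seed = 4)
    refs <- list(GM = getMask(st, "GM"),
                 femoral_head = getMask(st, "femoral_head"),
                 bladder = getMask(st, "bladder"))
    d <- dim(gridValues(studyVolumes(st)$t2))
    expect_error(
        normalizeT2(studyVolumes(st)$t2,
                    within(refs, GM <- RoiMask(array(FALSE, d), "GM")), targets),
        "empty")
    # colliding reference means make the map multi-valued
    stc <- refStudy(seed = 5, gm = 300, fh = 300)
    refsc <- list(GM = getMask(stc, "GM"),
                  femoral_head = getMask(stc, "femoral_head"),
                  bladder = getMask(stc, "bladder"))
    expect_error(normalizeT2(studyVolumes(stc)$t2, refsc, targets), "collide")
})

test_that("b-value normalization is an exact GM-referenced rescale", {
    d <- c(8L, 8L, 6L)
    gmM <- array(FALSE, d); gmM[2:3, 2:3, 2:3] <- TRUE
    gm <- RoiMask(gmM, "GM")
    vals <- array(50, d)
    vn <- normalizeB(VolumeGrid(vals, c(1, 1, 1), "b"), gm, 100)
    expect_true(all(gridValues(vn) == 100))

    vals2 <- array(10, d); vals2[gmM] <- 200; vals2[8, 8, 6] <- 340
    vn2 <- normalizeB(VolumeGrid(vals2, c(1, 1, 1), "b"), gm, 100)
    expect_equal(gridValues(vn2)[8, 8, 6], 170)
    expect_equal(mean(gridValues(vn2)[gmM]), 100)

    vals3 <- array(1, d); vals3[gmM] <- 100
    vn3 <- normalizeB(VolumeGrid(vals3, c(1, 1, 1), "b"), gm, 100)
    expect_equal(gridValues(vn3), vals3)     # already at target: identity

    expect_error(normalizeB(VolumeGrid(array(-5, d), c(1, 1, 1), "b"), gm, 100),
                 "positive")
})

test_that("normalizeStudy leaves the ADC map in native units", {
    st <- refStudy(seed = 6)
    nst <- normalizeStudy(st)
    expect_identical(gridValues(studyVolumes(nst)$adc),
                     gridValues(studyVolumes(st)$adc))
    expect_equal(mean(gridValues(studyVolumes(nst)$b)[maskArray(getMask(st, "GM"))]),
                 targets$b, tolerance = 1e-9)
})

test_that("noisy reference tissues are mapped close to, not exactly at, targets", {
    st <- refStudy(seed = 7, refNoiseSd = 8)
    refs <- list(GM = getMask(st, "GM"),
                 femoral_head = getMask(st, "femoral_head"),
                 bladder = getMask(st, "bladder"))
    t2n <- normalizeT2(studyVolumes(st)$t2, refs, targets)
    for (r in names(refs)) {
        m <- mean(gridValues(t2n)[maskArray(refs[[r]])])
        expect_equal(m, unname(targets$t2[r]), tolerance = 0.02)
    }
})
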