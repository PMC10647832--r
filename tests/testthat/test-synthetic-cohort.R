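test_that("the cohort is a deterministic function of (config, seed)", {
    cfg <- cohortConfig(nPatients = 4, seed = 31)
    a <- generateCohort(cfg)
    b <- generateCohort(cfg)
    expect_identical(cohortLesions(a), cohortLesions(b))
    for (eid in names(cohortStudies(a))) {
        sa <- cohortStudies(a)[[eid]]; sb <- cohortStudies(b)[[eid]]
        for (s in c("t2", "adc", "b"))
            expect_identical(gridValues(studyVolumes(sa)[[s]]),
                             gridValues(studyVolumes(sb)[[s]]))
        expect_identical(lapply(studyMasks(sa), maskArray),
                         lapply(studyMasks(sb), maskArray))
    }
    # and survives a full serialization round trip
    d <- withr::local_tempdir()
    writeCohort(a, d)
    back <- readCohort(d)
    expect_identical(gridValues(studyVolumes(back$studies[[1]])$t2),
                     gridValues(studyVolumes(cohortStudies(a)[[1]])$t2))
})

test_that("a pure low-risk mix yields only low-risk ground truth", {
    coh <- generateCohort(cohortConfig(nPatients = 10, fracLowRisk = 1, seed = 5))
    les <- cohortLesions(coh)
    expect_true(all(les$true_class == "low"))
    # DRE positives arise at the low-class rate (2%); none is the norm
    expect_lte(mean(les$dre > 0), 0.3)
    coh0 <- generateCohort(cohortConfig(nPatients = 10, fracLowRisk = 0, seed = 5))
    expect_true(all(cohortLesions(coh0)$true_class == "nonlow"))
})

test_that("lesion embedding shifts the in-mask mean and nothing else", {
    d <- c(12L, 12L, 8L)
    m <- array(FALSE, d); m[4:8, 4:8, 3:6] <- TRUE
    v <- VolumeGrid(array(100, d), c(1, 1, 1), "adc")

    same <- embedLesion(v, RoiMask(m, "L"), meanShift = 0, noiseSd = 0)
    expect_identical(gridValues(same), gridValues(v))

    set.seed(1)
    out <- embedLesion(v, RoiMask(m, "L"), meanShift = 50, noiseSd = 10,
                       correlationLength = 1)
    expect_identical(gridValues(out)[!m], gridValues(v)[!m])
    expect_equal(mean(gridValues(out)[m]), 150)   # noise is centered in-mask

    set.seed(2)
    a <- embedLesion(v, RoiMask(m, "L"), meanShift = -200, noiseSd = 15,
                     correlationLength = 0.8)
    b <- embedLesion(v, RoiMask(m, "L"), meanShift = 0, noiseSd = 15,
                     correlationLength = 0.8)
    expect_equal(mean(gridValues(b)[m]) - mean(gridValues(a)[m]), 200)

    expect_error(embedLesion(v, RoiMask(array(FALSE, d), "L"), 1, 1, 1), "empty")
})

test_that("generated masks are non-empty, disjoint and distinctly valued", {
    coh <- generateCohort(cohortConfig(nPatients = 6, seed = 8))
    for (st in cohortStudies(coh)) {
        masks <- studyMasks(st)
        roles <- vapply(masks, maskRole, character(1))
        expect_setequal(unique(roles),
                        c("GM", "femoral_head", "bladder", "NAPZ", "NATZ", "L"))
        for (m in masks) expect_gt(sum(maskArray(m)), 0)
        lesAll <- Reduce(`|`, lapply(masks[roles == "L"], maskArray))
        for (r in c("NAPZ", "NATZ")) {
            nat <- maskArray(masks[[which(roles == r)]])
            expect_equal(sum(nat & lesAll), 0)
        }
        # reference tissues carry distinct raw t2 intensities
        t2 <- gridValues(studyVolumes(st)$t2)
        mm <- vapply(c("GM", "femoral_head", "bladder"), function(r)
            mean(t2[maskArray(masks[[which(roles == r)]])]), numeric(1))
        expect_true(all(diff(sort(mm)) > 20))
    }
})

test_that("class separation grows with the configured effect size", {
    smd <- function(effect, seed = 77) {
        cfg <- cohortConfig(nPatients = 30, seed = seed,
                            effectSizes = c(t2 = 0, adc = -effect, b = 0),
                            natEffectSizes = c(t2 = 0, adc = 0, b = 0),
                            textureEffect = 0, volumeEffect = 0)
        coh <- generateCohort(cfg)
        les <- cohortLesions(coh)
        means <- vapply(seq_len(nrow(les)), function(i) {
            st <- cohortStudies(coh)[[les$exam_id[i]]]
            mean(gridValues(studyVolumes(st)$adc)[
                maskArray(getMask(st, "L", les$lesion_id[i]))])
        }, numeric(1))
        lo <- means[les$true_class == "low"]; hi <- means[les$true_class != "low"]
        (mean(lo) - mean(hi)) / sqrt((var(lo) + var(hi)) / 2)
    }
    sep <- vapply(c(0, 150, 400), smd, numeric(1))
    expect_true(all(diff(sep) > 0))
    expect_lt(abs(sep[1]), 0.75)     # null effect: no real separation
    expect_gt(sep[3], 1.5)
})

test_that("impossible geometry fails naming the constraint", {
    expect_error(generateCohort(cohortConfig(nPatients = 1, gridShape = c(10, 10, 8))),
                 "too small")
})

test_that("duplicate exams reuse the patient's lesions with fresh imaging", {
    cfg <- cohortConfig(nPatients = 4, duplicateExamRate = 1, seed = 13)
    coh <- generateCohort(cfg)
    les <- cohortLesions(coh)
    expect_equal(length(unique(les$exam_id)), 2 * length(unique(les$patient_id)))
    one <- split(les, les$patient_id)[[1]]
    e <- split(one, one$exam_id)
    expect_identical(e[[1]]$decipher, e[[2]]$decipher)
    expect_identical(e[[1]]$true_class, e[[2]]$true_class)
})
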