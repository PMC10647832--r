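test_that("standardization round-trips and handles degenerate columns", {
    set.seed(1)
    x <- cbind(a = rnorm(40, 5, 2), b = runif(40), flat = rep(3, 40))
    expect_warning(std <- standardizeFeatures(x), "zero-variance.*flat")
    expect_false("flat" %in% colnames(std$x))
    expect_equal(unname(colMeans(std$x)), c(0, 0), tolerance = 1e-12)
    expect_equal(unname(apply(std$x, 2, sd)), c(1, 1), tolerance = 1e-12)
    back <- sweep(sweep(std$x, 2, std$params$scale, "*"), 2,
                  std$params$center, "+")
    expect_equal(back, x[, c("a", "b")], tolerance = 1e-12)
    # stored parameters re-apply verbatim
    again <- standardizeFeatures(x, std$params)
    expect_identical(again$x, std$x)
    expect_error(standardizeFeatures(cbind(a = rep(NA_real_, 5))), "missing")
})

test_that("adaptive LASSO keeps planted signal and honors forced variables", {
    hits <- 0L
    for (s in 1:5) {
        set.seed(100 + s)
        X <- matrix(rnorm(200 * 50), 200, 50,
                    dimnames = list(NULL, paste0("V", 1:50)))
        y <- rbinom(200, 1, plogis(1.5 * X[, 1]))
        sel <- adaptiveLassoSelect(X, y, forced = "V50", seed = s)
        expect_true("V50" %in% sel$selected)
        hits <- hits + ("V1" %in% sel$selected)
    }
    expect_gte(hits, 5 * 0.95)
    X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("A", "B")))
    expect_error(adaptiveLassoSelect(X, rep(1, 20)), "single class")
})

test_that("model pools follow the study design", {
    p1 <- mpRadRisk:::modelPool(1)
    expect_setequal(p1$pool, c("age", "psad", "dre_pos", "pirads_high"))
    expect_false(p1$select)
    p2 <- mpRadRisk:::modelPool(2)
    expect_length(p2$pool, 163)            # HRS6 + 162 lesion features
    expect_equal(p2$forced, "HRS6")
    p3 <- mpRadRisk:::modelPool(3)
    expect_length(p3$pool, 487)
    p5 <- mpRadRisk:::modelPool(5)
    expect_true(all(c("age", "HRS6", "NATZ_b_hom_SD") %in% p5$pool))
    # intensities-only variant restricts to the first-order family
    p2i <- mpRadRisk:::modelPool(2, intensityOnly = TRUE)
    expect_length(p2i$pool, 28)            # HRS6 + 3 sequences x 9 descriptors
    expect_true(all(grepl("^HRS6$|_int_", p2i$pool)))
})

test_that("fitted models use their pools, force HRS6 and are reproducible", {
    md <- fakeModelData(n = 90, seed = 3, planted = TRUE)
    m1 <- fitRiskModel(md, 1, seed = 7)
    expect_setequal(m1$selected, c("age", "psad", "dre_pos", "pirads_high"))
    expect_length(m1$coefficients, 5)      # intercept + 4 clinical inputs

    m2 <- fitRiskModel(md, 2, seed = 7)
    expect_true("HRS6" %in% m2$selected)
    expect_true(all(grepl("^HRS6$|^L_", m2$selected)))
    m2b <- fitRiskModel(md, 2, seed = 7)
    expect_identical(m2$selected, m2b$selected)
    expect_identical(m2$coefficients, m2b$coefficients)

    m4 <- fitRiskModel(md, 4, seed = 7)
    expect_true(all(c("age", "psad", "dre_pos", "pirads_high", "HRS6")
                    %in% m4$selected))
})

test_that("lesion predictions are logistic in the stored coefficients", {
    md <- fakeModelData(n = 60, seed = 5)
    m1 <- fitRiskModel(md, 1, seed = 2)
    # records at the training center have all-zero standardized inputs
    ctr <- as.data.frame(as.list(m1$standardization$center))
    expect_equal(unname(predictLesion(m1, ctr)),
                 plogis(m1$coefficients[["(Intercept)"]]))
    # monotone in a positive-coefficient variable
    v <- names(which(m1$coefficients[-1] > 0))[1]
    if (!is.na(v)) {
        up <- ctr; up[[v]] <- up[[v]] + 10
        expect_gt(predictLesion(m1, up), predictLesion(m1, ctr))
    }
    # batch prediction equals per-record prediction
    batch <- predictLesion(m1, md)
    each <- vapply(seq_len(nrow(md)), function(i)
        predictLesion(m1, md[i, , drop = FALSE]), numeric(1))
    expect_equal(batch, each)
    expect_error(predictLesion(m1, md[, setdiff(names(md), "age")]), "age")
})

test_that("patient-level prediction policies behave as defined", {
    md <- fakeModelData(n = 40, seed = 6)
    m1 <- fitRiskModel(md, 1, seed = 2)
    single <- md[1, , drop = FALSE]
    pw <- predictPatient(m1, single, "worst_lesion_truth")
    pm <- predictPatient(m1, single, "min_prob")
    expect_equal(pw$prob, pm$prob)
    expect_equal(pw$prob, unname(predictLesion(m1, single)))

    two <- md[1:2, ]
    two$patient_id <- "PX"
    two$three_tier <- factor(c("low", "high"),
                             c("low", "intermediate", "high"), ordered = TRUE)
    probs <- predictLesion(m1, two)
    expect_equal(predictPatient(m1, two, "min_prob")$prob, min(probs))
    expect_equal(predictPatient(m1, two, "worst_lesion_truth")$prob, probs[2])
    expect_error(predictPatient(m1, two, "other"), "arg")
})

test_that("worst-lesion patient rows carry the patient outcome", {
    md <- fakeModelData(n = 30, seed = 8)
    md$patient_id <- rep(sprintf("P%02d", 1:10), each = 3)
    md$patient_low_risk <- rep(tapply(md$low_risk, md$patient_id, all)[
        sprintf("P%02d", 1:10)], each = 3)
    pr <- patientRows(md)
    expect_equal(nrow(pr), 10)
    expect_equal(pr$low_risk,
                 as.logical(tapply(md$low_risk, md$patient_id, all)))
    for (p in split(md, md$patient_id)) {
        worst <- max(as.integer(p$three_tier))
        expect_equal(as.integer(pr$three_tier[pr$patient_id == p$patient_id[1]]),
                     worst)
    }
})
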