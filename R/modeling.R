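## The five low-risk prediction models.
##
## Model 1: plain logistic regression on the four pre-biopsy clinical
## variables (age, PSAD, DRE dichotomized 0 vs 1-2, PI-RADS dichotomized
## 1-2 vs 3-5). Models 2-5: adaptive-LASSO variable selection over a
## radiomics pool (lesion only, or lesion + NAPZ/NATZ; optionally
## restricted to first-order intensity features), with the tumor volume
## (HRS6) always forced in; Models 4-5 add the clinical variables,
## unpenalized. The final fit is an unpenalized logistic regression on the
## selected + forced variables, with a ridge-stabilized fallback when
## separation prevents convergence. All inputs are standardized with
## stored parameters so fits and predictions share one scale.

CLINICAL_VARS <- c("age", "psad", "dre_pos", "pirads_high")

#' Standardize a feature matrix, or re-apply stored parameters
#'
#' Columns are centered and scaled to unit variance on training data;
#' missing values are imputed with the training-column median first;
#' zero-variance columns are dropped with a warning. The returned
#' parameters reproduce the exact transformation at prediction time.
#'
#' @param x Numeric matrix or data frame.
#' @param params Parameters from a previous call; when supplied they are
#'   re-applied verbatim.
#' @return List with `x` (standardized matrix) and `params`
#'   (`center`, `scale`, `median`, `keep`).
#' @export
standardizeFeatures <- function(x, params = NULL) {
    x <- as.matrix(x)
    if (is.null(params)) {
        med <- apply(x, 2, median, na.rm = TRUE)
        if (anyNA(med))
            stop(sprintf("column(s) entirely missing: %s",
                         paste(colnames(x)[is.na(med)], collapse = ", ")))
        for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
        ctr <- colMeans(x)
        scl <- apply(x, 2, sd)
        keep <- scl > 0
        if (any(!keep))
            warning(sprintf("dropping zero-variance column(s): %s",
                            paste(colnames(x)[!keep], collapse = ", ")))
        params <- list(center = ctr[keep], scale = scl[keep],
                       median = med, keep = colnames(x)[keep])
    }
    missingCols <- setdiff(params$keep, colnames(x))
    if (length(missingCols))
        stop(sprintf("missing feature column(s): %s",
                     paste(missingCols, collapse = ", ")))
    x <- x[, params$keep, drop = FALSE]
    for (j in colnames(x)) x[is.na(x[, j]), j] <- params$median[[j]]
    x <- sweep(sweep(x, 2, params$center[params$keep]), 2,
               params$scale[params$keep], "/")
    list(x = x, params = params)
}

#' Adaptive-LASSO variable selection for a binary outcome
#'
#' Two-stage procedure: a ridge-penalized logistic fit provides initial
#' coefficients, whose inverse absolute values (raised to `gamma`) become
#' per-variable penalty weights for an L1-penalized logistic path; the
#' penalty is chosen by stratified K-fold cross-validated deviance at its
#' minimum. Variables listed in `forced` carry zero penalty and are always
#' returned.
#'
#' @param x Standardized numeric matrix.
#' @param y Binary outcome (0/1 or logical), both classes present.
#' @param forced Column names exempt from penalization.
#' @param gamma Adaptive-weight exponent (default 1).
#' @param nfolds Cross-validation folds (default 10).
#' @param lambdaRule `"1se"` (default; the sparsest penalty within one
#'   standard error of the minimum CV deviance, the usual parsimony rule
#'   for variable selection) or `"min"`.
#' @param seed Integer seed controlling fold assignment.
#' @return List with `selected` (column names, including `forced`),
#'   `weights`, `lambda`, and the fitted `cv.glmnet` object.
#' @export
adaptiveLassoSelect <- function(x, y, forced = character(), gamma = 1,
                                nfolds = 10, lambdaRule = c("1se", "min"),
                                seed = 1L) {
    lambdaRule <- match.arg(lambdaRule)
    x <- as.matrix(x)
    y <- as.integer(y)
    if (length(unique(y)) < 2L)
        stop("outcome has a single class; selection is undefined")
    minClass <- min(table(y))
    if (minClass < 3L)
        stop("each outcome class needs at least 3 observations for cross-validated selection")
    if (!all(forced %in% colnames(x)))
        stop(sprintf("forced variable(s) absent from x: %s",
                     paste(setdiff(forced, colnames(x)), collapse = ", ")))
    set.seed(seed)
    nfolds <- max(3L, min(nfolds, minClass))
    foldid <- stratifiedFolds(y, nfolds)
    ridge <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                               foldid = foldid, standardize = FALSE)
    b0 <- as.numeric(coef(ridge, s = "lambda.min"))[-1]
    w <- 1 / pmax(abs(b0), 1e-8)^gamma
    w <- pmin(w / min(w), 1e8)
    w[colnames(x) %in% forced] <- 0
    lasso <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                               penalty.factor = w, foldid = foldid,
                               standardize = FALSE)
    s <- if (lambdaRule == "1se") lasso$lambda.1se else lasso$lambda.min
    beta <- as.matrix(coef(lasso, s = s))[-1, 1]
    selected <- union(names(beta)[beta != 0], forced)
    list(selected = colnames(x)[colnames(x) %in% selected], weights = w,
         lambda = s, cv = lasso)
}

#' Assemble the modeling table from features and scored lesions
#'
#' Merges the per-lesion feature table with the scored cohort table,
#' dichotomizes DRE (0 vs 1-2) and PI-RADS (1-2 vs 3-5) and exposes the
#' outcome `low_risk`.
#'
#' @param features `data.frame` with key columns `patient_id`, `exam_id`,
#'   `lesion_id` and the [allFeatureNames()] columns.
#' @param lesions Scored cohort table (see [scoreCohort()]).
#' @return Merged `data.frame` ready for [fitRiskModel()].
#' @export
assembleModelData <- function(features, lesions) {
    keys <- c("patient_id", "exam_id", "lesion_id")
    out <- merge(lesions, features, by = keys, sort = FALSE)
    out <- out[order(out$patient_id, out$exam_id, out$lesion_id), ]
    rownames(out) <- NULL
    out$dre_pos <- as.integer(out$dre > 0)
    out$pirads_high <- as.integer(out$pirads >= 3)
    out
}

modelPool <- function(modelId, intensityOnly = FALSE) {
    stopifnot(modelId %in% 1:5)
    lesion <- c("HRS6", featureNames("L", intensityOnly))
    all3 <- c("HRS6", featureNames(intensityOnly = intensityOnly))
    switch(modelId,
           `1` = list(pool = CLINICAL_VARS, forced = CLINICAL_VARS, select = FALSE),
           `2` = list(pool = lesion, forced = "HRS6", select = TRUE),
           `3` = list(pool = all3, forced = "HRS6", select = TRUE),
           `4` = list(pool = c(CLINICAL_VARS, lesion),
                      forced = c(CLINICAL_VARS, "HRS6"), select = TRUE),
           `5` = list(pool = c(CLINICAL_VARS, all3),
                      forced = c(CLINICAL_VARS, "HRS6"), select = TRUE))
}

#' Fit one of the five low-risk prediction models
#'
#' @param data Modeling table from [assembleModelData()]; the outcome is
#'   the logical/0-1 column named by `outcome`.
#' @param modelId Integer 1-5.
#' @param intensityOnly Restrict radiomics pools to first-order intensity
#'   features (the intensities-only model variant).
#' @param outcome Outcome column name (default `"low_risk"`).
#' @param gamma,nfolds,lambdaRule Selection settings, see
#'   [adaptiveLassoSelect()].
#' @param seed Seed for fold assignment.
#' @return A `riskModel` object: selected variables, standardization
#'   parameters, logistic coefficients, and fitting metadata.
#' @export
fitRiskModel <- function(data, modelId, intensityOnly = FALSE,
                         outcome = "low_risk", gamma = 1, nfolds = 10,
                         lambdaRule = "1se", seed = 1L) {
    spec <- modelPool(modelId, intensityOnly)
    y <- as.integer(data[[outcome]])
    if (length(unique(y)) < 2L)
        stop("outcome has a single class; the model cannot be fit")
    missingCols <- setdiff(spec$pool, names(data))
    if (length(missingCols))
        stop(sprintf("modeling table lacks %d pool column(s), e.g. %s",
                     length(missingCols), missingCols[1]))
    std <- standardizeFeatures(data[, spec$pool, drop = FALSE])
    forced <- intersect(spec$forced, colnames(std$x))
    selected <- if (spec$select)
        adaptiveLassoSelect(std$x, y, forced = forced, gamma = gamma,
                            nfolds = nfolds, lambdaRule = lambdaRule,
                            seed = seed)$selected
    else forced
    xsel <- std$x[, selected, drop = FALSE]
    df <- data.frame(y = y, xsel, check.names = FALSE)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    fallback <- !fit$converged || any(abs(coef(fit)) > 20, na.rm = TRUE) ||
        anyNA(coef(fit))
    if (fallback) {
        ## separation: ridge-stabilized refit at a small fixed penalty
        ## (glmnet needs >= 2 columns; pad with a void one if necessary)
        xr <- if (ncol(xsel) < 2L) cbind(xsel, `.void.` = 0) else xsel
        rf <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                             lambda = 1e-2, standardize = FALSE)
        cf <- setNames(c(as.numeric(rf$a0), as.numeric(rf$beta)),
                       c("(Intercept)", rownames(rf$beta)))
        cf <- cf[c("(Intercept)", colnames(xsel))]
    } else {
        cf <- coef(fit)
        names(cf) <- c("(Intercept)", colnames(xsel))
    }
    structure(list(modelId = modelId, intensityOnly = intensityOnly,
                   selected = selected, forced = forced,
                   standardization = std$params, coefficients = cf,
                   ridgeFallback = fallback, outcome = outcome, seed = seed),
              class = "riskModel")
}

#' @export
print.riskModel <- function(x, ...) {
    cat(sprintf("riskModel %d%s: %d variable(s)%s%s\n  %s\n", x$modelId,
                if (x$intensityOnly) " (intensity-only)" else "",
                length(x$selected),
                sprintf(" (forced: %s)", paste(x$forced, collapse = ", ")),
                if (x$ridgeFallback) " [ridge-stabilized]" else "",
                paste(x$selected, collapse = ", ")))
    invisible(x)
}

#' Predicted probability of low risk for lesion records
#'
#' @param model A `riskModel`.
#' @param data Table containing the model's variables on the raw scale.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predictLesion <- function(model, data) {
    vars <- model$selected
    missingCols <- setdiff(vars, names(data))
    if (length(missingCols))
        stop(sprintf("missing model variable(s): %s",
                     paste(missingCols, collapse = ", ")))
    keepParams <- model$standardization
    keepParams$keep <- vars
    x <- standardizeFeatures(data[, vars, drop = FALSE], keepParams)$x
    eta <- model$coefficients[["(Intercept)"]] +
        as.numeric(x %*% model$coefficients[vars])
    plogis(eta)
}

#' Patient-level predicted probability of low risk
#'
#' Policies: `"worst_lesion_truth"` evaluates the model on the lesion with
#' the highest true three-tier score (the study-design evaluation used for
#' patient-level performance); `"min_prob"` takes the minimum predicted
#' low-risk probability over the patient's lesions (deployable before
#' biopsy, when no truth is available).
#'
#' @param model A `riskModel`.
#' @param data Lesion rows of one or more patients, with `patient_id` and,
#'   for the default policy, the true `three_tier` column.
#' @param policy `"worst_lesion_truth"` or `"min_prob"`.
#' @return `data.frame` with one row per patient: `patient_id`, `prob`,
#'   `policy`.
#' @export
predictPatient <- function(model, data, policy = c("worst_lesion_truth", "min_prob")) {
    policy <- match.arg(policy)
    probs <- predictLesion(model, data)
    out <- lapply(split(seq_len(nrow(data)), data$patient_id), function(idx) {
        p <- if (policy == "min_prob") min(probs[idx])
        else {
            tier <- as.integer(factor(as.character(data$three_tier[idx]),
                                      levels = .TIER_LEVELS, ordered = TRUE))
            probs[idx][which.max(tier)]
        }
        data.frame(patient_id = data$patient_id[idx[1]], prob = p,
                   policy = policy)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Reduce a lesion-level modeling table to worst-lesion patient rows
#'
#' Selects, per patient, the lesion with the highest true three-tier score
#' (ties broken by Spratt numeric score, then table order); the patient
#' outcome is `patient_low_risk`.
#'
#' @param data Modeling table with `three_tier`, `spratt_numeric` and
#'   `patient_low_risk` columns.
#' @return One row per patient with `low_risk` replaced by the patient
#'   label.
#' @export
patientRows <- function(data) {
    pick <- vapply(split(seq_len(nrow(data)), data$patient_id), function(idx) {
        tier <- as.integer(factor(as.character(data$three_tier[idx]),
                                  levels = .TIER_LEVELS, ordered = TRUE))
        key <- tier * 10L + data$spratt_numeric[idx]
        idx[which.max(key)]
    }, integer(1))
    out <- data[sort(pick), , drop = FALSE]
    out$low_risk <- out$patient_low_risk
    rownames(out) <- NULL
    out
}
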