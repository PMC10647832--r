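## End-to-end orchestration over a run folder.
##
## Stages: simulate (phantom cohort to disk) -> extract (normalize +
## radiomics to features.csv) -> score (risk labels) -> fit (models) ->
## evaluate (result grid). Each stage reads only the previous stage's
## on-disk outputs, so re-running any stage with unchanged inputs
## reproduces its outputs; a full run is a deterministic function of
## (config, seed).

#' Default run configuration
#'
#' @param cohort A [cohortConfig()] for the simulate stage.
#' @param targets A [referenceTargets()] for normalization.
#' @param models Model ids fitted/evaluated.
#' @param variants `"full"` and/or `"intensity"`.
#' @param nBoot,nPerm Evaluation settings (see [runExperiment()]).
#' @param seed Global seed; stage seeds derive from it.
#' @return List of class `runConfig`.
#' @export
runConfig <- function(cohort = cohortConfig(), targets = referenceTargets(),
                      models = 1:5, variants = "full", nBoot = 0, nPerm = 0,
                      seed = 1L) {
    structure(list(cohort = cohort, targets = targets, models = models,
                   variants = variants, nBoot = nBoot, nPerm = nPerm,
                   seed = as.integer(seed)), class = "runConfig")
}

#' Pipeline stages over a run folder
#'
#' `stageSimulate()` writes the synthetic cohort under `<dir>/cohort/`;
#' `stageExtract()` normalizes every exam and writes the per-lesion
#' 487-column feature table (`features.csv`) with a JSON sidecar of the
#' extraction parameters; `stageScore()` appends the risk-label columns
#' (`scored.csv`); `stageFit()` fits the configured models and stores
#' their coefficients as JSON; `stageEvaluate()` writes the result grid
#' (`results.csv`). [runPipeline()] chains all five.
#'
#' @param config A [runConfig()].
#' @param dir Run folder.
#' @param force Overwrite an existing non-empty cohort folder.
#' @return The stage's main output, invisibly ([runPipeline()] returns the
#'   result grid).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
stageSimulate <- function(config, dir, force = FALSE) {
    out <- file.path(dir, "cohort")
    if (dir.exists(out) && length(list.files(out)) > 0 && !force)
        stop(sprintf("output folder %s exists and is not empty (use force = TRUE)", out))
    cohort <- generateCohort(config$cohort, seed = config$seed)
    writeCohort(cohort, out)
    invisible(cohort)
}

#' @rdname pipeline
#' @export
stageExtract <- function(config, dir) {
    cohort <- readCohort(file.path(dir, "cohort"))
    feats <- extractCohortFeatures(cohort$studies, cohort$lesions,
                                   targets = config$targets)
    write.csv(feats, file.path(dir, "features.csv"), row.names = FALSE)
    jsonlite::write_json(
        list(window = 5, n_bins = 128, offsets = "13 unit directions",
             symmetric = TRUE, percentile_rule = "linear interpolation (type 7)",
             sd = "sample (n-1)", kurtosis = "excess", entropy_log = "natural",
             seed = config$seed),
        file.path(dir, "extraction.json"), auto_unbox = TRUE)
    invisible(feats)
}

#' @rdname pipeline
#' @export
stageScore <- function(config, dir) {
    lesions <- readCohortTable(file.path(dir, "cohort", "cohort.csv"))
    scored <- scoreCohort(lesions)
    write.csv(scored, file.path(dir, "scored.csv"), row.names = FALSE)
    invisible(scored)
}

#' @rdname pipeline
#' @export
stageFit <- function(config, dir) {
    data <- .readModelData(dir)
    fits <- lapply(config$models, function(m)
        fitRiskModel(data, m, seed = config$seed))
    names(fits) <- paste0("model", config$models)
    jsonlite::write_json(
        lapply(fits, function(f)
            list(model_id = f$modelId, selected = f$selected,
                 coefficients = as.list(f$coefficients),
                 center = as.list(f$standardization$center[f$selected]),
                 scale = as.list(f$standardization$scale[f$selected]),
                 ridge_fallback = f$ridgeFallback, seed = f$seed)),
        file.path(dir, "models.json"), auto_unbox = TRUE, digits = NA)
    invisible(fits)
}

#' @rdname pipeline
#' @export
stageEvaluate <- function(config, dir) {
    data <- .readModelData(dir)
    grid <- runExperiment(data, models = config$models,
                          variants = config$variants, nBoot = config$nBoot,
                          nPerm = config$nPerm, seed = config$seed)
    write.csv(grid, file.path(dir, "results.csv"), row.names = FALSE)
    invisible(grid)
}

.readModelData <- function(dir) {
    feats <- read.csv(file.path(dir, "features.csv"), check.names = FALSE)
    scored <- read.csv(file.path(dir, "scored.csv"))
    scored$three_tier <- factor(scored$three_tier, levels = .TIER_LEVELS,
                                ordered = TRUE)
    assembleModelData(feats, scored)
}

#' @rdname pipeline
#' @export
runPipeline <- function(config, dir, force = FALSE) {
    stageSimulate(config, dir, force = force)
    stageExtract(config, dir)
    stageScore(config, dir)
    stageFit(config, dir)
    invisible(stageEvaluate(config, dir))
}

#' Extract features for every lesion of a cohort
#'
#' Normalizes each exam and extracts the 487-value feature vector per
#' lesion record.
#'
#' @param studies Named list of [MpmriStudy] (names = exam ids).
#' @param lesions Per-lesion table with `patient_id`, `exam_id`,
#'   `lesion_id`.
#' @param targets [referenceTargets()] used for normalization.
#' @param ... Passed to [extractFeatures()].
#' @return `data.frame`: key columns plus [allFeatureNames()] columns.
#' @export
extractCohortFeatures <- function(studies, lesions, targets = referenceTargets(),
                                  ...) {
    rows <- vector("list", nrow(lesions))
    cache <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(lesions))) {
        eid <- lesions$exam_id[i]
        if (is.null(cache[[eid]])) {
            st <- normalizeStudy(studies[[eid]], targets)
            ## NAPZ/NATZ features are shared by every lesion of an exam
            cache[[eid]] <- list(
                study = st,
                nat = c(extractRoiFeatures(st, getMask(st, "NAPZ"), ...),
                        extractRoiFeatures(st, getMask(st, "NATZ"), ...)))
        }
        st <- cache[[eid]]$study
        L <- getMask(st, "L", lesions$lesion_id[i])
        fv <- c(HRS6 = hrs6Volume(L, voxelSpacing(studyVolumes(st)$t2)),
                extractRoiFeatures(st, L, ...), cache[[eid]]$nat)
        stopifnot(identical(names(fv), allFeatureNames()))
        rows[[i]] <- data.frame(patient_id = lesions$patient_id[i],
                                exam_id = eid,
                                lesion_id = lesions$lesion_id[i],
                                as.list(fv), check.names = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
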