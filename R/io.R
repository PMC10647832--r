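## Readers/writers: NIfTI volumes and masks per exam (one file per
## sequence/mask plus a YAML layout file), CSV cohort tables, YAML configs.
## No resampling is performed anywhere: masks must share the volume grid,
## and any co-registration is assumed to have happened upstream.

.niftiWrite <- function(values, spacing, path) {
    img <- RNifti::asNifti(values)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, path)
    invisible(path)
}

.niftiRead <- function(path) {
    img <- RNifti::readNifti(path)
    list(values = array(as.numeric(img), dim(img)),
         spacing = as.numeric(RNifti::pixdim(img))[1:3])
}

#' Write an exam to a directory
#'
#' One uncompressed NIfTI file per sequence (`<seq>.nii`) and per mask
#' (`mask_<role>[_<lesionId>].nii`), plus `study.yaml` recording ids, roles
#' and file names.
#'
#' @param study An [MpmriStudy].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    layout <- list(patient_id = patientId(study), exam_id = examId(study),
                   sequences = list(), masks = list())
    for (s in names(studyVolumes(study))) {
        v <- studyVolumes(study)[[s]]
        f <- paste0(s, ".nii")
        .niftiWrite(gridValues(v), voxelSpacing(v), file.path(dir, f))
        layout$sequences[[s]] <- f
    }
    for (i in seq_along(studyMasks(study))) {
        m <- studyMasks(study)[[i]]
        tag <- if (is.na(lesionId(m))) maskRole(m)
               else paste(maskRole(m), lesionId(m), sep = "_")
        f <- paste0("mask_", tag, ".nii")
        .niftiWrite(array(as.integer(maskArray(m)), dim(maskArray(m))),
                    voxelSpacing(studyVolumes(study)[[1]]), file.path(dir, f))
        layout$masks[[length(layout$masks) + 1L]] <-
            list(role = maskRole(m), lesion_id = lesionId(m), file = f)
    }
    yaml::write_yaml(layout, file.path(dir, "study.yaml"))
    invisible(dir)
}

#' Read an exam from a directory written by [writeStudy()]
#'
#' Validates that all sequences share one grid shape and voxel spacing and
#' that every mask matches the grid; mismatches fail naming the offending
#' file.
#'
#' @param dir Directory containing `study.yaml`.
#' @return An [MpmriStudy].
#' @export
readStudy <- function(dir) {
    lay <- yaml::read_yaml(file.path(dir, "study.yaml"))
    missing <- setdiff(mriSequences(), names(lay$sequences))
    if (length(missing))
        stop(sprintf("study in %s is missing sequence(s): %s", dir,
                     paste(missing, collapse = ", ")))
    vols <- list()
    ref <- NULL
    for (s in mriSequences()) {
        f <- file.path(dir, lay$sequences[[s]])
        nii <- .niftiRead(f)
        if (is.null(ref)) ref <- nii
        if (!identical(dim(nii$values), dim(ref$values)))
            stop(sprintf("volume shape mismatch in %s: %s vs %s", f,
                         paste(dim(nii$values), collapse = "x"),
                         paste(dim(ref$values), collapse = "x")))
        if (max(abs(nii$spacing - ref$spacing)) > 1e-6)
            stop(sprintf("voxel spacing mismatch in %s", f))
        vols[[s]] <- VolumeGrid(nii$values, nii$spacing, s)
    }
    masks <- lapply(lay$masks, function(m) {
        f <- file.path(dir, m$file)
        nii <- .niftiRead(f)
        if (!identical(dim(nii$values), dim(ref$values)))
            stop(sprintf("mask shape mismatch in %s: %s vs grid %s", f,
                         paste(dim(nii$values), collapse = "x"),
                         paste(dim(ref$values), collapse = "x")))
        RoiMask(array(nii$values > 0.5, dim(nii$values)), m$role,
                if (is.null(m$lesion_id)) NA_character_ else m$lesion_id)
    })
    MpmriStudy(lay$patient_id, lay$exam_id, vols, masks)
}

.COHORT_REQUIRED <- c("patient_id", "lesion_id", "age", "psa", "dre",
                      "pirads", "t_stage", "grade_group", "decipher")

#' Read and validate a per-lesion cohort table
#'
#' Expects one row per lesion with the documented clinical columns plus a
#' Decipher score; `psad` is computed from `psa` and `prostate_volume` when
#' absent. Unknown columns are preserved. Out-of-range values fail with the
#' offending row index. An empty file yields an empty cohort.
#'
#' @param path CSV file path.
#' @return Validated `data.frame`, one row per lesion.
#' @export
readCohortTable <- function(path) {
    tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                    error = function(e) {
                        if (grepl("no lines available", conditionMessage(e)))
                            return(data.frame())
                        stop(e)
                    })
    if (nrow(tab) == 0L) return(tab)
    validateCohortTable(tab)
}

#' @rdname readCohortTable
#' @param tab In-memory cohort `data.frame` to validate.
#' @export
validateCohortTable <- function(tab) {
    missing <- setdiff(.COHORT_REQUIRED, names(tab))
    if (length(missing))
        stop(sprintf("cohort table is missing column(s): %s",
                     paste(missing, collapse = ", ")))
    if (!"psad" %in% names(tab)) {
        if (!"prostate_volume" %in% names(tab))
            stop("cohort table needs either psad or prostate_volume")
        tab$psad <- tab$psa / tab$prostate_volume
    }
    bad <- function(cond, what) {
        if (any(cond, na.rm = TRUE) || anyNA(cond))
            stop(sprintf("%s out of range at row(s): %s", what,
                         paste(which(cond | is.na(cond)), collapse = ", ")))
    }
    bad(!tab$dre %in% 0:2, "dre (must be 0, 1 or 2)")
    bad(!tab$pirads %in% 1:5, "pirads (must be 1..5)")
    bad(!tab$grade_group %in% 1:5, "grade_group (must be 1..5)")
    bad(tab$decipher < 0 | tab$decipher > 1, "decipher (must lie in [0,1])")
    bad(tab$psa <= 0, "psa (must be > 0)")
    bad(tab$psad <= 0, "psad (must be > 0)")
    bad(!tab$t_stage %in% .T_STAGES, "t_stage")
    tab
}

#' Write a cohort table as CSV
#'
#' @param lesions Per-lesion `data.frame`.
#' @param path Output CSV path.
#' @export
writeCohortTable <- function(lesions, path) {
    write.csv(lesions, path, row.names = FALSE)
    invisible(path)
}

#' Write a full synthetic cohort to a run directory
#'
#' Exams under `exams/<exam_id>/` (NIfTI), the per-lesion table as
#' `cohort.csv`, and the generating config as `config.yaml`.
#'
#' @param cohort An `MpmriCohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (st in cohortStudies(cohort))
        writeStudy(st, file.path(dir, "exams", examId(st)))
    writeCohortTable(cohortLesions(cohort), file.path(dir, "cohort.csv"))
    cfg <- cohort@config
    yaml::write_yaml(
        lapply(setNames(slotNames(cfg), slotNames(cfg)),
               function(s) { v <- slot(cfg, s); if (is.list(v)) v else as.vector(v) }),
        file.path(dir, "config.yaml"))
    invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir Cohort directory.
#' @return List with `studies` (list of [MpmriStudy]) and `lesions`
#'   (validated `data.frame`).
#' @export
readCohort <- function(dir) {
    examDirs <- list.dirs(file.path(dir, "exams"), recursive = FALSE)
    studies <- lapply(examDirs, readStudy)
    names(studies) <- vapply(studies, examId, character(1))
    list(studies = studies,
         lesions = readCohortTable(file.path(dir, "cohort.csv")))
}
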