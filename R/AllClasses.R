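## Central S4 data model: one MRI sequence on a voxel grid, a boolean ROI on
## the same grid, and a co-registered three-sequence exam with its masks.

#' @rdname VolumeGrid
#' @export
setClass("VolumeGrid",
    representation(values = "array", spacing = "numeric", sequence = "character"))

#' @rdname RoiMask
#' @export
setClass("RoiMask",
    representation(mask = "array", role = "character", lesionId = "character"))

#' @rdname MpmriStudy
#' @export
setClass("MpmriStudy",
    representation(patientId = "character", examId = "character",
                   volumes = "list", masks = "list"))

#' @rdname cohortConfig
#' @export
setClass("CohortConfig",
    representation(
        nPatients = "integer",
        lesionProbs = "numeric",
        fracLowRisk = "numeric",
        gridShape = "integer",
        voxelSpacing = "numeric",
        effectSizes = "numeric",
        natEffectSizes = "numeric",
        betweenLesionSd = "numeric",
        textureEffect = "numeric",
        textureJitterSd = "numeric",
        volumeEffect = "numeric",
        noiseSd = "numeric",
        dreRates = "numeric",
        decipherParams = "list",
        clinicalEffects = "list",
        duplicateExamRate = "numeric",
        seed = "integer"))

#' @rdname generateCohort
#' @export
setClass("MpmriCohort",
    representation(studies = "list", lesions = "data.frame",
                   config = "CohortConfig"))

mriSequences <- function() c("t2", "adc", "b")

maskRoles <- function() c("L", "NAPZ", "NATZ", "GM", "femoral_head", "bladder")

setValidity("VolumeGrid", function(object) {
    msg <- character()
    if (length(dim(object@values)) != 3L)
        msg <- c(msg, "values must be a 3D array")
    if (!all(is.finite(object@values)))
        msg <- c(msg, "all voxel values must be finite")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be three positive numbers (mm)")
    if (length(object@sequence) != 1L || !object@sequence %in% mriSequences())
        msg <- c(msg, sprintf("sequence must be one of: %s",
                              paste(mriSequences(), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

setValidity("RoiMask", function(object) {
    msg <- character()
    if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
        msg <- c(msg, "mask must be a 3D logical array")
    if (any(is.na(object@mask)))
        msg <- c(msg, "mask must not contain NA")
    if (length(object@role) != 1L || !object@role %in% maskRoles())
        msg <- c(msg, sprintf("role must be one of: %s",
                              paste(maskRoles(), collapse = ", ")))
    if (length(object@lesionId) != 1L)
        msg <- c(msg, "lesionId must be a single string (NA when not a lesion)")
    if (length(msg)) msg else TRUE
})

setValidity("MpmriStudy", function(object) {
    msg <- character()
    if (!identical(sort(names(object@volumes)), sort(mriSequences())))
        msg <- c(msg, sprintf("volumes must contain exactly the sequences %s; missing: %s",
                              paste(mriSequences(), collapse = ", "),
                              paste(setdiff(mriSequences(), names(object@volumes)),
                                    collapse = ", ")))
    else {
        dims <- lapply(object@volumes, function(v) dim(v@values))
        if (!all(vapply(dims, identical, logical(1), dims[[1]])))
            msg <- c(msg, "all sequence volumes must share one grid shape")
        sp <- lapply(object@volumes, function(v) v@spacing)
        if (!all(vapply(sp, function(s) isTRUE(all.equal(s, sp[[1]])), logical(1))))
            msg <- c(msg, "all sequence volumes must share one voxel spacing")
        bad <- vapply(object@masks, function(m)
            !identical(dim(m@mask), dims[[1]]), logical(1))
        if (any(bad))
            msg <- c(msg, sprintf("mask(s) %s are not shape-compatible with the grid",
                                  paste(which(bad), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' One MRI sequence as a 3D scalar field with voxel spacing
#'
#' @param values 3D numeric array of voxel intensities.
#' @param spacing Voxel spacing in mm along each axis (length 3).
#' @param sequence Sequence label: `"t2"` (T2-weighted), `"adc"` (apparent
#'   diffusion coefficient map) or `"b"` (high b-value DWI).
#' @return A `VolumeGrid` object.
#' @examples
#' v <- VolumeGrid(array(runif(8 * 8 * 4), c(8, 8, 4)), c(1, 1, 3), "t2")
#' voxelSpacing(v)
#' @export
VolumeGrid <- function(values, spacing, sequence) {
    new("VolumeGrid", values = values, spacing = as.numeric(spacing),
        sequence = as.character(sequence))
}

#' A binary region-of-interest mask aligned to a volume grid
#'
#' Roles follow the analysis vocabulary: `L` (lesion), `NAPZ` / `NATZ`
#' (normally appearing peripheral / transition zone), and the reference
#' tissues `GM` (gluteus maximus), `femoral_head` and `bladder`.
#'
#' @param mask 3D logical array, same shape as the grid it annotates.
#' @param role One of `"L"`, `"NAPZ"`, `"NATZ"`, `"GM"`, `"femoral_head"`,
#'   `"bladder"`.
#' @param lesionId Identifier for lesion masks; `NA` otherwise.
#' @return A `RoiMask` object.
#' @export
RoiMask <- function(mask, role, lesionId = NA_character_) {
    new("RoiMask", mask = mask, role = as.character(role),
        lesionId = as.character(lesionId))
}

#' A co-registered mpMRI exam: three sequences plus ROI and reference masks
#'
#' @param patientId,examId Identifiers.
#' @param volumes Named list with elements `t2`, `adc`, `b`, each a
#'   [VolumeGrid] on the same grid.
#' @param masks List of [RoiMask] objects, all shape-compatible with the grid.
#' @return An `MpmriStudy` object.
#' @export
MpmriStudy <- function(patientId, examId, volumes, masks) {
    new("MpmriStudy", patientId = as.character(patientId),
        examId = as.character(examId), volumes = volumes, masks = masks)
}

#' @describeIn VolumeGrid voxel value array
#' @param x,object A `VolumeGrid`.
#' @export
gridValues <- function(x) x@values

#' @describeIn VolumeGrid voxel spacing in mm
#' @export
voxelSpacing <- function(x) x@spacing

#' @describeIn VolumeGrid sequence label
#' @export
sequenceType <- function(x) x@sequence

#' @describeIn RoiMask logical voxel array
#' @param x,object A `RoiMask`.
#' @export
maskArray <- function(x) x@mask

#' @describeIn RoiMask role label
#' @export
maskRole <- function(x) x@role

#' @describeIn RoiMask lesion identifier (NA for non-lesion masks)
#' @export
lesionId <- function(x) x@lesionId

#' @describeIn MpmriStudy named list of sequence volumes
#' @param x,object An `MpmriStudy`.
#' @export
studyVolumes <- function(x) x@volumes

#' @describeIn MpmriStudy list of ROI and reference masks
#' @export
studyMasks <- function(x) x@masks

#' @describeIn MpmriStudy patient identifier
#' @export
patientId <- function(x) x@patientId

#' @describeIn MpmriStudy exam identifier
#' @export
examId <- function(x) x@examId

#' @describeIn MpmriStudy retrieve one mask by role (and lesion id for `"L"`)
#' @param role Mask role to retrieve.
#' @param lesion Lesion id, required when several lesion masks are present.
#' @export
getMask <- function(x, role, lesion = NULL) {
    hits <- Filter(function(m) m@role == role, x@masks)
    if (role == "L" && !is.null(lesion))
        hits <- Filter(function(m) identical(m@lesionId, as.character(lesion)), hits)
    if (length(hits) == 0L)
        stop(sprintf("study %s has no mask with role '%s'%s", x@examId, role,
                     if (is.null(lesion)) "" else sprintf(" and lesion id '%s'", lesion)))
    if (length(hits) > 1L)
        stop(sprintf("role '%s' is ambiguous in study %s; give a lesion id",
                     role, x@examId))
    hits[[1]]
}

#' @describeIn MpmriStudy all lesion masks of a study
#' @export
lesionMasks <- function(x) Filter(function(m) m@role == "L", x@masks)

setMethod("show", "VolumeGrid", function(object) {
    d <- dim(object@values)
    cat(sprintf("VolumeGrid [%s] %d x %d x %d voxels, spacing %s mm, range [%.4g, %.4g]\n",
                object@sequence, d[1], d[2], d[3],
                paste(format(object@spacing, digits = 3), collapse = " x "),
                min(object@values), max(object@values)))
})

setMethod("show", "RoiMask", function(object) {
    cat(sprintf("RoiMask [%s%s] %d voxels set of %s\n", object@role,
                if (is.na(object@lesionId)) "" else paste0(":", object@lesionId),
                sum(object@mask), length(object@mask)))
})

setMethod("show", "MpmriStudy", function(object) {
    cat(sprintf("MpmriStudy patient %s exam %s\n", object@patientId, object@examId))
    for (v in object@volumes) show(v)
    cat(sprintf("  masks: %s\n",
                paste(vapply(object@masks, function(m)
                    if (is.na(m@lesionId)) m@role else paste0(m@role, ":", m@lesionId),
                    character(1)), collapse = ", ")))
})

setMethod("show", "MpmriCohort", function(object) {
    cat(sprintf("MpmriCohort: %d exam(s), %d lesion record(s), %d low-risk / %d non-low\n",
                length(object@studies), nrow(object@lesions),
                sum(object@lesions$true_class == "low"),
                sum(object@lesions$true_class != "low")))
})

#' @describeIn generateCohort list of [MpmriStudy] exams of a cohort
#' @param x An `MpmriCohort`.
#' @export
cohortStudies <- function(x) x@studies

#' @describeIn generateCohort per-lesion table (clinical record, Decipher
#'   score and ground-truth class, one row per lesion)
#' @export
cohortLesions <- function(x) x@lesions
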