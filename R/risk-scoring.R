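## Clinical-genomic risk labeling.
##
## NCCN group (low / favorable intermediate / unfavorable intermediate /
## high-or-very-high, coded 0-3) and Decipher category (low / intermediate /
## high at the 0.45 and 0.60 cutoffs, coded 0-2) are summed into the Spratt
## numeric score (0-5), reported as a three-tier group. A lesion is low
## risk iff (i) NCCN low with Decipher low or intermediate, or (ii) NCCN
## low or intermediate with Decipher low. A patient is low risk iff all of
## their lesions are; the patient three-tier group is the worst lesion's.

.NCCN_LEVELS <- c("low", "favorable_intermediate", "unfavorable_intermediate", "high")
.DECIPHER_LEVELS <- c("low", "intermediate", "high")
.TIER_LEVELS <- c("low", "intermediate", "high")
.T_STAGES <- c("T1a", "T1b", "T1c", "T2a", "T2b", "T2c", "T3a", "T3b", "T4")

#' Decipher genomic-classifier category
#'
#' Categorizes a Decipher score in \[0, 1\] at the 0.45 and 0.60 cutoffs;
#' boundaries are half-open: `[0, 0.45)` low, `[0.45, 0.60)` intermediate,
#' `[0.60, 1]` high.
#'
#' @param score Numeric vector of Decipher scores in \[0, 1\].
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @examples
#' decipherCategory(c(0.30, 0.50, 0.60))
#' @export
decipherCategory <- function(score) {
    stopIfNot01(score, "Decipher score")
    cut(score, c(-Inf, 0.45, 0.60, Inf), labels = .DECIPHER_LEVELS, right = FALSE)
}

#' NCCN clinical risk group
#'
#' Default rule table: low = (stage at most T2a, grade group 1, PSA < 10);
#' high/very-high = any of (stage T3a or above, grade group 4-5, PSA > 20);
#' otherwise intermediate, split favorable vs unfavorable by counting
#' intermediate risk factors (stage T2b-T2c, grade group 2-3, PSA 10-20):
#' favorable requires a single factor, grade group 1-2 and < 50 percent
#' positive cores (missing core percentage is treated as < 50 percent).
#'
#' @param tStage Character vector of T stages (`T1a` ... `T4`).
#' @param gradeGroup Integer vector, 1-5.
#' @param psa PSA in ng/mL.
#' @param pctPositiveCores Optional proportion of positive cores in
#'   \[0, 1\]; used only to split the intermediate group.
#' @return Factor with levels `low`, `favorable_intermediate`,
#'   `unfavorable_intermediate`, `high`.
#' @export
nccnGroup <- function(tStage, gradeGroup, psa, pctPositiveCores = NA_real_) {
    n <- max(length(tStage), length(gradeGroup), length(psa))
    tStage <- rep_len(as.character(tStage), n)
    gradeGroup <- rep_len(as.integer(gradeGroup), n)
    psa <- rep_len(as.numeric(psa), n)
    pctPositiveCores <- rep_len(as.numeric(pctPositiveCores), n)
    miss <- c(tStage = anyNA(tStage), gradeGroup = anyNA(gradeGroup), psa = anyNA(psa))
    if (any(miss))
        stop(sprintf("missing required field(s): %s",
                     paste(names(miss)[miss], collapse = ", ")))
    if (!all(tStage %in% .T_STAGES))
        stop(sprintf("unknown T stage(s): %s",
                     paste(unique(tStage[!tStage %in% .T_STAGES]), collapse = ", ")))
    if (any(gradeGroup < 1L | gradeGroup > 5L))
        stop("grade group must lie in 1..5")
    tIdx <- match(tStage, .T_STAGES)
    high <- tIdx >= match("T3a", .T_STAGES) | gradeGroup >= 4L | psa > 20
    low <- !high & tIdx <= match("T2a", .T_STAGES) & gradeGroup == 1L & psa < 10
    irf <- (tIdx %in% match(c("T2b", "T2c"), .T_STAGES)) +
        (gradeGroup %in% 2:3) + (psa >= 10 & psa <= 20)
    coresOk <- is.na(pctPositiveCores) | pctPositiveCores < 0.5
    fav <- !high & !low & irf == 1L & gradeGroup <= 2L & coresOk
    out <- ifelse(high, "high",
           ifelse(low, "low",
           ifelse(fav, "favorable_intermediate", "unfavorable_intermediate")))
    factor(out, levels = .NCCN_LEVELS)
}

#' Spratt clinical-genomic risk labels
#'
#' Adds the NCCN numeric value (0-3) and the Decipher numeric value (0-2)
#' into the six-tier Spratt score, maps it to the three-tier group, and
#' flags low-risk lesions. The default three-tier map assigns `low` to
#' exactly the low-risk rule cells, `high` to Spratt score >= 4, and
#' `intermediate` to everything else. With `rule = "strict"`, the
#' "NCCN low-or-intermediate with Decipher low" arm of the low-risk rule
#' accepts only favorable intermediate.
#'
#' @param nccn Factor/character of NCCN groups (see [nccnGroup()]).
#' @param decipher Factor/character of Decipher categories (see
#'   [decipherCategory()]).
#' @param rule `"default"` (intermediate includes unfavorable) or
#'   `"strict"`.
#' @return `data.frame` with columns `nccn_group`, `nccn_value`,
#'   `decipher_category`, `decipher_value`, `spratt_numeric`, `three_tier`,
#'   `low_risk`.
#' @export
sprattLabels <- function(nccn, decipher, rule = c("default", "strict")) {
    rule <- match.arg(rule)
    nccn <- factor(as.character(nccn), levels = .NCCN_LEVELS)
    decipher <- factor(as.character(decipher), levels = .DECIPHER_LEVELS)
    if (anyNA(nccn)) stop("invalid NCCN group value")
    if (anyNA(decipher)) stop("invalid Decipher category value")
    nv <- as.integer(nccn) - 1L
    dv <- as.integer(decipher) - 1L
    numeric <- nv + dv
    maxNccn <- if (rule == "default") 2L else 1L
    lowRisk <- (nv == 0L & dv <= 1L) | (nv <= maxNccn & dv == 0L)
    tier <- ifelse(lowRisk, "low", ifelse(numeric >= 4L, "high", "intermediate"))
    data.frame(nccn_group = nccn, nccn_value = nv,
               decipher_category = decipher, decipher_value = dv,
               spratt_numeric = numeric,
               three_tier = factor(tier, levels = .TIER_LEVELS, ordered = TRUE),
               low_risk = lowRisk)
}

#' Patient-level risk label from lesion labels
#'
#' The patient three-tier group is the maximum over the lesions; the
#' patient is low risk iff every lesion is (equivalently, iff the worst
#' lesion is).
#'
#' @param threeTier Ordered factor/character of lesion three-tier groups.
#' @return List with `three_tier` (ordered factor, length 1) and
#'   `low_risk`.
#' @export
patientLabel <- function(threeTier) {
    threeTier <- factor(as.character(threeTier), levels = .TIER_LEVELS,
                        ordered = TRUE)
    if (length(threeTier) == 0L || anyNA(threeTier))
        stop("patientLabel needs at least one valid lesion label")
    worst <- max(threeTier)
    list(three_tier = worst, low_risk = worst == "low")
}

#' Append risk-label columns to a per-lesion cohort table
#'
#' Computes NCCN group, Decipher category, Spratt score, three-tier group
#' and low-risk flag per lesion, plus the patient-level aggregate
#' (`patient_three_tier`, `patient_low_risk`) over each `patient_id`.
#'
#' @param lesions Per-lesion `data.frame` with columns `patient_id`,
#'   `t_stage`, `grade_group`, `psa`, `decipher` and optionally
#'   `pct_positive_cores`.
#' @param rule Passed to [sprattLabels()].
#' @return The input with the label columns appended.
#' @export
scoreCohort <- function(lesions, rule = "default") {
    cores <- if ("pct_positive_cores" %in% names(lesions))
        lesions$pct_positive_cores else NA_real_
    nccn <- nccnGroup(lesions$t_stage, lesions$grade_group, lesions$psa, cores)
    lab <- sprattLabels(nccn, decipherCategory(lesions$decipher), rule = rule)
    out <- cbind(lesions, lab)
    byPatient <- split(seq_len(nrow(out)), out$patient_id)
    out$patient_three_tier <- factor(NA, levels = .TIER_LEVELS, ordered = TRUE)
    out$patient_low_risk <- NA
    for (idx in byPatient) {
        p <- patientLabel(out$three_tier[idx])
        out$patient_three_tier[idx] <- p$three_tier
        out$patient_low_risk[idx] <- p$low_risk
    }
    out
}
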