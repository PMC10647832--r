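## Performance machinery: ROC/AUC, the Venkatraman-Begg permutation test
## for equality of paired ROC curves, Harrell's bootstrap
## optimism-corrected AUC, and the full experiment grid
## (model x lesion/patient level x all/DRE-negative subset).

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney statistic (ties counted 1/2), which equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return List of class `rocResult`: `auc`, `fpr`, `tpr`, `nPos`, `nNeg`.
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.integer(labels)
    if (length(scores) != length(labels))
        stop("scores and labels differ in length")
    nPos <- sum(labels == 1L)
    nNeg <- sum(labels == 0L)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be present to compute a ROC curve")
    r <- rank(scores)
    auc <- (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    thr <- sort(unique(scores), decreasing = TRUE)
    tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
    fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
    structure(list(auc = auc, fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos),
                   nPos = nPos, nNeg = nNeg), class = "rocResult")
}

#' @export
print.rocResult <- function(x, ...) {
    cat(sprintf("ROC: AUC = %.4f (%d positive / %d negative)\n",
                x$auc, x$nPos, x$nNeg))
    invisible(x)
}

## Venkatraman-Begg error-count statistic for one marker given subject
## order by increasing rank: e(k) = n0 + cumsum(2*y - 1) counts the
## misclassifications when subjects with rank > k are called positive.
.vbErrorCurve <- function(ord, y, n0) {
    n0 + cumsum(2 * y[ord] - 1)
}

#' Venkatraman-Begg permutation test for equality of paired ROC curves
#'
#' Both markers score the same records. Scores are converted to
#' within-sample ranks; the statistic is the summed absolute difference,
#' over all rank cut-points, of the two markers' classification error
#' counts. The null distribution is built by exchanging the paired ranks
#' of each record with probability 1/2 and re-ranking (ties introduced by
#' the exchange are broken at random); the p-value is
#' `(1 + #{permuted >= observed}) / (nPerm + 1)`. The statistic is
#' invariant to strictly monotone transforms of either score.
#'
#' @param scoresA,scoresB Paired score vectors.
#' @param labels Binary labels, both classes present.
#' @param nPerm Number of permutations (default 2000).
#' @param seed Integer seed.
#' @return List of class `vbResult`: `statistic`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
venkatramanBeggTest <- function(scoresA, scoresB, labels, nPerm = 2000,
                                seed = 1L) {
    if (length(scoresA) != length(scoresB) ||
        length(scoresA) != length(labels))
        stop("scoresA, scoresB and labels must have equal length")
    y <- as.integer(labels)
    n <- length(y)
    n0 <- sum(y == 0L)
    if (n0 == 0L || n0 == n) stop("both classes must be present")
    set.seed(seed)
    ra <- rank(scoresA, ties.method = "average")
    rb <- rank(scoresB, ties.method = "average")
    statOf <- function(ra, rb) {
        ea <- .vbErrorCurve(order(ra), y, n0)
        eb <- .vbErrorCurve(order(rb), y, n0)
        sum(abs(ea - eb)[seq_len(n - 1)])
    }
    obs <- statOf(ra, rb)
    perm <- numeric(nPerm)
    for (b in seq_len(nPerm)) {
        swap <- runif(n) < 0.5
        pa <- ifelse(swap, rb, ra)
        pb <- ifelse(swap, ra, rb)
        perm[b] <- statOf(rank(pa, ties.method = "random"),
                          rank(pb, ties.method = "random"))
    }
    structure(list(statistic = obs,
                   p_value = (1 + sum(perm >= obs - 1e-12)) / (nPerm + 1),
                   n_permutations = nPerm, seed = seed,
                   permuted = perm), class = "vbResult")
}

#' @export
print.vbResult <- function(x, ...) {
    cat(sprintf("Venkatraman-Begg: statistic = %g, p = %.4g (%d permutations)\n",
                x$statistic, x$p_value, x$n_permutations))
    invisible(x)
}

#' Bootstrap optimism-corrected AUC
#'
#' Harrell's internal validation: the model-building procedure is re-run
#' on each bootstrap resample; its AUC on the resample minus its AUC on
#' the original data estimates the optimism, whose mean is subtracted from
#' the apparent AUC. Resamples containing a single outcome class are
#' redrawn (and counted).
#'
#' @param data Modeling table.
#' @param labels Binary outcome vector aligned to `data` rows.
#' @param builder Function `(data, labels) -> function(data) -> scores`;
#'   must be deterministic given the RNG state.
#' @param nBoot Number of bootstrap runs (the reference analysis uses
#'   1000).
#' @param seed Integer seed.
#' @return List of class `optimismResult`: `apparent`, `optimism`,
#'   `corrected`, `nBoot`, `redrawn`, `seed`.
#' @export
optimismCorrectedAuc <- function(data, labels, builder, nBoot = 1000,
                                 seed = 1L) {
    y <- as.integer(labels)
    set.seed(seed)
    f0 <- builder(data, y)
    apparent <- rocAuc(f0(data), y)$auc
    opt <- numeric(nBoot)
    redrawn <- 0L
    n <- nrow(data)
    for (b in seq_len(nBoot)) {
        repeat {
            idx <- sample(n, replace = TRUE)
            if (length(unique(y[idx])) == 2L) break
            redrawn <- redrawn + 1L
        }
        db <- data[idx, , drop = FALSE]
        fb <- builder(db, y[idx])
        opt[b] <- rocAuc(fb(db), y[idx])$auc - rocAuc(fb(data), y)$auc
    }
    structure(list(apparent = apparent, optimism = mean(opt),
                   corrected = apparent - mean(opt), nBoot = nBoot,
                   redrawn = redrawn, seed = seed), class = "optimismResult")
}

#' @export
print.optimismResult <- function(x, ...) {
    cat(sprintf("AUC: apparent %.4f, optimism %.4f, corrected %.4f (%d bootstrap runs)\n",
                x$apparent, x$optimism, x$corrected, x$nBoot))
    invisible(x)
}

#' Run the full model-evaluation grid
#'
#' Fits the requested models on the full lesion-level table (and, for the
#' patient level, on the worst-lesion patient rows), then evaluates each
#' fitted model on all records and on the DRE-negative subset. Optionally
#' adds the bootstrap optimism-corrected AUC and the Venkatraman-Begg
#' p-value against Model 1 within each cell. Cells whose subset holds a
#' single outcome class are reported as `NA`.
#'
#' @param data Modeling table from [assembleModelData()] +
#'   [scoreCohort()].
#' @param models Model ids to run (default 1:5).
#' @param levels `"lesion"`, `"patient"` or both.
#' @param variants `"full"`, `"intensity"` or both.
#' @param nBoot Bootstrap runs for optimism correction (0 = skip).
#' @param nPerm Venkatraman-Begg permutations (0 = skip).
#' @param seed Integer seed for selection folds, bootstrap and
#'   permutations.
#' @return `data.frame` with one row per (model, level, subset, variant)
#'   cell: counts, `auc`, `oc_auc`, `p_vs_model1`; the fitted models are
#'   attached as the `"models"` attribute.
#' @export
runExperiment <- function(data, models = 1:5,
                          levels = c("lesion", "patient"),
                          variants = "full", nBoot = 0, nPerm = 0,
                          seed = 1L) {
    rows <- list()
    fits <- list()
    for (variant in variants) {
        intOnly <- variant == "intensity"
        for (lev in levels) {
            tab <- if (lev == "patient") patientRows(data) else data
            y <- as.integer(tab$low_risk)
            scores <- list()
            for (m in models) {
                fit <- fitRiskModel(tab, m, intensityOnly = intOnly,
                                    seed = seed)
                fits[[sprintf("%s_%s_m%d", variant, lev, m)]] <- fit
                scores[[as.character(m)]] <- predictLesion(fit, tab)
            }
            for (sub in c("all", "dre0")) {
                keep <- if (sub == "dre0") tab$dre == 0L else rep(TRUE, nrow(tab))
                for (m in models) {
                    sc <- scores[[as.character(m)]][keep]
                    ys <- y[keep]
                    ok <- length(unique(ys)) == 2L
                    auc <- if (ok) rocAuc(sc, ys)$auc else NA_real_
                    oc <- NA_real_
                    if (ok && nBoot > 0) {
                        builder <- local({
                            mid <- m; io <- intOnly; sd0 <- seed
                            function(d, yy) {
                                d$low_risk <- yy
                                fit <- fitRiskModel(d, mid, intensityOnly = io,
                                                    seed = sd0)
                                function(newd) predictLesion(fit, newd)
                            }
                        })
                        oc <- optimismCorrectedAuc(tab[keep, , drop = FALSE],
                                                   ys, builder, nBoot = nBoot,
                                                   seed = seed)$corrected
                    }
                    pv <- NA_real_
                    if (ok && nPerm > 0 && m != 1 && "1" %in% names(scores))
                        pv <- venkatramanBeggTest(sc, scores[["1"]][keep], ys,
                                                  nPerm = nPerm,
                                                  seed = seed)$p_value
                    rows[[length(rows) + 1L]] <- data.frame(
                        model = m, level = lev, subset = sub,
                        variant = variant, n_pos = sum(ys == 1L),
                        n_neg = sum(ys == 0L), auc = auc, oc_auc = oc,
                        p_vs_model1 = pv, seed = seed)
                }
            }
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "models") <- fits
    out
}
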