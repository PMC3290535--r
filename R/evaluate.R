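#' @include AllClasses.R config.R
NULL

#' Random subsample of stranded reads
#'
#' Draws a simple random sample without replacement of
#' \code{floor(fraction * n)} reads from the pooled forward + reverse
#' read list (strands sampled jointly), deterministically given the
#' seed.  Used to emulate shallower sequencing.
#'
#' @param reads A [StrandedReads-class].
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return A [StrandedReads-class] with the sampled reads.
#' @export
subsampleReads <- function(reads, fraction, seed = 1L) {
    stopifnot(is(reads, "StrandedReads"))
    if (fraction <= 0 || fraction > 1)
        stop("'fraction' must be in (0, 1]")
    nf <- length(reads@fwd); n <- nf + length(reads@rev)
    m <- floor(fraction * n)
    set.seed(seed)
    take <- sample.int(n, m)
    StrandedReads(reads@chrom,
        fwd = reads@fwd[take[take <= nf]],
        rev = reads@rev[take[take > nf] - nf])
}

#' Match predictions to reference nucleosomes
#'
#' A reference is detected when any prediction lies within \code{dist}
#' of its center.  True-positive labels are assigned one-to-one by
#' greedy matching in order of increasing center distance, so one
#' prediction cannot detect several references; unmatched predictions
#' are false positives.
#'
#' @param predCenters Predicted centers (bp).
#' @param refCenters Reference centers (bp).
#' @param dist Detection distance (bp), > 0.
#' @return List with \code{detected} (logical per reference) and
#'   \code{truePos} (logical per prediction).
#' @export
matchToReference <- function(predCenters, refCenters, dist) {
    if (dist <= 0) stop("'dist' must be > 0")
    nP <- length(predCenters); nR <- length(refCenters)
    detected <- logical(nR); truePos <- logical(nP)
    if (nP && nR) {
        dmat <- abs(outer(predCenters, refCenters, "-"))
        detected <- apply(dmat <= dist, 2, any)
        cand <- which(dmat <= dist, arr.ind = TRUE)
        if (nrow(cand)) {
            dd <- dmat[cand]
            ## deterministic greedy: by distance, then ref, then pred
            ord <- order(dd, cand[, 2], cand[, 1])
            usedR <- logical(nR)
            for (i in ord) {
                p <- cand[i, 1]; r <- cand[i, 2]
                if (!truePos[p] && !usedR[r]) {
                    truePos[p] <- TRUE
                    usedR[r] <- TRUE
                }
            }
        }
    }
    list(detected = detected, truePos = truePos)
}

#' Area under a specificity-truncated ROC curve
#'
#' Sweeps score thresholds from high to low, traces sensitivity against
#' 1 - specificity, and integrates by trapezoid over 1 - specificity in
#' \code{[0, 1 - specMin]}, interpolating linearly at the truncation
#' point.  With the default truncation at specificity 0.8, a perfect
#' ranking scores 0.2 (the ceiling) and random scores about 0.02.
#'
#' @param labels Logical vector: TRUE for true-positive predictions.
#' @param scoresVec Matching prediction scores.
#' @param specMin Minimum specificity kept, default 0.8.
#' @return AUC value in \code{[0, 1 - specMin]}.
#' @export
truncatedRocAuc <- function(labels, scoresVec, specMin = 0.8) {
    stopifnot(length(labels) == length(scoresVec))
    P <- sum(labels); N <- sum(!labels)
    if (P == 0L || N == 0L)
        stop("need at least one positive and one negative label")
    ord <- order(scoresVec, decreasing = TRUE)
    lab <- labels[ord]; sc <- scoresVec[ord]
    ## curve points at each distinct threshold (ties move together)
    tp <- cumsum(lab); fp <- cumsum(!lab)
    last <- c(sc[-1] != sc[-length(sc)], TRUE)
    sens <- c(0, tp[last] / P)
    fpr <- c(0, fp[last] / N)
    fmax <- 1 - specMin
    auc <- 0
    for (i in seq_len(length(fpr) - 1L)) {
        x0 <- fpr[i]; x1 <- fpr[i + 1L]
        y0 <- sens[i]; y1 <- sens[i + 1L]
        if (x0 >= fmax) break
        if (x1 > fmax) {   # clip the crossing segment
            y1 <- y0 + (y1 - y0) * (fmax - x0) / (x1 - x0)
            x1 <- fmax
        }
        auc <- auc + (x1 - x0) * (y0 + y1) / 2
    }
    auc
}

#' Evaluate predicted nucleosomes against a reference set
#'
#' Combines [matchToReference()] and [truncatedRocAuc()] into the
#' standard report.  When the predictions contain no false positives the
#' ROC curve is a vertical segment at specificity 1 and the truncated
#' area equals \code{(1 - specMin)} times the maximum sensitivity; that
#' limit is reported instead of an error.
#'
#' @param predCenters,predScores Predicted centers and their scores.
#' @param refCenters Reference centers.
#' @param dist Detection distance (bp).
#' @param specMin Specificity truncation, default 0.8.
#' @return List with \code{nRef}, \code{nPred}, \code{detected} (count),
#'   \code{detectionRate}, and \code{auc}.
#' @export
evaluateCalls <- function(predCenters, predScores, refCenters, dist,
                          specMin = 0.8) {
    m <- matchToReference(predCenters, refCenters, dist)
    nRef <- length(refCenters)
    sens <- if (nRef) sum(m$detected) / nRef else NA_real_
    auc <- if (!length(m$truePos) || all(m$truePos) || !any(m$truePos)) {
        ## degenerate ROC: report the curve's limit
        (1 - specMin) * (if (length(m$truePos))
            sum(m$detected) / max(1L, nRef) else 0)
    } else {
        ## sensitivity axis uses detected references; positives among
        ## predictions approximate it when matching is one-to-one
        truncatedRocAuc(m$truePos, predScores, specMin)
    }
    list(nRef = nRef, nPred = length(predCenters),
         detected = sum(m$detected), detectionRate = sens, auc = auc)
}
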