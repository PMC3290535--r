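#' @import methods
#' @importFrom stats dt qt rt rnorm rgamma runif quantile var median setNames
#'   qnbinom dnorm
#' @importFrom utils write.table read.delim head tail
NULL

#' Stranded 5' read positions on one chromosome
#'
#' Container for the single-end read evidence the nucleosome model sees:
#' the sorted 0-based 5' alignment coordinates of forward- and
#' reverse-strand reads on one chromosome.  For a forward read the 5' end
#' is its leftmost aligned base; for a reverse read it is the rightmost
#' aligned base (BED \code{chromEnd - 1}).
#'
#' @slot chrom Chromosome name (single string).
#' @slot fwd Sorted integer vector of forward-strand 5' positions (bp).
#' @slot rev Sorted integer vector of reverse-strand 5' positions (bp).
#'
#' @seealso [readReadsBed()], [readReadsBam()], [filterDuplicates()],
#'   [segmentReads()]
#' @export
setClass("StrandedReads",
    representation(chrom = "character", fwd = "integer", rev = "integer"))

setValidity("StrandedReads", function(object) {
    msg <- character()
    if (length(object@chrom) != 1L || is.na(object@chrom))
        msg <- c(msg, "'chrom' must be a single non-NA string")
    if (anyNA(object@fwd) || anyNA(object@rev))
        msg <- c(msg, "read positions must not contain NA")
    if (is.unsorted(object@fwd))
        msg <- c(msg, "'fwd' must be nondecreasing")
    if (is.unsorted(object@rev))
        msg <- c(msg, "'rev' must be nondecreasing")
    if ((length(object@fwd) && min(object@fwd) < 0L) ||
        (length(object@rev) && min(object@rev) < 0L))
        msg <- c(msg, "read positions must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a StrandedReads object
#'
#' Positions are coerced to integer and sorted; counts are conserved.
#'
#' @param chrom Chromosome name.
#' @param fwd Forward-strand 5' positions (bp, 0-based).
#' @param rev Reverse-strand 5' positions (bp, 0-based).
#' @return A [StrandedReads-class] object.
#' @examples
#' StrandedReads("chr1", fwd = c(120, 100), rev = 260)
#' @export
StrandedReads <- function(chrom, fwd = integer(), rev = integer()) {
    new("StrandedReads", chrom = as.character(chrom),
        fwd = sort(as.integer(round(fwd))),
        rev = sort(as.integer(round(rev))))
}

#' A candidate region for model fitting
#'
#' A 0-based half-open genomic interval together with its member stranded
#' reads; the unit on which one bidirectional mixture model is fitted.
#'
#' @slot chrom Chromosome name.
#' @slot start,end Interval bounds, 0-based half-open (bp).
#' @slot fwd,rev Sorted member 5' positions, all within `[start, end)`.
#' @export
setClass("CandidateRegion",
    representation(chrom = "character", start = "numeric", end = "numeric",
                   fwd = "integer", rev = "integer"))

setValidity("CandidateRegion", function(object) {
    msg <- character()
    if (object@start >= object@end)
        msg <- c(msg, "'start' must be < 'end'")
    pos <- c(object@fwd, object@rev)
    if (length(pos) && (min(pos) < object@start || max(pos) >= object@end))
        msg <- c(msg, "all member reads must lie in [start, end)")
    if (is.unsorted(object@fwd) || is.unsorted(object@rev))
        msg <- c(msg, "member reads must be sorted")
    if (length(msg)) msg else TRUE
})

CandidateRegion <- function(chrom, start, end, fwd, rev) {
    new("CandidateRegion", chrom = as.character(chrom),
        start = as.numeric(start), end = as.numeric(end),
        fwd = sort(as.integer(fwd)), rev = sort(as.integer(rev)))
}

#' A fitted bidirectional mixture model for one region
#'
#' Per-nucleosome parameters of the Student-t(4) read-position mixture:
#' shared weight \code{w}, center \code{mu} (bp), mean fragment length
#' \code{delta} (bp), and forward/reverse read-position variances
#' \code{varF}, \code{varR} (bp^2).  Components are ordered by center.
#'
#' @slot K Number of components.
#' @slot w,mu,delta,varF,varR Numeric vectors of length \code{K}.
#' @slot loglik Observed-data log-likelihood at the returned estimate.
#' @slot logpostPen Penalized model-selection objective: \code{loglik}
#'   plus the spatial (GMRF) log-prior of the centers.
#' @slot objTrace Full MAP objective (likelihood + all log-priors) per EM
#'   iteration; nondecreasing.
#' @slot nIter Number of EM iterations run.
#' @slot converged Logical convergence flag.
#' @export
setClass("NucleosomeFit",
    representation(K = "integer", w = "numeric", mu = "numeric",
                   delta = "numeric", varF = "numeric", varR = "numeric",
                   loglik = "numeric", logpostPen = "numeric",
                   objTrace = "numeric", nIter = "integer",
                   converged = "logical"))

setValidity("NucleosomeFit", function(object) {
    msg <- character()
    K <- object@K
    for (s in c("w", "mu", "delta", "varF", "varR"))
        if (length(slot(object, s)) != K)
            msg <- c(msg, sprintf("'%s' must have length K", s))
    if (K > 0L) {
        if (is.unsorted(object@mu, strictly = FALSE))
            msg <- c(msg, "'mu' must be nondecreasing")
        if (any(object@w <= 0) || sum(object@w) > 1 + 1e-6)
            msg <- c(msg, "'w' must be positive with sum <= 1")
        if (any(object@varF <= 0) || any(object@varR <= 0))
            msg <- c(msg, "variances must be positive")
        if (any(object@delta <= 0))
            msg <- c(msg, "'delta' must be positive")
    }
    if (isTRUE(object@converged) && !is.finite(object@logpostPen))
        msg <- c(msg, "'logpostPen' must be finite when converged")
    if (length(msg)) msg else TRUE
})

NucleosomeFit <- function(w, mu, delta, varF, varR,
                          loglik = NA_real_, logpostPen = NA_real_,
                          objTrace = numeric(), nIter = 0L,
                          converged = FALSE) {
    o <- order(mu)
    new("NucleosomeFit", K = length(mu), w = as.numeric(w)[o],
        mu = as.numeric(mu)[o], delta = as.numeric(delta)[o],
        varF = as.numeric(varF)[o], varR = as.numeric(varR)[o],
        loglik = loglik, logpostPen = logpostPen,
        objTrace = as.numeric(objTrace), nIter = as.integer(nIter),
        converged = converged)
}

#' Scored nucleosome calls
#'
#' The pipeline's result object: one row per predicted nucleosome with its
#' center, fragment length, strand-specific read-position scales, mixture
#' weight, core read counts, width-normalized enrichment score, and (when
#' a control sample was supplied) control-relative score and empirical
#' false discovery rate.
#'
#' @slot calls A \code{data.frame} with columns \code{chrom}, \code{mu},
#'   \code{delta}, \code{sigmaF}, \code{sigmaR}, \code{w}, \code{nF},
#'   \code{nR}, \code{score}, \code{scoreRel}, \code{fdr}, \code{region}.
#' @export
setClass("NucleosomeCalls", representation(calls = "data.frame"))

.CALL_COLS <- c("chrom", "mu", "delta", "sigmaF", "sigmaR", "w",
                "nF", "nR", "score", "scoreRel", "fdr", "region")

setValidity("NucleosomeCalls", function(object) {
    df <- object@calls
    msg <- character()
    if (!all(.CALL_COLS %in% names(df)))
        msg <- c(msg, paste("missing columns:",
                 paste(setdiff(.CALL_COLS, names(df)), collapse = ", ")))
    else if (nrow(df)) {
        if (any(df$sigmaF <= 0) || any(df$sigmaR <= 0))
            msg <- c(msg, "sigmas must be positive")
        if (any(df$w <= 0 | df$w > 1))
            msg <- c(msg, "weights must be in (0, 1]")
        if (any(df$score < 0))
            msg <- c(msg, "scores must be >= 0")
        fdr <- df$fdr[!is.na(df$fdr)]
        if (length(fdr) && (any(fdr < 0) || any(fdr > 1)))
            msg <- c(msg, "fdr must be in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a NucleosomeCalls object
#'
#' @param calls data.frame of per-nucleosome fields; missing optional
#'   columns (\code{scoreRel}, \code{fdr}, \code{region}) are filled with
#'   \code{NA}.
#' @return A [NucleosomeCalls-class] object sorted by chromosome and
#'   center.
#' @export
NucleosomeCalls <- function(calls) {
    for (col in .CALL_COLS)
        if (is.null(calls[[col]]))
            calls[[col]] <- rep(NA_real_, nrow(calls))
    calls <- calls[, .CALL_COLS, drop = FALSE]
    if (nrow(calls))
        calls <- calls[order(calls$chrom, calls$mu), , drop = FALSE]
    rownames(calls) <- NULL
    new("NucleosomeCalls", calls = calls)
}

setMethod("show", "StrandedReads", function(object) {
    cat(sprintf("StrandedReads on %s: %d forward / %d reverse reads\n",
        object@chrom, length(object@fwd), length(object@rev)))
    if (length(object@fwd) + length(object@rev))
        cat(sprintf("  span: [%d, %d]\n",
            min(object@fwd, object@rev), max(object@fwd, object@rev)))
})

setMethod("show", "CandidateRegion", function(object) {
    cat(sprintf("CandidateRegion %s:%d-%d (%d bp): %d fwd / %d rev reads\n",
        object@chrom, object@start, object@end, object@end - object@start,
        length(object@fwd), length(object@rev)))
})

setMethod("show", "NucleosomeFit", function(object) {
    cat(sprintf("NucleosomeFit: K=%d, loglik=%.2f, penalized=%.2f, %s in %d iter\n",
        object@K, object@loglik, object@logpostPen,
        if (object@converged) "converged" else "not converged",
        object@nIter))
    if (object@K)
        print(data.frame(w = round(object@w, 3), mu = round(object@mu, 1),
                         delta = round(object@delta, 1),
                         sigmaF = round(sqrt(object@varF), 1),
                         sigmaR = round(sqrt(object@varR), 1)))
})

setMethod("show", "NucleosomeCalls", function(object) {
    df <- object@calls
    cat(sprintf("NucleosomeCalls: %d nucleosomes on %d chromosome(s)\n",
        nrow(df), length(unique(df$chrom))))
    if (nrow(df)) {
        cat(sprintf("  median score %.3g; %s control-relative scores; %s FDR\n",
            median(df$score),
            if (all(is.na(df$scoreRel))) "no" else "with",
            if (all(is.na(df$fdr))) "no" else "with"))
        print(head(df, 5))
        if (nrow(df) > 5) cat("  ...\n")
    }
})
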