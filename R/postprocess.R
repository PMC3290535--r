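#' @include AllClasses.R config.R model.R
NULL

## two-sided t4 contour multiplier for a central probability q
.t4Mult <- function(q) qt((1 + q) / 2, df = 4)

## core intervals [lo, hi] per strand for one call
.coreIntervals <- function(mu, delta, sigmaF, sigmaR, q) {
    m <- .t4Mult(q)
    list(fwd = c(mu - delta / 2 - m * sigmaF, mu - delta / 2 + m * sigmaF),
         rev = c(mu + delta / 2 - m * sigmaR, mu + delta / 2 + m * sigmaR))
}

#' Count core reads under a fitted nucleosome
#'
#' Forward reads are counted inside the central \code{q} contour of the
#' fitted forward read-position density, i.e. within \code{(mu - delta/2)
#' +/- t4q * sigmaF} with \code{t4q} the two-sided \code{q} quantile of
#' the standardized t(4); reverse reads symmetrically around
#' \code{mu + delta/2}.
#'
#' @param mu,delta,sigmaF,sigmaR Parameters of one fitted nucleosome.
#' @param fwd,rev Sorted member read positions of its region.
#' @param q Central contour probability, in (0, 1); default 0.90.
#' @return Integer vector \code{c(nF, nR)}.
#' @export
countCoreReads <- function(mu, delta, sigmaF, sigmaR, fwd, rev, q = 0.90) {
    if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
    iv <- .coreIntervals(mu, delta, sigmaF, sigmaR, q)
    c(nF = sum(fwd >= iv$fwd[1] & fwd <= iv$fwd[2]),
      nR = sum(rev >= iv$rev[1] & rev <= iv$rev[2]))
}

#' Width-normalized enrichment score
#'
#' \code{(nF + nR)/(sigmaF + sigmaR)}, in reads per bp: the observed
#' density of enriched fragments after outlier removal, normalized by the
#' peak widths so that diffuse fits score lower than sharp ones.
#'
#' @param nF,nR Core read counts.
#' @param sigmaF,sigmaR Read-position scales (bp).
#' @return Numeric score, >= 0.
#' @export
enrichmentScore <- function(nF, nR, sigmaF, sigmaR) {
    (nF + nR) / (sigmaF + sigmaR)
}

#' Control-relative enrichment score
#'
#' Control reads are counted in the same core intervals that were
#' estimated from the treatment fit, and the ratio is depth-normalized:
#' \code{((nF + nR)/(nFc + nRc + 1)) * (Nctrl/Nchip)}; the added 1
#' guards against division by zero.
#'
#' @param nF,nR Treatment core counts.
#' @param nFc,nRc Control read counts in the same intervals.
#' @param nChip,nCtrl Total read counts of the treatment and control
#'   samples.
#' @return Numeric relative score.
#' @export
relativeScore <- function(nF, nR, nFc, nRc, nChip, nCtrl) {
    if (nChip <= 0) stop("'nChip' must be > 0")
    ((nF + nR) / (nFc + nRc + 1)) * (nCtrl / nChip)
}

#' Empirical FDR from treatment and control score distributions
#'
#' For a score threshold s, \code{FDR(s) = min(1, (#{ctrl >= s}/#{chip >=
#' s}) * (Nchip/Nctrl))}, computed at every attained treatment score and
#' made monotone nonincreasing in s by a running maximum from high scores
#' downward.
#'
#' @param chipScores Scores of treatment-sample calls (nonempty).
#' @param ctrlScores Scores of calls from running the same pipeline on
#'   the control sample.
#' @param nChip,nCtrl Total read counts of the two samples (default:
#'   equal depths).
#' @return List with \code{thresholds} (sorted attained chip scores),
#'   \code{fdr} (monotone curve), and \code{at(s)} a step function
#'   returning the FDR at arbitrary scores.
#' @export
estimateFdr <- function(chipScores, ctrlScores, nChip = 1, nCtrl = 1) {
    if (!length(chipScores)) stop("'chipScores' must be nonempty")
    s <- sort(unique(chipScores))
    nGeChip <- vapply(s, function(t) sum(chipScores >= t), numeric(1))
    nGeCtrl <- vapply(s, function(t) sum(ctrlScores >= t), numeric(1))
    raw <- pmin(1, (nGeCtrl / nGeChip) * (nChip / nCtrl))
    fdr <- rev(cummax(rev(raw)))
    atFun <- function(x) {
        idx <- findInterval(x, s)
        out <- rep(1, length(x))
        out[idx >= 1] <- fdr[idx[idx >= 1]]
        out
    }
    list(thresholds = s, fdr = fdr, at = atFun)
}

#' Adaptive negative-binomial count threshold
#'
#' Given a neighborhood nucleosome with \code{nNb} core reads and width
#' \code{sNb}, the count of a reference nucleosome of width \code{sRef}
#' with the same underlying read density has mean \code{m = nNb *
#' sRef/sNb}; sampling and density uncertainty make it
#' negative-binomially distributed with that mean and size \code{nNb}
#' (variance \code{m + m^2/nNb}).  The returned threshold is the
#' \code{alpha} quantile: a reference count below it is significantly
#' lower than the neighbor's.
#'
#' @param nNb Neighbor core read count (>= 1).
#' @param sRef,sNb Widths (sigmaF + sigmaR, bp) of the reference and
#'   neighbor nucleosomes.
#' @param alpha Quantile level in (0, 0.5].
#' @return Integer threshold count.
#' @export
nbThreshold <- function(nNb, sRef, sNb, alpha) {
    if (alpha <= 0 || alpha > 0.5) stop("'alpha' must be in (0, 0.5]")
    if (nNb < 1) stop("'nNb' must be >= 1")
    if (sRef <= 0 || sNb <= 0) stop("widths must be > 0")
    qnbinom(alpha, size = nNb, mu = nNb * sRef / sNb)
}

#' Flag and remove low-density nucleosome calls
#'
#' Each call (the reference) is compared against its neighborhood: calls
#' within \code{nbRadius} bp of its center, excluding any separated from
#' it by a nucleosome-free gap (adjacent center distance minus the 147-bp
#' core) longer than \code{nbGapThreshold}.  The reference is flagged as
#' falsely called when its total core count falls below the
#' negative-binomial threshold of any neighbor.  Flags are computed
#' against the unfiltered set in a single pass, so the result does not
#' depend on removal order.
#'
#' @param calls A [NucleosomeCalls-class] object.
#' @param cfg A [NucConfig-class].
#' @return List with \code{kept} (a filtered [NucleosomeCalls-class])
#'   and \code{flagged} (logical vector over the input rows).
#' @export
removeLowDensity <- function(calls, cfg) {
    df <- as.data.frame(calls)
    n <- nrow(df)
    flagged <- logical(n)
    if (n >= 2L) {
        counts <- df$nF + df$nR
        widths <- df$sigmaF + df$sigmaR
        for (chr in unique(df$chrom)) {
            idx <- which(df$chrom == chr)     # already sorted by mu
            mus <- df$mu[idx]
            gapBlock <- c(diff(mus) - 147 > cfg@nbGapThreshold, TRUE)
            for (a in seq_along(idx)) {
                ## walk outward on each side until radius or blocking gap
                nb <- integer()
                b <- a - 1L
                while (b >= 1L && mus[a] - mus[b] <= cfg@nbRadius &&
                       !gapBlock[b]) { nb <- c(nb, b); b <- b - 1L }
                b <- a + 1L
                while (b <= length(idx) && mus[b] - mus[a] <= cfg@nbRadius &&
                       !gapBlock[b - 1L]) { nb <- c(nb, b); b <- b + 1L }
                for (j in nb) {
                    if (counts[idx[j]] < 1) next
                    thr <- nbThreshold(counts[idx[j]], widths[idx[a]],
                                       widths[idx[j]], cfg@nbAlpha)
                    if (counts[idx[a]] < thr) { flagged[idx[a]] <- TRUE; break }
                }
            }
        }
    }
    list(kept = calls[!flagged], flagged = flagged)
}
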