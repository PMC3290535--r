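#' @include AllClasses.R config.R
NULL

## type-1 empirical quantile: smallest value with cdf >= q
.empQuantile <- function(x, q) {
    xs <- sort(x)
    xs[max(1L, ceiling(q * length(xs)))]
}

#' Cap duplicate reads at an adaptive quantile threshold
#'
#' Single-end reads sharing a 5' coordinate may be PCR/library artifacts.
#' The per-(strand, position) duplicate counts are pooled, their
#' \code{quantile} empirical quantile (smallest count with cdf at or above
#' the level, hence an integer >= 1) becomes the cap, and every position
#' keeps at most that many reads.  MNase data tolerate a higher quantile
#' than sonicated data because read starts genuinely pile up at
#' well-positioned nucleosome ends.  The operation is idempotent.
#'
#' @param reads A [StrandedReads-class] object.
#' @param quantile Cap quantile in (0, 1]; 1 disables capping.
#' @return A [StrandedReads-class] with capped multiplicities.
#' @export
filterDuplicates <- function(reads, quantile) {
    stopifnot(is(reads, "StrandedReads"))
    if (quantile <= 0 || quantile > 1)
        stop("'quantile' must be in (0, 1]")
    nf <- length(reads@fwd); nr <- length(reads@rev)
    if (nf + nr == 0L) return(reads)
    cntF <- table(reads@fwd); cntR <- table(reads@rev)
    cap <- .empQuantile(c(as.integer(cntF), as.integer(cntR)), quantile)
    capPos <- function(pos, cnt) {
        keep <- pmin(as.integer(cnt), cap)
        rep(as.integer(names(cnt)), keep)
    }
    StrandedReads(reads@chrom,
        fwd = if (nf) capPos(reads@fwd, cntF) else integer(),
        rev = if (nr) capPos(reads@rev, cntR) else integer())
}

## count of sorted values in closed interval [lo, hi]
.countIn <- function(sorted, lo, hi) {
    findInterval(hi, sorted) - findInterval(lo - 0.5, sorted)
}

#' Segment stranded reads into candidate regions
#'
#' A window of width \code{windowWidth} slides along the chromosome in
#' steps of \code{windowStep}; forward reads are counted in the left
#' half-window and reverse reads in the right half-window (both halves
#' closed, reads within \code{centerExclusion} bp of the window center
#' excluded).  Windows with at least \code{minReads} reads on each strand
#' are kept, overlapping kept windows are merged left to right, every read
#' inside a merged window is assigned to it, regions are trimmed to their
#' read span, and regions shorter than \code{minRegionLength} are dropped.
#' Regions longer than \code{maxRegionLength} are split recursively
#' ([splitLongRegions()]).
#'
#' @param reads A [StrandedReads-class] object.
#' @param cfg A [NucConfig-class].
#' @param split Logical; also apply [splitLongRegions()] (default TRUE).
#' @return A list of disjoint, sorted [CandidateRegion-class] objects.
#' @export
segmentReads <- function(reads, cfg, split = TRUE) {
    stopifnot(is(reads, "StrandedReads"), is(cfg, "NucConfig"))
    fwd <- reads@fwd; rev <- reads@rev
    if (!length(fwd) || !length(rev)) return(list())
    w <- cfg@windowWidth; s <- cfg@windowStep; cx <- cfg@centerExclusion
    lo <- min(fwd, rev); hi <- max(fwd, rev)
    starts <- seq(s * floor((lo - w) / s), s * ceiling(hi / s), by = s)
    ctr <- starts + w / 2
    nf <- .countIn(fwd, starts, ctr - cx)
    nr <- .countIn(rev, ctr + cx, starts + w)
    keep <- nf >= cfg@minReads & nr >= cfg@minReads
    if (!any(keep)) return(list())
    ks <- starts[keep]
    ## merge overlapping/adjacent kept windows [a, a+w] left to right
    breaks <- which(ks[-1] - ks[-length(ks)] > w)
    from <- ks[c(1L, breaks + 1L)]
    to <- ks[c(breaks, length(ks))] + w
    regions <- list()
    for (i in seq_along(from)) {
        f <- fwd[fwd >= from[i] & fwd <= to[i]]
        r <- rev[rev >= from[i] & rev <= to[i]]
        if (!length(f) || !length(r)) next
        a <- min(f, r); b <- max(f, r) + 1
        if (b - a < cfg@minRegionLength) next
        regions[[length(regions) + 1L]] <-
            CandidateRegion(reads@chrom, a, b, f, r)
    }
    if (split)
        regions <- do.call(c, c(list(list()),
            lapply(regions, splitLongRegions, cfg = cfg)))
    regions
}

## widest pooled-read gap whose midpoint lies in the central third;
## returns candidate split points ordered by decreasing gap width
.centralGapSplits <- function(region) {
    pos <- sort(c(region@fwd, region@rev))
    if (length(pos) < 2L) return(numeric())
    gapLo <- pos[-length(pos)]; gapHi <- pos[-1]
    mid <- (gapLo + gapHi) / 2
    wid <- gapHi - gapLo
    L <- region@end - region@start
    inC <- mid >= region@start + L / 3 & mid <= region@start + 2 * L / 3
    if (!any(inC)) return(numeric())
    mids <- mid[inC]; wids <- wid[inC]
    mids[order(-wids, mids)]
}

#' Recursively split over-long candidate regions
#'
#' A region longer than \code{maxRegionLength} is cut at the midpoint of
#' the widest gap between consecutive pooled read positions within its
#' central third (restricting to the central third guarantees geometric
#' shrinkage).  If a cut would leave a half with fewer than
#' \code{minReads} reads on some strand, the next-widest central gap is
#' tried; if none works the region is returned unsplit with a warning.
#' Reads are partitioned exactly between the halves.
#'
#' @param region A [CandidateRegion-class].
#' @param cfg A [NucConfig-class].
#' @return List of [CandidateRegion-class] objects covering the input.
#' @export
splitLongRegions <- function(region, cfg) {
    stopifnot(is(region, "CandidateRegion"), is(cfg, "NucConfig"))
    if (region@end - region@start <= cfg@maxRegionLength)
        return(list(region))
    for (cut in ceiling(.centralGapSplits(region))) {
        fL <- region@fwd[region@fwd < cut]; fR <- region@fwd[region@fwd >= cut]
        rL <- region@rev[region@rev < cut]; rR <- region@rev[region@rev >= cut]
        if (min(length(fL), length(rL), length(fR), length(rR)) <
            cfg@minReads) next
        left <- CandidateRegion(region@chrom, region@start, cut, fL, rL)
        right <- CandidateRegion(region@chrom, cut, region@end, fR, rR)
        return(c(splitLongRegions(left, cfg), splitLongRegions(right, cfg)))
    }
    warning(sprintf(
        "region %s:%d-%d exceeds maxRegionLength but cannot be split without violating minReads",
        region@chrom, region@start, region@end))
    list(region)
}
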