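#' @include AllClasses.R config.R
NULL

#' Classify binding-site summits by nucleosome modality
#'
#' A summit with no nucleosome center within \code{noneDist} is
#' \code{"NoNuc"}; one with a center within \code{monoDist} (i.e. the
#' site sits inside nucleosomal DNA) is \code{"monomodal"}; all remaining
#' sites — typically flanked by nucleosomes on either side — are
#' \code{"bimodal"}.
#'
#' @param summits Numeric vector of summit positions (bp), same
#'   chromosome as \code{nucCenters}.
#' @param nucCenters Numeric vector of predicted nucleosome centers
#'   (weak calls should already be removed).
#' @param monoDist Monomodal distance (bp), default 50.
#' @param noneDist NoNuc distance (bp), default 1000.
#' @return Character vector of labels, one per summit.
#' @export
classifySites <- function(summits, nucCenters, monoDist = 50,
                          noneDist = 1000) {
    if (!length(nucCenters))
        return(rep("NoNuc", length(summits)))
    nc <- sort(nucCenters)
    vapply(summits, function(p) {
        d <- min(abs(nc - p))
        if (d > noneDist) "NoNuc"
        else if (d <= monoDist) "monomodal"
        else "bimodal"
    }, character(1))
}

#' Gene-level modality from its binding sites
#'
#' A gene with several associated binding sites takes the label of its
#' most informative site with strict precedence bimodal > monomodal >
#' NoNuc: monomodal sites override NoNuc sites, and a single bimodal
#' site overrides everything.
#'
#' @param genes Character vector of gene identifiers, one per site.
#' @param labels Matching site labels from [classifySites()].
#' @return Named character vector: one label per gene (genes with no
#'   sites are absent).
#' @export
geneModality <- function(genes, labels) {
    stopifnot(length(genes) == length(labels),
              all(labels %in% c("bimodal", "monomodal", "NoNuc")))
    rank <- c(bimodal = 3L, monomodal = 2L, NoNuc = 1L)
    out <- tapply(rank[labels], genes, max)
    setNames(names(rank)[match(as.integer(out), rank)], names(out))
}

#' Average nucleosome occupancy profile around anchors
#'
#' Each nucleosome contributes a Gaussian kernel at its center (sd 30
#' bp) with peak height equal to its score normalized to the maximum
#' score in the set; contributions are summed in anchor-relative
#' coordinates and averaged over anchors (anchor strand ignored).
#'
#' @param nucCenters Nucleosome centers (bp).
#' @param nucScores Matching scores.
#' @param anchors Anchor positions (bp), nonempty.
#' @param halfwidth Profile half-width (bp).
#' @param kernelSd Kernel sd (bp), default 30.
#' @return Numeric vector of length \code{2*halfwidth + 1}, named by
#'   offset.
#' @export
occupancyProfile <- function(nucCenters, nucScores, anchors, halfwidth,
                             kernelSd = 30) {
    if (!length(anchors)) stop("'anchors' must be nonempty")
    if (halfwidth <= 0) stop("'halfwidth' must be > 0")
    stopifnot(length(nucCenters) == length(nucScores))
    offs <- seq(-halfwidth, halfwidth)
    prof <- numeric(length(offs))
    if (length(nucCenters)) {
        h <- nucScores / max(nucScores)
        for (anchor in anchors) {
            rel <- nucCenters - anchor
            near <- which(abs(rel) <= halfwidth + 5 * kernelSd)
            for (k in near)
                prof <- prof + h[k] * exp(-(offs - rel[k])^2 /
                                          (2 * kernelSd^2))
        }
    }
    setNames(prof / length(anchors), offs)
}

#' Signed distances from summits to their nearest nucleosome dyad
#'
#' Pairs each (monomodal) summit with its nearest predicted center and
#' histograms the signed distance (summit minus center) in 1-bp bins over
#' \code{[-truncate, truncate]}; distances beyond the truncation are
#' counted in an overflow tally.  Optionally restricted to the
#' \code{topN} nucleosomes by score before pairing.
#'
#' @param summits Summit positions (bp).
#' @param nucCenters Predicted centers (bp).
#' @param nucScores Scores matching \code{nucCenters} (needed when
#'   \code{topN} is used).
#' @param truncate Histogram half-range (bp), default 100.
#' @param topN Optional count of top-scoring nucleosomes to keep.
#' @return List with \code{offsets} (-truncate..truncate), \code{counts},
#'   and \code{overflow}.
#' @export
siteVsDyadProfile <- function(summits, nucCenters, nucScores = NULL,
                              truncate = 100, topN = NULL) {
    if (!is.null(topN) && length(nucCenters) > topN) {
        if (is.null(nucScores))
            stop("'nucScores' needed to apply 'topN'")
        keep <- order(nucScores, decreasing = TRUE)[seq_len(topN)]
        nucCenters <- nucCenters[keep]
    }
    offs <- seq(-truncate, truncate)
    counts <- setNames(integer(length(offs)), offs)
    overflow <- 0L
    if (length(nucCenters) && length(summits)) {
        nc <- sort(nucCenters)
        for (p in summits) {
            d <- p - nc[which.min(abs(nc - p))]
            if (abs(d) > truncate) overflow <- overflow + 1L
            else counts[as.character(round(d))] <-
                counts[as.character(round(d))] + 1L
        }
    }
    list(offsets = offs, counts = counts, overflow = overflow)
}

#' Elbow of a score distribution
#'
#' Scores are sorted decreasingly; the elbow is the point of maximum
#' perpendicular distance to the chord joining the first and last points
#' of the sorted-score curve.  Used to separate confident calls from the
#' weak tail before modality classification.
#'
#' @param scores Numeric scores.
#' @return The score value at the elbow (calls with scores below it are
#'   considered weak).
#' @export
scoreElbow <- function(scores) {
    s <- sort(scores, decreasing = TRUE)
    n <- length(s)
    if (n < 3L) return(min(s))
    x <- seq_len(n)
    ## distance from (x, s) to the chord (1, s1)-(n, sn)
    dx <- n - 1; dy <- s[n] - s[1]
    d <- abs(dy * (x - 1) - dx * (s - s[1])) / sqrt(dx^2 + dy^2)
    s[which.max(d)]
}
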