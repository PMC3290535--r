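#' @include AllClasses.R
NULL

#' Accessors for nucleofit objects
#'
#' @param x A nucleofit S4 object.
#' @return \code{chrom} returns the chromosome name; \code{fwdReads} /
#'   \code{revReads} the sorted stranded 5' positions; \code{nReads} the
#'   total read count; \code{centers} the nucleosome centers (bp);
#'   \code{fragLengths} the per-nucleosome mean fragment lengths (bp);
#'   \code{scores} the enrichment scores; \code{nComponents} the number of
#'   mixture components.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))
#' @rdname accessors
#' @export
setGeneric("fwdReads", function(x) standardGeneric("fwdReads"))
#' @rdname accessors
#' @export
setGeneric("revReads", function(x) standardGeneric("revReads"))
#' @rdname accessors
#' @export
setGeneric("nReads", function(x) standardGeneric("nReads"))
#' @rdname accessors
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))
#' @rdname accessors
#' @export
setGeneric("fragLengths", function(x) standardGeneric("fragLengths"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname accessors
setMethod("chrom", "StrandedReads", function(x) x@chrom)
#' @rdname accessors
setMethod("chrom", "CandidateRegion", function(x) x@chrom)
#' @rdname accessors
setMethod("fwdReads", "StrandedReads", function(x) x@fwd)
#' @rdname accessors
setMethod("fwdReads", "CandidateRegion", function(x) x@fwd)
#' @rdname accessors
setMethod("revReads", "StrandedReads", function(x) x@rev)
#' @rdname accessors
setMethod("revReads", "CandidateRegion", function(x) x@rev)
#' @rdname accessors
setMethod("nReads", "StrandedReads",
    function(x) length(x@fwd) + length(x@rev))
#' @rdname accessors
setMethod("nReads", "CandidateRegion",
    function(x) length(x@fwd) + length(x@rev))
#' @rdname accessors
setMethod("centers", "NucleosomeFit", function(x) x@mu)
#' @rdname accessors
setMethod("centers", "NucleosomeCalls", function(x) x@calls$mu)
#' @rdname accessors
setMethod("fragLengths", "NucleosomeFit", function(x) x@delta)
#' @rdname accessors
setMethod("fragLengths", "NucleosomeCalls", function(x) x@calls$delta)
#' @rdname accessors
setMethod("scores", "NucleosomeCalls", function(x) x@calls$score)
#' @rdname accessors
setMethod("nComponents", "NucleosomeFit", function(x) x@K)

#' @rdname accessors
#' @export
setMethod("length", "NucleosomeCalls", function(x) nrow(x@calls))

#' Coerce nucleosome calls to a data.frame
#'
#' @param x A [NucleosomeCalls-class] object.
#' @param ... Ignored.
#' @return The underlying per-nucleosome \code{data.frame}.
#' @export
setMethod("as.data.frame", "NucleosomeCalls",
    function(x, ...) x@calls)

#' Subset nucleosome calls
#'
#' @param x A [NucleosomeCalls-class] object.
#' @param i Row index (logical or integer).
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "NucleosomeCalls", function(x, i, j, ..., drop = FALSE) {
    NucleosomeCalls(x@calls[i, , drop = FALSE])
})

#' Nucleosome calls as genomic ranges
#'
#' Each call becomes a 147-bp range (the canonical nucleosome core)
#' centered on its estimated dyad.
#'
#' @param calls A [NucleosomeCalls-class] object.
#' @return A [GenomicRanges::GRanges] with the call fields as metadata
#'   columns.
#' @export
callsAsGRanges <- function(calls) {
    df <- as.data.frame(calls)
    start0 <- round(df$mu) - 73
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = start0 + 1, width = 147))
    S4Vectors::mcols(gr) <- df[, setdiff(names(df), "chrom"), drop = FALSE]
    gr
}
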