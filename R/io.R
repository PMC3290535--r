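#' @include AllClasses.R
NULL

.grToStranded <- function(gr, source) {
    str <- as.character(BiocGenerics::strand(gr))
    if (any(str == "*"))
        stop("missing strand in ", source, ": every read needs '+' or '-'")
    ## 0-based 5' position: chromStart for +, chromEnd - 1 for -
    pos5 <- ifelse(str == "+",
                   BiocGenerics::start(gr) - 1L,
                   BiocGenerics::end(gr) - 1L)
    chroms <- as.character(GenomicRanges::seqnames(gr))
    out <- lapply(sort(unique(chroms)), function(ch) {
        sel <- chroms == ch
        StrandedReads(ch, fwd = pos5[sel & str == "+"],
                          rev = pos5[sel & str == "-"])
    })
    names(out) <- sort(unique(chroms))
    out
}

#' Read stranded 5' read positions from a BED6 file
#'
#' Forward reads contribute their chromStart as the 5' position; reverse
#' reads contribute chromEnd - 1 (BED end is exclusive).  Coordinates stay
#' 0-based throughout the package.
#'
#' @param path Path to a BED file with at least 6 columns (strand in
#'   column 6).
#' @return A named list of [StrandedReads-class], one element per
#'   chromosome, sorted by name.
#' @seealso [readReadsBam()] for the same contract on alignments.
#' @export
readReadsBed <- function(path) {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
        error = function(e) {
            ## recover a line number for the standard malformed-line case
            n <- tryCatch(length(readLines(path)), error = function(e2) NA)
            stop("failed to parse BED file '", path, "' (", n,
                 " lines read): ", conditionMessage(e), call. = FALSE)
        })
    .grToStranded(gr, paste0("BED file '", path, "'"))
}

## reference-consuming CIGAR length (ops M, D, N, =, X)
.cigarRefWidth <- function(cigar) {
    vapply(cigar, function(cg) {
        if (is.na(cg) || cg == "*") return(NA_integer_)
        ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
        toks <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
        n <- as.integer(sub("[A-Z=]$", "", toks))
        op <- sub("^\\d+", "", toks)
        sum(n[op %in% c("M", "D", "N", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
}

#' Read stranded 5' read positions from a BAM file
#'
#' Unmapped and secondary alignments are skipped; the result is identical
#' to [readReadsBed()] on the equivalent intervals.
#'
#' @param path Path to a BAM file.
#' @return A named list of [StrandedReads-class] per chromosome.
#' @export
readReadsBam <- function(path) {
    param <- Rsamtools::ScanBamParam(
        what = c("rname", "pos", "strand", "cigar"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                      isSecondaryAlignment = FALSE))
    rec <- Rsamtools::scanBam(path, param = param)[[1]]
    keep <- !is.na(rec$pos)
    if (!any(keep)) return(setNames(list(), character()))
    rname <- as.character(rec$rname)[keep]
    pos0 <- rec$pos[keep] - 1L                     # BAM pos is 1-based
    wid <- .cigarRefWidth(rec$cigar[keep])
    str <- as.character(rec$strand)[keep]
    pos5 <- ifelse(str == "+", pos0, pos0 + wid - 1L)
    out <- lapply(sort(unique(rname)), function(ch) {
        sel <- rname == ch
        StrandedReads(ch, fwd = pos5[sel & str == "+"],
                          rev = pos5[sel & str == "-"])
    })
    names(out) <- sort(unique(rname))
    out
}

.PRED_HEADER <- c("chrom", "start", "end", "mu", "delta", "sigma_f",
                  "sigma_r", "w", "n_f", "n_r", "score", "score_rel",
                  "fdr")

#' Write nucleosome calls to a predictions table and BED companion
#'
#' The tab-delimited table keeps the fractional center estimate and
#' round-trips losslessly through [readPredictions()].  Each call is also
#' written as a 147-bp BED6 feature (the canonical core footprint)
#' centered on the rounded dyad, with the BED score column holding the
#' rank-scaled enrichment score (0-1000).
#'
#' @param calls A [NucleosomeCalls-class] object.
#' @param path Output path for the tab-delimited table.
#' @param bedPath Output path for the BED6 companion; default replaces the
#'   extension of \code{path} with \code{.bed}.
#' @return Invisibly, \code{path}.
#' @export
writePredictions <- function(calls, path,
        bedPath = paste0(sub("\\.[^./]*$", "", path), ".bed")) {
    df <- as.data.frame(calls)
    out <- data.frame(chrom = df$chrom,
        start = round(df$mu) - 73, end = round(df$mu) + 74,
        mu = df$mu, delta = df$delta, sigma_f = df$sigmaF,
        sigma_r = df$sigmaR, w = df$w, n_f = df$nF, n_r = df$nR,
        score = df$score, score_rel = df$scoreRel, fdr = df$fdr)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(df)) {
        n <- nrow(df)
        bedScore <- if (n == 1L) 1000 else
            round(1000 * (rank(df$score, ties.method = "average") - 1) /
                  (n - 1))
        gr <- GenomicRanges::GRanges(df$chrom,
            IRanges::IRanges(start = out$start + 1, end = out$end),
            strand = "*")
        gr$name <- sprintf("nuc_%d", seq_len(n))
        gr$score <- as.integer(bedScore)
        rtracklayer::export(gr, bedPath, format = "BED")
    } else {
        file.create(bedPath)
    }
    invisible(path)
}

#' Read back a predictions table
#'
#' @param path Path written by [writePredictions()].
#' @return A [NucleosomeCalls-class] object.
#' @export
readPredictions <- function(path) {
    df <- read.delim(path, check.names = FALSE)
    missing <- setdiff(.PRED_HEADER, names(df))
    if (length(missing))
        stop("predictions table '", path, "' lacks column(s): ",
             paste(missing, collapse = ", "))
    NucleosomeCalls(data.frame(chrom = as.character(df$chrom), mu = df$mu,
        delta = df$delta, sigmaF = df$sigma_f, sigmaR = df$sigma_r,
        w = df$w, nF = df$n_f, nR = df$n_r, score = df$score,
        scoreRel = df$score_rel, fdr = df$fdr))
}

#' Read binding-site summits from a BED file
#'
#' @param path BED file of summit features; for intervals wider than 1 bp
#'   the interval midpoint is used.
#' @return data.frame with columns \code{chrom} and \code{pos} (0-based).
#' @export
readSummitsBed <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = floor((BiocGenerics::start(gr) - 1 +
                     BiocGenerics::end(gr) - 1) / 2))
}

#' Read a gene to binding-site association table
#'
#' @param path Tab-delimited file with columns \code{gene} and
#'   \code{site}.
#' @return data.frame with those two character columns.
#' @export
readGeneSiteMap <- function(path) {
    df <- read.delim(path)
    if (!all(c("gene", "site") %in% names(df)))
        stop("gene map '", path, "' needs columns 'gene' and 'site'")
    data.frame(gene = as.character(df$gene), site = as.character(df$site))
}

#' Write candidate regions as BED, with per-strand read counts in the
#' name field
#'
#' @param regions List of [CandidateRegion-class] objects.
#' @param path Output BED path.
#' @return Invisibly, \code{path}.
#' @export
writeRegionsBed <- function(regions, path) {
    if (!length(regions)) { file.create(path); return(invisible(path)) }
    gr <- GenomicRanges::GRanges(
        vapply(regions, chrom, character(1)),
        IRanges::IRanges(
            start = vapply(regions, function(r) r@start, numeric(1)) + 1,
            end = vapply(regions, function(r) r@end, numeric(1))))
    gr$name <- vapply(regions, function(r)
        sprintf("f%d_r%d", length(r@fwd), length(r@rev)), character(1))
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Write an occupancy profile as a wiggle track
#'
#' @param profile Numeric vector of per-bp occupancy values.
#' @param chrom Chromosome name.
#' @param start 0-based position of the first profile value.
#' @param path Output path (.wig).
#' @return Invisibly, \code{path}.
#' @export
writeOccupancyWig <- function(profile, chrom, start, path) {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start + seq_along(profile), width = 1),
        score = as.numeric(profile))
    rtracklayer::export(gr, path, format = "WIG")
    invisible(path)
}
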