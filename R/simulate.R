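#' @include AllClasses.R config.R
NULL

#' Ground truth of a simulated nucleosome array
#'
#' @slot chrom Chromosome name.
#' @slot centers Sorted true dyad positions (bp).
#' @slot deltas,sigmaF,sigmaR Per-nucleosome fragment lengths and
#'   strand-specific read-position scales (bp).
#' @slot readsPerNuc Reads drawn per strand per nucleosome.
#' @slot protocol Preset the parameters were drawn under.
#' @export
setClass("SimTruth",
    representation(chrom = "character", centers = "numeric",
                   deltas = "numeric", sigmaF = "numeric",
                   sigmaR = "numeric", readsPerNuc = "integer",
                   protocol = "character"))

setValidity("SimTruth", function(object) {
    msg <- character()
    K <- length(object@centers)
    if (is.unsorted(object@centers))
        msg <- c(msg, "'centers' must be sorted")
    for (s in c("deltas", "sigmaF", "sigmaR"))
        if (length(slot(object, s)) != K || any(slot(object, s) <= 0))
            msg <- c(msg, sprintf("'%s' must be positive, length K", s))
    if (length(msg)) msg else TRUE
})

setMethod("show", "SimTruth", function(object) {
    cat(sprintf("SimTruth (%s): %d nucleosomes on %s, %d reads/strand each\n",
        object@protocol, length(object@centers), object@chrom,
        object@readsPerNuc))
})

#' Sample nucleosome centers from the spatial prior
#'
#' Sequential (causal) sampling of the chain: the first center sits at
#' \code{start}, each next center adds \code{delta0} plus Gaussian noise
#' with sd \code{1/sqrt(2*rhoS)}; steps outside
#' \code{cfg@spacingBounds} are rejection-resampled.
#'
#' @param K Number of centers, >= 1.
#' @param start First center position (bp).
#' @param cfg A [NucConfig-class].
#' @param seed Integer seed.
#' @return Sorted numeric vector of K centers.
#' @export
sampleCenters <- function(K, start, cfg, seed = 1L) {
    stopifnot(K >= 1L, is(cfg, "NucConfig"))
    set.seed(seed)
    sdStep <- 1 / sqrt(2 * cfg@rhoS)
    centers <- numeric(K)
    centers[1] <- start
    for (k in seq_len(K - 1L) + 1L) {
        repeat {
            step <- cfg@delta0 + rnorm(1, 0, sdStep)
            if (step >= cfg@spacingBounds[1] &&
                step <= cfg@spacingBounds[2]) break
        }
        centers[k] <- centers[k - 1L] + step
    }
    centers
}

#' Draw per-nucleosome shape parameters from the priors
#'
#' Fragment lengths are Normal(\code{xi}, \code{deltaPriorScale/
#' sqrt(kappa)}) truncated to \code{deltaBounds}; read-position scales
#' come from the Gamma precision prior truncated to \code{sigmaBounds}.
#'
#' @param K Number of nucleosomes.
#' @param cfg A [NucConfig-class].
#' @param seed Integer seed.
#' @return List with \code{deltas}, \code{sigmaF}, \code{sigmaR}.
#' @export
samplePriorShapes <- function(K, cfg, seed = 1L) {
    set.seed(seed)
    rTrunc <- function(n, draw, lo, hi) {
        out <- numeric(n)
        for (i in seq_len(n)) {
            repeat { x <- draw(); if (x >= lo && x <= hi) break }
            out[i] <- x
        }
        out
    }
    sdD <- cfg@deltaPriorScale / sqrt(cfg@kappa)
    deltas <- rTrunc(K, function() rnorm(1, cfg@xi, sdD),
                     cfg@deltaBounds[1], cfg@deltaBounds[2])
    drawSigma <- function() 1 / sqrt(rgamma(1, cfg@alphaPrec,
                                            rate = cfg@betaPrec))
    list(deltas = deltas,
         sigmaF = rTrunc(K, drawSigma, cfg@sigmaBounds[1],
                         cfg@sigmaBounds[2]),
         sigmaR = rTrunc(K, drawSigma, cfg@sigmaBounds[1],
                         cfg@sigmaBounds[2]))
}

#' Simulate stranded reads from a nucleosome array
#'
#' For nucleosome k, \code{readsPerNuc} forward 5' positions are drawn
#' as \code{mu_k - delta_k/2 + sigmaF_k * T4} and as many reverse
#' positions as \code{mu_k + delta_k/2 + sigmaR_k * T4} (T4 a standard
#' t with 4 df), rounded to integers and clipped at 0.
#'
#' @param truth A [SimTruth-class].
#' @param seed Integer seed.
#' @return A [StrandedReads-class].
#' @export
sampleReads <- function(truth, seed = 1L) {
    stopifnot(is(truth, "SimTruth"))
    set.seed(seed)
    n <- truth@readsPerNuc
    fwd <- rev <- integer()
    for (k in seq_along(truth@centers)) {
        if (n == 0L) next
        fwd <- c(fwd, round(truth@centers[k] - truth@deltas[k] / 2 +
                            truth@sigmaF[k] * rt(n, df = 4)))
        rev <- c(rev, round(truth@centers[k] + truth@deltas[k] / 2 +
                            truth@sigmaR[k] * rt(n, df = 4)))
    }
    StrandedReads(truth@chrom, fwd = pmax(fwd, 0), rev = pmax(rev, 0))
}

#' Simulate a multi-region synthetic chromosome
#'
#' Generates \code{nRegions} independent nucleosome arrays with
#' between-array gaps larger than \code{maxRegionLength} (so
#' segmentation cannot merge them), each with a K drawn uniformly from
#' \code{kRange} and shape parameters from the priors.
#'
#' @param nRegions Number of arrays.
#' @param kRange Integer range of nucleosomes per array, e.g.
#'   \code{1:4}.
#' @param cfg A [NucConfig-class] (presets define the regime).
#' @param readsPerNuc Reads per strand per nucleosome, default 150.
#' @param seed Integer seed.
#' @param chrom Chromosome name, default \code{"chrS"}.
#' @return List with \code{reads} (one pooled [StrandedReads-class]),
#'   \code{truths} (list of [SimTruth-class]), and \code{manifest}
#'   (named list of every generation parameter).
#' @export
simulateDataset <- function(nRegions, kRange, cfg, readsPerNuc = 150L,
                            seed = 1L, chrom = "chrS") {
    stopifnot(nRegions >= 1L, all(kRange >= 1L), is(cfg, "NucConfig"))
    gap <- 2 * cfg@maxRegionLength
    truths <- vector("list", nRegions)
    allF <- allR <- integer()
    pos <- 1000
    set.seed(seed)
    Ks <- kRange[sample.int(length(kRange), nRegions, replace = TRUE)]
    for (i in seq_len(nRegions)) {
        K <- Ks[i]
        centers <- sampleCenters(K, pos, cfg, seed = seed + 7L * i)
        shp <- samplePriorShapes(K, cfg, seed = seed + 7L * i + 3L)
        truth <- new("SimTruth", chrom = chrom, centers = centers,
            deltas = shp$deltas, sigmaF = shp$sigmaF, sigmaR = shp$sigmaR,
            readsPerNuc = as.integer(readsPerNuc), protocol = cfg@protocol)
        truths[[i]] <- truth
        rd <- sampleReads(truth, seed = seed + 7L * i + 5L)
        allF <- c(allF, rd@fwd); allR <- c(allR, rd@rev)
        pos <- max(centers) + gap
    }
    list(reads = StrandedReads(chrom, allF, allR), truths = truths,
         manifest = list(nRegions = nRegions, kRange = kRange,
             K = as.integer(Ks), preset = cfg@protocol,
             readsPerNuc = as.integer(readsPerNuc), seed = as.integer(seed),
             chrom = chrom, delta0 = cfg@delta0, rhoS = cfg@rhoS,
             spacingBounds = cfg@spacingBounds, xi = cfg@xi,
             kappa = cfg@kappa, deltaPriorScale = cfg@deltaPriorScale,
             alphaPrec = cfg@alphaPrec, betaPrec = cfg@betaPrec))
}

#' Write a simulated dataset to disk
#'
#' Writes the reads as BED6 (75-bp features whose 5' ends encode the
#' read positions), the true nucleosomes as a 147-bp BED track, and a
#' JSON manifest from which the dataset regenerates bit-exactly.
#'
#' @param nRegions,kRange,cfg,readsPerNuc,seed,chrom As in
#'   [simulateDataset()].
#' @param outDir Output directory (created if needed).
#' @param readLength Length of the BED read features, default 75.
#' @return Invisibly, the [simulateDataset()] result with added file
#'   paths.
#' @export
makeDataset <- function(nRegions, kRange, cfg, outDir,
                        readsPerNuc = 150L, seed = 1L, chrom = "chrS",
                        readLength = 75L) {
    sim <- simulateDataset(nRegions, kRange, cfg, readsPerNuc, seed,
                           chrom)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    rd <- sim$reads
    nF <- length(rd@fwd); nR <- length(rd@rev)
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(
            start = c(rd@fwd + 1L, rd@rev - readLength + 2L),
            width = readLength),
        strand = rep(c("+", "-"), c(nF, nR)))
    gr$name <- sprintf("r%d", seq_len(nF + nR))
    gr$score <- rep(0L, nF + nR)
    readsPath <- file.path(outDir, "reads.bed")
    rtracklayer::export(gr, readsPath, format = "BED")
    ctrs <- unlist(lapply(sim$truths, function(t) t@centers))
    tg <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = round(ctrs) - 73 + 1L, width = 147))
    tg$name <- sprintf("truth_%d", seq_along(ctrs))
    tg$score <- rep(0L, length(ctrs))
    truthPath <- file.path(outDir, "truth.bed")
    rtracklayer::export(tg, truthPath, format = "BED")
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(sim$manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA)
    sim$paths <- list(reads = readsPath, truth = truthPath,
                      manifest = manifestPath)
    invisible(sim)
}

#' Regenerate a dataset from its manifest
#'
#' @param manifestPath Path to a manifest written by [makeDataset()].
#' @param outDir Output directory for the regenerated files.
#' @return As [makeDataset()].
#' @export
regenerateDataset <- function(manifestPath, outDir) {
    m <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    cfg <- nucConfig(m$preset, delta0 = m$delta0, rhoS = m$rhoS,
        spacingBounds = m$spacingBounds, xi = m$xi, kappa = m$kappa,
        deltaPriorScale = m$deltaPriorScale, alphaPrec = m$alphaPrec,
        betaPrec = m$betaPrec)
    makeDataset(m$nRegions, m$kRange, cfg, outDir,
                readsPerNuc = m$readsPerNuc, seed = m$seed,
                chrom = m$chrom)
}
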