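#' @include AllClasses.R config.R preprocess.R model.R postprocess.R
NULL

## score the components of one region's selected fit
.scoreRegionFit <- function(region, fit, cfg, control = NULL,
                            nChip = 1, nCtrl = 1) {
    K <- fit@K
    if (!K) return(NULL)
    sF <- sqrt(fit@varF); sR <- sqrt(fit@varR)
    rows <- lapply(seq_len(K), function(k) {
        cnt <- countCoreReads(fit@mu[k], fit@delta[k], sF[k], sR[k],
                              region@fwd, region@rev, cfg@coreQuantile)
        sc <- enrichmentScore(cnt["nF"], cnt["nR"], sF[k], sR[k])
        scRel <- NA_real_
        if (!is.null(control)) {
            iv <- .coreIntervals(fit@mu[k], fit@delta[k], sF[k], sR[k],
                                 cfg@coreQuantile)
            nFc <- sum(control@fwd >= iv$fwd[1] & control@fwd <= iv$fwd[2])
            nRc <- sum(control@rev >= iv$rev[1] & control@rev <= iv$rev[2])
            scRel <- relativeScore(cnt["nF"], cnt["nR"], nFc, nRc,
                                   nChip, nCtrl)
        }
        data.frame(chrom = region@chrom, mu = fit@mu[k],
            delta = fit@delta[k], sigmaF = sF[k], sigmaR = sR[k],
            w = fit@w[k], nF = as.integer(cnt["nF"]),
            nR = as.integer(cnt["nR"]), score = as.numeric(sc),
            scoreRel = as.numeric(scRel), fdr = NA_real_)
    })
    do.call(rbind, rows)
}

#' Run the full nucleosome-positioning pipeline on one chromosome
#'
#' Duplicate filtering, candidate-region segmentation with recursive
#' splitting, per-region EM/MAP mixture fitting over the dynamic K
#' range, penalized-likelihood model selection, post-fit screening,
#' core-read scoring, optional control-relative scoring and empirical
#' FDR, and the adaptive negative-binomial low-density filter.
#'
#' @param reads A [StrandedReads-class] (treatment sample).
#' @param cfg A [NucConfig-class]; see [nucConfig()].
#' @param control Optional [StrandedReads-class] control sample; enables
#'   \code{scoreRel} and \code{fdr}.
#' @param lowDensityFilter Apply [removeLowDensity()] (default TRUE).
#' @param restarts,seed Passed to [fitRegion()].
#' @return A [NucleosomeCalls-class] object.
#' @examples
#' cfg <- nucConfig("sonicated")
#' sim <- simulateDataset(2, 1:2, cfg, readsPerNuc = 120, seed = 42)
#' calls <- callNucleosomes(sim$reads, cfg)
#' calls
#' @export
callNucleosomes <- function(reads, cfg = nucConfig(), control = NULL,
                            lowDensityFilter = TRUE, restarts = 0L,
                            seed = 1L) {
    stopifnot(is(reads, "StrandedReads"), is(cfg, "NucConfig"))
    reads <- filterDuplicates(reads, cfg@dupQuantile)
    if (!is.null(control))
        control <- filterDuplicates(control, cfg@dupQuantile)
    regions <- segmentReads(reads, cfg)
    nChip <- nReads(reads)
    nCtrl <- if (is.null(control)) 1 else nReads(control)
    tabs <- lapply(seq_along(regions), function(i) {
        fit <- fitRegionAuto(regions[[i]], cfg, restarts, seed)
        if (is.null(fit)) return(NULL)
        tab <- .scoreRegionFit(regions[[i]], fit, cfg, control,
                               nChip, nCtrl)
        if (!is.null(tab) && nrow(tab)) tab$region <- i
        tab
    })
    tabs <- Filter(Negate(is.null), tabs)
    calls <- NucleosomeCalls(if (length(tabs)) do.call(rbind, tabs)
        else data.frame(chrom = character(), mu = numeric()))
    if (!is.null(control) && length(calls)) {
        ctrlCalls <- callNucleosomesNoControl(control, cfg,
                                              lowDensityFilter = FALSE)
        if (length(ctrlCalls)) {
            fdrFit <- estimateFdr(scores(calls), scores(ctrlCalls),
                                  nChip = nChip, nCtrl = nCtrl)
            calls@calls$fdr <- fdrFit$at(scores(calls))
        } else {
            calls@calls$fdr <- 0
        }
    }
    if (lowDensityFilter && length(calls))
        calls <- removeLowDensity(calls, cfg)$kept
    calls
}

## the pipeline without control handling (used on the control itself)
callNucleosomesNoControl <- function(reads, cfg, lowDensityFilter = TRUE) {
    callNucleosomes(reads, cfg, control = NULL,
                    lowDensityFilter = lowDensityFilter)
}

#' Run the pipeline over a list of chromosomes
#'
#' @param readsList Named list of [StrandedReads-class] as returned by
#'   [readReadsBed()].
#' @param cfg A [NucConfig-class].
#' @param controlList Optional matching named list for a control sample.
#' @param ... Passed to [callNucleosomes()].
#' @return A single [NucleosomeCalls-class] across chromosomes.
#' @export
callNucleosomesGenome <- function(readsList, cfg = nucConfig(),
                                  controlList = NULL, ...) {
    tabs <- lapply(names(readsList), function(ch) {
        ctrl <- if (!is.null(controlList)) controlList[[ch]] else NULL
        as.data.frame(callNucleosomes(readsList[[ch]], cfg,
                                      control = ctrl, ...))
    })
    NucleosomeCalls(do.call(rbind, c(tabs,
        list(data.frame(chrom = character(), mu = numeric())))))
}
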