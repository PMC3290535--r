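#' @include AllClasses.R
NULL

#' Tunable parameters of the nucleosome-positioning pipeline
#'
#' Collects every knob of the pipeline, with complete presets for
#' MNase-digested and sonicated protocols.  See [nucConfig()] for the
#' meaning, units and defaults of each slot.
#'
#' @export
setClass("NucConfig",
    representation(
        protocol = "character",
        dupQuantile = "numeric",
        windowWidth = "numeric", windowStep = "numeric",
        centerExclusion = "numeric", minReads = "integer",
        maxRegionLength = "numeric", minRegionLength = "numeric",
        delta0 = "numeric", rhoS = "numeric", spacingBounds = "numeric",
        nu = "numeric", xi = "numeric", kappa = "numeric",
        deltaPriorScale = "numeric",
        alphaPrec = "numeric", betaPrec = "numeric",
        kMargin = "integer",
        deltaBounds = "numeric", sigmaBounds = "numeric",
        mergeDistance = "numeric", minWeightPerK = "numeric",
        coreQuantile = "numeric",
        nbRadius = "numeric", nbGapThreshold = "numeric",
        nbAlpha = "numeric",
        monoDist = "numeric", noneDist = "numeric",
        detectDist = "numeric",
        tol = "numeric", maxIter = "integer"))

setValidity("NucConfig", function(object) {
    msg <- character()
    chk1 <- function(x, nm) if (length(slot(object, x)) != 1L ||
            !is.finite(slot(object, x)))
        msg <<- c(msg, sprintf("'%s' must be a single finite value", x))
    for (nm in c("dupQuantile", "windowWidth", "windowStep", "minReads",
                 "maxRegionLength", "minRegionLength", "delta0", "rhoS",
                 "nu", "xi", "kappa", "deltaPriorScale", "alphaPrec",
                 "betaPrec", "kMargin", "mergeDistance", "minWeightPerK",
                 "coreQuantile", "nbRadius", "nbGapThreshold", "nbAlpha",
                 "monoDist", "noneDist", "detectDist", "tol", "maxIter"))
        chk1(nm, nm)
    if (length(msg)) return(msg)
    if (!object@protocol %in% c("mnase", "sonicated"))
        msg <- c(msg, "'protocol' must be 'mnase' or 'sonicated'")
    if (object@dupQuantile <= 0 || object@dupQuantile > 1)
        msg <- c(msg, "'dupQuantile' must be in (0, 1]")
    for (nm in c("windowWidth", "windowStep", "maxRegionLength",
                 "minRegionLength", "delta0", "rhoS", "xi", "kappa",
                 "deltaPriorScale", "betaPrec", "mergeDistance",
                 "nbRadius", "nbGapThreshold", "monoDist", "noneDist",
                 "detectDist", "tol"))
        if (slot(object, nm) <= 0)
            msg <- c(msg, sprintf("'%s' must be > 0", nm))
    if (object@centerExclusion < 0)
        msg <- c(msg, "'centerExclusion' must be >= 0")
    if (object@minReads < 1L)
        msg <- c(msg, "'minReads' must be >= 1")
    if (object@nu != 4)
        msg <- c(msg, "'nu' is fixed at 4 degrees of freedom")
    if (object@alphaPrec <= 1)
        msg <- c(msg, "'alphaPrec' must be > 1 (finite prior mean variance)")
    if (object@coreQuantile <= 0 || object@coreQuantile >= 1)
        msg <- c(msg, "'coreQuantile' must be in (0, 1)")
    if (object@nbAlpha <= 0 || object@nbAlpha > 0.5)
        msg <- c(msg, "'nbAlpha' must be in (0, 0.5]")
    for (nm in c("spacingBounds", "deltaBounds", "sigmaBounds")) {
        b <- slot(object, nm)
        if (length(b) != 2L || any(!is.finite(b)) || b[1] <= 0 ||
            b[1] >= b[2])
            msg <- c(msg, sprintf("'%s' must be increasing positive bounds", nm))
    }
    if (length(msg)) msg else TRUE
})

#' Pipeline configuration with protocol presets
#'
#' Builds a complete, validated parameter set.  The two presets differ
#' only where the data types differ: MNase digestion yields tightly
#' size-selected mononucleosomal fragments (tight fragment-length prior,
#' more tolerated genuine duplicates), while sonication yields broader
#' fragment lengths (looser prior, stricter duplicate cap).
#'
#' @param preset \code{"sonicated"} (default) or \code{"mnase"}.
#' @param ... Named overrides for any slot listed below.
#'
#' @details Parameters (units bp unless noted):
#' \describe{
#'   \item{dupQuantile}{Quantile of the per-position duplicate-count
#'     distribution used as duplicate cap; 0.999 (MNase) / 0.99
#'     (sonicated).}
#'   \item{windowWidth, windowStep, centerExclusion, minReads}{Sliding
#'     window (150), step (10), center-exclusion radius (0) and minimum
#'     per-strand read count (2) for region segmentation.}
#'   \item{maxRegionLength, minRegionLength}{Regions longer than 1200 bp
#'     are split recursively; regions shorter than 100 bp are dropped.}
#'   \item{delta0, rhoS, spacingBounds}{Spatial prior: target spacing of
#'     adjacent nucleosome centers (200), quadratic penalty strength
#'     (bp^-2, default \code{1/(2*25^2)}, implied spacing sd 25), and the
#'     spacing bounds (150, 250) used by the simulator's rejection step.}
#'   \item{nu}{Degrees of freedom of the read-position t density; fixed 4.}
#'   \item{xi, kappa, deltaPriorScale}{Fragment-length prior mean (150
#'     MNase / 200 sonicated), prior pseudo-count (16 / 4), and the scale
#'     (50) such that the prior sd is \code{deltaPriorScale/sqrt(kappa)}.}
#'   \item{alphaPrec, betaPrec}{Gamma(shape, rate) prior on read-position
#'     precision; prior mean variance \code{betaPrec/(alphaPrec-1)}:
#'     400 bp^2 (MNase) / 2500 bp^2 (sonicated).}
#'   \item{kMargin}{Half-width (2) of the searched interval of component
#'     counts around the expected count \code{round(length/delta0)}.}
#'   \item{deltaBounds, sigmaBounds, mergeDistance, minWeightPerK}{Post-fit
#'     screening: admissible fragment lengths (80, 250) and read-position
#'     sds (5, 150); centers closer than 60 bp are merged; components with
#'     weight below \code{minWeightPerK/K} (0.05/K) are dropped.}
#'   \item{coreQuantile}{Density contour (0.90) within which core reads
#'     are counted for scoring.}
#'   \item{nbRadius, nbGapThreshold, nbAlpha}{Low-density filter:
#'     neighborhood radius (500), nucleosome-free gap that truncates a
#'     neighborhood (250), and the negative-binomial quantile level
#'     (0.01).}
#'   \item{monoDist, noneDist}{Binding-site classification distances:
#'     monomodal within 50 bp, NoNuc beyond 1000 bp.}
#'   \item{detectDist}{Center distance under which a reference nucleosome
#'     counts as detected: 50 (MNase) / 100 (sonicated).}
#'   \item{tol, maxIter}{EM stopping rule: relative change of the
#'     penalized objective below 1e-6, at most 500 iterations.}
#' }
#'
#' @return A validated [NucConfig-class] object.
#' @examples
#' cfg <- nucConfig("mnase", minReads = 3)
#' cfg@xi
#' @export
nucConfig <- function(preset = c("sonicated", "mnase"), ...) {
    preset <- match.arg(preset)
    defaults <- list(
        protocol = preset,
        dupQuantile = if (preset == "mnase") 0.999 else 0.99,
        windowWidth = 150, windowStep = 10, centerExclusion = 0,
        minReads = 2L, maxRegionLength = 1200, minRegionLength = 100,
        delta0 = 200, rhoS = 1 / (2 * 25^2), spacingBounds = c(150, 250),
        nu = 4,
        xi = if (preset == "mnase") 150 else 200,
        kappa = if (preset == "mnase") 16 else 4,
        deltaPriorScale = 50,
        alphaPrec = if (preset == "mnase") 10 else 5,
        betaPrec = if (preset == "mnase") 3600 else 10000,
        kMargin = 2L,
        deltaBounds = c(80, 250), sigmaBounds = c(5, 150),
        mergeDistance = 60, minWeightPerK = 0.05,
        coreQuantile = 0.90,
        nbRadius = 500, nbGapThreshold = 250, nbAlpha = 0.01,
        monoDist = 50, noneDist = 1000,
        detectDist = if (preset == "mnase") 50 else 100,
        tol = 1e-6, maxIter = 500L)
    over <- list(...)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
        stop("unknown configuration parameter(s): ",
             paste(bad, collapse = ", "))
    defaults[names(over)] <- over
    for (nm in c("minReads", "kMargin", "maxIter"))
        defaults[[nm]] <- as.integer(defaults[[nm]])
    do.call(new, c(list("NucConfig"), defaults))
}

setMethod("show", "NucConfig", function(object) {
    cat(sprintf("NucConfig (%s preset)\n", object@protocol))
    cat(sprintf("  segmentation: window %g/%g bp, minReads %d, regions %g-%g bp\n",
        object@windowWidth, object@windowStep, object@minReads,
        object@minRegionLength, object@maxRegionLength))
    cat(sprintf("  spatial prior: delta0 %g bp, rhoS %.3g bp^-2\n",
        object@delta0, object@rhoS))
    cat(sprintf("  fragment prior: xi %g bp, kappa %g; precision Gamma(%g, %g)\n",
        object@xi, object@kappa, object@alphaPrec, object@betaPrec))
})
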