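#' @include AllClasses.R config.R
NULL

#' Location-scale Student-t(4) density
#'
#' The read-position density building block: a t distribution with 4
#' degrees of freedom, heavy-tailed enough to absorb outlier reads while
#' keeping a finite variance (2 sd^2).
#'
#' @param x Positions (bp).
#' @param center Location (bp).
#' @param sd Scale (bp), > 0.
#' @return Density per bp at \code{x}.
#' @examples
#' t4Density(0, 0, 1)  # 3/8
#' @export
t4Density <- function(x, center, sd) {
    if (any(sd <= 0)) stop("'sd' must be > 0")
    dt((x - center) / sd, df = 4) / sd
}

#' Bidirectional mixture density of read positions
#'
#' Forward reads concentrate at \code{mu - delta/2}, reverse reads at
#' \code{mu + delta/2}; both strands share the mixture weights because a
#' fragment contributes either end with equal probability.
#'
#' @param x Positions (bp).
#' @param strand \code{"fwd"} or \code{"rev"}.
#' @param fit A [NucleosomeFit-class].
#' @return Density per bp at each \code{x}.
#' @export
mixtureDensity <- function(x, strand = c("fwd", "rev"), fit) {
    strand <- match.arg(strand)
    stopifnot(is(fit, "NucleosomeFit"))
    ctr <- if (strand == "fwd") fit@mu - fit@delta / 2
           else fit@mu + fit@delta / 2
    sds <- sqrt(if (strand == "fwd") fit@varF else fit@varR)
    dens <- numeric(length(x))
    for (k in seq_len(fit@K))
        dens <- dens + fit@w[k] * t4Density(x, ctr[k], sds[k])
    dens
}

#' Spatial (GMRF) log-prior of ordered nucleosome centers
#'
#' Unnormalized chain prior penalizing deviations of successive center
#' spacings from the target spacing: \code{-rhoS * sum((diff(mus) -
#' delta0)^2)}.  A single center has log-prior 0.
#'
#' @param mus Sorted centers (bp).
#' @param delta0 Target spacing (bp).
#' @param rhoS Penalty strength (bp^-2).
#' @return Unnormalized log-density.
#' @export
gmrfLogPrior <- function(mus, delta0, rhoS) {
    if (is.unsorted(mus)) stop("'mus' must be sorted")
    if (length(mus) < 2L) return(0)
    -rhoS * sum((diff(mus) - delta0)^2)
}

## ---- EM internals ------------------------------------------------------

## strand-wise E-step: responsibilities z (n x K), latent t-scale weights
## u (n x K), and per-read mixture density
.eStepStrand <- function(x, ctr, sds, w) {
    n <- length(x); K <- length(ctr)
    D <- (matrix(x, n, K) - matrix(ctr, n, K, byrow = TRUE)) /
         matrix(sds, n, K, byrow = TRUE)
    dens <- (dt(D, df = 4) / matrix(sds, n, K, byrow = TRUE)) *
            matrix(w, n, K, byrow = TRUE)
    rs <- rowSums(dens)
    bad <- rs <= 0 | !is.finite(rs)
    z <- dens / rs
    if (any(bad)) {
        z[bad, ] <- 1 / K
        rs[bad] <- .Machine$double.xmin
    }
    list(z = z, u = 5 / (4 + D^2), dens = rs, underflow = any(bad))
}

#' E-step of the mixture EM
#'
#' Computes per-read responsibilities (posterior component memberships)
#' and the latent scale weights of the normal scale-mixture
#' representation of the t density, \code{u = (nu + 1)/(nu + d^2)} with
#' \code{d} the standardized residual.  Reads whose density underflows on
#' every component get uniform responsibilities (with a warning).
#'
#' @param region A [CandidateRegion-class].
#' @param fit A [NucleosomeFit-class] holding the current parameters.
#' @return List with matrices \code{zF}, \code{uF} (forward reads by
#'   component), \code{zR}, \code{uR}, and \code{loglik}.
#' @export
eStep <- function(region, fit) {
    stopifnot(is(region, "CandidateRegion"), is(fit, "NucleosomeFit"))
    ef <- .eStepStrand(region@fwd, fit@mu - fit@delta / 2,
                       sqrt(fit@varF), fit@w)
    er <- .eStepStrand(region@rev, fit@mu + fit@delta / 2,
                       sqrt(fit@varR), fit@w)
    if (ef$underflow || er$underflow)
        warning("density underflow for some reads; uniform responsibilities assigned")
    list(zF = ef$z, uF = ef$u, zR = er$z, uR = er$u,
         loglik = sum(log(ef$dens)) + sum(log(er$dens)))
}

## exact solve of a symmetric tridiagonal system (Thomas algorithm)
.solveTridiag <- function(diagv, off, rhs) {
    K <- length(diagv)
    if (K == 1L) return(rhs / diagv)
    cp <- numeric(K - 1L); dp <- numeric(K)
    cp[1] <- off[1] / diagv[1]
    dp[1] <- rhs[1] / diagv[1]
    for (k in 2:K) {
        m <- diagv[k] - off[k - 1L] * cp[k - 1L]
        if (k < K) cp[k] <- off[k] / m
        dp[k] <- (rhs[k] - off[k - 1L] * dp[k - 1L]) / m
    }
    x <- numeric(K)
    x[K] <- dp[K]
    for (k in (K - 1L):1L) x[k] <- dp[k] - cp[k] * x[k + 1L]
    x
}

#' Spatially coupled center update (M-step)
#'
#' Maximizes the expected complete-data log posterior jointly in all
#' centers: each center has a quadratic data term (forward reads inform
#' \code{mu - delta/2}, reverse reads \code{mu + delta/2}, weighted by
#' responsibility times latent scale weight over the variance) and the
#' GMRF prior couples adjacent centers.  The stationarity conditions form
#' a symmetric tridiagonal linear system, solved exactly; the result is
#' returned sorted (components are relabeled if the update reorders
#' them).
#'
#' @param region A [CandidateRegion-class].
#' @param es E-step output from [eStep()].
#' @param fit Current [NucleosomeFit-class].
#' @param delta0,rhoS Spatial prior parameters.
#' @return List \code{mu} (sorted centers) and \code{ord} (relabeling
#'   permutation applied).
#' @export
mStepCenters <- function(region, es, fit, delta0, rhoS) {
    K <- fit@K
    aF <- es$zF * es$uF; aR <- es$zR * es$uR
    AF <- colSums(aF) / fit@varF
    AR <- colSums(aR) / fit@varR
    BF <- colSums(aF * region@fwd) / fit@varF + AF * fit@delta / 2
    BR <- colSums(aR * region@rev) / fit@varR - AR * fit@delta / 2
    A <- AF + AR; B <- BF + BR
    hasLeft <- c(FALSE, rep(TRUE, K - 1L))
    hasRight <- c(rep(TRUE, K - 1L), FALSE)
    diagv <- A + 2 * rhoS * (hasLeft + hasRight)
    rhs <- B + 2 * rhoS * delta0 * (hasLeft - hasRight)
    if (all(A <= 0) || any(!is.finite(diagv)) || any(diagv <= 0))
        stop("singular center system: no effective reads")
    mu <- .solveTridiag(diagv, rep(-2 * rhoS, max(0L, K - 1L)), rhs)
    ord <- order(mu)
    list(mu = mu[ord], ord = ord)
}

#' Weight, fragment-length and variance updates (M-step)
#'
#' Mixture weights are the normalized responsibility totals over both
#' strands.  The fragment length is the exact MAP under the prior
#' \code{delta ~ N(xi, deltaPriorScale^2/kappa)}: a precision-weighted
#' blend of the data's forward/reverse offset estimate with the prior
#' mean, shrinking toward \code{xi} as \code{kappa} grows.  The variances
#' are the exact MAP under the Gamma(\code{alphaPrec}, \code{betaPrec})
#' precision prior, \code{(2*beta + weighted SSE)/(sum z + 2*alpha - 2)}.
#' Fragment lengths and variances are truncated to their configured
#' bounds (a projection, so each update still maximizes the objective
#' over the feasible box).
#'
#' @param region A [CandidateRegion-class].
#' @param es E-step output from [eStep()] (already relabeled if
#'   [mStepCenters()] reordered components).
#' @param mu Updated sorted centers.
#' @param fit Current [NucleosomeFit-class] (for the old delta used in
#'   the center residuals).
#' @param cfg A [NucConfig-class].
#' @return List with \code{w}, \code{delta}, \code{varF}, \code{varR},
#'   and \code{lowCount} (logical flag per component: effective count
#'   below 1, candidate for post-fit removal).
#' @export
mStepRest <- function(region, es, mu, fit, cfg) {
    aF <- es$zF * es$uF; aR <- es$zR * es$uR
    PF <- colSums(aF) / fit@varF; PR <- colSums(aR) / fit@varR
    MF <- colSums(aF * region@fwd) / fit@varF
    MR <- colSums(aR * region@rev) / fit@varR
    ## data estimate of delta and its curvature (quadratic coefficient /4)
    denom <- PF + PR
    deltaHat <- ifelse(denom > 0,
        2 * ((MR - PR * mu) - (MF - PF * mu)) / denom, cfg@xi)
    qPrec <- denom / 4
    tau0 <- cfg@kappa / cfg@deltaPriorScale^2
    delta <- (tau0 * cfg@xi + qPrec * deltaHat) / (tau0 + qPrec)
    delta <- pmin(pmax(delta, cfg@deltaBounds[1]), cfg@deltaBounds[2])
    resF <- matrix(region@fwd, nrow(aF), length(mu)) -
        matrix(mu - delta / 2, nrow(aF), length(mu), byrow = TRUE)
    resR <- matrix(region@rev, nrow(aR), length(mu)) -
        matrix(mu + delta / 2, nrow(aR), length(mu), byrow = TRUE)
    SF <- colSums(es$zF); SR <- colSums(es$zR)
    varF <- (2 * cfg@betaPrec + colSums(aF * resF^2)) /
            (SF + 2 * cfg@alphaPrec - 2)
    varR <- (2 * cfg@betaPrec + colSums(aR * resR^2)) /
            (SR + 2 * cfg@alphaPrec - 2)
    vb <- cfg@sigmaBounds^2
    varF <- pmin(pmax(varF, vb[1]), vb[2])
    varR <- pmin(pmax(varR, vb[1]), vb[2])
    w <- (SF + SR) / (length(region@fwd) + length(region@rev))
    list(w = w, delta = delta, varF = varF, varR = varR,
         lowCount = (SF + SR) < 1)
}

## full MAP objective tracked across EM iterations (up to constants)
.mapObjective <- function(region, fit, cfg) {
    ef <- .eStepStrand(region@fwd, fit@mu - fit@delta / 2,
                       sqrt(fit@varF), fit@w)
    er <- .eStepStrand(region@rev, fit@mu + fit@delta / 2,
                       sqrt(fit@varR), fit@w)
    ll <- sum(log(ef$dens)) + sum(log(er$dens))
    tau0 <- cfg@kappa / cfg@deltaPriorScale^2
    ll + gmrfLogPrior(fit@mu, cfg@delta0, cfg@rhoS) -
        tau0 / 2 * sum((fit@delta - cfg@xi)^2) +
        sum((cfg@alphaPrec - 1) * log(1 / fit@varF) -
            cfg@betaPrec / fit@varF) +
        sum((cfg@alphaPrec - 1) * log(1 / fit@varR) -
            cfg@betaPrec / fit@varR)
}

.initFit <- function(region, K, cfg) {
    pooled <- c(region@fwd + cfg@xi / 2, region@rev - cfg@xi / 2)
    mu <- as.numeric(quantile(pooled, (seq_len(K) - 0.5) / K,
                              names = FALSE, type = 7))
    mu <- sort(mu + seq(0, 1e-3, length.out = K))   # break exact ties
    v <- max(var(pooled) / max(1, K), cfg@sigmaBounds[1]^2 * 4)
    v <- min(v, cfg@sigmaBounds[2]^2)
    NucleosomeFit(w = rep(1 / K, K), mu = mu, delta = rep(cfg@xi, K),
                  varF = rep(v, K), varR = rep(v, K))
}

#' Fit a K-component bidirectional mixture to one region by EM/MAP
#'
#' Deterministic given the data: centers start at evenly spaced quantiles
#' of the pooled strand-recentered reads, fragment lengths at the prior
#' mean, variances from the pooled spread, weights uniform.  E and M
#' steps alternate until the relative change of the full MAP objective
#' falls below \code{cfg@tol} or \code{cfg@maxIter} iterations; the
#' objective is nondecreasing across iterations.  Optional seeded jitter
#' restarts keep the best objective.
#'
#' @param region A [CandidateRegion-class] with at least \code{minReads}
#'   reads per strand.
#' @param K Number of components, >= 1.
#' @param cfg A [NucConfig-class].
#' @param restarts Number of additional jittered starts (default 0).
#' @param seed Seed for the jitter when \code{restarts > 0}.
#' @return A [NucleosomeFit-class]; its \code{objTrace} slot holds the
#'   objective after every iteration, \code{logpostPen} the penalized
#'   model-selection objective (log-likelihood + spatial log-prior).
#' @export
fitRegion <- function(region, K, cfg, restarts = 0L, seed = 1L) {
    stopifnot(is(region, "CandidateRegion"), K >= 1L, is(cfg, "NucConfig"))
    if (length(region@fwd) < cfg@minReads ||
        length(region@rev) < cfg@minReads)
        stop("region has fewer than 'minReads' reads on some strand")
    runOne <- function(init) {
        fit <- init
        trace <- .mapObjective(region, fit, cfg)
        for (it in seq_len(cfg@maxIter)) {
            es <- eStep(region, fit)
            upd <- tryCatch(
                mStepCenters(region, es, fit, cfg@delta0, cfg@rhoS),
                error = function(e) NULL)
            if (is.null(upd)) return(NULL)
            if (any(upd$ord != seq_len(K))) {
                es$zF <- es$zF[, upd$ord, drop = FALSE]
                es$uF <- es$uF[, upd$ord, drop = FALSE]
                es$zR <- es$zR[, upd$ord, drop = FALSE]
                es$uR <- es$uR[, upd$ord, drop = FALSE]
                fit <- NucleosomeFit(fit@w[upd$ord], fit@mu[upd$ord],
                    fit@delta[upd$ord], fit@varF[upd$ord],
                    fit@varR[upd$ord])
            }
            rest <- mStepRest(region, es, upd$mu, fit, cfg)
            fit <- NucleosomeFit(rest$w, upd$mu, rest$delta,
                                 rest$varF, rest$varR)
            obj <- .mapObjective(region, fit, cfg)
            if (!is.finite(obj)) return(NULL)
            trace <- c(trace, obj)
            rel <- abs(obj - trace[it]) / (abs(trace[it]) + 1e-10)
            if (rel < cfg@tol) {
                es2 <- eStep(region, fit)
                return(NucleosomeFit(fit@w, fit@mu, fit@delta, fit@varF,
                    fit@varR, loglik = es2$loglik,
                    logpostPen = es2$loglik +
                        gmrfLogPrior(fit@mu, cfg@delta0, cfg@rhoS),
                    objTrace = trace, nIter = it, converged = TRUE))
            }
        }
        es2 <- eStep(region, fit)
        NucleosomeFit(fit@w, fit@mu, fit@delta, fit@varF, fit@varR,
            loglik = es2$loglik,
            logpostPen = es2$loglik +
                gmrfLogPrior(fit@mu, cfg@delta0, cfg@rhoS),
            objTrace = trace, nIter = cfg@maxIter, converged = FALSE)
    }
    best <- runOne(.initFit(region, K, cfg))
    if (restarts > 0L) {
        span <- max(1, (region@end - region@start) / (4 * K))
        for (r in seq_len(restarts)) {
            set.seed(seed + r)
            init <- .initFit(region, K, cfg)
            init <- NucleosomeFit(init@w,
                sort(init@mu + rnorm(K, 0, span)), init@delta,
                init@varF, init@varR)
            cand <- runOne(init)
            if (!is.null(cand) && (is.null(best) ||
                tail(cand@objTrace, 1) > tail(best@objTrace, 1)))
                best <- cand
        }
    }
    if (is.null(best))
        stop("model fit failed for K = ", K,
             " (singular or non-finite objective)")
    best
}

#' Searched interval of component counts for a region
#'
#' Centered on the expected count \code{E = max(1,
#' round(length/delta0))}: \code{[max(1, E - kMargin), E + kMargin]},
#' additionally capped at the per-strand read count so every component
#' can claim at least one read per strand.
#'
#' @param region A [CandidateRegion-class].
#' @param cfg A [NucConfig-class].
#' @return Integer vector of candidate K values.
#' @export
kSearchRange <- function(region, cfg) {
    E <- max(1, round((region@end - region@start) / cfg@delta0))
    cap <- max(1L, min(length(region@fwd), length(region@rev)))
    lo <- min(max(1, E - cfg@kMargin), cap)
    hi <- min(E + cfg@kMargin, cap)
    seq.int(lo, hi)
}

#' Select the number of nucleosomes by penalized log-likelihood
#'
#' Returns the candidate fit maximizing the log-likelihood penalized by
#' the spatial prior of its centers; ties go to the smaller K.
#'
#' @param fits List of [NucleosomeFit-class] candidates (failed fits may
#'   be NULL and are skipped).
#' @return The selected [NucleosomeFit-class], or NULL if every fit
#'   failed.
#' @export
selectK <- function(fits) {
    fits <- Filter(function(f) !is.null(f) && is.finite(f@logpostPen),
                   fits)
    if (!length(fits)) return(NULL)
    fits <- fits[order(vapply(fits, function(f) f@K, integer(1)))]
    best <- fits[[1]]
    for (f in fits[-1])
        if (f@logpostPen > best@logpostPen) best <- f
    best
}

#' Post-fit screening of mixture components
#'
#' Drops components with weight below \code{minWeightPerK/K}, fragment
#' length outside \code{deltaBounds}, or read-position sd outside
#' \code{sigmaBounds}; then iteratively merges center pairs closer than
#' \code{mergeDistance} (the higher-weight member keeps its shape, the
#' weights add).  Surviving weights are renormalized and components
#' re-sorted.
#'
#' @param fit A [NucleosomeFit-class].
#' @param cfg A [NucConfig-class].
#' @return A screened [NucleosomeFit-class]; possibly with K = 0.
#' @export
postfitFilter <- function(fit, cfg) {
    stopifnot(is(fit, "NucleosomeFit"), is(cfg, "NucConfig"))
    keep <- fit@w >= cfg@minWeightPerK / max(1L, fit@K) &
        fit@delta >= cfg@deltaBounds[1] & fit@delta <= cfg@deltaBounds[2] &
        sqrt(fit@varF) >= cfg@sigmaBounds[1] &
        sqrt(fit@varF) <= cfg@sigmaBounds[2] &
        sqrt(fit@varR) >= cfg@sigmaBounds[1] &
        sqrt(fit@varR) <= cfg@sigmaBounds[2]
    w <- fit@w[keep]; mu <- fit@mu[keep]; delta <- fit@delta[keep]
    vF <- fit@varF[keep]; vR <- fit@varR[keep]
    while (length(mu) >= 2L && min(diff(mu)) < cfg@mergeDistance) {
        i <- which.min(diff(mu))          # closest adjacent pair
        a <- i; b <- i + 1L
        keepIdx <- if (w[a] >= w[b]) a else b
        w[keepIdx] <- w[a] + w[b]
        drop <- if (keepIdx == a) b else a
        w <- w[-drop]; mu <- mu[-drop]; delta <- delta[-drop]
        vF <- vF[-drop]; vR <- vR[-drop]
    }
    if (length(w)) w <- w / sum(w)
    NucleosomeFit(w = w, mu = mu, delta = delta, varF = vF, varR = vR,
        loglik = fit@loglik, logpostPen = fit@logpostPen,
        objTrace = fit@objTrace, nIter = fit@nIter,
        converged = fit@converged)
}

#' Fit one candidate region across its K search range
#'
#' Convenience wrapper: [kSearchRange()], [fitRegion()] for each K,
#' [selectK()], [postfitFilter()].
#'
#' @param region A [CandidateRegion-class].
#' @param cfg A [NucConfig-class].
#' @param restarts,seed Passed to [fitRegion()].
#' @return The screened selected [NucleosomeFit-class], or NULL if all
#'   fits failed.
#' @export
fitRegionAuto <- function(region, cfg, restarts = 0L, seed = 1L) {
    fits <- lapply(kSearchRange(region, cfg), function(K)
        tryCatch(fitRegion(region, K, cfg, restarts, seed),
                 error = function(e) NULL))
    sel <- selectK(fits)
    if (is.null(sel)) return(NULL)
    postfitFilter(sel, cfg)
}
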