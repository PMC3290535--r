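test_that("t(4) density has the closed-form mode and unit mass", {
    expect_equal(t4Density(0, 0, 1), 3 / 8)       # Gamma(5/2)/(sqrt(4*pi)*Gamma(2))
    a <- 13.7
    expect_equal(t4Density(100 + a, 100, 7), t4Density(100 - a, 100, 7))
    q <- integrate(t4Density, -500, 500, center = 0, sd = 1,
                   rel.tol = 1e-9)
    expect_equal(q$value, 1, tolerance = 1e-6)
    expect_error(t4Density(0, 0, -1), "sd")
})

test_that("mixture density matches direct summation and strand offsets", {
    fit1 <- NucleosomeFit(w = 1, mu = 1000, delta = 200, varF = 900,
                          varR = 900)
    x <- seq(700, 1300, 0.5)
    dens <- mixtureDensity(x, "fwd", fit1)
    expect_equal(x[which.max(dens)], 900)          # mode at mu - delta/2
    # mirror components: symmetric about the midpoint
    fit2 <- NucleosomeFit(w = c(0.5, 0.5), mu = c(900, 1100),
        delta = c(180, 180), varF = c(800, 800), varR = c(800, 800))
    xs <- seq(-400, 400, 7)
    expect_equal(mixtureDensity(1000 + xs, "fwd", fit2),
                 mixtureDensity(1000 - xs, "rev", fit2))
    # brute-force sum over random parameters
    for (seed in 1:5) {
        fit <- randomFit(4, seed)
        x <- seq(900, 3100, 11)
        for (strand in c("fwd", "rev")) {
            sgn <- if (strand == "fwd") -1 else 1
            ref <- rowSums(sapply(1:4, function(k)
                fit@w[k] * dt((x - (fit@mu[k] + sgn * fit@delta[k] / 2)) /
                    sqrt(if (strand == "fwd") fit@varF[k]
                         else fit@varR[k]), 4) /
                    sqrt(if (strand == "fwd") fit@varF[k]
                         else fit@varR[k])))
            expect_equal(mixtureDensity(x, strand, fit), ref)
        }
    }
})

test_that("spatial log-prior is the quadratic in spacing deviations", {
    expect_identical(gmrfLogPrior(500, 200, 0.01), 0)
    expect_identical(gmrfLogPrior(c(100, 300, 500), 200, 0.013), 0)
    expect_equal(gmrfLogPrior(c(0, 220, 400), 200, 0.003),
                 -0.003 * (400 + 400))
    expect_error(gmrfLogPrior(c(300, 100), 200, 0.01), "sorted")
})

test_that("E-step responsibilities and latent weights are exact", {
    # read equidistant between two identical components
    reg <- CandidateRegion("c", 0, 2000, fwd = 1000L, rev = 1100L)
    fit <- NucleosomeFit(w = c(0.5, 0.5), mu = c(900, 1300),
        delta = c(200, 200), varF = c(900, 900), varR = c(900, 900))
    es <- eStep(reg, fit)   # fwd centers 800, 1200: read at 1000
    expect_equal(as.numeric(es$zF), c(0.5, 0.5))
    # read exactly at a strand center: u = (nu+1)/nu
    reg2 <- CandidateRegion("c", 0, 2000, fwd = 800L, rev = 1000L)
    fit2 <- NucleosomeFit(w = 1, mu = 900, delta = 200, varF = 400,
                          varR = 400)
    es2 <- eStep(reg2, fit2)
    expect_equal(as.numeric(es2$uF), 1.25)
    # brute-force normalized densities on random instances
    for (seed in 1:4) {
        set.seed(seed)
        fit <- randomFit(3, seed)
        fwd <- sort(as.integer(runif(30, 900, 3100)))
        rev <- sort(as.integer(runif(25, 900, 3100)))
        reg <- CandidateRegion("c", 800, 3200, fwd, rev)
        es <- eStep(reg, fit)
        ref <- t(sapply(fwd, function(x) {
            d <- sapply(1:3, function(k) fit@w[k] *
                t4Density(x, fit@mu[k] - fit@delta[k] / 2,
                          sqrt(fit@varF[k])))
            d / sum(d)
        }))
        expect_equal(unname(es$zF), unname(ref), tolerance = 1e-12)
        expect_equal(rowSums(es$zR), rep(1, length(rev)))
    }
})

test_that("coupled center update solves the penalized quadratic exactly", {
    cfg <- nucConfig()
    # K=1: no coupling; reduces to the weighted strand-recentered mean
    tr <- toyRegion(K = 1, seed = 3)
    fit <- NucleosomeFit(w = 1, mu = 2020, delta = 200, varF = 1200,
                         varR = 1200)
    es <- eStep(tr$region, fit)
    upd <- mStepCenters(tr$region, es, fit, cfg@delta0, cfg@rhoS)
    aF <- es$zF * es$uF; aR <- es$zR * es$uR
    ref <- (sum(aF * (fwdReads(tr$region) + 100)) +
            sum(aR * (revReads(tr$region) - 100))) / (sum(aF) + sum(aR))
    expect_equal(upd$mu, ref)
    # rhoS -> 0 equals the uncoupled per-component solution
    tr3 <- toyRegion(K = 3, seed = 4)
    fit3 <- NucleosomeFit(w = rep(1 / 3, 3), mu = tr3$mus + 15,
        delta = rep(200, 3), varF = rep(1200, 3), varR = rep(1200, 3))
    es3 <- eStep(tr3$region, fit3)
    updFree <- mStepCenters(tr3$region, es3, fit3, cfg@delta0, 1e-12)
    aF <- es3$zF * es3$uF; aR <- es3$zR * es3$uR
    refFree <- sapply(1:3, function(k)
        (sum(aF[, k] * (fwdReads(tr3$region) + 100)) +
         sum(aR[, k] * (revReads(tr3$region) - 100))) /
        (sum(aF[, k]) + sum(aR[, k])))
    expect_equal(updFree$mu, sort(refFree), tolerance = 1e-6)
})

test_that("tridiagonal center solve equals a dense solve", {
    for (seed in 1:100) {
        set.seed(seed)
        K <- sample(1:6, 1)
        A <- runif(K, 0.01, 2)          # data precisions
        B <- A * runif(K, 500, 3000)    # data targets
        rho <- runif(1, 1e-4, 1e-2)
        d0 <- 200
        hasL <- c(FALSE, rep(TRUE, K - 1)); hasR <- rev(hasL)
        M <- diag(A + 2 * rho * (hasL + hasR), K)
        if (K > 1) for (k in 1:(K - 1)) M[k, k + 1] <- M[k + 1, k] <- -2 * rho
        rhs <- B + 2 * rho * d0 * (hasL - hasR)
        dense <- solve(M, rhs)
        tri <- nucleofit:::.solveTridiag(diag(M),
            if (K > 1) rep(-2 * rho, K - 1) else numeric(), rhs)
        expect_equal(tri, dense, tolerance = 1e-8)
    }
})

test_that("fragment-length update shrinks toward the prior mean", {
    tr <- toyRegion(K = 1, delta = 190, seed = 5)
    fit <- NucleosomeFit(w = 1, mu = tr$mus, delta = 200, varF = 1200,
                         varR = 1200)
    es <- eStep(tr$region, fit)
    # kappa -> 0: pure data estimate = twice the strand-mean gap
    cfg0 <- nucConfig(kappa = 1e-9)
    r0 <- mStepRest(tr$region, es, tr$mus, fit, cfg0)
    aF <- es$zF * es$uF; aR <- es$zR * es$uR
    dataDelta <- 2 * ((sum(aR * revReads(tr$region)) - sum(aR) * tr$mus) -
                      (sum(aF * fwdReads(tr$region)) - sum(aF) * tr$mus)) /
                 (sum(aF) + sum(aR))
    expect_equal(r0$delta, dataDelta, tolerance = 1e-4)
    # kappa -> Inf: prior mean exactly
    cfgInf <- nucConfig(kappa = 1e12)
    expect_equal(mStepRest(tr$region, es, tr$mus, fit, cfgInf)$delta,
                 nucConfig()@xi, tolerance = 1e-4)
})

test_that("variance update matches numeric maximization of its objective", {
    cfg <- nucConfig(sigmaBounds = c(1, 500))   # keep the optimum interior
    for (seed in 1:5) {
        tr <- toyRegion(K = 2, seed = seed)
        fit <- NucleosomeFit(w = c(0.5, 0.5), mu = tr$mus + 10,
            delta = c(200, 200), varF = c(1600, 1600),
            varR = c(1600, 1600))
        es <- eStep(tr$region, fit)
        out <- mStepRest(tr$region, es, fit@mu, fit, cfg)
        for (k in 1:2) {
            resid <- fwdReads(tr$region) - (fit@mu[k] - out$delta[k] / 2)
            zz <- es$zF[, k]; aa <- es$zF[, k] * es$uF[, k]
            obj <- function(v) -sum(zz) / 2 * log(v) -
                sum(aa * resid^2) / (2 * v) -
                (cfg@alphaPrec - 1) * log(v) - cfg@betaPrec / v
            vhat <- optimize(obj, c(1, 250000), maximum = TRUE,
                             tol = 1e-6)$maximum
            expect_equal(out$varF[k], vhat, tolerance = 1e-3)
        }
    }
})

test_that("EM recovers a single simulated nucleosome and is monotone", {
    tr <- toyRegion(K = 1, nPerStrand = 100, seed = 11)   # 200 reads
    fit <- fitRegion(tr$region, 1, nucConfig())
    expect_true(fit@converged)
    expect_lt(abs(fit@mu - tr$mus), 5)
    expect_true(all(diff(fit@objTrace) >= -1e-8))
    # iid likelihood: read order cannot matter
    perm <- CandidateRegion("chrT", tr$region@start, tr$region@end,
        sample(fwdReads(tr$region)), sample(revReads(tr$region)))
    fit2 <- fitRegion(perm, 1, nucConfig())
    expect_equal(fit2@mu, fit@mu)
    expect_equal(fit2@logpostPen, fit@logpostPen)
})

test_that("fits are translation-equivariant", {
    shift <- 25000
    for (K in 1:2) {
        tr <- toyRegion(K = K, seed = 20 + K)
        f1 <- fitRegion(tr$region, K, nucConfig())
        reg2 <- CandidateRegion("chrT", tr$region@start + shift,
            tr$region@end + shift, fwdReads(tr$region) + shift,
            revReads(tr$region) + shift)
        f2 <- fitRegion(reg2, K, nucConfig())
        expect_equal(f2@mu, f1@mu + shift, tolerance = 1e-4)
        expect_equal(f2@delta, f1@delta, tolerance = 1e-4)
        expect_equal(f2@varF, f1@varF, tolerance = 1e-3)
        expect_equal(f2@loglik, f1@loglik, tolerance = 1e-6)
    }
})

test_that("K search brackets the expected nucleosome count", {
    cfg <- nucConfig(kMargin = 2)
    mk <- function(len, nf, nr) CandidateRegion("c", 0, len,
        fwd = as.integer(seq(10, len - 20, length.out = nf)),
        rev = as.integer(seq(15, len - 10, length.out = nr)))
    expect_identical(kSearchRange(mk(200, 20, 20), cfg), 1:3)
    expect_identical(kSearchRange(mk(1000, 50, 50), cfg), 3:7)
    # cap: at most one component per read on the thinner strand
    expect_identical(kSearchRange(mk(1000, 2, 30), cfg), 2:2)
})

test_that("model selection maximizes the penalized likelihood, ties to smaller K", {
    f1 <- NucleosomeFit(w = 1, mu = 100, delta = 200, varF = 900,
        varR = 900, loglik = -50, logpostPen = -50, converged = TRUE)
    expect_identical(selectK(list(f1))@K, 1L)
    f2 <- NucleosomeFit(w = c(0.5, 0.5), mu = c(100, 300),
        delta = c(200, 200), varF = c(900, 900), varR = c(900, 900),
        loglik = -50, logpostPen = -50, converged = TRUE)
    expect_identical(selectK(list(f2, f1))@K, 1L)   # tie -> smaller K
    f2b <- NucleosomeFit(w = c(0.5, 0.5), mu = c(100, 300),
        delta = c(200, 200), varF = c(900, 900), varR = c(900, 900),
        loglik = -45, logpostPen = -45, converged = TRUE)
    expect_identical(selectK(list(f1, f2b))@K, 2L)
    expect_null(selectK(list(NULL, NULL)))
})

test_that("three well-separated nucleosomes select K = 3 in most replicates", {
    cfg <- nucConfig()
    hits <- 0L
    nrep <- 50L
    for (seed in seq_len(nrep)) {
        tr <- toyRegion(K = 3, nPerStrand = 150, spacing = 200,
                        seed = 900 + seed)
        fits <- lapply(kSearchRange(tr$region, cfg), function(K)
            tryCatch(fitRegion(tr$region, K, cfg),
                     error = function(e) NULL))
        sel <- selectK(fits)
        if (!is.null(sel) && postfitFilter(sel, cfg)@K == 3L)
            hits <- hits + 1L
    }
    expect_gte(hits / nrep, 0.9)
})

test_that("post-fit screening drops, merges and renormalizes correctly", {
    cfg <- nucConfig()
    ok <- NucleosomeFit(w = c(0.6, 0.4), mu = c(500, 700),
        delta = c(200, 190), varF = c(900, 900), varR = c(900, 900))
    expect_equal(postfitFilter(ok, cfg)@w, ok@w)
    weak <- NucleosomeFit(w = c(0.799, 0.2, 0.001), mu = c(500, 700, 900),
        delta = c(200, 190, 210), varF = rep(900, 3), varR = rep(900, 3))
    out <- postfitFilter(weak, cfg)
    expect_identical(out@K, 2L)
    expect_equal(sum(out@w), 1)
    close <- NucleosomeFit(w = c(0.7, 0.3), mu = c(500, 510),
        delta = c(200, 200), varF = c(900, 400), varR = c(900, 400))
    merged <- postfitFilter(close, cfg)
    expect_identical(merged@K, 1L)
    expect_equal(merged@mu, 500)           # higher-weight member keeps shape
    expect_equal(merged@varF, 900)
    expect_equal(merged@w, 1)
    oob <- NucleosomeFit(w = c(0.5, 0.5), mu = c(500, 800),
        delta = c(200, 600), varF = c(900, 900), varR = c(900, 900))
    expect_identical(postfitFilter(oob, cfg)@K, 1L)
})
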