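# shared fixture builders (everything generated in code; no binary files)

# write a BED6 file from position/strand vectors; returns the path
writeBed6 <- function(chrom, start, end, strand,
                      path = tempfile(fileext = ".bed")) {
    df <- data.frame(chrom = chrom, start = start, end = end,
        name = sprintf("r%d", seq_along(start)), score = 0L,
        strand = strand)
    write.table(df, path, sep = "\t", quote = FALSE, col.names = FALSE,
                row.names = FALSE)
    path
}

# a small region with reads drawn around K truth nucleosomes
toyRegion <- function(K = 2, nPerStrand = 120, spacing = 200,
                      delta = 200, sigma = 35, start = 2000, seed = 1) {
    set.seed(seed)
    mus <- start + spacing * (seq_len(K) - 1)
    fwd <- rev <- integer()
    for (m in mus) {
        fwd <- c(fwd, round(m - delta / 2 + sigma * rt(nPerStrand, 4)))
        rev <- c(rev, round(m + delta / 2 + sigma * rt(nPerStrand, 4)))
    }
    fwd <- pmax(fwd, 0); rev <- pmax(rev, 0)
    lo <- min(fwd, rev); hi <- max(fwd, rev) + 1
    list(region = CandidateRegion("chrT", lo, hi, fwd, rev), mus = mus)
}

# a valid random mixture fit for oracle comparisons
randomFit <- function(K, seed = 1) {
    set.seed(seed)
    w <- runif(K); w <- w / sum(w)
    NucleosomeFit(w = w, mu = sort(runif(K, 1000, 3000)),
        delta = runif(K, 150, 250), varF = runif(K, 400, 2500),
        varR = runif(K, 400, 2500))
}

# brute-force sliding-window segmentation used as an independent oracle
oracleSegment <- function(fwd, rev, w, s, cx, minReads) {
    lo <- min(fwd, rev); hi <- max(fwd, rev)
    starts <- seq(s * floor((lo - w) / s), s * ceiling(hi / s), by = s)
    kept <- c()
    for (a in starts) {
        ctr <- a + w / 2
        nf <- sum(fwd >= a & fwd <= ctr - cx)
        nr <- sum(rev >= ctr + cx & rev <= a + w)
        if (nf >= minReads && nr >= minReads) kept <- c(kept, a)
    }
    if (!length(kept)) return(list())
    out <- list()
    cur <- c(kept[1], kept[1] + w)
    for (a in kept[-1]) {
        if (a <= cur[2]) cur[2] <- a + w
        else { out[[length(out) + 1]] <- cur; cur <- c(a, a + w) }
    }
    out[[length(out) + 1]] <- cur
    out
}
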