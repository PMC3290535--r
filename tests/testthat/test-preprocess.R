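test_that("duplicate cap never binds on unique positions", {
    rs <- StrandedReads("c", fwd = c(1, 5, 9), rev = c(20, 40))
    for (q in c(0.1, 0.5, 0.99))
        expect_identical(filterDuplicates(rs, q), rs)
})

test_that("duplicate cap equals the brute-force empirical quantile", {
    # counts {1 x 9, 10}: the 0.9 quantile by cdf scan
    rs <- StrandedReads("c", fwd = c(1:9, rep(50L, 10L)))
    counts <- c(rep(1, 9), 10)
    cdfScan <- function(cnt, q) {   # smallest value with cdf >= q
        v <- sort(unique(cnt))
        v[which(sapply(v, function(x) mean(cnt <= x)) >= q)[1]]
    }
    capped <- filterDuplicates(rs, 0.9)
    expect_identical(sum(fwdReads(capped) == 50L),
                     as.integer(cdfScan(counts, 0.9)))
    # all other positions untouched
    expect_identical(fwdReads(capped)[1:9], 1:9)
})

test_that("quantile 1 disables the duplicate cap", {
    rs <- StrandedReads("c", fwd = rep(c(10L, 20L), c(30L, 2L)),
                        rev = rep(15L, 8L))
    expect_identical(filterDuplicates(rs, 1), rs)
})

test_that("duplicate filtering is idempotent and handles empty input", {
    empty <- StrandedReads("c")
    expect_identical(filterDuplicates(empty, 0.5), empty)
    for (seed in 1:5) {
        set.seed(seed)
        rs <- StrandedReads("c",
            fwd = sample.int(50, 200, replace = TRUE),
            rev = sample.int(50, 150, replace = TRUE) + 100L)
        once <- filterDuplicates(rs, 0.8)
        expect_identical(filterDuplicates(once, 0.8), once)
    }
})

test_that("segmentation finds the bridging window of the worked example", {
    # fwd 100,110 and rev 240,250 are only jointly covered by the
    # window starting at 100 (halves closed): exactly one region
    rs <- StrandedReads("c", fwd = c(100, 110), rev = c(240, 250))
    cfg <- nucConfig(windowWidth = 150, windowStep = 10,
                     centerExclusion = 0, minReads = 2)
    regs <- segmentReads(rs, cfg)
    expect_length(regs, 1L)
    expect_identical(fwdReads(regs[[1]]), c(100L, 110L))
    expect_identical(revReads(regs[[1]]), c(240L, 250L))
})

test_that("single-strand data yield no regions", {
    rs <- StrandedReads("c", fwd = seq(100, 400, 10))
    expect_length(segmentReads(rs, nucConfig()), 0L)
})

test_that("well-separated read clusters give disjoint regions", {
    rs <- StrandedReads("c",
        fwd = c(seq(1000, 1040, 10), seq(5000, 5040, 10)),
        rev = c(seq(1150, 1190, 10), seq(5150, 5190, 10)))
    regs <- segmentReads(rs, nucConfig())
    expect_length(regs, 2L)
    expect_lt(regs[[1]]@end, regs[[2]]@start)
})

test_that("segmentation agrees with a brute-force window scan", {
    cfg <- nucConfig()
    for (seed in 1:5) {
        set.seed(seed)
        n <- 80
        fwd <- sort(sample.int(4000, n, replace = TRUE))
        rev <- sort(sample.int(4000, n, replace = TRUE))
        regs <- segmentReads(StrandedReads("c", fwd, rev), cfg,
                             split = FALSE)
        oracle <- oracleSegment(fwd, rev, cfg@windowWidth,
            cfg@windowStep, cfg@centerExclusion, cfg@minReads)
        # same number of merged windows surviving the length filter,
        # and every returned region sits inside one oracle window
        keptOracle <- Filter(function(iv) {
            f <- fwd[fwd >= iv[1] & fwd <= iv[2]]
            r <- rev[rev >= iv[1] & rev <= iv[2]]
            length(f) && length(r) &&
                (max(f, r) + 1 - min(f, r)) >= cfg@minRegionLength
        }, oracle)
        expect_length(regs, length(keptOracle))
        for (i in seq_along(regs)) {
            expect_gte(regs[[i]]@start, keptOracle[[i]][1])
            expect_lte(regs[[i]]@end, keptOracle[[i]][2] + 1)
        }
    }
})

test_that("every retained read lands in exactly one sorted region", {
    set.seed(42)
    rs <- StrandedReads("c",
        fwd = sample.int(20000, 600, replace = TRUE),
        rev = sample.int(20000, 600, replace = TRUE))
    regs <- segmentReads(rs, nucConfig())
    if (length(regs) >= 2L) {
        starts <- vapply(regs, function(r) r@start, numeric(1))
        ends <- vapply(regs, function(r) r@end, numeric(1))
        expect_true(all(diff(starts) > 0))
        expect_true(all(ends[-length(ends)] <= starts[-1]))
    }
    # raising minReads cannot increase the region count
    n1 <- length(segmentReads(rs, nucConfig(minReads = 2)))
    n2 <- length(segmentReads(rs, nucConfig(minReads = 4)))
    expect_lte(n2, n1)
})

test_that("regions at the length bound are not split", {
    cfg <- nucConfig()
    r <- CandidateRegion("c", 0, cfg@maxRegionLength,
        fwd = as.integer(seq(10, 1100, 50)),
        rev = as.integer(seq(40, 1150, 50)))
    expect_identical(splitLongRegions(r, cfg), list(r))
})

test_that("over-long regions split inside the widest central gap", {
    cfg <- nucConfig()
    # 2200-bp region with a ~400-bp read gap at its center
    left <- as.integer(seq(50, 900, 25))
    right <- as.integer(seq(1300, 2150, 25))
    r <- CandidateRegion("c", 0, 2200, fwd = c(left, right),
                         rev = c(left + 5L, right + 5L))
    out <- splitLongRegions(r, cfg)
    expect_length(out, 2L)
    cut <- out[[1]]@end
    expect_gte(cut, 905)
    expect_lte(out[[2]]@start, 1300)
    # read multiset preserved across the partition
    expect_identical(sort(c(fwdReads(out[[1]]), fwdReads(out[[2]]))),
                     fwdReads(r))
    expect_identical(sort(c(revReads(out[[1]]), revReads(out[[2]]))),
                     revReads(r))
    expect_true(all(vapply(out, function(x) x@end - x@start,
                           numeric(1)) <= cfg@maxRegionLength))
})

test_that("unsplittable regions are returned whole with a warning", {
    cfg <- nucConfig(maxRegionLength = 300)
    # all reverse reads on the left, all forward on the right: any cut
    # leaves a strand empty on one side
    r <- CandidateRegion("c", 0, 800,
        fwd = as.integer(seq(500, 780, 20)),
        rev = as.integer(seq(10, 290, 20)))
    expect_warning(out <- splitLongRegions(r, cfg), "cannot be split")
    expect_length(out, 1L)
})
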