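test_that("bin grid tiles the genome with 0-based half-open bins", {
    grid <- BinGrid(c(chr1 = 250, chr2 = 100), binSize = 100)
    expect_equal(unname(binCountPerChrom(grid)), c(3L, 1L))
    expect_equal(binCount(grid), 4L)
    bins <- gridBins(grid)
    expect_equal(GenomicRanges::width(bins), c(100, 100, 50, 100))
    expect_equal(chromBinIndices(grid, "chr2"), 4L)
    expect_error(BinGrid(c(chr1 = 250), binSize = 0))
})

test_that("reading a bedGraph length-weight-averages records into bins", {
    grid <- toyGrid(nbins = 4, binSize = 50000)
    path <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines(c("chrT\t0\t50000\t2.0",          # exactly bin 1
                 "chrT\t50000\t75000\t1.0",       # half of bin 2
                 "chrT\t75000\t100000\t3.0"),     # other half of bin 2
               path)
    tr <- readTrack(path, grid)
    expect_equal(trackValues(tr)[1:2], c(2.0, 2.0))
    expect_true(all(trackMask(tr)[3:4]))
})

test_that("record spanning two bins matches the per-base oracle", {
    grid <- toyGrid(nbins = 3, binSize = 100)
    path <- withr::local_tempfile(fileext = ".bedgraph")
    starts <- c(30, 170)
    ends <- c(170, 260)
    vals <- c(4, 10)
    writeLines(sprintf("chrT\t%d\t%d\t%g", starts, ends, vals), path)
    tr <- readTrack(path, grid)
    oracle <- perBaseBinOracle(starts, ends, vals, 300, 100)
    expect_equal(trackValues(tr), oracle)
})

test_that("track reading rejects unknown chromosomes and overlaps", {
    grid <- toyGrid(nbins = 2, binSize = 100)
    p1 <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines("chrZ\t0\t100\t1.0", p1)
    expect_error(readTrack(p1, grid), "chrZ")
    p2 <- withr::local_tempfile(fileext = ".bedgraph")
    writeLines(c("chrT\t0\t100\t1.0", "chrT\t50\t150\t2.0"), p2)
    expect_error(readTrack(p2, grid), "overlap")
})

test_that("bedGraph write/read round-trips unmasked values", {
    grid <- toyGrid(nbins = 20, binSize = 1000)
    set.seed(7)
    v <- runif(20) * 1000
    v[c(3, 11)] <- NA
    tr <- BinnedTrack(grid, v)
    path <- withr::local_tempfile(fileext = ".bedgraph")
    writeTrack(tr, path)
    back <- readTrack(path, grid)
    ok <- !trackMask(tr)
    expect_equal(trackValues(back)[ok], v[ok], tolerance = 1e-6)
    expect_equal(trackMask(back), trackMask(tr))
})

test_that("read binning yields documented RPKM and fractional counts", {
    # 2 reads fully inside one 1 kb bin, 4 reads total
    grid <- BinGrid(c(chrT = 2000), binSize = 1000)
    reads <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
        c(101, 201, 1101, 1201), width = 50), strand = "+")
    tr <- binCoverage(reads, grid)
    expect_equal(trackValues(tr)[1], 2 / (4e-6 * 1.0))  # 500000
    # plus-strand read at 0, length 50, extended to 250, bins of 100
    grid2 <- BinGrid(c(chrT = 1000), binSize = 100)
    one <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 50),
                                  strand = "+")
    tr2 <- binCoverage(one, grid2, extendTo = 250)
    counts <- trackValues(tr2) * (1 / 1e6) * (100 / 1e3)
    expect_equal(counts[1:3], c(0.4, 0.4, 0.2))
    expect_equal(sum(counts), 1)
})

test_that("fractional counting conserves reads exactly", {
    grid <- BinGrid(c(c1 = 950, c2 = 430), binSize = 100)
    set.seed(11)
    n <- 200
    chrom <- sample(c("c1", "c2"), n, replace = TRUE)
    len <- chromLengths(grid)[chrom]
    start <- floor(runif(n) * (len - 30)) + 1
    reads <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start, width = 30),
        strand = sample(c("+", "-"), n, replace = TRUE))
    tr <- binCoverage(reads, grid, extendTo = 120)  # extension clips at ends
    counts <- trackValues(tr) * (n / 1e6) *
        (GenomicRanges::width(gridBins(grid)) / 1e3)
    expect_equal(sum(counts), n)
})

test_that("zero reads give an all-zero track and blacklist masks bins", {
    grid <- toyGrid(nbins = 5, binSize = 100)
    bl <- GenomicRanges::GRanges("chrT", IRanges::IRanges(250, 260))
    tr <- binCoverage(GenomicRanges::GRanges(), grid, blacklist = bl)
    expect_equal(trackValues(tr)[-3], rep(0, 4))
    expect_true(is.na(trackValues(tr)[3]) && trackMask(tr)[3])
})

test_that("unstranded reads warn and are extended as plus strand", {
    grid <- toyGrid(nbins = 5, binSize = 100)
    r <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 50))
    expect_warning(tr <- binCoverage(r, grid, extendTo = 200),
                   "plus strand")
    counts <- trackValues(tr) * (1 / 1e6) * 0.1
    expect_equal(counts[1:2], c(0.5, 0.5))
})

test_that("rebin averages unmasked fine bins and composes", {
    grid <- toyGrid(nbins = 8, binSize = 100)
    v <- c(1, 3, 5, NA, 2, 2, NA, NA)
    tr <- BinnedTrack(grid, v)
    r2 <- rebin(tr, 200)
    expect_equal(trackValues(r2), c(2, 5, 2, NA))
    expect_true(trackMask(r2)[4])
    # rebin-rebin equals single rebin (on unmasked input; under partial
    # masking the mean-of-unmasked definition is not associative)
    full <- BinnedTrack(grid, c(1, 3, 5, 7, 2, 2, 0, 4))
    expect_identical(trackValues(rebin(rebin(full, 200), 400)),
                     trackValues(rebin(full, 400)))
    expect_error(rebin(tr, 150), "multiple")
    # constant track stays constant
    const <- BinnedTrack(grid, rep(4, 8))
    expect_equal(trackValues(rebin(const, 400)), c(4, 4))
})

test_that("track Spearman weights chromosomes by length", {
    grid <- BinGrid(c(cA = 100e6, cB = 50e6), binSize = 10e6)
    idxA <- chromBinIndices(grid, "cA")
    idxB <- chromBinIndices(grid, "cB")
    a <- numeric(binCount(grid)); b <- numeric(binCount(grid))
    a[idxA] <- 1:10;        b[idxA] <- (1:10) * 3         # rho = 1
    set.seed(3)
    # construct rho = 0 on cB
    a[idxB] <- c(1, 2, 3, 4, 5)
    b[idxB] <- c(3, 5, 1, 4, 2)
    while (abs(cor(a[idxB], b[idxB], method = "spearman")) > 1e-12)
        b[idxB] <- sample(b[idxB])
    res <- trackSpearman(BinnedTrack(grid, a), BinnedTrack(grid, b))
    expect_equal(unname(res$perChromosome), c(1, 0))
    expect_equal(res$genome, (1 * 100e6 + 0 * 50e6) / 150e6)
})

test_that("track Spearman is symmetric and monotone-invariant", {
    grid <- toyGrid(nbins = 30, binSize = 1000)
    set.seed(5)
    a <- runif(30); b <- runif(30)
    ta <- BinnedTrack(grid, a); tb <- BinnedTrack(grid, b)
    r1 <- trackSpearman(ta, tb)$genome
    expect_equal(trackSpearman(tb, ta)$genome, r1)
    expect_equal(trackSpearman(BinnedTrack(grid, exp(3 * a)), tb)$genome,
                 r1)
    # identical and rank-reversed tracks
    expect_equal(trackSpearman(ta, ta)$genome, 1)
    expect_equal(trackSpearman(ta, BinnedTrack(grid, -a))$genome, -1)
})

test_that("relative enrichment matches log2 ratio plus kernel oracle", {
    grid <- toyGrid(nbins = 5, binSize = 1000)
    a <- c(1, 2, 4, 8, 16)
    b <- c(2, 2, 2, 2, 2)
    ta <- BinnedTrack(grid, a); tb <- BinnedTrack(grid, b)
    expect_error(relativeEnrichment(ta, tb, pseudocount = 0), "positive")
    # identical tracks -> 0 everywhere
    expect_equal(trackValues(relativeEnrichment(ta, ta, bandwidth = 0)),
                 rep(0, 5))
    # a = 2b with vanishing pseudocount -> +1
    t2 <- BinnedTrack(grid, 2 * b)
    expect_equal(trackValues(relativeEnrichment(t2, tb, 1e-12,
                                                bandwidth = 0)),
                 rep(1, 5), tolerance = 1e-9)
    # unsmoothed values are the hand computation
    p <- 0.1
    raw <- trackValues(relativeEnrichment(ta, tb, p, bandwidth = 0))
    expect_equal(raw, log2((a + p) / (b + p)))
    # smoothing matches a direct moving-kernel oracle
    sm <- trackValues(relativeEnrichment(ta, tb, p, bandwidth = 1000))
    sdB <- 1
    half <- 3
    oracle <- vapply(1:5, function(i) {
        o <- (-half):half
        j <- i + o
        ok <- j >= 1 & j <= 5
        k <- exp(-o[ok]^2 / (2 * sdB^2))
        sum(k * log2((a[j[ok]] + p) / (b[j[ok]] + p))) / sum(k)
    }, numeric(1))
    expect_equal(sm, oracle)
})

test_that("paired Cohen's d has the closed form and antisymmetry", {
    expect_equal(cohensDPaired(c(2, 4, 6), c(1, 2, 3))$d, 2.0)
    expect_equal(cohensDPaired(c(1, 2, 3), c(1, 2, 3))$d, 0)
    x <- c(1.2, 5, 3.3, 0.4); y <- c(0.1, 4, 4.4, 1)
    expect_equal(cohensDPaired(x, y)$d, -cohensDPaired(y, x)$d)
    degen <- cohensDPaired(c(2, 3, 4), c(1, 2, 3))
    expect_true(is.infinite(degen$d) && degen$degenerate)
})

test_that("TSS effect size uses strand-aware windows", {
    grid <- BinGrid(c(chrT = 10000), binSize = 100)
    # signal high around TSS at 5000, low 2 kb upstream
    mkTrack <- function(tssLevel, upLevel) {
        v <- rep(0, 100)
        v[47:53] <- tssLevel   # bins covering 4600-5300
        v[27:33] <- upLevel    # bins covering 2600-3300
        BinnedTrack(grid, v)
    }
    tss <- GenomicRanges::GRanges("chrT", IRanges::IRanges(5000, 5000),
                                  strand = "+")
    tracks <- list(mkTrack(10, 2), mkTrack(12, 3), mkTrack(9, 1))
    res <- tssEffectSize(tracks, tss)
    diffs <- res$tssMeans - res$upstreamMeans
    expect_equal(res$d, mean(diffs) / sd(diffs))
    expect_gt(res$d, 0)
    expect_equal(res$tssMeans, c(10, 12, 9))
    expect_equal(res$upstreamMeans, c(2, 3, 1))
    # on the minus strand the upstream window sits downstream in genome
    # coordinates (here over empty signal)
    resMinus <- tssEffectSize(tracks, GenomicRanges::GRanges(
        "chrT", IRanges::IRanges(5000, 5000), strand = "-"))
    expect_equal(resMinus$upstreamMeans, c(0, 0, 0))
})
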