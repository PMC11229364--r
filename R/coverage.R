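#' Bin sequencing reads into an RPKM coverage track
#'
#' Each read is (optionally) extended at its 3' end to `extendTo` bp,
#' clipped at the chromosome end, and counted fractionally into every bin it
#' overlaps (weight = overlapped bp / extended read length, so each read
#' contributes exactly 1 in total). Counts are converted to RPKM
#' \eqn{= count / (total_{reads}/10^6) / (bin_{bp}/10^3)} and bins
#' overlapping the blacklist are masked afterwards.
#'
#' @param reads `GRanges` of aligned reads (strand used for extension;
#'   unstranded reads are treated as plus strand with a warning when
#'   extension is requested).
#' @param grid target [BinGrid-class].
#' @param blacklist optional `GRanges` of regions to mask.
#' @param extendTo extend reads to this length in bp (0 = no extension).
#' @return a [BinnedTrack-class] of RPKM values.
#' @export
binCoverage <- function(reads, grid, blacklist = NULL, extendTo = 0) {
    if (length(reads) == 0)
        return(maskBlacklist(
            BinnedTrack(grid, rep(0, binCount(grid)),
                        mask = rep(FALSE, binCount(grid))), blacklist))
    bad <- setdiff(unique(as.character(GenomeInfoDb::seqnames(reads))),
                   chromNames(grid))
    if (length(bad))
        stop("unknown chromosome(s) in reads: ", paste(bad, collapse = ", "))
    total <- length(reads)
    if (extendTo > 0) {
        str <- as.character(GenomicRanges::strand(reads))
        if (any(str == "*")) {
            warning("unstranded reads treated as plus strand for extension")
            str[str == "*"] <- "+"
        }
        if (any(extendTo < GenomicRanges::width(reads)))
            stop("extendTo must be 0 or >= every read length")
        st <- GenomicRanges::start(reads)
        en <- GenomicRanges::end(reads)
        en[str == "+"] <- st[str == "+"] + extendTo - 1L
        st[str == "-"] <- en[str == "-"] - extendTo + 1L
        sl <- chromLengths(grid)[as.character(GenomeInfoDb::seqnames(reads))]
        st <- pmax(st, 1L)
        en <- pmin(en, sl)
        reads <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(reads),
                                        IRanges::IRanges(st, en))
    }
    bins <- gridBins(grid)
    ov <- GenomicRanges::findOverlaps(reads, bins)
    w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(reads)[S4Vectors::queryHits(ov)],
        GenomicRanges::ranges(bins)[S4Vectors::subjectHits(ov)])) /
        GenomicRanges::width(reads)[S4Vectors::queryHits(ov)]
    counts <- rep(0, binCount(grid))
    agg <- rowsum(w, S4Vectors::subjectHits(ov))
    counts[as.integer(rownames(agg))] <- agg[, 1]
    binKb <- GenomicRanges::width(bins) / 1e3
    rpkm <- counts / (total / 1e6) / binKb
    maskBlacklist(BinnedTrack(grid, rpkm, mask = rep(FALSE, length(rpkm))),
                  blacklist)
}

# mask bins overlapping blacklist intervals
maskBlacklist <- function(track, blacklist) {
    if (is.null(blacklist) || length(blacklist) == 0) return(track)
    bins <- gridBins(trackGrid(track))
    hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(bins, blacklist)))
    mask <- trackMask(track)
    mask[hit] <- TRUE
    BinnedTrack(trackGrid(track), trackValues(track), mask = mask)
}

#' Rebin a track onto a coarser grid
#'
#' The target bin size must be an integer multiple of the source bin size.
#' Each target value is the mean of the unmasked source bins inside it; a
#' target bin is masked iff all its source bins are masked.
#'
#' @param track a [BinnedTrack-class].
#' @param targetBinSize target bin width in bp.
#' @return a [BinnedTrack-class] on the coarser grid.
#' @export
rebin <- function(track, targetBinSize) {
    src <- trackGrid(track)
    if (targetBinSize %% binSize(src) != 0)
        stop("target bin size must be an integer multiple of ",
             binSize(src))
    dst <- BinGrid(chromLengths(src), targetBinSize)
    k <- targetBinSize / binSize(src)
    out <- rep(NA_real_, binCount(dst))
    for (chrom in chromNames(src)) {
        v <- trackValues(track)[chromBinIndices(src, chrom)]
        g <- (seq_along(v) - 1L) %/% k
        mean_na <- vapply(split(v, g), function(x) {
            x <- x[!is.na(x)]
            if (length(x)) mean(x) else NA_real_
        }, numeric(1))
        out[chromBinIndices(dst, chrom)] <- mean_na
    }
    BinnedTrack(dst, out)
}

#' Rebin a FractionMatrix onto a coarser grid
#'
#' Applies [rebin()] column-wise.
#'
#' @param fm a [FractionMatrix-class].
#' @param targetBinSize target bin width in bp.
#' @return a [FractionMatrix-class] on the coarser grid.
#' @export
rebinFractions <- function(fm, targetBinSize) {
    grid <- fractionGrid(fm)
    tracks <- lapply(seq_along(fractionNames(fm)), function(j)
        rebin(BinnedTrack(grid, fractionValues(fm)[, j]), targetBinSize))
    names(tracks) <- fractionNames(fm)
    fractionMatrixFromTracks(tracks)
}

#' Spearman correlation between two tracks
#'
#' Computed per chromosome over shared unmasked bins (average ranks for
#' ties), then summarized genome-wide by a chromosome-length-weighted mean.
#' Chromosomes with fewer than 3 shared bins are reported as `NA` and
#' excluded from the weighted mean.
#'
#' @param trackA,trackB [BinnedTrack-class] objects on the same grid.
#' @return list with `perChromosome` (named numeric) and `genome` (scalar).
#' @export
trackSpearman <- function(trackA, trackB) {
    grid <- trackGrid(trackA)
    stopifnot(identical(chromLengths(grid),
                        chromLengths(trackGrid(trackB))),
              binSize(grid) == binSize(trackGrid(trackB)))
    rho <- setNames(rep(NA_real_, length(chromNames(grid))),
                    chromNames(grid))
    for (chrom in chromNames(grid)) {
        idx <- chromBinIndices(grid, chrom)
        a <- trackValues(trackA)[idx]
        b <- trackValues(trackB)[idx]
        ok <- !is.na(a) & !is.na(b)
        if (sum(ok) >= 3)
            rho[chrom] <- cor(a[ok], b[ok], method = "spearman")
    }
    w <- chromLengths(grid)
    use <- !is.na(rho)
    genome <- if (any(use)) sum(rho[use] * w[use]) / sum(w[use]) else NA_real_
    list(perChromosome = rho, genome = genome)
}

#' Relative enrichment between two fraction tracks
#'
#' Smoothed log2 ratio: \eqn{\log_2((a+p)/(b+p))} followed by Gaussian
#' kernel smoothing over the stated bandwidth (kernel sd = bandwidth,
#' truncated at 3 sd, renormalized over unmasked neighbours). Masked where
#' either input is masked.
#'
#' @param trackA,trackB library-size-normalized (RPKM)
#'   [BinnedTrack-class] objects on the same grid.
#' @param pseudocount positive pseudocount in RPKM units (default 0.5).
#' @param bandwidth smoothing bandwidth in bp (default 500); 0 disables
#'   smoothing.
#' @return a [BinnedTrack-class] of log2 enrichment values.
#' @export
relativeEnrichment <- function(trackA, trackB, pseudocount = 0.5,
                               bandwidth = 500) {
    if (pseudocount <= 0) stop("pseudocount must be positive")
    grid <- trackGrid(trackA)
    stopifnot(identical(chromLengths(grid),
                        chromLengths(trackGrid(trackB))),
              binSize(grid) == binSize(trackGrid(trackB)))
    a <- trackValues(trackA)
    b <- trackValues(trackB)
    raw <- log2((a + pseudocount) / (b + pseudocount))
    mask <- trackMask(trackA) | trackMask(trackB)
    raw[mask] <- NA_real_
    if (bandwidth > 0) {
        sdBins <- bandwidth / binSize(grid)
        half <- max(1L, ceiling(3 * sdBins))
        kern <- exp(-((-half:half)^2) / (2 * sdBins^2))
        out <- raw
        for (chrom in chromNames(grid)) {
            idx <- chromBinIndices(grid, chrom)
            out[idx] <- .kernelSmooth(raw[idx], kern, half)
        }
        raw <- out
        raw[mask] <- NA_real_
    }
    BinnedTrack(grid, raw, mask = mask)
}

# NA-aware discrete kernel smoothing of one chromosome's values
.kernelSmooth <- function(v, kern, half) {
    n <- length(v)
    out <- rep(NA_real_, n)
    vv <- ifelse(is.na(v), 0, v)
    wv <- as.numeric(!is.na(v))
    num <- rep(0, n); den <- rep(0, n)
    for (o in -half:half) {
        kw <- kern[o + half + 1L]
        src <- seq_len(n) + o
        ok <- src >= 1L & src <= n
        num[ok] <- num[ok] + kw * vv[src[ok]]
        den[ok] <- den[ok] + kw * wv[src[ok]]
    }
    ifelse(den > 0, num / pmax(den, .Machine$double.xmin), NA_real_)
}

#' Paired Cohen's d
#'
#' \eqn{d = mean(x - y) / sd(x - y)} with the sample (n-1) standard
#' deviation. Zero variance of the differences gives `d = 0` when the mean
#' difference is zero, `+/-Inf` with `degenerate = TRUE` otherwise.
#'
#' @param x,y paired numeric vectors (length >= 2).
#' @return list with `d` and logical `degenerate`.
#' @export
cohensDPaired <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 2)
    diff <- x - y
    s <- sd(diff)
    m <- mean(diff)
    if (s == 0) {
        if (m == 0) return(list(d = 0, degenerate = FALSE))
        return(list(d = sign(m) * Inf, degenerate = TRUE))
    }
    list(d = m / s, degenerate = FALSE)
}

#' TSS enrichment effect size across replicates
#'
#' For each replicate track, averages the signal over a 500 bp window
#' centred on each TSS (TSS +/- 250 bp) and over a 500 bp window centred
#' 2 kb upstream of the TSS (strand-aware), takes the mean across genes,
#' and computes the paired effect size (Cohen's d) of TSS vs upstream
#' across replicates.
#'
#' @param replicateTracks list of >= 2 [BinnedTrack-class] objects on one
#'   (fine) grid.
#' @param tss `GRanges` of TSS positions (width-1 anchors; strand used to
#'   place the upstream window).
#' @param window window width in bp (default 500).
#' @param upstream distance of the upstream window centre from the TSS in
#'   bp (default 2000).
#' @return list with `d`, `degenerate`, per-replicate `tssMeans` and
#'   `upstreamMeans`, and the window parameters used.
#' @export
tssEffectSize <- function(replicateTracks, tss, window = 500,
                          upstream = 2000) {
    stopifnot(length(replicateTracks) >= 2)
    half <- window / 2
    pos <- GenomicRanges::start(tss)
    str <- as.character(GenomicRanges::strand(tss))
    str[str == "*"] <- "+"
    upCentre <- ifelse(str == "+", pos - upstream, pos + upstream)
    chrom <- as.character(GenomeInfoDb::seqnames(tss))
    tssWin <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(pmax(1, pos - half), pos + half - 1))
    upWin <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(pmax(1, upCentre - half), upCentre + half - 1))
    meanOver <- function(track, win) {
        bins <- gridBins(trackGrid(track))
        ov <- GenomicRanges::findOverlaps(win, bins)
        w <- GenomicRanges::width(IRanges::pintersect(
            GenomicRanges::ranges(win)[S4Vectors::queryHits(ov)],
            GenomicRanges::ranges(bins)[S4Vectors::subjectHits(ov)]))
        v <- trackValues(track)[S4Vectors::subjectHits(ov)]
        ok <- !is.na(v)
        per <- rowsum(cbind(w[ok] * v[ok], w[ok]),
                      S4Vectors::queryHits(ov)[ok])
        mean(per[, 1] / per[, 2])
    }
    x <- vapply(replicateTracks, meanOver, numeric(1), win = tssWin)
    y <- vapply(replicateTracks, meanOver, numeric(1), win = upWin)
    res <- cohensDPaired(x, y)
    list(d = res$d, degenerate = res$degenerate,
         tssMeans = x, upstreamMeans = y,
         window = window, upstream = upstream)
}

#' Per-bin gene density track
#'
#' Gene density of a bin = gene-covered bp overlapping the bin / bin length
#' (genes are collapsed with `reduce` first so overlapping annotations do
#' not double-count).
#'
#' @param genes `GRanges` of gene bodies.
#' @param grid a [BinGrid-class].
#' @return a [BinnedTrack-class] of densities in [0, 1] (no masking).
#' @export
geneDensityTrack <- function(genes, grid) {
    bins <- gridBins(grid)
    genes <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
    dens <- rep(0, binCount(grid))
    if (length(genes)) {
        ov <- GenomicRanges::findOverlaps(genes, bins)
        w <- GenomicRanges::width(IRanges::pintersect(
            GenomicRanges::ranges(genes)[S4Vectors::queryHits(ov)],
            GenomicRanges::ranges(bins)[S4Vectors::subjectHits(ov)]))
        agg <- rowsum(w, S4Vectors::subjectHits(ov))
        dens[as.integer(rownames(agg))] <- agg[, 1]
    }
    BinnedTrack(grid, dens / GenomicRanges::width(bins),
                mask = rep(FALSE, binCount(grid)))
}
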