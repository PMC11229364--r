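#' Read a coverage track onto a bin grid
#'
#' Reads a bedGraph (or 4-column binned TSV) and projects it onto `grid` by
#' length-weighted averaging: each bin's value is the average of the record
#' values covering it, weighted by covered bp; bins with no covering record
#' are masked. Input records must not overlap each other.
#'
#' @param path file path (gzip transparent for bedGraph/TSV).
#' @param grid target [BinGrid-class].
#' @param format `"bedgraph"`, `"tsv"` (tab-separated chrom/start/end/value,
#'   no header), or `"auto"` (by file extension).
#' @return a [BinnedTrack-class].
#' @export
readTrack <- function(path, grid, format = c("auto", "bedgraph", "tsv")) {
    format <- match.arg(format)
    if (format == "auto") {
        base <- sub("\\.gz$", "", path)
        format <- if (grepl("\\.(bedgraph|bdg)$", base, ignore.case = TRUE))
            "bedgraph" else "tsv"
    }
    if (format == "bedgraph") {
        gr <- rtracklayer::import(path, format = "bedGraph")
        value <- gr$score
    } else {
        df <- read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "value"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
        gr <- GenomicRanges::GRanges(df$chrom,
                                     IRanges::IRanges(df$start + 1, df$end))
        value <- df$value
    }
    binFromIntervals(gr, value, grid)
}

# length-weighted average of interval values into grid bins
binFromIntervals <- function(gr, value, grid) {
    bad <- setdiff(unique(as.character(GenomeInfoDb::seqnames(gr))),
                   chromNames(grid))
    if (length(bad))
        stop("unknown chromosome(s) in track: ", paste(bad, collapse = ", "))
    red <- GenomicRanges::reduce(gr)
    if (sum(GenomicRanges::width(gr)) > sum(GenomicRanges::width(red)))
        stop("overlapping records in coverage input")
    bins <- gridBins(grid)
    ov <- GenomicRanges::findOverlaps(gr, bins)
    w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(gr)[S4Vectors::queryHits(ov)],
        GenomicRanges::ranges(bins)[S4Vectors::subjectHits(ov)]))
    n <- binCount(grid)
    num <- rep(0, n); den <- rep(0, n)
    idx <- S4Vectors::subjectHits(ov)
    num[seq_len(n)] <- 0
    agg <- rowsum(cbind(w * value[S4Vectors::queryHits(ov)], w), idx)
    rows <- as.integer(rownames(agg))
    num[rows] <- agg[, 1]
    den[rows] <- agg[, 2]
    vals <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
    BinnedTrack(grid, vals, mask = den == 0)
}

#' Write a BinnedTrack as bedGraph
#'
#' Unmasked bins only, 0-based half-open coordinates, values printed with 10
#' significant digits (round-trips to at least 6).
#'
#' @param track a [BinnedTrack-class].
#' @param path output path.
#' @export
writeTrack <- function(track, path) {
    grid <- trackGrid(track)
    bins <- gridBins(grid)
    keep <- !trackMask(track)
    lines <- sprintf("%s\t%d\t%d\t%.10g",
                     as.character(GenomeInfoDb::seqnames(bins))[keep],
                     GenomicRanges::start(bins)[keep] - 1L,
                     GenomicRanges::end(bins)[keep],
                     trackValues(track)[keep])
    writeLines(lines, path)
    invisible(path)
}

#' Read a BED interval file
#'
#' Thin wrapper over `rtracklayer::import` returning a sorted `GRanges`
#' (gzip transparent; BED3/BED6 accepted).
#'
#' @param path BED file path.
#' @return sorted `GRanges`.
#' @export
readIntervals <- function(path) {
    gr <- rtracklayer::import(path, format = "BED")
    GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Read raw Hi-C contacts from a triplet TSV
#'
#' Expects tab-separated columns chrom, bin_i, bin_j, count with 0-based
#' chromosome-local bin indices on the stated grid. Only intra-chromosomal
#' rows are accepted; the matrix is symmetrized on ingest.
#'
#' @param path triplet TSV path (no header).
#' @param grid the [BinGrid-class] the bin indices refer to.
#' @return a [ContactMatrix-class].
#' @export
readContacts <- function(path, grid) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "bin_i", "bin_j", "count"))
    bad <- setdiff(unique(df$chrom), chromNames(grid))
    if (length(bad))
        stop("unknown chromosome(s) in contacts: ",
             paste(bad, collapse = ", "))
    nb <- binCountPerChrom(grid)
    counts <- list()
    for (chrom in unique(df$chrom)) {
        sub <- df[df$chrom == chrom, ]
        n <- nb[[chrom]]
        if (any(sub$bin_i < 0 | sub$bin_i >= n | sub$bin_j < 0 |
                sub$bin_j >= n))
            stop("bin index out of range for ", chrom)
        m <- matrix(0, n, n)
        m[cbind(sub$bin_i + 1L, sub$bin_j + 1L)] <- sub$count
        counts[[chrom]] <- m
    }
    ContactMatrix(grid, counts)
}

#' Write a ContactMatrix as a triplet TSV
#'
#' Upper triangle (including diagonal) of the raw counts, 0-based
#' chromosome-local bin indices, zero entries omitted.
#'
#' @param cm a [ContactMatrix-class].
#' @param path output path.
#' @export
writeContacts <- function(cm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (chrom in contactChroms(cm)) {
        m <- contactCounts(cm, chrom)
        idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
        if (nrow(idx))
            writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom,
                               idx[, 1] - 1L, idx[, 2] - 1L,
                               m[idx]), con)
    }
    invisible(path)
}

#' Write compartment calls as BED
#'
#' One record per called bin: name = A/B label, score column = scaled
#' eigenvector value.
#'
#' @param call a [CompartmentCall-class].
#' @param path output path.
#' @export
writeCompartmentBED <- function(call, path) {
    grid <- call@grid
    bins <- gridBins(grid)
    keep <- !is.na(call@label)
    lines <- sprintf("%s\t%d\t%d\t%s\t%.6f",
                     as.character(GenomeInfoDb::seqnames(bins))[keep],
                     GenomicRanges::start(bins)[keep] - 1L,
                     GenomicRanges::end(bins)[keep],
                     as.character(call@label)[keep],
                     call@eigen[keep])
    writeLines(lines, path)
    invisible(path)
}

#' Read compartment calls from BED
#'
#' Inverse of [writeCompartmentBED()].
#'
#' @param path BED path.
#' @param grid the [BinGrid-class] of the calls.
#' @return a [CompartmentCall-class].
#' @export
readCompartmentBED <- function(path, grid) {
    df <- read.table(path, sep = "\t", header = FALSE,
                     col.names = c("chrom", "start", "end", "name", "score"))
    bad <- setdiff(unique(df$chrom), chromNames(grid))
    if (length(bad))
        stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
    n <- binCount(grid)
    eig <- rep(NA_real_, n)
    lab <- rep(NA_character_, n)
    offset <- c(0, cumsum(binCountPerChrom(grid)))
    names(offset) <- c(chromNames(grid), "_end")
    bin <- offset[df$chrom] + df$start %/% binSize(grid) + 1L
    eig[bin] <- df$score
    lab[bin] <- df$name
    new("CompartmentCall", grid = grid, eigen = eig,
        label = factor(lab, levels = c("A", "B")))
}

#' Write sub-compartment calls as BED
#'
#' name = sub-compartment label, score column = leaf rank (1..8).
#'
#' @param call a [SubCompartmentCall-class].
#' @param path output path.
#' @export
writeSubCompartmentBED <- function(call, path) {
    bins <- gridBins(call@grid)
    keep <- !is.na(call@label)
    lines <- sprintf("%s\t%d\t%d\t%s\t%d",
                     as.character(GenomeInfoDb::seqnames(bins))[keep],
                     GenomicRanges::start(bins)[keep] - 1L,
                     GenomicRanges::end(bins)[keep],
                     as.character(call@label)[keep],
                     call@rank[keep])
    writeLines(lines, path)
    invisible(path)
}
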