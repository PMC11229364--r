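#' Construct a BinGrid
#'
#' @param seqlengths named numeric vector of chromosome lengths in bp; the
#'   names give the chromosome order.
#' @param binSize bin width in bp.
#' @return a [BinGrid-class] object.
#' @examples
#' grid <- BinGrid(c(chrS = 1e6, chrT = 5e5), binSize = 50000)
#' binCount(grid)
#' @export
BinGrid <- function(seqlengths, binSize) {
    if (is.null(names(seqlengths)) || any(names(seqlengths) == ""))
        stop("seqlengths must be a named vector of chromosome lengths")
    new("BinGrid",
        seqnames = names(seqlengths),
        seqlengths = as.numeric(unname(seqlengths)),
        binSize = as.numeric(binSize))
}

#' @describeIn BinGrid number of bins per chromosome (named vector).
#' @param grid a [BinGrid-class].
#' @export
binCountPerChrom <- function(grid) {
    setNames(as.integer(ceiling(grid@seqlengths / grid@binSize)),
             grid@seqnames)
}

#' @describeIn BinGrid total number of bins across all chromosomes.
#' @export
binCount <- function(grid) sum(binCountPerChrom(grid))

#' @describeIn BinGrid bin width in bp.
#' @export
binSize <- function(grid) grid@binSize

#' @describeIn BinGrid ordered chromosome names.
#' @export
chromNames <- function(grid) grid@seqnames

#' @describeIn BinGrid named vector of chromosome lengths.
#' @export
chromLengths <- function(grid) setNames(grid@seqlengths, grid@seqnames)

#' Bins of a grid as a GRanges
#'
#' Materializes all bins of the grid as a `GRanges`, in global bin-index
#' order (0-based half-open internally; GRanges uses 1-based closed).
#'
#' @param grid a [BinGrid-class].
#' @return `GRanges` with one range per bin.
#' @export
gridBins <- function(grid) {
    sl <- chromLengths(grid)
    tiles <- GenomicRanges::tileGenome(sl, tilewidth = grid@binSize,
                                       cut.last.tile.in.chrom = TRUE)
    tiles
}

#' Global bin indices of a chromosome
#'
#' @param grid a [BinGrid-class].
#' @param chrom chromosome name.
#' @return integer vector of global (1-based) bin indices.
#' @export
chromBinIndices <- function(grid, chrom) {
    nb <- binCountPerChrom(grid)
    i <- match(chrom, grid@seqnames)
    if (is.na(i)) stop("unknown chromosome '", chrom, "'")
    offset <- if (i == 1L) 0L else sum(nb[seq_len(i - 1L)])
    offset + seq_len(nb[[i]])
}

# width in bp of each bin of a chromosome (last bin may be short)
.binWidths <- function(grid, chrom) {
    len <- chromLengths(grid)[[chrom]]
    nb <- binCountPerChrom(grid)[[chrom]]
    w <- rep(grid@binSize, nb)
    w[nb] <- len - (nb - 1L) * grid@binSize
    w
}

setMethod("show", "BinGrid", function(object) {
    cat("BinGrid:", length(object@seqnames), "chromosome(s),",
        "bin size", object@binSize, "bp,",
        binCount(object), "bins\n")
})
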