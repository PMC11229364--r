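#' Construct a BinnedTrack
#'
#' @param grid a [BinGrid-class].
#' @param values numeric vector, one value per bin; NA allowed where masked.
#' @param mask logical vector of excluded bins; defaults to `is.na(values)`.
#' @return a [BinnedTrack-class].
#' @export
BinnedTrack <- function(grid, values, mask = is.na(values)) {
    values[mask] <- NA_real_
    new("BinnedTrack", grid = grid, values = as.numeric(values),
        mask = as.logical(mask))
}

#' @describeIn BinnedTrack per-bin values (NA where masked).
#' @param x a [BinnedTrack-class].
#' @export
trackValues <- function(x) x@values

#' @describeIn BinnedTrack logical mask of excluded bins.
#' @export
trackMask <- function(x) x@mask

#' @describeIn BinnedTrack the underlying [BinGrid-class].
#' @export
trackGrid <- function(x) x@grid

setMethod("show", "BinnedTrack", function(object) {
    n <- binCount(object@grid)
    cat("BinnedTrack:", n, "bins of", object@grid@binSize, "bp;",
        sum(object@mask), "masked\n")
    v <- object@values[!object@mask]
    if (length(v))
        cat("  values: median", signif(stats::median(v), 4),
            "range [", signif(min(v), 4), ",", signif(max(v), 4), "]\n")
})

#' Construct a FractionMatrix
#'
#' @param grid a [BinGrid-class].
#' @param values numeric matrix, bins x fractions.
#' @param fractions fraction names; defaults to `colnames(values)`.
#' @return a [FractionMatrix-class].
#' @export
FractionMatrix <- function(grid, values, fractions = colnames(values)) {
    values <- as.matrix(values)
    if (is.null(fractions))
        fractions <- paste0("F", seq_len(ncol(values)))
    colnames(values) <- fractions
    new("FractionMatrix", grid = grid, values = values,
        fractions = as.character(fractions))
}

#' Assemble a FractionMatrix from per-fraction tracks
#'
#' @param tracks named list of [BinnedTrack-class] objects on one grid; the
#'   names are the fraction names in protocol order.
#' @return a [FractionMatrix-class]; bins masked in any fraction are NA in
#'   that column.
#' @export
fractionMatrixFromTracks <- function(tracks) {
    stopifnot(length(tracks) >= 2L, !is.null(names(tracks)))
    grid <- trackGrid(tracks[[1L]])
    for (t in tracks)
        if (!identical(chromLengths(trackGrid(t)), chromLengths(grid)) ||
            binSize(trackGrid(t)) != binSize(grid))
            stop("all fraction tracks must share one grid")
    values <- vapply(tracks, trackValues, numeric(binCount(grid)))
    FractionMatrix(grid, values, names(tracks))
}

#' @describeIn FractionMatrix the bins x fractions value matrix.
#' @param x a [FractionMatrix-class].
#' @export
fractionValues <- function(x) x@values

#' @describeIn FractionMatrix fraction names in column order.
#' @export
fractionNames <- function(x) x@fractions

#' @describeIn FractionMatrix the underlying [BinGrid-class].
#' @export
fractionGrid <- function(x) x@grid

setMethod("show", "FractionMatrix", function(object) {
    cat("FractionMatrix:", nrow(object@values), "bins x",
        ncol(object@values), "fractions (",
        paste(object@fractions, collapse = ", "), ")\n")
})

#' Construct a ContactMatrix
#'
#' Contacts are symmetrized on ingest (`pmax(M, t(M))`, so a one-triangle
#' input is reflected and a symmetric input is unchanged); only
#' intra-chromosomal matrices are stored.
#'
#' @param grid a [BinGrid-class].
#' @param counts named list of square count matrices, one per chromosome.
#'   Matrices may be given as upper/lower triangles; they are symmetrized.
#' @return a [ContactMatrix-class].
#' @export
ContactMatrix <- function(grid, counts) {
    counts <- lapply(counts, function(m) {
        m <- as.matrix(m)
        pmax(m, t(m))
    })
    new("ContactMatrix", grid = grid, counts = counts, weights = list())
}

#' @describeIn ContactMatrix raw count matrix of one chromosome.
#' @param x a [ContactMatrix-class].
#' @param chrom chromosome name.
#' @export
contactCounts <- function(x, chrom) {
    m <- x@counts[[chrom]]
    if (is.null(m)) stop("no contacts stored for '", chrom, "'")
    m
}

#' @describeIn ContactMatrix balancing weights of one chromosome (NULL
#'   before [iceBalance()]).
#' @export
contactWeights <- function(x, chrom) x@weights[[chrom]]

#' @describeIn ContactMatrix chromosomes with stored contacts.
#' @export
contactChroms <- function(x) names(x@counts)

setMethod("show", "ContactMatrix", function(object) {
    cat("ContactMatrix:", length(object@counts), "chromosome(s) at",
        object@grid@binSize, "bp bins;",
        if (length(object@weights)) "balanced" else "unbalanced", "\n")
})
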