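#' @import methods
#' @importFrom stats cor sd var dist lowess prcomp quantile rbinom rgeom
#'   rnbinom rpois runif setNames complete.cases
#' @importFrom utils head tail read.table write.table
NULL

.SUBCOMPARTMENT_LEVELS <- c("B.2.2", "B.2.1", "B.1.2", "B.1.1",
                            "A.2.2", "A.2.1", "A.1.2", "A.1.1")

#' BinGrid: a fixed-width binning of a genome
#'
#' A `BinGrid` tiles an ordered set of chromosomes with 0-based half-open
#' bins of a fixed width; the last bin of each chromosome is cut at the
#' chromosome end. It defines the global bin index used by every binned
#' container in the package (concatenation of per-chromosome indices in
#' chromosome order).
#'
#' @slot seqnames ordered character vector of chromosome names.
#' @slot seqlengths numeric vector of chromosome lengths (bp), parallel to
#'   `seqnames`.
#' @slot binSize bin width in bp (> 0).
#' @export
setClass("BinGrid", representation(
    seqnames = "character",
    seqlengths = "numeric",
    binSize = "numeric"
))

setValidity("BinGrid", function(object) {
    msg <- NULL
    if (length(object@binSize) != 1L || !is.finite(object@binSize) ||
        object@binSize <= 0 || object@binSize != round(object@binSize))
        msg <- c(msg, "binSize must be a single positive integer")
    if (length(object@seqnames) != length(object@seqlengths))
        msg <- c(msg, "seqnames and seqlengths must have equal length")
    if (anyDuplicated(object@seqnames))
        msg <- c(msg, "duplicated chromosome names")
    if (any(!is.finite(object@seqlengths)) || any(object@seqlengths <= 0))
        msg <- c(msg, "chromosome lengths must be positive")
    if (is.null(msg)) TRUE else msg
})

#' BinnedTrack: one real value per genome bin
#'
#' Holds a per-bin signal (RPKM or enrichment units) on a [BinGrid], plus a
#' mask marking bins excluded by a blacklist or lacking data. Masked bins
#' carry `NA` in `values`, never a silent zero.
#'
#' @slot grid the [BinGrid].
#' @slot values numeric vector, one value per bin (NA where masked).
#' @slot mask logical vector, `TRUE` = excluded.
#' @export
setClass("BinnedTrack", representation(
    grid = "BinGrid",
    values = "numeric",
    mask = "logical"
))

setValidity("BinnedTrack", function(object) {
    n <- binCount(object@grid)
    msg <- NULL
    if (length(object@values) != n)
        msg <- c(msg, "values length must equal grid bin count")
    if (length(object@mask) != n)
        msg <- c(msg, "mask length must equal grid bin count")
    if (any(!is.na(object@values) & object@mask))
        msg <- c(msg, "masked bins must carry NA values")
    if (is.null(msg)) TRUE else msg
})

#' FractionMatrix: per-bin coverage across chromatin fractions
#'
#' An `n_bins x m` matrix of RPKM coverage, one column per sequenced
#' chromatin fraction (m = 3 for the three-fraction protocol S2/S3/S4,
#' m = 4 for the four-fraction protocol S2S/S2L/S3/S4; any m >= 2 is
#' accepted). Row order is the global bin index of the grid.
#'
#' @slot grid the [BinGrid].
#' @slot values numeric matrix, bins x fractions, NA where masked.
#' @slot fractions character vector of fraction names (column order).
#' @export
setClass("FractionMatrix", representation(
    grid = "BinGrid",
    values = "matrix",
    fractions = "character"
))

setValidity("FractionMatrix", function(object) {
    msg <- NULL
    if (nrow(object@values) != binCount(object@grid))
        msg <- c(msg, "row count must equal grid bin count")
    if (ncol(object@values) != length(object@fractions))
        msg <- c(msg, "column count must equal number of fraction names")
    if (length(object@fractions) < 2L)
        msg <- c(msg, "at least 2 fractions are required")
    v <- object@values
    if (any(v[!is.na(v)] < 0))
        msg <- c(msg, "coverage values must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' ContactMatrix: per-chromosome raw bin-pair contact counts
#'
#' Symmetric intra-chromosomal contact counts on a [BinGrid], stored as one
#' dense matrix per chromosome, with optional per-bin ICE balancing weights.
#' Symmetry is enforced on construction; only cis contacts are represented.
#'
#' @slot grid the [BinGrid].
#' @slot counts named list of dense symmetric matrices, one per chromosome.
#' @slot weights named list of per-bin balancing weight vectors (may be
#'   empty before [iceBalance()]).
#' @export
setClass("ContactMatrix", representation(
    grid = "BinGrid",
    counts = "list",
    weights = "list"
))

setValidity("ContactMatrix", function(object) {
    msg <- NULL
    nb <- binCountPerChrom(object@grid)
    for (chrom in names(object@counts)) {
        m <- object@counts[[chrom]]
        if (!chrom %in% object@grid@seqnames) {
            msg <- c(msg, paste0("unknown chromosome '", chrom, "'"))
            next
        }
        if (!is.matrix(m) || nrow(m) != nb[[chrom]] || ncol(m) != nb[[chrom]])
            msg <- c(msg, paste0("counts for ", chrom, " have wrong dimension"))
        else if (max(abs(m - t(m))) > 1e-8)
            msg <- c(msg, paste0("counts for ", chrom, " are not symmetric"))
        else if (any(m[!is.na(m)] < 0))
            msg <- c(msg, paste0("negative counts on ", chrom))
    }
    if (is.null(msg)) TRUE else msg
})

#' CompartmentCall: per-bin A/B compartment assignment
#'
#' Per-bin first-eigenvector value (scaled per chromosome so that
#' max |E1| = 1 over called bins) and the derived label: A where E1 > 0,
#' B where E1 < 0, NA where the bin was removed or E1 is exactly zero.
#'
#' @slot grid the [BinGrid].
#' @slot eigen numeric per-bin scaled eigenvector (NA for removed bins).
#' @slot label factor with levels A, B (NA for removed bins).
#' @export
setClass("CompartmentCall", representation(
    grid = "BinGrid",
    eigen = "numeric",
    label = "factor"
))

setValidity("CompartmentCall", function(object) {
    n <- binCount(object@grid)
    msg <- NULL
    if (length(object@eigen) != n || length(object@label) != n)
        msg <- c(msg, "eigen and label must have one entry per bin")
    if (!identical(levels(object@label), c("A", "B")))
        msg <- c(msg, "label levels must be A, B")
    ok <- !is.na(object@eigen)
    lab <- as.character(object@label)
    if (any(ok & object@eigen > 0 & (is.na(lab) | lab != "A")) ||
        any(ok & object@eigen < 0 & (is.na(lab) | lab != "B")))
        msg <- c(msg, "labels inconsistent with eigenvector sign")
    if (any(abs(object@eigen[ok]) > 1 + 1e-9))
        msg <- c(msg, "scaled eigenvector must lie in [-1, 1]")
    if (is.null(msg)) TRUE else msg
})

#' SubCompartmentCall: per-bin eight-level sub-compartment assignment
#'
#' Per-bin label among the eight ordered sub-compartments, from the most
#' closed (B.2.2, rank 1) to the most open (A.1.1, rank 8), plus the domain
#' hierarchies that produced them (one per chromosome).
#'
#' @slot grid the [BinGrid].
#' @slot label factor over the 8 canonical levels (NA for removed bins).
#' @slot rank integer per-bin rank 1..8 (NA for removed bins).
#' @slot hierarchy named list of per-chromosome domain hierarchies.
#' @export
setClass("SubCompartmentCall", representation(
    grid = "BinGrid",
    label = "factor",
    rank = "integer",
    hierarchy = "list"
))

setValidity("SubCompartmentCall", function(object) {
    n <- binCount(object@grid)
    msg <- NULL
    if (length(object@label) != n || length(object@rank) != n)
        msg <- c(msg, "label and rank must have one entry per bin")
    if (!identical(levels(object@label), .SUBCOMPARTMENT_LEVELS))
        msg <- c(msg, "label levels must be the 8 canonical sub-compartments")
    ok <- !is.na(object@rank)
    if (any(object@rank[ok] < 1L | object@rank[ok] > 8L))
        msg <- c(msg, "rank must lie in 1..8")
    if (any(ok != !is.na(object@label)))
        msg <- c(msg, "rank and label NA patterns must agree")
    if (any(ok) &&
        !all(as.integer(object@label[ok]) == object@rank[ok]))
        msg <- c(msg, "rank must equal the canonical index of the label")
    if (is.null(msg)) TRUE else msg
})
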