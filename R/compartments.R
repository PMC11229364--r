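#' Drop uninformative bins before correlation
#'
#' For a fraction matrix (bins x fractions), removes bins that are masked
#' (any NA), have zero coverage across all fractions, or have zero variance
#' across fractions (Pearson correlation is undefined on constant vectors).
#' For a contact matrix, removes bins whose row sum of contacts is zero.
#'
#' @param x numeric matrix: bins x fractions, or a square symmetric contact
#'   matrix.
#' @param mode `"fractions"` or `"contacts"`.
#' @return list with `values` (the reduced matrix) and `keep` (integer
#'   indices of retained rows in the input, the map back to coordinates).
#' @export
dropNullBins <- function(x, mode = c("fractions", "contacts")) {
    mode <- match.arg(mode)
    if (mode == "fractions") {
        ok <- stats::complete.cases(x)
        v <- rep(FALSE, nrow(x))
        v[ok] <- apply(x[ok, , drop = FALSE], 1, function(r)
            sum(r) > 0 && var(r) > 0)
        keep <- which(v)
    } else {
        rs <- rowSums(x, na.rm = TRUE)
        keep <- which(rs > 0)
    }
    list(values = x[keep, , drop = FALSE][, if (mode == "contacts") keep
                                          else seq_len(ncol(x)),
                                          drop = FALSE],
         keep = keep)
}

#' Bin-bin Pearson correlation of fraction profiles
#'
#' Entry (i, j) is the Pearson correlation between the m-dimensional
#' coverage vectors of bins i and j across fractions. With m = 2 every
#' off-diagonal entry is +/-1 (allowed, warned).
#'
#' @param x reduced bins x fractions matrix (null bins dropped).
#' @return symmetric n x n correlation matrix with unit diagonal.
#' @export
sammyCorrelation <- function(x) {
    if (ncol(x) == 2)
        warning("m = 2 fractions: correlations are degenerate (+/-1)")
    C <- cor(t(x))
    diag(C) <- 1
    C
}

#' ICE matrix balancing
#'
#' Iterative correction: finds multiplicative per-bin weights b such that
#' the balanced matrix \eqn{B_{ij} = b_i M_{ij} b_j} has equal row sums.
#' Iterates until the maximum relative row-sum deviation drops below `tol`
#' or `maxIter` is reached (then warns and returns best-effort weights).
#'
#' @param m square symmetric non-negative contact matrix with no all-zero
#'   rows (apply [dropNullBins()] first).
#' @param maxIter maximum iterations (default 200).
#' @param tol convergence tolerance on the relative row-sum deviation
#'   (default 1e-12).
#' @return list with `balanced` (matrix), `weights` (per-bin b), and
#'   `converged`/`iterations` diagnostics.
#' @export
iceBalance <- function(m, maxIter = 200, tol = 1e-12) {
    n <- nrow(m)
    if (any(rowSums(m) == 0))
        stop("all-zero row: drop null bins before balancing")
    b <- rep(1, n)
    converged <- FALSE
    it <- 0L
    for (it in seq_len(maxIter)) {
        bal <- m * (b %o% b)
        s <- rowSums(bal)
        dev <- max(abs(s / mean(s) - 1))
        if (dev < tol) { converged <- TRUE; break }
        b <- b / sqrt(s / mean(s))
    }
    if (!converged)
        warning(sprintf(
            "ICE did not reach tol %g in %d iterations (deviation %g)",
            tol, maxIter, dev))
    bal <- m * (b %o% b)
    list(balanced = bal, weights = b, converged = converged,
         iterations = it)
}

#' Balance the stored contacts of a ContactMatrix
#'
#' Runs [iceBalance()] per chromosome on the bins kept by
#' [dropNullBins()] and stores the per-bin weights (NA for dropped bins).
#'
#' @param cm a [ContactMatrix-class].
#' @param maxIter,tol passed to [iceBalance()].
#' @return the [ContactMatrix-class] with its `weights` slot filled.
#' @export
balanceContacts <- function(cm, maxIter = 200, tol = 1e-12) {
    weights <- list()
    for (chrom in contactChroms(cm)) {
        m <- contactCounts(cm, chrom)
        red <- dropNullBins(m, mode = "contacts")
        w <- rep(NA_real_, nrow(m))
        if (length(red$keep) >= 2)
            w[red$keep] <- iceBalance(red$values, maxIter, tol)$weights
        weights[[chrom]] <- w
    }
    cm@weights <- weights
    cm
}

#' Observed/expected normalization of a balanced contact matrix
#'
#' Divides each entry by the mean balanced contact at the same bin
#' distance (the expected value; plain mean over the unmasked entries of
#' the corresponding diagonal, computed within the chromosome). Distances
#' whose mean is zero (or that have no unmasked entries) yield masked (NA)
#' entries.
#'
#' @param m balanced square symmetric matrix.
#' @return O/E matrix of the same dimension.
#' @export
oeNormalize <- function(m) {
    n <- nrow(m)
    d <- abs(row(m) - col(m))
    expByDist <- vapply(0:(n - 1), function(k) {
        v <- m[d == k]
        v <- v[!is.na(v)]
        if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    e <- expByDist[d + 1L]
    out <- m / e
    out[!is.finite(out)] <- NA_real_
    out
}

#' Bin-bin Pearson correlation of O/E contact profiles
#'
#' Entry (i, j) is the Pearson correlation between rows i and j of the O/E
#' matrix, pairwise-complete over unmasked entries; entries backed by fewer
#' than 3 complete pairs are masked.
#'
#' @param oe O/E matrix (null bins dropped).
#' @param minPairs minimum complete pairs per entry (default 3).
#' @return symmetric correlation matrix with unit diagonal; NA where
#'   undefined.
#' @export
hicCorrelation <- function(oe, minPairs = 3) {
    C <- suppressWarnings(cor(t(oe), use = "pairwise.complete.obs"))
    obs <- !is.na(oe)
    npair <- tcrossprod(obs * 1)
    C[npair < minPairs] <- NA_real_
    diag(C) <- 1
    C
}

#' First eigenvector of a bin correlation matrix
#'
#' Reproduces an uncentered, scaled principal component analysis: each
#' column of the correlation matrix is divided by its root-mean-square
#' about zero (no centering), and the returned vector is the unit-norm
#' dominant eigenvector of the cross-product of the scaled matrix (the
#' first principal axis). Masked entries are imputed to 0 -- the
#' no-information value for a correlation -- with a warning reporting the
#' count. If the top two eigenvalues tie within `tieTol` (relative), the
#' eigenvector with the larger absolute projection onto the all-ones
#' vector is chosen (deterministic) and a warning is issued.
#'
#' @param C symmetric correlation matrix (null bins dropped).
#' @param tieTol relative tolerance declaring a degenerate dominant
#'   eigenvalue (default 1e-9).
#' @return unit-norm numeric vector of length `nrow(C)`.
#' @export
firstEigenvector <- function(C, tieTol = 1e-9) {
    nimp <- sum(is.na(C))
    if (nimp > 0) {
        warning(nimp, " masked correlation entries imputed to 0")
        C[is.na(C)] <- 0
    }
    s <- sqrt(colMeans(C^2))
    if (any(s == 0))
        stop("all-zero column in correlation matrix")
    Cs <- sweep(C, 2, s, "/")
    M <- crossprod(Cs)
    ee <- eigen(M, symmetric = TRUE)
    v <- ee$vectors[, 1]
    if (nrow(C) >= 2) {
        gap <- ee$values[1] - ee$values[2]
        if (gap <= tieTol * max(1, abs(ee$values[1]))) {
            warning("degenerate dominant eigenvalue; using ones-projection",
                    " tie-break")
            ones <- rep(1, nrow(C))
            tied <- which(ee$values[1] - ee$values <=
                          tieTol * max(1, abs(ee$values[1])))
            proj <- abs(as.numeric(crossprod(ee$vectors[, tied,
                                                        drop = FALSE],
                                             ones)))
            v <- ee$vectors[, tied[which.max(proj)]]
        }
    }
    v
}

#' Orient an eigenvector by gene density
#'
#' Gene density per bin is gene-covered bp / bin length. If the mean
#' density over negative-value bins exceeds the mean over positive-value
#' bins, the eigenvector is negated, so the gene-dense group carries the
#' positive sign (the A compartment). Applied per chromosome; if all
#' entries share one sign, or the two means tie within 1e-12, the vector is
#' returned unchanged with a warning.
#'
#' @param e1 eigenvector over kept bins of one chromosome.
#' @param density gene density of the same bins (from
#'   [geneDensityTrack()]).
#' @return the (possibly negated) eigenvector.
#' @export
orientSign <- function(e1, density) {
    pos <- e1 > 0
    neg <- e1 < 0
    if (!any(pos) || !any(neg)) {
        warning("eigenvector has a single sign; orientation unchanged")
        return(e1)
    }
    mp <- mean(density[pos])
    mn <- mean(density[neg])
    if (abs(mp - mn) <= 1e-12) {
        warning("equal gene density in both groups; orientation unchanged")
        return(e1)
    }
    if (mn > mp) -e1 else e1
}

# run orientation + per-chromosome scaling + labelling for one chromosome
.finishChromosome <- function(e1, density) {
    e1 <- orientSign(e1, density)
    e1 / max(abs(e1))
}

#' Call A/B compartments from a FractionMatrix
#'
#' The SAMMY-seq path: per chromosome, drops null bins, computes the
#' bin-bin Pearson correlation of fraction coverage vectors, extracts the
#' first eigenvector of the correlation matrix (uncentered scaled PCA),
#' orients its sign so the gene-dense group is positive (A), and scales by
#' the per-chromosome absolute maximum. Chromosomes retaining fewer than
#' `minBins` bins are skipped with a warning.
#'
#' @param fm a [FractionMatrix-class] (typically on a 250 kb grid).
#' @param genes `GRanges` of gene bodies used for sign orientation.
#' @param minBins minimum kept bins per chromosome (default 10).
#' @return a [CompartmentCall-class].
#' @export
compartmentsFromFractions <- function(fm, genes, minBins = 10) {
    grid <- fractionGrid(fm)
    dens <- trackValues(geneDensityTrack(genes, grid))
    eig <- rep(NA_real_, binCount(grid))
    for (chrom in chromNames(grid)) {
        idx <- chromBinIndices(grid, chrom)
        red <- dropNullBins(fractionValues(fm)[idx, , drop = FALSE],
                            mode = "fractions")
        if (length(red$keep) < minBins) {
            warning("chromosome ", chrom, " skipped: fewer than ",
                    minBins, " informative bins")
            next
        }
        C <- sammyCorrelation(red$values)
        e1 <- firstEigenvector(C)
        eig[idx[red$keep]] <- .finishChromosome(e1, dens[idx[red$keep]])
    }
    .asCompartmentCall(grid, eig)
}

#' Call A/B compartments from Hi-C contacts
#'
#' The Hi-C comparison path: per chromosome, drops bins with zero contact
#' row sums, ICE-balances the remaining cis matrix, normalizes observed
#' over expected by distance, computes the bin-bin Pearson correlation of
#' O/E rows, and proceeds as in [compartmentsFromFractions()].
#'
#' @param cm a [ContactMatrix-class].
#' @param genes `GRanges` of gene bodies used for sign orientation.
#' @param minBins minimum kept bins per chromosome (default 10).
#' @param maxIter,tol ICE balancing controls.
#' @return a [CompartmentCall-class].
#' @export
compartmentsFromContacts <- function(cm, genes, minBins = 10,
                                     maxIter = 200, tol = 1e-12) {
    grid <- cm@grid
    dens <- trackValues(geneDensityTrack(genes, grid))
    eig <- rep(NA_real_, binCount(grid))
    for (chrom in contactChroms(cm)) {
        idx <- chromBinIndices(grid, chrom)
        red <- dropNullBins(contactCounts(cm, chrom), mode = "contacts")
        if (length(red$keep) < minBins) {
            warning("chromosome ", chrom, " skipped: fewer than ",
                    minBins, " informative bins")
            next
        }
        bal <- iceBalance(red$values, maxIter, tol)$balanced
        oe <- oeNormalize(bal)
        C <- hicCorrelation(oe)
        e1 <- firstEigenvector(C)
        eig[idx[red$keep]] <- .finishChromosome(e1, dens[idx[red$keep]])
    }
    .asCompartmentCall(grid, eig)
}

.asCompartmentCall <- function(grid, eig) {
    lab <- rep(NA_character_, length(eig))
    lab[!is.na(eig) & eig > 0] <- "A"
    lab[!is.na(eig) & eig < 0] <- "B"
    eig[!is.na(eig) & eig == 0] <- NA_real_
    new("CompartmentCall", grid = grid, eigen = eig,
        label = factor(lab, levels = c("A", "B")))
}

#' @describeIn compartmentsFromFractions accessors for compartment calls.
#' @param call a [CompartmentCall-class].
#' @export
compartmentLabels <- function(call) call@label

#' @rdname compartmentsFromFractions
#' @export
compartmentEigen <- function(call) call@eigen

setMethod("show", "CompartmentCall", function(object) {
    tab <- table(object@label, useNA = "always")
    cat("CompartmentCall:", binCount(object@grid), "bins; A =",
        tab[["A"]], "B =", tab[["B"]], "NA =",
        sum(is.na(object@label)), "\n")
})
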