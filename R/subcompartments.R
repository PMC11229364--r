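#' Euclidean distance between bin fraction profiles
#'
#' D(i, j) = sqrt(sum_f (v_if - v_jf)^2) on the coverage values as given
#' (use `log1p = TRUE` in the pipeline wrappers to damp the dynamic range
#' first).
#'
#' @param x reduced bins x fractions matrix (null bins dropped).
#' @return symmetric distance matrix with zero diagonal.
#' @export
euclideanBinDistance <- function(x) {
    as.matrix(dist(x, method = "euclidean"))
}

#' Bin-bin correlation of distance (or contact) profiles
#'
#' Entry (i, j) is the Pearson correlation between rows i and j of a
#' symmetric input matrix (a Euclidean distance matrix on the SAMMY path, a
#' balanced contact matrix on the Hi-C path) with the two self-entries
#' (positions i and j) excluded pairwise. Constant rows give masked
#' entries; the affected bins are reported in the `"flagged"` attribute.
#'
#' @param m symmetric numeric matrix (n >= 5).
#' @return symmetric correlation matrix with unit diagonal and a
#'   `"flagged"` attribute of bins with constant profiles.
#' @export
profileCorrelation <- function(m) {
    n <- nrow(m)
    stopifnot(n >= 5, ncol(m) == n)
    dg <- diag(m)
    S <- rowSums(m)
    Q <- rowSums(m^2)
    P <- tcrossprod(m)
    np <- n - 2
    # row sums / sums of squares / cross products with entries i, j removed
    Sa <- outer(S - dg, rep(1, n)) - m
    Qa <- outer(Q - dg^2, rep(1, n)) - m^2
    Pab <- P - outer(dg, rep(1, n)) * m - m * outer(rep(1, n), dg)
    num <- np * Pab - Sa * t(Sa)
    varA <- np * Qa - Sa^2
    den2 <- varA * t(varA)
    C <- matrix(NA_real_, n, n)
    ok <- den2 > 0
    C[ok] <- num[ok] / sqrt(den2[ok])
    C[C > 1] <- 1
    C[C < -1] <- -1
    diag(C) <- 1
    flagged <- which(apply(m, 1, function(r) var(r) == 0))
    C[flagged, ] <- NA_real_
    C[, flagged] <- NA_real_
    diag(C) <- 1
    attr(C, "flagged") <- flagged
    C
}

#' Detect contiguous domains from a correlation matrix
#'
#' The boundary score at the gap between bins k and k+1 is one minus the
#' mean correlation between the `minBins` bins on each side (windows
#' clipped at the chromosome ends). Local maxima of the score above its
#' `boundaryQuantile` quantile become boundaries; domains shorter than
#' `minBins` are then merged into the neighbour they correlate with more
#' strongly. A flat score profile yields a single domain with a warning.
#'
#' @param C bin correlation matrix (null bins dropped).
#' @param minBins boundary window width and minimum domain length in bins
#'   (default 5, i.e. 250 kb at 50 kb resolution).
#' @param boundaryQuantile quantile of the score above which local maxima
#'   are boundaries (default 0.9).
#' @return data.frame with columns `start`, `end` (1-based inclusive bin
#'   indices into the reduced matrix), partitioning `1..nrow(C)`.
#' @export
detectDomains <- function(C, minBins = 5, boundaryQuantile = 0.9) {
    n <- nrow(C)
    stopifnot(n >= 2 * minBins)
    score <- boundaryScore(C, minBins)
    if (max(score) - min(score) < 1e-12) {
        warning("flat boundary score; returning a single domain")
        return(data.frame(start = 1L, end = n))
    }
    thr <- quantile(score, boundaryQuantile, names = FALSE)
    isMax <- vapply(seq_along(score), function(k) {
        left <- if (k > 1) score[k - 1] else -Inf
        right <- if (k < length(score)) score[k + 1] else -Inf
        score[k] >= left && score[k] >= right
    }, logical(1))
    cuts <- which(isMax & score >= thr)
    # collapse plateau runs of tied maxima to their first gap
    if (length(cuts) > 1)
        cuts <- cuts[c(TRUE, diff(cuts) > 1 |
                       score[cuts[-1]] != score[cuts[-length(cuts)]])]
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    dom <- data.frame(start = starts, end = ends)
    mergeShortDomains(dom, C, minBins)
}

# 1 - mean correlation across the gap, windows of w bins on each side
boundaryScore <- function(C, w) {
    n <- nrow(C)
    vapply(seq_len(n - 1), function(k) {
        L <- max(1, k - w + 1):k
        R <- (k + 1):min(n, k + w)
        1 - mean(C[L, R, drop = FALSE], na.rm = TRUE)
    }, numeric(1))
}

# merge domains shorter than minBins into the more-correlated neighbour
mergeShortDomains <- function(dom, C, minBins) {
    repeat {
        len <- dom$end - dom$start + 1L
        short <- which(len < minBins)
        if (length(short) == 0 || nrow(dom) == 1) break
        i <- short[which.min(len[short])]
        bins <- dom$start[i]:dom$end[i]
        corWith <- function(j) {
            if (j < 1 || j > nrow(dom)) return(-Inf)
            mean(C[bins, dom$start[j]:dom$end[j], drop = FALSE],
                 na.rm = TRUE)
        }
        j <- if (corWith(i - 1) >= corWith(i + 1)) i - 1L else i + 1L
        lo <- min(i, j); hi <- max(i, j)
        dom$end[lo] <- dom$end[hi]
        dom <- dom[-hi, , drop = FALSE]
        rownames(dom) <- NULL
    }
    dom
}

# aggregate a bin-level matrix to domain level by the mean
domainAggregate <- function(C, dom) {
    d <- nrow(dom)
    Cd <- matrix(NA_real_, d, d)
    for (i in seq_len(d)) for (j in i:d) {
        v <- mean(C[dom$start[i]:dom$end[i], dom$start[j]:dom$end[j],
                    drop = FALSE], na.rm = TRUE)
        Cd[i, j] <- v
        Cd[j, i] <- v
    }
    Cd
}

#' Binary trend matrix of domain correlation profiles
#'
#' The bin correlation matrix is aggregated to domain level by the mean
#' (Cd, d x d); T[i, k] = 1 if Cd[i, k+1] >= Cd[i, k] else 0 for
#' k = 1..d-1 -- the along-chromosome trend (first differences) of each
#' domain's similarity profile.
#'
#' @param C bin correlation matrix.
#' @param dom domain table from [detectDomains()].
#' @return binary d x (d-1) matrix.
#' @export
binaryTrendMatrix <- function(C, dom) {
    stopifnot(nrow(dom) >= 2)
    Cd <- domainAggregate(C, dom)
    d <- nrow(Cd)
    (Cd[, 2:d, drop = FALSE] >= Cd[, 1:(d - 1), drop = FALSE]) * 1
}

#' Principal-component embedding of the binary trend matrix
#'
#' Centered PCA scores of the rows of T, first `nComponents` components
#' (fewer, with a warning, when d - 1 < `nComponents`). Each component's
#' loading vector is oriented to a positive sum so the embedding is
#' deterministic.
#'
#' @param T binary trend matrix (d x (d-1)).
#' @param nComponents number of components to keep (default 10).
#' @return d x k score matrix.
#' @export
trendEmbedding <- function(T, nComponents = 10) {
    d <- nrow(T)
    if (all(apply(T, 2, var) == 0))
        stop("degenerate trend matrix: zero variance")
    k <- min(nComponents, d - 1, ncol(T))
    if (k < nComponents)
        warning("fewer domains than requested components; using ", k)
    pc <- prcomp(T, center = TRUE, scale. = FALSE)
    k <- min(k, ncol(pc$rotation))
    rot <- pc$rotation[, seq_len(k), drop = FALSE]
    flip <- colSums(rot) < 0
    rot[, flip] <- -rot[, flip]
    sweep(T, 2, colMeans(T)) %*% rot
}

#' Bisecting 2-means hierarchy over domain embeddings
#'
#' Recursive two-means clustering, initialized deterministically by the
#' sign of the projection on the cluster's first principal direction
#' (loading oriented to positive sum), then iterated to convergence
#' (Lloyd). Recursion stops at `depth` levels or when a cluster holds
#' fewer than 2 distinct points, yielding at most 2^depth leaves.
#'
#' @param emb domain embedding matrix from [trendEmbedding()].
#' @param depth recursion depth (default 3, so at most 8 leaves).
#' @return nested list tree; leaves are `list(leaf = TRUE, domains = idx)`.
#' @export
bisectHierarchy <- function(emb, depth = 3) {
    .bisect(seq_len(nrow(emb)), emb, depth)
}

.bisect <- function(idx, emb, depth) {
    leaf <- list(leaf = TRUE, domains = idx)
    if (depth == 0 || length(idx) < 2) return(leaf)
    X <- emb[idx, , drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    if (max(abs(Xc)) < 1e-12) return(leaf)   # identical embeddings
    sv <- svd(Xc, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (sum(v) < 0) v <- -v
    assign <- as.numeric(Xc %*% v) > 0
    if (!any(assign) || all(assign)) return(leaf)
    # Lloyd iterations from the deterministic split
    for (it in seq_len(100)) {
        c1 <- colMeans(X[assign, , drop = FALSE])
        c0 <- colMeans(X[!assign, , drop = FALSE])
        d1 <- rowSums(sweep(X, 2, c1)^2)
        d0 <- rowSums(sweep(X, 2, c0)^2)
        newAssign <- d1 < d0
        if (!any(newAssign) || all(newAssign)) break
        if (identical(newAssign, assign)) break
        assign <- newAssign
    }
    if (!any(assign) || all(assign)) return(leaf)
    list(leaf = FALSE,
         left = .bisect(idx[!assign], emb, depth - 1),
         right = .bisect(idx[assign], emb, depth - 1))
}

# arc-length coordinate of each domain projected on the lowess curve of
# component 2 vs component 1
lowessProjection <- function(emb, span = 0.5) {
    x <- emb[, 1]
    y <- if (ncol(emb) >= 2) emb[, 2] else rep(0, length(x))
    if (length(unique(x)) < 3 || stats::sd(y) == 0)
        return(x)       # degenerate cloud: component 1 is the coordinate
    fit <- lowess(x, y, f = span)
    px <- fit$x
    py <- fit$y
    keep <- !duplicated(px)
    px <- px[keep]; py <- py[keep]
    if (length(px) < 2) return(x)
    seg <- sqrt(diff(px)^2 + diff(py)^2)
    cum <- c(0, cumsum(seg))
    proj <- numeric(length(x))
    for (i in seq_along(x)) {
        best <- Inf; coord <- 0
        for (s in seq_len(length(px) - 1)) {
            dx <- px[s + 1] - px[s]; dy <- py[s + 1] - py[s]
            L2 <- dx^2 + dy^2
            t <- if (L2 == 0) 0 else
                ((x[i] - px[s]) * dx + (y[i] - py[s]) * dy) / L2
            t <- min(max(t, 0), 1)
            qx <- px[s] + t * dx; qy <- py[s] + t * dy
            d2 <- (x[i] - qx)^2 + (y[i] - qy)^2
            if (d2 < best) { best <- d2; coord <- cum[s] + t * sqrt(L2) }
        }
        proj[i] <- coord
    }
    proj
}

# reorder siblings at every level by mean projected coordinate; return the
# ordered leaf list (each element = integer vector of domain indices)
orderLeaves <- function(tree, proj) {
    if (isTRUE(tree$leaf)) return(list(tree$domains))
    lMean <- mean(proj[unlist(leafDomains(tree$left))])
    rMean <- mean(proj[unlist(leafDomains(tree$right))])
    first <- if (lMean <= rMean) tree$left else tree$right
    second <- if (lMean <= rMean) tree$right else tree$left
    c(orderLeaves(first, proj), orderLeaves(second, proj))
}

leafDomains <- function(tree) {
    if (isTRUE(tree$leaf)) return(list(tree$domains))
    c(leafDomains(tree$left), leafDomains(tree$right))
}

#' Rank ordered leaves and assign the eight sub-compartment labels
#'
#' Orders the hierarchy's leaves by mean projected coordinate along the
#' lowess curve of the first two embedding components (siblings reordered
#' consistently at every tree level), orients the order so the end with
#' the higher mean openness reference becomes A.1.1, and assigns the
#' canonical labels B.2.2 (most closed) through A.1.1 (most open). With
#' fewer than 8 leaves, labels are assigned from both extremes inward and
#' middle labels stay unused.
#'
#' @param tree hierarchy from [bisectHierarchy()].
#' @param emb domain embedding matrix.
#' @param domOpenness per-domain mean openness reference (gene density or
#'   an open fraction's RPKM).
#' @param span lowess span (default 0.5).
#' @return list with `leaves` (ordered list of domain-index vectors),
#'   `labels` (one per leaf), and `projection` (per-domain coordinate).
#' @export
rankAndLabel <- function(tree, emb, domOpenness, span = 0.5) {
    proj <- lowessProjection(emb, span)
    leaves <- orderLeaves(tree, proj)
    k <- length(leaves)
    stopifnot(k <= 8)
    leafOpen <- vapply(leaves, function(d) mean(domOpenness[d]), numeric(1))
    if (max(leafOpen) - min(leafOpen) <= 1e-12) {
        warning("flat openness reference; leaf order left unoriented")
    } else if (k >= 2) {
        nh <- floor(k / 2)
        lowEnd <- mean(leafOpen[seq_len(nh)])
        highEnd <- mean(leafOpen[(k - nh + 1):k])
        if (lowEnd > highEnd) leaves <- rev(leaves)
    }
    nb <- ceiling(k / 2)
    nt <- k - nb
    labels <- c(.SUBCOMPARTMENT_LEVELS[seq_len(nb)],
                if (nt > 0) .SUBCOMPARTMENT_LEVELS[(8 - nt + 1):8])
    list(leaves = leaves, labels = labels, projection = proj)
}

# run the hierarchy on one chromosome's reduced profile matrix
.subcompartmentChromosome <- function(profile, openness, minBins,
                                      boundaryQuantile, nComponents,
                                      depth, span) {
    C <- profileCorrelation(profile)
    dom <- detectDomains(C, minBins, boundaryQuantile)
    if (nrow(dom) < 2) {
        return(list(labels = rep(.SUBCOMPARTMENT_LEVELS[1], nrow(C)),
                    single = TRUE, domains = dom))
    }
    T <- binaryTrendMatrix(C, dom)
    emb <- trendEmbedding(T, nComponents)
    tree <- bisectHierarchy(emb, depth)
    domOpen <- vapply(seq_len(nrow(dom)), function(i)
        mean(openness[dom$start[i]:dom$end[i]]), numeric(1))
    rl <- rankAndLabel(tree, emb, domOpen, span)
    binLabels <- rep(NA_character_, nrow(C))
    for (li in seq_along(rl$leaves))
        for (di in rl$leaves[[li]])
            binLabels[dom$start[di]:dom$end[di]] <- rl$labels[li]
    list(labels = binLabels, single = FALSE, domains = dom,
         tree = tree, embedding = emb, rank = rl)
}

#' Call sub-compartments from a FractionMatrix
#'
#' The SAMMY-seq path of the hierarchy: per chromosome, drops null bins,
#' computes the pairwise Euclidean distance of the m-dimensional fraction
#' vectors (50 kb bins), derives the bin correlation matrix of distance
#' profiles, detects domains, embeds them through the binary trend matrix
#' and ten principal components, bisects recursively into at most eight
#' leaves, and ranks the leaves along the lowess projection, oriented by
#' the openness reference.
#'
#' @param fm a [FractionMatrix-class] (typically on a 50 kb grid).
#' @param genes `GRanges` of gene bodies; the default openness reference
#'   is their per-bin density.
#' @param openness optional [BinnedTrack-class] to use as the openness
#'   reference instead of gene density (e.g. the most open fraction's
#'   RPKM).
#' @param log1p take log1p of coverage before computing distances
#'   (default TRUE: the fractions' dynamic ranges differ by orders of
#'   magnitude, and on the raw RPKM scale the open-enriched fraction
#'   dominates every distance, collapsing resolution among closed bins;
#'   set FALSE for raw-scale distances).
#' @param minBins,boundaryQuantile domain detection controls (defaults 5
#'   bins, 0.9).
#' @param nComponents embedding dimension (default 10).
#' @param depth bisection depth (default 3).
#' @param span lowess span for the ranking projection (default 0.5).
#' @return a [SubCompartmentCall-class].
#' @export
subCompartmentsFromFractions <- function(fm, genes, openness = NULL,
                                         log1p = TRUE, minBins = 5,
                                         boundaryQuantile = 0.9,
                                         nComponents = 10, depth = 3,
                                         span = 0.5) {
    grid <- fractionGrid(fm)
    open <- if (is.null(openness)) trackValues(geneDensityTrack(genes, grid))
            else trackValues(openness)
    labels <- rep(NA_character_, binCount(grid))
    hier <- list()
    for (chrom in chromNames(grid)) {
        idx <- chromBinIndices(grid, chrom)
        red <- dropNullBins(fractionValues(fm)[idx, , drop = FALSE],
                            mode = "fractions")
        if (length(red$keep) < 2 * minBins) {
            warning("chromosome ", chrom, " skipped: too few bins")
            next
        }
        vals <- if (log1p) log1p(red$values) else red$values
        D <- euclideanBinDistance(vals)
        res <- .subcompartmentChromosome(D, open[idx[red$keep]], minBins,
                                         boundaryQuantile, nComponents,
                                         depth, span)
        labels[idx[red$keep]] <- res$labels
        hier[[chrom]] <- c(res, list(keep = red$keep))
    }
    .asSubCompartmentCall(grid, labels, hier)
}

#' Call sub-compartments from Hi-C contacts
#'
#' The Hi-C comparison path: per chromosome, drops null bins, ICE-balances
#' the cis contact matrix, normalizes observed over expected by distance
#' (without this the power-law distance decay dominates every contact
#' profile and washes out compartment similarity; distances with no
#' expected value are imputed to the neutral O/E value 1), and runs the
#' same domain/trend/bisect/rank procedure on the bin correlation of the
#' O/E profiles.
#'
#' @inheritParams subCompartmentsFromFractions
#' @param cm a [ContactMatrix-class] (typically on a 50 kb grid).
#' @param maxIter,tol ICE balancing controls.
#' @return a [SubCompartmentCall-class].
#' @export
subCompartmentsFromContacts <- function(cm, genes, openness = NULL,
                                        minBins = 5,
                                        boundaryQuantile = 0.9,
                                        nComponents = 10, depth = 3,
                                        span = 0.5, maxIter = 200,
                                        tol = 1e-12) {
    grid <- cm@grid
    open <- if (is.null(openness)) trackValues(geneDensityTrack(genes, grid))
            else trackValues(openness)
    labels <- rep(NA_character_, binCount(grid))
    hier <- list()
    for (chrom in contactChroms(cm)) {
        idx <- chromBinIndices(grid, chrom)
        red <- dropNullBins(contactCounts(cm, chrom), mode = "contacts")
        if (length(red$keep) < 2 * minBins) {
            warning("chromosome ", chrom, " skipped: too few bins")
            next
        }
        bal <- iceBalance(red$values, maxIter, tol)$balanced
        oe <- oeNormalize(bal)
        oe[is.na(oe)] <- 1
        res <- .subcompartmentChromosome(oe, open[idx[red$keep]], minBins,
                                         boundaryQuantile, nComponents,
                                         depth, span)
        labels[idx[red$keep]] <- res$labels
        hier[[chrom]] <- c(res, list(keep = red$keep))
    }
    .asSubCompartmentCall(grid, labels, hier)
}

.asSubCompartmentCall <- function(grid, labels, hier) {
    fac <- factor(labels, levels = .SUBCOMPARTMENT_LEVELS)
    new("SubCompartmentCall", grid = grid, label = fac,
        rank = as.integer(fac), hierarchy = hier)
}

#' @describeIn subCompartmentsFromFractions accessors for
#'   sub-compartment calls.
#' @param call a [SubCompartmentCall-class].
#' @export
subCompartmentLabels <- function(call) call@label

#' @rdname subCompartmentsFromFractions
#' @export
subCompartmentRanks <- function(call) call@rank

#' Canonical ordered sub-compartment labels
#'
#' @return character vector B.2.2 ... A.1.1 (most closed to most open).
#' @export
subCompartmentLevels <- function() .SUBCOMPARTMENT_LEVELS

setMethod("show", "SubCompartmentCall", function(object) {
    cat("SubCompartmentCall:", binCount(object@grid), "bins;",
        sum(!is.na(object@label)), "called\n")
    print(table(object@label))
})

#' Export a hierarchy as JSON
#'
#' Writes the per-chromosome domain tables and leaf composition (domain
#' bin ranges in chromosome-local kept-bin coordinates, plus the kept-bin
#' index map) as pretty-printed JSON.
#'
#' @param call a [SubCompartmentCall-class].
#' @param path output path.
#' @export
writeHierarchyJSON <- function(call, path) {
    out <- lapply(call@hierarchy, function(h) {
        list(domains = h$domains,
             keep = h$keep,
             leaves = if (!is.null(h$rank))
                 lapply(seq_along(h$rank$leaves), function(i)
                     list(label = h$rank$labels[i],
                          domains = h$rank$leaves[[i]]))
             else list())
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
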