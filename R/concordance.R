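#' Jaccard index between two compartment callsets
#'
#' Restricted to bins called (non-NA) in both sets:
#' J(label) = |bins with `label` in both| / |bins with `label` in either|.
#' The overall index is the mean of J(A) and J(B).
#'
#' @param callA,callB [CompartmentCall-class] objects on the same grid.
#' @return list with `A`, `B`, `overall`, and logical `undefined` flags
#'   for labels with an empty union (reported as NA, never 0).
#' @export
jaccardIndex <- function(callA, callB) {
    stopifnot(binCount(callA@grid) == binCount(callB@grid))
    a <- as.character(callA@label)
    b <- as.character(callB@label)
    shared <- !is.na(a) & !is.na(b)
    one <- function(lab) {
        inter <- sum(shared & a == lab & b == lab)
        union <- sum(shared & (a == lab | b == lab))
        if (union == 0) NA_real_ else inter / union
    }
    jA <- one("A")
    jB <- one("B")
    both <- c(jA, jB)
    list(A = jA, B = jB,
         overall = if (all(is.na(both))) NA_real_ else
             mean(both, na.rm = TRUE),
         undefined = c(A = is.na(jA), B = is.na(jB)))
}

#' Pearson correlation of compartment eigenvectors
#'
#' Per-chromosome Pearson correlation of the scaled eigenvector values
#' over shared non-NA bins, plus a genome-wide value computed on the
#' concatenation of all shared bins (after per-chromosome scaling).
#' Chromosomes with fewer than 3 shared bins, or a constant vector, are
#' flagged NA.
#'
#' @param callA,callB [CompartmentCall-class] objects on the same grid.
#' @return list with `perChromosome` (named numeric) and `genome`.
#' @export
eigenvectorPearson <- function(callA, callB) {
    grid <- callA@grid
    stopifnot(binCount(grid) == binCount(callB@grid))
    a <- callA@eigen
    b <- callB@eigen
    shared <- !is.na(a) & !is.na(b)
    r <- setNames(rep(NA_real_, length(chromNames(grid))),
                  chromNames(grid))
    for (chrom in chromNames(grid)) {
        idx <- chromBinIndices(grid, chrom)
        ok <- shared[idx]
        if (sum(ok) >= 3 && sd(a[idx][ok]) > 0 && sd(b[idx][ok]) > 0)
            r[chrom] <- cor(a[idx][ok], b[idx][ok])
    }
    genome <- if (sum(shared) >= 3 && sd(a[shared]) > 0 &&
                  sd(b[shared]) > 0)
        cor(a[shared], b[shared]) else NA_real_
    list(perChromosome = r, genome = genome)
}

#' Per-bin compartment discordance classes
#'
#' Classifies each bin as `A-A` or `B-B` when the two calls agree, `A->B`
#' when the reference says A and the test says B, `B->A` for the
#' opposite; NA propagates from either call.
#'
#' @param reference,test [CompartmentCall-class] objects on the same grid
#'   (the paper's convention: reference = Hi-C, test = SAMMY-seq, so
#'   `A->B` means active by Hi-C, inactive by SAMMY-seq).
#' @return list with per-bin `classes` (character, NA where uncalled) and
#'   `counts` (named integer vector over the four classes).
#' @export
discordanceClasses <- function(reference, test) {
    stopifnot(binCount(reference@grid) == binCount(test@grid))
    a <- as.character(reference@label)
    b <- as.character(test@label)
    cls <- rep(NA_character_, length(a))
    ok <- !is.na(a) & !is.na(b)
    cls[ok & a == "A" & b == "A"] <- "A-A"
    cls[ok & a == "B" & b == "B"] <- "B-B"
    cls[ok & a == "A" & b == "B"] <- "A->B"
    cls[ok & a == "B" & b == "A"] <- "B->A"
    counts <- vapply(c("A-A", "B-B", "A->B", "B->A"),
                     function(x) sum(cls == x, na.rm = TRUE), integer(1))
    list(classes = cls, counts = counts)
}

#' Difference in A-compartment percentage per chromatin state
#'
#' For each state s and each call, \%A(s) = (bp of s overlapping A bins) /
#' (bp of s overlapping A or B bins) x 100, with overlaps bp-weighted;
#' the reported value is \%A(callA) - \%A(callB). States with zero bp in
#' classified bins are reported NA.
#'
#' @param states `GRanges` with a `name` (or `state`) metadata column of
#'   state labels.
#' @param callA,callB [CompartmentCall-class] objects on the same grid.
#' @return data.frame with columns `state`, `pctA_A`, `pctA_B`, `delta`.
#' @export
stateOccupancyDifference <- function(states, callA, callB) {
    lab <- if (!is.null(states$name)) states$name else states$state
    if (is.null(lab)) stop("states need a 'name' or 'state' column")
    pct <- function(call) {
        bins <- gridBins(call@grid)
        cl <- as.character(call@label)
        ov <- GenomicRanges::findOverlaps(states, bins)
        w <- GenomicRanges::width(IRanges::pintersect(
            GenomicRanges::ranges(states)[S4Vectors::queryHits(ov)],
            GenomicRanges::ranges(bins)[S4Vectors::subjectHits(ov)]))
        binLab <- cl[S4Vectors::subjectHits(ov)]
        stLab <- lab[S4Vectors::queryHits(ov)]
        keep <- !is.na(binLab)
        aBp <- tapply(w[keep] * (binLab[keep] == "A"), stLab[keep], sum)
        abBp <- tapply(w[keep], stLab[keep], sum)
        out <- setNames(rep(NA_real_, length(unique(lab))), unique(lab))
        out[names(abBp)] <- 100 * aBp[names(abBp)] / abBp
        out
    }
    pa <- pct(callA)
    pb <- pct(callB)
    data.frame(state = names(pa), pctA_A = unname(pa),
               pctA_B = unname(pb[names(pa)]),
               delta = unname(pa - pb[names(pa)]),
               row.names = NULL)
}

#' Mark enrichment per sub-compartment
#'
#' Standardizes the mark track per chromosome over unmasked bins
#' (z-score: subtract the mean, divide by the standard deviation; set
#' `standardError = TRUE` to divide by sd/sqrt(n) instead), then averages
#' the standardized values per sub-compartment label genome-wide.
#' Chromosomes with fewer than 3 unmasked bins are excluded.
#'
#' @param mark a [BinnedTrack-class] on the call's grid.
#' @param call a [SubCompartmentCall-class].
#' @param standardError divide by the standard error instead of the
#'   standard deviation (default FALSE).
#' @return named numeric vector of mean z per label, ordered B.2.2 ...
#'   A.1.1 (NA for labels with no bins).
#' @export
subcompartmentMarkEnrichment <- function(mark, call,
                                         standardError = FALSE) {
    grid <- call@grid
    stopifnot(binCount(trackGrid(mark)) == binCount(grid))
    v <- trackValues(mark)
    z <- rep(NA_real_, length(v))
    for (chrom in chromNames(grid)) {
        idx <- chromBinIndices(grid, chrom)
        x <- v[idx]
        ok <- !is.na(x)
        if (sum(ok) < 3) next
        s <- sd(x[ok])
        if (standardError) s <- s / sqrt(sum(ok))
        if (s == 0) {
            z[idx[ok]] <- 0      # degenerate constant chromosome
        } else {
            z[idx[ok]] <- (x[ok] - mean(x[ok])) / s
        }
    }
    lab <- call@label
    out <- vapply(.SUBCOMPARTMENT_LEVELS, function(l) {
        zz <- z[!is.na(lab) & lab == l]
        zz <- zz[!is.na(zz)]
        if (length(zz)) mean(zz) else NA_real_
    }, numeric(1))
    out
}

#' Classify genes by expression and compartment
#'
#' Intersects a window of +/-500 bp around each TSS (strand-aware) with
#' the compartment call: genes whose window misses classified bins, or
#' spans more than one compartment label, are discarded (and counted).
#' Genes with zero expression are "Not detected"; the rest are split by
#' expression quartiles into Low / Moderate / High / Very high (ties at a
#' boundary go to the lower class). Returns the per-gene table and the
#' class x compartment cross-tabulation.
#'
#' @param genes `GRanges` of gene bodies with strand; TSS = 5' end.
#' @param expression numeric vector of expression values (>= 0), parallel
#'   to `genes`.
#' @param call a [CompartmentCall-class].
#' @param window half-window around the TSS in bp (default 500).
#' @return list with `genes` (data.frame gene/class/compartment),
#'   `table` (class x compartment), `discardedMissing`,
#'   `discardedStraddling`.
#' @export
classifyGenesByCompartment <- function(genes, expression, call,
                                       window = 500) {
    stopifnot(length(genes) == length(expression), all(expression >= 0))
    grid <- call@grid
    str <- as.character(GenomicRanges::strand(genes))
    str[str == "*"] <- "+"
    tssPos <- ifelse(str == "+", GenomicRanges::start(genes),
                     GenomicRanges::end(genes))
    win <- GenomicRanges::GRanges(
        as.character(GenomeInfoDb::seqnames(genes)),
        IRanges::IRanges(pmax(1, tssPos - window), tssPos + window))
    bins <- gridBins(grid)
    cl <- as.character(call@label)
    ov <- GenomicRanges::findOverlaps(win, bins)
    labPerGene <- tapply(cl[S4Vectors::subjectHits(ov)],
                         S4Vectors::queryHits(ov),
                         function(x) {
                             u <- unique(x[!is.na(x)])
                             if (length(u) == 0) "missing"
                             else if (length(u) > 1) "straddling"
                             else u
                         })
    gene_lab <- rep("missing", length(genes))
    gene_lab[as.integer(names(labPerGene))] <- labPerGene
    discardedMissing <- sum(gene_lab == "missing")
    discardedStraddling <- sum(gene_lab == "straddling")
    keep <- gene_lab %in% c("A", "B")
    expr <- expression[keep]
    cls <- rep(NA_character_, sum(keep))
    cls[expr == 0] <- "Not detected"
    pos <- expr > 0
    if (any(pos)) {
        q <- quantile(expr[pos], c(0.25, 0.5, 0.75), names = FALSE)
        cls[pos] <- cut(expr[pos], breaks = c(-Inf, q, Inf),
                        labels = c("Low", "Moderate", "High", "Very high"),
                        right = TRUE)
        cls[pos] <- c("Low", "Moderate", "High",
                      "Very high")[as.integer(cls[pos])]
    }
    classes <- factor(cls, levels = c("Not detected", "Low", "Moderate",
                                      "High", "Very high"))
    df <- data.frame(
        gene = if (!is.null(genes$name)) genes$name[keep] else which(keep),
        expression = expr,
        class = classes,
        compartment = factor(gene_lab[keep], levels = c("A", "B")))
    list(genes = df,
         table = table(df$class, df$compartment),
         discardedMissing = discardedMissing,
         discardedStraddling = discardedStraddling)
}

#' Full concordance report between two compartment callsets
#'
#' Bundles [jaccardIndex()], [eigenvectorPearson()] and
#' [discordanceClasses()] into one report (reference first, test second).
#'
#' @param reference,test [CompartmentCall-class] objects on one grid.
#' @return list with `jaccard`, `pearson`, `discordance`, `sharedBins`.
#' @export
concordanceReport <- function(reference, test) {
    dc <- discordanceClasses(reference, test)
    list(jaccard = jaccardIndex(reference, test),
         pearson = eigenvectorPearson(reference, test),
         discordance = dc,
         sharedBins = sum(!is.na(reference@label) & !is.na(test@label)))
}

#' Write a concordance report as JSON
#'
#' @param report output of [concordanceReport()].
#' @param path output path.
#' @export
writeConcordanceJSON <- function(report, path) {
    out <- list(jaccard = report$jaccard[c("A", "B", "overall")],
                pearson = report$pearson,
                discordanceCounts = as.list(report$discordance$counts),
                sharedBins = report$sharedBins)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
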