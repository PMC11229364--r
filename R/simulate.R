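#' Simulate a genome with a latent openness field
#'
#' Tiles each chromosome with domains of geometric lengths (mean
#' `meanDomainLen` bins, minimum 1), draws each domain's latent openness u
#' uniformly from the 8-level grid \{-1, -5/7, ..., +1\} (mirroring the
#' eight sub-compartments so rank recovery has a well-defined truth), and
#' places genes by a Poisson process with per-bin intensity proportional
#' to (1 + u) / 2, so genes concentrate in open chromatin. If
#' `meanDomainLen` is at least the chromosome's bin count, the chromosome
#' is a single domain.
#'
#' @param chromSizes named numeric vector of chromosome lengths in bp.
#' @param binSize bin width in bp (default 50000).
#' @param meanDomainLen mean domain length in bins (>= 5; default 20,
#'   i.e. 1 Mb at 50 kb).
#' @param geneRate mean genes per bin at u = +1 is `geneRate` (the per-bin
#'   Poisson intensity is `geneRate * (1 + u) / 2`; default 1).
#' @param geneLength gene length in bp (default 2000).
#' @param seed RNG seed (required; every draw depends on it).
#' @return `SyntheticTruth`: list with `grid`, per-bin `u`, `compartment`
#'   (factor A/B), `level` (integer 1..8, most closed to most open),
#'   `domains` (data.frame), `genes` (`GRanges`), `seed`.
#' @export
simulateGenome <- function(chromSizes, binSize = 50000,
                           meanDomainLen = 20, geneRate = 1,
                           geneLength = 2000, seed) {
    stopifnot(meanDomainLen >= 5)
    set.seed(seed)
    grid <- BinGrid(chromSizes, binSize)
    uLevels <- seq(-1, 1, length.out = 8)
    nb <- binCountPerChrom(grid)
    u <- rep(NA_real_, binCount(grid))
    domains <- NULL
    geneChrom <- character(0); geneStart <- numeric(0)
    for (chrom in chromNames(grid)) {
        n <- nb[[chrom]]
        # domain lengths (bins)
        lens <- integer(0)
        if (meanDomainLen >= n) {
            lens <- n
        } else {
            while (sum(lens) < n)
                lens <- c(lens, 1L + rgeom(1, 1 / meanDomainLen))
            extra <- sum(lens) - n
            lens[length(lens)] <- lens[length(lens)] - extra
            lens <- lens[lens > 0]
        }
        du <- sample(uLevels, length(lens), replace = TRUE)
        uc <- rep(du, lens)
        idx <- chromBinIndices(grid, chrom)
        u[idx] <- uc
        ends <- cumsum(lens)
        domains <- rbind(domains, data.frame(
            chrom = chrom, startBin = c(1L, head(ends, -1) + 1L),
            endBin = ends, u = du))
        # genes: Poisson per bin, uniform position within the bin
        lam <- geneRate * (1 + uc) / 2
        ng <- rpois(length(lam), lam)
        if (sum(ng) > 0) {
            binIdx <- rep(seq_along(ng), ng)
            start0 <- (binIdx - 1) * binSize +
                floor(runif(sum(ng)) * binSize)
            geneChrom <- c(geneChrom, rep(chrom, sum(ng)))
            geneStart <- c(geneStart, start0)
        }
    }
    sl <- chromLengths(grid)
    geneEnd <- pmin(geneStart + geneLength, sl[geneChrom])
    geneStart <- pmin(geneStart, sl[geneChrom] - 1)
    genes <- GenomicRanges::GRanges(
        geneChrom, IRanges::IRanges(geneStart + 1, geneEnd),
        strand = sample(c("+", "-"), length(geneChrom), replace = TRUE))
    genes$name <- if (length(genes)) paste0("g", seq_along(genes))
                  else character(0)
    structure(list(grid = grid, u = u,
                   compartment = factor(ifelse(u > 0, "A", "B"),
                                        levels = c("A", "B")),
                   level = match(u, uLevels),
                   domains = domains, genes = genes, seed = seed),
              class = "SyntheticTruth")
}

#' @export
print.SyntheticTruth <- function(x, ...) {
    cat("SyntheticTruth:", binCount(x$grid), "bins,",
        nrow(x$domains), "domains,", length(x$genes), "genes (seed",
        x$seed, ")\n")
    invisible(x)
}

#' Truth rebinned to a coarser resolution
#'
#' Mean u per coarse bin; compartment A iff mean u > 0; level = nearest of
#' the 8 canonical u levels.
#'
#' @param truth a `SyntheticTruth`.
#' @param binSize coarse bin size (multiple of the truth bin size).
#' @return list with `grid`, `u`, `compartment`, `level`.
#' @export
truthAtResolution <- function(truth, binSize) {
    tr <- rebin(BinnedTrack(truth$grid, truth$u,
                            mask = rep(FALSE, binCount(truth$grid))),
                binSize)
    u <- trackValues(tr)
    uLevels <- seq(-1, 1, length.out = 8)
    level <- vapply(u, function(x)
        if (is.na(x)) NA_integer_ else which.min(abs(uLevels - x)),
        integer(1))
    list(grid = trackGrid(tr), u = u,
         compartment = factor(ifelse(u > 0, "A", "B"),
                              levels = c("A", "B")),
         level = level)
}

#' Default 4f fraction parameters
#'
#' Log-linear openness response per fraction: expected coverage
#' \eqn{\mu_f(u) = \exp(a_f + b_f u)}. S2S/S2L (DNase-digested, size
#' selected) are open-enriched (b > 0); S3 (high salt) and S4 (urea) are
#' closed-enriched (b < 0). The contrasts are calibrated so that every
#' fraction's per-bin signal-to-noise ratio (|b| x sd(u) over the
#' negative-binomial log-coverage noise at the default depth and
#' dispersion) is at least 3, the regime in which compartment recovery
#' is expected to be near-perfect; the strongest fraction then spans a
#' ~36-fold coverage contrast between the most open and the most closed
#' chromatin, consistent with the near-complete depletion of digested
#' accessible chromatin over constitutive heterochromatin.
#'
#' @return data.frame with columns `fraction`, `a`, `b`.
#' @export
defaultFractionParams <- function() {
    data.frame(fraction = c("S2S", "S2L", "S3", "S4"),
               a = 0,
               b = c(1.8, 1.6, -1.6, -1.8))
}

#' Simulate fraction coverage tracks from a truth
#'
#' Per bin and fraction, counts are negative binomial with mean
#' \eqn{\mu_f(u) \cdot depth} (\eqn{\mu_f(u) = \exp(a_f + b_f u)}) and the
#' given dispersion (`Inf` = Poisson), then converted to RPKM with the
#' fraction's own total as library size.
#'
#' @param truth a `SyntheticTruth`.
#' @param fractionParams data.frame fraction/a/b
#'   (default [defaultFractionParams()]); b > 0 = open-enriched,
#'   b < 0 = closed-enriched.
#' @param depth scales the expected count per bin (default 50, the mean
#'   count per bin and fraction at u = 0).
#' @param dispersion negative binomial size parameter (> 0; default 10).
#' @param seed RNG seed.
#' @return a [FractionMatrix-class] on the truth grid; the raw counts are
#'   attached as attribute `"counts"`.
#' @export
simulateFractionTracks <- function(truth,
                                   fractionParams =
                                       defaultFractionParams(),
                                   depth = 50, dispersion = 10, seed) {
    if (!is.infinite(dispersion) && dispersion <= 0)
        stop("dispersion must be positive (Inf = Poisson)")
    set.seed(seed)
    grid <- truth$grid
    n <- binCount(grid)
    m <- nrow(fractionParams)
    counts <- matrix(0, n, m)
    rpkm <- matrix(0, n, m)
    binKb <- numeric(0)
    for (chrom in chromNames(grid))
        binKb <- c(binKb, .binWidths(grid, chrom) / 1e3)
    for (f in seq_len(m)) {
        mu <- exp(fractionParams$a[f] + fractionParams$b[f] * truth$u) *
            depth
        counts[, f] <- if (is.infinite(dispersion)) rpois(n, mu)
                       else rnbinom(n, mu = mu, size = dispersion)
        total <- sum(counts[, f])
        if (total == 0) stop("fraction ", f, " drew zero total reads")
        rpkm[, f] <- counts[, f] / (total / 1e6) / binKb
    }
    fm <- FractionMatrix(grid, rpkm, fractionParams$fraction)
    attr(fm, "counts") <- counts
    fm
}

#' Simulate a toy Hi-C contact matrix from a truth
#'
#' Distance decay modulated by compartment affinity:
#' \eqn{\lambda_{ij} = depth \cdot \max(|i-j|, 1)^{-decay} \cdot
#' (1 + affinity \cdot u_i u_j)}, counts Poisson, symmetric. The truth is
#' first rebinned to `binSize` (mean u per coarse bin).
#'
#' @param truth a `SyntheticTruth`.
#' @param binSize contact bin size (default 250000).
#' @param decayExponent power-law decay of contacts with distance
#'   (default 1).
#' @param affinity compartment affinity in [0, 1) (default 0.7).
#' @param depth expected contact count at distance 1 for neutral bins
#'   (default 100).
#' @param seed RNG seed.
#' @return a [ContactMatrix-class] on the coarse grid.
#' @export
simulateContacts <- function(truth, binSize = 250000, decayExponent = 1,
                             affinity = 0.7, depth = 100, seed) {
    stopifnot(affinity >= 0, affinity < 1)
    set.seed(seed)
    coarse <- truthAtResolution(truth, binSize)
    grid <- coarse$grid
    counts <- list()
    for (chrom in chromNames(grid)) {
        idx <- chromBinIndices(grid, chrom)
        u <- coarse$u[idx]
        n <- length(u)
        d <- pmax(abs(row(matrix(0, n, n)) - col(matrix(0, n, n))), 1)
        lam <- depth * d^(-decayExponent) * (1 + affinity * (u %o% u))
        lam[lam < 0] <- 0
        up <- upper.tri(lam, diag = TRUE)
        m <- matrix(0, n, n)
        m[up] <- rpois(sum(up), lam[up])
        m <- pmax(m, t(m))
        counts[[chrom]] <- m
    }
    ContactMatrix(grid, counts)
}

#' Simulate chromatin-state segments from a truth
#'
#' Per bin, draws one of three toy states with probabilities conditioned
#' on openness: P(Active) = (1 - pQuies)(1 + u)/2, P(Repressed) =
#' (1 - pQuies)(1 - u)/2, P(Quies) = pQuies. With
#' `deterministic = TRUE` the state is Active where u > 0 and Repressed
#' where u < 0 (so states exactly tile the sign of u). Adjacent bins with
#' the same state are merged into one segment.
#'
#' @param truth a `SyntheticTruth`.
#' @param pQuies probability of the neutral Quies state (default 0.2).
#' @param deterministic make the draw degenerate (default FALSE).
#' @param seed RNG seed.
#' @return `GRanges` with a `name` column of state labels.
#' @export
simulateStates <- function(truth, pQuies = 0.2, deterministic = FALSE,
                           seed) {
    set.seed(seed)
    grid <- truth$grid
    if (binCount(grid) == 0)
        return(GenomicRanges::GRanges())
    states <- character(binCount(grid))
    for (chrom in chromNames(grid)) {
        idx <- chromBinIndices(grid, chrom)
        u <- truth$u[idx]
        if (deterministic) {
            states[idx] <- ifelse(u > 0, "Active", "Repressed")
        } else {
            pA <- (1 - pQuies) * (1 + u) / 2
            pR <- (1 - pQuies) * (1 - u) / 2
            r <- runif(length(u))
            states[idx] <- ifelse(r < pA, "Active",
                                  ifelse(r < pA + pR, "Repressed",
                                         "Quies"))
        }
    }
    bins <- gridBins(grid)
    chromV <- as.character(GenomeInfoDb::seqnames(bins))
    newSeg <- c(TRUE, states[-1] != states[-length(states)] |
                      chromV[-1] != chromV[-length(chromV)])
    segId <- cumsum(newSeg)
    st <- tapply(GenomicRanges::start(bins), segId, min)
    en <- tapply(GenomicRanges::end(bins), segId, max)
    lab <- states[newSeg]
    gr <- GenomicRanges::GRanges(chromV[newSeg],
                                 IRanges::IRanges(st, en))
    gr$name <- lab
    gr
}

#' Default two-chromosome simulation scenario
#'
#' 2000 bins of 50 kb over two chromosomes (50 Mb each), mean domain
#' length 20 bins, gene rate 1 per bin, fraction depth 50 with dispersion
#' 10, contacts at 250 kb with decay exponent 1, affinity 0.7, depth 100.
#'
#' @param seed RNG seed; sub-draws use seed, seed+1, ... (keep below
#'   2^31 - 10).
#' @param bins total number of 50 kb bins (default 2000, split over two
#'   chromosomes).
#' @return list with `truth`, `fractions` ([FractionMatrix-class]),
#'   `contacts` ([ContactMatrix-class]), `states` (`GRanges`), and the
#'   component seeds.
#' @export
simulateScenario <- function(seed, bins = 2000) {
    binSize <- 50000
    half <- floor(bins / 2)
    chromSizes <- c(simA = half * binSize, simB = (bins - half) * binSize)
    truth <- simulateGenome(chromSizes, binSize = binSize, seed = seed)
    fractions <- simulateFractionTracks(truth, seed = seed + 1)
    contacts <- simulateContacts(truth, seed = seed + 2)
    states <- simulateStates(truth, seed = seed + 3)
    list(truth = truth, fractions = fractions, contacts = contacts,
         states = states, seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Writes per-fraction bedGraph tracks, a contacts triplet TSV, genes and
#' states BED files, a truth table (TSV with full-precision u), and a
#' JSON manifest. All outputs are deterministic given the scenario.
#'
#' @param sim output of [simulateScenario()].
#' @param dir output directory (created if missing).
#' @return invisible named vector of written paths.
#' @export
writeSimulation <- function(sim, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c()
    grid <- sim$truth$grid
    for (f in fractionNames(sim$fractions)) {
        p <- file.path(dir, paste0("track_", f, ".bedgraph"))
        j <- match(f, fractionNames(sim$fractions))
        writeTrack(BinnedTrack(grid, fractionValues(sim$fractions)[, j],
                               mask = rep(FALSE, binCount(grid))), p)
        paths[paste0("track_", f)] <- p
    }
    paths["contacts"] <- file.path(dir, "contacts.tsv")
    writeContacts(sim$contacts, paths["contacts"])
    paths["genes"] <- file.path(dir, "genes.bed")
    .writeBed(sim$truth$genes, paths[["genes"]])
    paths["states"] <- file.path(dir, "states.bed")
    .writeBed(sim$states, paths[["states"]])
    paths["truth"] <- file.path(dir, "truth.tsv")
    bins <- gridBins(grid)
    writeLines(c("chrom\tstart\tend\tu\tcompartment\tlevel",
                 sprintf("%s\t%d\t%d\t%.17g\t%s\t%d",
                         as.character(GenomeInfoDb::seqnames(bins)),
                         GenomicRanges::start(bins) - 1L,
                         GenomicRanges::end(bins),
                         sim$truth$u,
                         as.character(sim$truth$compartment),
                         sim$truth$level)),
               paths[["truth"]])
    paths["manifest"] <- file.path(dir, "manifest.json")
    jsonlite::write_json(
        list(seed = sim$seed,
             binSize = binSize(grid),
             chromLengths = as.list(chromLengths(grid)),
             fractions = fractionNames(sim$fractions),
             files = as.list(vapply(
                 paths[names(paths) != "manifest"], basename, ""))),
        paths[["manifest"]], auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(paths)
}

.writeBed <- function(gr, path) {
    if (length(gr) == 0) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    name <- if (!is.null(gr$name)) gr$name else "."
    str <- as.character(GenomicRanges::strand(gr))
    str[str == "*"] <- "."
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       as.character(GenomeInfoDb::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr),
                       name, str),
               path)
    invisible(path)
}
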