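# Independent oracles and small fixture builders used across test files.

# dominant eigenvector of the rms-scaled cross-product, by power iteration
powerIterationE1 <- function(C, steps = 10000) {
    C[is.na(C)] <- 0
    s <- sqrt(colMeans(C^2))
    Cs <- sweep(C, 2, s, "/")
    M <- crossprod(Cs)
    set.seed(424242)
    v <- rnorm(nrow(M))
    v <- v / sqrt(sum(v^2))
    for (i in seq_len(steps)) {
        v <- as.numeric(M %*% v)
        v <- v / sqrt(sum(v^2))
    }
    v
}

# textbook Pearson correlation from raw sums
pearsonOracle <- function(a, b) {
    n <- length(a)
    (n * sum(a * b) - sum(a) * sum(b)) /
        sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
}

# profile correlation with pairwise self-entry exclusion, by direct loops
profileCorrelationOracle <- function(m) {
    n <- nrow(m)
    C <- diag(1, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        keep <- setdiff(seq_len(n), c(i, j))
        C[i, j] <- C[j, i] <- pearsonOracle(m[i, keep], m[j, keep])
    }
    C
}

# per-base average of interval values over covered bases of each bin
perBaseBinOracle <- function(starts, ends, values, chromLen, binSize) {
    base <- rep(NA_real_, chromLen)
    for (k in seq_along(starts))
        base[(starts[k] + 1):ends[k]] <- values[k]
    nb <- ceiling(chromLen / binSize)
    vapply(seq_len(nb), function(i) {
        seg <- base[((i - 1) * binSize + 1):min(i * binSize, chromLen)]
        seg <- seg[!is.na(seg)]
        if (length(seg)) mean(seg) else NA_real_
    }, numeric(1))
}

# adjusted Rand index between two labelings
adjustedRand <- function(x, y) {
    tab <- table(x, y)
    a <- sum(choose(tab, 2))
    b <- sum(choose(rowSums(tab), 2))
    c <- sum(choose(colSums(tab), 2))
    n <- sum(tab)
    expd <- b * c / choose(n, 2)
    (a - expd) / ((b + c) / 2 - expd)
}

# scale a vector so max |x| = 1 (valid CompartmentCall eigen values)
scale01 <- function(x) x / max(abs(x))

# small single-chromosome grid
toyGrid <- function(nbins = 10, binSize = 100, name = "chrT") {
    sizes <- setNames(nbins * binSize, name)
    BinGrid(sizes, binSize)
}

# wrap a truth compartment vector as a CompartmentCall for concordance ops
truthCompartmentCall <- function(grid, compartment) {
    eig <- ifelse(compartment == "A", 1, -1)
    eig[is.na(compartment)] <- NA_real_
    new("CompartmentCall", grid = grid, eigen = eig,
        label = factor(as.character(compartment), levels = c("A", "B")))
}

# manual CompartmentCall from label characters (eigen +/-1)
makeCall <- function(grid, labels) {
    truthCompartmentCall(grid, labels)
}

# shared simulation cache so acceptance blocks reuse scenarios
.scenarioCache <- new.env(parent = emptyenv())
cachedScenario <- function(seed) {
    key <- as.character(seed)
    if (is.null(.scenarioCache[[key]]))
        .scenarioCache[[key]] <- simulateScenario(seed)
    .scenarioCache[[key]]
}
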