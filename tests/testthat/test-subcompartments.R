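test_that("Euclidean bin distance matches componentwise brute force", {
    expect_equal(euclideanBinDistance(rbind(c(1, 2), c(1, 2)))[1, 2], 0)
    expect_equal(euclideanBinDistance(rbind(c(3, 4), c(0, 0)))[1, 2], 5)
    set.seed(12)
    x <- matrix(runif(20, 0, 10), 5)
    D <- euclideanBinDistance(x)
    for (i in 1:5) for (j in 1:5)
        expect_equal(D[i, j], sqrt(sum((x[i, ] - x[j, ])^2)),
                     tolerance = 1e-12)
    expect_equal(unname(diag(D)), rep(0, 5))
})

test_that("profile correlation excludes self-entries pairwise", {
    set.seed(4)
    m <- matrix(runif(64), 8); m <- (m + t(m)) / 2; diag(m) <- 0
    C <- profileCorrelation(m)
    O <- profileCorrelationOracle(m)
    expect_equal(C[upper.tri(C)], O[upper.tri(O)], tolerance = 1e-10)
    expect_equal(diag(C), rep(1, 8))
    # identical row structure correlates to 1
    base <- runif(8)
    m3 <- outer(base, rep(1, 8)) + outer(rep(1, 8), base)
    C3 <- profileCorrelation(m3)
    expect_equal(C3[1, 2], 1, tolerance = 1e-9)
})

test_that("block-structured distances give higher within-block correlation", {
    u <- rep(c(0, 5), each = 4)
    x <- cbind(u + runif(8, 0, 0.1), u + runif(8, 0, 0.1))
    D <- euclideanBinDistance(x)
    C <- profileCorrelation(D)
    within <- C[1:4, 1:4][upper.tri(matrix(0, 4, 4))]
    cross <- C[1:4, 5:8]
    expect_gt(min(within), max(cross))
})

test_that("domain detection recovers block junctions", {
    blockCor <- function(sizes) {
        lab <- rep(seq_along(sizes), sizes)
        C <- outer(lab, lab, function(a, b) ifelse(a == b, 0.9, -0.5))
        diag(C) <- 1
        C
    }
    # perfect two-block matrix -> exactly one boundary at the junction
    C2 <- blockCor(c(10, 10))
    dom <- detectDomains(C2, minBins = 5, boundaryQuantile = 0.9)
    expect_equal(nrow(dom), 2)
    expect_equal(dom$end[1], 10)
    # uniform matrix -> single domain with a warning
    U <- matrix(0.8, 20, 20); diag(U) <- 1
    expect_warning(domU <- detectDomains(U, 5, 0.9), "flat")
    expect_equal(nrow(domU), 1)
    # three blocks: both junctions recovered and scores match the
    # windowed-mean oracle
    C3 <- blockCor(c(8, 8, 8))
    dom3 <- detectDomains(C3, minBins = 5, boundaryQuantile = 0.8)
    expect_equal(dom3$end, c(8, 16, 24))
    w <- 5
    score <- sammycomp:::boundaryScore(C3, w)
    oracle <- vapply(1:23, function(k) {
        L <- max(1, k - w + 1):k
        R <- (k + 1):min(24, k + w)
        1 - mean(C3[L, R])
    }, numeric(1))
    expect_equal(score, oracle)
    # domains partition the bins
    expect_equal(sum(dom3$end - dom3$start + 1), 24)
})

test_that("short domains merge into the more-correlated neighbour", {
    lab <- rep(1:3, c(10, 2, 10))
    C <- outer(lab, lab, function(a, b)
        ifelse(a == b, 0.9, ifelse(abs(a - b) == 1 & pmin(a, b) == 2,
                                   0.6, -0.5)))
    # the 2-bin middle block correlates 0.6 with block 3 only
    C[11:12, 13:22] <- 0.6; C[13:22, 11:12] <- 0.6
    C[11:12, 1:10] <- -0.2; C[1:10, 11:12] <- -0.2
    diag(C) <- 1
    dom <- data.frame(start = c(1L, 11L, 13L), end = c(10L, 12L, 22L))
    merged <- sammycomp:::mergeShortDomains(dom, C, 5)
    expect_equal(merged$start, c(1L, 11L))
    expect_equal(merged$end, c(10L, 22L))
})

test_that("binary trend matrix takes along-chromosome first differences", {
    # monotone domain profiles give all-ones / all-zero rows
    Cd4 <- rbind(c(0.10, 0.20, 0.30, 0.40),
                 c(0.20, 0.90, 0.60, 0.50),
                 c(0.30, 0.60, 0.10, 0.95),
                 c(0.40, 0.50, 0.95, 0.20))
    dom <- data.frame(start = 1:4, end = 1:4)
    T <- binaryTrendMatrix(Cd4, dom)
    expect_equal(dim(T), c(4, 3))
    expect_equal(T[1, ], c(1, 1, 1))       # monotonically rising profile
    expect_equal(rev(T[1, ]), (Cd4[1, 4:2] >= Cd4[1, 3:1]) * 1)
    oracle <- (Cd4[, -1] >= Cd4[, -4]) * 1
    expect_equal(unname(T), unname(oracle))
})

test_that("trend embedding is deterministic PCA with oriented loadings", {
    T <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1),
               c(0, 0, 1, 1), c(1, 0, 1, 0))
    expect_warning(emb <- trendEmbedding(T, 10), "fewer domains")
    # duplicated rows embed identically
    expect_equal(emb[1, ], emb[2, ])
    expect_equal(emb[3, ], emb[4, ])
    # the two main patterns separate on component 1
    expect_gt(abs(emb[1, 1] - emb[3, 1]), 1e-6)
    expect_error(trendEmbedding(matrix(1, 4, 3)), "degenerate")
    # PCA optimality: rank-k reconstruction beats random projections
    set.seed(6)
    T2 <- matrix(rbinom(120, 1, 0.5), 12)
    emb2 <- suppressWarnings(trendEmbedding(T2, 5))
    Tc <- sweep(T2, 2, colMeans(T2))
    pcErr <- sum((Tc - emb2 %*% MASS::ginv(emb2) %*% Tc)^2)
    for (r in 1:5) {
        P <- matrix(rnorm(ncol(T2) * 5), ncol = 5)
        S <- Tc %*% P
        randErr <- sum((Tc - S %*% MASS::ginv(S) %*% Tc)^2)
        expect_lte(pcErr, randErr + 1e-9)
    }
})

test_that("bisecting hierarchy splits separated clouds deterministically", {
    # identical embeddings -> a single leaf
    same <- matrix(1, 6, 3)
    tree <- bisectHierarchy(same, depth = 3)
    expect_true(tree$leaf)
    expect_equal(tree$domains, 1:6)
    # two well-separated clouds, depth 1 -> the exact 2-partition
    emb <- rbind(matrix(rnorm(10, 0, 0.05), 5),
                 matrix(rnorm(10, 10, 0.05), 5))
    t1 <- bisectHierarchy(emb, depth = 1)
    parts <- lapply(sammycomp:::leafDomains(t1), sort)
    expect_setequal(parts, list(1:5, 6:10))
    # 8 separated Gaussian clusters are recovered (adjusted Rand >= 0.95)
    ari <- replicate(5, {
        centers <- cbind(seq(0, 70, by = 10), rep(c(0, 30), 4))
        lab <- rep(1:8, each = 6)
        pts <- centers[lab, ] + matrix(rnorm(96, 0, 0.3), ncol = 2)
        tr <- bisectHierarchy(pts, depth = 3)
        leaves <- sammycomp:::leafDomains(tr)
        got <- integer(48)
        for (i in seq_along(leaves)) got[leaves[[i]]] <- i
        adjustedRand(lab, got)
    })
    expect_gte(mean(ari), 0.95)
})

test_that("leaf ranking follows the projection and openness orientation", {
    # domains strung along component 1, genes dense at high values
    emb <- cbind(seq(-4, 4, length.out = 16), rnorm(16, 0, 0.01))
    tree <- bisectHierarchy(emb, depth = 3)
    open <- seq(0, 1, length.out = 16)   # openness rises with comp 1
    rl <- rankAndLabel(tree, emb, open)
    k <- length(rl$leaves)
    expect_lte(k, 8)
    leafMean <- vapply(rl$leaves, function(d) mean(emb[d, 1]), numeric(1))
    expect_true(all(diff(leafMean) > 0))
    expect_equal(rl$labels[1], "B.2.2")
    expect_equal(rl$labels[k], "A.1.1")
    # reversing the openness reference reverses the label order exactly
    rl2 <- rankAndLabel(tree, emb, rev(open))
    expect_equal(lapply(rl2$leaves, sort),
                 lapply(rev(rl$leaves), sort))
    # flat openness warns and leaves order unoriented
    expect_warning(rankAndLabel(tree, emb, rep(0.5, 16)), "flat openness")
})

test_that("sub-compartment calls partition kept bins and are deterministic", {
    sim <- cachedScenario(33)
    call1 <- subCompartmentsFromFractions(sim$fractions, sim$truth$genes)
    call2 <- subCompartmentsFromFractions(sim$fractions, sim$truth$genes)
    expect_identical(subCompartmentLabels(call1),
                     subCompartmentLabels(call2))
    # domains partition kept bins exactly, per chromosome
    for (chrom in names(call1@hierarchy)) {
        h <- call1@hierarchy[[chrom]]
        expect_equal(sum(h$domains$end - h$domains$start + 1),
                     length(h$keep))
    }
    ranks <- subCompartmentRanks(call1)
    labs <- subCompartmentLabels(call1)
    ok <- !is.na(ranks)
    expect_true(all(ranks[ok] == as.integer(labs[ok])))
    expect_true(all(levels(labs) == subCompartmentLevels()))
    # BED output round-trips the labels
    path <- withr::local_tempfile(fileext = ".bed")
    writeSubCompartmentBED(call1, path)
    df <- read.table(path, sep = "\t")
    expect_equal(nrow(df), sum(ok))
    expect_true(all(df$V4 %in% subCompartmentLevels()))
})

test_that("sub-compartment ranks track the latent openness staircase", {
    sim <- cachedScenario(34)
    call <- subCompartmentsFromFractions(sim$fractions, sim$truth$genes)
    ranks <- subCompartmentRanks(call)
    ok <- !is.na(ranks)
    rho <- cor(ranks[ok], sim$truth$level[ok], method = "spearman")
    expect_gte(rho, 0.8)
    # mean latent openness per leaf is essentially monotone in leaf rank
    mu <- tapply(sim$truth$u[ok], ranks[ok], mean)
    expect_lte(sum(diff(mu[order(as.integer(names(mu)))]) < 0), 1)
})

test_that("hi-c path sub-compartments agree with the fraction path", {
    rho <- vapply(33:35, function(s) {
        sim <- cachedScenario(s)
        fr <- subCompartmentsFromFractions(sim$fractions, sim$truth$genes)
        # contacts at the 50 kb truth resolution for a like-for-like run
        cm <- simulateContacts(sim$truth, binSize = 50000,
                               seed = sim$seed + 9)
        hc <- subCompartmentsFromContacts(cm, sim$truth$genes)
        ok <- !is.na(subCompartmentRanks(fr)) &
            !is.na(subCompartmentRanks(hc))
        cor(subCompartmentRanks(fr)[ok], subCompartmentRanks(hc)[ok],
            method = "spearman")
    }, numeric(1))
    expect_gte(mean(rho), 0.7)
})
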