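test_that("single-layer tensor reduces to the Newman modularity matrix", {
    A <- matrix(0, 4, 4)
    A[1, 2] <- A[2, 1] <- 1
    A[3, 4] <- A[4, 3] <- 1
    bt <- buildModularityTensor(array(A, c(4, 4, 1)),
                                qualityParams(omega = 0))
    k <- rowSums(A)
    B <- A - tcrossprod(k) / sum(k)
    expect_equal(as.matrix(bt@supra), B, ignore_attr = TRUE)
    expect_equal(bt@twomu, sum(k))
})

test_that("omega = 0 leaves decoupled layer blocks", {
    A <- matrix(0, 3, 3)
    A[1, 2] <- A[2, 1] <- 1
    A[2, 3] <- A[3, 2] <- 1
    bt <- buildModularityTensor(array(A, c(3, 3, 2)),
                                qualityParams(omega = 0))
    sup <- as.matrix(bt@supra)
    expect_true(all(sup[1:3, 4:6] == 0))
    expect_true(all(sup[4:6, 1:3] == 0))
})

test_that("ordinal coupling inserts exactly 2 N (L-1) interlayer entries", {
    set.seed(3)
    N <- 5L
    L <- 3L
    a <- array(0, c(N, N, L))
    for (l in seq_len(L)) {
        r <- abs(cor(matrix(rnorm(30 * N), 30, N)))
        diag(r) <- 0
        a[, , l] <- r
    }
    bt <- buildModularityTensor(a, qualityParams(omega = 1))
    sup <- as.matrix(bt@supra)
    # brute-force scan of all off-block entries
    inter <- 0L
    for (i in seq_len(N * L)) for (j in seq_len(N * L)) {
        li <- (i - 1L) %/% N
        lj <- (j - 1L) %/% N
        if (li != lj && sup[i, j] != 0) {
            inter <- inter + 1L
            expect_equal(sup[i, j], 1)
            expect_equal((i - 1L) %% N, (j - 1L) %% N) # same node only
            expect_equal(abs(li - lj), 1L)             # adjacent only
        }
    }
    expect_equal(inter, 2L * N * (L - 1L))
    # categorical couples all pairs
    btc <- buildModularityTensor(a, qualityParams(omega = 1,
                                                  coupling = "categorical"))
    expect_equal(Matrix::nnzero(btc@supra) - Matrix::nnzero(bt@supra),
                 2L * N * choose(L, 2L) - 2L * N * (L - 1L))
})

test_that("clean planted cliques give a constant partition, zero flexibility", {
    A <- matrix(0, 8, 8)
    A[1:4, 1:4] <- 1
    A[5:8, 5:8] <- 1
    diag(A) <- 0
    p <- louvainMultilayer(buildModularityTensor(array(rep(A, 3),
                                                       c(8, 8, 3))),
                           seed = 2)
    S <- partitionMatrix(p)
    expect_equal(length(unique(S[1:4, 1L])), 1L)
    expect_equal(length(unique(S[5:8, 1L])), 1L)
    expect_false(S[1L, 1L] == S[5L, 1L])
    expect_true(all(S == S[, 1L]))
    expect_equal(flexibility(p), rep(0, 8))
})

test_that("optimizer attains the exhaustive single-layer optimum", {
    set.seed(11)
    for (rep in seq_len(6L)) {
        n <- sample(5:7, 1L)
        A <- randomConnectedGraph(n)
        qStar <- exhaustiveModularity(A)
        bt <- buildModularityTensor(array(A, c(n, n, 1)),
                                    qualityParams(omega = 0))
        qBest <- max(sapply(1:10, function(s)
            modularity(louvainMultilayer(bt, seed = s))))
        expect_lt(abs(qBest - qStar), 1e-9)
    }
})

test_that("quality evaluation matches closed forms and direct summation", {
    set.seed(21)
    n <- 6L
    A <- randomConnectedGraph(n)
    bt <- buildModularityTensor(array(A, c(n, n, 1)),
                                qualityParams(omega = 0))
    # all nodes in one community: sum(B) = 0 at gamma 1
    one <- matrix(1L, n, 1L)
    expect_equal(evaluateQuality(one, bt), 0, tolerance = 1e-12)
    # all singletons: -gamma * sum(k_i^2) / (2m)^2
    singletons <- matrix(seq_len(n), n, 1L)
    k <- rowSums(A)
    expect_equal(evaluateQuality(singletons, bt),
                 -sum(k^2) / sum(k)^2, tolerance = 1e-12)
    # label-permutation invariance
    perm <- matrix(as.integer(c(5, 3, 1, 6, 2, 4))[singletons], n, 1L)
    expect_equal(evaluateQuality(perm, bt),
                 evaluateQuality(singletons, bt))
})

test_that("multilayer quality matches the raw-stack summation oracle", {
    spec <- toySpec(nRegions = 12L, nTimepoints = 60L)
    ts <- subjects(generateCohort(spec))[[1L]]
    st <- dynamicConnectivity(ts, windowScheme(20, 8))
    bt <- buildModularityTensor(st)
    p <- louvainMultilayer(bt, seed = 5)
    expect_equal(modularity(p), evaluateQuality(p, bt), tolerance = 1e-10)
    expect_equal(modularity(p),
                 directMultilayerQ(partitionMatrix(p), st@tensor),
                 tolerance = 1e-10)
})

test_that("optimizer runs are reproducible and labels canonical", {
    spec <- toySpec(nRegions = 12L, nTimepoints = 60L)
    ts <- subjects(generateCohort(spec))[[1L]]
    bt <- buildModularityTensor(dynamicConnectivity(ts, windowScheme(20, 4)))
    a <- louvainMultilayer(bt, seed = 42)
    b <- louvainMultilayer(bt, seed = 42)
    expect_identical(partitionMatrix(a), partitionMatrix(b))
    # canonical: labels numbered by first appearance scanning layers
    lab <- as.vector(partitionMatrix(a))
    expect_identical(unique(lab), seq_len(max(lab)))
})

test_that("large omega freezes community labels across layers", {
    spec <- toySpec(nRegions = 10L, nTimepoints = 60L,
                    switchRates = c(0.5, 0.5))
    ts <- subjects(generateCohort(spec))[[1L]]
    st <- dynamicConnectivity(ts, windowScheme(20, 4))
    p <- louvainMultilayer(buildModularityTensor(st,
                               qualityParams(omega = 50)), seed = 3)
    expect_equal(max(flexibility(p)), 0)
})

test_that("repeated runs use consecutive seeds and stay stable", {
    spec <- toySpec(nRegions = 12L, nTimepoints = 60L,
                    withinModuleCorr = 0.8, noiseSd = 0.1,
                    switchRates = c(0, 0))
    ts <- subjects(generateCohort(spec))[[1L]]
    st <- dynamicConnectivity(ts, windowScheme(30, 10))
    parts <- repeatPartitions(st, nReps = 5L, baseSeed = 7L)
    expect_length(parts, 5L)
    expect_equal(sapply(parts, function(p) p@seed), 7:11)
    # strong signal: partitions agree across repetitions
    skip_if_not_installed("mclust")
    aris <- utils::combn(5L, 2L, function(ij)
        mclust::adjustedRandIndex(as.vector(partitionMatrix(parts[[ij[1L]]])),
                                  as.vector(partitionMatrix(parts[[ij[2L]]]))))
    expect_gt(mean(aris), 0.9)
})

test_that("degenerate layers are reported", {
    a <- array(0, c(3, 3, 1))
    a[1, 2, 1] <- a[2, 1, 1] <- -1
    expect_error(buildModularityTensor(a), "non-positive total weight")
})
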