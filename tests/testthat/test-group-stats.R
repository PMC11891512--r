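test_that("adjusted t reduces to the pooled two-sample t", {
    x1 <- c(1, 2, 3)
    x2 <- c(4, 5, 6)
    t <- adjustedT(c(x1, x2), rep(1:2, each = 3))
    expect_equal(t, pooledT(x1, x2), tolerance = 1e-12)
    expect_equal(round(t, 3), -3.674)
    # location invariance
    expect_equal(adjustedT(c(x1, x2) + 100, rep(1:2, each = 3)), t)
    # random data vs the oracle
    set.seed(4)
    for (rep in seq_len(20L)) {
        y1 <- rnorm(7)
        y2 <- rnorm(9, mean = 0.5)
        expect_equal(adjustedT(c(y1, y2), rep(1:2, c(7, 9))),
                     pooledT(y1, y2), tolerance = 1e-10)
    }
})

test_that("an imbalanced confound is absorbed by adjustment", {
    set.seed(9)
    group <- rep(1:2, each = 10)
    covar <- c(rep(0, 9), 1, rep(1, 9), 0)
    values <- 5 * covar + rnorm(20, sd = 0.1)  # effect is covariate-only
    tAdj <- adjustedT(values, group, data.frame(c = covar))
    tRaw <- adjustedT(values, group)
    # unadjusted comparison is driven by the confound; adjustment kills it
    expect_gt(abs(tRaw), 5)
    expect_lt(abs(tAdj), 2.5)
    # dual route: the linear-model oracle gives the same statistic
    oracle <- summary(lm(values ~ I(group == 1) + covar))$coefficients[2, 3]
    expect_equal(tAdj, unname(oracle), tolerance = 1e-10)
})

test_that("collinear designs are rejected with the offending column", {
    group <- rep(1:2, each = 5)
    expect_error(adjustedT(rnorm(10), group,
                           data.frame(g2 = as.numeric(group == 1))),
                 "rank deficient")
})

test_that("tiny cohorts switch to exact enumeration", {
    y <- c(0.1, 0.3, 2.5, 2.7)
    group <- c(1, 1, 2, 2)
    expect_warning(res <- permutationTest(y, group,
                                          spec = comparisonSpec(1000L)),
                   "enumerating")
    expect_true(res$exact)
    # 6 assignments; only the observed and its mirror reach |t_obs|
    expect_equal(res$p, 2 / 6, tolerance = 1e-12)
})

test_that("permutation p agrees with the classical t-test under normality", {
    set.seed(14)
    y <- c(rnorm(12), rnorm(12, mean = 1.4))
    group <- rep(1:2, each = 12)
    res <- permutationTest(y, group,
                           spec = comparisonSpec(4000L, seed = 3L))
    classical <- t.test(y[1:12], y[13:24], var.equal = TRUE)$p.value
    expect_lt(abs(res$p - classical), 0.02)
})

test_that("permutation stream is seeded and shared across features", {
    set.seed(21)
    Y <- matrix(rnorm(20 * 3), 20, 3)
    group <- rep(1:2, each = 10)
    a <- permutationTest(Y, group, spec = comparisonSpec(200L, seed = 5L))
    b <- permutationTest(Y, group, spec = comparisonSpec(200L, seed = 5L))
    expect_identical(a$p, b$p)
})

test_that("Benjamini-Hochberg step-up with monotonicity", {
    expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
    expect_equal(fdrAdjust(0.2), 0.2)
    expect_equal(fdrAdjust(rep(1, 5L)), rep(1, 5L))
    p <- c(0.003, 0.04, 0.2, 0.9)
    adj <- fdrAdjust(p)
    expect_true(all(diff(adj[order(p)]) >= 0))
    expect_true(all(adj >= p))
})

test_that("compareGroups detects a planted mean shift at every level", {
    set.seed(33)
    nPer <- 10L
    makeTable <- function(shift) {
        S <- randomLabelMatrix(10L, 12L, 3L)
        nd <- nodeDynamics(S, networkLabels = rep(c("A", "B"), each = 5L))
        nd@table$flexibility <- pmin(pmax(
            nd@table$flexibility + shift + rnorm(10L, sd = 0.02), 0), 1)
        nd@table$cohesion <- nd@table$flexibility - nd@table$disjointedness
        nd
    }
    tables <- c(lapply(seq_len(nPer), function(i) makeTable(-0.2)),
                lapply(seq_len(nPer), function(i) makeTable(0.2)))
    res <- compareGroups(tables, rep(1:2, each = nPer),
                         spec = comparisonSpec(400L, seed = 2L),
                         levels = c("global", "network"))
    glob <- res[res$level == "global" & res$metric == "flexibility", ]
    expect_lt(glob$t, 0)          # group 1 lower -> negative t
    expect_true(glob$significant)
    nets <- res[res$level == "network" & res$metric == "flexibility", ]
    expect_equal(nrow(nets), 2L)
    expect_true(all(nets$p_fdr <= 1 & nets$p_perm > 0))
})
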