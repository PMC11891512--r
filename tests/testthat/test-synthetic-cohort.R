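test_that("switch endpoints: no switching and forced switching", {
    spec0 <- toySpec(switchRates = c(0, 0))
    pp0 <- generatePartitionSequence(spec0, 1, seed = 4)
    expect_true(all(pp0@labels == pp0@labels[, 1L]))

    spec1 <- toySpec(switchRates = c(1, 1), nTimepoints = 60L,
                     epochLength = 30L)
    pp1 <- generatePartitionSequence(spec1, 1, seed = 4)
    expect_equal(ncol(pp1@labels), 2L)
    expect_true(all(pp1@labels[, 1L] != pp1@labels[, 2L]))
})

test_that("planted switch frequency matches the nominal rate", {
    rate <- 0.3
    spec <- cohortSpec(nSubjects = c(1, 1), nRegions = 20L,
                       nTimepoints = 300L, nModules = 4L,
                       epochLength = 30L, switchRates = c(rate, rate),
                       seed = 7L)
    nSeeds <- 200L
    switches <- 0L
    opportunities <- 0L
    for (s in seq_len(nSeeds)) {
        pp <- generatePartitionSequence(spec, 1, seed = s)
        d <- pp@labels[, -1L, drop = FALSE] !=
             pp@labels[, -ncol(pp@labels), drop = FALSE]
        switches <- switches + sum(d)
        opportunities <- opportunities + length(d)
    }
    phat <- switches / opportunities
    tolerance <- 3 * sqrt(rate * (1 - rate) / opportunities)
    # empty-module re-draws perturb the realized rate slightly beyond the
    # pure binomial band, so allow the same margin again
    expect_lt(abs(phat - rate), tolerance + 0.01)
})

test_that("cohesive fraction of planted changes tracks the knob", {
    frac <- sapply(c(0.2, 0.8), function(cf) {
        spec <- cohortSpec(nSubjects = c(1, 1), nRegions = 40L,
                           nTimepoints = 300L, nModules = 4L,
                           epochLength = 30L, switchRates = c(0.4, 0.4),
                           cohesiveFraction = cf, seed = 1L)
        coh <- 0L
        tot <- 0L
        for (s in seq_len(40L)) {
            pp <- generatePartitionSequence(spec, 1, seed = 1000L + s)
            cc <- changeCountOracle(pp@labels)
            coh <- coh + sum(cc$cohesion)
            tot <- tot + sum(cc$cohesion) + sum(cc$disjointedness)
        }
        coh / tot
    })
    expect_lt(frac[1L], frac[2L])
    expect_lt(abs(frac[2L] - 0.8), 0.15)
})

test_that("time-series sampler reproduces the planted correlation", {
    spec <- cohortSpec(nSubjects = c(1, 1), nRegions = 20L,
                       nTimepoints = 500L, nModules = 2L,
                       epochLength = 500L, switchRates = c(0, 0),
                       withinModuleCorr = 0.6, noiseSd = 0.05,
                       seed = 2L)
    pp <- generatePartitionSequence(spec, 1, seed = 3)
    ts <- simulateTimeSeries(pp, spec, seed = 4)
    r <- cor(seriesMatrix(ts))
    lab <- pp@labels[, 1L]
    same <- outer(lab, lab, "==") & upper.tri(r)
    diff <- (!outer(lab, lab, "==")) & upper.tri(r)
    expect_gt(mean(r[same]), 0.5)
    expect_lt(mean(r[same]), 0.7)
    expect_lt(max(abs(r[diff])), 0.25)
})

test_that("generation is deterministic given the seed", {
    spec <- toySpec()
    a <- generateCohort(spec)
    b <- generateCohort(spec)
    expect_identical(seriesMatrix(subjects(a)[[3L]]),
                     seriesMatrix(subjects(b)[[3L]]))
    expect_identical(groundTruth(a)[[2L]]@labels,
                     groundTruth(b)[[2L]]@labels)
    expect_identical(cohortManifest(a), cohortManifest(b))
})

test_that("cohort bookkeeping: groups, sizes, minimal cohort", {
    coh <- generateCohort(cohortSpec(nSubjects = c(13, 14),
                                     nRegions = 10L, nTimepoints = 40L,
                                     nModules = 3L, seed = 9L))
    man <- cohortManifest(coh)
    expect_equal(nrow(man), 27L)
    expect_equal(as.integer(table(man$group)), c(13L, 14L))

    tiny <- generateCohort(toySpec(nSubjects = c(1L, 1L)))
    expect_length(subjects(tiny), 2L)
})

test_that("invalid specifications are rejected", {
    expect_error(cohortSpec(nModules = 30L, nRegions = 20L), "nModules")
    expect_error(cohortSpec(withinModuleCorr = 1.2), "withinModuleCorr")
    expect_error(cohortSpec(epochLength = 1L), "epochLength")
    expect_error(generatePartitionSequence(toySpec(), 3, 1), "groupIndex")
})

test_that("cohort round-trips through the delimited text format", {
    dir <- withr::local_tempdir()
    coh <- generateCohort(toySpec(nSubjects = c(2L, 1L)))
    manifest <- writeCohort(coh, dir)
    back <- readCohort(manifest)
    expect_length(back$subjects, 3L)
    expect_equal(seriesMatrix(back$subjects[[1L]]),
                 seriesMatrix(subjects(coh)[[1L]]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_identical(networkLabels(back$subjects[[2L]]),
                     networkLabels(subjects(coh)[[2L]]))
})
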