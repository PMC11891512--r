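test_that("flexibility counts transitions over L - 1", {
    expect_equal(flexibility(matrix(rep(1L, 201), 1)), 0)
    expect_equal(flexibility(matrix(rep(c(1L, 2L), length.out = 201), 1)), 1)
    expect_equal(flexibility(matrix(c(1L, 1L, 2L, 2L, 3L), 1)), 0.5)
    expect_error(flexibility(matrix(1L, 3, 1)), "single layer")
})

test_that("promiscuity is distinct-labels over total communities", {
    S <- rbind(c(1L, 1L, 2L), c(2L, 2L, 2L), c(3L, 1L, 1L))
    expect_equal(promiscuity(S), c(2 / 3, 1 / 3, 2 / 3))
    # endpoints: every community visited -> 1; constant -> 1/C
    S2 <- rbind(c(1L, 2L, 3L, 4L), c(1L, 1L, 1L, 1L))
    expect_equal(promiscuity(S2), c(1, 1 / 4))
})

test_that("cohesive and disjoint moves are told apart", {
    S <- rbind(c(1L, 2L), c(1L, 2L), c(3L, 3L))
    ch <- classifyChanges(S)
    expect_equal(ch$cohesion, c(1, 1, 0))
    expect_equal(ch$disjointedness, c(0, 0, 0))

    S2 <- rbind(c(1L, 2L), c(1L, 1L), c(3L, 3L))
    ch2 <- classifyChanges(S2)
    expect_equal(ch2$cohesion, c(0, 0, 0))
    expect_equal(ch2$disjointedness, c(1, 0, 0))
})

test_that("flexibility = cohesion + disjointedness on random partitions", {
    set.seed(99)
    for (rep in seq_len(500L)) {
        S <- randomLabelMatrix(10L, 20L, sample(2:6, 1L))
        ch <- classifyChanges(S)
        expect_equal(ch$cohesion + ch$disjointedness, flexibility(S),
                     tolerance = 1e-12)
    }
})

test_that("classification matches the loop-based counting oracle", {
    set.seed(17)
    for (rep in seq_len(25L)) {
        S <- randomLabelMatrix(8L, 12L, 3L)
        got <- classifyChanges(S)
        want <- changeCountOracle(S)
        expect_equal(got$cohesion, want$cohesion)
        expect_equal(got$disjointedness, want$disjointedness)
    }
})

test_that("metrics stay in [0, 1] and promiscuity above 1/C", {
    set.seed(31)
    for (rep in seq_len(50L)) {
        S <- randomLabelMatrix(12L, 15L, 4L)
        C <- length(unique(as.vector(S)))
        vals <- c(flexibility(S), promiscuity(S),
                  unlist(classifyChanges(S)))
        expect_true(all(vals >= 0 & vals <= 1))
        expect_true(all(promiscuity(S) >= 1 / C))
    }
})

test_that("averaging over repetitions is the element-wise mean", {
    t1 <- nodeDynamics(rbind(c(1L, 2L, 2L), c(1L, 1L, 1L)))
    t2 <- nodeDynamics(rbind(c(1L, 1L, 2L), c(2L, 1L, 1L)))
    avg <- averageOverRepetitions(list(t1, t2))
    expect_equal(metricsTable(avg)$flexibility,
                 (metricsTable(t1)$flexibility +
                  metricsTable(t2)$flexibility) / 2)
    expect_equal(avg@nReps, 2L)
    # identity preserved through the mean
    m <- metricsTable(avg)
    expect_equal(m$flexibility, m$cohesion + m$disjointedness)
    # idempotence
    same <- averageOverRepetitions(list(t1, t1))
    expect_equal(metricsTable(same)$flexibility,
                 metricsTable(t1)$flexibility)
})

test_that("aggregation takes unweighted means per network and globally", {
    S <- rbind(c(1L, 2L), c(1L, 1L), c(2L, 2L), c(2L, 1L), c(1L, 1L),
               c(1L, 2L), c(2L, 2L), c(1L, 1L), c(2L, 1L), c(1L, 1L))
    nets <- c(rep("A", 3L), rep("B", 7L))
    nd <- nodeDynamics(S, networkLabels = nets)
    agg <- aggregateDynamics(nd)
    m <- metricsTable(nd)
    flexA <- mean(m$flexibility[1:3])
    flexB <- mean(m$flexibility[4:10])
    get <- function(level, unit) agg$value[agg$level == level &
                                           agg$unit == unit &
                                           agg$metric == "flexibility"]
    expect_equal(get("network", "A"), flexA)
    expect_equal(get("network", "B"), flexB)
    expect_equal(get("global", "all"), mean(m$flexibility))
    # constant input: every mean equals the constant
    constant <- nodeDynamics(matrix(1L, 5, 4),
                             networkLabels = c("A", "A", "B", "B", "B"))
    aggc <- aggregateDynamics(constant)
    expect_true(all(aggc$value[aggc$metric == "flexibility"] == 0))
})

test_that("higher planted switch rates yield higher recovered flexibility", {
    rates <- c(0.02, 0.15, 0.45)
    flex <- sapply(rates, function(r) {
        vals <- sapply(1:4, function(s) {
            spec <- cohortSpec(nSubjects = c(1, 1), nRegions = 16L,
                               nTimepoints = 120L, nModules = 4L,
                               switchRates = c(r, r),
                               withinModuleCorr = 0.7, noiseSd = 0.2,
                               seed = 100L + s)
            pp <- generatePartitionSequence(spec, 1, seed = 10L + s)
            ts <- simulateTimeSeries(pp, spec, seed = 20L + s)
            st <- dynamicConnectivity(ts, windowScheme(30, 2))
            parts <- repeatPartitions(st, nReps = 3L, baseSeed = s)
            mean(metricsTable(dynamicsFromPartitions(parts))$flexibility)
        })
        mean(vals)
    })
    expect_true(all(diff(flex) > 0))
})
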