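# Cohort-level experiment helpers shared by the recovery and calibration
# tests: simulate a cohort, push every subject through the per-subject
# chain, and compare groups on the global mean of one metric.

cohortGlobalComparison <- function(spec, width = 30L, step = 1L,
                                   nReps = 10L, nPerm = 1000L,
                                   metrics = "flexibility",
                                   statSeed = 1L,
                                   negativeEdges = "zero") {
    coh <- generateCohort(spec)
    man <- cohortManifest(coh)
    scheme <- windowScheme(width, step)
    tables <- lapply(seq_along(subjects(coh)), function(s)
        subjectDynamics(subjects(coh)[[s]], scheme,
                        nReps = nReps, baseSeed = spec@seed + 37L * s,
                        negativeEdges = negativeEdges))
    covs <- man[, c("age", "gender", "mean_fd")]
    compareGroups(tables, man$group, covs,
                  comparisonSpec(nPerm, seed = statSeed),
                  levels = "global", metrics = metrics)
}
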