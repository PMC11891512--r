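#' Per-subject analysis: dFC to averaged node dynamics
#'
#' Runs the complete single-subject chain: sliding-window connectivity,
#' supra-modularity matrix, repeated Louvain optimization, per-repetition
#' metrics and averaging.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param scheme a [WindowScheme-class].
#' @param params a [QualityParams-class].
#' @param nReps optimizer repetitions.
#' @param baseSeed first optimizer seed.
#' @param negativeEdges negative-edge policy forwarded to
#'   [dynamicConnectivity()].
#' @return a [NodeDynamicsTable-class].
#' @export
subjectDynamics <- function(ts, scheme = windowScheme(),
                            params = qualityParams(), nReps = 100L,
                            baseSeed = 1L, negativeEdges = "keep") {
    stack <- dynamicConnectivity(ts, scheme, negativeEdges = negativeEdges)
    tensor <- buildModularityTensor(stack, params)
    parts <- repeatPartitions(tensor, nReps = nReps, baseSeed = baseSeed)
    dynamicsFromPartitions(parts, regionIds = regionIds(ts),
                           networkLabels = networkLabels(ts))
}

#' Pipeline configuration
#'
#' Assembles (and validates) the settings of a full run. Matches the YAML
#' configuration consumed by the command-line wrapper; every field can be
#' overridden programmatically.
#'
#' @param manifest path to a cohort manifest JSON (as written by
#'   [writeCohort()]), or `NULL` to simulate a cohort from `cohort`.
#' @param cohort a [CohortSpec-class] used when no manifest is given.
#' @param width,step sliding-window scheme.
#' @param gamma,omega,coupling quality-function parameters.
#' @param nReps optimizer repetitions per subject.
#' @param nPermutations permutations of the group test.
#' @param coreFraction core/periphery quantile fraction.
#' @param covariateNames manifest columns used as nuisance covariates in
#'   the group comparison; use `character(0)` for an unadjusted test
#'   (small cohorts may not have the degrees of freedom for the full
#'   default set).
#' @param negativeEdges negative-edge policy.
#' @param seed master seed for optimizer and permutation streams.
#' @param outputDir where result tables are written.
#' @param sweep list of `c(width, step)` pairs for [runSweep()].
#' @return a named list.
#' @export
pipelineConfig <- function(manifest = NULL, cohort = NULL,
                           width = 30L, step = 1L,
                           gamma = 1, omega = 1, coupling = "ordinal",
                           nReps = 100L, nPermutations = 5000L,
                           coreFraction = 0.10,
                           covariateNames = c("age", "gender", "mean_fd"),
                           negativeEdges = "keep",
                           seed = 1L, outputDir = "dynetflex_results",
                           sweep = list(c(30L, 1L), c(30L, 2L),
                                        c(40L, 1L), c(20L, 1L))) {
    if (is.null(manifest) && is.null(cohort))
        stopf("either a manifest path or a cohort spec is required")
    if (!is.null(manifest) && !file.exists(manifest))
        stopf("manifest '%s' does not exist", manifest)
    list(manifest = manifest, cohort = cohort,
         width = as.integer(width), step = as.integer(step),
         gamma = gamma, omega = omega, coupling = coupling,
         nReps = as.integer(nReps),
         nPermutations = as.integer(nPermutations),
         coreFraction = coreFraction,
         covariateNames = covariateNames, negativeEdges = negativeEdges,
         seed = as.integer(seed), outputDir = outputDir, sweep = sweep)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()] (snake_case accepted).
#'
#' @param path YAML file.
#' @param overrides named list of values taking precedence over the file.
#' @return a configuration list.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
    raw <- yaml::read_yaml(path)
    names(raw) <- sub("n_reps", "nReps",
                 sub("n_permutations", "nPermutations",
                 sub("core_fraction", "coreFraction",
                 sub("covariate_names", "covariateNames",
                 sub("negative_edges", "negativeEdges",
                 sub("output_dir", "outputDir", names(raw)))))))
    if (!is.null(raw$cohort) && !is(raw$cohort, "CohortSpec"))
        raw$cohort <- do.call(cohortSpec, raw$cohort)
    if (!is.null(raw$covariateNames))
        raw$covariateNames <- as.character(unlist(raw$covariateNames))
    raw[names(overrides)] <- overrides
    do.call(pipelineConfig, raw)
}

loadOrSimulateCohort <- function(config) {
    if (!is.null(config$manifest)) {
        loaded <- readCohort(config$manifest)
        list(subjects = loaded$subjects,
             manifest = loaded$manifest)
    } else {
        coh <- generateCohort(config$cohort)
        list(subjects = subjects(coh), manifest = cohortManifest(coh))
    }
}

#' Run the full pipeline
#'
#' For every subject: dFC stack, repeated multilayer community detection
#' and averaged node dynamics. Then cohort-level aggregation, per-group
#' temporal core-periphery maps, and covariate-adjusted permutation
#' statistics at the global, network and nodal levels. All tables are
#' written as tab-separated text under `config$outputDir`, together with
#' a JSON run report recording parameters and seeds.
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()].
#' @param levels statistic levels to compute.
#' @param writeOutputs set `FALSE` to skip writing files.
#' @return invisibly, a list with `nodeTables`, `aggregates`, `stats`,
#'   `corePeriphery` and `manifest`.
#' @export
runPipeline <- function(config, levels = c("global", "network", "nodal"),
                        writeOutputs = TRUE) {
    cohort <- loadOrSimulateCohort(config)
    subjectsList <- cohort$subjects
    man <- cohort$manifest
    scheme <- windowScheme(config$width, config$step)
    params <- qualityParams(config$gamma, config$omega, config$coupling)
    seeds <- deriveSeeds(config$seed, length(subjectsList), salt = 11L)

    nodeTables <- vector("list", length(subjectsList))
    for (s in seq_along(subjectsList)) {
        nodeTables[[s]] <- tryCatch(
            subjectDynamics(subjectsList[[s]], scheme, params,
                            nReps = config$nReps, baseSeed = seeds[s],
                            negativeEdges = config$negativeEdges),
            error = function(e) stopf("subject %s failed at %s",
                                      man$subject[s], conditionMessage(e)))
    }

    aggregates <- lapply(seq_along(nodeTables), function(s) {
        agg <- aggregateDynamics(nodeTables[[s]])
        cbind(subject = man$subject[s], group = man$group[s], agg)
    })
    aggregates <- do.call(rbind, aggregates)

    covs <- man[, intersect(config$covariateNames, names(man)),
                drop = FALSE]
    if (!ncol(covs)) covs <- NULL
    stats <- compareGroups(nodeTables, man$group, covs,
                           comparisonSpec(config$nPermutations,
                                          seed = config$seed),
                           levels = levels)

    corePeriphery <- lapply(split(seq_along(nodeTables), man$group),
        function(idx) {
            flexMean <- rowMeans(vapply(nodeTables[idx], function(tb)
                tb@table$flexibility, numeric(nrow(nodeTables[[1L]]@table))))
            assign <- assignCorePeriphery(flexMean, config$coreFraction,
                regionIds = nodeTables[[1L]]@table$region)
            comp <- networkComposition(assign,
                nodeTables[[1L]]@table$network)
            list(assignment = assign, composition = comp)
        })

    result <- list(nodeTables = nodeTables, aggregates = aggregates,
                   stats = stats, corePeriphery = corePeriphery,
                   manifest = man)
    if (writeOutputs) writePipelineOutputs(result, config)
    invisible(result)
}

writePipelineOutputs <- function(result, config) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$outputDir, name)
    nodeLong <- do.call(rbind, lapply(seq_along(result$nodeTables),
        function(s) cbind(subject = result$manifest$subject[s],
                          result$nodeTables[[s]]@table)))
    utils::write.table(nodeLong, out("node_dynamics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(result$aggregates, out("aggregate_dynamics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(result$stats, out("group_statistics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in names(result$corePeriphery)) {
        cp <- result$corePeriphery[[g]]
        utils::write.table(cp$assignment,
                           out(sprintf("core_periphery_group%s.tsv", g)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(cp$composition,
                           out(sprintf("composition_group%s.tsv", g)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(list(
        package_version = as.character(utils::packageVersion("dynetflex")),
        width = config$width, step = config$step,
        gamma = config$gamma, omega = config$omega,
        coupling = config$coupling, n_reps = config$nReps,
        n_permutations = config$nPermutations,
        core_fraction = config$coreFraction,
        negative_edges = config$negativeEdges, seed = config$seed,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
        out("run_report.json"), auto_unbox = TRUE, digits = NA)
    invisible(NULL)
}

#' Window-parameter robustness sweep
#'
#' Re-runs the full pipeline for each `(width, step)` setting with shared
#' seeds and reports the cross-setting Spearman rank correlation of
#' per-subject global metrics plus the sign of the global group t
#' statistic per setting.
#'
#' @param config a pipeline configuration; `config$sweep` supplies the
#'   settings (at least two).
#' @param metric global metric used for the concordance table.
#' @return list with `runs` (per-setting pipeline results),
#'   `concordance` (pairwise rank correlations) and `tSigns`
#'   (data.frame of global t statistics per setting and metric).
#' @export
runSweep <- function(config, metric = "flexibility") {
    settings <- config$sweep
    if (length(settings) < 2L)
        stopf("a sweep needs at least two (width, step) settings")
    runs <- list()
    globals <- list()
    tRows <- list()
    for (st in settings) {
        cfg <- config
        cfg$width <- st[1L]
        cfg$step <- st[2L]
        key <- sprintf("w%d_s%d", st[1L], st[2L])
        cfg$outputDir <- file.path(config$outputDir, key)
        res <- runPipeline(cfg, levels = "global",
                           writeOutputs = FALSE)
        runs[[key]] <- res
        globals[[key]] <- vapply(res$nodeTables, function(tb)
            mean(tb@table[[metric]]), numeric(1L))
        gstats <- res$stats[res$stats$level == "global", ]
        tRows[[key]] <- data.frame(setting = key,
                                   metric = gstats$metric, t = gstats$t,
                                   stringsAsFactors = FALSE)
    }
    keys <- names(globals)
    conc <- list()
    for (a in seq_along(keys)) for (b in seq_along(keys)) if (a < b) {
        conc[[length(conc) + 1L]] <- data.frame(
            setting_a = keys[a], setting_b = keys[b],
            spearman = stats::cor(globals[[keys[a]]], globals[[keys[b]]],
                                  method = "spearman"),
            stringsAsFactors = FALSE)
    }
    list(runs = runs, concordance = do.call(rbind, conc),
         tSigns = do.call(rbind, tRows))
}
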