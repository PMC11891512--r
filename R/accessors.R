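#' Extract the community-assignment matrix
#'
#' @param x a [MultilayerPartition-class].
#' @return integer matrix, regions x layers.
#' @export
setGeneric("partitionMatrix", function(x) standardGeneric("partitionMatrix"))

#' @rdname partitionMatrix
#' @export
setMethod("partitionMatrix", "MultilayerPartition", function(x) x@S)

#' Modularity value of a partition
#'
#' @param x a [MultilayerPartition-class].
#' @return the quality value Q.
#' @export
setGeneric("modularity", function(x) standardGeneric("modularity"))

#' @rdname modularity
#' @export
setMethod("modularity", "MultilayerPartition", function(x) x@Q)

#' Region identifiers
#'
#' @param x a [SubjectTimeSeries-class] or [DynamicConnectivityStack-class].
#' @return character vector of region ids.
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))

#' @rdname regionIds
#' @export
setMethod("regionIds", "SubjectTimeSeries", function(x) x@regionIds)

#' @rdname regionIds
#' @export
setMethod("regionIds", "DynamicConnectivityStack", function(x) x@regionIds)

#' Functional-network labels per region
#'
#' @param x a [SubjectTimeSeries-class].
#' @return character vector of network names.
#' @export
setGeneric("networkLabels", function(x) standardGeneric("networkLabels"))

#' @rdname networkLabels
#' @export
setMethod("networkLabels", "SubjectTimeSeries", function(x) x@networkLabels)

#' Signal matrix of a subject (time x regions)
#'
#' @param x a [SubjectTimeSeries-class].
#' @return numeric matrix.
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))

#' @rdname seriesMatrix
#' @export
setMethod("seriesMatrix", "SubjectTimeSeries", function(x) x@data)

#' Subject covariates
#'
#' @param x a [SubjectTimeSeries-class].
#' @return named list with `age`, `gender` and `mean_fd`.
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname covariates
#' @export
setMethod("covariates", "SubjectTimeSeries", function(x) x@covariates)

#' Edge-weight tensor of a connectivity stack
#'
#' @param x a [DynamicConnectivityStack-class].
#' @return numeric array, regions x regions x layers.
#' @export
setGeneric("connectivityTensor", function(x) standardGeneric("connectivityTensor"))

#' @rdname connectivityTensor
#' @export
setMethod("connectivityTensor", "DynamicConnectivityStack",
          function(x) x@tensor)

#' Number of layers (windows)
#'
#' @param x a [DynamicConnectivityStack-class] or [ModularityTensor-class].
#' @return integer.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname nLayers
#' @export
setMethod("nLayers", "DynamicConnectivityStack",
          function(x) dim(x@tensor)[3L])

#' @rdname nLayers
#' @export
setMethod("nLayers", "ModularityTensor", function(x) x@nLayers)

#' Per-node metric table
#'
#' @param x a [NodeDynamicsTable-class].
#' @return data.frame with one row per region.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname metricsTable
#' @export
setMethod("metricsTable", "NodeDynamicsTable", function(x) x@table)

#' Subjects of a cohort
#'
#' @param x a [Cohort-class].
#' @return list of [SubjectTimeSeries-class] objects.
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname subjects
#' @export
setMethod("subjects", "Cohort", function(x) x@subjects)

#' Cohort manifest
#'
#' @param x a [Cohort-class].
#' @return data.frame listing subject id, group, covariates and seeds.
#' @export
setGeneric("cohortManifest", function(x) standardGeneric("cohortManifest"))

#' @rdname cohortManifest
#' @export
setMethod("cohortManifest", "Cohort", function(x) x@manifest)

#' Planted partition sequences of a cohort
#'
#' @param x a [Cohort-class].
#' @return list of [PlantedPartitionSequence-class] objects.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "Cohort", function(x) x@truth)

setMethod("show", "CohortSpec", function(object) {
    cat("CohortSpec:", sum(object@nSubjects), "subjects (",
        object@nSubjects[1L], "+", object@nSubjects[2L], "),",
        object@nRegions, "regions x", object@nTimepoints, "time points\n")
    cat("  modules:", object@nModules, " epoch length:", object@epochLength,
        " switch rates:", paste(object@switchRates, collapse = "/"), "\n")
    cat("  cohesive fraction:", object@cohesiveFraction,
        " within-module corr:", object@withinModuleCorr,
        " noise sd:", object@noiseSd, "\n")
})

setMethod("show", "SubjectTimeSeries", function(object) {
    cat("SubjectTimeSeries", object@subjectId, "- group",
        object@group, "\n")
    cat("  ", nrow(object@data), "time points x", ncol(object@data),
        "regions,", length(unique(object@networkLabels)), "networks\n")
})

setMethod("show", "Cohort", function(object) {
    cat("Cohort of", length(object@subjects), "subjects (",
        object@spec@nSubjects[1L], "+", object@spec@nSubjects[2L], ")\n")
})

setMethod("show", "DynamicConnectivityStack", function(object) {
    d <- dim(object@tensor)
    cat("DynamicConnectivityStack:", d[1L], "x", d[2L], "x", d[3L],
        "(width", object@scheme@width, ", step", object@scheme@step, ")\n")
})

setMethod("show", "ModularityTensor", function(object) {
    cat("ModularityTensor:", object@nNodes, "nodes x", object@nLayers,
        "layers,", Matrix::nnzero(object@supra), "stored entries, 2mu =",
        format(object@twomu), "\n")
})

setMethod("show", "MultilayerPartition", function(object) {
    cat("MultilayerPartition:", nrow(object@S), "regions x", ncol(object@S),
        "layers, C =", max(object@S), ", Q =", format(object@Q), "\n")
})

setMethod("show", "NodeDynamicsTable", function(object) {
    cat("NodeDynamicsTable:", nrow(object@table), "regions, averaged over",
        object@nReps, "repetition(s)\n")
    print(utils::head(object@table, 4L))
    if (nrow(object@table) > 4L) cat("  ...\n")
})
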