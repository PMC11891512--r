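#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Matrix sparseMatrix dgCMatrix
#' @useDynLib dynetflex, .registration = TRUE
NULL

#' Cohort simulation specification
#'
#' Parameters of the two-group synthetic cohort generator. The generator
#' plants piecewise-stationary community structure: region labels are held
#' fixed within epochs of `epochLength` time points and may change at epoch
#' boundaries at a group-specific per-node rate. A switching node either
#' moves together with at least one partner from its source module
#' (a cohesive move, probability `cohesiveFraction`) or moves alone to a
#' module no co-member moves to (a disjoint move).
#'
#' @slot nSubjects integer(2), subjects per group.
#' @slot nRegions number of regions (nodes).
#' @slot nTimepoints number of time points per subject.
#' @slot nModules number of planted modules.
#' @slot epochLength time points per stable community epoch.
#' @slot switchRates numeric(2), per-epoch-boundary probability that a node
#'   changes module, one value per group.
#' @slot cohesiveFraction probability in `[0, 1]` that a planted change is
#'   cohesive rather than solo.
#' @slot withinModuleCorr latent correlation in (0, 1) between same-module
#'   regions within an epoch.
#' @slot noiseSd standard deviation of the independent observation noise
#'   added to the unit-variance latent signal.
#' @slot samplingInterval sampling interval in seconds (the fMRI TR).
#' @slot seed master seed of the cohort.
#'
#' @seealso [cohortSpec()]
#' @exportClass CohortSpec
setClass("CohortSpec",
    slots = c(
        nSubjects = "integer",
        nRegions = "integer",
        nTimepoints = "integer",
        nModules = "integer",
        epochLength = "integer",
        switchRates = "numeric",
        cohesiveFraction = "numeric",
        withinModuleCorr = "numeric",
        noiseSd = "numeric",
        samplingInterval = "numeric",
        seed = "integer"
    )
)

setValidity("CohortSpec", function(object) {
    msg <- character()
    if (length(object@nSubjects) != 2L || any(object@nSubjects < 1L))
        msg <- c(msg, "nSubjects must be two positive integers")
    if (object@nRegions < 2L) msg <- c(msg, "nRegions must be >= 2")
    if (object@nTimepoints < 2L) msg <- c(msg, "nTimepoints must be >= 2")
    if (object@nModules < 2L) msg <- c(msg, "nModules must be >= 2")
    if (object@nModules > object@nRegions)
        msg <- c(msg, "nModules may not exceed nRegions")
    if (object@epochLength < 2L) msg <- c(msg, "epochLength must be >= 2")
    if (length(object@switchRates) != 2L ||
        any(object@switchRates < 0) || any(object@switchRates > 1))
        msg <- c(msg, "switchRates must be two probabilities in [0, 1]")
    if (object@cohesiveFraction < 0 || object@cohesiveFraction > 1)
        msg <- c(msg, "cohesiveFraction must lie in [0, 1]")
    if (object@withinModuleCorr <= 0 || object@withinModuleCorr >= 1)
        msg <- c(msg, "withinModuleCorr must lie in (0, 1)")
    if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
    if (object@samplingInterval <= 0)
        msg <- c(msg, "samplingInterval must be positive")
    if (length(msg)) msg else TRUE
})

#' Planted partition sequence
#'
#' Ground-truth module labels for one subject: one label per region and
#' epoch, together with the epoch start indices (1-based time points).
#'
#' @slot labels integer matrix, regions x epochs, entries in
#'   `1..nModules`.
#' @slot epochStarts strictly increasing 1-based start time of each epoch;
#'   the epochs tile `1..nTimepoints`.
#' @slot nTimepoints series length the sequence covers.
#'
#' @exportClass PlantedPartitionSequence
setClass("PlantedPartitionSequence",
    slots = c(
        labels = "matrix",
        epochStarts = "integer",
        nTimepoints = "integer"
    )
)

setValidity("PlantedPartitionSequence", function(object) {
    msg <- character()
    if (!is.integer(object@labels) || any(object@labels < 1L))
        msg <- c(msg, "labels must be positive integers")
    if (ncol(object@labels) != length(object@epochStarts))
        msg <- c(msg, "one epoch start per label column required")
    if (is.unsorted(object@epochStarts, strictly = TRUE) ||
        object@epochStarts[1L] != 1L)
        msg <- c(msg, "epochStarts must be strictly increasing from 1")
    if (length(msg)) msg else TRUE
})

#' One subject's regional time series
#'
#' The container every downstream stage consumes: a time-by-region signal
#' matrix with region identifiers, a functional-network label per region,
#' and the subject-level covariates used by the group comparison (age in
#' years, gender as a 0/1 code, mean framewise displacement in mm).
#'
#' @slot data numeric matrix, time points (rows) x regions (columns).
#' @slot regionIds character, one identifier per region.
#' @slot networkLabels character, one functional-network name per region.
#' @slot covariates named list with elements `age`, `gender`, `mean_fd`.
#' @slot subjectId subject identifier.
#' @slot group group index (1 or 2) or `NA` for ungrouped data.
#'
#' @exportClass SubjectTimeSeries
setClass("SubjectTimeSeries",
    slots = c(
        data = "matrix",
        regionIds = "character",
        networkLabels = "character",
        covariates = "list",
        subjectId = "character",
        group = "integer"
    )
)

setValidity("SubjectTimeSeries", function(object) {
    msg <- character()
    if (anyNA(object@data)) msg <- c(msg, "data must not contain NA")
    if (ncol(object@data) != length(object@regionIds))
        msg <- c(msg, "one regionId per data column required")
    if (length(object@networkLabels) != length(object@regionIds))
        msg <- c(msg, "one networkLabel per region required")
    need <- c("age", "gender", "mean_fd")
    if (!all(need %in% names(object@covariates)))
        msg <- c(msg, "covariates must contain age, gender and mean_fd")
    if (length(msg)) msg else TRUE
})

#' Synthetic two-group cohort
#'
#' @slot spec the generating [CohortSpec-class].
#' @slot subjects list of [SubjectTimeSeries-class].
#' @slot truth list of [PlantedPartitionSequence-class], one per subject.
#' @slot manifest data.frame: subject id, group, covariates, per-subject
#'   seeds.
#'
#' @exportClass Cohort
setClass("Cohort",
    slots = c(
        spec = "CohortSpec",
        subjects = "list",
        truth = "list",
        manifest = "data.frame"
    )
)

#' Sliding-window scheme
#'
#' @slot width window width in time points.
#' @slot step sliding step in time points.
#' @exportClass WindowScheme
setClass("WindowScheme",
    slots = c(width = "integer", step = "integer")
)

setValidity("WindowScheme", function(object) {
    if (object@width < 2L) return("width must be >= 2")
    if (object@step < 1L) return("step must be >= 1")
    TRUE
})

#' Sliding-window dynamic connectivity stack
#'
#' An N x N x L array of edge weights: slice `l` is the Pearson correlation
#' matrix of the `l`-th window with its diagonal set to zero, so self-edges
#' never enter the modularity normalization.
#'
#' @slot tensor numeric array, regions x regions x layers.
#' @slot regionIds region identifiers.
#' @slot windowStarts 1-based start time point of each window.
#' @slot scheme the [WindowScheme-class] used.
#'
#' @exportClass DynamicConnectivityStack
setClass("DynamicConnectivityStack",
    slots = c(
        tensor = "array",
        regionIds = "character",
        windowStarts = "integer",
        scheme = "WindowScheme"
    )
)

setValidity("DynamicConnectivityStack", function(object) {
    d <- dim(object@tensor)
    if (length(d) != 3L || d[1L] != d[2L])
        return("tensor must be a square N x N x L array")
    if (d[3L] != length(object@windowStarts))
        return("one window start per layer required")
    if (d[1L] != length(object@regionIds))
        return("one regionId per node required")
    TRUE
})

#' Multilayer modularity parameters
#'
#' `gamma` is the intralayer resolution scaling the Newman-Girvan null
#' term (larger favours more, smaller communities); `omega` the interlayer
#' coupling rewarding a node for keeping its community across coupled
#' layers. Coupling topology is ordinal (adjacent windows) by default,
#' with all-pairs categorical coupling as an option.
#'
#' @slot gamma resolution, scalar or one value per layer.
#' @slot omega non-negative interlayer coupling.
#' @slot coupling `"ordinal"` or `"categorical"`.
#' @exportClass QualityParams
setClass("QualityParams",
    slots = c(gamma = "numeric", omega = "numeric", coupling = "character")
)

setValidity("QualityParams", function(object) {
    if (any(object@gamma <= 0)) return("gamma must be positive")
    if (object@omega < 0) return("omega must be non-negative")
    if (!object@coupling %in% c("ordinal", "categorical"))
        return("coupling must be 'ordinal' or 'categorical'")
    TRUE
})

#' Supra-modularity matrix
#'
#' The sparse symmetric (N*L) x (N*L) matrix holding the intralayer
#' modularity blocks `A - gamma * k k' / (2 m)` and the interlayer
#' couplings `omega` on the same-node off-block diagonals, together with
#' the normalizer `2 mu` (total edge weight over all layers plus the total
#' interlayer weight).
#'
#' @slot supra sparse symmetric matrix (Matrix::dgCMatrix).
#' @slot twomu total weight normalizer.
#' @slot nNodes regions per layer.
#' @slot nLayers number of layers.
#' @slot params the [QualityParams-class] used.
#' @exportClass ModularityTensor
setClass("ModularityTensor",
    slots = c(
        supra = "sparseMatrix",
        twomu = "numeric",
        nNodes = "integer",
        nLayers = "integer",
        params = "QualityParams"
    )
)

setValidity("ModularityTensor", function(object) {
    if (object@twomu <= 0) return("twomu must be positive")
    nl <- object@nNodes * object@nLayers
    if (!all(dim(object@supra) == c(nl, nl)))
        return("supra matrix dimension must be (N*L) x (N*L)")
    TRUE
})

#' Multilayer community partition
#'
#' The S matrix of community assignments: one integer label per region
#' (row) and layer (column), canonicalized so labels appear in order of
#' first appearance when scanning layer by layer. `Q` is the value of the
#' multilayer modularity quality function at this partition.
#'
#' @slot S integer matrix, regions x layers.
#' @slot Q modularity of the partition.
#' @slot seed seed of the optimizer run.
#' @slot nSweeps number of local-move sweeps performed.
#' @exportClass MultilayerPartition
setClass("MultilayerPartition",
    slots = c(S = "matrix", Q = "numeric", seed = "integer",
              nSweeps = "integer")
)

setValidity("MultilayerPartition", function(object) {
    if (!is.integer(object@S) || any(object@S < 1L))
        return("S must contain positive integer labels")
    TRUE
})

#' Per-node reconfiguration metrics
#'
#' One row per region with the four dynamic metrics, each in `[0, 1]`,
#' averaged over `nReps` optimizer repetitions. Flexibility equals
#' cohesion + disjointedness exactly, per repetition and after averaging.
#'
#' @slot table data.frame with columns `region`, `network`, `flexibility`,
#'   `promiscuity`, `cohesion`, `disjointedness`.
#' @slot nReps number of optimizer repetitions averaged.
#' @exportClass NodeDynamicsTable
setClass("NodeDynamicsTable",
    slots = c(table = "data.frame", nReps = "integer")
)

setValidity("NodeDynamicsTable", function(object) {
    need <- c("region", "network", "flexibility", "promiscuity",
              "cohesion", "disjointedness")
    if (!all(need %in% names(object@table)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    TRUE
})
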