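#' Node flexibility
#'
#' Fraction of layer transitions at which a node changes community:
#' `F_i = m_i / (L - 1)` with `m_i` the number of transitions
#' `g_{i,l} != g_{i,l+1}`. Ranges from 0 (never changes) to 1 (changes at
#' every transition).
#'
#' @param partition a [MultilayerPartition-class] or an N x L integer
#'   label matrix.
#' @return numeric vector, one value per region.
#' @examples
#' S <- rbind(c(1, 1, 2, 2, 3), c(1, 1, 1, 1, 1))
#' flexibility(S)  # 0.5, 0
#' @export
flexibility <- function(partition) {
    S <- asLabelMatrix(partition)
    L <- ncol(S)
    if (L < 2L) stopf("flexibility undefined for a single layer")
    rowSums(S[, -1L, drop = FALSE] != S[, -L, drop = FALSE]) / (L - 1)
}

#' Node promiscuity
#'
#' Fraction of all detected communities a node ever belongs to:
#' `P_i = c_i / C` where `c_i` counts the distinct labels in row `i` and
#' `C` the distinct labels anywhere in the partition. A node that visits
#' every community scores 1; a node that never leaves its community
#' scores `1 / C` (the attainable minimum).
#'
#' @param partition a [MultilayerPartition-class] or label matrix.
#' @return numeric vector, one value per region.
#' @examples
#' S <- rbind(c(1, 1, 2), c(2, 2, 2), c(3, 1, 1))
#' promiscuity(S)  # 2/3, 1/3, 2/3
#' @export
promiscuity <- function(partition) {
    S <- asLabelMatrix(partition)
    C <- length(unique(as.vector(S)))
    apply(S, 1L, function(row) length(unique(row))) / C
}

#' Classify community changes as cohesive or disjoint
#'
#' At each transition where node `i` changes community, the change is
#' cohesive when at least one other node moves from the same source
#' community to the same destination at that transition, and disjoint
#' when the node moves alone. Both counts are normalized by the `L - 1`
#' change opportunities, so cohesion + disjointedness equals flexibility
#' exactly, node by node.
#'
#' @param partition a [MultilayerPartition-class] or label matrix.
#' @return list with numeric vectors `cohesion` and `disjointedness`.
#' @examples
#' S <- rbind(c(1, 2), c(1, 2), c(3, 3))
#' classifyChanges(S)  # nodes 1-2 cohesive movers, node 3 static
#' @export
classifyChanges <- function(partition) {
    S <- asLabelMatrix(partition)
    n <- nrow(S)
    L <- ncol(S)
    if (L < 2L) stopf("cohesion undefined for a single layer")
    cohesive <- numeric(n)
    disjoint <- numeric(n)
    for (l in seq_len(L - 1L)) {
        from <- S[, l]
        to <- S[, l + 1L]
        changed <- which(from != to)
        if (!length(changed)) next
        key <- paste(from[changed], to[changed])
        shared <- table(key)[key] >= 2L   # a partner made the same move
        cohesive[changed[shared]] <- cohesive[changed[shared]] + 1
        disjoint[changed[!shared]] <- disjoint[changed[!shared]] + 1
    }
    list(cohesion = cohesive / (L - 1), disjointedness = disjoint / (L - 1))
}

asLabelMatrix <- function(partition) {
    S <- if (is(partition, "MultilayerPartition")) partition@S
         else as.matrix(partition)
    storage.mode(S) <- "integer"
    S
}

#' Per-node dynamics of one partition
#'
#' Computes all four reconfiguration metrics for a single optimizer run.
#'
#' @param partition a [MultilayerPartition-class] or label matrix.
#' @param regionIds optional region identifiers.
#' @param networkLabels optional functional-network label per region.
#' @return a [NodeDynamicsTable-class] with `nReps = 1`.
#' @export
nodeDynamics <- function(partition, regionIds = NULL,
                         networkLabels = NULL) {
    S <- asLabelMatrix(partition)
    n <- nrow(S)
    if (is.null(regionIds)) regionIds <- sprintf("roi_%03d", seq_len(n))
    if (is.null(networkLabels)) networkLabels <- rep(NA_character_, n)
    ch <- classifyChanges(S)
    tab <- data.frame(
        region = regionIds,
        network = networkLabels,
        flexibility = flexibility(S),
        promiscuity = promiscuity(S),
        cohesion = ch$cohesion,
        disjointedness = ch$disjointedness,
        stringsAsFactors = FALSE)
    new("NodeDynamicsTable", table = tab, nReps = 1L)
}

#' Average metric tables over optimizer repetitions
#'
#' Element-wise arithmetic mean of the four metrics across repetitions.
#' The additive identity flexibility = cohesion + disjointedness is
#' preserved by linearity.
#'
#' @param tables list of [NodeDynamicsTable-class] over identical regions.
#' @return a [NodeDynamicsTable-class] with `nReps` set to the total
#'   number of repetitions averaged.
#' @export
averageOverRepetitions <- function(tables) {
    stopifnot(length(tables) >= 1L)
    ref <- tables[[1L]]@table
    metrics <- c("flexibility", "promiscuity", "cohesion",
                 "disjointedness")
    acc <- as.matrix(ref[, metrics])
    nReps <- tables[[1L]]@nReps
    if (length(tables) > 1L) for (k in 2L:length(tables)) {
        tab <- tables[[k]]@table
        if (!identical(tab$region, ref$region))
            stopf("repetition %d covers a different region set", k)
        acc <- acc + as.matrix(tab[, metrics])
        nReps <- nReps + tables[[k]]@nReps
    }
    out <- ref
    out[, metrics] <- acc / length(tables)
    new("NodeDynamicsTable", table = out, nReps = as.integer(nReps))
}

#' Compute averaged node dynamics from repeated partitions
#'
#' Convenience wrapper: per-repetition metrics followed by averaging.
#'
#' @param partitions list of [MultilayerPartition-class] (e.g. from
#'   [repeatPartitions()]).
#' @param regionIds,networkLabels forwarded to [nodeDynamics()].
#' @return a [NodeDynamicsTable-class].
#' @export
dynamicsFromPartitions <- function(partitions, regionIds = NULL,
                                   networkLabels = NULL) {
    averageOverRepetitions(lapply(partitions, nodeDynamics,
                                  regionIds = regionIds,
                                  networkLabels = networkLabels))
}

#' Aggregate node metrics to network and global level
#'
#' Unweighted means of every metric over the member nodes of each
#' functional network and over all nodes (global level).
#'
#' @param table a [NodeDynamicsTable-class].
#' @param networkLabels optional replacement network labels; by default
#'   the labels carried in the table are used.
#' @return data.frame with columns `level` (`"global"`/`"network"`),
#'   `unit`, `metric`, `value`.
#' @export
aggregateDynamics <- function(table, networkLabels = NULL) {
    stopifnot(is(table, "NodeDynamicsTable"))
    tab <- table@table
    if (!is.null(networkLabels)) tab$network <- networkLabels
    if (anyNA(tab$network))
        stopf("every region needs a network label for aggregation")
    metrics <- c("flexibility", "promiscuity", "cohesion",
                 "disjointedness")
    rows <- list()
    for (m in metrics) {
        rows[[length(rows) + 1L]] <- data.frame(
            level = "global", unit = "all", metric = m,
            value = mean(tab[[m]]), stringsAsFactors = FALSE)
        nm <- tapply(tab[[m]], tab$network, mean)
        rows[[length(rows) + 1L]] <- data.frame(
            level = "network", unit = names(nm), metric = m,
            value = as.numeric(nm), stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
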