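#' Multilayer modularity parameters
#'
#' @param gamma intralayer resolution (scalar, or one value per layer).
#' @param omega interlayer coupling strength.
#' @param coupling `"ordinal"` (adjacent layers, the temporal-network
#'   convention) or `"categorical"` (all layer pairs).
#' @return a [QualityParams-class].
#' @examples
#' qualityParams()          # gamma = omega = 1, ordinal coupling
#' @export
qualityParams <- function(gamma = 1, omega = 1,
                          coupling = c("ordinal", "categorical")) {
    new("QualityParams", gamma = as.numeric(gamma),
        omega = as.numeric(omega), coupling = match.arg(coupling))
}

#' Build the supra-modularity matrix
#'
#' Assembles the sparse symmetric (N L) x (N L) matrix whose intralayer
#' block for layer `l` is `A_l - gamma_l * k_l k_l' / (2 m_l)` with
#' `k_il = sum_j A_ijl` and `2 m_l = sum_ij A_ijl` (the Newman-Girvan
#' null), and whose interlayer entries couple each node to itself across
#' coupled layers with weight `omega`. The normalizer `2 mu` is the total
#' intralayer weight plus the total interlayer weight.
#'
#' State nodes are ordered layer-major: state index `(l - 1) N + i`.
#'
#' @param stack a [DynamicConnectivityStack-class], or a plain N x N x L
#'   array of symmetric zero-diagonal edge weights.
#' @param params a [QualityParams-class].
#' @return a [ModularityTensor-class].
#' @examples
#' a <- array(0, c(4, 4, 2))
#' a[1, 2, ] <- a[2, 1, ] <- a[3, 4, ] <- a[4, 3, ] <- 1
#' bt <- buildModularityTensor(a, qualityParams(omega = 0.5))
#' bt
#' @export
buildModularityTensor <- function(stack, params = qualityParams()) {
    stopifnot(is(params, "QualityParams"))
    validObject(params)
    tensor <- if (is(stack, "DynamicConnectivityStack")) stack@tensor
              else stack
    d <- dim(tensor)
    if (length(d) != 3L || d[1L] != d[2L])
        stopf("stack must be an N x N x L array")
    n <- d[1L]
    L <- d[3L]
    gamma <- rep_len(params@gamma, L)

    blocks <- vector("list", L)
    intraWeight <- 0
    for (l in seq_len(L)) {
        a <- tensor[, , l]
        k <- rowSums(a)
        twom <- sum(k)
        if (twom <= 0)
            stopf("layer %d has non-positive total weight (2m = %g)%s",
                  l, twom, "; choose another negative-edge policy")
        blocks[[l]] <- a - gamma[l] * tcrossprod(k) / twom
        intraWeight <- intraWeight + twom
    }
    supra <- Matrix::bdiag(blocks)

    omega <- params@omega
    interWeight <- 0
    if (omega > 0 && L > 1L) {
        if (params@coupling == "ordinal") {
            lo <- rep(seq_len(L - 1L), each = n)
            i <- (lo - 1L) * n + seq_len(n)
            j <- lo * n + seq_len(n)
        } else { # categorical: all layer pairs
            pairs <- utils::combn(L, 2L)
            i <- as.vector(outer(seq_len(n), (pairs[1L, ] - 1L) * n, "+"))
            j <- as.vector(outer(seq_len(n), (pairs[2L, ] - 1L) * n, "+"))
        }
        nl <- n * L
        inter <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                                      x = omega, dims = c(nl, nl))
        supra <- supra + inter
        interWeight <- 2 * omega * length(i)
    }
    # force general (full symmetric) storage: both triangles must be
    # present for the neighbour scans and the double-sum normalization
    supra <- methods::as(methods::as(supra, "generalMatrix"),
                         "CsparseMatrix")
    new("ModularityTensor",
        supra = supra,
        twomu = intraWeight + interWeight,
        nNodes = as.integer(n), nLayers = as.integer(L),
        params = params)
}

# canonical relabelling: labels numbered by first appearance when the
# state-node vector is scanned layer by layer (our native ordering)
canonicalizeLabels <- function(labels) {
    match(labels, unique(labels))
}

#' Optimize multilayer modularity with iterated Louvain
#'
#' Greedy local moves of state nodes between communities (in an order
#' randomized by `seed`), followed by aggregation of communities into
#' super-nodes; the two-phase cycle repeats until no move improves the
#' quality by more than `tol`. Returns the partition with canonicalized
#' labels and its quality value.
#'
#' @param tensor a [ModularityTensor-class].
#' @param seed integer seed controlling node order and tie-breaking.
#' @param tol minimum accepted quality gain per move.
#' @return a [MultilayerPartition-class].
#' @examples
#' a <- array(0, c(4, 4, 2))
#' a[1, 2, ] <- a[2, 1, ] <- a[3, 4, ] <- a[4, 3, ] <- 1
#' p <- louvainMultilayer(buildModularityTensor(a), seed = 1)
#' partitionMatrix(p)
#' @export
louvainMultilayer <- function(tensor, seed = 1L, tol = 1e-10) {
    stopifnot(is(tensor, "ModularityTensor"))
    supra <- tensor@supra
    res <- louvain_supra_cpp(supra@i, supra@p, supra@x,
                             nrow(supra), tensor@twomu,
                             as.integer(seed), tol)
    labels <- canonicalizeLabels(res$labels)
    S <- matrix(as.integer(labels), nrow = tensor@nNodes,
                ncol = tensor@nLayers)
    new("MultilayerPartition", S = S, Q = res$Q,
        seed = as.integer(seed), nSweeps = res$n_sweeps)
}

#' Evaluate the multilayer quality function on a partition
#'
#' Independent evaluation of
#' `Q = (1 / 2 mu) * sum_{ijlr} [(A_ijl - gamma_l P_ijl) d_lr +
#' d_ij omega_jlr] d(g_il, g_jr)`
#' by direct summation of the supra-matrix entries whose two state nodes
#' share a community. Invariant under label permutation; used as the
#' self-consistency check against the optimizer's own Q.
#'
#' @param partition a [MultilayerPartition-class] or an N x L integer
#'   label matrix.
#' @param tensor the [ModularityTensor-class] the partition refers to.
#' @return the quality value Q.
#' @export
evaluateQuality <- function(partition, tensor) {
    stopifnot(is(tensor, "ModularityTensor"))
    S <- if (is(partition, "MultilayerPartition")) partition@S
         else partition
    if (nrow(S) != tensor@nNodes || ncol(S) != tensor@nLayers)
        stopf("partition is %d x %d; tensor expects %d x %d",
              nrow(S), ncol(S), tensor@nNodes, tensor@nLayers)
    g <- as.vector(S)
    supra <- tensor@supra
    cols <- rep.int(seq_len(ncol(supra)), diff(supra@p))
    rows <- supra@i + 1L
    sum(supra@x[g[rows] == g[cols]]) / tensor@twomu
}

#' Repeated optimizer runs
#'
#' Runs the Louvain optimizer `nReps` times with consecutive seeds
#' `baseSeed ... baseSeed + nReps - 1`. Downstream metrics are computed
#' per repetition and averaged; no consensus partition is formed.
#'
#' @param stack a [DynamicConnectivityStack-class] (or array) from which
#'   the modularity tensor is built once, or a prebuilt
#'   [ModularityTensor-class].
#' @param params a [QualityParams-class]; ignored when `stack` is already
#'   a tensor.
#' @param nReps number of repetitions.
#' @param baseSeed first seed.
#' @return list of [MultilayerPartition-class] objects.
#' @export
repeatPartitions <- function(stack, params = qualityParams(),
                             nReps = 100L, baseSeed = 1L) {
    stopifnot(nReps >= 1L)
    tensor <- if (is(stack, "ModularityTensor")) stack
              else buildModularityTensor(stack, params)
    lapply(seq_len(nReps) - 1L, function(k)
        louvainMultilayer(tensor, seed = as.integer(baseSeed) + k))
}

#' Write a partition to delimited text
#'
#' The S matrix as a tab-separated integer table (rows = regions,
#' columns = layers) plus a JSON sidecar with Q, the seed and sweep count.
#'
#' @param partition a [MultilayerPartition-class].
#' @param path output file for the matrix; the sidecar takes the same
#'   path with extension `.json`.
#' @return invisibly, `path`.
#' @export
writePartition <- function(partition, path) {
    stopifnot(is(partition, "MultilayerPartition"))
    utils::write.table(partition@S, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(list(Q = partition@Q, seed = partition@seed,
                              n_sweeps = partition@nSweeps),
                         sub("\\.[^.]*$", ".json", path),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}
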