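# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quality values by direct summation over the
# raw stack, optima by exhaustive enumeration, t statistics by the
# textbook formula.

# all set partitions of n elements as restricted growth strings
allSetPartitions <- function(n) {
    out <- list()
    recurse <- function(prefix, maxLabel) {
        k <- length(prefix)
        if (k == n) {
            out[[length(out) + 1L]] <<- prefix
            return(invisible(NULL))
        }
        for (lab in seq_len(maxLabel + 1L))
            recurse(c(prefix, lab), max(maxLabel, lab))
    }
    recurse(integer(0), 0L)
    out
}

# exhaustive single-layer modularity maximum: Q(g) = sum_ij B_ij d(gi,gj)/2m
# with B = A - gamma * k k'/2m, diagonal of A zero, i = j included
exhaustiveModularity <- function(A, gamma = 1) {
    k <- rowSums(A)
    twom <- sum(k)
    B <- A - gamma * tcrossprod(k) / twom
    best <- -Inf
    for (g in allSetPartitions(nrow(A))) {
        q <- sum(B[outer(g, g, "==")]) / twom
        if (q > best) best <- q
    }
    best
}

# direct summation of the multilayer quality function from the raw stack,
# ordinal coupling
directMultilayerQ <- function(S, tensor, gamma = 1, omega = 1) {
    L <- dim(tensor)[3L]
    n <- dim(tensor)[1L]
    tot <- 0
    twomu <- 0
    for (l in seq_len(L)) {
        a <- tensor[, , l]
        k <- rowSums(a)
        twom <- sum(k)
        twomu <- twomu + twom
        B <- a - gamma * tcrossprod(k) / twom
        tot <- tot + sum(B[outer(S[, l], S[, l], "==")])
    }
    if (L > 1L) for (l in seq_len(L - 1L)) {
        tot <- tot + 2 * omega * sum(S[, l] == S[, l + 1L])
        twomu <- twomu + 2 * omega * n
    }
    tot / twomu
}

# random connected weighted graph (unit weights), guaranteed connected by
# a random spanning tree plus extra edges
randomConnectedGraph <- function(n, extraProb = 0.35) {
    A <- matrix(0, n, n)
    perm <- sample.int(n)
    for (i in 2:n) {
        j <- perm[sample.int(i - 1L, 1L)]
        A[perm[i], j] <- A[j, perm[i]] <- 1
    }
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        if (A[i, j] == 0 && runif(1) < extraProb)
            A[i, j] <- A[j, i] <- 1
    }
    A
}

# textbook pooled two-sample t (group 1 minus group 2)
pooledT <- function(x1, x2) {
    n1 <- length(x1)
    n2 <- length(x2)
    sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
    (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# label matrices with a controlled number of communities
randomLabelMatrix <- function(n, L, C) {
    matrix(sample.int(C, n * L, replace = TRUE), n, L)
}

# transition-counting oracle: per-node change counts split by whether any
# partner made the same (from, to) move, written as plain loops
changeCountOracle <- function(S) {
    n <- nrow(S)
    L <- ncol(S)
    coh <- integer(n)
    dis <- integer(n)
    for (i in seq_len(n)) for (l in seq_len(L - 1L)) {
        if (S[i, l] == S[i, l + 1L]) next
        partner <- FALSE
        for (j in seq_len(n)) {
            if (j != i && S[j, l] == S[i, l] &&
                S[j, l + 1L] == S[i, l + 1L]) {
                partner <- TRUE
                break
            }
        }
        if (partner) coh[i] <- coh[i] + 1L else dis[i] <- dis[i] + 1L
    }
    list(cohesion = coh / (L - 1), disjointedness = dis / (L - 1))
}

# small planted-cohort spec used by several tests
toySpec <- function(...) {
    defaults <- list(nSubjects = c(2L, 2L), nRegions = 16L,
                     nTimepoints = 70L, nModules = 4L,
                     switchRates = c(0.1, 0.3), seed = 101L)
    args <- utils::modifyList(defaults, list(...))
    do.call(cohortSpec, args)
}
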