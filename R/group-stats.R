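#' Covariate-adjusted two-sample t statistic
#'
#' The t statistic of the group term in the linear model
#' `value ~ group + covariates`, with the group coded as an indicator for
#' group 1 so that a negative t means group 1 is lower than group 2 after
#' adjustment. With no covariates this equals the classic pooled
#' two-sample t statistic.
#'
#' @param values numeric vector, one value per subject.
#' @param group group membership per subject, coercible to two levels;
#'   the first level (in order of first appearance for character input,
#'   numeric order otherwise) is "group 1".
#' @param covariates optional data.frame or matrix of per-subject
#'   covariates.
#' @return the t statistic (scalar).
#' @examples
#' adjustedT(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))  # -3.674
#' @export
adjustedT <- function(values, group, covariates = NULL) {
    unname(drop(groupTStats(matrix(values, ncol = 1L), group, covariates)))
}

# group indicator: 1 for the first group, 0 for the second
groupIndicator <- function(group) {
    lv <- if (is.character(group) || is.factor(group))
        unique(as.character(group)) else sort(unique(group))
    if (length(lv) != 2L) stopf("exactly two groups required")
    as.numeric(as.character(group) == as.character(lv[1L]))
}

# vectorized adjusted-t over the columns of Y for one group labelling
groupTStats <- function(Y, group, covariates = NULL) {
    g <- if (is.numeric(group) && all(group %in% c(0, 1)))
        as.numeric(group) else groupIndicator(group)
    n <- nrow(Y)
    X <- cbind(intercept = 1, g = g)
    if (!is.null(covariates) && length(covariates)) {
        Z <- as.matrix(as.data.frame(covariates))
        storage.mode(Z) <- "double"
        X <- cbind(X, Z)
    }
    if (min(table(g)) < 2L) stopf("at least 2 subjects per group required")
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
        stopf("design matrix rank deficient (collinear: %s)",
              paste(bad, collapse = ", "))
    }
    xtxInv <- chol2inv(qr.R(qrX))
    beta <- qr.coef(qrX, Y)
    resid <- Y - X %*% beta
    df <- n - ncol(X)
    sigma2 <- colSums(resid^2) / df
    se <- sqrt(sigma2 * xtxInv[2L, 2L])
    t <- beta[2L, ] / se
    t[se == 0] <- 0
    t
}

#' Group comparison specification
#'
#' @param nPermutations number of label permutations (default 5000).
#' @param alpha significance level after FDR adjustment.
#' @param covariateNames covariates taken from the cohort manifest.
#' @param seed seed of the permutation stream.
#' @return a plain list used by [permutationTest()] and
#'   [compareGroups()].
#' @export
comparisonSpec <- function(nPermutations = 5000L, alpha = 0.05,
                           covariateNames = c("age", "gender", "mean_fd"),
                           seed = 1L) {
    stopifnot(nPermutations >= 1L, alpha > 0, alpha < 1)
    list(nPermutations = as.integer(nPermutations), alpha = alpha,
         covariateNames = covariateNames, seed = as.integer(seed))
}

#' Permutation test of covariate-adjusted group differences
#'
#' Builds the null distribution by randomly redistributing subjects into
#' two groups (covariates stay attached to their subjects) and
#' recomputing the adjusted t statistic; the two-sided p-value is
#' `(1 + #{|t_perm| >= |t_obs|}) / (1 + n_permutations)`. The same
#' permutation sequence is applied to every feature column. When the
#' number of distinct group assignments does not exceed the requested
#' permutations, the null is enumerated exactly (with a warning) and the
#' p-value is the exact tail proportion, observed assignment included.
#'
#' @param Y numeric matrix, subjects x features (a vector is treated as
#'   one feature).
#' @param group two-level group labels.
#' @param covariates optional per-subject covariate data.frame.
#' @param spec a [comparisonSpec()] list.
#' @return list with `t` (observed statistics), `p` (permutation
#'   p-values) and `exact` (whether the null was enumerated).
#' @export
permutationTest <- function(Y, group, covariates = NULL,
                            spec = comparisonSpec()) {
    if (is.vector(Y)) Y <- matrix(Y, ncol = 1L)
    Y <- as.matrix(Y)
    g <- groupIndicator(group)
    n <- length(g)
    n1 <- sum(g == 1)
    tObs <- groupTStats(Y, g, covariates)

    nDistinct <- choose(n, n1)
    exact <- nDistinct <= spec$nPermutations
    eps <- 1e-12
    # a permuted grouping may coincide with a binary covariate, leaving
    # the group coefficient undefined; such assignments carry no
    # information about the statistic and are excluded from the null
    permT <- function(gp) tryCatch(groupTStats(Y, gp, covariates),
                                   error = function(e) NULL)
    if (exact) {
        warning(sprintf(
            "only %d distinct group assignments; enumerating exactly",
            nDistinct))
        combos <- utils::combn(n, n1)
        count <- numeric(ncol(Y))
        valid <- 0L
        for (k in seq_len(ncol(combos))) {
            gp <- numeric(n)
            gp[combos[, k]] <- 1
            tp <- permT(gp)
            if (is.null(tp)) next
            valid <- valid + 1L
            count <- count + (abs(tp) >= abs(tObs) - eps)
        }
        p <- count / valid
    } else {
        count <- numeric(ncol(Y))
        valid <- 0L
        withSeed(spec$seed, {
            while (valid < spec$nPermutations) {
                tp <- permT(g[sample.int(n)])
                if (is.null(tp)) next
                valid <- valid + 1L
                count <- count + (abs(tp) >= abs(tObs) - eps)
            }
        })
        p <- (1 + count) / (1 + spec$nPermutations)
    }
    list(t = tObs, p = as.numeric(p), exact = exact)
}

#' Benjamini-Hochberg adjustment within a test family
#'
#' Step-up FDR adjustment with the usual monotonicity enforcement. A
#' family is all units of one level for one metric (e.g. the ten network
#' means of flexibility, or all nodal values of cohesion).
#'
#' @param p numeric vector of raw p-values in one family.
#' @return adjusted p-values in input order.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdrAdjust <- function(p) {
    stopifnot(length(p) >= 1L)
    stats::p.adjust(p, method = "BH")
}

#' Compare every metric between groups at all levels
#'
#' Runs the covariate-adjusted permutation test for each metric at the
#' global, network and nodal level, applying FDR correction within each
#' metric x level family. Feature matrices are per-subject values: the
#' global mean, the ten network means, or the per-region values of one
#' metric.
#'
#' @param nodeTables list of [NodeDynamicsTable-class], one per subject.
#' @param group two-level group label per subject.
#' @param covariates per-subject covariate data.frame (or NULL).
#' @param spec a [comparisonSpec()] list.
#' @param levels subset of `c("global", "network", "nodal")`.
#' @param metrics subset of the four dynamic metrics to test.
#' @return data.frame with columns `level`, `unit`, `metric`, `t`,
#'   `p_perm`, `p_fdr`, `significant`.
#' @export
compareGroups <- function(nodeTables, group, covariates = NULL,
                          spec = comparisonSpec(),
                          levels = c("global", "network", "nodal"),
                          metrics = c("flexibility", "promiscuity",
                                      "cohesion", "disjointedness")) {
    metrics <- match.arg(metrics, several.ok = TRUE)
    ref <- nodeTables[[1L]]@table
    results <- list()
    permSeeds <- deriveSeeds(spec$seed, length(levels) * length(metrics),
                             salt = 3L)
    si <- 0L
    for (lev in levels) {
        for (m in metrics) {
            si <- si + 1L
            feat <- featureMatrix(nodeTables, m, lev)
            sp <- spec
            sp$seed <- permSeeds[si]
            pt <- permutationTest(feat$Y, group, covariates, sp)
            pf <- fdrAdjust(pt$p)
            results[[length(results) + 1L]] <- data.frame(
                level = lev, unit = feat$units, metric = m,
                t = as.numeric(pt$t), p_perm = pt$p, p_fdr = pf,
                significant = pf < spec$alpha,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, results)
    rownames(out) <- NULL
    out
}

# subjects x units matrix of one metric at one level
featureMatrix <- function(nodeTables, metric, level) {
    ref <- nodeTables[[1L]]@table
    if (level == "global") {
        Y <- vapply(nodeTables, function(tb) mean(tb@table[[metric]]),
                    numeric(1L))
        list(Y = matrix(Y, ncol = 1L), units = "all")
    } else if (level == "network") {
        nets <- sort(unique(ref$network))
        Y <- t(vapply(nodeTables, function(tb)
            tapply(tb@table[[metric]], tb@table$network, mean)[nets],
            numeric(length(nets))))
        list(Y = Y, units = nets)
    } else if (level == "nodal") {
        Y <- t(vapply(nodeTables, function(tb) tb@table[[metric]],
                      numeric(nrow(ref))))
        list(Y = Y, units = ref$region)
    } else stopf("unknown level '%s'", level)
}
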