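#' Temporal core-periphery assignment
#'
#' Classifies the `fraction` of nodes with the lowest flexibility as the
#' temporal core (stably affiliated regions) and the same fraction with
#' the highest flexibility as the temporal periphery (frequently
#' reassigned regions). `k = round(fraction * N)` nodes per class, with
#' halves rounded away from zero; ties at either boundary are broken by
#' the stable input region order and flagged with a warning.
#'
#' @param flex numeric vector of node flexibility values (typically the
#'   group mean across subjects).
#' @param fraction quantile fraction per class, in (0, 0.5].
#' @param regionIds optional region identifiers.
#' @return data.frame with columns `region`, `flexibility` and `class`
#'   (`"core"`, `"periphery"` or `"neither"`), in input region order.
#' @examples
#' assignCorePeriphery(1:10 / 10, fraction = 0.2)
#' @export
assignCorePeriphery <- function(flex, fraction = 0.10,
                                regionIds = NULL) {
    n <- length(flex)
    if (fraction <= 0 || fraction > 0.5)
        stopf("fraction must lie in (0, 0.5]")
    k <- as.integer(roundHalfUp(fraction * n))
    if (k < 1L) stopf("fraction %.3f of %d nodes selects no node",
                      fraction, n)
    if (is.null(regionIds)) regionIds <- sprintf("roi_%03d", seq_len(n))
    ord <- order(flex) # stable: ties keep input region order
    core <- ord[seq_len(k)]
    periphery <- ord[seq.int(n - k + 1L, n)]
    boundaryTies <- (sum(flex == flex[core[k]]) >
                         sum(flex[core] == flex[core[k]])) ||
                    (sum(flex == flex[periphery[1L]]) >
                         sum(flex[periphery] == flex[periphery[1L]]))
    if (boundaryTies)
        warning("ties at a core/periphery boundary broken by region order")
    cls <- rep("neither", n)
    cls[core] <- "core"
    cls[periphery] <- "periphery"
    data.frame(region = regionIds, flexibility = flex, class = cls,
               stringsAsFactors = FALSE)
}

#' Network composition of core and periphery
#'
#' For each class, the proportion of its nodes falling in each functional
#' network; proportions sum to one within a class.
#'
#' @param assignment data.frame from [assignCorePeriphery()].
#' @param networkLabels one network label per region, in the same order.
#' @return data.frame with columns `class`, `network`, `proportion`.
#' @export
networkComposition <- function(assignment, networkLabels) {
    if (length(networkLabels) != nrow(assignment))
        stopf("one network label per region required")
    nets <- sort(unique(networkLabels))
    rows <- list()
    for (cl in c("core", "periphery")) {
        inClass <- assignment$class == cl
        if (!any(inClass)) stopf("class '%s' is empty", cl)
        counts <- table(factor(networkLabels[inClass], levels = nets))
        rows[[cl]] <- data.frame(
            class = cl, network = nets,
            proportion = as.numeric(counts) / sum(counts),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
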