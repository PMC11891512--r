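#' Sliding-window scheme
#'
#' @param width window width in time points (default 30, i.e. 60 s at a
#'   2-s sampling interval).
#' @param step sliding step in time points (default 1).
#' @return a [WindowScheme-class].
#' @examples
#' windowScheme(30, 1)
#' @export
windowScheme <- function(width = 30L, step = 1L) {
    new("WindowScheme", width = as.integer(width), step = as.integer(step))
}

#' Enumerate sliding windows
#'
#' Windows start at `1, 1 + step, 1 + 2 step, ...` and have fixed width,
#' giving `floor((T - width) / step) + 1` windows over a series of length
#' `T`. With the default scheme (width 30, step 1) a 230-point series
#' yields 201 windows.
#'
#' @param seriesLength series length `T` in time points.
#' @param scheme a [WindowScheme-class].
#' @return integer matrix with columns `start` and `end` (1-based, both
#'   inclusive), one row per window.
#' @examples
#' nrow(enumerateWindows(230, windowScheme(30, 1)))  # 201
#' @export
enumerateWindows <- function(seriesLength, scheme = windowScheme()) {
    stopifnot(is(scheme, "WindowScheme"))
    validObject(scheme)
    seriesLength <- as.integer(seriesLength)
    if (scheme@width > seriesLength)
        stopf("window width %d exceeds series length %d",
              scheme@width, seriesLength)
    starts <- seq.int(1L, seriesLength - scheme@width + 1L,
                      by = scheme@step)
    cbind(start = starts, end = starts + scheme@width - 1L)
}

#' Sliding-window dynamic functional connectivity
#'
#' Builds the N x N x L stack of windowed Pearson correlation matrices
#' from a subject's time-by-region signal matrix. Each slice has its
#' diagonal set to zero so self-edges never contribute to node strengths
#' or the modularity normalization. Edge weights are raw correlations by
#' default; a Fisher z-transform and a negative-edge policy are exposed
#' because both interact with the Newman-Girvan null downstream.
#'
#' @param ts a [SubjectTimeSeries-class] or a plain time-by-region matrix.
#' @param scheme a [WindowScheme-class].
#' @param fisherZ if `TRUE`, apply `atanh` to the correlations.
#' @param negativeEdges `"keep"` (default), `"zero"` (set negative
#'   weights to 0) or `"absolute"` (use `|r|`).
#' @return a [DynamicConnectivityStack-class].
#' @examples
#' spec <- cohortSpec(nSubjects = c(1, 1), nRegions = 12, nTimepoints = 60,
#'                    nModules = 3)
#' ts <- simulateTimeSeries(generatePartitionSequence(spec, 1, 1), spec, 2)
#' stack <- dynamicConnectivity(ts, windowScheme(30, 5))
#' nLayers(stack)
#' @export
dynamicConnectivity <- function(ts, scheme = windowScheme(),
                                fisherZ = FALSE,
                                negativeEdges = c("keep", "zero",
                                                  "absolute")) {
    negativeEdges <- match.arg(negativeEdges)
    if (is(ts, "SubjectTimeSeries")) {
        mat <- ts@data
        ids <- ts@regionIds
    } else {
        mat <- as.matrix(ts)
        ids <- colnames(mat)
        if (is.null(ids)) ids <- sprintf("roi_%03d", seq_len(ncol(mat)))
    }
    if (anyNA(mat)) stopf("time series contains missing values")
    windows <- enumerateWindows(nrow(mat), scheme)
    n <- ncol(mat)
    L <- nrow(windows)
    tensor <- array(0, dim = c(n, n, L))
    for (l in seq_len(L)) {
        seg <- mat[windows[l, "start"]:windows[l, "end"], , drop = FALSE]
        sds <- apply(seg, 2L, stats::sd)
        if (any(sds == 0))
            stopf("region %s has zero variance in window %d",
                  ids[which(sds == 0)[1L]], l)
        r <- stats::cor(seg)
        diag(r) <- 0
        if (negativeEdges == "zero") r[r < 0] <- 0
        else if (negativeEdges == "absolute") r <- abs(r)
        if (fisherZ) r <- atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
        tensor[, , l] <- r
    }
    new("DynamicConnectivityStack",
        tensor = tensor, regionIds = ids,
        windowStarts = as.integer(windows[, "start"]), scheme = scheme)
}

#' Write a connectivity stack as delimited matrices
#'
#' One tab-separated N x N matrix per layer plus a JSON sidecar recording
#' the region ids, window starts and scheme.
#'
#' @param stack a [DynamicConnectivityStack-class].
#' @param dir output directory.
#' @return invisibly, the sidecar path.
#' @export
writeConnectivityStack <- function(stack, dir) {
    stopifnot(is(stack, "DynamicConnectivityStack"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    L <- nLayers(stack)
    for (l in seq_len(L))
        utils::write.table(stack@tensor[, , l],
                           file.path(dir, sprintf("layer_%03d.tsv", l)),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    sidecar <- file.path(dir, "stack.json")
    jsonlite::write_json(list(
        region_ids = stack@regionIds,
        window_starts = stack@windowStarts,
        width = stack@scheme@width, step = stack@scheme@step,
        n_layers = L), sidecar, auto_unbox = TRUE, digits = NA)
    invisible(sidecar)
}
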