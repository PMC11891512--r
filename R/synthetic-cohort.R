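#' Build a cohort simulation specification
#'
#' Defines a two-group synthetic cohort whose regional time series carry
#' planted, time-varying community structure. The defaults emulate the
#' geometry of a resting-state study: 227 regions, 230 retained volumes at
#' a 2-second sampling interval, and groups of 13 and 14 subjects. Module
#' memberships are piecewise stationary: they are constant within epochs
#' of `epochLength` time points and may change at epoch boundaries at the
#' group's `switchRates`. A change is cohesive (made together with at
#' least one partner from the same source module, to a common destination)
#' with probability `cohesiveFraction`, otherwise solo.
#'
#' @param nSubjects integer(2): subjects in group 1 and group 2.
#' @param nRegions number of regions.
#' @param nTimepoints number of time points.
#' @param nModules number of planted modules (each keeps at least one
#'   member at all times).
#' @param epochLength time points per stable epoch; the default matches
#'   the default sliding-window width so one window spans one epoch.
#' @param switchRates numeric(2): per-boundary module-switch probability
#'   for each group.
#' @param cohesiveFraction probability that a switch is cohesive.
#' @param withinModuleCorr latent correlation between same-module regions.
#' @param noiseSd standard deviation of added independent noise; the
#'   observable within-module correlation is
#'   `withinModuleCorr / (1 + noiseSd^2)`.
#' @param samplingInterval sampling interval in seconds.
#' @param seed master seed; all subject-level randomness derives from it.
#'
#' @return a validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(nSubjects = c(2, 2), nRegions = 20, nTimepoints = 90)
#' spec
#' @export
cohortSpec <- function(nSubjects = c(13L, 14L),
                       nRegions = 227L,
                       nTimepoints = 230L,
                       nModules = 5L,
                       epochLength = 30L,
                       switchRates = c(0.1, 0.1),
                       cohesiveFraction = 0.5,
                       withinModuleCorr = 0.6,
                       noiseSd = 0.3,
                       samplingInterval = 2.0,
                       seed = 1L) {
    new("CohortSpec",
        nSubjects = as.integer(nSubjects),
        nRegions = as.integer(nRegions),
        nTimepoints = as.integer(nTimepoints),
        nModules = as.integer(nModules),
        epochLength = as.integer(epochLength),
        switchRates = as.numeric(switchRates),
        cohesiveFraction = as.numeric(cohesiveFraction),
        withinModuleCorr = as.numeric(withinModuleCorr),
        noiseSd = as.numeric(noiseSd),
        samplingInterval = as.numeric(samplingInterval),
        seed = as.integer(seed))
}

# initial balanced assignment: modules filled round-robin after shuffling
initialModules <- function(nRegions, nModules) {
    base <- rep_len(seq_len(nModules), nRegions)
    base[sample.int(nRegions)]
}

# apply one epoch transition to `labels`; returns the new label vector or
# NULL when the draw left some module empty (caller re-draws)
drawTransition <- function(labels, nModules, switchRate, cohesiveFraction) {
    n <- length(labels)
    flagged <- which(stats::runif(n) < switchRate)
    out <- labels
    if (length(flagged)) {
        cohesive <- flagged[stats::runif(length(flagged)) < cohesiveFraction]
        solo <- setdiff(flagged, cohesive)
        takenDest <- vector("list", nModules) # destinations used per source
        for (src in unique(labels[cohesive])) {
            movers <- cohesive[labels[cohesive] == src]
            if (length(movers) >= 2L) {
                pool <- setdiff(seq_len(nModules), src)
                dest <- pool[sample.int(length(pool), 1L)]
                out[movers] <- dest
                takenDest[[src]] <- c(takenDest[[src]], dest)
            } else {
                # a cohesive move needs a partner from the same module;
                # a lone designee falls back to a solo move
                solo <- c(solo, movers)
            }
        }
        for (v in solo) {
            src <- labels[v]
            avoid <- c(src, takenDest[[src]])
            pool <- setdiff(seq_len(nModules), avoid)
            if (!length(pool)) pool <- setdiff(seq_len(nModules), src)
            dest <- pool[sample.int(length(pool), 1L)]
            out[v] <- dest
            takenDest[[src]] <- c(takenDest[[src]], dest)
        }
    }
    if (length(unique(out)) < nModules) NULL else out
}

#' Generate a planted partition sequence
#'
#' Draws the ground-truth module labels of one subject: an initial
#' balanced assignment followed by independent per-node switch decisions
#' at every epoch boundary, honouring the cohesive/solo move mechanism and
#' the constraint that every module keeps at least one member (boundary
#' draws violating it are re-drawn).
#'
#' @param spec a [CohortSpec-class].
#' @param groupIndex 1 or 2; selects the group's switch rate.
#' @param seed seed for this subject's partition stream.
#' @return a [PlantedPartitionSequence-class].
#' @examples
#' spec <- cohortSpec(nSubjects = c(1, 1), nRegions = 20, nTimepoints = 90,
#'                    nModules = 4, switchRates = c(0.3, 0.3))
#' pp <- generatePartitionSequence(spec, 1, seed = 7)
#' dim(pp@labels)
#' @export
generatePartitionSequence <- function(spec, groupIndex, seed) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    if (!groupIndex %in% c(1L, 2L))
        stopf("groupIndex must be 1 or 2")
    rate <- spec@switchRates[groupIndex]
    nEpochs <- ceiling(spec@nTimepoints / spec@epochLength)
    starts <- as.integer(seq(1L, by = spec@epochLength,
                             length.out = nEpochs))
    withSeed(seed, {
        labels <- matrix(0L, spec@nRegions, nEpochs)
        repeat {
            init <- initialModules(spec@nRegions, spec@nModules)
            if (length(unique(init)) == spec@nModules) break
        }
        labels[, 1L] <- init
        if (nEpochs > 1L) for (e in 2L:nEpochs) {
            tries <- 0L
            repeat {
                nxt <- drawTransition(labels[, e - 1L], spec@nModules,
                                      rate, spec@cohesiveFraction)
                tries <- tries + 1L
                if (!is.null(nxt)) break
                if (tries > 1000L)
                    stopf("could not keep all %d modules occupied; %s",
                          spec@nModules,
                          "reduce nModules or the switch rate")
            }
            labels[, e] <- nxt
        }
        new("PlantedPartitionSequence",
            labels = labels, epochStarts = starts,
            nTimepoints = spec@nTimepoints)
    })
}

# cohort-wide network label assignment: the ten canonical resting-state
# networks; for fewer regions than the canonical 227 the label sequence
# is downsampled proportionally so every simulated cohort still spans
# several networks
defaultNetworkAssignment <- function(nRegions) {
    nets <- restingStateNetworks()
    full <- rep(nets$network, nets$n_rois)
    if (nRegions <= length(full))
        full[round(seq(1L, length(full), length.out = nRegions))]
    else rep_len(full, nRegions)
}

#' Simulate a subject's time series from a planted partition
#'
#' Within each epoch, samples are drawn from a zero-mean multivariate
#' normal whose correlation is `withinModuleCorr` for same-module pairs
#' and zero otherwise (unit diagonal), after which independent Gaussian
#' noise of sd `noiseSd` is added. Covariates (age, gender, mean framewise
#' displacement) are drawn independently of group, so they are null
#' confounders by construction.
#'
#' @param partitions a [PlantedPartitionSequence-class].
#' @param spec the generating [CohortSpec-class].
#' @param seed seed for this subject's signal stream.
#' @param subjectId identifier stored in the result.
#' @param group group index stored in the result.
#' @return a [SubjectTimeSeries-class].
#' @examples
#' spec <- cohortSpec(nSubjects = c(1, 1), nRegions = 20, nTimepoints = 90,
#'                    nModules = 4)
#' pp <- generatePartitionSequence(spec, 1, seed = 7)
#' ts <- simulateTimeSeries(pp, spec, seed = 11)
#' dim(seriesMatrix(ts))
#' @export
simulateTimeSeries <- function(partitions, spec, seed,
                               subjectId = "sub-01", group = 1L) {
    stopifnot(is(partitions, "PlantedPartitionSequence"),
              is(spec, "CohortSpec"))
    if (nrow(partitions@labels) != spec@nRegions ||
        partitions@nTimepoints != spec@nTimepoints)
        stopf("partition sequence inconsistent with spec")
    n <- spec@nRegions
    T <- spec@nTimepoints
    rho <- spec@withinModuleCorr
    withSeed(seed, {
        data <- matrix(0, T, n)
        starts <- partitions@epochStarts
        ends <- c(starts[-1L] - 1L, T)
        for (e in seq_along(starts)) {
            lab <- partitions@labels[, e]
            sigma <- outer(lab, lab, "==") * rho
            diag(sigma) <- 1
            ch <- tryCatch(chol(sigma), error = function(err)
                stopf("block correlation not positive definite (%s)",
                      conditionMessage(err)))
            len <- ends[e] - starts[e] + 1L
            z <- matrix(stats::rnorm(len * n), len, n)
            data[starts[e]:ends[e], ] <- z %*% ch
        }
        data <- data + matrix(stats::rnorm(T * n, sd = spec@noiseSd), T, n)
        ids <- sprintf("roi_%03d", seq_len(n))
        colnames(data) <- ids
        new("SubjectTimeSeries",
            data = data,
            regionIds = ids,
            networkLabels = defaultNetworkAssignment(n),
            covariates = list(
                age = sample(17:28, 1L),
                gender = stats::rbinom(1L, 1L, 0.5),
                mean_fd = round(stats::runif(1L, 0.05, 0.25), 4L)),
            subjectId = subjectId,
            group = as.integer(group))
    })
}

#' Generate a full two-group cohort
#'
#' Derives independent per-subject seeds from the spec's master seed, then
#' draws one planted partition sequence and one time series per subject.
#' The manifest records subject id, group, covariates and both seeds so a
#' cohort can be reproduced subject by subject.
#'
#' @param spec a [CohortSpec-class].
#' @return a [Cohort-class].
#' @examples
#' spec <- cohortSpec(nSubjects = c(2, 2), nRegions = 20, nTimepoints = 90,
#'                    nModules = 4, seed = 42)
#' coh <- generateCohort(spec)
#' cohortManifest(coh)
#' @export
generateCohort <- function(spec) {
    stopifnot(is(spec, "CohortSpec"))
    validObject(spec)
    nTotal <- sum(spec@nSubjects)
    groups <- rep(c(1L, 2L), spec@nSubjects)
    partSeeds <- deriveSeeds(spec@seed, nTotal, salt = 1L)
    dataSeeds <- deriveSeeds(spec@seed, nTotal, salt = 2L)
    subjects <- vector("list", nTotal)
    truth <- vector("list", nTotal)
    rows <- vector("list", nTotal)
    for (s in seq_len(nTotal)) {
        id <- sprintf("sub-%02d", s)
        pp <- generatePartitionSequence(spec, groups[s], partSeeds[s])
        ts <- simulateTimeSeries(pp, spec, dataSeeds[s],
                                 subjectId = id, group = groups[s])
        subjects[[s]] <- ts
        truth[[s]] <- pp
        rows[[s]] <- data.frame(
            subject = id, group = groups[s],
            age = ts@covariates$age, gender = ts@covariates$gender,
            mean_fd = ts@covariates$mean_fd,
            partition_seed = partSeeds[s], data_seed = dataSeeds[s],
            stringsAsFactors = FALSE)
    }
    new("Cohort", spec = spec, subjects = subjects, truth = truth,
        manifest = do.call(rbind, rows))
}

#' Ground-truth module labels per time point
#'
#' Expands a planted partition sequence from epochs to individual time
#' points, e.g. to compare detected window communities against the epoch
#' containing each window's centre.
#'
#' @param partitions a [PlantedPartitionSequence-class].
#' @return integer matrix, regions x time points.
#' @export
truthPerTimepoint <- function(partitions) {
    stopifnot(is(partitions, "PlantedPartitionSequence"))
    starts <- partitions@epochStarts
    ends <- c(starts[-1L] - 1L, partitions@nTimepoints)
    reps <- ends - starts + 1L
    partitions@labels[, rep(seq_along(starts), reps), drop = FALSE]
}

#' Write a cohort to delimited text files
#'
#' One tab-separated file per subject (rows = time points, columns =
#' regions, header row of region ids), one ground-truth label file per
#' subject (regions x epochs), and a JSON manifest tying them together.
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory, created if needed.
#' @return invisibly, the manifest file path.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "Cohort"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    man <- cohort@manifest
    man$file <- file.path(dir, paste0(man$subject, "_timeseries.tsv"))
    man$truth_file <- file.path(dir, paste0(man$subject, "_truth.tsv"))
    for (s in seq_len(nrow(man))) {
        ts <- cohort@subjects[[s]]
        utils::write.table(ts@data, man$file[s], sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(cohort@truth[[s]]@labels, man$truth_file[s],
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
    }
    manifestPath <- file.path(dir, "cohort_manifest.json")
    jsonlite::write_json(list(
        n_regions = cohort@spec@nRegions,
        n_timepoints = cohort@spec@nTimepoints,
        epoch_starts = cohort@truth[[1L]]@epochStarts,
        network_labels = networkLabels(cohort@subjects[[1L]]),
        subjects = man), manifestPath, auto_unbox = TRUE, digits = NA)
    invisible(manifestPath)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param manifestPath path to `cohort_manifest.json`.
#' @return a list with elements `subjects` (list of
#'   [SubjectTimeSeries-class]) and `manifest` (data.frame).
#' @export
readCohort <- function(manifestPath) {
    man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    subs <- man$subjects
    nets <- man$network_labels
    subjects <- lapply(seq_len(nrow(subs)), function(s) {
        dat <- as.matrix(utils::read.table(subs$file[s], header = TRUE,
                                           sep = "\t", check.names = FALSE))
        new("SubjectTimeSeries",
            data = dat,
            regionIds = colnames(dat),
            networkLabels = nets,
            covariates = list(age = subs$age[s], gender = subs$gender[s],
                              mean_fd = subs$mean_fd[s]),
            subjectId = subs$subject[s],
            group = as.integer(subs$group[s]))
    })
    list(subjects = subjects, manifest = subs)
}
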