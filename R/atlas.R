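#' The ten resting-state functional networks
#'
#' Summary of the region parcellation the pipeline assumes: a 264-region
#' functional atlas from which 37 regions without a stable network
#' affiliation are excluded, leaving 227 regions (214 cortical and 13
#' subcortical) assigned to ten canonical resting-state networks.
#'
#' @return data.frame with columns `network` (abbreviation), `n_rois`
#'   (regions in the network) and `domain` (`cortical`/`subcortical`).
#' @examples
#' sum(restingStateNetworks()$n_rois)  # 227
#' @export
restingStateNetworks <- function() {
    data.frame(
        network = c("SMN", "CON", "AUN", "DMN", "VSN",
                    "FPN", "SAN", "SUN", "VAN", "DAN"),
        n_rois = c(35L, 14L, 13L, 58L, 31L,
                   25L, 18L, 13L, 9L, 11L),
        domain = c("cortical", "cortical", "cortical", "cortical",
                   "cortical", "cortical", "cortical", "subcortical",
                   "cortical", "cortical"),
        stringsAsFactors = FALSE)
}

#' Region manifest for the 227-region parcellation
#'
#' Reads the packaged region manifest: one row per retained region with a
#' synthetic region identifier, its network label and cortical/subcortical
#' domain. Region identifiers are synthetic placeholders (no stereotaxic
#' coordinates are shipped); the network sizes follow the published
#' ten-network grouping of the 264-region functional atlas.
#'
#' @return data.frame with columns `region`, `network`, `domain`.
#' @export
regionManifest <- function() {
    path <- system.file("extdata", "region_manifest_227_synthetic.tsv",
                        package = "dynetflex", mustWork = TRUE)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}

#' Validate a region manifest
#'
#' Checks the bookkeeping of the retained-region table against the atlas
#' it is derived from: `nAtlas` regions minus `nExcluded` unaffiliated
#' regions must equal the manifest's row count, network labels must come
#' from the declared ten-network set, and the cortical/subcortical split
#' must match the declared counts.
#'
#' @param manifest data.frame with columns `region`, `network`, `domain`.
#' @param nAtlas regions in the source atlas (default 264).
#' @param nExcluded excluded regions (default 37).
#' @param nCortical,nSubcortical expected domain split (defaults 214/13).
#' @return invisibly `TRUE`; stops with a message on any inconsistency.
#' @export
validateRegionManifest <- function(manifest, nAtlas = 264L,
                                   nExcluded = 37L, nCortical = 214L,
                                   nSubcortical = 13L) {
    need <- c("region", "network", "domain")
    if (!all(need %in% names(manifest)))
        stopf("manifest must have columns: %s", paste(need, collapse = ", "))
    nKept <- nAtlas - nExcluded
    if (nrow(manifest) != nKept)
        stopf("manifest has %d regions; expected %d (= %d - %d)",
              nrow(manifest), nKept, nAtlas, nExcluded)
    nets <- restingStateNetworks()
    bad <- setdiff(manifest$network, nets$network)
    if (length(bad))
        stopf("unknown network label(s): %s", paste(bad, collapse = ", "))
    domains <- table(factor(manifest$domain,
                            levels = c("cortical", "subcortical")))
    if (domains[["cortical"]] != nCortical ||
        domains[["subcortical"]] != nSubcortical)
        stopf("domain split %d/%d does not match expected %d/%d",
              domains[["cortical"]], domains[["subcortical"]],
              nCortical, nSubcortical)
    counts <- table(factor(manifest$network, levels = nets$network))
    if (!all(as.integer(counts) == nets$n_rois))
        stopf("per-network region counts do not match the declared sizes")
    invisible(TRUE)
}
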