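#' @import methods
#' @importFrom S4Vectors isSorted
NULL

#' GeneModule: a disease module inferred from clique evidence
#'
#' A named set of genes forming a transcriptomic disease module, together
#' with the significant maximal cliques it was assembled from (provenance),
#' the per-clique statistics of every clique that was tested, and the
#' parameter record of the inference run.
#'
#' @slot genes character vector of module gene identifiers (union of the
#'   significant cliques' members).
#' @slot cliques list of character vectors, one per significant clique.
#' @slot cliqueStats data.frame with one row per tested clique: `size`,
#'   `score` (Fisher's combined statistic), `p_value` (+1-smoothed empirical
#'   p), `adj_p`, `significant`, and `genes` (comma-separated members).
#' @slot params list of the inference parameters used.
#'
#' @seealso [inferCliqueSumModule()]
#' @aliases GeneModule
#' @export
setClass("GeneModule",
  representation(
    genes = "character",
    cliques = "list",
    cliqueStats = "data.frame",
    params = "list"
  ),
  prototype(
    genes = character(0), cliques = list(),
    cliqueStats = data.frame(), params = list()
  )
)

setValidity("GeneModule", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@genes))
    msg <- c(msg, "duplicate genes in module")
  cu <- unique(unlist(object@cliques, use.names = FALSE))
  if (!setequal(object@genes, if (is.null(cu)) character(0) else cu))
    msg <- c(msg, "module genes must equal the union of source clique genes")
  if (length(msg)) msg else TRUE
})

#' RankedEdgeList: directed regulator-to-target edges from one GRN method
#'
#' Output of a single gene-regulatory-network inference method: directed
#' TF-to-target edges ordered by non-increasing confidence, with regulators
#' restricted to the supplied transcription-factor list.
#'
#' @slot method label of the inference method.
#' @slot edges data.frame with columns `regulator`, `target`, `confidence`,
#'   ordered by non-increasing confidence (ties broken by regulator then
#'   target identifier).
#'
#' @seealso [inferGRN()]
#' @aliases RankedEdgeList
#' @export
setClass("RankedEdgeList",
  representation(method = "character", edges = "data.frame"),
  prototype(method = NA_character_,
            edges = data.frame(regulator = character(0),
                               target = character(0),
                               confidence = numeric(0)))
)

setValidity("RankedEdgeList", function(object) {
  e <- object@edges
  msg <- character(0)
  if (!all(c("regulator", "target", "confidence") %in% names(e)))
    return("edges must have columns regulator, target, confidence")
  if (any(e$regulator == e$target))
    msg <- c(msg, "self-edges are not allowed")
  if (anyDuplicated(paste(e$regulator, e$target, sep = "\r")))
    msg <- c(msg, "duplicate (regulator, target) pairs")
  if (nrow(e) > 1L && any(diff(e$confidence) > 1e-12))
    msg <- c(msg, "edges must be ordered by non-increasing confidence")
  if (length(msg)) msg else TRUE
})

#' RegulatorScores: per-TF outdegree averaged across GRN methods
#'
#' @slot averageOutdegree named numeric vector, one entry per TF in the
#'   input TF list (0 if never ranked by any method).
#' @slot perMethod numeric matrix of per-method outdegrees (TFs x methods),
#'   retained for audit; rowMeans equal `averageOutdegree`.
#'
#' @seealso [averageOutdegree()], [selectHubs()]
#' @aliases RegulatorScores
#' @export
setClass("RegulatorScores",
  representation(averageOutdegree = "numeric", perMethod = "matrix")
)

setValidity("RegulatorScores", function(object) {
  msg <- character(0)
  if (is.null(names(object@averageOutdegree)))
    msg <- c(msg, "averageOutdegree must be named by TF")
  if (any(object@averageOutdegree < 0))
    msg <- c(msg, "outdegrees must be non-negative")
  if (nrow(object@perMethod) != length(object@averageOutdegree))
    msg <- c(msg, "perMethod rows must match averageOutdegree length")
  if (length(msg)) msg else TRUE
})

#' HubSet: the selected top fraction of regulators
#'
#' @slot hubs character vector of hub TF identifiers, ordered by decreasing
#'   score (ties by identifier).
#' @slot fraction fraction of the TF list selected, in (0, 1].
#' @slot scores named numeric vector of the selected hubs' average
#'   outdegrees.
#'
#' @seealso [selectHubs()]
#' @aliases HubSet
#' @export
setClass("HubSet",
  representation(hubs = "character", fraction = "numeric",
                 scores = "numeric")
)

setValidity("HubSet", function(object) {
  msg <- character(0)
  if (length(object@fraction) != 1L || object@fraction <= 0 ||
      object@fraction > 1)
    msg <- c(msg, "fraction must be a single value in (0, 1]")
  if (anyDuplicated(object@hubs))
    msg <- c(msg, "duplicate hubs")
  if (length(msg)) msg else TRUE
})

#' ConsensusNetwork: rank-averaged directed regulatory network
#'
#' Directed regulator-to-target edges scored by the mean over methods of
#' `1 - (rank - 1) / max_edges`, with edges unranked by a method
#' contributing 0 for that method.
#'
#' @slot edges data.frame with columns `regulator`, `target`,
#'   `mean_rank_score`, ordered by non-increasing score.
#' @slot nMethods number of edge lists averaged.
#'
#' @seealso [consensusNetwork()]
#' @aliases ConsensusNetwork
#' @export
setClass("ConsensusNetwork",
  representation(edges = "data.frame", nMethods = "integer"),
  prototype(edges = data.frame(regulator = character(0),
                               target = character(0),
                               mean_rank_score = numeric(0)),
            nMethods = 0L)
)

setValidity("ConsensusNetwork", function(object) {
  e <- object@edges
  if (!all(c("regulator", "target", "mean_rank_score") %in% names(e)))
    return("edges must have columns regulator, target, mean_rank_score")
  if (any(e$mean_rank_score <= 0) || any(e$mean_rank_score > 1))
    return("mean_rank_score must lie in (0, 1]")
  TRUE
})

#' HubFilterResult: hub enrichment statistics and the filtered module
#'
#' For every candidate hub, the 2x2 contingency table of its
#' consensus-network targets against the module within the evaluation
#' universe, the sample odds ratio and one-sided Fisher's exact p-value,
#' and the significance call (odds ratio > OR_min and p < p_max). The
#' filtered module keeps the module genes regulated by at least one
#' significant hub; if no hub is significant it is empty.
#'
#' @slot hubStats data.frame, one row per hub: `hub`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p_value`, `significant`.
#' @slot filteredModule character vector of surviving module genes.
#' @slot significantHubs character vector of hubs passing both thresholds.
#' @slot params list: `OR_min`, `p_max`, `correction`, universe size.
#'
#' @seealso [filterModule()]
#' @aliases HubFilterResult
#' @export
setClass("HubFilterResult",
  representation(hubStats = "data.frame", filteredModule = "character",
                 significantHubs = "character", params = "list")
)

setValidity("HubFilterResult", function(object) {
  msg <- character(0)
  need <- c("hub", "a", "b", "c", "d", "odds_ratio", "p_value",
            "significant")
  if (!all(need %in% names(object@hubStats)))
    msg <- c(msg, paste("hubStats must have columns:",
                        paste(need, collapse = ", ")))
  if (length(object@significantHubs) == 0L &&
      length(object@filteredModule) > 0L)
    msg <- c(msg, "filtered module must be empty when no hub is significant")
  if (length(msg)) msg else TRUE
})

#' EnrichmentResult: over-representation analysis against a GMT collection
#'
#' @slot table data.frame ordered by `p_value`: `term`, `description`,
#'   `overlap`, `set_size`, `module_size`, `background_size`, `p_value`,
#'   `adjusted_p` (Benjamini-Hochberg), `genes` (comma-separated overlap).
#'
#' @seealso [enrichCollection()]
#' @aliases EnrichmentResult
#' @export
setClass("EnrichmentResult", representation(table = "data.frame"))

setValidity("EnrichmentResult", function(object) {
  t <- object@table
  msg <- character(0)
  if (nrow(t)) {
    if (any(t$overlap > pmin(t$set_size, t$module_size)))
      msg <- c(msg, "overlap cannot exceed min(set size, module size)")
    if (any(t$adjusted_p + 1e-12 < t$p_value))
      msg <- c(msg, "adjusted p must be >= raw p")
    if (is.unsorted(t$p_value))
      msg <- c(msg, "rows must be ordered by p_value")
  }
  if (length(msg)) msg else TRUE
})

#' PermutationResult: permutation test of SNP overlap with regions
#'
#' @slot observed observed number of SNPs overlapping at least one region.
#' @slot nullOverlaps integer vector of overlap counts from `nPerm`
#'   random re-placements of the regions.
#' @slot empiricalP `(#\{null >= observed\} + 1) / (nPerm + 1)`.
#' @slot zScore `(observed - mean(null)) / sd(null)` (0 if sd is 0).
#' @slot nPerm number of permutations.
#' @slot seed seed used for the permutations.
#'
#' @seealso [permutationEnrichment()]
#' @aliases PermutationResult
#' @export
setClass("PermutationResult",
  representation(observed = "integer", nullOverlaps = "integer",
                 empiricalP = "numeric", zScore = "numeric",
                 nPerm = "integer", seed = "integer")
)

setValidity("PermutationResult", function(object) {
  msg <- character(0)
  if (length(object@nullOverlaps) != object@nPerm)
    msg <- c(msg, "nullOverlaps must have length nPerm")
  lo <- 1 / (object@nPerm + 1)
  if (object@empiricalP < lo - 1e-12 || object@empiricalP > 1 + 1e-12)
    msg <- c(msg, "empiricalP out of [1/(nPerm+1), 1]")
  if (length(msg)) msg else TRUE
})
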