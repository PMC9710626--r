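#' @include AllClasses.R
NULL

#' Accessors for modhub result objects
#'
#' Small camelCase accessors so downstream code never touches slots
#' directly.
#'
#' @param x a modhub S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(x) standardGeneric("moduleGenes"))

#' @rdname accessors
#' @export
setGeneric("sourceCliques", function(x) standardGeneric("sourceCliques"))

#' @rdname accessors
#' @export
setGeneric("cliqueStats", function(x) standardGeneric("cliqueStats"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname accessors
#' @export
setGeneric("hubNames", function(x) standardGeneric("hubNames"))

#' @rdname accessors
#' @export
setGeneric("hubScores", function(x) standardGeneric("hubScores"))

#' @rdname accessors
#' @export
setGeneric("hubStats", function(x) standardGeneric("hubStats"))

#' @rdname accessors
#' @export
setGeneric("filteredGenes", function(x) standardGeneric("filteredGenes"))

#' @rdname accessors
#' @export
setGeneric("significantHubs", function(x) standardGeneric("significantHubs"))

#' @rdname accessors
#' @export
setGeneric("enrichTable", function(x) standardGeneric("enrichTable"))

#' @rdname accessors
#' @export
setGeneric("observedOverlap", function(x) standardGeneric("observedOverlap"))

#' @rdname accessors
#' @export
setGeneric("nullOverlaps", function(x) standardGeneric("nullOverlaps"))

#' @rdname accessors
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))

#' @rdname accessors
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))

#' @rdname accessors
#' @export
setMethod("moduleGenes", "GeneModule", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("sourceCliques", "GeneModule", function(x) x@cliques)

#' @rdname accessors
#' @export
setMethod("cliqueStats", "GeneModule", function(x) x@cliqueStats)

#' @rdname accessors
#' @export
setMethod("edgeTable", "RankedEdgeList", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("edgeTable", "ConsensusNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("methodName", "RankedEdgeList", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("hubNames", "HubSet", function(x) x@hubs)

#' @rdname accessors
#' @export
setMethod("hubScores", "HubSet", function(x) x@scores)

#' @rdname accessors
#' @export
setMethod("hubScores", "RegulatorScores", function(x) x@averageOutdegree)

#' @rdname accessors
#' @export
setMethod("hubStats", "HubFilterResult", function(x) x@hubStats)

#' @rdname accessors
#' @export
setMethod("filteredGenes", "HubFilterResult", function(x) x@filteredModule)

#' @rdname accessors
#' @export
setMethod("significantHubs", "HubFilterResult",
          function(x) x@significantHubs)

#' @rdname accessors
#' @export
setMethod("enrichTable", "EnrichmentResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("observedOverlap", "PermutationResult", function(x) x@observed)

#' @rdname accessors
#' @export
setMethod("nullOverlaps", "PermutationResult", function(x) x@nullOverlaps)

#' @rdname accessors
#' @export
setMethod("empiricalP", "PermutationResult", function(x) x@empiricalP)

#' @rdname accessors
#' @export
setMethod("zScore", "PermutationResult", function(x) x@zScore)

setMethod("show", "GeneModule", function(object) {
  cat("GeneModule with", length(object@genes), "genes from",
      length(object@cliques), "significant cliques (",
      nrow(object@cliqueStats), "tested )\n")
})

setMethod("show", "RankedEdgeList", function(object) {
  cat("RankedEdgeList [", object@method, "]:", nrow(object@edges),
      "edges,", length(unique(object@edges$regulator)), "regulators\n")
})

setMethod("show", "RegulatorScores", function(object) {
  cat("RegulatorScores for", length(object@averageOutdegree), "TFs over",
      ncol(object@perMethod), "methods\n")
})

setMethod("show", "HubSet", function(object) {
  cat("HubSet:", length(object@hubs), "hubs (fraction",
      object@fraction, ")\n")
  if (length(object@hubs))
    cat(" ", paste(utils::head(object@hubs, 10), collapse = ", "),
        if (length(object@hubs) > 10) "..." else "", "\n")
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat("ConsensusNetwork:", nrow(object@edges), "edges averaged over",
      object@nMethods, "methods\n")
})

setMethod("show", "HubFilterResult", function(object) {
  cat("HubFilterResult:", length(object@significantHubs), "of",
      nrow(object@hubStats), "hubs significant; filtered module of",
      length(object@filteredModule), "genes\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult with", nrow(object@table), "terms\n")
  if (nrow(object@table))
    print(utils::head(object@table[, c("term", "overlap", "set_size",
                                       "p_value", "adjusted_p")], 5))
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: observed", object@observed, "overlaps;",
      "empirical p =", format(object@empiricalP, digits = 4),
      "( z =", format(object@zScore, digits = 3), ",", object@nPerm,
      "permutations )\n")
})
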