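#' Enumerate maximal cliques of a PPI network
#'
#' Pivoting Bron-Kerbosch enumeration (via igraph) of all maximal cliques
#' of at least `minSize` vertices, returned in a canonical order that does
#' not depend on the input edge order: genes sorted within each clique,
#' cliques sorted by size then lexicographically.
#'
#' @param network undirected `igraph` graph with named vertices.
#' @param minSize minimum clique size (>= 2).
#' @param degreeCap optional maximum vertex degree; vertices above the cap
#'   are excluded before enumeration (guard for pathological hub-dense
#'   inputs). Default `Inf` (no cap).
#' @return list of character vectors.
#' @export
enumerateMaximalCliques <- function(network, minSize = 2L,
                                    degreeCap = Inf) {
  stopifnot(minSize >= 2L)
  if (igraph::vcount(network) == 0L) return(list())
  if (is.finite(degreeCap)) {
    keep <- igraph::V(network)[igraph::degree(network) <= degreeCap]
    network <- igraph::induced_subgraph(network, keep)
  }
  cl <- igraph::max_cliques(network, min = minSize)
  cl <- lapply(cl, function(v) sort(names(v)))
  ord <- order(lengths(cl),
               vapply(cl, paste, "", collapse = "\r"))
  cl[ord]
}

.lookupLogP <- function(genes, de, warn = TRUE) {
  p <- de$p_value[match(genes, de$gene)]
  nmiss <- sum(is.na(p))
  if (nmiss > 0L) {
    if (warn)
      message(sprintf("%d gene(s) absent from DE table scored as p = 1",
                      nmiss))
    p[is.na(p)] <- 1
  }
  log(p)
}

#' Fisher's combined score of a clique
#'
#' `-2 * sum(log p)` over the members' differential-expression p-values.
#' Members absent from the DE table contribute p = 1 (logged), so the
#' score is 0 when no member carries evidence and adding an uninformative
#' member never changes it.
#'
#' @param genes character vector of clique members.
#' @param de data.frame with columns `gene`, `p_value` (see
#'   [readDETable()]).
#' @return non-negative score.
#' @export
cliqueScore <- function(genes, de) {
  -2 * sum(.lookupLogP(genes, de))
}

#' Empirical null distribution of clique scores
#'
#' Draws `nPerm` random gene sets of the given size uniformly without
#' replacement from the DE table and scores each with [cliqueScore()].
#' Under uniform p-values the scores follow a chi-squared distribution
#' with `2 * size` degrees of freedom (Fisher's method).
#'
#' @param size clique size.
#' @param de DE table (data.frame `gene`, `p_value`).
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return numeric vector of `nPerm` null scores.
#' @export
cliqueNull <- function(size, de, nPerm = 10000L, seed = 1L) {
  stopifnot(nPerm >= 100L)
  n <- nrow(de)
  if (size > n)
    stop("clique size exceeds the number of genes in the DE table")
  logp <- log(de$p_value)
  set.seed(seed)
  -2 * vapply(seq_len(nPerm),
              function(i) sum(logp[sample.int(n, size)]), 0)
}

#' Infer a Clique-Sum disease module
#'
#' Scores every maximal clique of the PPI network by Fisher's combined
#' statistic over its members' DE p-values, compares each score to a
#' size-matched permutation null (genes drawn uniformly from the DE
#' table), and returns the union of the cliques whose +1-smoothed
#' empirical p-value passes `alpha` after multiple-testing adjustment
#' across cliques. Network genes missing from the DE table are kept with
#' p = 1 so cliques remain cliques.
#'
#' @param network undirected `igraph` PPI (see [readPPIEdgeList()]).
#' @param de DE table (data.frame `gene`, `p_value`).
#' @param minSize minimum clique size (default 3).
#' @param nPerm permutations per clique size (default 10000).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param multipleTesting `"BH"` (Benjamini-Hochberg, default) or
#'   `"none"`.
#' @param seed RNG seed; nulls for different clique sizes use
#'   deterministic offsets of it.
#' @param degreeCap passed to [enumerateMaximalCliques()].
#' @return [GeneModule].
#' @export
inferCliqueSumModule <- function(network, de, minSize = 3L,
                                 nPerm = 10000L, alpha = 0.05,
                                 multipleTesting = c("BH", "none"),
                                 seed = 1L, degreeCap = Inf) {
  multipleTesting <- match.arg(multipleTesting)
  params <- list(minSize = minSize, nPerm = nPerm, alpha = alpha,
                 multipleTesting = multipleTesting, seed = seed)
  cliques <- enumerateMaximalCliques(network, minSize, degreeCap)
  if (length(cliques) == 0L)
    return(new("GeneModule", genes = character(0), cliques = list(),
               cliqueStats = data.frame(), params = params))
  netGenes <- igraph::V(network)$name
  nmiss <- sum(!netGenes %in% de$gene)
  if (nmiss > 0L)
    message(sprintf("%d network gene(s) absent from DE table scored as p = 1",
                    nmiss))
  extra <- setdiff(netGenes, de$gene)
  deFull <- if (length(extra))
    rbind(de, data.frame(gene = extra, p_value = rep(1, length(extra))))
  else de
  logp <- stats::setNames(log(deFull$p_value), deFull$gene)
  scores <- vapply(cliques, function(cl) -2 * sum(logp[cl]), 0)
  sizes <- lengths(cliques)
  pvals <- numeric(length(cliques))
  for (s in sort(unique(sizes))) {
    null <- cliqueNull(s, deFull, nPerm = nPerm,
                       seed = (seed + s) %% .Machine$integer.max)
    idx <- which(sizes == s)
    ecdfGE <- function(x) sum(null >= x - 1e-12)
    pvals[idx] <- (vapply(scores[idx], ecdfGE, 0L) + 1) / (nPerm + 1)
  }
  adj <- stats::p.adjust(pvals, method = ifelse(multipleTesting == "BH",
                                                "BH", "none"))
  sig <- adj <= alpha
  stats <- data.frame(
    size = sizes, score = scores, p_value = pvals, adj_p = adj,
    significant = sig,
    genes = vapply(cliques, paste, "", collapse = ","))
  stats <- stats[order(stats$p_value, -stats$score), , drop = FALSE]
  rownames(stats) <- NULL
  sigCliques <- cliques[sig]
  new("GeneModule",
      genes = as.character(sort(unique(
        unlist(sigCliques, use.names = FALSE)))),
      cliques = sigCliques, cliqueStats = stats, params = params)
}
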