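#' 2x2 contingency table of a hub's targets against a module
#'
#' Cross-tabulates membership in the hub's consensus-network regulon
#' against membership in the disease module over the evaluation universe
#' (by default all consensus-network target genes). The hub itself is
#' excluded from the universe, and the module is intersected with the
#' universe.
#'
#' @param hub TF identifier.
#' @param module [GeneModule] or character vector of module genes.
#' @param net [ConsensusNetwork].
#' @param universe gene universe; default the consensus target genes.
#' @return integer vector `c(a, b, c, d)`: regulated-in-module,
#'   regulated-outside, unregulated-in-module, unregulated-outside.
#' @export
hubContingency <- function(hub, module, net, universe = NULL) {
  genes <- if (is(module, "GeneModule")) moduleGenes(module) else module
  e <- edgeTable(net)
  if (is.null(universe)) universe <- unique(e$target)
  universe <- setdiff(universe, hub)
  targets <- intersect(unique(e$target[e$regulator == hub]), universe)
  mod <- intersect(genes, universe)
  a <- length(intersect(targets, mod))
  b <- length(targets) - a
  cc <- length(mod) - a
  d <- length(universe) - a - b - cc
  c(a = a, b = b, c = cc, d = d)
}

#' One-sided Fisher's exact test for overrepresentation
#'
#' Conditional (hypergeometric) test of the 2x2 table with alternative
#' "greater", as used to ask whether a hub's targets are overrepresented
#' in a module. The odds ratio is the sample odds ratio `(a d) / (b c)`,
#' reported as `Inf` when `b c = 0` and `a d > 0`, and as 1 for
#' degenerate tables with no information.
#'
#' @param table integer vector `c(a, b, c, d)` or 2x2 matrix (row-major
#'   a, b / c, d).
#' @return list with elements `odds_ratio` and `p_value`.
#' @export
fisherExactEnrichment <- function(table) {
  t <- as.integer(table)
  stopifnot(length(t) == 4L, all(t >= 0L))
  a <- as.numeric(t[1L]); b <- as.numeric(t[2L])
  cc <- as.numeric(t[3L]); d <- as.numeric(t[4L])
  N <- a + b + cc + d
  if (N == 0) return(list(odds_ratio = 1, p_value = 1))
  K <- a + b          # hub targets
  n <- a + cc         # module genes
  p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  or <- if (b * cc > 0) (a * d) / (b * cc)
        else if (a * d > 0) Inf
        else 1
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Filter a module to the genes regulated by significant hubs
#'
#' For every hub, tests overrepresentation of its consensus-network
#' targets inside the module with a one-sided Fisher's exact test; hubs
#' with sample odds ratio > `ORmin` and p < `pMax` (raw thresholds, no
#' correction, per the defaults OR > 2 and P < 0.05) are called
#' significant. The filtered module keeps the module genes with a
#' consensus edge from at least one significant hub; a hub that is itself
#' a module gene survives only if regulated by another significant hub.
#' When no hub is significant the filtered module is empty while the full
#' per-hub statistics table is still returned.
#'
#' @param module [GeneModule] or character vector of module genes.
#' @param hubs [HubSet] or character vector of hub TFs.
#' @param net [ConsensusNetwork].
#' @param ORmin odds-ratio threshold (exclusive), default 2.
#' @param pMax p-value threshold (exclusive), default 0.05.
#' @param correction `"none"` (default, per the raw published thresholds)
#'   or `"BH"` to Benjamini-Hochberg-adjust across hubs before applying
#'   `pMax`.
#' @param universe evaluation universe; default the consensus target
#'   genes.
#' @return [HubFilterResult].
#' @export
filterModule <- function(module, hubs, net, ORmin = 2, pMax = 0.05,
                         correction = c("none", "BH"), universe = NULL) {
  correction <- match.arg(correction)
  genes <- if (is(module, "GeneModule")) moduleGenes(module) else module
  hubIds <- if (is(hubs, "HubSet")) hubNames(hubs) else hubs
  e <- edgeTable(net)
  if (is.null(universe)) universe <- unique(e$target)
  rows <- lapply(hubIds, function(h) {
    tab <- hubContingency(h, genes, net, universe)
    fe <- fisherExactEnrichment(tab)
    data.frame(hub = h, a = tab[["a"]], b = tab[["b"]], c = tab[["c"]],
               d = tab[["d"]], odds_ratio = fe$odds_ratio,
               p_value = fe$p_value)
  })
  stats <- do.call(rbind, rows)
  if (is.null(stats))
    stats <- data.frame(hub = character(0), a = integer(0), b = integer(0),
                        c = integer(0), d = integer(0),
                        odds_ratio = numeric(0), p_value = numeric(0))
  pEff <- if (correction == "BH")
    stats::p.adjust(stats$p_value, "BH") else stats$p_value
  stats$significant <- stats$odds_ratio > ORmin & pEff < pMax
  rownames(stats) <- NULL
  sigHubs <- stats$hub[stats$significant]
  kept <- character(0)
  if (length(sigHubs)) {
    regulated <- unique(e$target[e$regulator %in% sigHubs])
    kept <- sort(intersect(genes, regulated))
  }
  new("HubFilterResult", hubStats = stats, filteredModule = kept,
      significantHubs = as.character(sigHubs),
      params = list(OR_min = ORmin, p_max = pMax,
                    correction = correction,
                    universe_size = length(setdiff(universe, NULL))))
}
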