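#' Infer a ranked gene-regulatory edge list with one method
#'
#' Runs a single network-inference method on a genes x samples expression
#' matrix and returns the top TF-to-target edges ranked by the method's
#' confidence:
#'
#' * `pearson` / `spearman`: absolute correlation between the TF and the
#'   target profile;
#' * `clr`: context-likelihood score from squared Pearson correlation,
#'   standardized per TF (row) and per target (column), combined as
#'   `sqrt(max(z_row, 0)^2 + max(z_col, 0)^2)`;
#' * `regression`: per-target multiple linear regression of the
#'   (per-gene standardized) target on all TFs; confidence is the
#'   absolute standardized coefficient.
#'
#' Externally computed predictions can join the compendium by
#' constructing a [RankedEdgeList] directly (see [makeRankedEdgeList()]).
#'
#' @param expr numeric matrix, genes x samples.
#' @param tfs character vector of regulator identifiers; TFs absent from
#'   `expr` are dropped with a warning.
#' @param method one of `"pearson"`, `"spearman"`, `"clr"`,
#'   `"regression"`.
#' @param maxEdges number of top edges kept; default
#'   `min(100000, |TFs| * |genes| / 10)`.
#' @param seed RNG seed, accepted for interface uniformity (the four
#'   shipped methods are deterministic).
#' @return [RankedEdgeList].
#' @export
inferGRN <- function(expr, tfs,
                     method = c("pearson", "spearman", "clr",
                                "regression"),
                     maxEdges = NULL, seed = 1L) {
  method <- match.arg(method)
  missing <- setdiff(tfs, rownames(expr))
  if (length(missing))
    warning(sprintf("%d TF(s) absent from the expression matrix dropped",
                    length(missing)))
  tfs <- intersect(tfs, rownames(expr))
  if (length(tfs) == 0L) stop("no TFs present in the expression matrix")
  genes <- rownames(expr)
  if (is.null(maxEdges))
    maxEdges <- min(100000L,
                    max(1L, floor(length(tfs) * length(genes) / 10)))
  stopifnot(maxEdges >= 1L)
  set.seed(seed)
  conf <- switch(method,
    pearson = .absCor(expr, tfs, "pearson"),
    spearman = .absCor(expr, tfs, "spearman"),
    clr = .clrScores(expr, tfs),
    regression = .regressionScores(expr, tfs))
  df <- data.frame(
    regulator = rep(tfs, times = length(genes)),
    target = rep(genes, each = length(tfs)),
    confidence = as.vector(conf))
  df <- df[df$regulator != df$target, , drop = FALSE]
  df <- df[order(-df$confidence, df$regulator, df$target), , drop = FALSE]
  df <- utils::head(df, maxEdges)
  rownames(df) <- NULL
  new("RankedEdgeList", method = method, edges = df)
}

.absCor <- function(expr, tfs, method) {
  cc <- suppressWarnings(
    stats::cor(t(expr[tfs, , drop = FALSE]), t(expr), method = method))
  if (anyNA(cc)) {
    message("constant-expression gene(s): correlations set to 0")
    cc[is.na(cc)] <- 0
  }
  abs(cc)
}

.clrScores <- function(expr, tfs) {
  r2 <- .absCor(expr, tfs, "pearson")^2
  zr <- t(scale(t(r2)))          # per TF, across all targets
  zc <- scale(r2)                # per target, across TFs
  zr[is.na(zr)] <- 0
  zc[is.na(zc)] <- 0
  sqrt(pmax(zr, 0)^2 + pmax(zc, 0)^2)
}

.regressionScores <- function(expr, tfs) {
  std <- function(m) {
    s <- apply(m, 1L, stats::sd)
    if (any(s == 0)) {
      message("constant-expression gene(s): coefficients set to 0")
      s[s == 0] <- Inf
    }
    (m - rowMeans(m)) / s
  }
  z <- std(expr)
  X <- t(z[tfs, , drop = FALSE])            # samples x TFs
  Y <- t(z)                                 # samples x genes
  beta <- qr.coef(qr(cbind(1, X)), Y)[-1L, , drop = FALSE]
  rownames(beta) <- tfs
  for (tf in intersect(tfs, colnames(Y))) {  # self-regression excluded
    others <- setdiff(tfs, tf)
    if (length(others)) {
      b <- qr.coef(qr(cbind(1, X[, others, drop = FALSE])), Y[, tf])[-1L]
      beta[others, tf] <- b
    }
    beta[tf, tf] <- 0
  }
  beta[is.na(beta)] <- 0
  abs(beta)
}

#' Construct a RankedEdgeList from an external prediction
#'
#' Entry point for in-house network predictions joining the compendium:
#' edges are restricted to the supplied TF list, self-edges dropped,
#' duplicate pairs keep the maximum confidence, and the list is sorted by
#' non-increasing confidence with deterministic tie-breaking.
#'
#' @param edges data.frame with columns `regulator`, `target`,
#'   `confidence`.
#' @param method label for the prediction.
#' @param tfs optional TF list to restrict regulators to.
#' @return [RankedEdgeList].
#' @export
makeRankedEdgeList <- function(edges, method = "external", tfs = NULL) {
  stopifnot(all(c("regulator", "target", "confidence") %in% names(edges)))
  df <- edges[, c("regulator", "target", "confidence")]
  if (!is.null(tfs)) df <- df[df$regulator %in% tfs, , drop = FALSE]
  df <- df[df$regulator != df$target, , drop = FALSE]
  df <- df[order(-df$confidence, df$regulator, df$target), , drop = FALSE]
  key <- paste(df$regulator, df$target, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  df <- df[order(-df$confidence, df$regulator, df$target), , drop = FALSE]
  rownames(df) <- NULL
  new("RankedEdgeList", method = method, edges = df)
}

#' Per-regulator outdegree at an edge cutoff
#'
#' Counts, among the `topE` highest-confidence edges, how many originate
#' from each regulator. The counts sum to `min(topE, nrow(edges))`.
#'
#' @param edgeList [RankedEdgeList].
#' @param topE edge cutoff; edges beyond it are ignored (default: all).
#' @return named integer vector (regulators with >= 1 edge in the slice).
#' @export
regulatorOutdegree <- function(edgeList, topE = NULL) {
  e <- edgeTable(edgeList)
  n <- if (is.null(topE)) nrow(e) else min(topE, nrow(e))
  top <- e$regulator[seq_len(n)]
  tab <- table(top)
  stats::setNames(as.integer(tab), names(tab))
}

#' Average per-regulator outdegree across methods
#'
#' Arithmetic mean of the per-method outdegrees; a TF absent from a
#' method's map counts 0 for that method, and every TF in `tfs` receives
#' a score (0 if never ranked).
#'
#' @param perMethod non-empty list of named numeric vectors, e.g. from
#'   [regulatorOutdegree()]; names of the list label the methods.
#' @param tfs TF universe; default the union of names seen.
#' @return [RegulatorScores].
#' @export
averageOutdegree <- function(perMethod, tfs = NULL) {
  if (length(perMethod) == 0L)
    stop("at least one outdegree map is required")
  if (is.null(tfs))
    tfs <- sort(unique(unlist(lapply(perMethod, names))))
  m <- matrix(0, length(tfs), length(perMethod),
              dimnames = list(tfs, names(perMethod)))
  for (j in seq_along(perMethod)) {
    v <- perMethod[[j]]
    hit <- intersect(names(v), tfs)
    m[hit, j] <- v[hit]
  }
  new("RegulatorScores", averageOutdegree = rowMeans(m), perMethod = m)
}

#' Select the top fraction of regulators as hubs
#'
#' Takes the `ceiling(fraction * n)` TFs with the highest average
#' outdegree; ties are broken lexicographically by TF identifier so the
#' selection is deterministic. The default fraction of 10% follows the
#' ComHub default.
#'
#' @param scores [RegulatorScores].
#' @param fraction fraction of the TF list to select, in (0, 1].
#' @return [HubSet].
#' @export
selectHubs <- function(scores, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  avg <- hubScores(scores)
  k <- ceiling(fraction * length(avg))
  ord <- order(-avg, names(avg))
  sel <- ord[seq_len(k)]
  new("HubSet", hubs = names(avg)[sel], fraction = fraction,
      scores = avg[sel])
}

#' Rank-averaged consensus network
#'
#' Each method contributes, for its rank-`r` edge out of `m`, a
#' normalized score `1 - (r - 1) / m` in (0, 1]; edges a method did not
#' rank contribute 0 for that method. The consensus score of an edge is
#' the mean over all methods, and the `topE` highest-scoring edges are
#' returned (ties broken by regulator then target identifier).
#'
#' @param edgeLists non-empty list of [RankedEdgeList] objects.
#' @param topE number of consensus edges kept (default: all edges ranked
#'   by at least one method).
#' @return [ConsensusNetwork].
#' @export
consensusNetwork <- function(edgeLists, topE = NULL) {
  if (length(edgeLists) == 0L)
    stop("at least one edge list is required")
  pieces <- lapply(edgeLists, function(el) {
    e <- edgeTable(el)
    m <- nrow(e)
    data.frame(key = paste(e$regulator, e$target, sep = "\r"),
               score = 1 - (seq_len(m) - 1) / m)
  })
  all <- do.call(rbind, pieces)
  tot <- tapply(all$score, all$key, sum)
  keys <- names(tot)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  df <- data.frame(
    regulator = vapply(parts, `[[`, "", 1L),
    target = vapply(parts, `[[`, "", 2L),
    mean_rank_score = as.numeric(tot) / length(edgeLists))
  df <- df[order(-df$mean_rank_score, df$regulator, df$target),
           , drop = FALSE]
  if (!is.null(topE)) df <- utils::head(df, topE)
  rownames(df) <- NULL
  new("ConsensusNetwork", edges = df, nMethods = length(edgeLists))
}

#' Predict hub regulators with the full method compendium
#'
#' Convenience wrapper chaining [inferGRN()] over a set of methods,
#' [regulatorOutdegree()] at a common edge cutoff, [averageOutdegree()]
#' and [selectHubs()]. The default cutoff is `min(100000, 2 * nGenes)`:
#' outdegree is evaluated at an edge budget on the order of a few
#' regulators per gene, the density at which regulatory networks are
#' usually benchmarked, rather than a fixed share of all possible pairs.
#'
#' @param expr numeric matrix, genes x samples.
#' @param tfs regulator identifiers.
#' @param methods inference methods passed to [inferGRN()].
#' @param topE outdegree edge cutoff (default `min(100000, 2 * nrow(expr))`).
#' @param fraction hub fraction for [selectHubs()].
#' @param maxEdges per-method ranked-list length, passed to [inferGRN()].
#' @param seed RNG seed passed to [inferGRN()].
#' @return list with `edgeLists` (per-method [RankedEdgeList]), `scores`
#'   ([RegulatorScores]) and `hubs` ([HubSet]).
#' @export
predictHubs <- function(expr, tfs,
                        methods = c("pearson", "spearman", "clr",
                                    "regression"),
                        topE = NULL, fraction = 0.10, maxEdges = NULL,
                        seed = 1L) {
  if (is.null(topE)) topE <- defaultEdgeBudget(nrow(expr))
  edgeLists <- lapply(methods, function(m)
    inferGRN(expr, tfs, method = m, maxEdges = maxEdges, seed = seed))
  names(edgeLists) <- methods
  od <- lapply(edgeLists, regulatorOutdegree, topE = topE)
  scores <- averageOutdegree(od, tfs = intersect(tfs, rownames(expr)))
  list(edgeLists = edgeLists, scores = scores,
       hubs = selectHubs(scores, fraction = fraction))
}

#' Default edge budget for outdegree evaluation and consensus trimming
#'
#' `min(100000, 2 * nGenes)`: regulatory networks are sparse, with on
#' the order of a few regulators per gene, so outdegree counting and the
#' consensus network are evaluated at an edge budget proportional to the
#' number of genes rather than to the number of possible TF-gene pairs.
#'
#' @param nGenes number of genes in the expression matrix.
#' @return integer edge count.
#' @export
defaultEdgeBudget <- function(nGenes) {
  min(100000L, 2L * as.integer(nGenes))
}
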