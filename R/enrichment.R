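#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= overlap)` of drawing at least the
#' observed overlap between a gene set of interest and an annotation term
#' when sampling `|genes|` genes from the background without replacement.
#' The term set is intersected with the background; genes outside the
#' background are ignored.
#'
#' @param genes gene set of interest (e.g. a module).
#' @param termSet annotation term members.
#' @param background background gene universe (non-empty).
#' @return p-value in (0, 1].
#' @export
hypergeomORA <- function(genes, termSet, background) {
  if (length(background) == 0L) stop("background must be non-empty")
  background <- unique(background)
  genes <- intersect(unique(genes), background)
  termSet <- intersect(unique(termSet), background)
  k <- length(intersect(genes, termSet))
  min(stats::phyper(k - 1, length(termSet),
                    length(background) - length(termSet),
                    length(genes), lower.tail = FALSE), 1)
}

#' Over-representation analysis against a GMT collection
#'
#' Applies [hypergeomORA()] to every term whose (background-restricted)
#' size lies in `[minSet, maxSet]` and adjusts the retained p-values with
#' Benjamini-Hochberg. Rows are ordered by raw p-value (ties broken by
#' term identifier).
#'
#' @param genes gene set of interest.
#' @param collection named list of character vectors from [readGMT()].
#' @param background background gene universe; conventionally all genes
#'   in the DE table.
#' @param minSet,maxSet term-size bounds (defaults 3 and 500).
#' @param labels optional named character vector of user-chosen gene
#'   labels; matching term genes are annotated in an extra column.
#' @return [EnrichmentResult].
#' @export
enrichCollection <- function(genes, collection, background,
                             minSet = 3L, maxSet = 500L, labels = NULL) {
  stopifnot(minSet <= maxSet)
  background <- unique(background)
  genes <- intersect(unique(genes), background)
  desc <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(term) {
    set <- intersect(unique(collection[[term]]), background)
    if (length(set) < minSet || length(set) > maxSet) return(NULL)
    ov <- intersect(genes, set)
    data.frame(
      term = term,
      description = if (!is.null(desc)) desc[[term]] else term,
      overlap = length(ov), set_size = length(set),
      module_size = length(genes),
      background_size = length(background),
      p_value = hypergeomORA(genes, set, background),
      genes = paste(sort(ov), collapse = ","))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(term = character(0), description = character(0),
                      overlap = integer(0), set_size = integer(0),
                      module_size = integer(0),
                      background_size = integer(0),
                      p_value = numeric(0), genes = character(0))
  tab$adjusted_p <- stats::p.adjust(tab$p_value, "BH")
  if (!is.null(labels)) {
    tab$labeled_genes <- vapply(strsplit(tab$genes, ",", fixed = TRUE),
      function(g) {
        hit <- intersect(g, names(labels))
        paste(sprintf("%s=%s", hit, labels[hit]), collapse = ",")
      }, "")
  }
  tab <- tab[order(tab$p_value, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  new("EnrichmentResult", table = tab)
}
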