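#' @importFrom utils read.delim write.table head count.fields
#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame
NULL

## All genomic files use the BED convention (0-based, half-open). GRanges
## is 1-based closed, so [s, e) on file becomes IRanges(s + 1, e) in memory;
## the two are bijective and the writers invert the shift.

.grFromBed0 <- function(chrom, start0, end0, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0), ...)
}

#' Read a normalized expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Rows containing any missing value are dropped (counted in a
#' warning); duplicate gene rows are collapsed by keeping the row with the
#' highest variance.
#'
#' @param path TSV file path.
#' @param transpose set to `TRUE` if the file is samples x genes.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
readExpressionMatrix <- function(path, transpose = FALSE) {
  raw <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2L) stop("expression matrix needs >= 1 sample column")
  ids <- raw[[1L]]
  num <- raw[-1L]
  m <- matrix(NA_real_, nrow(num), ncol(num),
              dimnames = list(ids, colnames(num)))
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]) &
                   !num[[j]] %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   num[[j]][bad[1L]], ids[bad[1L]], colnames(num)[j]))
    m[, j] <- v
  }
  if (transpose) m <- t(m)
  nmiss <- sum(!stats::complete.cases(m))
  if (nmiss > 0L) {
    warning(sprintf("dropped %d gene row(s) with missing values", nmiss))
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  if (anyDuplicated(rownames(m))) {
    ndup <- sum(duplicated(rownames(m)))
    v <- apply(m, 1L, stats::var)
    ord <- order(rownames(m), -v)
    m <- m[ord, , drop = FALSE]
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
    warning(sprintf(
      "collapsed %d duplicated gene row(s), keeping highest variance", ndup))
  }
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  if (ncol(m) < 3L) stop("expression matrix must have at least 3 samples")
  m
}

#' Write an expression matrix as TSV (inverse of [readExpressionMatrix()])
#' @param expr numeric matrix, genes x samples.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a differential-expression table (columns: gene, pvalue)
#'
#' Zero p-values are clamped to the smallest positive representable value;
#' values outside (0, 1] are an error. One row per gene.
#'
#' @param path TSV with a header; the p-value column may be named `pvalue`,
#'   `p_value` or `p.value`.
#' @return data.frame with columns `gene`, `p_value`.
#' @export
readDETable <- function(path) {
  df <- read.delim(path, header = TRUE)
  pcol <- intersect(c("pvalue", "p_value", "p.value"), names(df))
  if (!"gene" %in% names(df) || length(pcol) == 0L)
    stop("DE table must have columns 'gene' and 'pvalue'")
  out <- data.frame(gene = as.character(df$gene),
                    p_value = as.numeric(df[[pcol[1L]]]))
  if (anyDuplicated(out$gene)) stop("duplicate genes in DE table")
  if (anyNA(out$p_value)) stop("missing p-values in DE table")
  nzero <- sum(out$p_value == 0)
  if (nzero > 0L) {
    message(sprintf("clamped %d zero p-value(s) to %.3g", nzero,
                    .Machine$double.xmin))
    out$p_value[out$p_value == 0] <- .Machine$double.xmin
  }
  if (any(out$p_value < 0 | out$p_value > 1))
    stop("p-values must lie in (0, 1]")
  out
}

#' Write a DE table as TSV (columns gene, pvalue)
#' @param de data.frame with columns `gene`, `p_value`.
#' @param path output path.
#' @export
writeDETable <- function(de, path) {
  write.table(data.frame(gene = de$gene, pvalue = de$p_value), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a STRING-style PPI edge list
#'
#' Whitespace- or tab-delimited lines `geneA geneB score`. Confidence
#' scores are accepted on either the 0-1000 STRING combined-score scale or
#' a 0-1 scale, auto-detected from the maximum score; the cutoff is
#' interpreted on the detected scale (a cutoff <= 1 against 0-1000 scores
#' is rescaled by 1000). Self-loops are dropped; duplicate unordered pairs
#' keep the maximum score; edges below the cutoff are dropped.
#'
#' @param path edge list file (an optional header line is skipped).
#' @param scoreCutoff confidence cutoff, default 0.7 (= 700 on the
#'   0-1000 scale).
#' @return undirected `igraph` graph with edge attribute `score`.
#' @export
readPPIEdgeList <- function(path, scoreCutoff = 0.7) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^(protein1|geneA|gene_a|source)\\b",
                             lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  if (length(lines) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("malformed edge line %d: '%s'", bad[1L], lines[bad[1L]]))
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(s)) stop("non-numeric confidence score in edge list")
  if (any(s < 0)) stop("negative confidence scores are not allowed")
  scale1000 <- max(s) > 1
  cutoff <- if (scale1000 && scoreCutoff <= 1) scoreCutoff * 1000
            else scoreCutoff
  keep <- a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  smax <- tapply(s, key, max)
  first <- !duplicated(key)
  lo <- lo[first]; hi <- hi[first]
  s <- as.numeric(smax[key[first]])
  keep <- s >= cutoff
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[keep], to = hi[keep], score = s[keep]),
    directed = FALSE)
  g
}

#' Write a network as a plain edge-list file
#'
#' For an undirected `igraph` PPI, writes `geneA geneB score` TSV (the
#' inverse of [readPPIEdgeList()]); for a [RankedEdgeList] or
#' [ConsensusNetwork], writes `regulator target confidence` with a header.
#' `format = "graphml"` delegates to [igraph::write_graph()].
#'
#' @param network `igraph`, [RankedEdgeList] or [ConsensusNetwork].
#' @param path output path.
#' @param format `"tsv"` or `"graphml"`.
#' @export
writeEdgeList <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (is(network, "RankedEdgeList") || is(network, "ConsensusNetwork")) {
    e <- edgeTable(network)
    names(e)[3L] <- "confidence"
    if (format == "graphml") {
      g <- igraph::graph_from_data_frame(e, directed = TRUE)
      igraph::write_graph(g, path, format = "graphml")
    } else {
      write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(path))
  }
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    e <- igraph::as_data_frame(network, what = "edges")
    if (is.null(e$score)) e$score <- 1
    write.table(e[, c("from", "to", "score")], path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: `term <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Member lists are deduplicated; sets left empty are dropped with a
#' warning.
#'
#' @param path GMT file.
#' @return named list of character vectors with a `descriptions`
#'   attribute (named character vector).
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    warning(sprintf("dropped %d GMT line(s) with no member genes",
                    length(short)))
    parts <- parts[-short]
  }
  terms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(terms)) stop("duplicate term identifiers in GMT")
  desc <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- terms
  names(desc) <- terms
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a gene-set collection as GMT (inverse of [readGMT()])
#' @param collection named list of character vectors, optionally with a
#'   `descriptions` attribute.
#' @param path output path.
#' @export
writeGMT <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(names(collection),
                                             names(collection))
  lines <- vapply(names(collection), function(term) {
    paste(c(term, desc[[term]], collection[[term]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic regions from BED or narrowPeak
#'
#' Files are 0-based half-open; the returned `GRanges` is the usual
#' 1-based closed representation of the same intervals. narrowPeak summit
#' offsets (column 10) are ignored.
#'
#' @param path input file.
#' @param dialect `"bed"` (3-6 columns) or `"narrowPeak"` (10 columns).
#' @return `GRanges` with metadata columns `name` and `score` where the
#'   file carries them.
#' @export
readRegions <- function(path, dialect = c("bed", "narrowPeak")) {
  dialect <- match.arg(dialect)
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (dialect == "narrowPeak" && ncol(df) != 10L)
    stop("narrowPeak requires exactly 10 columns")
  start0 <- as.numeric(df[[2L]]); end0 <- as.numeric(df[[3L]])
  if (anyNA(start0) || anyNA(end0)) stop("non-numeric BED coordinates")
  bad <- which(start0 >= end0)
  if (length(bad))
    stop(sprintf("start >= end at line %d", bad[1L]))
  gr <- .grFromBed0(df[[1L]], as.integer(start0), as.integer(end0))
  if (ncol(df) >= 4L) mcols(gr)$name <- df[[4L]]
  if (ncol(df) >= 5L) mcols(gr)$score <- as.numeric(df[[5L]])
  gr
}

#' Write regions as BED (inverse of [readRegions()] for the BED dialect)
#' @param regions `GRanges`.
#' @param path output path.
#' @export
writeRegionsBED <- function(regions, path) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions))
  mc <- mcols(regions)
  if (!is.null(mc$name)) {
    df$name <- mc$name
    if (!is.null(mc$score)) df$score <- mc$score
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a SNP/SNV table
#'
#' BED-like TSV with columns `chrom`, `pos` (0-based), `id`, and optional
#' `is_eqtl` (0/1) and `annotation` (`intergenic`, `promoter` or `other`)
#' columns; a header line starting with `chrom` is accepted and otherwise
#' inferred from the column count. Identifiers must be unique and
#' positions non-negative.
#'
#' @param path input file.
#' @return `GRanges` of width-1 positions with metadata columns `id` and,
#'   when present, `is_eqtl` and `annotation`.
#' @export
readSNPs <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("^chrom\\b", first, ignore.case = TRUE)
  df <- read.delim(path, header = hasHeader, colClasses = "character")
  if (!hasHeader)
    names(df) <- c("chrom", "pos", "id", "is_eqtl",
                   "annotation")[seq_len(ncol(df))]
  pos <- as.numeric(df$pos)
  if (anyNA(pos)) stop("non-numeric SNP positions")
  if (any(pos < 0)) stop("SNP positions must be non-negative")
  if (anyDuplicated(df$id)) stop("duplicate SNP identifiers")
  gr <- .grFromBed0(df$chrom, as.integer(pos), as.integer(pos) + 1L)
  mcols(gr)$id <- df$id
  if (!is.null(df$is_eqtl))
    mcols(gr)$is_eqtl <- as.logical(as.integer(df$is_eqtl))
  if (!is.null(df$annotation)) {
    ok <- df$annotation %in% c("intergenic", "promoter", "other")
    if (!all(ok)) stop("annotation must be intergenic, promoter or other")
    mcols(gr)$annotation <- df$annotation
  }
  gr
}

#' Write a SNP table (inverse of [readSNPs()])
#' @param snps `GRanges` as returned by [readSNPs()].
#' @param path output path.
#' @export
writeSNPs <- function(snps, path) {
  df <- data.frame(chrom = as.character(seqnames(snps)),
                   pos = start(snps) - 1L, id = mcols(snps)$id)
  if (!is.null(mcols(snps)$is_eqtl))
    df$is_eqtl <- as.integer(mcols(snps)$is_eqtl)
  if (!is.null(mcols(snps)$annotation))
    df$annotation <- mcols(snps)$annotation
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes (TSV: chrom, length)
#' @param path two-column TSV, no header.
#' @return named numeric vector of chromosome lengths in bp.
#' @export
readChromSizes <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  len <- as.numeric(df[[2L]])
  if (anyNA(len) || any(len <= 0)) stop("chromosome lengths must be > 0")
  stats::setNames(len, df[[1L]])
}

#' Write chromosome sizes (inverse of [readChromSizes()])
#' @param genome named numeric vector of chromosome lengths.
#' @param path output path.
#' @export
writeChromSizes <- function(genome, path) {
  write.table(data.frame(names(genome), genome), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor list (one identifier per line)
#' @param path text file.
#' @return character vector.
#' @export
readTFList <- function(path) {
  tf <- trimws(readLines(path))
  tf <- tf[nzchar(tf)]
  if (anyDuplicated(tf)) stop("duplicate TF identifiers")
  tf
}

#' Write a module table
#'
#' One row per module gene with columns `gene`, `in_filtered_module` and
#' `regulating_hubs` (comma-separated significant hubs with a consensus
#' edge to the gene; empty when no filter result is supplied).
#'
#' @param module [GeneModule].
#' @param path output path.
#' @param filter optional [HubFilterResult] for the same module.
#' @param net optional [ConsensusNetwork] used for the `regulating_hubs`
#'   column.
#' @export
writeModuleTable <- function(module, path, filter = NULL, net = NULL) {
  genes <- sort(moduleGenes(module))
  inFiltered <- if (is.null(filter)) rep(NA, length(genes))
                else genes %in% filteredGenes(filter)
  hubsOf <- rep("", length(genes))
  if (!is.null(filter) && !is.null(net) &&
      length(significantHubs(filter))) {
    e <- edgeTable(net)
    e <- e[e$regulator %in% significantHubs(filter), , drop = FALSE]
    tab <- split(e$regulator, e$target)
    hit <- genes %in% names(tab)
    hubsOf[hit] <- vapply(tab[genes[hit]],
                          function(h) paste(sort(unique(h)),
                                            collapse = ","), "")
  }
  write.table(data.frame(gene = genes, in_filtered_module = inFiltered,
                         regulating_hubs = hubsOf),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module table written by [writeModuleTable()]
#' @param path module TSV.
#' @return data.frame with columns `gene`, `in_filtered_module`,
#'   `regulating_hubs`.
#' @export
readModuleTable <- function(path) {
  read.delim(path, header = TRUE,
             colClasses = c("character", "logical", "character"),
             na.strings = "NA")
}
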