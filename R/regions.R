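#' @importFrom IRanges overlapsAny
NULL

#' Count SNPs overlapping at least one region
#'
#' Each SNP is counted once, no matter how many regions cover it.
#' Interval semantics are the half-open file convention (a SNP at the
#' exclusive end of a region does not overlap it).
#'
#' @param snps width-1 `GRanges` (see [readSNPs()]).
#' @param regions `GRanges` (see [readRegions()]).
#' @return integer count.
#' @export
countSNPOverlaps <- function(snps, regions) {
  sum(suppressWarnings(IRanges::overlapsAny(snps, regions)))
}

## uniform start for a width-w region on a chromosome of length L,
## 0-based: any start in [0, L - w]
.randomStarts <- function(widths, lens) {
  floor(stats::runif(length(widths)) * (lens - widths + 1))
}

#' Randomly re-place regions on their own chromosomes
#'
#' Each region is moved to a uniformly random position on the chromosome
#' it came from, preserving its length and staying within bounds
#' (regioneR-style region randomization).
#'
#' @param regions `GRanges`.
#' @param genome named numeric vector of chromosome lengths (see
#'   [readChromSizes()]).
#' @param seed RNG seed.
#' @return `GRanges` of re-placed regions (metadata columns preserved).
#' @export
permuteRegions <- function(regions, genome, seed = 1L) {
  chrom <- as.character(seqnames(regions))
  if (!all(chrom %in% names(genome)))
    stop("regions on chromosomes absent from the genome")
  lens <- genome[chrom]
  w <- width(regions)
  if (any(w > lens))
    stop("region longer than its chromosome")
  set.seed(seed)
  s0 <- .randomStarts(w, lens)
  out <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, width = w))
  mcols(out) <- mcols(regions)
  out
}

## exact covered-SNP count from 0-based positions and half-open intervals,
## via merged-interval boundary search (odd findInterval index = inside)
.countCovered <- function(posByChrom, chrom, s0, e0) {
  total <- 0L
  for (ch in names(posByChrom)) {
    i <- which(chrom == ch)
    if (length(i) == 0L) next
    o <- i[order(s0[i])]
    s <- s0[o]; e <- e0[o]
    ms <- s[1L]; me <- e[1L]
    bounds <- numeric(0)
    if (length(o) > 1L) {
      for (j in 2L:length(o)) {
        if (s[j] > me) {
          bounds <- c(bounds, ms, me)
          ms <- s[j]; me <- e[j]
        } else me <- max(me, e[j])
      }
    }
    bounds <- c(bounds, ms, me)
    total <- total + sum(findInterval(posByChrom[[ch]], bounds) %% 2L == 1L)
  }
  total
}

#' Permutation test for SNP enrichment in regions
#'
#' Compares the observed number of SNPs falling in the region set with
#' the counts obtained after randomly re-placing the regions on their
#' chromosomes `nPerm` times ([permuteRegions()] scheme). The empirical
#' p-value uses +1 smoothing, `(#\{null >= observed\} + 1) / (nPerm + 1)`,
#' so it can never be exactly zero.
#'
#' @param snps width-1 `GRanges`.
#' @param regions `GRanges`.
#' @param genome named numeric vector of chromosome lengths.
#' @param nPerm number of permutations (>= 100; default 10000).
#' @param seed RNG seed.
#' @return [PermutationResult].
#' @export
permutationEnrichment <- function(snps, regions, genome,
                                  nPerm = 10000L, seed = 1L) {
  stopifnot(nPerm >= 100L)
  chrom <- as.character(seqnames(regions))
  if (!all(chrom %in% names(genome)))
    stop("regions on chromosomes absent from the genome")
  lens <- unname(genome[chrom])
  w <- width(regions)
  if (any(w > lens)) stop("region longer than its chromosome")
  pos0 <- start(snps) - 1L
  posByChrom <- split(pos0, as.character(seqnames(snps)))
  s0 <- start(regions) - 1L
  observed <- .countCovered(posByChrom, chrom, s0, s0 + w)
  set.seed(seed)
  null <- integer(nPerm)
  for (i in seq_len(nPerm)) {
    rs <- .randomStarts(w, lens)
    null[i] <- .countCovered(posByChrom, chrom, rs, rs + w)
  }
  p <- (sum(null >= observed) + 1) / (nPerm + 1)
  sdn <- stats::sd(null)
  z <- if (sdn == 0) { warning("degenerate null (sd = 0); z set to 0"); 0 }
       else (observed - mean(null)) / sdn
  new("PermutationResult", observed = as.integer(observed),
      nullOverlaps = null, empiricalP = p, zScore = z,
      nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Label SNPs or regions that fall in promoter windows
#'
#' A promoter is the window `[tss - upstream, tss + downstream)` around a
#' transcription start site on the + strand (0-based half-open file
#' convention), mirrored around the TSS on the - strand. An element is
#' labeled `promoter` if it intersects at least one window.
#'
#' @param x `GRanges` of SNPs or regions.
#' @param tss data.frame with columns `gene`, `chromosome`, `strand`
#'   (`+`/`-`), `tss` (0-based position).
#' @param upstream,downstream window extent in bp (defaults 2000 and
#'   500).
#' @return `x` with a logical metadata column `promoter`.
#' @export
annotatePromoters <- function(x, tss, upstream = 2000L,
                              downstream = 500L) {
  stopifnot(all(c("gene", "chromosome", "strand", "tss") %in% names(tss)))
  if (!all(tss$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  plus <- tss$strand == "+"
  s0 <- ifelse(plus, tss$tss - upstream, tss$tss - downstream + 1)
  e0 <- ifelse(plus, tss$tss + downstream, tss$tss + upstream + 1)
  s0 <- pmax(s0, 0)
  keep <- e0 > s0
  prom <- GenomicRanges::GRanges(tss$chromosome[keep],
                                 IRanges::IRanges(s0[keep] + 1, e0[keep]))
  mcols(x)$promoter <- suppressWarnings(IRanges::overlapsAny(x, prom))
  x
}

#' eQTL fold-enrichment between two SNP sets
#'
#' Ratio of the eQTL fraction in the foreground set over the background
#' set, with a one-sided Fisher's exact test on the 2x2 table
#' (eQTL / not x foreground / background).
#'
#' @param foreground,background non-empty `GRanges` with a logical
#'   `is_eqtl` metadata column, or plain logical vectors of flags.
#' @return list with elements `fold` (ratio of eQTL fractions; `Inf`
#'   when the background fraction is 0) and `p_value`.
#' @export
eqtlFoldEnrichment <- function(foreground, background) {
  flag <- function(x) {
    if (is.logical(x)) x
    else {
      f <- mcols(x)$is_eqtl
      if (is.null(f)) stop("missing is_eqtl column")
      f
    }
  }
  fg <- flag(foreground); bg <- flag(background)
  if (length(fg) == 0L || length(bg) == 0L)
    stop("both SNP sets must be non-empty")
  a <- sum(fg); b <- sum(!fg); cc <- sum(bg); d <- sum(!bg)
  fracFg <- a / (a + b)
  fracBg <- cc / (cc + d)
  fold <- if (fracBg == 0) { if (fracFg > 0) Inf else NaN }
          else fracFg / fracBg
  fe <- fisherExactEnrichment(c(a, b, cc, d))
  list(fold = fold, p_value = fe$p_value)
}
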