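#' Synthetic expression with planted hub regulons
#'
#' Emulates the regulatory structure the hub-prediction stage is meant to
#' recover: hub TF profiles are standard normal, each hub target equals
#' `weight * hub + noise` with weights drawn from Uniform(0.5, 1.5) under
#' a random sign, decoy TFs regulate at most 2 weak targets, and all
#' remaining genes are pure noise. Defaults are the planted-model study
#' conditions: 5 hubs with 40 targets each among 50 TFs, 200 samples,
#' noise sd 0.5.
#'
#' @param nGenes number of non-TF genes (>= `nHubs * targetsPerHub`).
#' @param nTFs number of TFs.
#' @param nHubs number of planted hub TFs (<= `nTFs`).
#' @param targetsPerHub regulon size per hub (disjoint regulons).
#' @param nSamples number of samples (>= 3).
#' @param noiseSd sd of the additive Gaussian noise on targets.
#' @param seed RNG seed; the output is a pure function of seed and
#'   parameters.
#' @return list with `expr` (matrix, (nTFs + nGenes) x nSamples), `tfs`
#'   (character), and `truth` (list: `plantedHubs`, `hubRegulons`,
#'   `decoyRegulons`).
#' @export
generateRegulatoryExpression <- function(nGenes = 250L, nTFs = 50L,
                                         nHubs = 5L, targetsPerHub = 40L,
                                         nSamples = 200L, noiseSd = 0.5,
                                         seed = 1L) {
  if (nHubs > nTFs) stop("nHubs must not exceed nTFs")
  if (nHubs * targetsPerHub > nGenes)
    stop("not enough genes for the requested hub regulons")
  stopifnot(nSamples >= 3L)
  set.seed(seed)
  tfs <- sprintf("TF%03d", seq_len(nTFs))
  genes <- sprintf("G%04d", seq_len(nGenes))
  tfExpr <- matrix(stats::rnorm(nTFs * nSamples), nTFs,
                   dimnames = list(tfs, NULL))
  hubs <- sort(sample(tfs, nHubs))
  pool <- sample(genes)
  regulons <- split(pool[seq_len(nHubs * targetsPerHub)],
                    rep(hubs, each = targetsPerHub))
  geneExpr <- matrix(stats::rnorm(nGenes * nSamples, sd = 1), nGenes,
                     dimnames = list(genes, NULL))
  wire <- function(target, tf, sdNoise) {
    w <- stats::runif(1, 0.5, 1.5) * sample(c(-1, 1), 1)
    w * tfExpr[tf, ] + stats::rnorm(nSamples, sd = sdNoise)
  }
  for (h in hubs)
    for (g in regulons[[h]]) geneExpr[g, ] <- wire(g, h, noiseSd)
  decoys <- setdiff(tfs, hubs)
  free <- setdiff(genes, unlist(regulons, use.names = FALSE))
  decoyRegulons <- list()
  for (tf in decoys) {
    k <- min(sample(0:2, 1), length(free))
    if (k == 0L) next
    tg <- free[seq_len(k)]
    free <- free[-seq_len(k)]
    # decoy targets get double noise so decoy edges rank below hub edges
    for (g in tg) geneExpr[g, ] <- wire(g, tf, 2 * noiseSd)
    decoyRegulons[[tf]] <- tg
  }
  expr <- rbind(tfExpr, geneExpr)
  colnames(expr) <- sprintf("S%03d", seq_len(nSamples))
  list(expr = expr, tfs = tfs,
       truth = list(plantedHubs = hubs, hubRegulons = regulons,
                    decoyRegulons = decoyRegulons))
}

#' Erdos-Renyi PPI network with planted cliques
#'
#' Background G(n, p) graph over named genes, with complete subgraphs
#' planted on disjoint node subsets. All edges carry a confidence score
#' of 999 (top STRING scale) so the network is unaffected by score
#' cutoffs.
#'
#' @param nNodes number of nodes.
#' @param edgeProb background edge probability in `[0, 1]`.
#' @param plantedCliqueSizes integer vector of clique sizes (their sum
#'   must not exceed `nNodes`).
#' @param seed RNG seed.
#' @param geneNames optional node names (default `G0001`, ...).
#' @return list with `network` (undirected `igraph`, edge attribute
#'   `score`) and `truth` (list: `plantedCliques`).
#' @export
generatePPIWithCliques <- function(nNodes, edgeProb = 0.05,
                                   plantedCliqueSizes = integer(0),
                                   seed = 1L, geneNames = NULL) {
  stopifnot(edgeProb >= 0, edgeProb <= 1)
  if (sum(plantedCliqueSizes) > nNodes)
    stop("planted cliques do not fit in the network")
  if (any(plantedCliqueSizes > nNodes))
    stop("planted clique larger than the network")
  if (is.null(geneNames)) geneNames <- sprintf("G%04d", seq_len(nNodes))
  stopifnot(length(geneNames) == nNodes)
  set.seed(seed)
  g <- igraph::sample_gnp(nNodes, edgeProb)
  igraph::V(g)$name <- geneNames
  members <- sample(geneNames)
  cliques <- list()
  at <- 1L
  for (s in plantedCliqueSizes) {
    cl <- sort(members[at:(at + s - 1L)])
    at <- at + s
    idx <- match(cl, geneNames)
    pairs <- t(utils::combn(idx, 2L))
    g <- igraph::add_edges(g, t(pairs))
    cliques[[length(cliques) + 1L]] <- cl
  }
  g <- igraph::simplify(g)
  igraph::E(g)$score <- 999
  list(network = g, truth = list(plantedCliques = cliques))
}

#' Differential-expression table with planted signal genes
#'
#' Signal genes receive small p-values, log-uniform between 1e-8 and the
#' `signalP` cap (a bounded heavy-left-tail, so that no single gene can
#' dominate Fisher's combined statistic of a whole clique); all other
#' genes are Uniform(0, 1). Zeros are clamped to the smallest positive
#' double.
#'
#' @param genes full gene universe.
#' @param signalGenes genes carrying differential-expression signal.
#' @param signalP cap on signal p-values (default 1e-3).
#' @param seed RNG seed.
#' @return data.frame with columns `gene`, `p_value`.
#' @export
generateDETable <- function(genes, signalGenes = character(0),
                            signalP = 1e-3, seed = 1L) {
  stopifnot(all(signalGenes %in% genes))
  set.seed(seed)
  p <- stats::runif(length(genes))
  hit <- genes %in% signalGenes
  lo <- -log10(signalP)
  p[hit] <- 10^-stats::runif(sum(hit), lo, max(8, lo + 1))
  p[p == 0] <- .Machine$double.xmin
  data.frame(gene = genes, p_value = p)
}

#' Genomic regions and SNPs with planted overlap enrichment
#'
#' Regions are placed uniformly on the genome; each SNP falls inside a
#' random region with probability `insideFraction` and uniformly on the
#' genome otherwise. eQTL flags are drawn per stratum (inside vs outside
#' placement). Defaults plant the strong-enrichment study condition:
#' half of the SNPs inside regions that cover 1% of a 5 Mb genome.
#'
#' @param genome named numeric vector of chromosome lengths; default 3
#'   chromosomes totalling 5 Mb.
#' @param nRegions,regionLen region count and fixed length (defaults 50
#'   x 1 kb = 1% of the default genome).
#' @param nSnps number of SNPs.
#' @param insideFraction probability a SNP is planted inside a region.
#' @param eqtlRates numeric vector `c(inside = , outside = )` of eQTL
#'   rates per placement stratum.
#' @param seed RNG seed.
#' @return list with `regions` (`GRanges` with `name`), `snps` (width-1
#'   `GRanges` with `id`, `is_eqtl`) and `genome`.
#' @export
generateGenomeTracks <- function(genome = c(chr1 = 2e6, chr2 = 2e6,
                                            chr3 = 1e6),
                                 nRegions = 50L, regionLen = 1000L,
                                 nSnps = 200L, insideFraction = 0.5,
                                 eqtlRates = c(inside = 0.4,
                                               outside = 0.05),
                                 seed = 1L) {
  stopifnot(insideFraction >= 0, insideFraction <= 1,
            all(eqtlRates >= 0), all(eqtlRates <= 1))
  set.seed(seed)
  chrom <- sample(names(genome), nRegions, replace = TRUE,
                  prob = genome / sum(genome))
  rs0 <- .randomStarts(rep(regionLen, nRegions), genome[chrom])
  regions <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(rs0 + 1, width = regionLen))
  mcols(regions)$name <- sprintf("peak%03d", seq_len(nRegions))
  inside <- stats::runif(nSnps) < insideFraction
  pos0 <- numeric(nSnps)
  schrom <- character(nSnps)
  for (i in seq_len(nSnps)) {
    if (inside[i]) {
      j <- sample.int(nRegions, 1L)
      schrom[i] <- chrom[j]
      pos0[i] <- rs0[j] + sample.int(regionLen, 1L) - 1L
    } else {
      schrom[i] <- sample(names(genome), 1L, prob = genome / sum(genome))
      pos0[i] <- sample.int(genome[[schrom[i]]], 1L) - 1L
    }
  }
  snps <- GenomicRanges::GRanges(schrom,
                                 IRanges::IRanges(pos0 + 1, width = 1L))
  mcols(snps)$id <- sprintf("rs%05d", seq_len(nSnps))
  mcols(snps)$is_eqtl <- ifelse(
    inside, stats::runif(nSnps) < eqtlRates[["inside"]],
    stats::runif(nSnps) < eqtlRates[["outside"]])
  list(regions = regions, snps = snps, genome = genome)
}

#' Gene-set collection with a planted disease term
#'
#' Builds a miniature disease-ontology-style GMT: one term containing the
#' planted disease genes plus `nTerms - 1` random terms.
#'
#' @param genes gene universe.
#' @param diseaseGenes members of the planted `DISEASE` term.
#' @param nTerms total number of terms.
#' @param setSize size of the random terms.
#' @param seed RNG seed.
#' @return named list of character vectors with `descriptions` attribute.
#' @export
generateGeneSets <- function(genes, diseaseGenes, nTerms = 10L,
                             setSize = 30L, seed = 1L) {
  set.seed(seed)
  sets <- c(list(DISEASE = sort(unique(diseaseGenes))),
            lapply(seq_len(nTerms - 1L), function(i)
              sort(sample(genes, min(setSize, length(genes))))))
  names(sets)[-1L] <- sprintf("TERM%03d", seq_len(nTerms - 1L))
  attr(sets, "descriptions") <- stats::setNames(
    c("planted disease term",
      sprintf("random term %d", seq_len(nTerms - 1L))), names(sets))
  sets
}

#' End-to-end planted disease study
#'
#' Composes every input of the pipeline with a single known truth:
#' planted hub TFs regulate the planted disease genes (expression),
#' the disease genes form planted cliques in the PPI network and carry
#' small DE p-values, and a second group of decoy-signal genes forms
#' cliques with small p-values but is regulated by no hub -- so hub
#' filtering should discard them and raise the precision of the module
#' for disease genes.
#'
#' @param seed RNG seed.
#' @param nTFs number of TFs (default 30).
#' @param nHubs planted hubs (default 3; top 10% of 30 TFs).
#' @param genesPerHub disease genes per hub regulon (default 20).
#' @param nDecoySignal decoy-signal genes in cliques but unregulated
#'   (default 30).
#' @param nOtherGenes background genes (default 310).
#' @param cliqueSize size of the planted cliques (default 5).
#' @param nSamples samples in the expression matrix (default 150).
#' @param noiseSd expression noise sd (default 0.5).
#' @param edgeProb background PPI edge probability (default 0.02).
#' @param signalP DE signal cap (default 1e-4).
#' @return list with `expr`, `tfs`, `ppi` (igraph), `de` (data.frame)
#'   and `truth` (list: `diseaseGenes`, `decoyGenes`, `plantedHubs`,
#'   `hubRegulons`, `plantedCliques`).
#' @export
generateDiseaseStudy <- function(seed = 1L, nTFs = 30L, nHubs = 3L,
                                 genesPerHub = 20L, nDecoySignal = 30L,
                                 nOtherGenes = 310L, cliqueSize = 5L,
                                 nSamples = 150L, noiseSd = 0.5,
                                 edgeProb = 0.02, signalP = 1e-4) {
  nDisease <- nHubs * genesPerHub
  stopifnot(nDisease %% cliqueSize == 0L,
            nDecoySignal %% cliqueSize == 0L)
  reg <- generateRegulatoryExpression(
    nGenes = nDisease + nDecoySignal + nOtherGenes, nTFs = nTFs,
    nHubs = nHubs, targetsPerHub = genesPerHub, nSamples = nSamples,
    noiseSd = noiseSd, seed = seed)
  disease <- sort(unlist(reg$truth$hubRegulons, use.names = FALSE))
  nonTf <- setdiff(rownames(reg$expr), reg$tfs)
  set.seed(seed + 1000L)
  decoy <- sort(sample(setdiff(nonTf, disease), nDecoySignal))
  ## planted cliques tile the disease and decoy gene groups
  allGenes <- nonTf
  ppi <- generatePPIWithCliques(
    nNodes = length(allGenes), edgeProb = edgeProb,
    seed = seed + 2000L, geneNames = sort(allGenes))
  g <- ppi$network
  cliques <- c(split(disease, rep(seq_len(nDisease / cliqueSize),
                                  each = cliqueSize)),
               split(decoy, rep(seq_len(nDecoySignal / cliqueSize),
                                each = cliqueSize)))
  for (cl in cliques) {
    idx <- match(cl, igraph::V(g)$name)
    g <- igraph::add_edges(g, t(t(utils::combn(idx, 2L))))
  }
  g <- igraph::simplify(g)
  igraph::E(g)$score <- 999
  de <- generateDETable(allGenes, signalGenes = c(disease, decoy),
                        signalP = signalP, seed = seed + 3000L)
  list(expr = reg$expr, tfs = reg$tfs, ppi = g, de = de,
       truth = list(diseaseGenes = disease, decoyGenes = decoy,
                    plantedHubs = reg$truth$plantedHubs,
                    hubRegulons = reg$truth$hubRegulons,
                    plantedCliques = unname(cliques)))
}

#' Write a complete synthetic input bundle to disk
#'
#' Generates a planted disease study plus genome tracks and a gene-set
#' collection, and writes every file the pipeline consumes: expression
#' TSV, TF list, DE TSV, PPI edge list, GMT, regions BED, SNP TSV,
#' chromosome sizes and a `truth.json` record of the planted ground
#' truth.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param ... passed to [generateDiseaseStudy()].
#' @return invisibly, a named list of the file paths written.
#' @export
simulateBundle <- function(dir, seed = 1L, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  study <- generateDiseaseStudy(seed = seed, ...)
  tracks <- generateGenomeTracks(seed = seed + 4000L)
  gmt <- generateGeneSets(study$de$gene, study$truth$diseaseGenes,
                          seed = seed + 5000L)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    tf_list = file.path(dir, "tf_list.txt"),
    de_table = file.path(dir, "de_table.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    gmt = file.path(dir, "genesets.gmt"),
    regions = file.path(dir, "regions.bed"),
    snps = file.path(dir, "snps.tsv"),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    truth = file.path(dir, "truth.json"))
  writeExpressionMatrix(study$expr, paths$expression)
  writeLines(study$tfs, paths$tf_list)
  writeDETable(study$de, paths$de_table)
  writeEdgeList(study$ppi, paths$ppi)
  writeGMT(gmt, paths$gmt)
  writeRegionsBED(tracks$regions, paths$regions)
  writeSNPs(tracks$snps, paths$snps)
  writeChromSizes(tracks$genome, paths$chrom_sizes)
  jsonlite::write_json(
    list(seed = seed, diseaseGenes = study$truth$diseaseGenes,
         decoyGenes = study$truth$decoyGenes,
         plantedHubs = study$truth$plantedHubs,
         hubRegulons = study$truth$hubRegulons),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
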