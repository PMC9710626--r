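#!/usr/bin/env Rscript
# Thin command-line wrapper over the modhub package.
#
#   Rscript scripts/modhub.R <command> [options]
#
# Commands: simulate, module, hubs, filter, enrich, snp-enrich, pipeline

suppressPackageStartupMessages({
  library(modhub)
  library(optparse)
})

usage <- function() {
  cat("usage: Rscript scripts/modhub.R <command> [options]\n",
      "commands: simulate | module | hubs | filter | enrich |",
      "snp-enrich | pipeline\n",
      "run a command with --help for its options\n")
  quit(status = 1L)
}

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L) usage()
cmd <- argv[1L]
rest <- argv[-1L]

parse <- function(opts) {
  parse_args(OptionParser(option_list = opts,
                          prog = paste("modhub.R", cmd)), args = rest)
}

if (cmd == "simulate") {
  o <- parse(list(
    make_option("--out", type = "character", default = "simulated"),
    make_option("--seed", type = "integer", default = 1L)))
  paths <- simulateBundle(o$out, seed = o$seed)
  cat("wrote bundle to", o$out, "\n")

} else if (cmd == "module") {
  o <- parse(list(
    make_option("--ppi", type = "character"),
    make_option("--de", type = "character"),
    make_option("--out", type = "character", default = "module"),
    make_option("--score-cutoff", type = "double", default = 0.7,
                dest = "cutoff"),
    make_option("--min-size", type = "integer", default = 3L,
                dest = "minSize"),
    make_option("--n-perm", type = "integer", default = 10000L,
                dest = "nPerm"),
    make_option("--alpha", type = "double", default = 0.05),
    make_option("--seed", type = "integer", default = 1L)))
  net <- readPPIEdgeList(o$ppi, o$cutoff)
  de <- readDETable(o$de)
  mod <- inferCliqueSumModule(net, de, minSize = o$minSize,
                              nPerm = o$nPerm, alpha = o$alpha,
                              seed = o$seed)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  writeModuleTable(mod, file.path(o$out, "module.tsv"))
  write.table(cliqueStats(mod), file.path(o$out, "clique_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("module of", length(moduleGenes(mod)), "genes ->", o$out, "\n")

} else if (cmd == "hubs") {
  o <- parse(list(
    make_option("--expression", type = "character"),
    make_option("--tf-list", type = "character", dest = "tfs"),
    make_option("--out", type = "character", default = "hubs"),
    make_option("--fraction", type = "double", default = 0.10),
    make_option("--top-e", type = "integer", default = NULL,
                dest = "topE"),
    make_option("--seed", type = "integer", default = 1L)))
  expr <- readExpressionMatrix(o$expression)
  tfs <- intersect(readTFList(o$tfs), rownames(expr))
  pred <- predictHubs(expr, tfs, topE = o$topE, fraction = o$fraction,
                      seed = o$seed)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  for (m in names(pred$edgeLists))
    writeEdgeList(pred$edgeLists[[m]],
                  file.path(o$out, sprintf("edges_%s.tsv", m)))
  sc <- hubScores(pred$scores)
  write.table(data.frame(tf = names(sc), average_outdegree = unname(sc)),
              file.path(o$out, "hub_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(hubNames(pred$hubs), file.path(o$out, "hubs.txt"))
  cons <- consensusNetwork(pred$edgeLists,
                           topE = defaultEdgeBudget(nrow(expr)))
  writeEdgeList(cons, file.path(o$out, "consensus_network.tsv"))
  cat(length(hubNames(pred$hubs)), "hubs ->", o$out, "\n")

} else if (cmd == "filter") {
  o <- parse(list(
    make_option("--module", type = "character"),
    make_option("--hubs", type = "character"),
    make_option("--consensus", type = "character"),
    make_option("--out", type = "character", default = "filtered"),
    make_option("--or-min", type = "double", default = 2, dest = "orMin"),
    make_option("--p-max", type = "double", default = 0.05,
                dest = "pMax")))
  modGenes <- readModuleTable(o$module)$gene
  hubs <- readTFList(o$hubs)
  e <- read.delim(o$consensus)
  names(e)[3L] <- "mean_rank_score"
  cons <- new("ConsensusNetwork", edges = e, nMethods = 1L)
  filt <- filterModule(modGenes, hubs, cons, ORmin = o$orMin,
                       pMax = o$pMax)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  write.table(hubStats(filt), file.path(o$out, "hub_filter.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(filteredGenes(filt),
             file.path(o$out, "filtered_module.tsv"))
  cat(length(significantHubs(filt)), "significant hub(s); filtered",
      "module of", length(filteredGenes(filt)), "genes ->", o$out, "\n")

} else if (cmd == "enrich") {
  o <- parse(list(
    make_option("--genes", type = "character",
                help = "one gene per line"),
    make_option("--gmt", type = "character"),
    make_option("--background", type = "character",
                help = "one gene per line"),
    make_option("--out", type = "character", default = "enrichment.tsv")))
  res <- enrichCollection(readLines(o$genes), readGMT(o$gmt),
                          readLines(o$background))
  write.table(enrichTable(res), o$out, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat("enrichment table ->", o$out, "\n")

} else if (cmd == "snp-enrich") {
  o <- parse(list(
    make_option("--snps", type = "character"),
    make_option("--regions", type = "character"),
    make_option("--dialect", type = "character", default = "bed"),
    make_option("--chrom-sizes", type = "character", dest = "sizes"),
    make_option("--tss", type = "character", default = NULL),
    make_option("--pvalue-max", type = "double", default = NULL,
                dest = "pMax", help = "optional SNP p-value filter"),
    make_option("--n-perm", type = "integer", default = 10000L,
                dest = "nPerm"),
    make_option("--out", type = "character", default = "snp_enrich"),
    make_option("--seed", type = "integer", default = 1L)))
  snps <- readSNPs(o$snps)
  regions <- readRegions(o$regions, o$dialect)
  genome <- readChromSizes(o$sizes)
  res <- permutationEnrichment(snps, regions, genome, nPerm = o$nPerm,
                               seed = o$seed)
  dir.create(o$out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(observed = observedOverlap(res), empirical_p = empiricalP(res),
         z_score = zScore(res), n_perm = o$nPerm, seed = o$seed),
    file.path(o$out, "permutation_result.json"), auto_unbox = TRUE,
    digits = NA)
  write.table(data.frame(null_overlap = nullOverlaps(res)),
              file.path(o$out, "null_distribution.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(o$tss)) {
    tss <- read.delim(o$tss)
    snps <- annotatePromoters(snps, tss)
    writeSNPs(snps, file.path(o$out, "snps_annotated.tsv"))
  }
  cat("observed", observedOverlap(res), "overlaps, empirical p",
      empiricalP(res), "->", o$out, "\n")

} else if (cmd == "pipeline") {
  o <- parse(list(
    make_option("--config", type = "character"),
    make_option("--out", type = "character", default = "run")))
  runPipeline(o$config, o$out)
  cat("pipeline outputs ->", o$out, "\n")

} else usage()
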