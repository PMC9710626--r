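#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default: hub fraction 0.10,
#' odds-ratio threshold 2 and p-value threshold 0.05 follow the published
#' defaults; the rest are the package's documented choices. Input paths
#' are `NULL` and must be supplied by the user (via YAML or the `config`
#' list).
#'
#' @return named list of parameters.
#' @export
defaultConfig <- function() {
  list(
    expression = NULL, tf_list = NULL, de_table = NULL, ppi = NULL,
    gmt = NULL,
    ppi_score_cutoff = 0.7,
    min_size = 3L, n_perm = 10000L, alpha = 0.05,
    multiple_testing = "BH",
    grn_methods = c("pearson", "spearman", "clr", "regression"),
    max_edges = NULL, top_e = NULL, hub_fraction = 0.10,
    consensus_top_e = NULL,
    or_min = 2, p_max = 0.05, correction = "none",
    enrich_background = NULL, min_set = 3L, max_set = 500L,
    seed = 1L)
}

#' Read a pipeline configuration file (YAML), merged over defaults
#' @param path YAML file with flat keys as in [defaultConfig()].
#' @param overrides named list applied on top of the file.
#' @return configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  cfg
}

## content hash of a stage: parameters plus md5 of the input files
.stageHash <- function(params, files = character(0)) {
  md5 <- if (length(files)) unname(tools::md5sum(files)) else character(0)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(params = params, md5 = md5), tmp)
  unname(tools::md5sum(tmp))
}

.cacheHit <- function(outDir, stage, hash, outputs) {
  f <- file.path(outDir, ".cache", paste0(stage, ".hash"))
  file.exists(f) && identical(readLines(f, warn = FALSE), hash) &&
    all(file.exists(outputs))
}

.cacheRecord <- function(outDir, stage, hash) {
  d <- file.path(outDir, ".cache")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  writeLines(hash, file.path(d, paste0(stage, ".hash")))
}

#' Run the full disease-module pipeline
#'
#' Chains module inference, hub prediction, consensus-network
#' construction, hub filtering and (when a GMT is configured) enrichment
#' analysis, writing every result plus a machine-readable manifest to
#' `outDir`. Stages are cached by a content hash of their inputs and
#' parameters, so rerunning with an unchanged configuration reuses
#' upstream results and reproduces identical outputs.
#'
#' @param config configuration list (see [defaultConfig()]) or path to a
#'   YAML file.
#' @param outDir output directory.
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir, quiet = FALSE) {
  cfg <- if (is.character(config)) readRunConfig(config) else
    readRunConfig(NULL, config)
  say <- function(...) if (!quiet) message("[modhub] ", ...)
  need <- c("expression", "tf_list", "de_table", "ppi")
  miss <- need[vapply(cfg[need], is.null, TRUE)]
  if (length(miss))
    stop("config is missing input path(s): ", paste(miss, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  out <- function(f) file.path(outDir, f)
  manifest <- list(package = "modhub",
                   version = as.character(utils::packageVersion("modhub")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   parameters = cfg[setdiff(names(cfg), need)],
                   inputs = cfg[need], stages = list())

  ## stage: module inference -------------------------------------------
  modFiles <- c(out("module.tsv"), out("clique_stats.tsv"))
  modParams <- cfg[c("ppi_score_cutoff", "min_size", "n_perm", "alpha",
                     "multiple_testing", "seed")]
  h <- .stageHash(modParams, c(cfg$ppi, cfg$de_table))
  de <- tryCatch(readDETable(cfg$de_table),
                 error = function(e) stop("stage module: ",
                                          conditionMessage(e)))
  if (.cacheHit(outDir, "module", h, modFiles)) {
    say("module: cached")
    moduleGeneSet <- readModuleTable(out("module.tsv"))$gene
    module <- NULL
  } else {
    say("module: inferring Clique-Sum module")
    net <- tryCatch(readPPIEdgeList(cfg$ppi, cfg$ppi_score_cutoff),
                    error = function(e) stop("stage module: ",
                                             conditionMessage(e)))
    module <- inferCliqueSumModule(
      net, de, minSize = cfg$min_size, nPerm = cfg$n_perm,
      alpha = cfg$alpha,
      multipleTesting = cfg$multiple_testing, seed = cfg$seed)
    writeModuleTable(module, out("module.tsv"))
    utils::write.table(cliqueStats(module), out("clique_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .cacheRecord(outDir, "module", h)
    moduleGeneSet <- moduleGenes(module)
  }
  manifest$stages$module <- list(hash = h, n_genes = length(moduleGeneSet))

  ## stage: hub prediction + consensus ---------------------------------
  hubFiles <- c(out("hub_scores.tsv"), out("hubs.txt"),
                out("consensus_network.tsv"))
  grnParams <- cfg[c("grn_methods", "max_edges", "top_e", "hub_fraction",
                     "consensus_top_e", "seed")]
  h2 <- .stageHash(grnParams, c(cfg$expression, cfg$tf_list))
  if (.cacheHit(outDir, "hubs", h2, hubFiles)) {
    say("hubs: cached")
    hubIds <- readTFList(out("hubs.txt"))
    cons <- {
      e <- utils::read.delim(out("consensus_network.tsv"))
      names(e)[3L] <- "mean_rank_score"
      new("ConsensusNetwork", edges = e,
          nMethods = length(cfg$grn_methods))
    }
  } else {
    say("hubs: inferring GRNs (", paste(cfg$grn_methods, collapse = ", "),
        ")")
    expr <- readExpressionMatrix(cfg$expression)
    tfs <- readTFList(cfg$tf_list)
    tfsIn <- intersect(tfs, rownames(expr))
    pred <- predictHubs(expr, tfsIn, methods = cfg$grn_methods,
                        topE = cfg$top_e, fraction = cfg$hub_fraction,
                        maxEdges = cfg$max_edges, seed = cfg$seed)
    edgeLists <- pred$edgeLists
    for (m in names(edgeLists))
      writeEdgeList(edgeLists[[m]], out(sprintf("edges_%s.tsv", m)))
    scores <- pred$scores
    hubs <- pred$hubs
    consTopE <- if (is.null(cfg$consensus_top_e))
      defaultEdgeBudget(nrow(expr)) else cfg$consensus_top_e
    utils::write.table(
      data.frame(tf = names(hubScores(scores)),
                 average_outdegree = unname(hubScores(scores)),
                 scores@perMethod, check.names = FALSE),
      out("hub_scores.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    writeLines(hubNames(hubs), out("hubs.txt"))
    cons <- consensusNetwork(edgeLists, topE = consTopE)
    writeEdgeList(cons, out("consensus_network.tsv"))
    .cacheRecord(outDir, "hubs", h2)
    hubIds <- hubNames(hubs)
  }
  manifest$stages$hubs <- list(hash = h2, n_hubs = length(hubIds))

  ## stage: hub filtering ----------------------------------------------
  say("filter: testing hub overrepresentation")
  filt <- filterModule(moduleGeneSet, hubIds, cons,
                       ORmin = cfg$or_min, pMax = cfg$p_max,
                       correction = cfg$correction)
  utils::write.table(hubStats(filt), out("hub_filter.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(filteredGenes(filt), out("filtered_module.tsv"))
  e <- edgeTable(cons)
  hg <- e[e$regulator %in% significantHubs(filt) &
            e$target %in% filteredGenes(filt), , drop = FALSE]
  utils::write.table(hg, out("hub_gene_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest$stages$filter <- list(
    n_significant_hubs = length(significantHubs(filt)),
    significant_hubs = significantHubs(filt),
    n_filtered = length(filteredGenes(filt)),
    empty_filtered_module = length(filteredGenes(filt)) == 0L)
  if (length(filteredGenes(filt)) == 0L)
    say("filter: empty filtered module (no significant hub)")

  ## stage: enrichment --------------------------------------------------
  if (!is.null(cfg$gmt)) {
    say("enrich: over-representation analysis")
    gmt <- readGMT(cfg$gmt)
    bg <- if (is.null(cfg$enrich_background)) de$gene
          else readTFList(cfg$enrich_background)
    for (what in c("module", "filtered")) {
      gs <- if (what == "module") moduleGeneSet else filteredGenes(filt)
      res <- enrichCollection(gs, gmt, bg, minSet = cfg$min_set,
                              maxSet = cfg$max_set)
      utils::write.table(enrichTable(res),
                         out(sprintf("enrichment_%s.tsv", what)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$enrich <- list(background_size = length(unique(bg)))
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
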