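# modhub

Disease-module inference and hub-regulator filtering on molecular
networks.

Transcriptomic disease modules — sets of genes on a protein–protein
interaction (PPI) network that jointly carry differential-expression
(DE) evidence — typically span hundreds to thousands of genes, far too
many for follow-up. `modhub` is for systems-biology and network-medicine
analysts who want to reduce such modules to a regulatory core. It chains
four ideas:

1. **Clique-Sum module inference.** Every maximal clique *C* of the PPI
   network is scored with Fisher's combined statistic over its members'
   DE p-values, *S(C) = −2 Σ<sub>g∈C</sub> ln p<sub>g</sub>*, and
   compared with a size-matched permutation null (empirical p with +1
   smoothing, BH-adjusted across cliques). The module is the union of
   the significant cliques.
2. **Consensus hub prediction.** Several gene-regulatory-network
   inference methods (Pearson, Spearman, CLR-style, TF regression; plus
   any external ranked edge list) each produce TF→target edges. The
   per-regulator outdegree at a common edge budget is averaged across
   methods and the top 10% of TFs become hub candidates.
3. **Hub filtering.** Each hub's consensus-network regulon is tested for
   overrepresentation inside the module with a one-sided Fisher's exact
   test; hubs with sample odds ratio > 2 and *P* < 0.05 are significant,
   and only module genes regulated by a significant hub are kept.
4. **Evaluation and validation.** Hypergeometric over-representation
   analysis against GMT collections, plus genomic validation of
   candidate regulators: a permutation test for SNP enrichment in
   binding regions and an eQTL fold-enrichment test.

A synthetic-data generator with planted ground truth
(`generateDiseaseStudy()`, `simulateBundle()`) makes the whole pipeline
testable offline.

## Worked example

```r
library(modhub)

study  <- generateDiseaseStudy(seed = 1)      # planted ground truth
module <- inferCliqueSumModule(study$ppi, study$de, seed = 1)
module
#> GeneModule with 93 genes from 31 significant cliques ( 118 tested )

pred <- predictHubs(study$expr, study$tfs)    # 4-method compendium
pred$hubs
#> HubSet: 3 hubs (fraction 0.1 )
#>   TF020, TF013, TF029

cons <- consensusNetwork(pred$edgeLists,
                         topE = defaultEdgeBudget(nrow(study$expr)))
filt <- filterModule(module, pred$hubs, cons)
filt
#> HubFilterResult: 3 of 3 hubs significant; filtered module of 65 genes
hubStats(filt)
#>     hub  a  b  c   d odds_ratio      p_value significant
#> 1 TF020 22 21 70 290   4.340136 1.486075e-05        TRUE
#> 2 TF013 23 22 69 290   4.393939 8.710352e-06        TRUE
#> 3 TF029 23 15 69 297   6.600000 1.315427e-07        TRUE

mean(moduleGenes(module)  %in% study$truth$diseaseGenes)  # 0.645
mean(filteredGenes(filt)  %in% study$truth$diseaseGenes)  # 0.923
```

The 93-gene Clique-Sum module mixes the 60 planted disease genes with
decoy-signal cliques; all three planted hub TFs are recovered and pass
the OR > 2, *P* < 0.05 rule (the `a..d` columns are each hub's 2×2
contingency table over the consensus-target universe), and filtering
shrinks the module to 65 genes while raising its precision for the
planted disease genes from 0.65 to 0.92.

The same flow is available from the shell via
`Rscript scripts/modhub.R <simulate|module|hubs|filter|enrich|snp-enrich|pipeline>`,
and `runPipeline()` executes every stage from one YAML config with a
manifest and content-hash stage caching.

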