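gr0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
}
snp0 <- function(chrom, pos0) gr0(chrom, pos0, pos0 + 1)

test_that("SNP-region overlap respects half-open boundaries", {
  region <- gr0("chr1", 0, 10)
  expect_identical(countSNPOverlaps(snp0("chr1", 5), region), 1L)
  expect_identical(countSNPOverlaps(snp0("chr1", 10), region), 0L)
  expect_identical(countSNPOverlaps(snp0("chr1", 0), region), 1L)
  expect_identical(countSNPOverlaps(snp0("chr2", 5), region), 0L)
})

test_that("overlap counting matches the quadratic oracle", {
  set.seed(8)
  chroms <- c("chr1", "chr2", "chr3")
  sc <- sample(chroms, 1000, TRUE)
  sp <- sample.int(1e5, 1000, TRUE) - 1L
  rc <- sample(chroms, 50, TRUE)
  rs <- sample.int(1e5 - 500, 50, TRUE) - 1L
  re <- rs + sample.int(500, 50, TRUE)
  got <- countSNPOverlaps(snp0(sc, sp), gr0(rc, rs, re))
  expect_identical(got, oracleCoveredCount(sc, sp, rc, rs, re))
})

test_that("overlap count is invariant to region order and splitting", {
  sc <- rep("chr1", 100)
  set.seed(3)
  sp <- sample.int(1000, 100) - 1L
  regions <- gr0("chr1", c(100, 400), c(300, 700))
  split2 <- gr0("chr1", c(400, 200, 100, 550), c(550, 300, 200, 700))
  expect_identical(countSNPOverlaps(snp0(sc, sp), regions),
                   countSNPOverlaps(snp0(sc, sp), split2))
})

test_that("region permutation preserves lengths and respects bounds", {
  genome <- c(chr1 = 1000, chr2 = 500)
  regions <- gr0(c("chr1", "chr1", "chr2"), c(0, 900, 0),
                 c(50, 990, 500))
  perm <- permuteRegions(regions, genome, seed = 6)
  expect_identical(GenomicRanges::width(perm),
                   GenomicRanges::width(regions))
  expect_true(all(GenomicRanges::start(perm) >= 1))
  expect_true(all(GenomicRanges::end(perm) <=
                    genome[as.character(GenomicRanges::seqnames(perm))]))
  # a region as long as its chromosome is forced to position 0
  expect_identical(GenomicRanges::start(perm)[3], 1L)
  expect_error(permuteRegions(gr0("chr2", 0, 501), genome),
               "longer than")
  expect_error(permuteRegions(gr0("chrX", 0, 10), genome), "absent")
})

test_that("permuted placements are uniform over valid starts", {
  genome <- c(chr1 = 1000)
  # 10000 independent placements of a 100 bp region (valid starts 0..900)
  regions <- gr0(rep("chr1", 10000), rep(0, 10000), rep(100, 10000))
  starts <- GenomicRanges::start(permuteRegions(regions, genome,
                                                seed = 19)) - 1L
  bins <- cut(starts, breaks = seq(0, 901, length.out = 11),
              include.lowest = TRUE, right = FALSE)
  cs <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(cs$p.value, 0.01)
})

test_that("permutation enrichment detects planted overlap", {
  tracks <- generateGenomeTracks(seed = 42)  # 50% inside 1% coverage
  res <- permutationEnrichment(tracks$snps, tracks$regions,
                               tracks$genome, nPerm = 999, seed = 1)
  expect_equal(empiricalP(res), 1 / 1000)
  expect_gt(zScore(res), 5)
  expect_identical(observedOverlap(res),
                   countSNPOverlaps(tracks$snps, tracks$regions))
  expect_length(nullOverlaps(res), 999L)
})

test_that("empirical p is 1 when every null beats the observation", {
  genome <- c(chr1 = 1000)
  region <- gr0("chr1", 0, 1000)   # covers the whole chromosome
  snps <- snp0(rep("chr1", 20), seq(0, 950, 50))
  expect_warning(
    res <- permutationEnrichment(snps, region, genome, nPerm = 100,
                                 seed = 2),
    "sd = 0")
  expect_equal(empiricalP(res), 1)
  expect_equal(zScore(res), 0)
})

test_that("promoter annotation mirrors the window across strands", {
  tss <- data.frame(gene = c("gPlus", "gMinus"),
                    chromosome = "chr1", strand = c("+", "-"),
                    tss = c(5000, 20000))
  lab <- function(pos) {
    out <- annotatePromoters(snp0("chr1", pos), tss,
                             upstream = 2000, downstream = 500)
    out$promoter
  }
  expect_true(lab(5000))            # exactly at TSS
  expect_false(lab(5500))           # tss + downstream, half-open
  expect_true(lab(5499))
  expect_true(lab(3000))            # tss - upstream
  expect_false(lab(2999))
  # minus strand: mirror image
  expect_true(lab(20000))
  expect_true(lab(22000))           # upstream on - strand
  expect_false(lab(22001))
  expect_true(lab(19501))
  expect_false(lab(19500))
  expect_error(annotatePromoters(snp0("chr1", 1),
                                 transform(tss, strand = "x")),
               "strand")
  # random positions against a direct interval oracle
  set.seed(14)
  pos <- sample.int(30000, 300) - 1L
  got <- annotatePromoters(snp0(rep("chr1", 300), pos), tss)$promoter
  want <- (pos >= 3000 & pos < 5500) | (pos >= 19501 & pos < 22001)
  expect_identical(got, want)
})

test_that("eQTL fold enrichment and its Fisher test", {
  same <- eqtlFoldEnrichment(rep(c(TRUE, FALSE), 10),
                             rep(c(TRUE, FALSE), 50))
  expect_equal(same$fold, 1)
  expect_gt(same$p_value, 0.5)

  fg <- c(rep(TRUE, 20), rep(FALSE, 80))
  bg <- c(rep(TRUE, 2), rep(FALSE, 98))
  res <- eqtlFoldEnrichment(fg, bg)
  expect_equal(res$fold, 10)
  expect_equal(res$p_value, oracleFisherTail(20, 80, 2, 98),
               tolerance = 1e-12)

  allIn <- eqtlFoldEnrichment(rep(TRUE, 10), c(rep(TRUE, 10),
                                               rep(FALSE, 90)))
  expect_equal(allIn$fold, 10)      # maximal: fg fraction 1 vs bg 0.1
  zeroBg <- eqtlFoldEnrichment(c(TRUE, FALSE), rep(FALSE, 10))
  expect_identical(zeroBg$fold, Inf)
  expect_lte(zeroBg$p_value, 1)
  expect_error(eqtlFoldEnrichment(logical(0), TRUE), "non-empty")

  # GRanges input with is_eqtl metadata
  s1 <- snp0(rep("chr1", 4), 1:4); s1$is_eqtl <- c(TRUE, TRUE, FALSE, FALSE)
  s2 <- snp0(rep("chr1", 4), 11:14); s2$is_eqtl <- c(TRUE, FALSE, FALSE, FALSE)
  expect_equal(eqtlFoldEnrichment(s1, s2)$fold, 2)
})
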