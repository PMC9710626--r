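consensusFromEdges <- function(reg, tgt) {
  n <- length(reg)
  new("ConsensusNetwork",
      edges = data.frame(regulator = reg, target = tgt,
                         mean_rank_score = seq(1, 0.5, length.out = n)),
      nMethods = 1L)
}

test_that("hub contingency counts the four set sizes", {
  universe <- sprintf("g%03d", 1:100)
  module <- universe[1:20]
  net <- consensusFromEdges(rep("H", 10), universe[1:10])
  tab <- hubContingency("H", module, net, universe)
  expect_identical(unname(tab), c(10L, 0L, 10L, 80L))

  netOut <- consensusFromEdges(rep("H", 10), universe[31:40])
  tab2 <- hubContingency("H", module, net = netOut, universe)
  expect_identical(unname(tab2[c("a")]), 0L)

  # zero-target hub
  tab3 <- hubContingency("H2", module, netOut, universe)
  expect_identical(unname(tab3[c("a", "b")]), c(0L, 0L))

  # random fixture vs direct set operations
  set.seed(31)
  for (rep in 1:10) {
    uni <- sprintf("g%03d", 1:60)
    mod <- sample(uni, 25)
    tgts <- sample(uni, 18)
    net <- consensusFromEdges(rep("H", 18), tgts)
    tab <- hubContingency("H", mod, net, uni)
    u <- setdiff(uni, "H")
    m <- intersect(mod, u); t <- intersect(tgts, u)
    expect_identical(unname(tab),
                     c(length(intersect(t, m)), length(setdiff(t, m)),
                       length(setdiff(m, t)),
                       length(setdiff(u, union(m, t)))))
  }
})

test_that("the hub itself is excluded from the universe", {
  uni <- c("H", sprintf("g%02d", 1:9))
  net <- consensusFromEdges(rep("H", 3), c("g01", "g02", "g03"))
  tab <- hubContingency("H", c("H", "g01"), net, uni)
  expect_identical(sum(tab), 9L)   # universe of 10 minus the hub
  expect_identical(unname(tab[["a"]]), 1L)
})

test_that("one-sided Fisher's exact matches the hypergeometric tail", {
  fe <- fisherExactEnrichment(c(10, 0, 10, 80))
  expect_identical(fe$odds_ratio, Inf)
  expect_equal(fe$p_value, oracleFisherTail(10, 0, 10, 80),
               tolerance = 1e-12)
  # closed form: P(X >= 10) = P(X = 10) = C(20,10) / C(100,10)
  expect_equal(fe$p_value, choose(20, 10) / choose(100, 10),
               tolerance = 1e-12)

  none <- fisherExactEnrichment(c(5, 5, 5, 5))
  expect_equal(none$odds_ratio, 1)
  expect_gt(none$p_value, 0.5)

  zero <- fisherExactEnrichment(c(0, 0, 0, 0))
  expect_equal(zero$odds_ratio, 1)
  expect_equal(zero$p_value, 1)

  # random sample of margin-fixed tables against the enumeration oracle
  set.seed(77)
  for (i in 1:200) {
    t <- as.integer(rmultinom(1, sample(1:40, 1), rep(0.25, 4)))
    fe <- fisherExactEnrichment(t)
    expect_equal(fe$p_value, oracleFisherTail(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
  }
  # and against stats::fisher.test as a second, conditional-test oracle
  for (i in 1:25) {
    t <- as.integer(rmultinom(1, 30, c(0.3, 0.2, 0.2, 0.3)))
    ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(fisherExactEnrichment(t)$p_value, ft$p.value,
                 tolerance = 1e-10)
  }
})

test_that("a planted regulating hub is significant and prunes the module", {
  universe <- sprintf("g%03d", 1:500)
  module <- universe[1:40]
  regulated <- c(universe[1:30], universe[41:50])  # 30 in, 10 out
  net <- consensusFromEdges(rep("H", 40), regulated)
  res <- filterModule(module, "H", net, universe = universe)
  expect_identical(significantHubs(res), "H")
  expect_identical(filteredGenes(res), sort(universe[1:30]))
  st <- hubStats(res)
  expect_identical(st$a, 30L)
  expect_gt(st$odds_ratio, 2)
})

test_that("no significant hub means an empty filtered module with stats", {
  uni <- sprintf("g%03d", 1:100)
  set.seed(5)
  net <- consensusFromEdges(rep(c("H1", "H2"), each = 10),
                            sample(uni, 20))
  module <- sample(uni, 30)
  res <- filterModule(module, c("H1", "H2"), net, ORmin = Inf,
                      universe = uni)
  expect_length(filteredGenes(res), 0L)
  expect_identical(nrow(hubStats(res)), 2L)
  expect_false(any(hubStats(res)$significant))

  # an empty module yields a complete, all-insignificant table too
  resEmpty <- filterModule(character(0), c("H1", "H2"), net,
                           universe = uni)
  expect_length(filteredGenes(resEmpty), 0L)
  expect_identical(nrow(hubStats(resEmpty)), 2L)
})

test_that("filtering is monotone in both thresholds", {
  set.seed(19)
  uni <- sprintf("g%03d", 1:200)
  module <- sample(uni, 60)
  reg <- rep(sprintf("H%d", 1:5), each = 30)
  tgt <- as.vector(vapply(1:5, function(i)
    c(sample(module, 20), sample(setdiff(uni, module), 10)),
    character(30)))
  key <- !duplicated(paste(reg, tgt))
  net <- consensusFromEdges(reg[key], tgt[key])
  hubs <- sprintf("H%d", 1:5)
  configs <- expand.grid(or = c(1, 2, 4, Inf),
                         p = c(0.001, 0.05, 0.5))
  for (i in seq_len(nrow(configs))) for (j in seq_len(nrow(configs))) {
    if (configs$or[i] >= configs$or[j] && configs$p[i] <= configs$p[j]) {
      fi <- filteredGenes(filterModule(module, hubs, net,
                                       ORmin = configs$or[i],
                                       pMax = configs$p[i],
                                       universe = uni))
      fj <- filteredGenes(filterModule(module, hubs, net,
                                       ORmin = configs$or[j],
                                       pMax = configs$p[j],
                                       universe = uni))
      expect_true(all(fi %in% fj))
    }
  }
})

test_that("module hubs survive only via another significant hub", {
  uni <- c("H1", "H2", sprintf("g%02d", 1:58))
  module <- c("H1", sprintf("g%02d", 1:20))
  # H2 regulates H1 and most module genes; H1 regulates nothing
  net <- consensusFromEdges(rep("H2", 19), c("H1", sprintf("g%02d", 1:18)))
  res <- filterModule(module, c("H1", "H2"), net, universe = uni)
  expect_true("H2" %in% significantHubs(res))
  expect_true("H1" %in% filteredGenes(res))  # regulated by H2
  res2 <- filterModule(module, "H1", net, universe = uni)
  expect_length(filteredGenes(res2), 0L)     # H1 itself regulates nothing
})
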