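smallExpr <- function(seed = 5) {
  set.seed(seed)
  m <- matrix(rnorm(5 * 30), 5, 30,
              dimnames = list(c("TF1", "TF2", "g1", "g2", "g3"), NULL))
  m
}

test_that("a perfectly correlated target ranks first for pearson", {
  set.seed(2)
  m <- matrix(rnorm(4 * 20), 4, 20,
              dimnames = list(c("TF1", "TF2", "t1", "t2"), NULL))
  m["t1", ] <- m["TF1", ]
  rel <- inferGRN(m, c("TF1", "TF2"), "pearson", maxEdges = 10)
  top <- edgeTable(rel)[1, ]
  expect_identical(top$regulator, "TF1")
  expect_identical(top$target, "t1")
  expect_equal(top$confidence, 1)
})

test_that("pearson confidences equal the pairwise correlation oracle", {
  m <- smallExpr()
  rel <- inferGRN(m, c("TF1", "TF2"), "pearson", maxEdges = 10)
  e <- edgeTable(rel)
  for (i in seq_len(nrow(e))) {
    expect_equal(e$confidence[i],
                 abs(cor(m[e$regulator[i], ], m[e$target[i], ])),
                 tolerance = 1e-12)
  }
  # spearman likewise, on ranks
  relS <- inferGRN(m, c("TF1", "TF2"), "spearman", maxEdges = 10)
  eS <- edgeTable(relS)
  for (i in seq_len(nrow(eS))) {
    expect_equal(eS$confidence[i],
                 abs(cor(rank(m[eS$regulator[i], ]),
                         rank(m[eS$target[i], ]))),
                 tolerance = 1e-12)
  }
})

test_that("edge lists are deterministic and drop self/missing TFs", {
  m <- smallExpr()
  r1 <- inferGRN(m, c("TF1", "TF2"), "regression")
  r2 <- inferGRN(m, c("TF1", "TF2"), "regression")
  expect_identical(edgeTable(r1), edgeTable(r2))
  expect_false(any(edgeTable(r1)$regulator == edgeTable(r1)$target))
  expect_warning(inferGRN(m, c("TF1", "TFmissing"), "pearson"),
                 "absent")
})

test_that("constant-expression genes get zero correlation", {
  m <- smallExpr()
  m["g1", ] <- 3
  expect_message(rel <- inferGRN(m, c("TF1", "TF2"), "pearson",
                                 maxEdges = 10), "constant")
  e <- edgeTable(rel)
  expect_equal(e$confidence[e$target == "g1"], c(0, 0))
})

test_that("clr scores combine row and column standardization", {
  m <- smallExpr()
  rel <- inferGRN(m, c("TF1", "TF2"), "clr", maxEdges = 10)
  e <- edgeTable(rel)
  r2 <- cor(t(m[c("TF1", "TF2"), ]), t(m))^2
  zr <- t(scale(t(r2))); zc <- scale(r2)
  want <- sqrt(pmax(zr, 0)^2 + pmax(zc, 0)^2)
  for (i in seq_len(nrow(e)))
    expect_equal(e$confidence[i], want[e$regulator[i], e$target[i]],
                 tolerance = 1e-12)
})

test_that("regulator outdegree counts the top slice and conserves mass", {
  e <- data.frame(regulator = rep("a", 10),
                  target = sprintf("t%02d", 1:10),
                  confidence = 10:1)
  rel <- new("RankedEdgeList", method = "x", edges = e)
  expect_identical(regulatorOutdegree(rel, 10), c(a = 10L))
  e2 <- data.frame(regulator = rep(c("a", "b"), 5),
                   target = sprintf("t%02d", 1:10),
                   confidence = 10:1)
  rel2 <- new("RankedEdgeList", method = "x", edges = e2)
  expect_identical(regulatorOutdegree(rel2, 4), c(a = 2L, b = 2L))
  set.seed(9)
  e3 <- data.frame(regulator = sample(LETTERS[1:6], 80, TRUE),
                   target = sprintf("t%03d", 1:80),
                   confidence = sort(runif(80), decreasing = TRUE))
  rel3 <- new("RankedEdgeList", method = "x", edges = e3)
  od <- regulatorOutdegree(rel3, 50)
  oracle <- table(e3$regulator[1:50])
  expect_identical(od[names(oracle)], stats::setNames(
    as.integer(oracle), names(oracle)))
  expect_identical(sum(od), 50L)
  # topE beyond the list length uses all edges
  expect_identical(sum(regulatorOutdegree(rel3, 1000)), 80L)
})

test_that("outdegree averaging is the elementwise mean with 0 fill", {
  one <- averageOutdegree(list(m1 = c(a = 3, b = 1)))
  expect_equal(hubScores(one), c(a = 3, b = 1))
  two <- averageOutdegree(list(m1 = c(a = 10), m2 = c(a = 0, b = 4)))
  expect_equal(hubScores(two), c(a = 5, b = 2))
  expect_error(averageOutdegree(list()), "at least one")
  set.seed(4)
  maps <- lapply(1:3, function(i)
    stats::setNames(rpois(4, 5), sample(letters[1:6], 4)))
  got <- hubScores(averageOutdegree(maps, tfs = letters[1:6]))
  for (tf in letters[1:6]) {
    want <- mean(vapply(maps, function(m)
      if (tf %in% names(m)) m[[tf]] else 0, 0))
    expect_equal(unname(got[tf]), want)
  }
})

test_that("hub selection takes the top ceiling(fraction * n) with ties", {
  sc <- averageOutdegree(list(m = c(a = 5, b = 5, c = 1,
                                    setNames(10:4, letters[4:10]))))
  expect_length(hubNames(selectHubs(sc, 0.10)), 1L)
  expect_identical(hubNames(selectHubs(sc, 0.10)), "d")  # max score 10
  expect_length(hubNames(selectHubs(sc, 1.0)), 10L)
  sc3 <- averageOutdegree(list(m = c(a = 5, b = 5, c = 1)))
  hubs <- selectHubs(sc3, 0.34)
  expect_identical(hubNames(hubs), c("a", "b"))
})

test_that("consensus network averages normalized ranks", {
  e1 <- data.frame(regulator = c("A", "A", "B"),
                   target = c("x", "y", "z"),
                   confidence = c(3, 2, 1))
  l1 <- new("RankedEdgeList", method = "m1", edges = e1)
  single <- consensusNetwork(list(l1))
  expect_identical(edgeTable(single)$target, c("x", "y", "z"))
  expect_equal(edgeTable(single)$mean_rank_score, c(1, 2 / 3, 1 / 3))

  e2 <- data.frame(regulator = c("A", "B", "A"),
                   target = c("x", "z", "y"),
                   confidence = c(9, 8, 7))
  l2 <- new("RankedEdgeList", method = "m2", edges = e2)
  cons <- consensusNetwork(list(l1, l2))
  ce <- edgeTable(cons)
  expect_equal(ce$mean_rank_score[ce$regulator == "A" & ce$target == "x"],
               1)                      # rank 1 in both methods
  expect_identical(ce$regulator[1], "A")

  set.seed(12)
  lists <- lapply(1:3, function(i) {
    ee <- data.frame(regulator = sample(LETTERS[1:4], 20, TRUE),
                     target = sprintf("t%02d", sample(40, 20)),
                     confidence = sort(runif(20), decreasing = TRUE))
    key <- paste(ee$regulator, ee$target)
    makeRankedEdgeList(ee[!duplicated(key), ], sprintf("m%d", i))
  })
  cons3 <- consensusNetwork(lists)
  ce3 <- edgeTable(cons3)
  # brute-force rank-average oracle
  for (i in seq_len(nrow(ce3))) {
    contrib <- vapply(lists, function(l) {
      e <- edgeTable(l)
      hit <- which(e$regulator == ce3$regulator[i] &
                     e$target == ce3$target[i])
      if (length(hit)) 1 - (hit - 1) / nrow(e) else 0
    }, 0)
    expect_equal(ce3$mean_rank_score[i], mean(contrib),
                 tolerance = 1e-12)
  }
})

test_that("planted hubs are recovered by cross-method averaging", {
  sim <- generateRegulatoryExpression(seed = 42)
  pred <- predictHubs(sim$expr, sim$tfs)
  scores <- pred$scores
  od <- lapply(pred$edgeLists, regulatorOutdegree,
               topE = min(100000L, 2L * nrow(sim$expr)))
  expect_gte(length(intersect(hubNames(pred$hubs),
                              sim$truth$plantedHubs)), 4L)

  # averaging is at least as good as the worst single method at ranking
  # the planted hubs
  meanRank <- function(v) {
    r <- rank(-v, ties.method = "average")
    mean(r[sim$truth$plantedHubs])
  }
  avgRank <- meanRank(hubScores(scores))
  worst <- max(vapply(od, function(m) {
    full <- stats::setNames(rep(0, length(sim$tfs)), sim$tfs)
    full[names(m)] <- m
    meanRank(full)
  }, 0))
  expect_lte(avgRank, worst)
})
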