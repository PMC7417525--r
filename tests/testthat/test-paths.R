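# Pathway enumeration and node-deletion influence ranking.

chainGraph <- function() {
  CausalPDAG(c("B", "C", "D", "E", "T"),
             directed = rbind(c("B", "C"), c("C", "D"), c("D", "E"),
                              c("E", "T")))
}

test_that("a single edge gives a single path", {
  g <- CausalPDAG(c("A", "T"), directed = rbind(c("A", "T")))
  ps <- enumeratePaths(g, "T")
  expect_identical(pathList(ps), list(c("A", "T")))
})

test_that("chain paths: suffixes are distinct paths, 5th step excluded", {
  ps <- enumeratePaths(chainGraph(), "T", maxLen = 4)
  expect_identical(length(ps), 4L)
  expect_setequal(vapply(pathList(ps), paste, "", collapse = ">"),
                  c("E>T", "D>E>T", "C>D>E>T", "B>C>D>E>T"))
  # with maxLen 3 the 4-edge path drops out
  expect_identical(length(enumeratePaths(chainGraph(), "T", maxLen = 3)),
                   3L)
  expect_error(enumeratePaths(chainGraph(), "T", maxLen = 0), "at least 1")
})

test_that("influence ranking matches the hand count on the chain", {
  ps <- enumeratePaths(chainGraph(), "T", maxLen = 4)
  rk <- rankingTable(influenceRanking(ps))
  expect_identical(rk$node, c("E", "D", "C", "B"))
  expect_equal(rk$proportion, c(1, 0.75, 0.5, 0.25))
  expect_identical(rk$rank, 1:4)
  # a node on no path ranks at zero
  rk2 <- rankingTable(influenceRanking(ps, nodes = c(nodeNames(chainGraph()),
                                                     "Z") ))
  expect_identical(rk2$count[rk2$node == "Z"], 0L)
})

test_that("deletion recount equals total minus containment", {
  g <- chainGraph()
  ps <- enumeratePaths(g, "T", maxLen = 4)
  rk <- rankingTable(influenceRanking(ps, nodes = nodeNames(g)))
  for (v in setdiff(nodeNames(g), "T")) {
    expect_identical(deleteAndRecount(g, "T", v, maxLen = 4),
                     length(ps) - rk$count[rk$node == v]
    )
  }
  expect_identical(deleteAndRecount(g, "T", "D", maxLen = 4), 1L)
  expect_identical(deleteAndRecount(g, "T", "E", maxLen = 4), 0L)
})

test_that("containment/deletion identity holds on random graphs", {
  set.seed(81)
  for (rep_ in 1:50) {
    a <- randomDagMat(15, 0.15)
    sys <- matToSystem(a)
    g <- trueGraph(sys)
    t <- "V15"
    ps <- enumeratePaths(g, t, maxLen = 4)
    for (v in sample(setdiff(nodeNames(g), t), 4)) {
      containing <- sum(vapply(pathList(ps), function(p) v %in% p, TRUE))
      expect_identical(deleteAndRecount(g, t, v, maxLen = 4),
                       length(ps) - containing)
    }
  }
})

test_that("enumeration agrees with brute-force sequence filtering", {
  set.seed(82)
  for (rep_ in 1:10) {
    p <- sample(5:7, 1)
    a <- randomDagMat(p, runif(1, 0.25, 0.5))
    sys <- matToSystem(a)
    g <- trueGraph(sys)
    t <- rownames(a)[p]
    for (L in 2:4) {
      mine <- vapply(pathList(enumeratePaths(g, t, maxLen = L)),
                     paste, "", collapse = ">")
      brute <- vapply(brutePaths(g, t, L), paste, "", collapse = ">")
      expect_setequal(mine, brute)
    }
  }
})

test_that("path count is monotone in maxLen", {
  set.seed(83)
  for (rep_ in 1:10) {
    a <- randomDagMat(10, 0.25)
    g <- trueGraph(matToSystem(a))
    counts <- vapply(1:5, function(L)
      length(enumeratePaths(g, "V10", maxLen = L)), 1L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("undirected edges are skipped or traversed per policy", {
  g <- CausalPDAG(c("A", "B", "T"), directed = rbind(c("B", "T")),
                  undirected = rbind(c("A", "B")))
  skip <- enumeratePaths(g, "T", undirectedPolicy = "skip")
  expect_identical(vapply(pathList(skip), paste, "", collapse = ">"),
                   "B>T")
  either <- enumeratePaths(g, "T", undirectedPolicy = "either")
  expect_setequal(vapply(pathList(either), paste, "", collapse = ">"),
                  c("B>T", "A>B>T"))
  # brute force agrees under both policies
  for (pol in c("skip", "either"))
    expect_setequal(
      vapply(pathList(enumeratePaths(g, "T", undirectedPolicy = pol)),
             paste, "", collapse = ">"),
      vapply(brutePaths(g, "T", 4, pol), paste, "", collapse = ">"))
})

test_that("empty path sets warn and rank empty", {
  g <- CausalPDAG(c("A", "T"), directed = rbind(c("T", "A")))
  ps <- enumeratePaths(g, "T")
  expect_identical(length(ps), 0L)
  expect_warning(rk <- influenceRanking(ps), "empty")
  expect_identical(nrow(rankingTable(rk)), 0L)
})

test_that("path and ranking files are written in the documented layout", {
  ps <- enumeratePaths(chainGraph(), "T", maxLen = 4)
  rk <- influenceRanking(ps, nodes = nodeNames(chainGraph()))
  fp <- tempfile(); fr <- tempfile()
  writePathReport(ps, rk, fp, fr)
  expect_true("B -> C -> D -> E -> T" %in% readLines(fp))
  tab <- utils::read.delim(fr)
  expect_identical(names(tab), c("node", "count", "proportion", "rank"))
  expect_equal(tab$proportion[tab$node == "D"], 0.75)
})
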