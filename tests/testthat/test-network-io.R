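# Network export/ingestion: edge-list TSV, SIF, GraphML, tolerant reader,
# and the CausalPDAG invariants.

test_that("CausalPDAG invariants reject malformed graphs", {
  expect_error(CausalPDAG(c("A", "B"), directed = rbind(c("A", "A"))),
               "self-loop")
  expect_error(CausalPDAG(c("A", "B"),
                          directed = rbind(c("A", "B"), c("B", "A"))),
               "2-cycle|more than one edge")
  expect_error(CausalPDAG(c("A", "B"), directed = rbind(c("A", "B")),
                          undirected = rbind(c("B", "A"))),
               "more than one edge")
  # directed cycle
  expect_error(CausalPDAG(c("A", "B", "C"),
                          directed = rbind(c("A", "B"), c("B", "C"),
                                           c("C", "A"))),
               "cycle")
  # directed edge against strictly increasing epoques
  expect_error(CausalPDAG(c("A", "B"), directed = rbind(c("B", "A")),
                          epoques = c(A = 1L, B = 2L)),
               "against time order")
  # same-tier edges may point either way
  expect_s4_class(CausalPDAG(c("A", "B"), directed = rbind(c("B", "A")),
                             epoques = c(A = 2L, B = 2L)),
                  "CausalPDAG")
})

test_that("TSV export has the documented layout and round-trips", {
  g <- CausalPDAG(c("A", "B", "T"), directed = rbind(c("A", "T")),
                  undirected = rbind(c("A", "B")))
  f <- tempfile(fileext = ".tsv")
  writeNetwork(g, f, "tsv")
  lines <- readLines(f)
  expect_identical(lines[1],
                   "source\ttarget\toriented\tprovenance\tstability_pct")
  expect_match(lines, "A\tT\ttrue\texternal\t", all = FALSE)
  expect_match(lines, "A\tB\tfalse\tunoriented\t", all = FALSE)
  g2 <- readNetwork(f, "tsv")
  expect_identical(edgeTable(g2)[, c("from", "to", "directed")],
                   edgeTable(g)[, c("from", "to", "directed")])
  expect_setequal(nodeNames(g2), nodeNames(g))
})

test_that("SIF uses 'causes' for directed and 'assoc' for undirected", {
  g <- CausalPDAG(c("A", "B", "T"), directed = rbind(c("A", "T")),
                  undirected = rbind(c("A", "B")))
  f <- tempfile(fileext = ".sif")
  writeNetwork(g, f, "sif")
  expect_setequal(readLines(f), c("A causes T", "A assoc B"))
  g2 <- readNetwork(f, "sif")
  expect_identical(edgeTable(g2)[, c("from", "to", "directed")],
                   edgeTable(g)[, c("from", "to", "directed")])
})

test_that("unknown format and malformed rows are rejected", {
  g <- CausalPDAG("A")
  expect_error(writeNetwork(g, tempfile(), "xgmml"))
  f <- tempfile()
  writeLines(c("source\ttarget\toriented", "A\tB\tmaybe"), f)
  expect_error(readNetwork(f, "tsv"), "line 2")
  f2 <- tempfile()
  writeLines(c("A causes B", "B maybe C"), f2)
  expect_error(readNetwork(f2, "sif"), "unknown SIF relation")
})

test_that("a pair duplicated in both directions fails the invariant check", {
  f <- tempfile()
  writeLines(c("source\ttarget\toriented", "A\tB\ttrue", "B\tA\ttrue"), f)
  expect_error(readNetwork(f, "tsv"), "more than one edge")
})

test_that("the tolerant reader accepts published-style column spellings", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("Source,Target,Direction,Stability(%)",
               "snpA,ptsSev,directed,95",
               "soc,ptsSev,,71",
               "x1,soc,->,100"), f)
  g <- readNetwork(f, "tsv")
  e <- edgeTable(g)
  expect_identical(nrow(e), 3L)
  expect_identical(sum(e$directed), 2L)
  und <- e[!e$directed, ]
  expect_setequal(c(und$from, und$to), c("soc", "ptsSev"))
  expect_identical(e$stability[e$from == "snpA"], 95)
})

test_that("GraphML round-trip preserves edges, provenance and tiers", {
  sys <- generateSystem(p = 15, nTiers = 4, density = 0.2, seed = 8)
  g <- orientAll(buildSkeleton(sys), schema(sys))
  f <- tempfile(fileext = ".graphml")
  writeNetwork(g, f, "graphml")
  g2 <- readNetwork(f, "graphml", epoques = epoques(sys))
  expect_setequal(nodeNames(g2), nodeNames(g))
  key <- function(x) {
    e <- edgeTable(x)
    sort(paste(e$from, e$to, e$directed))
  }
  expect_identical(key(g2), key(g))
  e2 <- edgeTable(g2)
  e1 <- edgeTable(g)
  m <- match(paste(e2$from, e2$to), paste(e1$from, e1$to))
  expect_identical(e2$provenance[e2$directed],
                   e1$provenance[m][e2$directed])
})

test_that("round-trip of a study-scale network reproduces the edge set", {
  # synthetic stand-in at the published scale: 148 nodes, exactly 345
  # edges, a few left unoriented
  set.seed(42)
  nodes <- sprintf("N%03d", 1:148)
  pool <- which(upper.tri(matrix(TRUE, 148, 148)), arr.ind = TRUE)
  # bias towards earlier nodes so a couple of nodes stay disconnected
  sel <- pool[sample.int(nrow(pool), 345, prob = 1 /
                           (pool[, 1] + pool[, 2])), ]
  oriented <- c(rep(TRUE, 326), rep(FALSE, 19))
  g <- CausalPDAG(nodes, directed = cbind(nodes[sel[oriented, 1]],
                                          nodes[sel[oriented, 2]]),
                  undirected = cbind(nodes[sel[!oriented, 1]],
                                     nodes[sel[!oriented, 2]]))
  expect_identical(nrow(edgeTable(g)), 345L)
  for (fmt in c("tsv", "sif", "graphml")) {
    f <- tempfile()
    writeNetwork(g, f, fmt)
    g2 <- readNetwork(f, fmt)
    expect_setequal(nodeNames(g2), nodes)
    key <- function(x) {
      e <- edgeTable(x)
      sort(paste(e$from, e$to, e$directed))
    }
    expect_identical(key(g2), key(g))
  }
})
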