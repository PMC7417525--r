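# Orientation: tiers, colliders, Meek propagation; soundness and
# completeness checked against an exhaustive DAG-extension enumerator.

mkSkeleton <- function(nodes, edges, sepsets = list()) {
  tab <- SepsetTable()
  for (s in sepsets)
    causalTiers:::.sepsetPut(tab, s[[1]], s[[2]],
                             if (length(s) >= 3) s[[3]] else character(),
                             0.5)
  e <- if (NROW(edges)) data.frame(from = edges[, 1], to = edges[, 2],
                                   stringsAsFactors = FALSE)
       else data.frame(from = character(), to = character(),
                       stringsAsFactors = FALSE)
  new("Skeleton", nodes = nodes, edges = e, sepsets = tab)
}

test_that("tier orientation directs cross-tier edges forward in time", {
  sch <- StudySchema(c("SNP", "X", "Y", "PTS"),
                     c("categorical", "continuous", "continuous",
                       "continuous"),
                     c(1L, 4L, 4L, 7L), target = "PTS", nTiers = 7)
  sk <- mkSkeleton(c("SNP", "X", "Y", "PTS"),
                   rbind(c("SNP", "PTS"), c("X", "Y")))
  g <- orientByTiers(sk, sch)
  e <- edgeTable(g)
  snp <- e[e$from == "SNP", ]
  expect_true(snp$directed && snp$to == "PTS" &&
                snp$provenance == "tier_oriented")
  xy <- e[e$from == "X", ]
  expect_false(xy$directed)  # same epoque stays undirected

  empty <- mkSkeleton(c("SNP", "X", "Y", "PTS"), NULL)
  expect_identical(nrow(edgeTable(orientByTiers(empty, sch))), 0L)

  # node without an epoque is a configuration error
  sch2 <- StudySchema(c("SNP", "X"), c("categorical", "continuous"),
                      c(1L, 4L), nTiers = 7)
  expect_error(orientByTiers(sk, sch2), "no epoque")
})

test_that("colliders: orientation, chain non-orientation, and conflicts", {
  nodes <- c("A", "B", "C")
  undirected <- function(sk) CausalPDAG(nodes,
    undirected = as.matrix(edgeTable(sk)[, c("from", "to")]))

  sk <- mkSkeleton(nodes, rbind(c("A", "C"), c("B", "C")),
                   list(list("A", "B")))
  g <- orientColliders(undirected(sk), sk@sepsets)
  e <- edgeTable(g)
  expect_true(all(e$directed))
  expect_setequal(paste(e$from, e$to), c("A C", "B C"))
  expect_true(all(e$provenance == "collider_oriented"))

  # chain sepset contains the middle node: nothing oriented
  sk2 <- mkSkeleton(nodes, rbind(c("A", "B"), c("B", "C")),
                    list(list("A", "C", "B")))
  g2 <- orientColliders(undirected(sk2), sk2@sepsets)
  expect_false(any(edgeTable(g2)$directed))

  # conflicting Y-structures on one edge: left undirected, logged
  nodes4 <- c("A", "B", "C", "D")
  sk3 <- mkSkeleton(nodes4,
                    rbind(c("A", "C"), c("C", "D"), c("B", "D")),
                    list(list("A", "D"),      # collider at C: A->C<-D
                         list("C", "B")))     # collider at D: C->D<-B
  g3 <- CausalPDAG(nodes4,
                   undirected = as.matrix(edgeTable(sk3)[, c("from", "to")]))
  expect_message(out <- orientColliders(g3, sk3@sepsets, verbose = TRUE),
                 "conflict")
  e3 <- edgeTable(out)
  cd <- e3[(e3$from == "C" & e3$to == "D") |
             (e3$from == "D" & e3$to == "C"), ]
  expect_false(cd$directed)
})

test_that("tier-oriented edges are never overridden by colliders", {
  nodes <- c("A", "B", "C")
  ep <- c(A = 2L, B = 2L, C = 1L)
  # time says C -> A, but the sepset claims a collider at C
  g <- CausalPDAG(nodes, directed = rbind(c("C", "A")),
                  undirected = rbind(c("B", "C")), epoques = ep,
                  provenance = "tier_oriented")
  tab <- SepsetTable()
  causalTiers:::.sepsetPut(tab, "A", "B", character(), 0.5)
  out <- orientColliders(g, tab)
  e <- edgeTable(out)
  ca <- e[e$from == "C" & e$to == "A", ]
  expect_true(nrow(ca) == 1L && ca$directed &&
                ca$provenance == "tier_oriented")
})

test_that("Meek rules R1 and R2 fire on their textbook configurations", {
  # R1: A->B, B-C, A,C non-adjacent  =>  B->C
  g <- CausalPDAG(c("A", "B", "C"), directed = rbind(c("A", "B")),
                  undirected = rbind(c("B", "C")))
  e <- edgeTable(propagateOrientations(g))
  bc <- e[e$from == "B" & e$to == "C", ]
  expect_true(bc$directed && bc$provenance == "propagated")

  # R2: A->B->C with A-C  =>  A->C
  g2 <- CausalPDAG(c("A", "B", "C"),
                   directed = rbind(c("A", "B"), c("B", "C")),
                   undirected = rbind(c("A", "C")))
  e2 <- edgeTable(propagateOrientations(g2))
  ac <- e2[e2$from == "A" & e2$to == "C", ]
  expect_true(ac$directed)

  # fully undirected triangle: no rule fires
  g3 <- CausalPDAG(c("A", "B", "C"),
                   undirected = rbind(c("A", "B"), c("B", "C"),
                                      c("A", "C")))
  expect_false(any(edgeTable(propagateOrientations(g3))$directed))
})

test_that("propagation is idempotent and never creates a cycle", {
  set.seed(61)
  for (rep_ in 1:20) {
    a <- randomDagMat(6, 0.4)
    sys <- matToSystem(a)
    sk <- buildSkeleton(sys, TestConfig(maxK = 4))
    g1 <- orientAll(sk, NULL)
    g2 <- propagateOrientations(g1)
    expect_identical(edgeTable(g2), edgeTable(g1))
    expect_s4_class(g2, "CausalPDAG")  # validity (incl. acyclicity) holds
  }
})

test_that("oracle orientation is sound on random tiered DAGs", {
  set.seed(62)
  for (rep_ in 1:30) {
    p <- sample(5:10, 1)
    tiers <- sort(sample.int(3, p, replace = TRUE))
    a <- randomDagMat(p, runif(1, 0.2, 0.4))
    sys <- matToSystem(a, tiers)
    sk <- buildSkeleton(sys, TestConfig(maxK = p - 2))
    g <- orientAll(sk, schema(sys))
    e <- edgeTable(g)
    for (i in which(e$directed))
      expect_true(a[e$from[i], e$to[i]],
                  info = sprintf("instance %d: %s->%s (%s)", rep_,
                                 e$from[i], e$to[i], e$provenance[i]))
  }
})

test_that("untiered oracle orientation equals the brute-force CPDAG", {
  set.seed(63)
  done <- 0
  while (done < 25) {
    p <- sample(4:6, 1)
    a <- randomDagMat(p, runif(1, 0.25, 0.55))
    if (sum(a) < 2 || sum(a) > 10) next
    done <- done + 1
    sys <- matToSystem(a)
    sk <- buildSkeleton(sys, TestConfig(maxK = p - 2))
    g <- orientAll(sk, NULL)
    expect_identical(pdagToMat(g), bruteCpdag(a),
                     info = paste("instance", done))
  }
})

test_that("orientAll composes the stages and reports provenance", {
  # A(1) - B(1) -> C(2): tier rule orients B->C only
  sch <- StudySchema(c("A", "B", "C"), rep("continuous", 3),
                     c(1L, 1L, 2L))
  chain <- syntheticSystem(sch, rbind(c("A", "B"), c("B", "C")))
  g <- orientAll(buildSkeleton(chain), sch)
  s <- orientationSummary(g)
  expect_identical(s$nEdges, 2L)
  expect_identical(s$nOriented, 1L)
  expect_identical(s$byProvenance$tier_oriented, 1L)
  e <- edgeTable(g)
  ab <- e[(e$from == "A" & e$to == "B"), ]
  expect_false(ab$directed)

  # same-tier collider: both arms collider_oriented
  sch2 <- StudySchema(c("A", "B", "C"), rep("continuous", 3),
                      c(2L, 2L, 2L))
  coll <- syntheticSystem(sch2, rbind(c("A", "C"), c("B", "C")))
  g2 <- orientAll(buildSkeleton(coll), sch2)
  s2 <- orientationSummary(g2)
  expect_identical(s2$byProvenance$collider_oriented, 2L)
  expect_identical(s2$pctOriented, 100)

  # strictly increasing epoques: everything tier-oriented
  sch3 <- StudySchema(c("A", "B", "C"), rep("continuous", 3),
                      c(1L, 2L, 3L))
  chain3 <- syntheticSystem(sch3, rbind(c("A", "B"), c("B", "C")))
  g3 <- orientAll(buildSkeleton(chain3), sch3)
  expect_identical(orientationSummary(g3)$byProvenance$tier_oriented, 2L)
  expect_identical(orientationSummary(g3)$pctOriented, 100)
})
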