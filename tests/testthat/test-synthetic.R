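# Synthetic tiered-cohort generator and recovery metrics.

test_that("generateSystem produces the study-scale stated world", {
  sys <- generateSystem(seed = 1)  # defaults: p = 148, 7 tiers
  sch <- schema(sys)
  expect_identical(nrow(sch@variables), 148L)
  expect_identical(sch@nTiers, 7L)
  expect_identical(sort(unique(unname(epoques(sch)))), 1:7)
  expect_identical(targetVariable(sch), "TARGET")
  expect_identical(unname(epoques(sch)["TARGET"]), 7L)
  # SNP-like trinary exogenous nodes sit in tier 1
  snp <- names(which(dtypes(sch) == "categorical"))
  expect_gt(length(snp), 0)
  expect_true(all(epoques(sch)[snp] == 1L))
  expect_false(any(trueEdges(sys)$to %in% snp))
  # the target has at least one parent
  expect_gte(sum(trueEdges(sys)$to == "TARGET"), 1)
})

test_that("every true edge respects the tier constraint", {
  for (s in 1:5) {
    sys <- generateSystem(p = 40, nTiers = 5, density = 0.1, seed = s)
    ep <- epoques(sys)
    e <- trueEdges(sys)
    expect_true(all(ep[e$from] <= ep[e$to]))
    expect_true(all(e$weight != 0))
    expect_true(all(abs(e$weight) >= 0.5 & abs(e$weight) <= 1.5))
  }
})

test_that("density 0 without retries gives an empty edge set", {
  sys <- generateSystem(p = 10, nTiers = 2, density = 0, seed = 2,
                        maxRetries = 0)
  expect_identical(nrow(trueEdges(sys)), 0L)
  expect_error(generateSystem(p = 10, nTiers = 2, density = 0, seed = 2,
                              maxRetries = 3), "parentless")
})

test_that("an edgeless system samples mutually independent columns", {
  sch <- StudySchema(sprintf("V%d", 1:5), rep("continuous", 5),
                     rep(1L, 5))
  sys <- syntheticSystem(sch, matrix(character(), 0, 2))
  d <- sampleData(sys, n = 500, geneticSubsample = 500, seed = 3)
  r <- cor(dataValues(d), method = "spearman")
  diag(r) <- 0
  expect_lt(max(abs(r)), 0.2)
})

test_that("a single weighted edge reproduces the closed-form correlation", {
  sch <- StudySchema(c("A", "B"), c("continuous", "continuous"),
                     c(1L, 2L), target = "B")
  sys <- syntheticSystem(sch, data.frame(from = "A", to = "B",
                                         weight = 1),
                         noiseSd = c(A = 1, B = 0.5))
  d <- sampleData(sys, n = 5000, geneticSubsample = 5000, seed = 4)
  v <- dataValues(d)
  expect_equal(cor(v[, "A"], v[, "B"]), 1 / sqrt(1.25), tolerance = 0.05)
})

test_that("the genetic sub-sample yields exactly the stated missing block", {
  sys <- generateSystem(p = 30, nTiers = 4, density = 0.1,
                        snpFraction = 0.2, seed = 5)
  d <- sampleData(sys, n = 207, geneticSubsample = 157, seed = 5)
  gen <- names(which(dtypes(schema(sys)) == "categorical"))
  missRows <- rowSums(d@missingMask[, gen, drop = FALSE]) > 0
  expect_identical(sum(missRows), 50L)
  expect_true(all(d@missingMask[missRows, gen]))
  expect_false(any(d@missingMask[, setdiff(variableNames(d), gen)]))
})

test_that("SNP columns are allele counts, ordinal columns small codes", {
  sys <- generateSystem(p = 30, nTiers = 3, density = 0.1,
                        snpFraction = 0.2, seed = 6)
  d <- sampleData(sys, n = 400, geneticSubsample = 400, seed = 6)
  dt <- dtypes(schema(sys))
  v <- dataValues(d)
  for (col in names(which(dt == "categorical")))
    expect_true(all(v[, col] %in% 0:2))
  for (col in names(which(dt == "ordinal")))
    expect_true(all(v[, col] %in% 0:2))
  # allele frequency near the configured maf
  snp1 <- v[, names(which(dt == "categorical"))[1]]
  expect_lt(abs(mean(snp1) / 2 - 0.3), 0.05)
})

test_that("recovery metrics follow their definitions", {
  sch <- StudySchema(c("A", "B", "C", "D"), rep("continuous", 4),
                     rep(1L, 4), target = "D")
  sys <- syntheticSystem(sch, rbind(c("A", "B"), c("B", "C")))
  # perfect estimate
  perfect <- trueGraph(sys)
  m <- evaluateRecovery(perfect, sys, target = "C")
  expect_identical(m@skeletonPrecision, 1)
  expect_identical(m@skeletonRecall, 1)
  expect_identical(m@orientationAccuracy, 1)
  expect_identical(m@mbJaccard, 1)
  # half right: truth {A-B, B-C}, estimate {A-B, B-D}
  est <- CausalPDAG(c("A", "B", "C", "D"),
                    directed = rbind(c("A", "B"), c("B", "D")))
  m2 <- evaluateRecovery(est, sys, target = "C")
  expect_identical(m2@skeletonPrecision, 0.5)
  expect_identical(m2@skeletonRecall, 0.5)
  # empty estimate: recall 0, precision reported 0 with a flag
  empty <- CausalPDAG(c("A", "B", "C", "D"))
  m3 <- evaluateRecovery(empty, sys, target = "C")
  expect_identical(m3@skeletonRecall, 0)
  expect_identical(m3@skeletonPrecision, 0)
  expect_match(m3@flags, "empty estimate", all = FALSE)
  expect_error(evaluateRecovery(CausalPDAG(c("A", "B")), sys),
               "node sets")
})

test_that("reversed orientation is scored as incorrect", {
  sch <- StudySchema(c("A", "B"), rep("continuous", 2), c(1L, 1L),
                     target = "B")
  sys <- syntheticSystem(sch, rbind(c("A", "B")))
  est <- CausalPDAG(c("A", "B"), directed = rbind(c("B", "A")))
  m <- evaluateRecovery(est, sys)
  expect_identical(m@skeletonRecall, 1)
  expect_identical(m@orientationAccuracy, 0)
})

test_that("the oracle on generated systems matches the brute checker", {
  set.seed(91)
  for (rep_ in 1:10) {
    sys <- generateSystem(p = 7, nTiers = 3, density = 0.3,
                          seed = 200 + rep_, maxRetries = 0)
    dir <- causalTiers:::.systemDirMatrix(sys)
    nms <- variableNames(sys)
    for (k in 1:10) {
      pair <- sample(7, 2)
      rest <- setdiff(1:7, pair)
      Z <- rest[runif(5) < 0.4]
      expect_identical(dsepOracle(nms[pair[1]], nms[pair[2]], nms[Z], sys),
                       bruteDsep(dir, pair[1], pair[2], Z))
    }
  }
})
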