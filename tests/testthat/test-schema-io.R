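# Variable-table / data-table loading and validation.

writeSchemaFile <- function(df, sep = ",") {
  f <- tempfile(fileext = if (sep == ",") ".csv" else ".tsv")
  utils::write.table(df, f, sep = sep, quote = FALSE, row.names = FALSE)
  f
}

test_that("loadSchema round-trips a small variable table", {
  f <- writeSchemaFile(data.frame(name = c("A", "B", "T"),
                                  dtype = c("continuous", "ordinal",
                                            "continuous"),
                                  epoque = c(1, 2, 7)))
  sch <- loadSchema(f, target = "T")
  expect_s4_class(sch, "StudySchema")
  expect_identical(variableNames(sch), c("A", "B", "T"))
  expect_identical(unname(epoques(sch)), c(1L, 2L, 7L))
  expect_identical(targetVariable(sch), "T")
  # canonical order is stable across repeated loads
  expect_identical(variableNames(loadSchema(f)), variableNames(sch))
})

test_that("loadSchema maps 'cardinal' to continuous and validates", {
  f <- writeSchemaFile(data.frame(name = c("A", "B"),
                                  dtype = c("cardinal", "ordinal"),
                                  epoque = c(1, 2)))
  expect_identical(unname(dtypes(loadSchema(f))["A"]), "continuous")

  dup <- writeSchemaFile(data.frame(name = c("A", "A"),
                                    dtype = c("continuous", "continuous"),
                                    epoque = c(1, 2)))
  expect_error(loadSchema(dup), "duplicate")

  badType <- writeSchemaFile(data.frame(name = c("A", "B"),
                                        dtype = c("continuous", "fuzzy"),
                                        epoque = c(1, 2)))
  expect_error(loadSchema(badType), "dtype 'fuzzy' in row 2")

  badEp <- writeSchemaFile(data.frame(name = c("A", "B"),
                                      dtype = c("continuous", "ordinal"),
                                      epoque = c(1, 9)))
  expect_error(loadSchema(badEp, nTiers = 7), "epoque outside 1..7")
})

test_that("a study-scale table (148 variables, 7 epoques) loads intact", {
  sys <- generateSystem(p = 148, nTiers = 7, seed = 11)
  v <- schema(sys)@variables
  f <- writeSchemaFile(v)
  sch <- loadSchema(f, target = "TARGET")
  expect_identical(nrow(sch@variables), 148L)
  expect_identical(sort(unique(unname(epoques(sch)))), 1:7)
  expect_identical(unname(epoques(sch)["TARGET"]), 7L)
  expect_identical(variableNames(sch), v$name)
})

test_that("loadData reorders columns, masks missing tokens, flags mismatches", {
  sch <- StudySchema(c("A", "B", "C"), rep("continuous", 3), c(1L, 1L, 2L))
  f <- tempfile(fileext = ".csv")
  writeLines(c("B,C,A", "1,2,3", "4,,6", "NA,8,9", "10,11,12"), f)
  d <- loadData(f, sch)
  expect_identical(variableNames(d), c("A", "B", "C"))  # reordered
  expect_identical(unname(dataValues(d)[1, ]), c(3, 1, 2))
  expect_true(d@missingMask[2, "C"] && d@missingMask[3, "B"])
  expect_identical(sum(d@missingMask), 2L)

  complete <- tempfile(fileext = ".csv")
  writeLines(c("A,B,C", "1,2,3", "4,5,6", "7,8,9", "0,1,2"), complete)
  expect_false(any(loadData(complete, sch)@missingMask))

  extra <- tempfile(fileext = ".csv")
  writeLines(c("A,B,C,Zz", "1,2,3,4"), extra)
  expect_error(loadData(extra, sch), "Zz")
  short <- tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,2"), short)
  expect_error(loadData(short, sch), "C")
})

test_that("block missingness yields per-column observed n of the sub-sample", {
  sys <- generateSystem(p = 20, nTiers = 3, density = 0.1,
                        snpFraction = 0.2, seed = 3)
  d <- sampleData(sys, n = 207, geneticSubsample = 157, seed = 3)
  genCols <- names(which(dtypes(schema(sys)) == "categorical"))
  expect_gt(length(genCols), 1)
  expect_true(all(observedN(d)[genCols] == 157L))
  expect_true(all(observedN(d)[setdiff(variableNames(d), genCols)] == 207L))
  # block structure: the same 50 rows are missing across genetic columns
  missRows <- which(d@missingMask[, genCols[1]])
  expect_identical(length(missRows), 50L)
  expect_true(all(d@missingMask[missRows, genCols]))
  # pairwise effective n reflects the block
  pn <- pairwiseN(d)
  expect_identical(unname(pn[genCols[1], genCols[2]]), 157L)
  expect_identical(unname(pn[genCols[1], "TARGET"]), 157L)
})

test_that("degenerate columns are flagged on load", {
  sch <- StudySchema(c("A", "B"), rep("continuous", 2), c(1L, 1L))
  f <- tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,5", "2,5", "3,5"), f)
  expect_warning(d <- loadData(f, sch), "degenerate.*B")
  expect_identical(unname(d@degenerate), c(FALSE, TRUE))
})

test_that("data/schema write-read round-trip is lossless", {
  sys <- generateSystem(p = 10, nTiers = 3, density = 0.2, seed = 4)
  d <- sampleData(sys, n = 50, geneticSubsample = 40, seed = 4)
  fd <- tempfile(fileext = ".csv"); fs <- tempfile(fileext = ".csv")
  writeData(d, fd, fs)
  sch2 <- loadSchema(fs, target = "TARGET")
  d2 <- loadData(fd, sch2)
  expect_identical(schema(d)@variables, sch2@variables)
  expect_equal(dataValues(d2), dataValues(d))
  expect_identical(d2@missingMask, d@missingMask)
})
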