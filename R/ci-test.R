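# Conditional-independence engine.
#
# One unified test is applied to all variable types: Fisher-z on the
# Spearman rank partial correlation. Categorical SNP-like variables enter
# as ordinal allele counts, so a single monotone-association test covers
# the study's mixed scales. Missing data are handled by test-wise
# complete-case deletion: each test runs on the rows jointly observed for
# {x, y} union Z, and reports that effective n.
#
# For speed, a per-dataset context caches the column ranks and the full
# Spearman correlation matrix over columns with no missing values; a test
# whose variables are all complete is then a (|Z|+2)-dimensional matrix
# inversion. Tests touching incomplete columns re-rank on the complete-row
# subset.

.ciContext <- function(data) {
  stopifnot(is(data, "DataMatrix"))
  vals <- data@values
  mask <- data@missingMask
  complete <- colSums(mask) == 0L
  p <- ncol(vals)
  ranks <- matrix(NA_real_, nrow(vals), p, dimnames = dimnames(vals))
  for (j in which(complete)) ranks[, j] <- rank(vals[, j])
  Rc <- matrix(NA_real_, p, p)
  if (sum(complete) >= 2L)
    Rc[complete, complete] <- stats::cor(ranks[, complete, drop = FALSE])
  # block missingness makes "rows complete for all columns" the subset
  # most incomplete-column tests end up using; cache its rank correlations
  rowsAll <- rowSums(mask) == 0L
  nAll <- sum(rowsAll)
  RcAll <- NULL
  degenerateAll <- data@degenerate
  if (!all(complete) && nAll >= 5L) {
    ranksAll <- apply(vals[rowsAll, , drop = FALSE], 2, rank)
    degenerateAll <- apply(ranksAll, 2, stats::sd) == 0
    RcAll <- suppressWarnings(stats::cor(ranksAll))
  }
  list(values = vals, mask = mask, complete = complete, ranks = ranks,
       Rc = Rc, rowsAll = rowsAll, nAll = nAll, RcAll = RcAll,
       degenerateAll = degenerateAll,
       degenerate = data@degenerate, n = nrow(vals),
       names = colnames(vals))
}

.untestable <- function(n) {
  list(stat = NA_real_, p = NA_real_, n = as.integer(n), testable = FALSE)
}

# x, y: column indices; Z: integer vector of column indices.
.ciTestRaw <- function(ctx, x, y, Z, alpha = 0.05, minEffN = 10L) {
  if (x > y) { tmp <- x; x <- y; y <- tmp }  # exact x/y symmetry
  cols <- c(x, y, Z)
  k <- length(Z)
  minN <- max(minEffN, k + 4L)
  if (all(ctx$complete[cols])) {
    n <- ctx$n
    if (n < minN || any(ctx$degenerate[cols]))
      return(.untestable(n))
    S <- ctx$Rc[cols, cols, drop = FALSE]
  } else {
    rows <- rowSums(ctx$mask[, cols, drop = FALSE]) == 0L
    n <- sum(rows)
    if (n < minN) return(.untestable(n))
    if (!is.null(ctx$RcAll) && n == ctx$nAll) {
      # the subset is exactly the fully-complete row block: cached path
      if (any(ctx$degenerateAll[cols])) return(.untestable(n))
      S <- ctx$RcAll[cols, cols, drop = FALSE]
      return(.ciFinish(S, n, k))
    }
    sub <- ctx$values[rows, cols, drop = FALSE]
    rk <- apply(sub, 2, rank)
    sds <- apply(rk, 2, stats::sd)
    if (any(sds == 0)) return(.untestable(n))
    S <- stats::cor(rk)
  }
  .ciFinish(S, n, k)
}

# Fisher z on the (partial) correlation read off a correlation submatrix
# ordered (x, y, Z...).
.ciFinish <- function(S, n, k) {
  if (k == 0L) {
    r <- S[1L, 2L]
  } else {
    P <- tryCatch(solve(S), error = function(e) NULL)
    if (is.null(P)) return(.untestable(n))
    r <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  }
  if (is.na(r)) return(.untestable(n))
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- atanh(r) * sqrt(n - k - 3)
  list(stat = z, p = 2 * stats::pnorm(-abs(z)), n = as.integer(n),
       testable = TRUE)
}

#' Test conditional independence of two variables given a set
#'
#' Fisher-z test on the Spearman rank partial correlation of \code{x} and
#' \code{y} given \code{Z}, computed on the rows jointly observed for all
#' variables involved. Symmetric in \code{x} and \code{y} and
#' deterministic for fixed input. When fewer complete rows than
#' \code{minEffectiveN} are available, or a variable is degenerate on the
#' complete rows, the result is flagged untestable; discovery treats such
#' results as failure to establish dependence (they can never add an edge)
#' while never removing an edge supported at smaller conditioning sets.
#'
#' @param x,y variable names (or column indices).
#' @param Z conditioning set: character vector of names (or indices);
#'   default empty.
#' @param data a \linkS4class{DataMatrix}.
#' @param config a \linkS4class{TestConfig}.
#' @return a \linkS4class{CITestResult}.
#' @examples
#' sch <- StudySchema(c("a", "b"), rep("continuous", 2), c(1L, 1L))
#' set.seed(1)
#' z <- rnorm(100)
#' d <- DataMatrix(cbind(a = z, b = z + rnorm(100, 0, 0.3)), sch)
#' ciTest("a", "b", data = d)
#' @export
ciTest <- function(x, y, Z = character(), data, config = TestConfig()) {
  ctx <- .ciContext(data)
  ix <- if (is.character(x)) match(x, ctx$names) else as.integer(x)
  iy <- if (is.character(y)) match(y, ctx$names) else as.integer(y)
  iz <- if (is.character(Z)) match(Z, ctx$names) else as.integer(Z)
  if (anyNA(c(ix, iy, iz))) stop("unknown variable name")
  if (ix == iy || ix %in% iz || iy %in% iz)
    stop("x, y and Z must be distinct")
  if (length(iz) > config@maxK)
    stop(sprintf("conditioning set larger than maxK = %d", config@maxK))
  r <- .ciTestRaw(ctx, ix, iy, iz, alpha = config@alpha,
                  minEffN = config@minEffectiveN)
  new("CITestResult", statistic = r$stat, pValue = r$p,
      effectiveN = as.integer(r$n), conditioningSize = length(iz),
      testable = r$testable)
}
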