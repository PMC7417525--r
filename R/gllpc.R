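# Local causal discovery (GLL-PC family) assembled local-to-global.
#
# The local step is a semi-interleaved inclusion/elimination scheme in the
# HITON-PC style: candidates enter a tentative parent-children set in
# order of marginal association strength, each admission triggers an
# elimination attempt against subsets (<= maxK) of the other current
# candidates, and a final symmetric sweep re-checks every survivor. The
# first separating set found for each rejected variable is recorded as its
# sepset — PC orientation needs one witness per pair, not all.

# Search for a separating set of x and t among subsets of cand (indices,
# ascending). Returns list(Z, p) or NULL. Untestable results never remove
# a candidate (failure to establish independence).
.findSepset <- function(x, t, cand, ciFun, alpha, maxK) {
  cand <- sort(cand)
  for (k in seq_len(min(maxK, length(cand)))) {
    for (Z in .subsetsOfSize(cand, k)) {
      r <- ciFun(x, t, Z)
      if (r$testable && r$p > alpha) return(list(Z = Z, p = r$p))
    }
  }
  NULL
}

# Core local discovery over column indices. Returns the candidate
# parent-children set of t plus sepsets for rejected variables.
.gllPcLocal <- function(t, p, ciFun, alpha, maxK) {
  others <- setdiff(seq_len(p), t)
  sep <- vector("list", p)
  untestable <- integer()
  open <- integer()
  margP <- rep(NA_real_, p); margS <- rep(NA_real_, p)
  for (x in others) {
    r <- ciFun(x, t, integer())
    if (!r$testable) { untestable <- c(untestable, x); next }
    if (r$p > alpha) { sep[[x]] <- list(Z = integer(), p = r$p); next }
    open <- c(open, x); margP[x] <- r$p; margS[x] <- abs(r$stat)
  }
  # admission order: strongest marginal association first, canonical ties
  open <- open[order(margP[open], -margS[open], open)]
  tpc <- integer()
  for (x in open) {
    tpc <- c(tpc, x)
    res <- .findSepset(x, t, setdiff(tpc, x), ciFun, alpha, maxK)
    if (!is.null(res)) { tpc <- setdiff(tpc, x); sep[[x]] <- res }
  }
  # final symmetric elimination sweep in canonical order
  for (x in sort(tpc)) {
    if (!(x %in% tpc)) next
    res <- .findSepset(x, t, setdiff(tpc, x), ciFun, alpha, maxK)
    if (!is.null(res)) { tpc <- setdiff(tpc, x); sep[[x]] <- res }
  }
  list(pc = sort(tpc), sep = sep, untestable = untestable)
}

.resolveCiFun <- function(x, config, ciFun) {
  if (!is.null(ciFun)) return(list(ciFun = ciFun, names = variableNames(x)))
  if (is(x, "SyntheticSystem"))
    return(list(ciFun = oracleCiFun(x), names = variableNames(x)))
  if (is(x, "DataMatrix")) {
    ctx <- .ciContext(x)
    f <- function(a, b, Z) .ciTestRaw(ctx, a, b, Z, alpha = config@alpha,
                                      minEffN = config@minEffectiveN)
    return(list(ciFun = f, names = ctx$names))
  }
  stop("x must be a DataMatrix or SyntheticSystem")
}

#' Local causal discovery around one variable
#'
#' Runs the GLL-PC local step for a single target: interleaved inclusion
#' of candidates in order of marginal association and elimination against
#' conditioning subsets of the other candidates, up to size \code{maxK}.
#' Returns the candidate parent-children set together with the first
#' separating set found for each rejected variable.
#'
#' @param target variable name.
#' @param x a \linkS4class{DataMatrix}, or a \linkS4class{SyntheticSystem}
#'   (then the d-separation oracle is used as the test).
#' @param config a \linkS4class{TestConfig}.
#' @param ciFun optional custom test, \code{function(xIdx, yIdx, zIdx)}
#'   returning \code{list(stat, p, n, testable)}.
#' @return list with \code{parentsChildren} (character vector in canonical
#'   order), \code{sepsets} (a \linkS4class{SepsetTable} of rejected
#'   pairs) and \code{untestable} (variables whose relation to the target
#'   could not be tested).
#' @examples
#' sys <- generateSystem(p = 6, nTiers = 3, density = 0.3, seed = 2)
#' gllPC(targetVariable(sys), sys)
#' @export
gllPC <- function(target, x, config = TestConfig(), ciFun = NULL) {
  rf <- .resolveCiFun(x, config, ciFun)
  nms <- rf$names
  t <- match(target, nms)
  if (is.na(t)) stop("target '", target, "' not in schema")
  res <- .gllPcLocal(t, length(nms), rf$ciFun, config@alpha, config@maxK)
  tab <- SepsetTable()
  for (i in seq_along(res$sep))
    if (!is.null(res$sep[[i]]))
      .sepsetPut(tab, nms[t], nms[i], nms[res$sep[[i]]$Z], res$sep[[i]]$p)
  list(parentsChildren = nms[res$pc], sepsets = tab,
       untestable = nms[res$untestable])
}

#' Build the undirected skeleton by local-to-global assembly
#'
#' Runs local discovery ([gllPC()]) for every variable and assembles the
#' global undirected skeleton. Under the AND symmetry rule (default) an
#' edge x--y is kept only when each endpoint lies in the other's candidate
#' parent-children set; the OR rule keeps either. Sepsets from all local
#' runs are merged, keeping the first recorded witness per pair
#' (iteration in canonical variable order makes the result deterministic
#' and invariant to data row order).
#'
#' @inheritParams gllPC
#' @param verbose print one progress line per variable.
#' @return a \linkS4class{Skeleton}.
#' @examples
#' sys <- generateSystem(p = 6, nTiers = 3, density = 0.3, seed = 2)
#' buildSkeleton(sys)  # oracle discovery: exact adjacency recovery
#' @export
buildSkeleton <- function(x, config = TestConfig(), ciFun = NULL,
                          verbose = FALSE) {
  rf <- .resolveCiFun(x, config, ciFun)
  nms <- rf$names
  p <- length(nms)
  if (p < 2L) stop("need at least 2 variables")
  pcs <- vector("list", p)
  seps <- vector("list", p)
  for (t in seq_len(p)) {
    res <- .gllPcLocal(t, p, rf$ciFun, config@alpha, config@maxK)
    pcs[[t]] <- res$pc
    seps[[t]] <- res$sep
    if (verbose)
      message(sprintf("[%d/%d] %s: %d candidate neighbour(s)", t, p,
                      nms[t], length(res$pc)))
  }
  adj <- matrix(FALSE, p, p)
  for (t in seq_len(p)) adj[t, pcs[[t]]] <- TRUE
  adj <- if (config@andRule) adj & t(adj) else adj | t(adj)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = nms[idx[, 1]], to = nms[idx[, 2]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(match(edges$from, nms), match(edges$to, nms)), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  tab <- SepsetTable()
  for (t in seq_len(p)) {
    st <- seps[[t]]
    for (i in seq_len(p)) {
      if (is.null(st[[i]]) || adj[t, i]) next  # never shadow a kept edge
      .sepsetPut(tab, nms[t], nms[i], nms[st[[i]]$Z], st[[i]]$p)
    }
  }
  new("Skeleton", nodes = nms, edges = edges, sepsets = tab)
}
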