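# d-separation oracle.
#
# Under the causal Markov and faithfulness conditions, the conditional
# (in)dependencies of a faithful distribution are exactly the
# d-separations of the generating DAG, so the oracle is a drop-in
# replacement for the statistical test when validating discovery against
# a known system.
#
# Implementation: x and y are d-separated by Z iff they are disconnected
# in the moralised ancestral graph of {x, y} union Z with Z removed
# (Lauritzen's criterion). The test suite cross-checks this against an
# independent brute-force path-blocking enumeration.

# dir: p x p logical directed adjacency; indices.
.dSep <- function(dir, x, y, Z) {
  anc <- .ancestorsOf(dir, c(x, y, Z))
  sub <- dir[anc, anc, drop = FALSE]
  m <- sub | t(sub)
  # marry co-parents
  for (v in seq_along(anc)) {
    pa <- which(sub[, v])
    if (length(pa) > 1L) m[pa, pa] <- TRUE
  }
  diag(m) <- FALSE
  keep <- !(anc %in% Z)
  m <- m[keep, keep, drop = FALSE]
  ids <- anc[keep]
  xi <- match(x, ids); yi <- match(y, ids)
  if (is.na(xi) || is.na(yi)) return(TRUE)  # x or y conditioned away
  # BFS from xi
  seen <- logical(nrow(m))
  seen[xi] <- TRUE
  queue <- xi
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- which(m[v, ] & !seen)
    if (yi %in% nb) return(FALSE)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  TRUE
}

.systemDirMatrix <- function(system) {
  nodes <- variableNames(system)
  p <- length(nodes)
  dir <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  e <- system@edges
  if (nrow(e)) dir[cbind(match(e$from, nodes), match(e$to, nodes))] <- TRUE
  dir
}

#' d-separation oracle on a known causal system
#'
#' Decides whether \code{x} and \code{y} are d-separated by \code{Z} in
#' the true DAG of a synthetic system. Under faithfulness this equals
#' conditional independence in any distribution the system generates, so
#' the oracle substitutes for [ciTest()] in correctness checks of the
#' discovery machinery.
#'
#' @param x,y node names.
#' @param Z character vector of conditioning node names (default empty).
#' @param system a \linkS4class{SyntheticSystem}, or a
#'   \linkS4class{CausalPDAG} whose edges are all directed.
#' @return \code{TRUE} iff x and y are d-separated by Z.
#' @examples
#' sys <- generateSystem(p = 5, nTiers = 2, density = 0.4, seed = 1)
#' dsepOracle(variableNames(sys)[1], variableNames(sys)[2],
#'            system = sys)
#' @export
dsepOracle <- function(x, y, Z = character(), system) {
  dir <- if (is(system, "SyntheticSystem")) {
    .systemDirMatrix(system)
  } else if (is(system, "CausalPDAG")) {
    if (nrow(undirectedEdges(system)))
      stop("d-separation needs a fully directed graph")
    .pdagMatrices(system)$dir
  } else stop("system must be a SyntheticSystem or CausalPDAG")
  nodes <- rownames(dir)
  ix <- match(x, nodes); iy <- match(y, nodes); iz <- match(Z, nodes)
  if (anyNA(c(ix, iy, iz)))
    stop("unknown node name: ",
         paste(setdiff(c(x, y, Z), nodes), collapse = ", "))
  if (ix == iy || ix %in% iz || iy %in% iz)
    stop("x, y and Z must be distinct")
  .dSep(dir, ix, iy, iz)
}

#' Oracle conditional-independence function for discovery
#'
#' Wraps a known system's d-separation relation in the
#' conditional-independence interface used by [buildSkeleton()] and
#' [gllPC()]: p-value 1 for d-separated pairs, 0 otherwise. Discovery run
#' with this oracle recovers the true adjacency structure of any faithful
#' DAG (given a large enough \code{maxK}), which is how the pipeline is
#' validated.
#'
#' @param system a \linkS4class{SyntheticSystem} (or fully directed
#'   \linkS4class{CausalPDAG}).
#' @return a function \code{(xIdx, yIdx, zIdx) -> list(stat, p, n,
#'   testable)} over canonical column indices.
#' @export
oracleCiFun <- function(system) {
  dir <- if (is(system, "SyntheticSystem")) .systemDirMatrix(system)
         else .pdagMatrices(system)$dir
  bigN <- 1e6L
  function(x, y, Z) {
    sep <- .dSep(dir, x, y, Z)
    list(stat = if (sep) 0 else Inf, p = if (sep) 1 else 0,
         n = bigN, testable = TRUE)
  }
}
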