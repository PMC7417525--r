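# Independent brute-force oracles used to validate the package's graph
# machinery. These deliberately share no code with the implementation:
# d-separation by exhaustive path blocking, CPDAGs by enumerating all
# consistent DAG extensions, path sets by filtering all node sequences.

# descendants of v (including v) in a directed adjacency matrix
.bruteDescendants <- function(dir, v) {
  seen <- logical(nrow(dir))
  seen[v] <- TRUE
  queue <- v
  while (length(queue)) {
    u <- queue[[1]]; queue <- queue[-1]
    ch <- which(dir[u, ] & !seen)
    seen[ch] <- TRUE
    queue <- c(queue, ch)
  }
  which(seen)
}

# d-separation by enumerating every simple undirected path and checking
# the blocking rule: a path is blocked iff some non-collider on it is in
# Z, or some collider on it has no descendant (itself included) in Z.
bruteDsep <- function(dir, x, y, Z) {
  sym <- dir | t(dir)
  paths <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == y) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    for (w in which(sym[v, ])) if (!(w %in% path)) rec(c(path, w))
  }
  rec(x)
  for (pt in paths) {
    if (length(pt) == 2L) return(FALSE)
    blocked <- FALSE
    for (k in 2:(length(pt) - 1L)) {
      v <- pt[k]
      collider <- dir[pt[k - 1L], v] && dir[pt[k + 1L], v]
      if (collider) {
        if (!any(.bruteDescendants(dir, v) %in% Z)) { blocked <- TRUE; break }
      } else if (v %in% Z) { blocked <- TRUE; break }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}

# random DAG as an upper-triangular adjacency matrix (canonical order is
# topological); names V01..
randomDagMat <- function(p, prob) {
  a <- matrix(FALSE, p, p)
  a[upper.tri(a)] <- runif(sum(upper.tri(a))) < prob
  dimnames(a) <- list(sprintf("V%02d", 1:p), sprintf("V%02d", 1:p))
  a
}

# wrap an adjacency matrix as a SyntheticSystem (for the oracle interface)
matToSystem <- function(a, tiers = NULL) {
  p <- nrow(a)
  nms <- rownames(a)
  if (is.null(tiers)) tiers <- rep(1L, p)
  sch <- StudySchema(nms, rep("continuous", p), tiers,
                     target = nms[p], nTiers = max(tiers))
  idx <- which(a, arr.ind = TRUE)
  edges <- if (nrow(idx)) cbind(nms[idx[, 1]], nms[idx[, 2]]) else
    matrix(character(), 0, 2)
  syntheticSystem(sch, edges)
}

# unshielded colliders of a DAG matrix, as canonical string keys
bruteColliders <- function(dir) {
  sym <- dir | t(dir)
  p <- nrow(dir)
  out <- character()
  for (cc in 1:p) {
    pa <- which(dir[, cc])
    if (length(pa) < 2L) next
    for (i in seq_len(length(pa) - 1L)) for (j in (i + 1L):length(pa)) {
      a <- pa[i]; b <- pa[j]
      if (!sym[a, b]) out <- c(out, paste(a, cc, b))
    }
  }
  sort(out)
}

.isAcyclicMat <- function(dir) {
  p <- nrow(dir)
  reach <- dir
  for (k in 1:p) reach <- reach | (reach %*% dir > 0)
  !any(diag(reach))
}

# maximal orientation knowable from skeleton + colliders of a true DAG:
# enumerate every acyclic orientation of the skeleton with the same
# unshielded colliders; an edge is directed iff all extensions agree.
# Returns a matrix: 2 = directed i->j in all extensions, 1 = undirected.
bruteCpdag <- function(trueDir) {
  p <- nrow(trueDir)
  sym <- trueDir | t(trueDir)
  target <- bruteColliders(trueDir)
  eIdx <- which(sym & upper.tri(sym), arr.ind = TRUE)
  m <- nrow(eIdx)
  stopifnot(m <= 16)
  exts <- list()
  for (bits in 0:(2^m - 1)) {
    dir <- matrix(FALSE, p, p)
    for (e in seq_len(m)) {
      if (bitwAnd(bits, bitwShiftL(1L, e - 1L)) > 0L)
        dir[eIdx[e, 1], eIdx[e, 2]] <- TRUE
      else dir[eIdx[e, 2], eIdx[e, 1]] <- TRUE
    }
    if (.isAcyclicMat(dir) && identical(bruteColliders(dir), target))
      exts[[length(exts) + 1L]] <- dir
  }
  out <- matrix(0L, p, p, dimnames = dimnames(trueDir))
  for (e in seq_len(m)) {
    i <- eIdx[e, 1]; j <- eIdx[e, 2]
    fwd <- all(vapply(exts, function(d) d[i, j], TRUE))
    bwd <- all(vapply(exts, function(d) d[j, i], TRUE))
    if (fwd) out[i, j] <- 2L
    else if (bwd) out[j, i] <- 2L
    else { out[i, j] <- 1L; out[j, i] <- 1L }
  }
  out
}

# CausalPDAG -> comparable matrix in the same encoding as bruteCpdag
pdagToMat <- function(g) {
  nodes <- nodeNames(g)
  p <- length(nodes)
  out <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  e <- edgeTable(g)
  for (i in seq_len(nrow(e))) {
    a <- match(e$from[i], nodes); b <- match(e$to[i], nodes)
    if (e$directed[i]) out[a, b] <- 2L
    else { out[a, b] <- 1L; out[b, a] <- 1L }
  }
  out
}

# brute-force path enumeration: filter all node sequences of length
# 2..maxLen+1 ending at the target
brutePaths <- function(g, target, maxLen,
                       undirectedPolicy = "skip") {
  nodes <- nodeNames(g)
  p <- length(nodes)
  e <- edgeTable(g)
  step <- matrix(FALSE, p, p)
  for (i in seq_len(nrow(e))) {
    a <- match(e$from[i], nodes); b <- match(e$to[i], nodes)
    step[a, b] <- TRUE
    if (!e$directed[i] && undirectedPolicy == "either") step[b, a] <- TRUE
    if (!e$directed[i] && undirectedPolicy == "skip")
      step[a, b] <- FALSE
  }
  t <- match(target, nodes)
  found <- list()
  for (len in 2:(maxLen + 1L)) {
    grid <- do.call(expand.grid, rep(list(1:p), len - 1L))
    for (r in seq_len(nrow(grid))) {
      seq_ <- c(as.integer(grid[r, ]), t)
      if (anyDuplicated(seq_)) next
      ok <- all(step[cbind(seq_[-length(seq_)], seq_[-1])])
      if (ok) found[[length(found) + 1L]] <- nodes[seq_]
    }
  }
  found
}

# minimal sufficient separating set of the target by exhaustive subset
# search over brute-force d-separation
bruteMb <- function(dir, t) {
  p <- nrow(dir)
  others <- setdiff(1:p, t)
  best <- NULL
  for (size in 0:length(others)) {
    for (S in if (size == 0) list(integer()) else
         utils::combn(others, size, simplify = FALSE)) {
      rest <- setdiff(others, S)
      if (all(vapply(rest, function(v) bruteDsep(dir, v, t, S), TRUE))) {
        best <- S
        break
      }
    }
    if (!is.null(best)) break
  }
  rownames(dir)[best]
}

# small helper: build a DataMatrix from a plain matrix with an all-equal
# tier continuous schema
quickData <- function(m, tiers = NULL, target = NA_character_) {
  p <- ncol(m)
  if (is.null(colnames(m))) colnames(m) <- sprintf("X%02d", 1:p)
  if (is.null(tiers)) tiers <- rep(1L, p)
  sch <- StudySchema(colnames(m), rep("continuous", p), tiers,
                     target = target, nTiers = max(tiers))
  suppressWarnings(DataMatrix(m, sch))
}
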