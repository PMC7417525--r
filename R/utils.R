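# Internal graph helpers. Graphs are passed around in two forms: the S4
# edge-table classes for users, and plain adjacency matrices internally.
# In an adjacency "amat" (p x p logical), amat[i, j] is TRUE iff i -> j;
# an undirected edge has both amat[i, j] and amat[j, i] TRUE.

# Kahn's algorithm on a directed edge data.frame / 2-col matrix.
.isAcyclic <- function(nodes, edges) {
  if (NROW(edges) == 0L) return(TRUE)
  from <- match(edges[[1]], nodes)
  to <- match(edges[[2]], nodes)
  p <- length(nodes)
  indeg <- tabulate(to, p)
  active <- rep(TRUE, p)
  queue <- which(indeg == 0L)
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    active[v] <- FALSE
    removed <- removed + 1L
    out <- which(from == v)
    for (w in to[out]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L && active[w]) queue <- c(queue, w)
    }
  }
  removed == p
}

# Sort an edge data.frame canonically: by from-index then to-index.
.sortEdges <- function(e, nodes) {
  if (nrow(e) == 0L) return(e)
  o <- order(match(e$from, nodes), match(e$to, nodes))
  e <- e[o, , drop = FALSE]
  rownames(e) <- NULL
  e
}

# CausalPDAG -> list(dir, und) of p x p logical matrices (canonical order).
.pdagMatrices <- function(g) {
  p <- length(g@nodes)
  dir <- matrix(FALSE, p, p, dimnames = list(g@nodes, g@nodes))
  und <- dir
  e <- g@edges
  if (nrow(e)) {
    fi <- match(e$from, g@nodes); ti <- match(e$to, g@nodes)
    d <- e$directed
    dir[cbind(fi[d], ti[d])] <- TRUE
    und[cbind(fi[!d], ti[!d])] <- TRUE
    und[cbind(ti[!d], fi[!d])] <- TRUE
  }
  list(dir = dir, und = und)
}

# Reassemble a CausalPDAG from matrices + provenance matrix (character,
# entries for directed edges at [from, to], for undirected at both).
.pdagFromMatrices <- function(nodes, dir, und, prov, epoques = integer(),
                              stability = NULL) {
  idx <- which(dir, arr.ind = TRUE)
  ed <- if (nrow(idx)) {
    data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
               directed = TRUE, provenance = prov[idx],
               stability = NA_real_, stringsAsFactors = FALSE)
  }
  uidx <- which(und & upper.tri(und), arr.ind = TRUE)
  eu <- if (nrow(uidx)) {
    data.frame(from = nodes[uidx[, 1]], to = nodes[uidx[, 2]],
               directed = FALSE, provenance = "unoriented",
               stability = NA_real_, stringsAsFactors = FALSE)
  }
  e <- rbind(ed, eu)
  if (is.null(e)) e <- .emptyEdges()
  new("CausalPDAG", nodes = nodes, edges = .sortEdges(e, nodes),
      epoques = epoques)
}

# All subsets of v of size k, in deterministic canonical order, as a list.
.subsetsOfSize <- function(v, k) {
  if (k == 0L) return(list(integer()))
  if (length(v) < k) return(list())
  if (k == 1L) return(as.list(v))
  utils::combn(v, k, simplify = FALSE)
}

# Ancestors (indices) of a set of nodes in a directed adjacency matrix,
# including the nodes themselves.
.ancestorsOf <- function(dir, nodes) {
  seen <- logical(nrow(dir))
  queue <- nodes
  seen[queue] <- TRUE
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    pa <- which(dir[, v])
    new_ <- pa[!seen[pa]]
    seen[new_] <- TRUE
    queue <- c(queue, new_)
  }
  which(seen)
}

.fmtSet <- function(x) {
  if (length(x) == 0L) "{}" else paste0("{", paste(x, collapse = ","), "}")
}
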