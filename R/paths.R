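#' Enumerate bounded-length causal pathways into a target
#'
#' Collects every simple directed path of 1 to \code{maxLen} edges that
#' terminates at the target, by depth-bounded reverse traversal. A path
#' and its suffixes are distinct paths (the suffix is itself a pathway
#' into the target). Undirected edges are handled per
#' \code{undirectedPolicy}: \code{"skip"} (default) does not traverse
#' them — an unoriented edge is not an established causal step — while
#' \code{"either"} allows an undirected edge to be walked in one
#' direction per path. Paths are returned in lexicographic order of
#' canonical node indices, so enumeration is deterministic.
#'
#' @param graph a \linkS4class{CausalPDAG}.
#' @param target node name.
#' @param maxLen maximum number of edges per path (default 4).
#' @param undirectedPolicy \code{"skip"} or \code{"either"}.
#' @return a \linkS4class{PathSet}.
#' @examples
#' g <- CausalPDAG(c("B", "C", "D", "E", "T"),
#'                 directed = rbind(c("B", "C"), c("C", "D"), c("D", "E"),
#'                                  c("E", "T")))
#' enumeratePaths(g, "T")  # 4 paths: E;T, D;E;T, C;D;E;T, B;C;D;E;T
#' @export
enumeratePaths <- function(graph, target, maxLen = 4,
                           undirectedPolicy = c("skip", "either")) {
  undirectedPolicy <- match.arg(undirectedPolicy)
  if (maxLen < 1) stop("maxLen must be at least 1")
  nodes <- graph@nodes
  if (!target %in% nodes) stop("target '", target, "' not in graph")
  m <- .pdagMatrices(graph)
  pred <- m$dir  # pred[u, v]: u can be the step before v
  if (undirectedPolicy == "either") pred <- pred | m$und
  t <- match(target, nodes)
  paths <- list()
  walk <- function(path) {
    head_ <- path[1L]
    for (u in which(pred[, head_])) {
      if (u %in% path) next
      newPath <- c(u, path)
      paths[[length(paths) + 1L]] <<- newPath
      if (length(newPath) <= maxLen) walk(newPath)
    }
  }
  walk(t)
  if (length(paths)) {
    keys <- vapply(paths, function(p)
      paste(formatC(p, width = 6, flag = "0"), collapse = "."), "")
    paths <- paths[order(keys)]
  }
  new("PathSet", target = target, maxLen = as.integer(maxLen),
      paths = lapply(paths, function(p) nodes[p]))
}

#' Rank variables by pathway influence under node deletion
#'
#' For each non-target node, counts the enumerated pathways whose node
#' sequence contains it; deleting the node eliminates exactly those
#' paths, so the proportion eliminated equals paths-containing divided by
#' the total path count. Nodes are ranked by proportion, descending, with
#' ties broken by canonical order.
#'
#' @param pathset a \linkS4class{PathSet} from [enumeratePaths()].
#' @param nodes node universe in canonical order; defaults to the nodes
#'   appearing in the paths. Pass the graph's node set to include
#'   zero-influence variables in the ranking.
#' @return an \linkS4class{InfluenceRanking}.
#' @export
influenceRanking <- function(pathset, nodes = NULL) {
  if (is.null(nodes))
    nodes <- unique(unlist(pathset@paths))
  nodes <- setdiff(nodes, pathset@target)
  nPaths <- length(pathset@paths)
  if (nPaths == 0L) {
    warning("empty path set: influence proportions undefined")
    rk <- data.frame(node = character(), count = integer(),
                     proportion = numeric(), rank = integer(),
                     stringsAsFactors = FALSE)
    return(new("InfluenceRanking", ranking = rk, nPaths = 0L,
               target = pathset@target))
  }
  cnt <- stats::setNames(integer(length(nodes)), nodes)
  for (p in pathset@paths) {
    hit <- intersect(p, nodes)
    cnt[hit] <- cnt[hit] + 1L
  }
  o <- order(-cnt, seq_along(nodes))
  rk <- data.frame(node = nodes[o], count = unname(cnt[o]),
                   proportion = unname(cnt[o]) / nPaths,
                   rank = seq_along(o), stringsAsFactors = FALSE)
  new("InfluenceRanking", ranking = rk, nPaths = as.integer(nPaths),
      target = pathset@target)
}

#' Re-enumerate paths after deleting a node
#'
#' Removes the node from the graph, re-runs [enumeratePaths()], and
#' returns the number of surviving paths. This is the direct reading of
#' the node-deletion influence heuristic and serves as the independent
#' check that counting path containment equals recounting after deletion.
#'
#' @inheritParams enumeratePaths
#' @param node node to delete (must differ from the target).
#' @return integer: number of paths remaining.
#' @export
deleteAndRecount <- function(graph, target, node, maxLen = 4,
                             undirectedPolicy = c("skip", "either")) {
  undirectedPolicy <- match.arg(undirectedPolicy)
  if (!node %in% graph@nodes) stop("node '", node, "' not in graph")
  if (node == target) stop("cannot delete the target")
  keep <- setdiff(graph@nodes, node)
  e <- graph@edges
  e <- e[e$from != node & e$to != node, , drop = FALSE]
  sub <- new("CausalPDAG", nodes = keep, edges = .sortEdges(e, keep),
             epoques = if (length(graph@epoques)) graph@epoques[keep]
                       else integer())
  length(enumeratePaths(sub, target, maxLen, undirectedPolicy))
}

#' Write paths and ranking to text files
#'
#' Paths as flat text (one per line, arrow-separated, matching the
#' published-network style) and the ranking as TSV with columns
#' \code{node}, \code{count}, \code{proportion}, \code{rank};
#' proportions are full precision in the TSV, whole percent in the
#' human-readable path header.
#'
#' @param pathset a \linkS4class{PathSet}.
#' @param ranking an \linkS4class{InfluenceRanking}.
#' @param pathsFile,rankingFile output paths (NULL to skip either).
#' @return invisibly, the file paths written.
#' @export
writePathReport <- function(pathset, ranking = NULL, pathsFile = NULL,
                            rankingFile = NULL) {
  if (!is.null(pathsFile))
    writeLines(vapply(pathset@paths, paste, "", collapse = " -> "),
               pathsFile)
  if (!is.null(rankingFile) && !is.null(ranking))
    utils::write.table(rankingTable(ranking), rankingFile, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(pathsFile, rankingFile))
}
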