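#' Write a causal network to file
#'
#' Three formats are supported, all readable back with [readNetwork()]:
#' \describe{
#'   \item{\code{tsv}}{edge-list TSV with columns \code{source},
#'     \code{target}, \code{oriented}, \code{provenance},
#'     \code{stability_pct} (empty when not computed).}
#'   \item{\code{sif}}{Cytoscape simple-interaction format; directed edges
#'     use relation \code{causes}, undirected edges \code{assoc}.}
#'   \item{\code{graphml}}{GraphML via igraph with edge attributes
#'     \code{oriented}, \code{provenance}, \code{stability} and node
#'     attribute \code{epoque} when tiers are attached.}
#' }
#' Write-then-read round-trips reproduce the identical edge set.
#'
#' @param graph a \linkS4class{CausalPDAG}.
#' @param path output file path.
#' @param format one of \code{"tsv"}, \code{"sif"}, \code{"graphml"}.
#' @return invisibly, \code{path}.
#' @seealso [readNetwork()]
#' @export
writeNetwork <- function(graph, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(is(graph, "CausalPDAG"))
  validObject(graph)
  e <- graph@edges
  switch(format,
    tsv = {
      out <- data.frame(source = e$from, target = e$to,
                        oriented = ifelse(e$directed, "true", "false"),
                        provenance = e$provenance,
                        stability_pct = ifelse(is.na(e$stability), "",
                                               format(e$stability)),
                        stringsAsFactors = FALSE)
      # isolated nodes kept as comment so round-trips preserve the node set
      iso <- setdiff(graph@nodes, c(e$from, e$to))
      con <- file(path, "w")
      on.exit(close(con))
      if (length(iso))
        writeLines(paste0("# node\t", iso), con)
      utils::write.table(out, con, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    sif = {
      rel <- ifelse(e$directed, "causes", "assoc")
      iso <- setdiff(graph@nodes, c(e$from, e$to))
      writeLines(c(paste(e$from, rel, e$to),
                   iso),  # bare node name = isolated node, SIF convention
                 path)
    },
    graphml = {
      g <- .asIgraph(graph)
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}

.asIgraph <- function(graph) {
  e <- graph@edges
  g <- igraph::make_empty_graph(n = length(graph@nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = graph@nodes)
  if (length(graph@epoques))
    g <- igraph::set_vertex_attr(g, "epoque",
                                 value = as.integer(
                                   graph@epoques[graph@nodes]))
  if (nrow(e)) {
    g <- igraph::add_edges(g, rbind(match(e$from, graph@nodes),
                                    match(e$to, graph@nodes)))
    g <- igraph::set_edge_attr(g, "oriented", value = e$directed)
    g <- igraph::set_edge_attr(g, "provenance", value = e$provenance)
    g <- igraph::set_edge_attr(g, "stability", value = e$stability)
  }
  g
}

#' Read a causal network from file
#'
#' Inverse of [writeNetwork()]. The TSV reader is tolerant to the column
#' spellings found in published supplementary edge lists: \code{source} /
#' \code{Source} / \code{from} / \code{Cause}, \code{target} /
#' \code{Target} / \code{to} / \code{Effect}, and a direction column named
#' \code{oriented} / \code{Direction} / \code{directed} whose values may
#' be logical, \code{directed}/\code{undirected}, or arrows
#' (\code{"->"} / \code{"--"}). A pair whose direction field is absent or
#' blank is read as undirected. Stability columns named
#' \code{stability_pct} / \code{stability} / \code{Stability(\%)} are
#' picked up when present.
#'
#' @param path input file path.
#' @param format one of \code{"tsv"}, \code{"sif"}, \code{"graphml"}.
#' @param epoques optional named tier vector; when supplied the tier
#'   invariant of the \linkS4class{CausalPDAG} is enforced.
#' @param nodes optional node universe (to retain isolated nodes known
#'   from elsewhere).
#' @return a validated \linkS4class{CausalPDAG}.
#' @export
readNetwork <- function(path, format = c("tsv", "sif", "graphml"),
                        epoques = NULL, nodes = NULL) {
  format <- match.arg(format)
  g <- switch(format,
              tsv = .readNetworkTsv(path),
              sif = .readNetworkSif(path),
              graphml = .readNetworkGraphml(path))
  if (!is.null(nodes)) {
    unknown <- setdiff(g$nodes, nodes)
    if (length(unknown))
      stop("edge list mentions nodes outside the supplied universe: ",
           paste(unknown, collapse = ", "))
    g$nodes <- nodes
  }
  if (!is.null(epoques) && is.null(names(epoques)))
    stop("epoques must be a named vector")
  pdag <- CausalPDAG(g$nodes, directed = g$directed,
                     undirected = g$undirected, epoques = epoques,
                     provenance = g$provenance)
  if (length(g$stability)) {
    key <- mapply(.sepsetKey, pdag@edges$from, pdag@edges$to)
    pdag@edges$stability <- unname(g$stability[key])
  }
  validObject(pdag)
  pdag
}

.dirTokens <- c("true", "t", "1", "directed", "->", "causes", "yes")
.undTokens <- c("false", "f", "0", "undirected", "--", "assoc", "no", "",
                "na")

.readNetworkTsv <- function(path) {
  lines <- readLines(path)
  isoNodes <- sub("^# node\t", "", lines[startsWith(lines, "# node\t")])
  body <- lines[!startsWith(lines, "#")]
  if (length(body) < 1L) stop("empty edge-list file: ", path)
  sep <- if (grepl("\t", body[1])) "\t" else ","
  tab <- utils::read.table(text = body, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           check.names = FALSE,
                           colClasses = "character")
  lc <- tolower(trimws(names(tab)))
  pick <- function(cands) {
    hit <- match(cands, lc)
    hit <- hit[!is.na(hit)]
    if (length(hit)) hit[1] else NA_integer_
  }
  si <- pick(c("source", "from", "cause", "node1", "a"))
  ti <- pick(c("target", "to", "effect", "node2", "b"))
  if (is.na(si) || is.na(ti))
    stop("cannot identify source/target columns in ", path,
         " (found: ", paste(names(tab), collapse = ", "), ")")
  di <- pick(c("oriented", "direction", "directed", "edge type", "type"))
  sti <- pick(c("stability_pct", "stability", "stability(%)",
                "stability (%)", "edge stability"))
  src <- trimws(tab[[si]]); tgt <- trimws(tab[[ti]])
  bad <- which(src == "" | tgt == "")
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s: empty endpoint",
                 bad[1] + 1L, path))
  oriented <- if (is.na(di)) rep(TRUE, nrow(tab)) else {
    tok <- tolower(trimws(tab[[di]]))
    tok[is.na(tok)] <- ""
    unknown <- !(tok %in% c(.dirTokens, .undTokens))
    if (any(unknown))
      stop(sprintf("malformed row at line %d of %s: direction token '%s'",
                   which(unknown)[1] + 1L, path, tok[which(unknown)[1]]))
    tok %in% .dirTokens
  }
  stability <- NULL
  if (!is.na(sti)) {
    sv <- suppressWarnings(as.numeric(tab[[sti]]))
    key <- mapply(.sepsetKey, src, tgt)
    stability <- stats::setNames(sv, key)
    stability <- stability[!is.na(stability)]
  }
  nodes <- unique(c(src, tgt, isoNodes))
  list(nodes = nodes,
       directed = cbind(src[oriented], tgt[oriented]),
       undirected = cbind(src[!oriented], tgt[!oriented]),
       provenance = "external", stability = stability)
}

.readNetworkSif <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  parts <- strsplit(lines, "[ \t]+")
  iso <- vapply(parts, length, 1L) == 1L
  edges <- parts[!iso]
  if (length(edges) && any(vapply(edges, length, 1L) != 3L))
    stop("malformed SIF line: ",
         lines[!iso][which(vapply(edges, length, 1L) != 3L)[1]])
  rel <- vapply(edges, `[[`, "", 2)
  bad <- !rel %in% c("causes", "assoc")
  if (any(bad)) stop("unknown SIF relation: ", rel[which(bad)[1]])
  src <- vapply(edges, `[[`, "", 1)
  tgt <- vapply(edges, `[[`, "", 3)
  dird <- rel == "causes"
  list(nodes = unique(c(src, tgt, unlist(parts[iso]))),
       directed = cbind(src[dird], tgt[dird]),
       undirected = cbind(src[!dird], tgt[!dird]),
       provenance = "external", stability = NULL)
}

.readNetworkGraphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g, names = TRUE)
  oriented <- igraph::edge_attr(g, "oriented")
  if (is.null(oriented)) oriented <- rep(TRUE, nrow(el))
  oriented <- as.logical(oriented)
  prov <- igraph::edge_attr(g, "provenance")
  if (is.null(prov)) prov <- "external"
  stab <- igraph::edge_attr(g, "stability")
  stability <- NULL
  if (!is.null(stab)) {
    key <- if (nrow(el)) mapply(.sepsetKey, el[, 1], el[, 2]) else character()
    stability <- stats::setNames(as.numeric(stab), key)
    stability <- stability[!is.na(stability)]
  }
  list(nodes = nodes,
       directed = el[oriented, , drop = FALSE],
       undirected = el[!oriented, , drop = FALSE],
       provenance = if (length(prov) == nrow(el) && any(oriented))
         prov[oriented] else "external",
       stability = stability)
}
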