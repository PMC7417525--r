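#' Markov boundary of the target read off the causal network
#'
#' The local causal network model of the target: its direct causes
#' (parents), direct effects (children), and spouses (direct causes of the
#' direct effects, excluding the target and its own direct causes). Under
#' faithfulness this is the minimal variable set rendering the target
#' independent of all others — the most parsimonious maximally predictive
#' set. Undirected edges incident to the target are neighbours of
#' undetermined role and are reported separately, never silently assigned
#' a direction.
#'
#' @param graph a \linkS4class{CausalPDAG}.
#' @param target node name.
#' @return a \linkS4class{MarkovBoundary}.
#' @examples
#' g <- CausalPDAG(c("A", "T", "C", "D"),
#'                 directed = rbind(c("A", "T"), c("T", "C"), c("D", "C")))
#' markovBoundary(g, "T")
#' @export
markovBoundary <- function(graph, target) {
  nodes <- graph@nodes
  if (!target %in% nodes) stop("target '", target, "' not in graph")
  m <- .pdagMatrices(graph)
  t <- match(target, nodes)
  parents <- nodes[m$dir[, t]]
  children <- nodes[m$dir[t, ]]
  spouses <- character()
  for (ch in which(m$dir[t, ]))
    spouses <- union(spouses, nodes[m$dir[, ch]])
  spouses <- setdiff(spouses, c(target, parents))
  # a spouse that is also a child keeps its child role
  spouses <- setdiff(spouses, children)
  undetermined <- nodes[m$und[t, ]]
  new("MarkovBoundary", target = target,
      directCauses = parents[order(match(parents, nodes))],
      directEffects = children[order(match(children, nodes))],
      spouses = spouses[order(match(spouses, nodes))],
      undetermined = undetermined[order(match(undetermined, nodes))])
}

#' Cross-validated predictivity of the Markov boundary
#'
#' Compares the out-of-fold predictive score (proportion of variance
#' explained by a linear predictor) of (a) the Markov-boundary members
#' only against (b) all other variables. Under faithfulness the boundary
#' achieves the predictivity of the full variable set — the parsimony
#' property this function lets you verify empirically. Rows incomplete on
#' any used variable are dropped; the same rows feed both models.
#'
#' @param data a \linkS4class{DataMatrix}.
#' @param mb a \linkS4class{MarkovBoundary} (or character vector of
#'   feature names).
#' @param target target variable name; must be continuous or ordinal.
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return named numeric: \code{scoreMb} and \code{scoreAll}.
#' @export
mbPredictivity <- function(data, mb, target, folds = 5, seed = 1) {
  feats <- if (is(mb, "MarkovBoundary")) mbMembers(mb) else as.character(mb)
  nms <- variableNames(data)
  if (!target %in% nms) stop("target not in data")
  if (dtypes(data@schema)[target] == "categorical")
    stop("predictivity score requires a continuous or ordinal target")
  feats <- setdiff(feats, target)
  allFeats <- setdiff(nms, target)
  rows <- which(rowSums(data@missingMask) == 0L)
  if (length(rows) < 2L * folds)
    stop("too few complete rows for ", folds, "-fold cross-validation")
  y <- data@values[rows, target]
  X <- data@values[rows, , drop = FALSE]
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = length(rows)))
  cvScore <- function(f) {
    sse <- 0; sst <- 0
    for (k in seq_len(folds)) {
      tr <- fold != k; te <- !tr
      if (length(f) == 0L) {
        pred <- rep(mean(y[tr]), sum(te))
      } else {
        df <- data.frame(X[, f, drop = FALSE])
        fit <- stats::lm(y ~ ., data = cbind(y = y, df)[tr, , drop = FALSE])
        pred <- suppressWarnings(
          stats::predict(fit, newdata = df[te, , drop = FALSE]))
      }
      sse <- sse + sum((y[te] - pred)^2)
      sst <- sst + sum((y[te] - mean(y[tr]))^2)
    }
    1 - sse / sst
  }
  c(scoreMb = cvScore(feats), scoreAll = cvScore(allFeats))
}

#' Second-degree neighbourhood subgraph of the target
#'
#' Induced subgraph on all nodes within \code{steps} edges of the target
#' (edge direction ignored for the distance) — the standard local
#' visualisation of a target's causal neighbourhood. Export it with
#' [writeNetwork()] for Cytoscape.
#'
#' @param graph a \linkS4class{CausalPDAG}.
#' @param target node name.
#' @param steps neighbourhood radius (default 2).
#' @return a \linkS4class{CausalPDAG} on the neighbourhood nodes.
#' @export
neighborhoodSubgraph <- function(graph, target, steps = 2) {
  nodes <- graph@nodes
  if (!target %in% nodes) stop("target '", target, "' not in graph")
  m <- .pdagMatrices(graph)
  sym <- m$dir | t(m$dir) | m$und
  keep <- match(target, nodes)
  frontier <- keep
  for (s in seq_len(steps)) {
    nxt <- which(colSums(sym[frontier, , drop = FALSE]) > 0)
    frontier <- setdiff(nxt, keep)
    keep <- union(keep, nxt)
    if (!length(frontier)) break
  }
  keep <- sort(keep)
  sub <- nodes[keep]
  e <- graph@edges
  e <- e[e$from %in% sub & e$to %in% sub, , drop = FALSE]
  g <- new("CausalPDAG", nodes = sub, edges = .sortEdges(e, sub),
           epoques = if (length(graph@epoques)) graph@epoques[sub]
                     else integer())
  validObject(g)
  g
}

#' Serialise a MarkovBoundary to JSON
#'
#' @param mb a \linkS4class{MarkovBoundary}.
#' @param path optional file path; when \code{NULL} the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to file.
#' @export
mbToJson <- function(mb, path = NULL) {
  x <- list(target = mb@target, direct_causes = mb@directCauses,
            direct_effects = mb@directEffects, spouses = mb@spouses,
            undetermined = mb@undetermined)
  js <- jsonlite::toJSON(x, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
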