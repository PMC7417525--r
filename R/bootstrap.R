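#' Bootstrap edge stability of the discovered network
#'
#' Resamples the rows of the data with replacement \code{B} times (at the
#' original n, preserving block-missingness structure within resampled
#' rows), re-runs skeleton discovery plus orientation on each resample,
#' and reports for every edge the percentage of bootstrap networks in
#' which its adjacency was detected. Stability is adjacency-based by
#' default — orientation can flip between resamples while the causal
#' relation persists — with an optional orientation-aware column giving
#' the percent of detections agreeing with the original direction.
#'
#' The report covers the union of edges seen in any iteration plus all
#' edges of the original network. A failed iteration is logged and
#' discarded with \code{B} adjusted, never silently. Identical seed and
#' inputs reproduce the report exactly.
#'
#' @param data a \linkS4class{DataMatrix}.
#' @param config a \linkS4class{TestConfig}.
#' @param B number of bootstrap iterations (default 100).
#' @param seed integer seed.
#' @param graph optional original \linkS4class{CausalPDAG}; computed from
#'   the full data when omitted.
#' @param orientationAware also report directed agreement percentages.
#' @param verbose progress messages.
#' @return a \linkS4class{StabilityReport}.
#' @seealso [mergeStability()] to attach the percentages to a graph.
#' @export
bootstrapStability <- function(data, config = TestConfig(), B = 100,
                               seed = 1, graph = NULL,
                               orientationAware = FALSE, verbose = FALSE) {
  stopifnot(B >= 1)
  if (is.null(graph))
    graph <- orientAll(buildSkeleton(data, config), schema(data))
  n <- nSamples(data)
  nodes <- variableNames(data)
  counts <- new.env(parent = emptyenv())
  dirCounts <- new.env(parent = emptyenv())
  origDir <- new.env(parent = emptyenv())
  de <- directedEdges(graph)
  for (i in seq_len(nrow(de)))
    origDir[[.sepsetKey(de$from[i], de$to[i])]] <- c(de$from[i], de$to[i])
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, B)
  ok <- 0L; failed <- 0L
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    rows <- sample.int(n, n, replace = TRUE)
    res <- tryCatch({
      boot <- new("DataMatrix", values = data@values[rows, , drop = FALSE],
                  missingMask = data@missingMask[rows, , drop = FALSE],
                  schema = data@schema,
                  degenerate = data@degenerate)
      g <- orientAll(buildSkeleton(boot, config), schema(data))
      g@edges
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      message(sprintf("bootstrap iteration %d failed and was discarded: %s",
                      b, conditionMessage(res)))
      next
    }
    ok <- ok + 1L
    if (verbose && b %% 10 == 0)
      message(sprintf("bootstrap %d/%d", b, B))
    for (i in seq_len(nrow(res))) {
      key <- .sepsetKey(res$from[i], res$to[i])
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      if (orientationAware && res$directed[i]) {
        od <- origDir[[key]]
        if (!is.null(od) && od[1] == res$from[i])
          dirCounts[[key]] <- (dirCounts[[key]] %||% 0L) + 1L
      }
    }
  }
  if (ok == 0L) stop("all bootstrap iterations failed")
  # union of bootstrap-seen edges and original-network edges
  e <- graph@edges
  origKeys <- if (nrow(e)) mapply(.sepsetKey, e$from, e$to) else character()
  allKeys <- union(origKeys, ls(counts))
  parts <- strsplit(allKeys, "\r", fixed = TRUE)
  from <- vapply(parts, `[[`, "", 1)
  to <- vapply(parts, `[[`, "", 2)
  # present pairs in canonical node order where known
  ix <- match(from, nodes); jx <- match(to, nodes)
  swap <- !is.na(ix) & !is.na(jx) & ix > jx
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  stab <- vapply(allKeys, function(k) 100 * (counts[[k]] %||% 0L) / ok,
                 0)
  out <- data.frame(from = from, to = to, stability = unname(stab),
                    stringsAsFactors = FALSE)
  if (orientationAware)
    out$directedPct <- vapply(allKeys, function(k)
      100 * (dirCounts[[k]] %||% 0L) / ok, 0)
  o <- order(match(out$from, nodes), match(out$to, nodes))
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  new("StabilityReport", B = ok, seed = as.numeric(seed), edges = out,
      failures = failed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Attach bootstrap stability percentages to a graph
#'
#' Fills the \code{stability} column of the graph's edge table from a
#' \linkS4class{StabilityReport}, so the combined edge list (edge plus
#' stability) can be exported with [writeNetwork()].
#'
#' @param graph a \linkS4class{CausalPDAG}.
#' @param report a \linkS4class{StabilityReport}.
#' @return the graph with stability filled in (0 for an original edge
#'   never seen in a bootstrap network).
#' @export
mergeStability <- function(graph, report) {
  e <- graph@edges
  if (!nrow(e)) return(graph)
  key <- mapply(.sepsetKey, e$from, e$to)
  rk <- mapply(.sepsetKey, report@edges$from, report@edges$to)
  hit <- match(key, rk)
  e$stability <- ifelse(is.na(hit), 0, report@edges$stability[hit])
  graph@edges <- e
  graph
}
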