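#' @import methods
NULL

.DTYPES <- c("continuous", "ordinal", "categorical")
.PROVENANCE <- c("tier_oriented", "collider_oriented", "propagated",
                 "unoriented", "external")

.emptyEdges <- function() {
  data.frame(from = character(), to = character(),
             directed = logical(), provenance = character(),
             stability = numeric(), stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------- schema ----

#' StudySchema: the encoded prior knowledge
#'
#' Holds the variable table of a study: one row per variable with its unique
#' name, numeric type (\code{continuous}, \code{ordinal} or
#' \code{categorical}) and time epoque (temporal tier, by default 1--7).
#' The row order is the canonical variable order used for all deterministic
#' tie-breaking in discovery, orientation and path enumeration.
#'
#' @slot variables data.frame with columns \code{name}, \code{dtype},
#'   \code{epoque}.
#' @slot target character, name of the designated outcome variable
#'   (\code{NA} if none designated).
#' @slot nTiers integer, the declared number of tiers.
#'
#' @seealso [loadSchema()] to read a schema from file.
#' @export
setClass("StudySchema",
         representation(variables = "data.frame",
                        target = "character",
                        nTiers = "integer"))

setValidity("StudySchema", function(object) {
  v <- object@variables
  msg <- character()
  if (!all(c("name", "dtype", "epoque") %in% names(v)))
    return("variables must have columns name, dtype, epoque")
  if (anyDuplicated(v$name))
    msg <- c(msg, sprintf("duplicate variable name(s): %s",
                          paste(unique(v$name[duplicated(v$name)]),
                                collapse = ", ")))
  bad <- !v$dtype %in% .DTYPES
  if (any(bad))
    msg <- c(msg, sprintf("unknown dtype(s): %s (row %s)",
                          paste(unique(v$dtype[bad]), collapse = ", "),
                          paste(which(bad), collapse = ", ")))
  ep <- v$epoque
  badEp <- is.na(ep) | ep < 1L | ep > object@nTiers | ep != as.integer(ep)
  if (any(badEp))
    msg <- c(msg, sprintf("epoque outside 1..%d (row %s)", object@nTiers,
                          paste(which(badEp), collapse = ", ")))
  if (!is.na(object@target) && !object@target %in% v$name)
    msg <- c(msg, sprintf("target '%s' is not a schema variable",
                          object@target))
  if (length(msg)) msg else TRUE
})

#' Construct a StudySchema
#'
#' @param name character vector of unique variable names.
#' @param dtype character vector, each one of \code{"continuous"},
#'   \code{"ordinal"}, \code{"categorical"}.
#' @param epoque integer vector of tiers.
#' @param target optional name of the outcome variable.
#' @param nTiers declared tier count; defaults to \code{max(epoque)}.
#' @return a \linkS4class{StudySchema}.
#' @examples
#' StudySchema(c("A", "B", "T"), c("continuous", "ordinal", "continuous"),
#'             c(1L, 2L, 7L), target = "T")
#' @export
StudySchema <- function(name, dtype, epoque, target = NA_character_,
                        nTiers = max(epoque)) {
  new("StudySchema",
      variables = data.frame(name = as.character(name),
                             dtype = as.character(dtype),
                             epoque = as.integer(epoque),
                             stringsAsFactors = FALSE),
      target = as.character(target)[1L],
      nTiers = as.integer(nTiers))
}

#' @describeIn StudySchema variable names in canonical order.
#' @param x a StudySchema.
#' @export
setMethod("variableNames", "StudySchema", function(x) x@variables$name)

#' @export
#' @describeIn StudySchema the designated outcome variable.
setMethod("targetVariable", "StudySchema", function(x) x@target)

#' @export
#' @describeIn StudySchema named integer vector of tiers.
setMethod("epoques", "StudySchema", function(x) {
  stats::setNames(x@variables$epoque, x@variables$name)
})

#' @export
#' @describeIn StudySchema named character vector of declared types.
setMethod("dtypes", "StudySchema", function(x) {
  stats::setNames(x@variables$dtype, x@variables$name)
})

setMethod("show", "StudySchema", function(object) {
  v <- object@variables
  cat(sprintf("StudySchema: %d variables over %d tiers\n",
              nrow(v), object@nTiers))
  tab <- table(factor(v$epoque, levels = seq_len(object@nTiers)))
  cat("  per tier:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = " "), "\n")
  if (!is.na(object@target))
    cat(sprintf("  target: %s (tier %d)\n", object@target,
                v$epoque[match(object@target, v$name)]))
})

## ------------------------------------------------------------ data matrix ---

#' DataMatrix: observations with a missingness mask
#'
#' An n-by-p numeric table of observations in canonical column order, with a
#' boolean missingness mask. Ordinal and categorical variables carry integer
#' codes. Columns with zero observed variance are flagged degenerate; they
#' are retained but every independence test touching them is untestable.
#'
#' @slot values numeric matrix, n rows by p columns, columns in canonical
#'   order; missing cells hold \code{NA}.
#' @slot missingMask logical matrix of the same shape; \code{TRUE} = missing.
#' @slot schema the \linkS4class{StudySchema}.
#' @slot degenerate named logical vector flagging zero-variance columns.
#' @seealso [loadData()], [sampleData()]
#' @export
setClass("DataMatrix",
         representation(values = "matrix", missingMask = "matrix",
                        schema = "StudySchema", degenerate = "logical"))

setValidity("DataMatrix", function(object) {
  msg <- character()
  p <- nrow(object@schema@variables)
  if (ncol(object@values) != p)
    msg <- c(msg, sprintf("values has %d columns, schema has %d variables",
                          ncol(object@values), p))
  if (!identical(dim(object@values), dim(object@missingMask)))
    msg <- c(msg, "values and missingMask dimensions differ")
  if (!identical(colnames(object@values), variableNames(object@schema)))
    msg <- c(msg, "column names must equal schema names in canonical order")
  if (length(msg)) msg else TRUE
})

#' Construct a DataMatrix from a numeric matrix or data.frame
#'
#' Columns are reordered to the schema's canonical order; \code{NA} cells
#' populate the missingness mask; zero-variance columns are flagged.
#'
#' @param values matrix or data.frame, columns named as schema variables.
#' @param schema a \linkS4class{StudySchema}.
#' @return a \linkS4class{DataMatrix}.
#' @export
DataMatrix <- function(values, schema) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  nm <- variableNames(schema)
  extra <- setdiff(colnames(values), nm)
  missing_ <- setdiff(nm, colnames(values))
  if (length(extra) || length(missing_))
    stop("column mismatch between data and schema",
         if (length(extra)) paste0("; not in schema: ",
                                   paste(extra, collapse = ", ")),
         if (length(missing_)) paste0("; absent from data: ",
                                      paste(missing_, collapse = ", ")))
  values <- values[, nm, drop = FALSE]
  mask <- is.na(values)
  degen <- vapply(seq_len(ncol(values)), function(j) {
    obs <- values[!mask[, j], j]
    length(obs) == 0L || length(unique(obs)) < 2L
  }, logical(1))
  names(degen) <- nm
  if (any(degen))
    warning("degenerate (zero observed variance) column(s): ",
            paste(nm[degen], collapse = ", "))
  new("DataMatrix", values = values, missingMask = mask, schema = schema,
      degenerate = degen)
}

#' @export
#' @describeIn DataMatrix canonical variable names.
#' @param x a DataMatrix.
setMethod("variableNames", "DataMatrix", function(x) colnames(x@values))

#' @export
#' @describeIn DataMatrix the schema.
setMethod("schema", "DataMatrix", function(x) x@schema)

#' @export
#' @describeIn DataMatrix tier assignment.
setMethod("epoques", "DataMatrix", function(x) epoques(x@schema))

#' Number of rows (subjects) in a DataMatrix
#' @param x a \linkS4class{DataMatrix}.
#' @return integer.
#' @export
nSamples <- function(x) nrow(x@values)

#' Observed values of a DataMatrix
#' @param x a \linkS4class{DataMatrix}.
#' @return numeric matrix with \code{NA} at missing cells.
#' @export
dataValues <- function(x) x@values

#' Per-column observed counts
#' @param x a \linkS4class{DataMatrix}.
#' @return named integer vector of non-missing counts per variable.
#' @export
observedN <- function(x) {
  stats::setNames(nrow(x@values) - colSums(x@missingMask),
                  colnames(x@values))
}

#' Pairwise effective sample sizes
#'
#' Number of rows jointly observed for each pair of variables; the sample
#' size available to a marginal independence test of that pair.
#'
#' @param x a \linkS4class{DataMatrix}.
#' @return p-by-p integer matrix.
#' @export
pairwiseN <- function(x) {
  obs <- !x@missingMask
  n <- crossprod(obs * 1L)
  storage.mode(n) <- "integer"
  n
}

setMethod("show", "DataMatrix", function(object) {
  cat(sprintf("DataMatrix: %d subjects x %d variables\n",
              nrow(object@values), ncol(object@values)))
  nmiss <- sum(object@missingMask)
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / length(object@values)))
  if (any(object@degenerate))
    cat("  degenerate columns:",
        paste(names(which(object@degenerate)), collapse = ", "), "\n")
})

## ------------------------------------------------------------- test config --

#' TestConfig: parameters of the conditional-independence machinery
#'
#' Defaults are the protocol's stated analysis parameters: rejection
#' threshold \code{alpha = 0.05} and maximum conditioning-set size
#' \code{maxK = 3}.
#'
#' @slot alpha numeric in (0,1), per-test rejection threshold.
#' @slot maxK integer >= 0, maximum conditioning-set size.
#' @slot minEffectiveN minimum complete rows required to attempt a test.
#' @slot andRule logical; keep an edge only if each endpoint is in the
#'   other's parent--children set (AND rule) rather than either (OR rule).
#' @export
setClass("TestConfig",
         representation(alpha = "numeric", maxK = "integer",
                        minEffectiveN = "integer", andRule = "logical"))

setValidity("TestConfig", function(object) {
  msg <- character()
  if (!(object@alpha > 0 && object@alpha < 1))
    msg <- c(msg, "alpha must be in (0,1)")
  if (object@maxK < 0L) msg <- c(msg, "maxK must be >= 0")
  if (object@minEffectiveN < 5L)
    msg <- c(msg, "minEffectiveN must be at least 5")
  if (length(msg)) msg else TRUE
})

#' Construct a TestConfig
#' @param alpha per-test rejection threshold (default 0.05).
#' @param maxK maximum conditioning-set size (default 3).
#' @param minEffectiveN minimum complete rows to attempt a test (default 10).
#' @param andRule edge symmetry rule, AND (default) vs OR.
#' @return a \linkS4class{TestConfig}.
#' @export
TestConfig <- function(alpha = 0.05, maxK = 3, minEffectiveN = 10,
                       andRule = TRUE) {
  new("TestConfig", alpha = alpha, maxK = as.integer(maxK),
      minEffectiveN = as.integer(minEffectiveN), andRule = andRule)
}

setMethod("show", "TestConfig", function(object) {
  cat(sprintf(
    "TestConfig: alpha=%g maxK=%d minEffectiveN=%d rule=%s\n",
    object@alpha, object@maxK, object@minEffectiveN,
    if (object@andRule) "AND" else "OR"))
})

#' CITestResult: outcome of one conditional-independence test
#'
#' @slot statistic the Fisher-z statistic (NA when untestable).
#' @slot pValue two-sided p-value in [0,1] (NA when untestable).
#' @slot effectiveN number of complete rows used.
#' @slot conditioningSize size of the conditioning set.
#' @slot testable FALSE when too few complete rows or a degenerate variable
#'   made the test impossible; such results never establish dependence.
#' @export
setClass("CITestResult",
         representation(statistic = "numeric", pValue = "numeric",
                        effectiveN = "integer", conditioningSize = "integer",
                        testable = "logical"))

setMethod("show", "CITestResult", function(object) {
  if (object@testable)
    cat(sprintf("CI test: z=%.4f p=%.4g (n=%d, |Z|=%d)\n", object@statistic,
                object@pValue, object@effectiveN, object@conditioningSize))
  else
    cat(sprintf("CI test: untestable (n=%d, |Z|=%d)\n", object@effectiveN,
                object@conditioningSize))
})

## ---------------------------------------------------------------- sepsets ---

#' SepsetTable: separating sets recorded during discovery
#'
#' For each pair removed during skeleton discovery, the first conditioning
#' set found to render the pair independent, with its p-value. Lookup is
#' symmetric in the two variables. These witnesses drive collider
#' orientation.
#'
#' @slot env environment keyed by sorted name pairs.
#' @export
setClass("SepsetTable", representation(env = "environment"))

#' @rdname SepsetTable-class
#' @return \code{SepsetTable()} returns an empty table.
#' @export
SepsetTable <- function() new("SepsetTable", env = new.env(parent = emptyenv()))

.sepsetKey <- function(a, b) {
  if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
}

.sepsetPut <- function(tab, a, b, Z, p, overwrite = FALSE) {
  key <- .sepsetKey(a, b)
  if (overwrite || is.null(tab@env[[key]]))
    tab@env[[key]] <- list(Z = Z, p = p)
  invisible(tab)
}

#' @export
#' @describeIn SepsetTable symmetric lookup; \code{NULL} when absent.
#' @param x a SepsetTable.
#' @param a,b variable names.
setMethod("sepset", "SepsetTable", function(x, a, b) {
  x@env[[.sepsetKey(a, b)]]
})

#' Number of recorded sepsets
#' @param x a \linkS4class{SepsetTable}.
#' @export
setMethod("length", "SepsetTable", function(x) length(ls(x@env)))

setMethod("show", "SepsetTable", function(object) {
  cat(sprintf("SepsetTable: %d pair(s)\n", length(object)))
})

## --------------------------------------------------------------- skeleton ---

#' Skeleton: undirected adjacency structure plus sepsets
#'
#' @slot nodes variable names in canonical order.
#' @slot edges data.frame with columns \code{from}, \code{to}; each
#'   unordered pair stored once with \code{from} before \code{to} in
#'   canonical order.
#' @slot sepsets the \linkS4class{SepsetTable} accumulated while removing
#'   pairs.
#' @seealso [buildSkeleton()]
#' @export
setClass("Skeleton",
         representation(nodes = "character", edges = "data.frame",
                        sepsets = "SepsetTable"))

setValidity("Skeleton", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c(e$from, e$to) %in% object@nodes))
    msg <- c(msg, "edge endpoint not in node set")
  if (any(e$from == e$to)) msg <- c(msg, "self-loop")
  key <- mapply(.sepsetKey, e$from, e$to)
  if (anyDuplicated(key)) msg <- c(msg, "duplicate edge")
  if (length(msg)) msg else TRUE
})

#' @export
#' @describeIn Skeleton node names.
#' @param x a Skeleton.
setMethod("nodeNames", "Skeleton", function(x) x@nodes)

#' @export
#' @describeIn Skeleton edge data.frame.
setMethod("edgeTable", "Skeleton", function(x) x@edges)

#' @export
#' @describeIn Skeleton sepset lookup.
#' @param a,b variable names.
setMethod("sepset", "Skeleton", function(x, a, b) sepset(x@sepsets, a, b))

setMethod("show", "Skeleton", function(object) {
  cat(sprintf("Skeleton: %d nodes, %d undirected edges, %d sepsets\n",
              length(object@nodes), nrow(object@edges),
              length(object@sepsets)))
})

## ------------------------------------------------------------ causal PDAG ---

#' CausalPDAG: a partially directed causal network
#'
#' Mixed graph of directed (cause -> effect) and undirected edges — the
#' global causal network model. Each edge carries a provenance tag
#' (\code{tier_oriented}, \code{collider_oriented}, \code{propagated},
#' \code{unoriented}, or \code{external} for ingested networks) and an
#' optional bootstrap stability percentage.
#'
#' Invariants enforced: no self-loops, each unordered pair appears at most
#' once, the directed part is acyclic, and — when tiers are attached — every
#' directed edge between different tiers points forward in time.
#'
#' @slot nodes variable names.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{directed} (logical), \code{provenance}, \code{stability}
#'   (percent, NA when not computed). Undirected edges are stored once with
#'   \code{from} before \code{to} in canonical node order.
#' @slot epoques named integer tier per node (length 0 when unknown).
#' @export
setClass("CausalPDAG",
         representation(nodes = "character", edges = "data.frame",
                        epoques = "integer"))

setValidity("CausalPDAG", function(object) {
  e <- object@edges
  msg <- character()
  need <- c("from", "to", "directed", "provenance", "stability")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicate node names")
  if (!all(c(e$from, e$to) %in% object@nodes))
    msg <- c(msg, "edge endpoint not in node set")
  if (any(e$from == e$to)) msg <- c(msg, "self-loop")
  key <- if (nrow(e)) mapply(.sepsetKey, e$from, e$to) else character()
  if (anyDuplicated(key))
    msg <- c(msg, "a pair appears in more than one edge (2-cycle or duplicate)")
  if (length(object@epoques)) {
    ep <- object@epoques
    if (!all(object@nodes %in% names(ep)))
      msg <- c(msg, "epoques missing for some nodes")
    else {
      d <- e[e$directed, , drop = FALSE]
      bad <- ep[d$from] > ep[d$to]
      if (any(bad))
        msg <- c(msg, sprintf("directed edge against time order: %s",
                              paste(sprintf("%s->%s", d$from[bad],
                                            d$to[bad]), collapse = ", ")))
    }
  }
  d <- e[e$directed, c("from", "to"), drop = FALSE]
  if (nrow(d) && !.isAcyclic(object@nodes, d))
    msg <- c(msg, "directed subgraph contains a cycle")
  if (length(msg)) msg else TRUE
})

#' Construct a CausalPDAG
#'
#' @param nodes character vector of node names (canonical order).
#' @param directed two-column matrix/data.frame of directed edges
#'   (from, to), or NULL.
#' @param undirected two-column matrix/data.frame of undirected edges, or
#'   NULL.
#' @param epoques optional named integer tier per node.
#' @param provenance provenance tag(s) for the directed edges (recycled);
#'   undirected edges are tagged \code{unoriented}.
#' @return a \linkS4class{CausalPDAG}.
#' @examples
#' g <- CausalPDAG(c("A", "B", "T"), directed = rbind(c("A", "T")),
#'                 undirected = rbind(c("A", "B")))
#' edgeTable(g)
#' @export
CausalPDAG <- function(nodes, directed = NULL, undirected = NULL,
                       epoques = NULL, provenance = "external") {
  mk <- function(x) {
    if (is.null(x) || NROW(x) == 0L)
      return(matrix(character(), 0, 2))
    x <- as.matrix(x)
    matrix(as.character(x), nrow(x), 2)
  }
  d <- mk(directed); u <- mk(undirected)
  ord <- match(u[, 1], nodes) > match(u[, 2], nodes)
  if (any(ord)) u[ord, ] <- u[ord, c(2, 1)]
  e <- rbind(
    if (nrow(d)) data.frame(from = d[, 1], to = d[, 2], directed = TRUE,
                            provenance = rep_len(provenance, nrow(d)),
                            stability = NA_real_, stringsAsFactors = FALSE),
    if (nrow(u)) data.frame(from = u[, 1], to = u[, 2], directed = FALSE,
                            provenance = "unoriented",
                            stability = NA_real_, stringsAsFactors = FALSE))
  if (is.null(e)) e <- .emptyEdges()
  new("CausalPDAG", nodes = as.character(nodes),
      edges = .sortEdges(e, nodes),
      epoques = if (is.null(epoques)) integer() else
        stats::setNames(as.integer(epoques), names(epoques)))
}

#' @export
#' @describeIn CausalPDAG node names.
#' @param x a CausalPDAG.
setMethod("nodeNames", "CausalPDAG", function(x) x@nodes)

#' @export
#' @describeIn CausalPDAG full edge table.
setMethod("edgeTable", "CausalPDAG", function(x) x@edges)

#' @export
#' @describeIn CausalPDAG tier assignment (may be empty).
setMethod("epoques", "CausalPDAG", function(x) x@epoques)

#' Directed edges of a CausalPDAG
#' @param x a \linkS4class{CausalPDAG}.
#' @return data.frame of the directed subset of [edgeTable()].
#' @export
directedEdges <- function(x) x@edges[x@edges$directed, , drop = FALSE]

#' Undirected edges of a CausalPDAG
#' @param x a \linkS4class{CausalPDAG}.
#' @return data.frame of the undirected subset of [edgeTable()].
#' @export
undirectedEdges <- function(x) x@edges[!x@edges$directed, , drop = FALSE]

setMethod("show", "CausalPDAG", function(object) {
  e <- object@edges
  nd <- sum(e$directed)
  iso <- sum(!object@nodes %in% c(e$from, e$to))
  cat(sprintf("CausalPDAG: %d nodes, %d edges (%d directed, %d undirected)\n",
              length(object@nodes), nrow(e), nd, nrow(e) - nd))
  if (nrow(e))
    cat(sprintf("  oriented: %.0f%%; disconnected nodes: %d\n",
                100 * nd / nrow(e), iso))
  tab <- table(e$provenance)
  if (length(tab))
    cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab),
                               collapse = " "), "\n")
})

## -------------------------------------------------------- markov boundary ---

#' MarkovBoundary: the local causal network model of the target
#'
#' Under faithfulness the Markov boundary of a target is its direct causes,
#' direct effects, and the direct causes of its direct effects (spouses) —
#' the smallest variable set achieving maximal predictive accuracy for the
#' target. Undirected edges incident to the target denote neighbours of
#' undetermined role; they are reported separately, never silently assigned.
#'
#' @slot target the outcome variable.
#' @slot directCauses,directEffects,spouses,undetermined character vectors.
#' @seealso [markovBoundary()]
#' @export
setClass("MarkovBoundary",
         representation(target = "character", directCauses = "character",
                        directEffects = "character", spouses = "character",
                        undetermined = "character"))

setValidity("MarkovBoundary", function(object) {
  sets <- list(object@directCauses, object@directEffects, object@spouses)
  all_ <- unlist(sets)
  msg <- character()
  if (anyDuplicated(all_)) msg <- c(msg, "member sets must be disjoint")
  if (object@target %in% c(all_, object@undetermined))
    msg <- c(msg, "target cannot be a member of its own boundary")
  if (length(msg)) msg else TRUE
})

#' Members of a MarkovBoundary
#' @param x a \linkS4class{MarkovBoundary}.
#' @return character vector: causes, effects and spouses (no undetermined
#'   neighbours).
#' @export
mbMembers <- function(x) c(x@directCauses, x@directEffects, x@spouses)

setMethod("show", "MarkovBoundary", function(object) {
  cat(sprintf("MarkovBoundary of %s\n", object@target))
  cat(sprintf("  direct causes (%d): %s\n", length(object@directCauses),
              paste(object@directCauses, collapse = ", ")))
  cat(sprintf("  direct effects (%d): %s\n", length(object@directEffects),
              paste(object@directEffects, collapse = ", ")))
  cat(sprintf("  spouses (%d): %s\n", length(object@spouses),
              paste(object@spouses, collapse = ", ")))
  if (length(object@undetermined))
    cat(sprintf("  undetermined neighbours (%d): %s\n",
                length(object@undetermined),
                paste(object@undetermined, collapse = ", ")))
})

## ------------------------------------------------------------------ paths ---

#' PathSet: bounded-length causal pathways into the target
#'
#' @slot target the outcome node every path terminates at.
#' @slot maxLen maximum path length in edges (default 4 in the pipeline).
#' @slot paths list of node sequences (character vectors), each a simple
#'   directed path ending at the target.
#' @seealso [enumeratePaths()]
#' @export
setClass("PathSet",
         representation(target = "character", maxLen = "integer",
                        paths = "list"))

#' @export
#' @describeIn PathSet the list of node sequences.
#' @param x a PathSet.
setMethod("pathList", "PathSet", function(x) x@paths)

#' Number of paths
#' @param x a \linkS4class{PathSet}.
#' @export
setMethod("length", "PathSet", function(x) length(x@paths))

setMethod("show", "PathSet", function(object) {
  cat(sprintf("PathSet: %d path(s) of <= %d step(s) into %s\n",
              length(object@paths), object@maxLen, object@target))
  for (p in utils::head(object@paths, 5))
    cat("  ", paste(p, collapse = " -> "), "\n")
  if (length(object@paths) > 5) cat("  ...\n")
})

#' InfluenceRanking: node-deletion pathway influence
#'
#' Ranks each non-target node by the proportion of enumerated pathways into
#' the target that are eliminated when the node is deleted (equivalently,
#' the proportion of paths containing it). Ties are broken by canonical
#' node order.
#'
#' @slot ranking data.frame with columns \code{node}, \code{count},
#'   \code{proportion}, \code{rank}.
#' @slot nPaths total number of paths the proportions refer to.
#' @slot target the outcome node.
#' @seealso [influenceRanking()]
#' @export
setClass("InfluenceRanking",
         representation(ranking = "data.frame", nPaths = "integer",
                        target = "character"))

#' @export
#' @describeIn InfluenceRanking the ranking data.frame.
#' @param x an InfluenceRanking.
setMethod("rankingTable", "InfluenceRanking", function(x) x@ranking)

setMethod("show", "InfluenceRanking", function(object) {
  cat(sprintf("InfluenceRanking over %d path(s) into %s\n", object@nPaths,
              object@target))
  top <- utils::head(object@ranking[object@ranking$count > 0, , drop = FALSE],
                     10)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %2d. %s  %d/%d paths (%.0f%%)\n", top$rank[i],
                top$node[i], top$count[i], object@nPaths,
                100 * top$proportion[i]))
})

## -------------------------------------------------------------- stability ---

#' StabilityReport: bootstrap edge stability
#'
#' @slot B number of successful bootstrap iterations.
#' @slot seed the seed the resampling started from.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{stability} (percent of bootstrap networks in which the adjacency
#'   was detected) and, in orientation-aware mode, \code{directedPct}.
#' @slot failures number of discarded failed iterations.
#' @seealso [bootstrapStability()]
#' @export
setClass("StabilityReport",
         representation(B = "integer", seed = "numeric",
                        edges = "data.frame", failures = "integer"))

#' @export
#' @describeIn StabilityReport the per-edge stability table.
#' @param x a StabilityReport.
setMethod("stabilityTable", "StabilityReport", function(x) x@edges)

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf("StabilityReport: %d bootstrap iterations (seed %s)\n",
              object@B, format(object@seed)))
  cat(sprintf("  %d edge(s) seen; %d >= 90%% stable\n", nrow(object@edges),
              sum(object@edges$stability >= 90)))
  if (object@failures)
    cat(sprintf("  %d failed iteration(s) discarded\n", object@failures))
})

## -------------------------------------------------------- synthetic truth ---

#' SyntheticSystem: a ground-truth tiered causal system
#'
#' A tiered DAG with linear structural-equation parameters, emulating the
#' design of a longitudinal cohort study: variables assigned to time
#' epoques, trinary SNP-like exogenous nodes in the first tier, ordinal
#' nodes discretised at fixed cutpoints, and a designated outcome in the
#' last tier. Provides the ground truth for recovery benchmarks and the
#' d-separation oracle.
#'
#' @slot schema the generated \linkS4class{StudySchema}.
#' @slot edges data.frame \code{from}, \code{to}, \code{weight}; every edge
#'   respects the tier order.
#' @slot noiseSd named numeric, per-node structural noise SD.
#' @slot cutpoints named list of z-scale cutpoints for ordinal nodes.
#' @slot maf minor-allele frequency of SNP-like nodes.
#' @slot seed generation seed.
#' @seealso [generateSystem()], [sampleData()], [dsepOracle()]
#' @export
setClass("SyntheticSystem",
         representation(schema = "StudySchema", edges = "data.frame",
                        noiseSd = "numeric", cutpoints = "list",
                        maf = "numeric", seed = "numeric"))

setValidity("SyntheticSystem", function(object) {
  msg <- character()
  ep <- epoques(object@schema)
  e <- object@edges
  if (nrow(e)) {
    if (any(ep[e$from] > ep[e$to]))
      msg <- c(msg, "true edge against tier order")
    if (any(e$weight == 0)) msg <- c(msg, "zero edge weight")
    if (!.isAcyclic(variableNames(object@schema), e[, c("from", "to")]))
      msg <- c(msg, "true graph contains a cycle")
  }
  if (length(msg)) msg else TRUE
})

#' @export
#' @describeIn SyntheticSystem canonical variable names.
#' @param x a SyntheticSystem.
setMethod("variableNames", "SyntheticSystem", function(x)
  variableNames(x@schema))

#' @export
#' @describeIn SyntheticSystem the generated schema.
setMethod("schema", "SyntheticSystem", function(x) x@schema)

#' @export
#' @describeIn SyntheticSystem the target variable.
setMethod("targetVariable", "SyntheticSystem", function(x)
  targetVariable(x@schema))

#' @export
#' @describeIn SyntheticSystem tier assignment.
setMethod("epoques", "SyntheticSystem", function(x) epoques(x@schema))

#' @export
#' @describeIn SyntheticSystem the true weighted edge list.
setMethod("trueEdges", "SyntheticSystem", function(x) x@edges)

setMethod("show", "SyntheticSystem", function(object) {
  cat(sprintf(
    "SyntheticSystem: %d variables, %d tiers, %d true edges (seed %s)\n",
    nrow(object@schema@variables), object@schema@nTiers,
    nrow(object@edges), format(object@seed)))
  cat(sprintf("  target: %s\n", targetVariable(object@schema)))
})

## ------------------------------------------------------- recovery metrics ---

#' RecoveryMetrics: how well discovery recovered a known system
#'
#' @slot skeletonPrecision,skeletonRecall adjacency precision/recall against
#'   the true skeleton.
#' @slot orientationAccuracy fraction of correctly directed edges among true
#'   edges the estimate oriented (NA when none oriented).
#' @slot mbJaccard Jaccard similarity of estimated vs true Markov boundary
#'   of the target.
#' @slot flags character notes for degenerate cases (e.g. empty estimate).
#' @seealso [evaluateRecovery()]
#' @export
setClass("RecoveryMetrics",
         representation(skeletonPrecision = "numeric",
                        skeletonRecall = "numeric",
                        orientationAccuracy = "numeric",
                        mbJaccard = "numeric", flags = "character"))

setMethod("show", "RecoveryMetrics", function(object) {
  cat(sprintf(paste0("RecoveryMetrics: precision=%.3f recall=%.3f ",
                     "orientation=%.3f mbJaccard=%.3f\n"),
              object@skeletonPrecision, object@skeletonRecall,
              object@orientationAccuracy, object@mbJaccard))
  if (length(object@flags)) cat("  flags:", paste(object@flags,
                                                  collapse = "; "), "\n")
})

## --------------------------------------------------------- discovery run ----

#' DiscoveryReport: the artefacts of one full pipeline run
#'
#' @slot graph the global causal network model (\linkS4class{CausalPDAG}).
#' @slot boundary the target's \linkS4class{MarkovBoundary}.
#' @slot paths the \linkS4class{PathSet} into the target.
#' @slot ranking the \linkS4class{InfluenceRanking}.
#' @slot stability a \linkS4class{StabilityReport} or NULL.
#' @slot summary list of run statistics (node/edge counts, orientation
#'   percentages per provenance).
#' @slot config list echoing the run parameters.
#' @seealso [runDiscovery()]
#' @export
setClass("DiscoveryReport",
         representation(graph = "CausalPDAG", boundary = "MarkovBoundary",
                        paths = "PathSet", ranking = "InfluenceRanking",
                        stability = "ANY", summary = "list",
                        config = "list"))

setMethod("show", "DiscoveryReport", function(object) {
  s <- object@summary
  cat("DiscoveryReport\n")
  cat(sprintf("  global model: %d nodes, %d edges (%d disconnected nodes)\n",
              s$nNodes, s$nEdges, s$nDisconnected))
  cat(sprintf("  oriented: %d (%.0f%%), unoriented: %d\n", s$nOriented,
              s$pctOriented, s$nEdges - s$nOriented))
  cat(sprintf("  paths (<= %d steps) into %s: %d\n",
              object@paths@maxLen, object@paths@target,
              length(object@paths)))
  cat(sprintf("  Markov boundary size: %d\n",
              length(mbMembers(object@boundary))))
})
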