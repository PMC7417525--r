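#' @title Generics for causalTiers classes
#' @name causalTiers-generics
#' @keywords internal
NULL

#' Variable names in canonical order
#'
#' The canonical order (row order of the variable table) is used for all
#' deterministic tie-breaking throughout the package.
#'
#' @param x a \linkS4class{StudySchema}, \linkS4class{DataMatrix} or
#'   \linkS4class{SyntheticSystem}.
#' @return character vector of variable names.
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' Designated outcome variable
#' @param x an object with a designated target.
#' @return character scalar.
#' @export
setGeneric("targetVariable", function(x) standardGeneric("targetVariable"))

#' Time-epoque (tier) assignment
#' @param x a schema-bearing object.
#' @return named integer vector, one tier per variable.
#' @export
setGeneric("epoques", function(x) standardGeneric("epoques"))

#' Declared numeric types
#' @param x a schema-bearing object.
#' @return named character vector with values in
#'   \code{c("continuous", "ordinal", "categorical")}.
#' @export
setGeneric("dtypes", function(x) standardGeneric("dtypes"))

#' Study schema of an object
#' @param x an object carrying a \linkS4class{StudySchema}.
#' @return a \linkS4class{StudySchema}.
#' @export
setGeneric("schema", function(x) standardGeneric("schema"))

#' Node names of a graph-like object
#' @param x a \linkS4class{CausalPDAG} or \linkS4class{Skeleton}.
#' @return character vector.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' Edge table of a graph-like object
#'
#' @param x a graph-like object.
#' @return a data.frame with one row per edge. For a
#'   \linkS4class{CausalPDAG} the columns are \code{from}, \code{to},
#'   \code{directed}, \code{provenance}, \code{stability}.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Look up the separating set recorded for a pair
#' @param x a \linkS4class{SepsetTable} or \linkS4class{Skeleton}.
#' @param a,b variable names (order irrelevant).
#' @return \code{NULL} if no sepset is recorded, otherwise a list with
#'   elements \code{Z} (character vector) and \code{p} (numeric).
#' @export
setGeneric("sepset", function(x, a, b) standardGeneric("sepset"))

#' Enumerated causal paths
#' @param x a \linkS4class{PathSet}.
#' @return list of character vectors, each ending at the target.
#' @export
setGeneric("pathList", function(x) standardGeneric("pathList"))

#' Influence ranking table
#' @param x an \linkS4class{InfluenceRanking}.
#' @return data.frame with columns \code{node}, \code{count},
#'   \code{proportion}, \code{rank}.
#' @export
setGeneric("rankingTable", function(x) standardGeneric("rankingTable"))

#' Bootstrap edge-stability table
#' @param x a \linkS4class{StabilityReport}.
#' @return data.frame with columns \code{from}, \code{to},
#'   \code{stability} (percent), and optionally \code{directedPct}.
#' @export
setGeneric("stabilityTable", function(x) standardGeneric("stabilityTable"))

#' True edge set of a synthetic system
#' @param x a \linkS4class{SyntheticSystem}.
#' @return data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @export
setGeneric("trueEdges", function(x) standardGeneric("trueEdges"))
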