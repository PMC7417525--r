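#' Run the full causal-discovery pipeline
#'
#' Orchestrates the protocol end to end: skeleton discovery via local
#' parent--children induction, orientation (tiers, colliders, Meek
#' propagation), Markov-boundary extraction for the target, bounded-length
#' pathway enumeration with node-deletion influence ranking, and — when
#' requested — bootstrap edge stability merged into the edge list. All
#' defaults are the protocol's stated analysis parameters: alpha 0.05,
#' max conditioning-set size 3, path length limit 4, 100 bootstrap
#' iterations.
#'
#' @param data a \linkS4class{DataMatrix} (see [loadData()] /
#'   [sampleData()]).
#' @param target outcome variable name; defaults to the schema's target.
#' @param alpha per-test rejection threshold.
#' @param maxK maximum conditioning-set size.
#' @param maxPathLen pathway length limit in edges.
#' @param bootstrapB bootstrap iterations (used when
#'   \code{bootstrap = TRUE}).
#' @param bootstrap run the bootstrap stability safeguard (off by default:
#'   it re-runs discovery \code{bootstrapB} times).
#' @param seed integer seed (bootstrap resampling and any other
#'   randomness).
#' @param undirectedPolicy path traversal across undirected edges,
#'   \code{"skip"} (default) or \code{"either"}.
#' @param andRule skeleton symmetry rule (AND, default).
#' @param minEffectiveN minimum complete rows per test.
#' @param outputDir optional directory; when given, all artifacts are
#'   written there via [writeRunArtifacts()].
#' @param verbose per-stage progress messages.
#' @return a \linkS4class{DiscoveryReport}.
#' @examples
#' sys <- generateSystem(p = 10, nTiers = 3, density = 0.25, seed = 5)
#' d <- sampleData(sys, n = 500, geneticSubsample = 500, seed = 5)
#' runDiscovery(d)
#' @export
runDiscovery <- function(data, target = targetVariable(schema(data)),
                         alpha = 0.05, maxK = 3, maxPathLen = 4,
                         bootstrapB = 100, bootstrap = FALSE, seed = 1,
                         undirectedPolicy = c("skip", "either"),
                         andRule = TRUE, minEffectiveN = 10,
                         outputDir = NULL, verbose = FALSE) {
  undirectedPolicy <- match.arg(undirectedPolicy)
  if (is.na(target)) stop("no target designated: pass target=")
  cfg <- TestConfig(alpha = alpha, maxK = maxK,
                    minEffectiveN = minEffectiveN, andRule = andRule)
  stage <- function(name, expr) {
    if (verbose) message("stage: ", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  skeleton <- stage("skeleton", buildSkeleton(data, cfg, verbose = verbose))
  graph <- stage("orientation",
                 orientAll(skeleton, schema(data), verbose = verbose))
  stab <- NULL
  if (bootstrap) {
    stab <- stage("bootstrap",
                  bootstrapStability(data, cfg, B = bootstrapB,
                                     seed = seed, graph = graph,
                                     verbose = verbose))
    graph <- mergeStability(graph, stab)
  }
  boundary <- stage("markov boundary", markovBoundary(graph, target))
  paths <- stage("paths",
                 enumeratePaths(graph, target, maxLen = maxPathLen,
                                undirectedPolicy = undirectedPolicy))
  if (length(paths) == 0L)
    warning("no causal pathway of <= ", maxPathLen,
            " steps terminates at ", target)
  ranking <- suppressWarnings(
    influenceRanking(paths, nodes = graph@nodes))
  os <- orientationSummary(graph)
  e <- graph@edges
  summary <- list(
    nNodes = length(graph@nodes),
    nEdges = os$nEdges,
    nDisconnected = sum(!graph@nodes %in% c(e$from, e$to)),
    nOriented = os$nOriented,
    pctOriented = os$pctOriented,
    byProvenance = os$byProvenance,
    nPaths = length(paths),
    mbSize = length(mbMembers(boundary)))
  config <- list(target = target, alpha = alpha, maxK = maxK,
                 maxPathLen = maxPathLen, bootstrapB = bootstrapB,
                 bootstrap = bootstrap, seed = seed,
                 undirectedPolicy = undirectedPolicy, andRule = andRule,
                 minEffectiveN = minEffectiveN)
  report <- new("DiscoveryReport", graph = graph, boundary = boundary,
                paths = paths, ranking = ranking, stability = stab,
                summary = summary, config = config)
  if (!is.null(outputDir)) writeRunArtifacts(report, outputDir)
  report
}

#' Analyze an already-discovered network
#'
#' Runs the post-discovery stages only — Markov boundary, pathway
#' enumeration and influence ranking — on a given network, e.g. a
#' published edge list ingested with [readNetwork()]. No raw data are
#' required.
#'
#' @param x a \linkS4class{CausalPDAG}, or a path to an edge-list file.
#' @param target outcome node name.
#' @param maxPathLen pathway length limit (default 4).
#' @param undirectedPolicy see [enumeratePaths()].
#' @param format file format when \code{x} is a path (see
#'   [readNetwork()]).
#' @return list with elements \code{graph}, \code{boundary},
#'   \code{paths}, \code{ranking}.
#' @export
analyzeNetwork <- function(x, target, maxPathLen = 4,
                           undirectedPolicy = c("skip", "either"),
                           format = "tsv") {
  undirectedPolicy <- match.arg(undirectedPolicy)
  graph <- if (is(x, "CausalPDAG")) x else readNetwork(x, format = format)
  if (!target %in% graph@nodes)
    stop("target '", target, "' not found in the network")
  boundary <- markovBoundary(graph, target)
  paths <- enumeratePaths(graph, target, maxLen = maxPathLen,
                          undirectedPolicy = undirectedPolicy)
  ranking <- suppressWarnings(influenceRanking(paths,
                                               nodes = graph@nodes))
  list(graph = graph, boundary = boundary, paths = paths,
       ranking = ranking)
}

#' Write all artifacts of a discovery run
#'
#' Edge-list TSV (with stability when computed), SIF and GraphML exports,
#' orientation-summary and Markov-boundary JSON, flat path list, ranking
#' TSV, and a machine-readable JSON run report echoing the configuration.
#' Two runs with identical config and seed produce byte-identical files.
#'
#' @param report a \linkS4class{DiscoveryReport}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeRunArtifacts <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  writeNetwork(report@graph, fp("edges.tsv"), "tsv")
  writeNetwork(report@graph, fp("network.sif"), "sif")
  writeNetwork(report@graph, fp("network.graphml"), "graphml")
  mbToJson(report@boundary, fp("markov_boundary.json"))
  writePathReport(report@paths, report@ranking, fp("paths.txt"),
                  fp("ranking.tsv"))
  if (!is.null(report@stability))
    utils::write.table(stabilityTable(report@stability),
                       fp("stability.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  rep_ <- list(config = report@config, summary = report@summary)
  writeLines(jsonlite::toJSON(rep_, pretty = TRUE, auto_unbox = TRUE,
                              na = "null"),
             fp("run_report.json"))
  invisible(dir)
}
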