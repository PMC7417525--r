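# Synthetic tiered-cohort generator.
#
# Emulates the design of a prospective longitudinal study: ~150 mixed-type
# variables over 7 time epoques, a couple of hundred subjects, trinary
# SNP-like exogenous variables in the first (constitutional/genetic) tier
# with block missingness for the subjects lacking genetic data, a sparse
# tier-respecting DAG, and linear structural equations with
# discretisation for ordinal nodes. Canonical variable order is sorted by
# tier, so it is simultaneously a topological order of the true DAG.

#' Construct a SyntheticSystem explicitly
#'
#' Low-level constructor for a ground-truth system with known structure —
#' chains, colliders and other hand-built fixtures. See
#' [generateSystem()] for the randomized study-scale generator.
#'
#' @param schema a \linkS4class{StudySchema} (canonical order must be a
#'   topological order of the edges).
#' @param edges data.frame or 2/3-column matrix: from, to and optional
#'   weight (default 1).
#' @param noiseSd scalar or named per-node structural noise SD.
#' @param maf minor-allele frequency for categorical (SNP-like) nodes.
#' @param cutpoints named list of z-scale cutpoints for ordinal nodes;
#'   defaults to standard-normal terciles for every ordinal node.
#' @param seed seed recorded with the system.
#' @return a \linkS4class{SyntheticSystem}.
#' @examples
#' sch <- StudySchema(c("A", "B", "C"), rep("continuous", 3),
#'                    c(1L, 1L, 2L), target = "C")
#' chain <- syntheticSystem(sch, rbind(c("A", "B"), c("B", "C")))
#' dsepOracle("A", "C", "B", chain)
#' @export
syntheticSystem <- function(schema, edges, noiseSd = 1, maf = 0.3,
                            cutpoints = NULL, seed = NA_real_) {
  nms <- variableNames(schema)
  if (NROW(edges) == 0L) {
    e <- data.frame(from = character(), to = character(),
                    weight = numeric(), stringsAsFactors = FALSE)
  } else if (is.matrix(edges)) {
    e <- data.frame(from = as.character(edges[, 1]),
                    to = as.character(edges[, 2]),
                    weight = if (ncol(edges) >= 3)
                      as.numeric(edges[, 3]) else 1,
                    stringsAsFactors = FALSE)
  } else {
    e <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (is.null(e$weight)) e$weight <- 1
  }
  if (length(noiseSd) == 1L && is.null(names(noiseSd)))
    noiseSd <- stats::setNames(rep(noiseSd, length(nms)), nms)
  if (is.null(cutpoints)) {
    cutpoints <- lapply(which(dtypes(schema) == "ordinal"),
                        function(i) stats::qnorm(c(1 / 3, 2 / 3)))
    names(cutpoints) <- nms[dtypes(schema) == "ordinal"]
  }
  sys <- new("SyntheticSystem", schema = schema, edges = e,
             noiseSd = noiseSd, cutpoints = cutpoints, maf = maf,
             seed = seed)
  validObject(sys)
  sys
}

#' Generate a random ground-truth tiered causal system
#'
#' Samples a sparse DAG whose every edge runs forward in tier (or within
#' a tier, forward in canonical order), assigns linear edge weights of
#' magnitude at least \code{weightRange[1]} with random sign, places
#' trinary SNP-like exogenous variables (no parents) in tier 1, and
#' designates a continuous outcome in the last tier with at least one
#' parent. Defaults emulate the police-cohort study design: 148
#' variables over 7 epoques with edge density matching a ~350-edge
#' network at that size.
#'
#' @param p number of variables (default 148).
#' @param nTiers number of time epoques (default 7).
#' @param density probability of each tier-admissible edge (default 0.03,
#'   giving around 2.2 edges per node at p = 148).
#' @param targetTier tier of the outcome (default the last).
#' @param snpFraction fraction of variables that are SNP-like trinary
#'   exogenous nodes in tier 1 (default 0.1).
#' @param ordinalFraction fraction of the remaining variables that are
#'   ordinal rather than continuous (default 0.5).
#' @param maf minor-allele frequency of SNP nodes (default 0.3).
#' @param noiseSd structural noise SD for every node (default 1).
#' @param weightRange magnitude range of edge weights (default 0.5--1.5).
#' @param seed integer seed.
#' @param maxRetries times to resample the edge set when the target ends
#'   up parentless; 0 disables the retry (an isolated target is then
#'   accepted, e.g. at density 0).
#' @return a \linkS4class{SyntheticSystem}.
#' @export
generateSystem <- function(p = 148, nTiers = 7, density = 0.03,
                           targetTier = nTiers, snpFraction = 0.1,
                           ordinalFraction = 0.5, maf = 0.3, noiseSd = 1,
                           weightRange = c(0.5, 1.5), seed = 1,
                           maxRetries = 20) {
  stopifnot(p >= 2, density >= 0, density < 1, nTiers >= 1,
            targetTier >= 1, targetTier <= nTiers)
  set.seed(seed)
  nSnp <- min(max(if (snpFraction > 0) 1L else 0L,
                  round(snpFraction * p)), p - 1L)
  # tier assignment: every tier non-empty, tier 1 large enough for SNPs,
  # the target tier non-empty; canonical order sorted by tier
  tier <- c(seq_len(nTiers),
            sample.int(nTiers, max(0L, p - nTiers), replace = TRUE))
  tier <- sort(tier)
  while (sum(tier == 1L) < nSnp + 1L) {
    shift <- which(tier > 1L)[1]
    tier[shift] <- 1L
    tier <- sort(tier)
  }
  dtype <- character(p)
  dtype[seq_len(nSnp)] <- "categorical"  # SNPs first in tier 1
  rest <- seq.int(nSnp + 1L, p)
  dtype[rest] <- ifelse(stats::runif(length(rest)) < ordinalFraction,
                        "ordinal", "continuous")
  # the target: last variable of the target tier, continuous
  tpos <- max(which(tier == targetTier))
  dtype[tpos] <- "continuous"
  name <- character(p)
  name[dtype == "categorical"] <- sprintf("SNP%02d",
                                          seq_len(sum(dtype ==
                                                      "categorical")))
  other <- which(dtype != "categorical")
  name[other] <- sprintf("V%03d", seq_along(other))
  name[tpos] <- "TARGET"
  schema <- StudySchema(name, dtype, tier, target = "TARGET",
                        nTiers = nTiers)
  # admissible ordered pairs: forward in tier, or within tier forward in
  # canonical order; no parents for SNP (exogenous) nodes
  adm <- which(outer(tier, tier, "<") |
                 (outer(tier, tier, "==") &
                    outer(seq_len(p), seq_len(p), "<")),
               arr.ind = TRUE)
  adm <- adm[dtype[adm[, 2]] != "categorical", , drop = FALSE]
  tries <- 0L
  repeat {
    pick <- stats::runif(nrow(adm)) < density
    if (any(adm[pick, 2] == tpos) || maxRetries == 0L) break
    tries <- tries + 1L
    if (tries > maxRetries)
      stop("target remained parentless after ", maxRetries,
           " retries; increase density")
  }
  sel <- adm[pick, , drop = FALSE]
  w <- stats::runif(nrow(sel), weightRange[1], weightRange[2]) *
    sample(c(-1, 1), nrow(sel), replace = TRUE)
  edges <- data.frame(from = name[sel[, 1]], to = name[sel[, 2]],
                      weight = w, stringsAsFactors = FALSE)
  syntheticSystem(schema, edges, noiseSd = noiseSd, maf = maf,
                  seed = seed)
}

#' Sample a cohort from a synthetic system
#'
#' Ancestral sampling of the linear structural equations in canonical
#' (topological) order. SNP-like nodes are drawn Binomial(2, maf) and
#' standardised before entering downstream equations; ordinal nodes are
#' discretised at their stored z-scale cutpoints, and the standardised
#' codes propagate downstream (the recorded measurement is the variable).
#' Rows beyond the genetic sub-sample get all SNP columns set missing,
#' reproducing the block-missingness of a cohort whose genetic assays
#' started late.
#'
#' @param system a \linkS4class{SyntheticSystem}.
#' @param n number of subjects (default 207, the study scale).
#' @param geneticSubsample number of rows with observed genetic columns
#'   (default \code{min(157, n)}; pass \code{n} for complete data).
#' @param seed integer seed.
#' @return a \linkS4class{DataMatrix}.
#' @export
sampleData <- function(system, n = 207, geneticSubsample = min(157, n),
                       seed = 1) {
  stopifnot(n >= 1, geneticSubsample >= 0, geneticSubsample <= n)
  sch <- system@schema
  nms <- variableNames(sch)
  dty <- dtypes(sch)
  p <- length(nms)
  e <- system@edges
  set.seed(seed)
  obs <- matrix(NA_real_, n, p, dimnames = list(NULL, nms))
  std <- matrix(0, n, p)
  for (j in seq_len(p)) {
    v <- nms[j]
    if (dty[j] == "categorical") {
      x <- stats::rbinom(n, 2L, system@maf)
      obs[, j] <- x
      std[, j] <- (x - 2 * system@maf) /
        sqrt(2 * system@maf * (1 - system@maf))
      next
    }
    inc <- e[e$to == v, , drop = FALSE]
    pa <- match(inc$from, nms)
    sdj <- system@noiseSd[[v]]
    latent <- stats::rnorm(n, 0, sdj)
    if (length(pa))
      latent <- latent + as.vector(std[, pa, drop = FALSE] %*% inc$weight)
    totVar <- sum(inc$weight^2) + sdj^2
    z <- latent / sqrt(totVar)
    if (dty[j] == "continuous") {
      obs[, j] <- latent
      std[, j] <- z
    } else {
      cut <- system@cutpoints[[v]]
      if (is.null(cut)) cut <- stats::qnorm(c(1 / 3, 2 / 3))
      code <- findInterval(z, cut)
      obs[, j] <- code
      probs <- diff(c(0, stats::pnorm(cut), 1))
      lv <- seq_along(probs) - 1
      mu <- sum(lv * probs)
      s2 <- sum(lv^2 * probs) - mu^2
      std[, j] <- (code - mu) / sqrt(s2)
    }
  }
  if (geneticSubsample < n) {
    genCols <- which(dty == "categorical")
    if (length(genCols)) {
      missRows <- sample.int(n, n - geneticSubsample)
      obs[missRows, genCols] <- NA_real_
    }
  }
  suppressWarnings(DataMatrix(obs, sch))
}

#' The true DAG of a synthetic system as a CausalPDAG
#'
#' @param system a \linkS4class{SyntheticSystem}.
#' @return a fully directed \linkS4class{CausalPDAG} with tiers attached.
#' @export
trueGraph <- function(system) {
  CausalPDAG(variableNames(system),
             directed = as.matrix(system@edges[, c("from", "to")]),
             epoques = epoques(system), provenance = "external")
}

#' Score a discovered network against the generating system
#'
#' Adjacency precision and recall against the true skeleton, orientation
#' accuracy (fraction of correctly directed edges among true edges the
#' estimate oriented), and the Jaccard similarity between the estimated
#' and true Markov boundary of the target.
#'
#' @param estimated a \linkS4class{CausalPDAG} on the system's node set.
#' @param system the generating \linkS4class{SyntheticSystem}.
#' @param target target name (default the system's designated target).
#' @return a \linkS4class{RecoveryMetrics}.
#' @export
evaluateRecovery <- function(estimated, system,
                             target = targetVariable(system)) {
  nodes <- variableNames(system)
  if (!setequal(estimated@nodes, nodes))
    stop("node sets of estimate and system differ")
  flags <- character()
  te <- system@edges
  trueKeys <- if (nrow(te)) mapply(.sepsetKey, te$from, te$to) else
    character()
  ee <- estimated@edges
  estKeys <- if (nrow(ee)) mapply(.sepsetKey, ee$from, ee$to) else
    character()
  tp <- length(intersect(trueKeys, estKeys))
  precision <- if (length(estKeys)) tp / length(estKeys) else {
    flags <- c(flags, "empty estimate: precision undefined, reported 0")
    0
  }
  recall <- if (length(trueKeys)) tp / length(trueKeys) else {
    flags <- c(flags, "empty truth: recall undefined, reported 1")
    1
  }
  # orientation accuracy over true edges oriented by the estimate
  de <- ee[ee$directed, , drop = FALSE]
  dirKey <- if (nrow(de)) mapply(.sepsetKey, de$from, de$to) else
    character()
  hit <- match(trueKeys, dirKey)
  nOriented <- sum(!is.na(hit))
  orientationAccuracy <- if (nOriented) {
    correct <- de$from[hit[!is.na(hit)]] ==
      te$from[!is.na(hit)] & de$to[hit[!is.na(hit)]] == te$to[!is.na(hit)]
    mean(correct)
  } else {
    flags <- c(flags, "no true edge oriented: orientation accuracy NA")
    NA_real_
  }
  estMb <- mbMembers(markovBoundary(estimated, target))
  trueMb <- mbMembers(markovBoundary(trueGraph(system), target))
  un <- union(estMb, trueMb)
  mbJaccard <- if (length(un)) length(intersect(estMb, trueMb)) /
    length(un) else 1
  new("RecoveryMetrics", skeletonPrecision = precision,
      skeletonRecall = recall,
      orientationAccuracy = orientationAccuracy, mbJaccard = mbJaccard,
      flags = flags)
}
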