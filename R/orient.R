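# Edge orientation: temporal tiers, collider (Y-structure) detection from
# sepsets, and Meek propagation rules R1-R4.
#
# Tier orientations are immutable: time order cannot be overruled by
# statistics, so collider and propagation steps never reverse a
# tier-oriented edge. When two Y-structures demand opposite directions for
# the same edge, the edge is left undirected and the conflict logged.
# Residual undirected edges are honoured as the Markov-equivalence limit
# of observational data; nothing is oriented arbitrarily.

# TRUE iff `to` is reachable from `from` in the directed matrix.
.reaches <- function(dir, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(dir))
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- which(dir[v, ] & !seen)
    if (to %in% nb) return(TRUE)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  FALSE
}

#' Orient skeleton edges by time epoque
#'
#' Every edge joining variables of different tiers is directed forward in
#' time (tagged \code{tier_oriented}); same-tier edges remain undirected.
#'
#' @param skeleton a \linkS4class{Skeleton}.
#' @param schema a \linkS4class{StudySchema} assigning a tier to every
#'   node (a node without a tier is a configuration error).
#' @return a \linkS4class{CausalPDAG} with tiers attached.
#' @export
orientByTiers <- function(skeleton, schema) {
  ep <- epoques(schema)
  missing_ <- setdiff(skeleton@nodes, names(ep))
  if (length(missing_))
    stop("no epoque for node(s): ", paste(missing_, collapse = ", "))
  e <- skeleton@edges
  fwd <- ep[e$from] < ep[e$to]
  bwd <- ep[e$from] > ep[e$to]
  directed <- rbind(cbind(e$from[fwd], e$to[fwd]),
                    cbind(e$to[bwd], e$from[bwd]))
  undirected <- cbind(e$from[!fwd & !bwd], e$to[!fwd & !bwd])
  CausalPDAG(skeleton@nodes, directed = directed, undirected = undirected,
             epoques = ep[skeleton@nodes], provenance = "tier_oriented")
}

#' Orient colliders (Y-structures) from sepsets
#'
#' For every unshielded triple a--c--b (a, b non-adjacent) whose recorded
#' sepset does not contain c, both arms are oriented into c
#' (\code{collider_oriented}). Tier-oriented arms are never overridden:
#' if time order already directs an arm out of c, the collider claim is
#' logged as a conflict and skipped. If two triples demand opposite
#' directions for one edge, the edge is left undirected and the conflict
#' logged. Orientations that would close a directed cycle are refused.
#' Triples are visited in canonical order, so the result is deterministic.
#'
#' @param pdag a \linkS4class{CausalPDAG} (typically from
#'   [orientByTiers()]).
#' @param sepsets the \linkS4class{SepsetTable} from skeleton discovery.
#' @param verbose log conflicts via \code{message()}.
#' @return a \linkS4class{CausalPDAG}.
#' @export
orientColliders <- function(pdag, sepsets, verbose = FALSE) {
  nodes <- pdag@nodes
  p <- length(nodes)
  m <- .pdagMatrices(pdag)
  dir <- m$dir; und <- m$und
  prov <- matrix(NA_character_, p, p)
  e <- pdag@edges
  d <- e$directed
  prov[cbind(match(e$from[d], nodes), match(e$to[d], nodes))] <-
    e$provenance[d]
  conflicted <- matrix(FALSE, p, p)
  note <- function(...) if (verbose) message(sprintf(...))

  adj <- function(i, j) dir[i, j] || dir[j, i] || und[i, j]
  for (cc in seq_len(p)) {
    nb <- which(und[cc, ] | dir[, cc] | dir[cc, ])
    if (length(nb) < 2L) next
    for (ai in seq_len(length(nb) - 1L)) {
      for (bi in seq((ai + 1L), length(nb))) {
        a <- nb[ai]; b <- nb[bi]
        if (adj(a, b)) next
        ss <- sepset(sepsets, nodes[a], nodes[b])
        if (is.null(ss)) {
          note("no sepset recorded for %s,%s; triple at %s skipped",
               nodes[a], nodes[b], nodes[cc])
          next
        }
        if (nodes[cc] %in% ss$Z) next  # not a collider
        for (n in c(a, b)) {
          if (conflicted[n, cc]) next
          if (dir[n, cc]) next  # already into the collider
          if (dir[cc, n]) {
            if (identical(prov[cc, n], "tier_oriented")) {
              note("collider at %s conflicts with time order on %s-%s",
                   nodes[cc], nodes[cc], nodes[n])
            } else {
              # opposite collider claim: revert and freeze
              dir[cc, n] <- FALSE
              und[cc, n] <- und[n, cc] <- TRUE
              prov[cc, n] <- NA_character_
              conflicted[n, cc] <- conflicted[cc, n] <- TRUE
              note("conflicting colliders on %s-%s; edge left undirected",
                   nodes[cc], nodes[n])
            }
            next
          }
          if (und[n, cc]) {
            ep <- pdag@epoques
            if (length(ep) && ep[nodes[n]] > ep[nodes[cc]]) {
              note("collider arm %s->%s points against time order; refused",
                   nodes[n], nodes[cc])
              next
            }
            if (.reaches(dir, cc, n)) {
              note("collider arm %s->%s would close a cycle; refused",
                   nodes[n], nodes[cc])
              next
            }
            dir[n, cc] <- TRUE
            und[n, cc] <- und[cc, n] <- FALSE
            prov[n, cc] <- "collider_oriented"
          }
        }
      }
    }
  }
  .pdagFromMatrices(nodes, dir, und, prov, pdag@epoques)
}

#' Propagate orientations with Meek rules R1-R4
#'
#' Applies the four sound propagation rules to a fixed point, tagging new
#' orientations \code{propagated}. The rules never reverse an existing
#' directed edge, never knowingly create a directed cycle, and create no
#' new unshielded collider, so the result stays within the Markov
#' equivalence class delimited by the colliders and background knowledge.
#' Propagation is idempotent.
#'
#' @param pdag a \linkS4class{CausalPDAG}.
#' @return a \linkS4class{CausalPDAG}.
#' @export
propagateOrientations <- function(pdag) {
  nodes <- pdag@nodes
  p <- length(nodes)
  m <- .pdagMatrices(pdag)
  dir <- m$dir; und <- m$und
  prov <- matrix(NA_character_, p, p)
  e <- pdag@edges
  d <- e$directed
  prov[cbind(match(e$from[d], nodes), match(e$to[d], nodes))] <-
    e$provenance[d]
  adj <- function(i, j) dir[i, j] || dir[j, i] || und[i, j]
  ep <- pdag@epoques
  orient <- function(i, j) {
    if (length(ep) && ep[nodes[i]] > ep[nodes[j]]) return(FALSE)  # tiers
    if (.reaches(dir, j, i)) return(FALSE)  # cycle guard
    dir[i, j] <<- TRUE
    und[i, j] <<- und[j, i] <<- FALSE
    prov[i, j] <<- "propagated"
    TRUE
  }
  repeat {
    changed <- FALSE
    ue <- which(und & upper.tri(und), arr.ind = TRUE)
    if (nrow(ue)) {
      ue <- ue[order(ue[, 1], ue[, 2]), , drop = FALSE]
    }
    for (r in seq_len(nrow(ue))) {
      for (pair in list(c(ue[r, 1], ue[r, 2]), c(ue[r, 2], ue[r, 1]))) {
        a <- pair[1]; b <- pair[2]   # consider orienting a -> b
        if (!und[a, b]) next
        fire <- FALSE
        # R1: c -> a, a - b, c,b non-adjacent  =>  a -> b
        for (cc in which(dir[, a])) {
          if (!adj(cc, b)) { fire <- TRUE; break }
        }
        # R2: a -> c -> b with a - b  =>  a -> b
        if (!fire && any(dir[a, ] & dir[, b])) fire <- TRUE
        # R3: a - c -> b, a - d -> b, c,d non-adjacent  =>  a -> b
        if (!fire) {
          cand <- which(und[a, ] & dir[, b])
          if (length(cand) >= 2L) {
            for (ci in seq_len(length(cand) - 1L)) {
              for (di in seq((ci + 1L), length(cand))) {
                if (!adj(cand[ci], cand[di])) { fire <- TRUE; break }
              }
              if (fire) break
            }
          }
        }
        # R4: c -> d -> b, a adjacent to both c and d, c,b non-adjacent
        if (!fire) {
          for (dd in which(dir[, b])) {
            if (!adj(a, dd)) next
            cs <- which(dir[, dd])
            for (cc in cs) {
              if (cc != a && cc != b && adj(a, cc) && !adj(cc, b)) {
                fire <- TRUE; break
              }
            }
            if (fire) break
          }
        }
        if (fire && orient(a, b)) { changed <- TRUE; break }
      }
    }
    if (!changed) break
  }
  .pdagFromMatrices(nodes, dir, und, prov, pdag@epoques)
}

#' Orient a skeleton into the global causal network model
#'
#' Composition of the three orientation stages: time-epoque orientation,
#' collider orientation from sepsets, and Meek propagation. The directed
#' part is guaranteed acyclic after every stage. Use
#' [orientationSummary()] on the result for the per-provenance counts and
#' percentage oriented.
#'
#' @param skeleton a \linkS4class{Skeleton}.
#' @param schema optional \linkS4class{StudySchema}; when \code{NULL} the
#'   tier stage is skipped (pure PC orientation).
#' @param sepsets a \linkS4class{SepsetTable}; defaults to the ones
#'   recorded in the skeleton.
#' @param verbose log collider conflicts.
#' @return a \linkS4class{CausalPDAG}.
#' @examples
#' sys <- generateSystem(p = 8, nTiers = 3, density = 0.3, seed = 3)
#' sk <- buildSkeleton(sys)
#' g <- orientAll(sk, schema(sys))
#' orientationSummary(g)
#' @export
orientAll <- function(skeleton, schema = NULL, sepsets = NULL,
                      verbose = FALSE) {
  if (is.null(sepsets)) sepsets <- skeleton@sepsets
  g <- if (is.null(schema)) {
    CausalPDAG(skeleton@nodes,
               undirected = as.matrix(skeleton@edges[, c("from", "to")]))
  } else {
    orientByTiers(skeleton, schema)
  }
  g <- orientColliders(g, sepsets, verbose = verbose)
  propagateOrientations(g)
}

#' Orientation summary of a causal network
#'
#' @param graph a \linkS4class{CausalPDAG}.
#' @return list with edge counts per provenance tag, the total number of
#'   edges, the number oriented and the percentage oriented — the
#'   reporting surface of a discovery run.
#' @export
orientationSummary <- function(graph) {
  e <- graph@edges
  tab <- table(factor(e$provenance,
                      levels = union(.PROVENANCE, unique(e$provenance))))
  nd <- sum(e$directed)
  list(nEdges = nrow(e), nOriented = nd,
       pctOriented = if (nrow(e)) 100 * nd / nrow(e) else NA_real_,
       byProvenance = as.list(tab))
}
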