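#' Permute edge weights over a fixed topology
#'
#' The weighted null model: the edge set is kept exactly as it is and the
#' multiset of weights is reassigned to edges by a uniformly random
#' permutation.  Any hourglass signal that survives only reflects the
#' topology; the drop in H-score relative to the observed network
#' therefore measures the contribution of the weight placement.
#' Deterministic given `seed`; the caller's RNG state is untouched.
#'
#' @param net a [RoleNetwork-class] with at least one edge
#' @param seed integer seed
#' @return a [RoleNetwork-class] with identical edges and permuted weights
#' @export
permuteEdgeWeights <- function(net, seed) {
  stopifnot(is(net, "RoleNetwork"))
  m <- nrow(net@edges)
  if (m < 1) stop("network has no edges")
  perm <- withSeed(seed, sample.int(m))
  edges <- net@edges
  edges$weight <- edges$weight[perm]
  RoleNetwork(edges, net@roles, name = net@name)
}

#' Precedence order of nodes for the edge-shuffling null
#'
#' Operationalizes the "partial ordering" preserved by the unweighted
#' shuffle: nodes are ranked by the topological level of their strongly
#' connected component in the condensation of the (feedback-removed)
#' network — the level is the longest condensation-path distance from any
#' root component, so all nodes of one component share a level — with ties
#' broken by role (source < intermediate < target) and then by node id.
#' This is one consistent reading of a constraint the shuffle inherits
#' from earlier unweighted work; it is switchable off in [shuffleEdges()].
#'
#' @param net a [RoleNetwork-class]
#' @return character vector of node ids, earliest first
#' @export
precedenceOrder <- function(net) {
  stopifnot(is(net, "RoleNetwork"))
  nodes <- names(net@roles)
  level <- setNames(rep(0L, length(nodes)), nodes)
  if (nrow(net@edges) > 0) {
    g <- asIgraph(net)
    comp <- igraph::components(g, mode = "strong")
    memb <- comp$membership  # named by node
    ce <- unique(data.frame(from = memb[net@edges$tail],
                            to = memb[net@edges$head]))
    ce <- ce[ce$from != ce$to, , drop = FALSE]
    compLevel <- rep(0L, comp$no)
    if (nrow(ce) > 0) {
      cg <- igraph::graph_from_data_frame(
        data.frame(from = as.character(ce$from), to = as.character(ce$to)),
        directed = TRUE,
        vertices = data.frame(name = as.character(seq_len(comp$no))))
      for (v in as.integer(names(igraph::topo_sort(cg, mode = "out")))) {
        preds <- ce$from[ce$to == v]
        if (length(preds) > 0)
          compLevel[v] <- 1L + max(compLevel[preds])
      }
    }
    level[nodes] <- compLevel[memb[nodes]]
  }
  roleRank <- c(source = 0L, intermediate = 1L, target = 2L)[net@roles[nodes]]
  nodes[lexOrder(level[nodes], roleRank, nodes)]
}

#' Shuffle edges preserving in-degrees and node precedence
#'
#' The unweighted null model: every edge keeps its head (so the in-degree
#' of every node, and the node and edge counts, are preserved) and is
#' assigned a new tail drawn uniformly from the nodes strictly earlier
#' than the head in the [precedenceOrder()], so no edge ever points from a
#' later to an earlier node.  Draws that would create a self-loop or a
#' duplicate edge are rejected with bounded retries; if no admissible
#' tail remains the original tail is kept (logged via `message`).  Edge
#' weights travel with their heads.  Deterministic given `seed`.
#'
#' @param net a [RoleNetwork-class], feedback edges already removed
#' @param seed integer seed
#' @param orderConstraint if FALSE, tails are drawn from all nodes other
#'   than the head (no precedence constraint)
#' @return a shuffled [RoleNetwork-class]
#' @export
shuffleEdges <- function(net, seed, orderConstraint = TRUE) {
  stopifnot(is(net, "RoleNetwork"))
  m <- nrow(net@edges)
  if (m < 1) stop("network has no edges")
  prec <- if (orderConstraint) precedenceOrder(net) else lexSort(names(net@roles))
  pos <- setNames(seq_along(prec), prec)

  edges <- net@edges
  withSeed(seed, {
    used <- new.env(parent = emptyenv())
    newTail <- character(m)
    fallbacks <- 0L
    for (i in seq_len(m)) {
      h <- edges$head[i]
      cand <- if (orderConstraint) prec[seq_len(pos[[h]] - 1L)]
              else setdiff(prec, h)
      tail_i <- NA_character_
      if (length(cand) > 0) {
        for (try in seq_len(100L)) {
          cnd <- cand[[sample.int(length(cand), 1L)]]
          if (is.null(used[[edgeKey(cnd, h)]])) { tail_i <- cnd; break }
        }
        if (is.na(tail_i)) {
          free <- cand[vapply(cand, function(cnd)
            is.null(used[[edgeKey(cnd, h)]]), logical(1))]
          if (length(free) > 0) tail_i <- free[[sample.int(length(free), 1L)]]
        }
      }
      if (is.na(tail_i)) {  # no admissible tail: keep the original
        tail_i <- edges$tail[i]
        fallbacks <- fallbacks + 1L
      }
      used[[edgeKey(tail_i, h)]] <- TRUE
      newTail[i] <- tail_i
    }
    if (fallbacks > 0)
      message(sprintf("shuffleEdges: kept the original tail for %d edge(s)",
                      fallbacks))
    edges$tail <- newTail
  })
  ## a kept original tail can collide with a resampled edge; aggregate then
  out <- data.frame(tail = edges$tail, head = edges$head,
                    weight = edges$weight, stringsAsFactors = FALSE)
  key <- edgeKey(out$tail, out$head)
  if (anyDuplicated(key)) {
    agg <- rowsum(out$weight, key)
    first <- !duplicated(key)
    out <- data.frame(tail = out$tail[first], head = out$head[first],
                      weight = as.numeric(agg[key[first], 1]),
                      stringsAsFactors = FALSE)
    message("shuffleEdges: aggregated colliding fallback edge(s)")
  }
  RoleNetwork(out, net@roles, name = net@name)
}

#' Null distribution of the H-score
#'
#' Compares the observed H-score against randomized replicates:
#' `"weight_permutation"` (the weighted null; topology fixed, weights
#' permuted, path enumeration done once and only path weights recomputed
#' per replicate) or `"edge_shuffle"` (the unweighted null; edges rewired
#' under [shuffleEdges()] and paths re-enumerated per replicate).  The
#' empirical p-value uses the add-one estimator
#' `(1 + #\{h_null >= h_emp\}) / (nReps + 1)`.  Replicate seeds are spawned
#' deterministically from the master seed (one `sample.int(2^31 - 1)` draw
#' per replicate under the master seed), so results are reproducible.
#'
#' @param net a [RoleNetwork-class] with feedback edges removed
#' @param method `"weight_permutation"` or `"edge_shuffle"`
#' @param nReps number of replicates (the headline analyses use 500)
#' @param tau coverage threshold, default 0.9
#' @param maxHops path length bound, default 4
#' @param scheme path weighting scheme, default `"product"` (MET)
#' @param seed master seed
#' @param flatCore `"greedy"` or `"exact"`
#' @return a [NullResult-class]
#' @export
#' @examples
#' net <- layeredHourglass(nSource = 3, nWaist = 1, nTarget = 3,
#'                         extraIntermediates = 2, pBypass = 0.5,
#'                         waistWeightBoost = 10, seed = 7)
#' nullHDistribution(net, "weight_permutation", nReps = 19, seed = 1)
nullHDistribution <- function(net,
                              method = c("weight_permutation", "edge_shuffle"),
                              nReps = 500L, tau = 0.9, maxHops = 4L,
                              scheme = c("product", "unit", "min", "invsum"),
                              seed = 1L, flatCore = c("greedy", "exact")) {
  stopifnot(is(net, "RoleNetwork"))
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  flatCore <- match.arg(flatCore)
  nReps <- as.integer(nReps)
  if (is.na(nReps) || nReps < 1) stop("'nReps' must be >= 1")
  if (method == "edge_shuffle" && scheme != "unit")
    warning("edge_shuffle is the null for the unweighted analysis; ",
            "consider scheme = 'unit'")

  topo <- enumerateStPaths(net, maxHops = maxHops)
  hEmp <- hScore(assignPathWeights(topo, net, scheme), tau,
                 flatCore = flatCore)@h
  repSeeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, nReps))
  hNull <- vapply(seq_len(nReps), function(i) {
    if (method == "weight_permutation") {
      pnet <- permuteEdgeWeights(net, repSeeds[i])
      hScore(assignPathWeights(topo, pnet, scheme), tau, flatCore = flatCore)@h
    } else {
      snet <- suppressMessages(shuffleEdges(net, repSeeds[i]))
      ps <- suppressWarnings(enumerateStPaths(snet, maxHops = maxHops))
      if (length(ps@paths) == 0) 0  # a pathless replicate has no hourglass
      else hScore(assignPathWeights(ps, snet, scheme), tau,
                  flatCore = flatCore)@h
    }
  }, numeric(1))
  p <- (1 + sum(hNull >= hEmp)) / (nReps + 1)
  new("NullResult", method = method, nReps = nReps, tau = tau,
      scheme = scheme, hEmpirical = hEmp, hNull = hNull, pValue = p,
      seed = as.integer(seed))
}
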