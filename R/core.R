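## Centrality over an arbitrary subset of paths (internal work-horse).
.centralityOver <- function(pathset, alive) {
  out <- setNames(numeric(length(pathset@nodes)), pathset@nodes)
  if (any(alive)) {
    nn <- unlist(pathset@paths[alive], use.names = FALSE)
    ww <- rep.int(pathset@weights[alive], lengths(pathset@paths[alive]))
    agg <- rowsum(ww, nn)
    out[rownames(agg)] <- agg[, 1]
  }
  out
}

#' Path centrality of every node
#'
#' The (weighted) path centrality of a node v is the summed weight of the
#' source-target paths that pass through v — under the unit scheme this is
#' the classical stress-like count of paths through v.  Every node of the
#' parent network is reported; nodes on no path get 0.  Each path
#' contributes its weight once per node on it, so the centralities sum to
#' `sum(w_p * length(p))` over paths p.
#'
#' @param pathset a [PathSet-class] with weights assigned
#' @return named numeric vector over all network nodes
#' @export
#' @examples
#' net <- tinyHourglass()
#' ps <- assignPathWeights(enumerateStPaths(net), net, "product")
#' pathCentrality(ps)["x"]  # 25
pathCentrality <- function(pathset) {
  stopifnot(is(pathset, "PathSet"))
  if (pathset@scheme == "unset")
    stop("assign path weights first (assignPathWeights)")
  .centralityOver(pathset, rep(TRUE, length(pathset@paths)))
}

#' Greedy tau-core of a path set
#'
#' The tau-core is the smallest node set whose paths cover at least a
#' fraction tau of the total path weight; finding it exactly is
#' NP-complete, so a greedy heuristic is used: repeatedly pick the node
#' with the highest path centrality over the still-uncovered paths, add it
#' to the core and remove the paths it covers, until the covered weight
#' reaches `tau * totalWeight` (stopping test uses `>=`).  Ties in the
#' argmax are broken by lexicographic (byte-order) node id for
#' determinism.  Only the covered paths are removed at each step; the
#' surviving paths keep all their nodes and edges.  Source and target
#' nodes are eligible core members.
#'
#' @param pathset a [PathSet-class] with weights assigned
#' @param tau coverage threshold in (0, 1]
#' @return a [CoreResult-class]
#' @export
#' @examples
#' net <- tinyHourglass()
#' ps <- assignPathWeights(enumerateStPaths(net), net, "product")
#' coreMembers(computeTauCore(ps, 0.9))  # the single hub node 'x'
computeTauCore <- function(pathset, tau) {
  stopifnot(is(pathset, "PathSet"))
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 1)
    stop("'tau' must be a single number in (0, 1]")
  if (pathset@scheme == "unset")
    stop("assign path weights first (assignPathWeights)")
  total <- pathset@totalWeight
  if (!isTRUE(total > 0)) stop("no source-target paths")

  alive <- rep(TRUE, length(pathset@paths))
  eps <- 1e-9 * total
  covered <- 0
  core <- character()
  marginal <- numeric()
  while (covered < tau * total - eps) {
    cent <- .centralityOver(pathset, alive)
    cent <- cent[setdiff(names(cent), core)]
    best <- max(cent)
    tied <- cent >= best - 1e-12 * max(1, abs(best))
    node <- lexSort(names(cent)[tied])[1]
    hit <- pathset@nodeIndex[[node]]
    hit <- hit[alive[hit]]
    gain <- sum(pathset@weights[hit])
    alive[hit] <- FALSE
    covered <- covered + gain
    core <- c(core, node)
    marginal <- c(marginal, gain)
  }
  members <- data.frame(rank = seq_along(core), node = core,
                        marginal = marginal,
                        cumulative_fraction = cumsum(marginal) / total,
                        stringsAsFactors = FALSE)
  new("CoreResult", tau = tau, members = members,
      coveredFraction = covered / total, nCore = length(core),
      scheme = pathset@scheme)
}

#' Cumulative coverage curve of a greedy core
#'
#' @param pathset the [PathSet-class] the core was computed from
#' @param core a [CoreResult-class]
#' @return data.frame `step`, `cumulative_fraction`, starting at (0, 0) and
#'   monotone nondecreasing, ending at `coveredFraction(core) >= tau`
#' @export
coverageCurve <- function(pathset, core) {
  stopifnot(is(pathset, "PathSet"), is(core, "CoreResult"))
  data.frame(step = 0:core@nCore,
             cumulative_fraction = c(0, core@members$cumulative_fraction))
}

#' Exact minimum tau-core by exhaustive search (test oracle)
#'
#' Enumerates node subsets of increasing size until one covers at least
#' `tau * totalWeight`, returning the lexicographically least minimum set.
#' Exponential in the subset size: intended as an independent oracle for
#' small instances, not for production use.
#'
#' @param pathset a [PathSet-class] with weights assigned
#' @param tau coverage threshold in (0, 1]
#' @param maxNodes largest subset size to try
#' @return character vector of node ids
#' @export
exactMinCore <- function(pathset, tau, maxNodes = 8L) {
  stopifnot(is(pathset, "PathSet"))
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau > 1)
    stop("'tau' must be a single number in (0, 1]")
  if (pathset@scheme == "unset")
    stop("assign path weights first (assignPathWeights)")
  total <- pathset@totalWeight
  if (!isTRUE(total > 0)) stop("no source-target paths")
  need <- tau * total - 1e-9 * total

  cand <- lexSort(names(pathset@nodeIndex))
  ## paths-by-candidate incidence
  inc <- vapply(cand, function(v) {
    out <- logical(length(pathset@paths))
    out[pathset@nodeIndex[[v]]] <- TRUE
    out
  }, logical(length(pathset@paths)))
  inc <- matrix(inc, nrow = length(pathset@paths))
  w <- pathset@weights
  for (k in seq_len(min(maxNodes, length(cand)))) {
    if (choose(length(cand), k) > 5e6)
      stop("subset enumeration too large; reduce maxNodes or the network")
    cmb <- utils::combn(seq_along(cand), k)
    for (j in seq_len(ncol(cmb))) {
      ix <- cmb[, j]
      if (sum(w[rowSums(inc[, ix, drop = FALSE]) > 0]) >= need)
        return(cand[ix])  # combn over sorted ids: first hit is lex-least
    }
  }
  stop(sprintf("no node set of size <= %d covers tau = %g", maxNodes, tau))
}
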