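#' Build the flat dependency network G_f
#'
#' The flat network keeps only the source and target nodes of the parent
#' network and joins each ordered (source, target) pair by a single edge
#' whose weight aggregates (sums) the weights of all paths between the
#' pair.  Under the unit scheme the flat edge weight is exactly the number
#' of source-target paths between the pair; under weighted schemes the sum
#' is the unique aggregation that conserves total coverage mass, so the
#' flat total weight always equals the path set's total weight.  The flat
#' network preserves all source-target dependencies but has no
#' intermediate nodes, so it cannot show an hourglass: it is the reference
#' the H-score compares against.
#'
#' @param pathset a [PathSet-class] with weights assigned
#' @return a [FlatNetwork-class]
#' @export
#' @examples
#' net <- tinyHourglass()
#' ps <- assignPathWeights(enumerateStPaths(net), net, "product")
#' edgeTable(buildFlatNetwork(ps))
buildFlatNetwork <- function(pathset) {
  stopifnot(is(pathset, "PathSet"))
  if (pathset@scheme == "unset")
    stop("assign path weights first (assignPathWeights)")
  if (length(pathset@paths) == 0)
    stop("empty path set: no source-target paths to flatten")
  s <- vapply(pathset@paths, `[`, character(1), 1L)
  t <- vapply(pathset@paths, function(p) p[length(p)], character(1))
  key <- edgeKey(s, t)
  agg <- rowsum(pathset@weights, key)
  first <- !duplicated(key)
  edges <- data.frame(source = s[first], target = t[first],
                      weight = as.numeric(agg[key[first], 1]),
                      stringsAsFactors = FALSE)
  edges <- edges[lexOrder(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  new("FlatNetwork", edges = edges,
      nodes = lexSort(c(pathset@sourceNodes, pathset@targetNodes)),
      totalWeight = sum(edges$weight), scheme = pathset@scheme)
}

## View a flat network as a PathSet of 2-node paths so the one greedy
## (and the exhaustive oracle) serves both C and C_f.
flatAsPathSet <- function(flat) {
  paths <- mapply(c, flat@edges$source, flat@edges$target,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  nodeIndex <- list()
  if (length(paths) > 0) {
    ids <- rep.int(seq_along(paths), lengths(paths))
    nodeIndex <- split(ids, unlist(paths))
    nodeIndex <- nodeIndex[lexSort(names(nodeIndex))]
  }
  new("PathSet",
      paths = paths, hops = rep(1L, length(paths)),
      weights = flat@edges$weight, scheme = "flat",
      totalWeight = flat@totalWeight,
      nodes = flat@nodes,
      sourceNodes = lexSort(unique(flat@edges$source)),
      targetNodes = lexSort(unique(flat@edges$target)),
      nodeIndex = nodeIndex, maxHops = 1L)
}

#' Core size of the flat dependency network
#'
#' Runs the same tau-core machinery on the flat network, treating each
#' aggregated (source, target) edge as a 2-node path.  `method = "greedy"`
#' (default) uses the same greedy heuristic as [computeTauCore()], so the
#' H-score compares like with like; `method = "exact"` uses the exhaustive
#' oracle and is only feasible for small networks.
#'
#' @param flat a [FlatNetwork-class]
#' @param tau coverage threshold in (0, 1]
#' @param method `"greedy"` or `"exact"`
#' @return integer core size C_f(tau)
#' @export
flatCoreSize <- function(flat, tau, method = c("greedy", "exact")) {
  stopifnot(is(flat, "FlatNetwork"))
  method <- match.arg(method)
  if (nrow(flat@edges) == 0) stop("empty flat network")
  ps <- flatAsPathSet(flat)
  if (method == "greedy") computeTauCore(ps, tau)@nCore
  else length(exactMinCore(ps, tau, maxNodes = length(ps@nodes)))
}

#' H-score: hourglass extent of a network
#'
#' `H(tau) = 1 - C(tau) / C_f(tau)`, where C is the tau-core size of the
#' network and C_f that of its flat dependency network.  H close to 1
#' means the network routes its source-target paths through a core far
#' smaller than any source/target cover could be — a strong hourglass.
#' For exact minimum cores `C <= C_f` always holds; the greedy heuristic
#' can in principle violate it, in which case H is clamped at 0 and the
#' result flagged (with a warning).
#'
#' @param pathset a [PathSet-class] with weights assigned
#' @param tau coverage threshold in (0, 1]
#' @param flatCore `"greedy"` or `"exact"`, passed to [flatCoreSize()]
#' @return an [HScoreResult-class]
#' @export
#' @examples
#' net <- tinyHourglass()
#' ps <- assignPathWeights(enumerateStPaths(net), net, "product")
#' hScore(ps, 0.9)  # C = 1, C_f = 2, H = 0.5
hScore <- function(pathset, tau, flatCore = c("greedy", "exact")) {
  flatCore <- match.arg(flatCore)
  core <- computeTauCore(pathset, tau)
  cf <- flatCoreSize(buildFlatNetwork(pathset), tau, method = flatCore)
  .hScoreFrom(core@nCore, cf, tau, pathset@scheme)
}

.hScoreFrom <- function(c, cFlat, tau, scheme) {
  raw <- 1 - c / cFlat
  clamped <- raw < 0
  if (clamped)
    warning(sprintf("greedy core (%d) larger than flat core (%d); H clamped to 0",
                    c, cFlat))
  new("HScoreResult", tau = tau, c = as.integer(c), cFlat = as.integer(cFlat),
      h = max(0, raw), clamped = clamped, scheme = scheme)
}

#' H-score across a grid of thresholds
#'
#' Computes the H-score at each threshold, reusing one path enumeration
#' and one flat network.
#'
#' @param pathset a [PathSet-class] with weights assigned
#' @param taus thresholds in (0, 1]; default grid 0.05 to 1 in steps of 0.05
#' @param flatCore `"greedy"` or `"exact"`
#' @return data.frame `tau`, `C`, `C_flat`, `H`, `clamped`
#' @export
hScoreCurve <- function(pathset, taus = seq(0.05, 1, by = 0.05),
                        flatCore = c("greedy", "exact")) {
  flatCore <- match.arg(flatCore)
  if (any(taus <= 0 | taus > 1)) stop("all taus must be in (0, 1]")
  flat <- buildFlatNetwork(pathset)
  flatPs <- flatAsPathSet(flat)
  rows <- lapply(taus, function(tau) {
    c <- computeTauCore(pathset, tau)@nCore
    cf <- if (flatCore == "greedy") computeTauCore(flatPs, tau)@nCore
          else length(exactMinCore(flatPs, tau, maxNodes = length(flatPs@nodes)))
    as.data.frame(.hScoreFrom(c, cf, tau, pathset@scheme))
  })
  do.call(rbind, rows)
}
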