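#' Enumerate bounded source-target paths
#'
#' Enumerates every simple directed path that starts at a source-role node,
#' ends at a target-role node and uses between 1 and `maxHops` edges.  With
#' the default bound of 4 this is the path set commonly written P4.
#' Interior nodes may hold any role (direct source-target edges count as
#' 1-hop paths); `strictInterior = TRUE` restricts interiors to
#' intermediate-role nodes for sensitivity analysis.  Enumeration is
#' deterministic: paths are returned in lexicographic order of their node
#' sequences (byte order), which coincides with a depth-first traversal
#' that visits neighbors in lexicographic order.
#'
#' Path weights are left unassigned so that one enumeration can serve all
#' weighting schemes (see [assignPathWeights()]); this matters for the
#' weight-permutation null, which reuses the topology across replicates.
#'
#' @param net a [RoleNetwork-class]; feedback edges should have been removed
#'   with [removeFeedbackEdges()] first (a warning is emitted otherwise)
#' @param maxHops maximum number of edges per path (>= 1), default 4
#' @param strictInterior if TRUE, drop paths whose interior nodes are not
#'   all intermediate-role
#' @return a [PathSet-class] with scheme `"unset"`
#' @export
#' @examples
#' ps <- enumerateStPaths(tinyHourglass())
#' nPaths(ps)  # 4
enumerateStPaths <- function(net, maxHops = 4L, strictInterior = FALSE) {
  stopifnot(is(net, "RoleNetwork"))
  maxHops <- as.integer(maxHops)
  if (is.na(maxHops) || maxHops < 1L) stop("'maxHops' must be an integer >= 1")
  if (any(.isFeedbackEdge(net)))
    warning("network contains feedback edges; run removeFeedbackEdges() first")

  sources <- lexSort(names(net@roles)[net@roles == "source"])
  targets <- lexSort(names(net@roles)[net@roles == "target"])
  paths <- list()
  if (length(sources) > 0 && length(targets) > 0 && nrow(net@edges) > 0) {
    g <- asIgraph(net)
    for (s in sources) {
      found <- igraph::all_simple_paths(g, from = s, to = targets,
                                        mode = "out", cutoff = maxHops)
      if (length(found) > 0)
        paths <- c(paths, lapply(found, function(v) names(v)))
    }
  }
  ## all_simple_paths ends paths at target-role nodes only (targets given as
  ## `to`); keep paths of >= 1 hop and optionally restrict interiors
  if (length(paths) > 0 && strictInterior) {
    ok <- vapply(paths, function(p) {
      length(p) <= 2 || all(net@roles[p[-c(1, length(p))]] == "intermediate")
    }, logical(1))
    paths <- paths[ok]
  }
  if (length(paths) > 0) {
    key <- vapply(paths, paste, character(1), collapse = "\x1f")
    paths <- paths[lexOrder(key)]
  }
  hops <- vapply(paths, length, integer(1)) - 1L

  nodeIndex <- list()
  if (length(paths) > 0) {
    ids <- rep.int(seq_along(paths), lengths(paths))
    nodeIndex <- split(ids, unlist(paths))
    nodeIndex <- nodeIndex[lexSort(names(nodeIndex))]
  }

  new("PathSet",
      paths = paths, hops = hops,
      weights = rep(NA_real_, length(paths)),
      scheme = "unset", totalWeight = NA_real_,
      nodes = lexSort(names(net@roles)),
      sourceNodes = sources, targetNodes = targets,
      nodeIndex = nodeIndex, maxHops = maxHops)
}

.SCHEME_FUN <- list(
  unit    = function(w) 1,
  product = function(w) prod(w),
  min     = function(w) min(w),
  invsum  = function(w) 1 / sum(1 / w)
)

#' Assign path weights under a weighting scheme
#'
#' Computes each path's weight from the weights of its edges:
#' \describe{
#'   \item{`"unit"`}{every path gets weight 1 (the unweighted analysis, UNW).}
#'   \item{`"product"`}{product of the edge weights — the multi-edge
#'     transformation (MET), in which an edge of integer weight w stands
#'     for w parallel unit edges, so each edge combination counts once.
#'     With all edge weights equal to 1 this reduces exactly to `"unit"`.}
#'   \item{`"min"`}{minimum edge weight: a max-flow reading for networks
#'     whose weights are capacities.}
#'   \item{`"invsum"`}{inverse of the sum of inverse edge weights: a
#'     communication-efficiency reading.}
#' }
#'
#' @param pathset a [PathSet-class] from [enumerateStPaths()]
#' @param net the [RoleNetwork-class] the paths were enumerated on (or one
#'   with identical topology, e.g. after [permuteEdgeWeights()])
#' @param scheme `"unit"`, `"product"`, `"min"` or `"invsum"`
#' @param strictInteger require whole-number edge weights under
#'   `"product"` (the parallel-edges reading presumes counts; the product
#'   itself is well-defined for any positive reals, so the check is off by
#'   default)
#' @return the [PathSet-class] with weights, total weight and scheme set
#' @export
#' @examples
#' net <- tinyHourglass()
#' ps <- assignPathWeights(enumerateStPaths(net), net, "product")
#' totalPathWeight(ps)  # 25
assignPathWeights <- function(pathset, net,
                              scheme = c("product", "unit", "min", "invsum"),
                              strictInteger = FALSE) {
  stopifnot(is(pathset, "PathSet"), is(net, "RoleNetwork"))
  scheme <- match.arg(scheme)
  if (strictInteger && scheme == "product" &&
      any(abs(net@edges$weight - round(net@edges$weight)) > 1e-9))
    stop("strictInteger: the product (MET) scheme requires integer edge weights")
  lookup <- setNames(net@edges$weight, edgeKey(net@edges$tail, net@edges$head))
  f <- .SCHEME_FUN[[scheme]]
  weights <- vapply(pathset@paths, function(p) {
    ew <- lookup[edgeKey(p[-length(p)], p[-1])]
    if (anyNA(ew))
      stop("path references an edge absent from the network (stale path set)")
    f(ew)
  }, numeric(1))
  pathset@weights <- weights
  pathset@scheme <- scheme
  pathset@totalWeight <- sum(weights)
  validObject(pathset)
  pathset
}

#' Export a path set as a data.frame
#'
#' @param x a [PathSet-class]
#' @param ... unused
#' @return data.frame with columns `path_id`, `nodes` (`|`-joined), `hops`,
#'   `weight`
#' @export
as.data.frame.PathSet <- function(x, ...) {
  data.frame(
    path_id = seq_along(x@paths),
    nodes = vapply(x@paths, paste, character(1), collapse = "|"),
    hops = x@hops,
    weight = x@weights,
    stringsAsFactors = FALSE)
}
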