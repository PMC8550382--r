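#' @import methods
NULL

.ROLES <- c("source", "intermediate", "target")
.SCHEMES <- c("unset", "unit", "product", "min", "invsum", "flat")

## Feedback edges run against the source -> intermediate -> target direction.
.FEEDBACK_PAIRS <- matrix(c(
  "intermediate", "source",
  "target",       "source",
  "target",       "intermediate"
), ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("tail", "head")))

#' RoleNetwork: a directed weighted network with node roles
#'
#' The central data container: a simple directed graph (no self-loops, at
#' most one edge per ordered node pair) with a positive weight per edge and
#' exactly one role per node, one of `"source"`, `"intermediate"` or
#' `"target"`.  For a connectome these correspond to sensory, inter- and
#' motor neurons, with the number of chemical synapses as the edge weight.
#'
#' @slot edges data.frame with character columns `tail`, `head` and numeric
#'   column `weight` (all weights strictly positive).
#' @slot roles named character vector mapping every node id to its role;
#'   nodes without incident edges are allowed.
#' @slot name free-text label for the network.
#'
#' @seealso [loadNetwork()], [removeFeedbackEdges()], [enumerateStPaths()]
#' @exportClass RoleNetwork
setClass("RoleNetwork",
  representation(edges = "data.frame", roles = "character", name = "character"),
  prototype(
    edges = data.frame(tail = character(), head = character(),
                       weight = numeric(), stringsAsFactors = FALSE),
    roles = setNames(character(), character()),
    name = ""
  )
)

setValidity("RoleNetwork", function(object) {
  ed <- object@edges
  msgs <- character()
  if (!all(c("tail", "head", "weight") %in% names(ed)))
    return("edges must have columns 'tail', 'head', 'weight'")
  if (nrow(ed) > 0 && (!is.character(ed$tail) || !is.character(ed$head)))
    msgs <- c(msgs, "edge endpoints must be character node ids")
  if (!is.numeric(ed$weight) || any(!is.finite(ed$weight)) || any(ed$weight <= 0))
    if (nrow(ed) > 0) msgs <- c(msgs, "all edge weights must be finite and > 0")
  if (nrow(ed) > 0 && any(ed$tail == ed$head))
    msgs <- c(msgs, "self-loops are not allowed")
  if (anyDuplicated(paste(ed$tail, ed$head, sep = "\x1f")))
    msgs <- c(msgs, "at most one edge per ordered node pair")
  if (is.null(names(object@roles)) && length(object@roles) > 0)
    msgs <- c(msgs, "roles must be a named vector")
  if (!all(object@roles %in% .ROLES))
    msgs <- c(msgs, sprintf("roles must be one of: %s", paste(.ROLES, collapse = ", ")))
  if (anyDuplicated(names(object@roles)))
    msgs <- c(msgs, "each node must have exactly one role")
  unknown <- setdiff(unique(c(ed$tail, ed$head)), names(object@roles))
  if (length(unknown) > 0)
    msgs <- c(msgs, sprintf("edge endpoints without a declared role: %s",
                            paste(utils::head(unknown, 5), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' NetworkSummary: node/edge counts and edge-type composition
#'
#' Produced by [summarizeNetwork()].  Counts refer to the network before
#' feedback-edge removal; `mAfterRemoval` is the edge count after removing
#' intermediate-to-source, target-to-source and target-to-intermediate
#' edges.  `edgeTypeFractions` is the 3x3 matrix of the fraction of edges
#' per (tail role, head role) combination, rows indexing the tail
#' (pre-synaptic) role.
#'
#' @exportClass NetworkSummary
setClass("NetworkSummary",
  representation(
    name = "character",
    n = "integer", m = "integer", mAfterRemoval = "integer",
    nByRole = "integer", mRemovedFeedback = "integer",
    edgeTypeFractions = "matrix"
  )
)

setValidity("NetworkSummary", function(object) {
  msgs <- character()
  if (!identical(names(object@nByRole), .ROLES))
    msgs <- c(msgs, "nByRole must be named source/intermediate/target")
  if (object@n != sum(object@nByRole))
    msgs <- c(msgs, "n must equal the sum of per-role counts")
  if (object@m > 0 && abs(sum(object@edgeTypeFractions) - 1) > 1e-9)
    msgs <- c(msgs, "edgeTypeFractions must sum to 1")
  if (length(msgs)) msgs else TRUE
})

#' PathSet: enumerated source-target paths with weights
#'
#' The bounded set of simple directed paths from source-role to target-role
#' nodes (at most `maxHops` edges; the default bound of 4 gives the path
#' set commonly written P4).  Paths are stored as ordered node-id vectors.
#' Weights are `NA` until a scheme is applied with [assignPathWeights()].
#'
#' @slot paths list of character vectors, each a node sequence.
#' @slot hops integer vector, edges per path.
#' @slot weights numeric vector of path weights (NA while scheme is "unset").
#' @slot scheme one of "unset", "unit", "product", "min", "invsum"
#'   ("flat" is used internally for flat-network cores).
#' @slot totalWeight sum of path weights (NA while unset).
#' @slot nodes all node ids of the parent network (so centralities can report
#'   zeros for nodes on no path).
#' @slot sourceNodes,targetNodes source/target node ids of the parent network.
#' @slot nodeIndex named list: node id -> integer ids of paths containing it.
#' @slot maxHops the enumeration bound.
#'
#' @exportClass PathSet
setClass("PathSet",
  representation(
    paths = "list", hops = "integer", weights = "numeric",
    scheme = "character", totalWeight = "numeric",
    nodes = "character", sourceNodes = "character", targetNodes = "character",
    nodeIndex = "list", maxHops = "integer"
  )
)

setValidity("PathSet", function(object) {
  msgs <- character()
  np <- length(object@paths)
  if (length(object@hops) != np || length(object@weights) != np)
    msgs <- c(msgs, "paths, hops and weights must have equal length")
  if (!object@scheme %in% .SCHEMES)
    msgs <- c(msgs, sprintf("scheme must be one of: %s", paste(.SCHEMES, collapse = ", ")))
  if (object@scheme == "unset") {
    if (np > 0 && !all(is.na(object@weights)))
      msgs <- c(msgs, "weights must be NA while scheme is unset")
  } else if (np > 0) {
    if (any(!is.finite(object@weights)) || any(object@weights <= 0))
      msgs <- c(msgs, "assigned path weights must be finite and > 0")
    tw <- sum(object@weights)
    if (abs(object@totalWeight - tw) > 1e-9 * max(1, abs(tw)))
      msgs <- c(msgs, "totalWeight must equal the sum of path weights")
    if (object@scheme == "unit" && !all(object@weights == 1))
      msgs <- c(msgs, "unit scheme requires every path weight to equal 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' CoreResult: the greedy tau-core and its coverage trace
#'
#' Ordered result of the greedy set-cover heuristic: nodes picked by
#' decreasing (current) path centrality until at least a fraction `tau` of
#' the total path weight is covered.
#'
#' @slot tau the path-coverage threshold in (0, 1].
#' @slot members data.frame with columns `rank`, `node`, `marginal` (weight
#'   newly covered at that step) and `cumulative_fraction`.
#' @slot coveredFraction final fraction of path weight covered (>= tau).
#' @slot nCore core size C(tau).
#' @slot scheme weighting scheme of the path set the core was computed from.
#'
#' @exportClass CoreResult
setClass("CoreResult",
  representation(tau = "numeric", members = "data.frame",
                 coveredFraction = "numeric", nCore = "integer",
                 scheme = "character")
)

setValidity("CoreResult", function(object) {
  msgs <- character()
  if (object@tau <= 0 || object@tau > 1)
    msgs <- c(msgs, "tau must be in (0, 1]")
  if (object@nCore != nrow(object@members))
    msgs <- c(msgs, "nCore must equal the number of member rows")
  cf <- object@members$cumulative_fraction
  if (length(cf) > 1 && any(diff(cf) <= 0))
    msgs <- c(msgs, "cumulative_fraction must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' FlatNetwork: the flat dependency network G_f
#'
#' Derived from a weighted [PathSet]: only the source and target nodes are
#' kept, and each ordered (source, target) pair is connected by one edge
#' whose weight aggregates the weights of all paths between the pair (under
#' the unit scheme this is the path count).  By construction the flat
#' network has no intermediate nodes and cannot show an hourglass.
#'
#' @slot edges data.frame `source`, `target`, `weight`.
#' @slot nodes all source and target nodes of the parent network.
#' @slot totalWeight aggregate weight; equals the parent path set's total.
#' @slot scheme weighting scheme of the parent path set.
#'
#' @exportClass FlatNetwork
setClass("FlatNetwork",
  representation(edges = "data.frame", nodes = "character",
                 totalWeight = "numeric", scheme = "character")
)

setValidity("FlatNetwork", function(object) {
  msgs <- character()
  if (!all(c("source", "target", "weight") %in% names(object@edges)))
    msgs <- c(msgs, "edges must have columns 'source', 'target', 'weight'")
  tw <- sum(object@edges$weight)
  if (abs(object@totalWeight - tw) > 1e-9 * max(1, abs(tw)))
    msgs <- c(msgs, "totalWeight must equal the summed flat edge weights")
  if (length(msgs)) msgs else TRUE
})

#' HScoreResult: core sizes and H-score at one threshold
#'
#' H(tau) = 1 - C(tau) / C_f(tau), clamped at 0 when the greedy core of the
#' original network comes out larger than the greedy flat core (the
#' inequality C <= C_f is guaranteed only for exact minimum cores).
#'
#' @slot tau threshold in (0, 1].
#' @slot c core size C(tau) of the network.
#' @slot cFlat core size C_f(tau) of the flat dependency network.
#' @slot h the H-score in [0, 1].
#' @slot clamped TRUE iff 1 - c/cFlat was negative and clamped to 0.
#' @slot scheme weighting scheme used.
#'
#' @exportClass HScoreResult
setClass("HScoreResult",
  representation(tau = "numeric", c = "integer", cFlat = "integer",
                 h = "numeric", clamped = "logical", scheme = "character")
)

setValidity("HScoreResult", function(object) {
  msgs <- character()
  expect <- max(0, 1 - object@c / object@cFlat)
  if (abs(object@h - expect) > 1e-12)
    msgs <- c(msgs, "h must equal max(0, 1 - c/cFlat)")
  if (!identical(object@clamped, (1 - object@c / object@cFlat) < 0))
    msgs <- c(msgs, "clamped flag inconsistent with c and cFlat")
  if (length(msgs)) msgs else TRUE
})

#' NullResult: null distribution of the H-score and its p-value
#'
#' Result of [nullHDistribution()].  The p-value uses the add-one
#' (pseudocount) permutation estimator
#' `(1 + #\{h_null >= h_empirical\}) / (nReps + 1)`, so it is never exactly 0.
#'
#' @slot method `"weight_permutation"` or `"edge_shuffle"`.
#' @slot nReps number of randomized replicates.
#' @slot tau threshold the H-scores were computed at.
#' @slot scheme path weighting scheme.
#' @slot hEmpirical H-score of the observed network.
#' @slot hNull numeric vector of replicate H-scores, length nReps.
#' @slot pValue empirical p-value in (0, 1].
#' @slot seed master seed the replicate seeds were spawned from.
#'
#' @exportClass NullResult
setClass("NullResult",
  representation(method = "character", nReps = "integer", tau = "numeric",
                 scheme = "character", hEmpirical = "numeric",
                 hNull = "numeric", pValue = "numeric", seed = "integer")
)

setValidity("NullResult", function(object) {
  msgs <- character()
  if (length(object@hNull) != object@nReps)
    msgs <- c(msgs, "hNull must have length nReps")
  p <- (1 + sum(object@hNull >= object@hEmpirical)) / (object@nReps + 1)
  if (abs(object@pValue - p) > 1e-12)
    msgs <- c(msgs, "pValue inconsistent with hNull and hEmpirical")
  if (length(msgs)) msgs else TRUE
})
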