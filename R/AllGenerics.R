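#' Accessors for hourglassNet objects
#'
#' Small accessor generics so user code never touches slots directly:
#' `edgeTable()` returns the edge data.frame of a [RoleNetwork] or
#' [FlatNetwork]; `nodeRoles()` the named role vector; `networkName()` the
#' label; `nNodes()`/`nEdges()` counts; `nPaths()`, `pathList()`,
#' `pathWeights()`, `weightScheme()` and `totalPathWeight()` describe a
#' [PathSet]; `coreMembers()`, `coreSize()` and `coveredFraction()` a
#' [CoreResult]; `hScoreValue()` an [HScoreResult]; `pValue()` and
#' `nullScores()` a [NullResult].
#'
#' @param x an object of the documented class
#' @return see the individual descriptions above
#' @name accessors
#' @aliases edgeTable nodeRoles networkName nNodes nEdges nPaths pathList
#'   pathWeights weightScheme totalPathWeight coreMembers coreSize
#'   coveredFraction hScoreValue pValue nullScores
#' @examples
#' net <- tinyHourglass()
#' edgeTable(net)
#' nodeRoles(net)
NULL

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("nodeRoles", function(x) standardGeneric("nodeRoles"))
#' @rdname accessors
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))
#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))
#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))
#' @rdname accessors
#' @export
setGeneric("nPaths", function(x) standardGeneric("nPaths"))
#' @rdname accessors
#' @export
setGeneric("pathList", function(x) standardGeneric("pathList"))
#' @rdname accessors
#' @export
setGeneric("pathWeights", function(x) standardGeneric("pathWeights"))
#' @rdname accessors
#' @export
setGeneric("weightScheme", function(x) standardGeneric("weightScheme"))
#' @rdname accessors
#' @export
setGeneric("totalPathWeight", function(x) standardGeneric("totalPathWeight"))
#' @rdname accessors
#' @export
setGeneric("coreMembers", function(x) standardGeneric("coreMembers"))
#' @rdname accessors
#' @export
setGeneric("coreSize", function(x) standardGeneric("coreSize"))
#' @rdname accessors
#' @export
setGeneric("coveredFraction", function(x) standardGeneric("coveredFraction"))
#' @rdname accessors
#' @export
setGeneric("hScoreValue", function(x) standardGeneric("hScoreValue"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))

#' @rdname accessors
setMethod("edgeTable", "RoleNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("edgeTable", "FlatNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("nodeRoles", "RoleNetwork", function(x) x@roles)
#' @rdname accessors
setMethod("networkName", "RoleNetwork", function(x) x@name)
#' @rdname accessors
setMethod("nNodes", "RoleNetwork", function(x) length(x@roles))
#' @rdname accessors
setMethod("nEdges", "RoleNetwork", function(x) nrow(x@edges))
#' @rdname accessors
setMethod("nPaths", "PathSet", function(x) length(x@paths))
#' @rdname accessors
setMethod("pathList", "PathSet", function(x) x@paths)
#' @rdname accessors
setMethod("pathWeights", "PathSet", function(x) x@weights)
#' @rdname accessors
setMethod("weightScheme", "PathSet", function(x) x@scheme)
#' @rdname accessors
setMethod("totalPathWeight", "PathSet", function(x) x@totalWeight)
#' @rdname accessors
setMethod("weightScheme", "CoreResult", function(x) x@scheme)
#' @rdname accessors
setMethod("coreMembers", "CoreResult", function(x) x@members)
#' @rdname accessors
setMethod("coreSize", "CoreResult", function(x) x@nCore)
#' @rdname accessors
setMethod("coveredFraction", "CoreResult", function(x) x@coveredFraction)
#' @rdname accessors
setMethod("hScoreValue", "HScoreResult", function(x) x@h)
#' @rdname accessors
setMethod("pValue", "NullResult", function(x) x@pValue)
#' @rdname accessors
setMethod("nullScores", "NullResult", function(x) x@hNull)

setMethod("show", "RoleNetwork", function(object) {
  rl <- table(factor(object@roles, levels = .ROLES))
  cat(sprintf("RoleNetwork%s: %d nodes (%d source, %d intermediate, %d target), %d edges\n",
              if (nzchar(object@name)) paste0(" '", object@name, "'") else "",
              length(object@roles), rl[["source"]], rl[["intermediate"]],
              rl[["target"]], nrow(object@edges)))
  if (nrow(object@edges) > 0)
    cat(sprintf("  weights: min %g, median %g, max %g\n",
                min(object@edges$weight), stats::median(object@edges$weight),
                max(object@edges$weight)))
})

setMethod("show", "NetworkSummary", function(object) {
  cat(sprintf("NetworkSummary%s\n",
              if (nzchar(object@name)) paste0(" '", object@name, "'") else ""))
  cat(sprintf("  n = %d (S %d, I %d, M %d); m = %d (%d after feedback removal, %d removed)\n",
              object@n, object@nByRole[["source"]],
              object@nByRole[["intermediate"]], object@nByRole[["target"]],
              object@m, object@mAfterRemoval, object@mRemovedFeedback))
  cat("  edge-type fractions (rows = tail role):\n")
  print(round(object@edgeTypeFractions, 3))
})

setMethod("show", "PathSet", function(object) {
  cat(sprintf("PathSet: %d source-target paths (max %d hops), scheme '%s'\n",
              length(object@paths), object@maxHops, object@scheme))
  if (object@scheme != "unset" && length(object@paths) > 0)
    cat(sprintf("  total path weight: %g\n", object@totalWeight))
})

setMethod("show", "CoreResult", function(object) {
  cat(sprintf("CoreResult: tau = %g, core size %d, covered fraction %.4f (scheme '%s')\n",
              object@tau, object@nCore, object@coveredFraction, object@scheme))
  print(utils::head(object@members, 10))
  if (nrow(object@members) > 10) cat(sprintf("  ... %d more\n", nrow(object@members) - 10))
})

setMethod("show", "FlatNetwork", function(object) {
  cat(sprintf("FlatNetwork: %d source/target nodes, %d aggregated edges, total weight %g (scheme '%s')\n",
              length(object@nodes), nrow(object@edges), object@totalWeight,
              object@scheme))
})

setMethod("show", "HScoreResult", function(object) {
  cat(sprintf("HScoreResult: tau = %g, C = %d, C_f = %d, H = %.4f%s (scheme '%s')\n",
              object@tau, object@c, object@cFlat, object@h,
              if (object@clamped) " [clamped]" else "", object@scheme))
})

setMethod("show", "NullResult", function(object) {
  cat(sprintf("NullResult (%s): %d replicates, tau = %g, scheme '%s'\n",
              object@method, object@nReps, object@tau, object@scheme))
  cat(sprintf("  H empirical = %.4f, null mean = %.4f, p = %.4g (seed %d)\n",
              object@hEmpirical, mean(object@hNull), object@pValue, object@seed))
})

#' @export
as.data.frame.HScoreResult <- function(x, ...) {
  data.frame(tau = x@tau, C = x@c, C_flat = x@cFlat, H = x@h,
             clamped = x@clamped, stringsAsFactors = FALSE)
}
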