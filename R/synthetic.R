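#' Fixed five-node hourglass fixture
#'
#' Two sources feeding one intermediate hub feeding two targets, with
#' integer weights: `s1 -> x` (2), `s2 -> x` (3), `x -> t1` (1),
#' `x -> t2` (4).  Every worked example in the documentation uses it: the
#' four paths have product weights 2, 8, 3 and 12 (total 25), the hub has
#' product-scheme centrality 25, the tau = 0.9 core is `{x}`, the flat core
#' has size 2 and H(0.9) = 0.5.
#'
#' @return a [RoleNetwork-class]
#' @export
#' @examples
#' tinyHourglass()
tinyHourglass <- function() {
  RoleNetwork(
    data.frame(tail = c("s1", "s2", "x", "x"),
               head = c("x", "x", "t1", "t2"),
               weight = c(2, 3, 1, 4), stringsAsFactors = FALSE),
    c(s1 = "source", s2 = "source", x = "intermediate",
      t1 = "target", t2 = "target"),
    name = "tinyHourglass")
}

#' Layered synthetic network with a controllable waist
#'
#' Generates a source / intermediate / target network in which a small set
#' of "waist" intermediates carries the bulk of the source-target traffic,
#' emulating the layered sensory -> inter -> motor organisation of a
#' connectome with synapse-count weights.  Structure:
#' \itemize{
#'   \item each (source, waist) and (waist, target) pair is connected with
#'     probability `pWaist`, then edges are added so every source reaches
#'     at least one waist node and every waist node at least one target —
#'     so at least one source-target path always exists;
#'   \item `extraIntermediates` additional intermediates form bypass
#'     routes: each (source, extra) and (extra, target) pair is connected
#'     with probability `pBypass`;
#'   \item optional within-class edges (source-source, intermediate-
#'     intermediate, target-target), each ordered pair with probability
#'     `pWithinClass`, and optional feedback edges (intermediate-to-source,
#'     target-to-source, target-to-intermediate) with probability
#'     `pFeedback`, for exercising the preprocessing steps;
#'   \item weights are integers drawn uniformly from
#'     `weightLow:weightHigh`; edges incident to a waist node are then
#'     multiplied by `waistWeightBoost`, concentrating weight on the
#'     waist when the boost exceeds 1.
#' }
#' Deterministic given `seed`.
#'
#' @param nSource,nWaist,nTarget layer sizes (each >= 1)
#' @param extraIntermediates number of bypass intermediates (>= 0)
#' @param pBypass probability of each source-extra and extra-target edge
#' @param pWaist probability of each source-waist and waist-target edge
#' @param weightLow,weightHigh inclusive integer weight range
#' @param waistWeightBoost multiplier (>= 1) for waist-incident weights
#' @param pWithinClass,pFeedback probabilities of within-class and
#'   feedback edges (default 0: a strictly layered feed-forward network)
#' @param seed integer seed
#' @return a [RoleNetwork-class]
#' @export
#' @examples
#' net <- layeredHourglass(seed = 1)
#' summarizeNetwork(net)
layeredHourglass <- function(nSource = 8L, nWaist = 2L, nTarget = 8L,
                             extraIntermediates = 8L, pBypass = 0.3,
                             pWaist = 0.8, weightLow = 1L, weightHigh = 3L,
                             waistWeightBoost = 1, pWithinClass = 0,
                             pFeedback = 0, seed = 1L) {
  stopifnot(nSource >= 1, nWaist >= 1, nTarget >= 1, extraIntermediates >= 0,
            pBypass >= 0, pBypass <= 1, pWaist >= 0, pWaist <= 1,
            weightLow >= 1, weightLow <= weightHigh, waistWeightBoost >= 1,
            pWithinClass >= 0, pWithinClass <= 1,
            pFeedback >= 0, pFeedback <= 1)
  src <- sprintf("s%02d", seq_len(nSource))
  waist <- sprintf("w%02d", seq_len(nWaist))
  extra <- if (extraIntermediates > 0)
    sprintf("e%02d", seq_len(extraIntermediates)) else character()
  tgt <- sprintf("t%02d", seq_len(nTarget))
  inter <- c(waist, extra)
  roles <- c(setNames(rep("source", nSource), src),
             setNames(rep("intermediate", length(inter)), inter),
             setNames(rep("target", nTarget), tgt))

  pairGrid <- function(a, b) {
    g <- expand.grid(tail = a, head = b, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    g[g$tail != g$head, , drop = FALSE]
  }
  withSeed(seed, {
    pick <- function(grid, p) grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
    sw <- pick(pairGrid(src, waist), pWaist)
    wt <- pick(pairGrid(waist, tgt), pWaist)
    ## guarantee every source reaches the waist and every waist a target
    for (s in setdiff(src, sw$tail))
      sw <- rbind(sw, data.frame(tail = s,
                                 head = waist[sample.int(nWaist, 1)]))
    for (w in setdiff(waist, wt$tail))
      wt <- rbind(wt, data.frame(tail = w,
                                 head = tgt[sample.int(nTarget, 1)]))
    se <- pick(pairGrid(src, extra), pBypass)
    et <- pick(pairGrid(extra, tgt), pBypass)
    within <- rbind(pick(pairGrid(src, src), pWithinClass),
                    pick(pairGrid(inter, inter), pWithinClass),
                    pick(pairGrid(tgt, tgt), pWithinClass))
    feedback <- rbind(pick(pairGrid(inter, src), pFeedback),
                      pick(pairGrid(tgt, src), pFeedback),
                      pick(pairGrid(tgt, inter), pFeedback))
    edges <- rbind(sw, wt, se, et, within, feedback)
    edges <- edges[!duplicated(edgeKey(edges$tail, edges$head)), , drop = FALSE]
    w <- weightLow +
      sample.int(weightHigh - weightLow + 1L, nrow(edges), replace = TRUE) - 1L
    onWaist <- edges$tail %in% waist | edges$head %in% waist
    w[onWaist] <- w[onWaist] * waistWeightBoost
    edges$weight <- w
    RoleNetwork(edges, roles,
                name = sprintf("layeredHourglass(seed=%d)", as.integer(seed)))
  })
}

#' Random bipartite source-target network
#'
#' Only direct source-to-target edges, each present with probability
#' `density` and weight 1; one edge is forced if the draw leaves none.
#' Such a network equals its own flat dependency network, so its H-score
#' is 0 at every threshold — the canonical hourglass-free control.
#'
#' @param nSource,nTarget layer sizes
#' @param density edge probability in (0, 1]
#' @param seed integer seed
#' @return a [RoleNetwork-class]
#' @export
flatBipartite <- function(nSource, nTarget, density = 0.5, seed = 1L) {
  stopifnot(nSource >= 1, nTarget >= 1, density > 0, density <= 1)
  src <- sprintf("s%02d", seq_len(nSource))
  tgt <- sprintf("t%02d", seq_len(nTarget))
  roles <- c(setNames(rep("source", nSource), src),
             setNames(rep("target", nTarget), tgt))
  withSeed(seed, {
    grid <- expand.grid(tail = src, head = tgt, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    keep <- stats::runif(nrow(grid)) < density
    if (!any(keep)) keep[sample.int(nrow(grid), 1)] <- TRUE
    edges <- grid[keep, , drop = FALSE]
    edges$weight <- 1
    RoleNetwork(edges, roles,
                name = sprintf("flatBipartite(seed=%d)", as.integer(seed)))
  })
}
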