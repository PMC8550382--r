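#' Construct a RoleNetwork from clean edge and role data
#'
#' Low-level constructor with full validity checking; most users should use
#' [loadNetwork()], which also aggregates duplicate edge rows, drops
#' self-loops and normalises role aliases.
#'
#' @param edges data.frame with columns `tail`, `head`, `weight`
#' @param roles named character vector, values `"source"`, `"intermediate"`
#'   or `"target"`
#' @param name optional label
#' @return a [RoleNetwork-class] object
#' @export
#' @examples
#' RoleNetwork(data.frame(tail = "s", head = "t", weight = 2),
#'             c(s = "source", t = "target"))
RoleNetwork <- function(edges, roles, name = "") {
  edges <- data.frame(tail = as.character(edges$tail),
                      head = as.character(edges$head),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  ord <- lexOrder(edges$tail, edges$head)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  roles <- roles[lexOrder(names(roles))]
  new("RoleNetwork", edges = edges, roles = roles, name = name)
}

.normalizeRole <- function(role) {
  key <- tolower(trimws(role))
  map <- c(source = "source", s = "source", sensory = "source",
           intermediate = "intermediate", i = "intermediate",
           inter = "intermediate", internal = "intermediate",
           target = "target", t = "target", m = "target", motor = "target")
  unname(map[key])
}

#' Load a role-annotated weighted network from edge and role tables
#'
#' Reads a directed weighted edge list plus a node-role table and returns a
#' validated [RoleNetwork-class].  Tables may be passed as data.frames or as
#' paths to delimited text files (`.csv` comma-separated, otherwise
#' tab-separated; headers `tail,head,weight` and `node,role`).  Role
#' aliases `S`/`I`/`M` (and `sensory`/`inter`/`motor`) are accepted.
#'
#' Cleaning rules: duplicate `(tail, head)` rows are aggregated by summing
#' their weights (synapse counts are additive); self-loops are dropped with
#' a message; every edge endpoint must appear in the role table unless
#' `dropUnlisted = TRUE`, in which case edges touching unlisted nodes are
#' dropped with a message.
#'
#' @param edgeTable data.frame or file path; columns `tail`, `head`, `weight`
#' @param roleTable data.frame or file path; columns `node`, `role`
#' @param dropUnlisted drop edges whose endpoints are missing from the role
#'   table instead of raising an error
#' @param name optional network label
#' @return a [RoleNetwork-class]
#' @export
#' @examples
#' ed <- data.frame(tail = c("s1", "s1"), head = c("x", "x"), weight = c(2, 3))
#' rl <- data.frame(node = c("s1", "x"), role = c("S", "I"))
#' net <- loadNetwork(ed, rl)
#' edgeTable(net)  # one aggregated edge of weight 5
loadNetwork <- function(edgeTable, roleTable, dropUnlisted = FALSE, name = "") {
  if (is.character(edgeTable)) edgeTable <- readDelimAuto(edgeTable)
  if (is.character(roleTable)) roleTable <- readDelimAuto(roleTable)
  req <- c("tail", "head", "weight")
  if (!all(req %in% names(edgeTable)))
    stop("edge table must have columns 'tail', 'head', 'weight'")
  if (!all(c("node", "role") %in% names(roleTable)))
    stop("role table must have columns 'node', 'role'")

  w <- suppressWarnings(as.numeric(edgeTable$weight))
  bad <- which(is.na(w) | !is.finite(w) | w <= 0)
  if (length(bad) > 0)
    stop(sprintf("non-positive or non-numeric weight in edge table row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))

  role <- .normalizeRole(roleTable$role)
  badRole <- which(is.na(role))
  if (length(badRole) > 0)
    stop(sprintf("unknown role '%s' in role table row %d (node '%s')",
                 roleTable$role[badRole[1]], badRole[1],
                 roleTable$node[badRole[1]]))
  node <- as.character(roleTable$node)
  conf <- tapply(role, node, function(r) length(unique(r)))
  if (any(conf > 1))
    stop(sprintf("node(s) with conflicting roles: %s",
                 paste(utils::head(names(conf)[conf > 1], 5), collapse = ", ")))
  roles <- setNames(role[!duplicated(node)], node[!duplicated(node)])

  tl <- as.character(edgeTable$tail); hd <- as.character(edgeTable$head)
  unlisted <- setdiff(unique(c(tl, hd)), names(roles))
  if (length(unlisted) > 0) {
    if (!dropUnlisted)
      stop(sprintf("edge endpoints missing from the role table: %s%s",
                   paste(utils::head(unlisted, 5), collapse = ", "),
                   if (length(unlisted) > 5) ", ..." else ""))
    keep <- !(tl %in% unlisted) & !(hd %in% unlisted)
    message(sprintf("dropped %d edge row(s) with unlisted endpoints",
                    sum(!keep)))
    tl <- tl[keep]; hd <- hd[keep]; w <- w[keep]
  }

  loops <- tl == hd
  if (any(loops)) {
    message(sprintf("dropped %d self-loop(s)", sum(loops)))
    tl <- tl[!loops]; hd <- hd[!loops]; w <- w[!loops]
  }

  if (length(tl) > 0) {
    agg <- rowsum(w, edgeKey(tl, hd))
    first <- !duplicated(edgeKey(tl, hd))
    edges <- data.frame(tail = tl[first], head = hd[first],
                        weight = as.numeric(agg[edgeKey(tl[first], hd[first]), 1]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(tail = character(), head = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  RoleNetwork(edges, roles, name = name)
}

## igraph view of a RoleNetwork (internal).  Isolated nodes are kept.
asIgraph <- function(net) {
  igraph::graph_from_data_frame(
    net@edges[, c("tail", "head", "weight")],
    directed = TRUE,
    vertices = data.frame(name = names(net@roles), role = unname(net@roles),
                          stringsAsFactors = FALSE))
}

.isFeedbackEdge <- function(net) {
  tailRole <- net@roles[net@edges$tail]
  headRole <- net@roles[net@edges$head]
  key <- paste(tailRole, headRole)
  key %in% paste(.FEEDBACK_PAIRS[, "tail"], .FEEDBACK_PAIRS[, "head"])
}

#' Remove feedback edges
#'
#' Feedback edges run against the source -> intermediate -> target
#' direction: intermediate-to-source, target-to-source and
#' target-to-intermediate (for a connectome, I-S, M-S and M-I connections).
#' They are removed before source-target path enumeration; all other
#' edges, including within-class edges (S-S, I-I, M-M), are retained.
#' The operation is idempotent.
#'
#' @param net a [RoleNetwork-class]
#' @return list with `network` (the filtered [RoleNetwork-class]) and
#'   `removed` (number of deleted edges)
#' @export
#' @examples
#' net <- tinyHourglass()
#' removeFeedbackEdges(net)$removed  # 0: strictly layered
removeFeedbackEdges <- function(net) {
  stopifnot(is(net, "RoleNetwork"))
  fb <- .isFeedbackEdge(net)
  out <- RoleNetwork(net@edges[!fb, , drop = FALSE], net@roles, name = net@name)
  list(network = out, removed = sum(fb))
}

#' Drop nodes with no incident edges
#'
#' @param net a [RoleNetwork-class]
#' @return list with `network` (pruned) and `removedNodes` (character
#'   vector of dropped node ids)
#' @export
pruneIsolated <- function(net) {
  stopifnot(is(net, "RoleNetwork"))
  touched <- unique(c(net@edges$tail, net@edges$head))
  iso <- lexSort(setdiff(names(net@roles), touched))
  out <- RoleNetwork(net@edges, net@roles[setdiff(names(net@roles), iso)],
                     name = net@name)
  list(network = out, removedNodes = iso)
}

#' Summarize a network's size and edge-type composition
#'
#' Computes node and edge counts, per-role node counts and the 3x3 matrix
#' of edge fractions per (tail role, head role) combination, all on the
#' network *before* feedback-edge removal; the edge count after removal is
#' taken from `netAfter` (computed internally when omitted).
#'
#' @param net a [RoleNetwork-class] before feedback removal
#' @param netAfter the same network after [removeFeedbackEdges()]; computed
#'   if `NULL`
#' @return a [NetworkSummary-class]
#' @export
#' @examples
#' summarizeNetwork(tinyHourglass())
summarizeNetwork <- function(net, netAfter = NULL) {
  stopifnot(is(net, "RoleNetwork"))
  if (is.null(netAfter)) netAfter <- removeFeedbackEdges(net)$network
  stopifnot(is(netAfter, "RoleNetwork"))
  if (!setequal(names(net@roles), names(netAfter@roles)))
    stop("'net' and 'netAfter' must share the same node set")
  m <- nrow(net@edges)
  frac <- matrix(0, 3, 3, dimnames = list(.ROLES, .ROLES))
  if (m > 0) {
    tailRole <- factor(net@roles[net@edges$tail], levels = .ROLES)
    headRole <- factor(net@roles[net@edges$head], levels = .ROLES)
    frac <- unclass(table(tailRole, headRole)) / m
    dimnames(frac) <- list(.ROLES, .ROLES)
  }
  nByRole <- as.integer(table(factor(net@roles, levels = .ROLES)))
  names(nByRole) <- .ROLES
  new("NetworkSummary",
      name = net@name,
      n = length(net@roles), m = m, mAfterRemoval = nrow(netAfter@edges),
      nByRole = nByRole,
      mRemovedFeedback = m - nrow(netAfter@edges),
      edgeTypeFractions = frac)
}

#' Write edge and role tables in the loader's format
#'
#' @param net a [RoleNetwork-class]
#' @param edgePath,rolePath output paths (`.csv` for comma, else tab)
#' @return invisibly, the two paths
#' @export
writeNetworkTables <- function(net, edgePath, rolePath) {
  sepFor <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  utils::write.table(net@edges, edgePath, sep = sepFor(edgePath),
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(node = names(net@roles),
                                role = unname(net@roles)),
                     rolePath, sep = sepFor(rolePath),
                     quote = FALSE, row.names = FALSE)
  invisible(c(edgePath, rolePath))
}
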