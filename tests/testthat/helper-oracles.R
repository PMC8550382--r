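# Independent oracles, deliberately implemented without the package's
# enumeration/centrality code paths: breadth-first extension of partial
# paths over the raw edge table, adjacency matrix powers, and brute force.

# All simple source->target paths of 1..maxHops edges, by iterative
# extension of partial paths over the edge data.frame.
brutePaths <- function(net, maxHops = 4) {
  ed <- edgeTable(net)
  roles <- nodeRoles(net)
  partials <- lapply(sort(names(roles)[roles == "source"]), function(s) s)
  found <- list()
  for (hop in seq_len(maxHops)) {
    nxt <- list()
    for (p in partials) {
      last <- p[length(p)]
      outs <- ed$head[ed$tail == last]
      for (h in sort(outs)) {
        if (h %in% p) next  # simple paths only
        q <- c(p, h)
        if (roles[[h]] == "target") found[[length(found) + 1]] <- q
        nxt[[length(nxt) + 1]] <- q
      }
    }
    partials <- nxt
    if (length(partials) == 0) break
  }
  found
}

# Path weight per scheme, computed straight from the edge table.
brutePathWeight <- function(net, path, scheme) {
  ed <- edgeTable(net)
  ew <- vapply(seq_len(length(path) - 1), function(i) {
    ed$weight[ed$tail == path[i] & ed$head == path[i + 1]]
  }, numeric(1))
  switch(scheme,
         unit = 1, product = prod(ew), min = min(ew),
         invsum = 1 / sum(1 / ew))
}

# Brute-force centrality: sum of path weights over paths containing v.
bruteCentrality <- function(net, v, scheme, maxHops = 4) {
  paths <- brutePaths(net, maxHops)
  sum(vapply(paths, function(p)
    if (v %in% p) brutePathWeight(net, p, scheme) else 0, numeric(1)))
}

# Number of source->target walks of length 1..maxHops via adjacency powers.
# Valid as a path-count oracle only when no walk of length <= maxHops
# repeats a node (e.g. layered DAGs).
walkCountOracle <- function(net, maxHops = 4) {
  roles <- nodeRoles(net)
  nodes <- names(roles)
  ed <- edgeTable(net)
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  A[cbind(ed$tail, ed$head)] <- 1
  S <- names(roles)[roles == "source"]
  T <- names(roles)[roles == "target"]
  total <- 0
  P <- diag(length(nodes)); dimnames(P) <- dimnames(A)
  for (k in seq_len(maxHops)) {
    P <- P %*% A
    total <- total + sum(P[S, T, drop = FALSE])
  }
  total
}

# Small random role network (<= 12 nodes) with cycles and feedback edges,
# fed through the package's preprocessing.
randomTinyNet <- function(seed) {
  set.seed(seed)
  net <- layeredHourglass(
    nSource = sample(1:3, 1), nWaist = sample(1:2, 1),
    nTarget = sample(1:3, 1), extraIntermediates = sample(0:3, 1),
    pBypass = runif(1, 0.2, 0.8), pWaist = 0.8,
    weightLow = 1, weightHigh = sample(1:4, 1),
    waistWeightBoost = sample(c(1, 2, 5), 1),
    pWithinClass = 0.15, pFeedback = 0.15,
    seed = sample.int(1e6, 1))
  removeFeedbackEdges(net)$network
}

# The documented replicate-seed spawning scheme: one sample.int draw per
# replicate under the master seed.
spawnSeeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

tinyTables <- function(dir, weights = c(2, 3, 1, 4)) {
  ed <- data.frame(tail = c("s1", "s2", "x", "x"),
                   head = c("x", "x", "t1", "t2"), weight = weights)
  rl <- data.frame(node = c("s1", "s2", "x", "t1", "t2"),
                   role = c("S", "S", "I", "M", "M"))
  ep <- file.path(dir, "edges.csv"); rp <- file.path(dir, "roles.csv")
  write.csv(ed, ep, row.names = FALSE, quote = FALSE)
  write.csv(rl, rp, row.names = FALSE, quote = FALSE)
  list(edges = ep, roles = rp)
}
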