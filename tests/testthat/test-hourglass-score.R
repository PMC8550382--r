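test_that("the flat network aggregates per-pair path weights and conserves mass", {
  net <- tinyHourglass()
  ps <- enumerateStPaths(net)

  met <- buildFlatNetwork(assignPathWeights(ps, net, "product"))
  ed <- edgeTable(met)
  got <- setNames(ed$weight, paste(ed$source, ed$target))
  expect_equal(got[c("s1 t1", "s1 t2", "s2 t1", "s2 t2")],
               c("s1 t1" = 2, "s1 t2" = 8, "s2 t1" = 3, "s2 t2" = 12))
  expect_equal(met@totalWeight, 25)

  unw <- buildFlatNetwork(assignPathWeights(ps, net, "unit"))
  expect_equal(edgeTable(unw)$weight, rep(1, 4))

  # an already-bipartite network equals its own flat network
  bi <- flatBipartite(3, 3, density = 0.6, seed = 2)
  psb <- assignPathWeights(enumerateStPaths(bi), bi, "unit")
  fb <- edgeTable(buildFlatNetwork(psb))
  eb <- edgeTable(bi)
  expect_equal(paste(fb$source, fb$target), paste(eb$tail, eb$head))
  expect_equal(fb$weight, eb$weight)

  # conservation holds for every scheme on a random network
  rnd <- randomTinyNet(7)
  for (scheme in c("unit", "product", "min", "invsum")) {
    psw <- assignPathWeights(enumerateStPaths(rnd), rnd, scheme)
    expect_equal(buildFlatNetwork(psw)@totalWeight, totalPathWeight(psw))
  }
})

test_that("flat core sizes come from the same greedy machinery", {
  net <- tinyHourglass()
  flat <- buildFlatNetwork(assignPathWeights(enumerateStPaths(net), net,
                                             "product"))
  # greedy picks t2 (20/25), then t1
  expect_equal(flatCoreSize(flat, 0.9), 2L)
  expect_equal(flatCoreSize(flat, 0.9, method = "exact"), 2L)

  one <- RoleNetwork(data.frame(tail = "s", head = "t", weight = 3),
                     c(s = "source", t = "target"))
  f1 <- buildFlatNetwork(assignPathWeights(enumerateStPaths(one), one, "product"))
  expect_equal(flatCoreSize(f1, 0.5), 1L)
  expect_equal(flatCoreSize(f1, 1), 1L)

  k <- 5  # k node-disjoint flat edges need k nodes at tau = 1
  ed <- data.frame(tail = sprintf("s%d", 1:k), head = sprintf("t%d", 1:k),
                   weight = 2)
  roles <- c(setNames(rep("source", k), sprintf("s%d", 1:k)),
             setNames(rep("target", k), sprintf("t%d", 1:k)))
  disj <- RoleNetwork(ed, roles)
  fd <- buildFlatNetwork(assignPathWeights(enumerateStPaths(disj), disj, "unit"))
  expect_equal(flatCoreSize(fd, 1), k)
})

test_that("H-scores compare the core against the flat core", {
  net <- tinyHourglass()
  ps <- assignPathWeights(enumerateStPaths(net), net, "product")
  hs <- hScore(ps, 0.9)
  expect_equal(hs@c, 1L)
  expect_equal(hs@cFlat, 2L)
  expect_equal(hScoreValue(hs), 0.5)
  expect_false(hs@clamped)

  # bipartite network: G equals G_f, so H = 0 at every tau
  bi <- flatBipartite(3, 4, density = 0.7, seed = 3)
  psb <- assignPathWeights(enumerateStPaths(bi), bi, "unit")
  curve <- hScoreCurve(psb, taus = c(0.3, 0.6, 0.9, 1))
  expect_equal(curve$H, rep(0, 4))

  # 5 sources -> hub -> 5 targets: C = 1, C_f = 5, H = 0.8 at tau = 1
  star <- RoleNetwork(
    data.frame(tail = c(sprintf("s%d", 1:5), rep("hub", 5)),
               head = c(rep("hub", 5), sprintf("t%d", 1:5)), weight = 1),
    c(setNames(rep("source", 5), sprintf("s%d", 1:5)), hub = "intermediate",
      setNames(rep("target", 5), sprintf("t%d", 1:5))))
  pss <- assignPathWeights(enumerateStPaths(star), star, "unit")
  hstar <- hScore(pss, 1)
  expect_equal(hstar@c, 1L)
  expect_equal(hstar@cFlat, 5L)
  expect_equal(hScoreValue(hstar), 0.8)
  # cross-checked against the exhaustive oracle
  expect_length(exactMinCore(pss, 1), 1L)
  expect_equal(flatCoreSize(buildFlatNetwork(pss), 1, method = "exact"), 5L)
})

test_that("H-score curves stay in [0, 1] and reuse one enumeration", {
  net <- tinyHourglass()
  ps <- assignPathWeights(enumerateStPaths(net), net, "product")
  curve <- hScoreCurve(ps, taus = c(0.5, 0.9))
  # at tau = 0.5 the greedy flat core is a single endpoint (t2 covers 0.8)
  expect_equal(curve$H, c(0, 0.5))
  expect_true(all(curve$H >= 0 & curve$H <= 1))

  full <- hScoreCurve(ps)
  expect_equal(nrow(full), 20L)
  expect_true(all(full$H >= 0 & full$H <= 1))
})

test_that("H is invariant to global weight rescaling on fixed-hop networks", {
  net <- layeredHourglass(waistWeightBoost = 5, pBypass = 0.4, seed = 13)
  ps <- assignPathWeights(enumerateStPaths(net), net, "product")
  expect_true(all(pathList(ps) |> lengths() == 3))  # every path has 2 hops

  ed <- edgeTable(net); ed$weight <- ed$weight * 7
  scaled <- RoleNetwork(ed, nodeRoles(net))
  pss <- assignPathWeights(enumerateStPaths(scaled), scaled, "product")
  a <- computeTauCore(ps, 0.9); b <- computeTauCore(pss, 0.9)
  expect_equal(coreMembers(a)$node, coreMembers(b)$node)
  expect_equal(coreMembers(a)$cumulative_fraction,
               coreMembers(b)$cumulative_fraction)
  expect_equal(hScoreValue(hScore(ps, 0.9)), hScoreValue(hScore(pss, 0.9)))
})

test_that("unit-weight networks give equal H under product and unit schemes", {
  for (seed in 1:10) {
    net <- layeredHourglass(weightLow = 1, weightHigh = 1, pBypass = 0.5,
                            seed = seed)
    ps <- enumerateStPaths(net)
    # clamping, when it occurs, must occur identically for both schemes
    hp <- suppressWarnings(hScore(assignPathWeights(ps, net, "product"), 0.9))
    hu <- suppressWarnings(hScore(assignPathWeights(ps, net, "unit"), 0.9))
    expect_equal(hScoreValue(hp), hScoreValue(hu))
    expect_equal(hp@c, hu@c)
    expect_equal(hp@cFlat, hu@cFlat)
  }
})
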