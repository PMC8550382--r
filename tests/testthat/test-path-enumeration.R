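test_that("paths respect the hop bound and start/end roles", {
  # 5-hop chain: no path within 4 hops
  chain <- RoleNetwork(
    data.frame(tail = c("s", "a", "b", "c", "d"),
               head = c("a", "b", "c", "d", "t"), weight = 1),
    c(s = "source", a = "intermediate", b = "intermediate",
      c = "intermediate", d = "intermediate", t = "target"))
  expect_equal(nPaths(enumerateStPaths(chain, maxHops = 4)), 0L)
  expect_equal(nPaths(enumerateStPaths(chain, maxHops = 5)), 1L)
  expect_error(enumerateStPaths(chain, maxHops = 0), ">= 1")

  # tiny fixture: 4 paths, matching the independent brute-force oracle
  net <- tinyHourglass()
  ps <- enumerateStPaths(net)
  expect_equal(nPaths(ps), 4L)
  expect_setequal(vapply(pathList(ps), paste, "", collapse = "|"),
                  vapply(brutePaths(net), paste, "", collapse = "|"))
})

test_that("interior nodes may hold any role; direct S->T edges are 1-hop paths", {
  net <- RoleNetwork(
    data.frame(tail = c("s1", "s2", "x", "s1"),
               head = c("s2", "x", "t", "t"), weight = 1),
    c(s1 = "source", s2 = "source", x = "intermediate", t = "target"))
  ps <- enumerateStPaths(net)
  keys <- vapply(pathList(ps), paste, "", collapse = "|")
  expect_true(all(c("s1|s2|x|t", "s2|x|t", "s1|t") %in% keys))

  strict <- enumerateStPaths(net, strictInterior = TRUE)
  skeys <- vapply(pathList(strict), paste, "", collapse = "|")
  expect_false("s1|s2|x|t" %in% skeys)  # interior source excluded
  expect_true(all(c("s2|x|t", "s1|t") %in% skeys))
})

test_that("enumeration terminates on cycles and never repeats a node", {
  net <- RoleNetwork(
    data.frame(tail = c("s", "i1", "i2", "i2"),
               head = c("i1", "i2", "i1", "t"), weight = 1),
    c(s = "source", i1 = "intermediate", i2 = "intermediate", t = "target"))
  ps <- enumerateStPaths(net, maxHops = 4)
  expect_true(all(vapply(pathList(ps), anyDuplicated, 0L) == 0))
  expect_equal(nPaths(ps), 1L)  # s -> i1 -> i2 -> t
})

test_that("path counts match the adjacency-power walk oracle on layered DAGs", {
  for (seed in 1:15) {
    net <- layeredHourglass(nSource = 3, nWaist = 2, nTarget = 3,
                            extraIntermediates = 3, pBypass = 0.5,
                            seed = seed)
    expect_equal(nPaths(enumerateStPaths(net, maxHops = 4)),
                 walkCountOracle(net, maxHops = 4))
  }
})

test_that("enumeration order is deterministic across runs", {
  net <- layeredHourglass(pWithinClass = 0.2, seed = 42)
  net <- removeFeedbackEdges(net)$network
  a <- enumerateStPaths(net)
  b <- enumerateStPaths(net)
  expect_identical(pathList(a), pathList(b))
})

test_that("a warning is raised when feedback edges are still present", {
  net <- layeredHourglass(nSource = 2, nWaist = 1, nTarget = 2,
                          extraIntermediates = 0, pFeedback = 1, seed = 1)
  expect_warning(enumerateStPaths(net), "feedback")
})

test_that("path weighting schemes follow their definitions", {
  two <- RoleNetwork(
    data.frame(tail = c("s", "i"), head = c("i", "t"), weight = c(2, 4)),
    c(s = "source", i = "intermediate", t = "target"))
  ps <- enumerateStPaths(two)
  expect_equal(pathWeights(assignPathWeights(ps, two, "product")), 8)
  expect_equal(pathWeights(assignPathWeights(ps, two, "min")), 2)
  expect_equal(pathWeights(assignPathWeights(ps, two, "unit")), 1)

  eq <- RoleNetwork(
    data.frame(tail = c("s", "i"), head = c("i", "t"), weight = c(2, 2)),
    c(s = "source", i = "intermediate", t = "target"))
  expect_equal(pathWeights(assignPathWeights(enumerateStPaths(eq), eq, "invsum")), 1)

  three <- RoleNetwork(
    data.frame(tail = c("s", "i", "j"), head = c("i", "j", "t"),
               weight = c(5, 3, 7)),
    c(s = "source", i = "intermediate", j = "intermediate", t = "target"))
  expect_equal(pathWeights(assignPathWeights(enumerateStPaths(three), three, "min")), 3)

  # unit-weight reduction: product == unit when all edge weights are 1
  u <- layeredHourglass(weightLow = 1, weightHigh = 1, seed = 9)
  pu <- enumerateStPaths(u)
  expect_equal(pathWeights(assignPathWeights(pu, u, "product")),
               pathWeights(assignPathWeights(pu, u, "unit")))

  # strict integer validation applies only to the MET (product) scheme
  frac <- RoleNetwork(data.frame(tail = c("s", "i"), head = c("i", "t"),
                                 weight = c(2.5, 4)),
                      c(s = "source", i = "intermediate", t = "target"))
  psf <- enumerateStPaths(frac)
  expect_error(assignPathWeights(psf, frac, "product", strictInteger = TRUE),
               "integer")
  expect_equal(pathWeights(assignPathWeights(psf, frac, "product")), 10)
  expect_equal(pathWeights(assignPathWeights(psf, frac, "min",
                                             strictInteger = TRUE)), 2.5)

  # stale path set: edge no longer in the network
  gone <- RoleNetwork(data.frame(tail = "s", head = "i", weight = 1),
                      c(s = "source", i = "intermediate", t = "target"))
  expect_error(assignPathWeights(ps, gone, "product"), "stale")
})

test_that("product weights multiply under path concatenation", {
  net <- layeredHourglass(waistWeightBoost = 3, pBypass = 0.5, seed = 5)
  ps <- assignPathWeights(enumerateStPaths(net), net, "product")
  lookup <- setNames(edgeTable(net)$weight,
                     paste(edgeTable(net)$tail, edgeTable(net)$head))
  segWeight <- function(p) prod(lookup[paste(p[-length(p)], p[-1])])
  for (i in which(vapply(pathList(ps), length, 0L) >= 3)) {
    p <- pathList(ps)[[i]]
    for (cut in 2:(length(p) - 1)) {
      expect_equal(pathWeights(ps)[i],
                   segWeight(p[1:cut]) * segWeight(p[cut:length(p)]))
    }
  }
})

test_that("path weights and totals agree with the brute-force oracle", {
  net <- randomTinyNet(3)
  ps <- enumerateStPaths(net)
  for (scheme in c("unit", "product", "min", "invsum")) {
    psw <- assignPathWeights(ps, net, scheme)
    expected <- vapply(pathList(psw), function(p)
      brutePathWeight(net, p, scheme), numeric(1))
    expect_equal(pathWeights(psw), expected)
    expect_equal(totalPathWeight(psw), sum(expected))
  }
})
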