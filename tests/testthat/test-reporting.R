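test_that("cmdSummarize writes table-style summaries", {
  dir <- withr::local_tempdir()
  tabs <- tinyTables(dir)
  cfg <- runConfig(edges = tabs$edges, roles = tabs$roles,
                   outDir = file.path(dir, "out"), name = "tiny")
  sm <- cmdSummarize(cfg)
  expect_equal(sm@n, 5L)
  expect_equal(sm@m, 4L)
  expect_equal(sm@mRemovedFeedback, 0L)

  tsv <- read.delim(file.path(dir, "out", "summary.tsv"))
  expect_equal(tsv$n, 5L)
  expect_equal(tsv$m, 4L)
  expect_equal(tsv$m_after_removal, 4L)
  expect_equal(c(tsv$n_S, tsv$n_I, tsv$n_M), c(2L, 1L, 2L))
  frac <- read.delim(file.path(dir, "out", "edge_type_fractions.tsv"))
  expect_equal(sum(frac[, -1]), 1)
  expect_true(file.exists(file.path(dir, "out", "config.json")))

  # a node missing from the role table is a named, hard error
  bad <- data.frame(tail = "s1", head = "mystery", weight = 1)
  write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE, quote = FALSE)
  cfgBad <- runConfig(edges = file.path(dir, "bad.csv"), roles = tabs$roles,
                      outDir = file.path(dir, "out2"))
  expect_error(cmdSummarize(cfgBad), "mystery")
})

test_that("cmdAnalyze writes the core report, curves and flat network", {
  dir <- withr::local_tempdir()
  tabs <- tinyTables(dir)
  cfg <- runConfig(edges = tabs$edges, roles = tabs$roles,
                   outDir = file.path(dir, "out"), scheme = "product",
                   tau = 0.9)
  res <- suppressMessages(cmdAnalyze(cfg))
  expect_equal(hScoreValue(res$hscore), 0.5)

  core <- read.delim(file.path(dir, "out", "core_report.tsv"))
  expect_equal(core$node[core$rank == 1], "x")
  expect_equal(core$role[1], "intermediate")
  expect_equal(core$cumulative_coverage[1], 1)

  hs <- read.delim(file.path(dir, "out", "h_score.tsv"))
  expect_equal(hs$H[hs$tau == 0.9], 0.5)

  flat <- read.delim(file.path(dir, "out", "flat_network.tsv"))
  expect_equal(sum(flat$weight), 25)

  expect_error(runConfig(edges = tabs$edges, roles = tabs$roles, tau = 0),
               "tau")
})

test_that("unit and product schemes give byte-identical reports on unit weights", {
  dir <- withr::local_tempdir()
  tabs <- tinyTables(dir, weights = c(1, 1, 1, 1))
  outs <- lapply(c("product", "unit"), function(scheme) {
    out <- file.path(dir, scheme)
    cfg <- runConfig(edges = tabs$edges, roles = tabs$roles, outDir = out,
                     scheme = scheme)
    suppressMessages(cmdAnalyze(cfg))
    out
  })
  for (f in c("core_report.tsv", "h_score.tsv", "coverage_curve.tsv",
              "flat_network.tsv", "paths.tsv")) {
    expect_identical(readBin(file.path(outs[[1]], f), "raw", 1e6),
                     readBin(file.path(outs[[2]], f), "raw", 1e6),
                     label = f)
  }
})

test_that("re-running a config reproduces every analysis file byte-identically", {
  dir <- withr::local_tempdir()
  net <- layeredHourglass(waistWeightBoost = 6, seed = 41)
  writeNetworkTables(net, file.path(dir, "e.csv"), file.path(dir, "r.csv"))
  runTo <- function(out) {
    cfg <- runConfig(edges = file.path(dir, "e.csv"),
                     roles = file.path(dir, "r.csv"), outDir = out, seed = 5)
    suppressMessages(cmdAnalyze(cfg))
    out
  }
  a <- runTo(file.path(dir, "a")); b <- runTo(file.path(dir, "b"))
  for (f in setdiff(list.files(a), "config.json")) {  # config records outDir
    expect_identical(readBin(file.path(a, f), "raw", 1e7),
                     readBin(file.path(b, f), "raw", 1e7), label = f)
  }
})

test_that("cmdNull writes replicate scores and a JSON summary", {
  dir <- withr::local_tempdir()
  net <- layeredHourglass(weightLow = 2, weightHigh = 2, seed = 3)
  writeNetworkTables(net, file.path(dir, "e.csv"), file.path(dir, "r.csv"))
  cfg <- runConfig(edges = file.path(dir, "e.csv"),
                   roles = file.path(dir, "r.csv"),
                   outDir = file.path(dir, "null"), nReps = 12, seed = 6)
  nr <- cmdNull(cfg)
  expect_equal(pValue(nr), 1)  # all-equal weights: permutation is a no-op

  js <- jsonlite::read_json(file.path(dir, "null", "null_summary.json"))
  expect_equal(js$method, "weight_permutation")
  expect_equal(js$n_reps, 12L)
  expect_equal(js$tau, 0.9)
  expect_equal(js$p_value, 1)
  expect_equal(js$seed, 6L)
  reps <- read.delim(file.path(dir, "null", "null_replicates.tsv"))
  expect_equal(nrow(reps), 12L)

  # determinism: identical config (and seed) gives identical JSON
  cfg2 <- runConfig(edges = file.path(dir, "e.csv"),
                    roles = file.path(dir, "r.csv"),
                    outDir = file.path(dir, "null2"), nReps = 12, seed = 6)
  cmdNull(cfg2)
  expect_identical(readLines(file.path(dir, "null", "null_summary.json")),
                   readLines(file.path(dir, "null2", "null_summary.json")))
})

test_that("the default configuration mirrors the headline analysis settings", {
  cfg <- runConfig()
  expect_equal(cfg$tau, 0.9)
  expect_equal(cfg$scheme, "product")
  expect_equal(cfg$maxHops, 4L)
  expect_equal(cfg$nReps, 500L)
})

test_that("cmdSynth round-trips the generator output through the loader", {
  dir <- withr::local_tempdir()
  net <- cmdSynth(file.path(dir, "synth"), nSource = 3, nTarget = 3,
                  waistWeightBoost = 5, seed = 11)
  back <- loadNetwork(file.path(dir, "synth", "edges.csv"),
                      file.path(dir, "synth", "roles.csv"))
  expect_equal(edgeTable(back), edgeTable(net))
  spec <- jsonlite::read_json(file.path(dir, "synth", "generator_spec.json"))
  expect_equal(spec$nSource, 3L)
  expect_equal(spec$waistWeightBoost, 5L)
})
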