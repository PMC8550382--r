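#' Assemble and validate a run configuration
#'
#' Collects every knob of the analysis pipeline into one validated list.
#' The resolved configuration (plus the package version) is serialized
#' verbatim into the output directory by each `cmd*` driver, so any output
#' directory can be reproduced byte-identically by re-running with its own
#' `config.json`.
#'
#' @param edges,roles paths to the edge and role tables (or data.frames)
#' @param outDir output directory (created if missing)
#' @param scheme path weighting scheme
#' @param maxHops path length bound
#' @param tau reporting threshold
#' @param tauGrid thresholds for the H-score curve (default 0.05..1 by 0.05)
#' @param nullMethod null model for [cmdNull()]
#' @param nReps null replicates (default 500)
#' @param seed master seed
#' @param dropUnlisted,strictInterior,orderConstraint,flatCore pipeline
#'   flags, see [loadNetwork()], [enumerateStPaths()], [shuffleEdges()] and
#'   [flatCoreSize()]
#' @param name network label
#' @return a list of class `hourglassRunConfig`
#' @export
runConfig <- function(edges = NULL, roles = NULL, outDir = tempfile("hourglass_"),
                      scheme = "product", maxHops = 4L, tau = 0.9,
                      tauGrid = seq(0.05, 1, by = 0.05),
                      nullMethod = "weight_permutation", nReps = 500L,
                      seed = 1L, dropUnlisted = FALSE, strictInterior = FALSE,
                      orderConstraint = TRUE, flatCore = "greedy", name = "") {
  scheme <- match.arg(scheme, c("product", "unit", "min", "invsum"))
  nullMethod <- match.arg(nullMethod, c("weight_permutation", "edge_shuffle"))
  flatCore <- match.arg(flatCore, c("greedy", "exact"))
  if (tau <= 0 || tau > 1) stop("'tau' must be in (0, 1]")
  cfg <- list(edges = edges, roles = roles, outDir = outDir, scheme = scheme,
              maxHops = as.integer(maxHops), tau = tau, tauGrid = tauGrid,
              nullMethod = nullMethod, nReps = as.integer(nReps),
              seed = as.integer(seed), dropUnlisted = dropUnlisted,
              strictInterior = strictInterior,
              orderConstraint = orderConstraint, flatCore = flatCore,
              name = name)
  class(cfg) <- "hourglassRunConfig"
  cfg
}

.writeConfig <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(config)
  out$edges <- if (is.character(out$edges)) out$edges else "<data.frame>"
  out$roles <- if (is.character(out$roles)) out$roles else "<data.frame>"
  out$version <- as.character(utils::packageVersion("hourglassNet"))
  jsonlite::write_json(out, file.path(config$outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.loadFromConfig <- function(config) {
  if (is.null(config$edges) || is.null(config$roles))
    stop("config must provide 'edges' and 'roles' tables")
  loadNetwork(config$edges, config$roles,
              dropUnlisted = config$dropUnlisted, name = config$name)
}

#' Summarize a network from a run configuration
#'
#' Load, prune isolated nodes, remove feedback edges and write
#' `summary.tsv` (n, m, m_after_removal and per-role counts) plus
#' `edge_type_fractions.tsv` (the 3x3 tail-role by head-role fractions)
#' and `config.json` into the output directory.
#'
#' @param config a [runConfig()] list
#' @return the [NetworkSummary-class], invisibly
#' @export
cmdSummarize <- function(config) {
  .writeConfig(config)
  net <- pruneIsolated(.loadFromConfig(config))$network
  after <- removeFeedbackEdges(net)$network
  sm <- summarizeNetwork(net, after)
  writeTsv(data.frame(network = sm@name, n = sm@n, m = sm@m,
                      m_after_removal = sm@mAfterRemoval,
                      n_S = sm@nByRole[["source"]],
                      n_I = sm@nByRole[["intermediate"]],
                      n_M = sm@nByRole[["target"]]),
           file.path(config$outDir, "summary.tsv"))
  frac <- as.data.frame(sm@edgeTypeFractions)
  frac <- cbind(tail_role = rownames(sm@edgeTypeFractions), frac)
  writeTsv(frac, file.path(config$outDir, "edge_type_fractions.tsv"))
  invisible(sm)
}

#' Run the full hourglass analysis from a run configuration
#'
#' Pipeline: load, prune isolated nodes, remove feedback edges, enumerate
#' bounded source-target paths, assign path weights, compute the greedy
#' tau-core, the coverage curve, the flat network and the H-score curve.
#' Writes `core_report.tsv` (rank, node, role, marginal and cumulative
#' coverage), `coverage_curve.tsv`, `h_score.tsv` (over the tau grid),
#' `flat_network.tsv`, `paths.tsv` and `config.json`.
#'
#' @param config a [runConfig()] list
#' @return invisibly, a list with the network, path set, core, H-score
#'   result at `config$tau` and the H-score curve
#' @export
cmdAnalyze <- function(config) {
  .writeConfig(config)
  net <- pruneIsolated(.loadFromConfig(config))$network
  fb <- removeFeedbackEdges(net)
  net <- fb$network
  message(sprintf("removed %d feedback edge(s); %d edges remain",
                  fb$removed, nrow(net@edges)))
  t0 <- Sys.time()
  ps <- enumerateStPaths(net, maxHops = config$maxHops,
                         strictInterior = config$strictInterior)
  ps <- assignPathWeights(ps, net, scheme = config$scheme)
  message(sprintf("enumerated %d paths (<= %d hops) in %.2fs",
                  length(ps@paths), config$maxHops,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  core <- computeTauCore(ps, config$tau)
  flat <- buildFlatNetwork(ps)
  curve <- hScoreCurve(ps, taus = config$tauGrid, flatCore = config$flatCore)
  hs <- hScore(ps, config$tau, flatCore = config$flatCore)

  rep <- core@members
  writeTsv(data.frame(rank = rep$rank, node = rep$node,
                      role = unname(net@roles[rep$node]),
                      marginal_coverage = rep$marginal / ps@totalWeight,
                      cumulative_coverage = rep$cumulative_fraction),
           file.path(config$outDir, "core_report.tsv"))
  writeTsv(coverageCurve(ps, core), file.path(config$outDir, "coverage_curve.tsv"))
  writeTsv(curve, file.path(config$outDir, "h_score.tsv"))
  writeTsv(flat@edges, file.path(config$outDir, "flat_network.tsv"))
  writeTsv(as.data.frame(ps), file.path(config$outDir, "paths.tsv"))
  invisible(list(network = net, pathset = ps, core = core, hscore = hs,
                 curve = curve))
}

#' Run a null-model experiment from a run configuration
#'
#' Wraps [nullHDistribution()]; writes `null_replicates.tsv` (replicate,
#' h) and `null_summary.json` (method, n_reps, tau, h_empirical, p_value,
#' seed) plus `config.json`.
#'
#' @param config a [runConfig()] list
#' @return the [NullResult-class], invisibly
#' @export
cmdNull <- function(config) {
  .writeConfig(config)
  net <- pruneIsolated(.loadFromConfig(config))$network
  net <- removeFeedbackEdges(net)$network
  nr <- nullHDistribution(net, method = config$nullMethod,
                          nReps = config$nReps, tau = config$tau,
                          maxHops = config$maxHops, scheme = config$scheme,
                          seed = config$seed, flatCore = config$flatCore)
  writeTsv(data.frame(replicate = seq_len(nr@nReps), h = nr@hNull),
           file.path(config$outDir, "null_replicates.tsv"))
  jsonlite::write_json(
    list(method = nr@method, n_reps = nr@nReps, tau = nr@tau,
         scheme = nr@scheme, h_empirical = nr@hEmpirical,
         p_value = nr@pValue, seed = nr@seed),
    file.path(config$outDir, "null_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(nr)
}

#' Generate a synthetic layered network and write its tables
#'
#' Calls [layeredHourglass()] with the supplied generator parameters,
#' writes `edges.csv` and `roles.csv` in the loader's format plus a
#' `generator_spec.json` sidecar recording every parameter.
#'
#' @param outDir output directory
#' @param ... parameters passed to [layeredHourglass()]
#' @return the generated [RoleNetwork-class], invisibly
#' @export
cmdSynth <- function(outDir, ...) {
  spec <- utils::modifyList(as.list(formals(layeredHourglass)), list(...))
  net <- do.call(layeredHourglass, spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeNetworkTables(net, file.path(outDir, "edges.csv"),
                     file.path(outDir, "roles.csv"))
  jsonlite::write_json(spec, file.path(outDir, "generator_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(net)
}
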