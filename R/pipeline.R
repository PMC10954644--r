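# Configuration-driven entry points: simulate -> infer -> train -> forecast.
#
# A run configuration is a plain named list (or a YAML file of one); every
# run writes a resolved copy of the configuration next to its outputs so an
# artifact directory is self-describing.

.defaultRunConfig <- list(
  seed = 1L,
  outDir = "hogrc-run",
  system = list(name = "lorenz63", m = 1L, dt = NULL, params = list(),
                steps = 5000L, transient = 1000L, noise = 0,
                noiseMode = "per-variable-std"),
  network = list(kind = "default5", degree = 2, edges = NULL, file = NULL),
  reservoir = list(),
  inference = list(),
  evaluation = list(methods = c("rc", "prc", "hogrc"), nStarts = 50L,
                    horizon = 1000L, epsR = 0.01, trainFrac = 0.6,
                    warmLen = 200L),
  structure = "infer",
  data = NULL
)

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a run configuration
#'
#' @param config a named list, or the path of a YAML file containing one;
#'   missing fields take package defaults.
#' @return The resolved configuration list.
#' @export
loadRunConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(.defaultRunConfig, config)
  if (!cfg$system$name %in% names(.systemDefs))
    stopf("config field system.name: unknown system '%s'", cfg$system$name)
  for (fld in c("steps", "transient")) {
    v <- cfg$system[[fld]]
    if (!is.numeric(v) || v < 0) stopf("config field system.%s must be >= 0", fld)
  }
  if (!is.numeric(cfg$seed)) stopf("config field seed must be an integer")
  cfg
}

resolveSystem <- function(cfg) {
  s <- cfg$system
  sys <- systemParams(s$name, m = s$m %||% 1L, dt = s$dt,
                      params = s$params %||% list(), seed = cfg$seed)
  net <- NULL
  if (sys@name != "lorenz63") {
    nw <- cfg$network
    net <- if (!is.null(nw$file)) readEdgeList(nw$file)
    else if (identical(nw$kind, "default5")) defaultNetwork5(cfg$seed)
    else generateNetwork(nw$kind, m = sys@m, degree = nw$degree %||% 2,
                         edges = nw$edges, seed = cfg$seed)
    if (sys@name == "kuramoto_ho" && nrow(net@triangles) == 0)
      net <- withTriangles(net)
  }
  list(sys = sys, net = net)
}

#' Simulate a configured system to disk
#'
#' Writes the trajectory CSV (+ JSON sidecar with dt, seed and parameters),
#' the coupling-network edge list if any, and the resolved configuration.
#' Idempotent given the seed.
#'
#' @param config run configuration (list or YAML path), see
#'   [loadRunConfig()].
#' @return Invisibly, a list with the written paths and the
#'   [Trajectory-class].
#' @export
cmdSimulate <- function(config = list()) {
  cfg <- loadRunConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  rs <- resolveSystem(cfg)
  traj <- simulateSystem(rs$sys, rs$net, steps = cfg$system$steps,
                         transient = cfg$system$transient, seed = cfg$seed)
  if (cfg$system$noise > 0)
    traj <- addObservationNoise(traj, cfg$system$noise,
                                mode = cfg$system$noiseMode, seed = cfg$seed)
  dataPath <- file.path(cfg$outDir, "trajectory.csv")
  writeTrajectoryCsv(traj, dataPath,
                     meta = list(system = rs$sys@name, seed = cfg$seed,
                                 m = rs$sys@m))
  netPath <- NULL
  if (!is.null(rs$net)) {
    netPath <- file.path(cfg$outDir, "network.edges")
    writeEdgeList(rs$net, netPath)
  }
  yaml::write_yaml(cfg, file.path(cfg$outDir, "config.yaml"))
  invisible(list(data = dataPath, network = netPath, traj = traj))
}

#' Run the full pipeline
#'
#' Simulate (or load) data, obtain the higher-order structure (inferred
#' from the training split, taken from the ground truth, or read from a
#' hyperedge-list file), train the requested methods, and score them by
#' closed-loop forecasting from test anchors.  All stage outputs are
#' persisted under \code{outDir}.
#'
#' @param config run configuration (list or YAML path).  Field
#'   \code{structure} selects the structure source: \code{"infer"},
#'   \code{"true"}, or a hyperedge-list path; field
#'   \code{evaluation$methods} the model families.
#' @return Invisibly, a list with the structure, the comparison table and
#'   the output paths.
#' @export
runPipeline <- function(config = list()) {
  cfg <- loadRunConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  rs <- resolveSystem(cfg)
  traj <- if (!is.null(cfg$data)) readTrajectoryCsv(cfg$data)
  else cmdSimulate(cfg)$traj
  trainEnd <- floor(cfg$evaluation$trainFrac * nSteps(traj))
  trainTraj <- windowTrajectory(traj, seq_len(trainEnd))

  icfg <- do.call(inferenceConfig, cfg$inference[setdiff(names(cfg$inference),
                                                         "reservoir")])
  if (!is.null(cfg$inference$reservoir))
    icfg@reservoir <- do.call(reservoirConfig,
                              mergeConfig(list(n = 120L, washout = 100L,
                                               seed = cfg$seed),
                                          cfg$inference$reservoir))
  else icfg@reservoir@seed <- as.integer(cfg$seed)

  structure <- if (identical(cfg$structure, "true")) {
    trueStructure(rs$sys, rs$net)
  } else if (identical(cfg$structure, "infer")) {
    inferStructure(trainTraj, cfg = icfg)
  } else {
    readHyperedges(cfg$structure, nodes = varNames(traj))
  }
  writeHyperedges(structure, file.path(cfg$outDir, "structure.hyperedges"))
  traces <- attr(structure, "traces")
  if (!is.null(traces))
    jsonlite::write_json(traces, file.path(cfg$outDir, "inference-trace.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")

  rcfg <- do.call(reservoirConfig,
                  mergeConfig(list(seed = cfg$seed), cfg$reservoir))
  ev <- cfg$evaluation
  cmp <- runComparison(traj, structure, methods = ev$methods, cfg = rcfg,
                       nStarts = ev$nStarts, horizon = ev$horizon,
                       trainFrac = ev$trainFrac, warmLen = ev$warmLen,
                       epsR = ev$epsR, seed = cfg$seed)
  write.csv(cmp, file.path(cfg$outDir, "comparison.csv"), row.names = FALSE)
  jsonlite::write_json(summarizeComparison(cmp),
                       file.path(cfg$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  yaml::write_yaml(cfg, file.path(cfg$outDir, "config.yaml"))
  invisible(list(structure = structure, comparison = cmp, outDir = cfg$outDir))
}

#' Generate small bundled example datasets
#'
#' Short trajectories (default 600 steps) of every benchmark system, for
#' examples and quick experiments.  Deterministic given the seed.
#'
#' @param seed master seed.
#' @param dir output directory.
#' @param steps samples per system.
#' @return Named character vector of the CSV paths.
#' @export
makeFixtures <- function(seed = 1L, dir = tempfile("hogrc-fixtures"),
                         steps = 600L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (name in names(.systemDefs)) {
    m <- if (name == "lorenz63") 1L else 5L
    sys <- systemParams(name, m = m, seed = seed)
    net <- if (name == "lorenz63") NULL else defaultNetwork5(seed)
    if (name == "kuramoto_ho" && !is.null(net)) net <- withTriangles(net)
    traj <- simulateSystem(sys, net, steps = steps, transient = 500,
                           seed = seed)
    path <- file.path(dir, paste0(name, ".csv"))
    writeTrajectoryCsv(traj, path, meta = list(system = name, seed = seed))
    out[name] <- path
  }
  out
}
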