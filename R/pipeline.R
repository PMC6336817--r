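#' Pipeline configuration
#'
#' Bundles the inputs and thresholds of the discovery and cascade workflows.
#' Exactly one of `simulation` (a [SimulationConfig-class]) or `cohortFiles`
#' (a list of `list(expr = , samples = )` TSV path pairs, see
#' [readCohort()]) must be supplied. All thresholds default to the study's
#' printed values: fold change > 2, FDR < 0.05, r > 0.5, 20 kb window.
#'
#' @param simulation a [SimulationConfig-class], or `NULL`.
#' @param cohortFiles list of per-cohort file-path pairs, or `NULL`.
#' @param tfs character vector of TF identifiers (required with
#'   `cohortFiles`; defaults to the simulation's planted TFs otherwise).
#' @param fcThreshold,fdrThreshold,rThreshold,window positive thresholds.
#' @param seed integer seed for the run.
#' @param outDir directory for stage outputs, or `NULL` to skip writing.
#' @return validated config (class `"PipelineConfig"`).
#' @export
pipelineConfig <- function(simulation = NULL, cohortFiles = NULL, tfs = NULL,
                           fcThreshold = 2, fdrThreshold = 0.05,
                           rThreshold = 0.5, window = 20000, seed = 1,
                           outDir = NULL) {
  if (is.null(simulation) == is.null(cohortFiles))
    stop("supply exactly one of 'simulation' or 'cohortFiles'")
  for (th in c(fcThreshold = fcThreshold, fdrThreshold = fdrThreshold,
               rThreshold = rThreshold, window = window))
    if (!is.numeric(th) || th <= 0) stop("thresholds must be positive")
  if (!is.null(simulation)) {
    stopifnot(is(simulation, "SimulationConfig"))
    if (is.null(tfs)) tfs <- simulation@plantedTFs
  } else if (is.null(tfs)) {
    stop("'tfs' is required when reading cohorts from files")
  }
  structure(list(simulation = simulation, cohortFiles = cohortFiles,
                 tfs = as.character(tfs), fcThreshold = fcThreshold,
                 fdrThreshold = fdrThreshold, rThreshold = rThreshold,
                 window = window, seed = as.integer(seed), outDir = outDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Expected keys: either `simulation:` (fields of [simulationConfig()]) or
#' `cohortFiles:` (list of `expr`/`samples` path pairs plus a `tfListFile`),
#' and optional `thresholds:` (`fc`, `fdr`, `r`, `window`), `seed`, `outDir`.
#'
#' @param path YAML file path.
#' @return a `"PipelineConfig"` (see [pipelineConfig()]).
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation)) do.call(simulationConfig, y$simulation)
  tfs <- if (!is.null(y$tfListFile)) readGeneList(y$tfListFile)
  th <- y$thresholds
  pipelineConfig(
    simulation = sim, cohortFiles = y$cohortFiles, tfs = tfs,
    fcThreshold = th$fc %||% 2, fdrThreshold = th$fdr %||% 0.05,
    rThreshold = th$r %||% 0.5, window = th$window %||% 20000,
    seed = y$seed %||% 1, outDir = y$outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

loadCohorts <- function(config) {
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    ## the pipeline seed overrides the simulation seed so one config can be
    ## replicated across seeds
    sim@seed <- config$seed
    simulateCohorts(sim)
  } else {
    cohorts <- lapply(config$cohortFiles, function(f)
      readCohort(f$expr, f$samples))
    names(cohorts) <- vapply(cohorts, cohortName, character(1))
    list(cohorts = cohorts, truth = NULL)
  }
}

#' Run the discovery workflow
#'
#' Executes the full master-regulator discovery route: per-cohort
#' differential up-calls ([callUpregulated()]), cross-cohort intersection
#' ([intersectUp()]), consensus network over the shared upregulated genes
#' ([buildConsensus()]), community detection ([detectCommunities()]) and
#' weighted-degree TF ranking in the top community ([rankMasterTFs()]).
#' For simulated inputs the report carries recovery metrics against the
#' planted ground truth (rank of the planted master TF, per-cohort up-call
#' precision and recall). Deterministic given the config seed; if
#' `config$outDir` is set, stage outputs (per-cohort DE tables, intersection
#' list, ranking, report JSON) are written there.
#'
#' @param config a `"PipelineConfig"` from [pipelineConfig()].
#' @return A `"DiscoveryReport"`: a structured list with elements
#'   `deCounts`, `intersection`, `network`, `ranking`, `recovery` (or
#'   `NULL`), `noCandidates`, `seed`, `thresholds`.
#' @export
runDiscovery <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  loaded <- loadCohorts(config)
  cohorts <- loaded$cohorts
  truth <- loaded$truth

  de <- lapply(cohorts, callUpregulated,
               fcThreshold = config$fcThreshold,
               fdrThreshold = config$fdrThreshold)
  upSets <- lapply(de, upGenes)
  shared <- if (length(upSets) >= 2L) intersectUp(upSets)
            else sort(upSets[[1]])
  tfsIn <- sort(intersect(shared, config$tfs))
  nonTF <- setdiff(shared, config$tfs)

  noCandidates <- length(shared) == 0L || length(tfsIn) == 0L
  if (!noCandidates) {
    net <- buildConsensus(cohorts, tfsIn, nonTF,
                          threshold = config$rThreshold)
    part <- detectCommunities(net, seed = config$seed)
    ranking <- rankMasterTFs(net, part)
    networkSummary <- list(nodes = nrow(net@nodes), edges = nrow(net@edges),
                           communities = length(unique(part@membership)),
                           modularity = part@modularity)
  } else {
    net <- NULL; part <- NULL
    ranking <- data.frame(tf = character(0), community = integer(0),
                          weightedDegree = integer(0))
    networkSummary <- list(nodes = 0L, edges = 0L, communities = 0L,
                           modularity = NA_real_)
  }

  recovery <- NULL
  if (!is.null(truth)) {
    recall <- vapply(names(upSets), function(nm) {
      planted <- truth@perCohortUp[[nm]]
      length(intersect(upSets[[nm]], planted)) / length(planted)
    }, numeric(1))
    precision <- vapply(upSets, function(s) {
      if (!length(s)) return(NA_real_)
      length(intersect(s, truth@sharedUp)) / length(s)
    }, numeric(1))
    recovery <- list(
      masterTF = truth@masterTF,
      masterTFRank = if (truth@masterTF %in% ranking$tf)
        match(truth@masterTF, ranking$tf) else NA_integer_,
      recall = recall, precision = precision)
  }

  report <- structure(list(
    deCounts = vapply(upSets, length, integer(1)),
    intersection = shared,
    network = networkSummary,
    ranking = ranking,
    recovery = recovery,
    noCandidates = noCandidates,
    seed = config$seed,
    thresholds = config[c("fcThreshold", "fdrThreshold", "rThreshold",
                          "window")]), class = "DiscoveryReport")

  if (!is.null(config$outDir))
    writeDiscoveryReport(report, de, config$outDir)
  report
}

#' Run the co-factor cascade workflow
#'
#' Differential up-calls and intersection as in [runDiscovery()], followed by
#' direct-target definition ([directTargets()]: shared upregulated genes with
#' a regulator peak within the window of their TSS) and the three-filter
#' cascade ([cofactorCascade()]). With a simulation config, genome fixtures
#' are generated with [simulateGenomeFixtures()]; otherwise supply `peaks`,
#' `tss`, `motifGenes` and `interactors`.
#'
#' @param config a `"PipelineConfig"`.
#' @param peaks,tss,motifGenes,interactors cascade inputs for the real-data
#'   route (ignored when `config$simulation` is set).
#' @return A `"CascadeReport"`: list with `directTargets`, `survivors`,
#'   `stages`, `recovery` (or `NULL`), `seed`.
#' @export
runCascade <- function(config, peaks = NULL, tss = NULL, motifGenes = NULL,
                       interactors = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  loaded <- loadCohorts(config)
  cohorts <- loaded$cohorts
  truth <- loaded$truth

  de <- lapply(cohorts, callUpregulated,
               fcThreshold = config$fcThreshold,
               fdrThreshold = config$fdrThreshold)
  upSets <- lapply(de, upGenes)
  shared <- if (length(upSets) >= 2L) intersectUp(upSets)
            else sort(upSets[[1]])

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim@seed <- config$seed
    fx <- simulateGenomeFixtures(sim, truth)
    peaks <- fx$peaks$tf
    tss <- fx$tss
    motifGenes <- fx$motifGenes
    interactors <- fx$interactors
  }
  if (is.null(peaks) || is.null(tss) || is.null(motifGenes) ||
      is.null(interactors))
    stop("cascade stage needs peaks, tss, motifGenes and interactors")

  direct <- directTargets(shared, peaks, tss, window = config$window)
  casc <- cofactorCascade(direct, motifGenes, interactors)

  recovery <- NULL
  if (!is.null(truth))
    recovery <- list(cofactor = truth@cofactor,
                     exact = identical(casc$survivors, truth@cofactor))

  structure(list(directTargets = direct, survivors = casc$survivors,
                 stages = casc$stages, recovery = recovery,
                 seed = config$seed), class = "CascadeReport")
}

writeDiscoveryReport <- function(report, de, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(de)) {
    df <- as.data.frame(de[[nm]])
    utils::write.table(data.frame(gene = rownames(df), df),
                       file.path(dir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeGeneList(report$intersection, file.path(dir, "intersection.txt"))
  utils::write.table(report$ranking, file.path(dir, "tf_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(reportAsList(report),
                       file.path(dir, "discovery_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

reportAsList <- function(report) {
  r <- unclass(report)
  r$deCounts <- as.list(r$deCounts)
  if (!is.null(r$recovery)) {
    r$recovery$recall <- as.list(r$recovery$recall)
    r$recovery$precision <- as.list(r$recovery$precision)
  }
  r
}

#' @export
print.DiscoveryReport <- function(x, ...) {
  cat("DiscoveryReport (seed", x$seed, ")\n")
  cat("  per-cohort up-calls:",
      paste(sprintf("%s=%d", names(x$deCounts), x$deCounts),
            collapse = ", "), "\n")
  cat("  shared upregulated genes:", length(x$intersection), "\n")
  if (x$noCandidates) {
    cat("  no candidates: intersection empty or contains no TF\n")
  } else {
    cat(sprintf("  network: %d nodes, %d edges, %d communities, Q = %.3f\n",
                x$network$nodes, x$network$edges, x$network$communities,
                x$network$modularity))
    if (nrow(x$ranking))
      cat("  top-ranked TF:", x$ranking$tf[1],
          "( weighted degree", x$ranking$weightedDegree[1], ")\n")
  }
  if (!is.null(x$recovery))
    cat("  planted master TF", x$recovery$masterTF, "rank:",
        x$recovery$masterTFRank, "| mean recall",
        sprintf("%.3f", mean(x$recovery$recall)), "| mean precision",
        sprintf("%.3f", mean(x$recovery$precision, na.rm = TRUE)), "\n")
  invisible(x)
}

#' @export
print.CascadeReport <- function(x, ...) {
  cat("CascadeReport (seed", x$seed, ")\n")
  print(x$stages, row.names = FALSE)
  cat("  survivors:", if (length(x$survivors))
    paste(x$survivors, collapse = ", ") else "(none)", "\n")
  if (!is.null(x$recovery))
    cat("  planted cofactor", x$recovery$cofactor, "recovered exactly:",
        x$recovery$exact, "\n")
  invisible(x)
}
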