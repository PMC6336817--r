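#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' ExpressionCohort: one cohort of nonnegative expression values
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a genes x samples
#' matrix of RPKM-like nonnegative expression values (assay `"exprs"`), a
#' two-level per-sample group factor in `colData(x)$group` (e.g. NET vs
#' non-NET, or tumor vs normal), and the cohort name in its metadata. The
#' first factor level is treated as the reference (e.g. non-NET) and the
#' second as the case throughout the package.
#'
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (any(!is.finite(m)))
      msg <- c(msg, "expression values must be finite")
    else if (any(m < 0))
      msg <- c(msg, "expression values must be nonnegative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  grp <- SummarizedExperiment::colData(object)$group
  if (is.null(grp) || !is.factor(grp))
    msg <- c(msg, "colData(x)$group must be a factor")
  else if (nlevels(grp) != 2L)
    msg <- c(msg, "group must have exactly two levels")
  else if (!all(levels(grp) %in% as.character(grp)))
    msg <- c(msg, "both group levels must be present among samples")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCohort
#'
#' @param exprs numeric matrix, genes in rows, samples in columns, with row
#'   and column names; values must be nonnegative and finite.
#' @param group per-sample two-level factor (or vector coerced to one). The
#'   first level is the reference group, the second the case group.
#' @param cohortName single string naming the cohort.
#' @return An [ExpressionCohort-class] object.
#' @examples
#' m <- matrix(rpois(40, 10), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' ec <- ExpressionCohort(m, rep(c("nonNET", "NET"), each = 5), "demo")
#' cohortName(ec)
#' @export
ExpressionCohort <- function(exprs, group, cohortName = "cohort") {
  exprs <- as.matrix(exprs)
  if (!is.factor(group)) group <- factor(group)
  group <- droplevels(group)
  if (length(group) != ncol(exprs))
    stop("length(group) must equal the number of samples (columns)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs),
    colData = S4Vectors::DataFrame(group = group, row.names = colnames(exprs)))
  S4Vectors::metadata(se)$cohortName <- as.character(cohortName)[1]
  new("ExpressionCohort", se)
}

#' Simulation configuration for synthetic multi-cohort expression data
#'
#' Defines the study conditions the simulator emulates: the number of cohorts,
#' gene universe size, arm sizes, the planted cross-cohort upregulated gene
#' set, the transcription factors among them, the TF-driven correlated module,
#' the planted NET shift (log2 units), the latent-factor loading that controls
#' within-module correlation, and the log-scale noise standard deviation.
#'
#' Pairwise Pearson correlation between module genes (on the log scale, NET
#' samples) has expectation `moduleRho^2`.
#'
#' @slot nCohorts,genesTotal,nNet,nNonNet,nPlantedUp,moduleSize integers
#' @slot plantedTFs character gene identifiers flagged as TFs (all planted
#'   in the upregulated set; the first is the master regulator)
#' @slot effectLog2FC,moduleRho,noiseSD numeric
#' @slot seed integer RNG seed; identical config + seed gives bitwise
#'   identical output
#' @export
setClass("SimulationConfig", representation(
  nCohorts = "integer", genesTotal = "integer",
  nNet = "integer", nNonNet = "integer",
  nPlantedUp = "integer", plantedTFs = "character",
  moduleSize = "integer", effectLog2FC = "numeric",
  moduleRho = "numeric", noiseSD = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  msg <- character()
  if (object@nCohorts < 1L) msg <- c(msg, bad("nCohorts", "must be >= 1"))
  if (object@genesTotal < 1L) msg <- c(msg, bad("genesTotal", "must be >= 1"))
  if (object@nNet < 1L) msg <- c(msg, bad("nNet", "must be >= 1"))
  if (object@nNonNet < 1L) msg <- c(msg, bad("nNonNet", "must be >= 1"))
  if (object@nPlantedUp > object@genesTotal)
    msg <- c(msg, bad("nPlantedUp", "must not exceed genesTotal"))
  if (object@moduleSize > object@nPlantedUp)
    msg <- c(msg, bad("moduleSize", "must not exceed nPlantedUp"))
  if (object@moduleSize < 1L) msg <- c(msg, bad("moduleSize", "must be >= 1"))
  if (length(object@plantedTFs) < 1L ||
      anyDuplicated(object@plantedTFs))
    msg <- c(msg, bad("plantedTFs", "must be a non-empty set of unique ids"))
  if (length(object@plantedTFs) > object@nPlantedUp)
    msg <- c(msg, bad("plantedTFs", "more TFs than planted upregulated genes"))
  if (object@moduleRho < 0 || object@moduleRho >= 1)
    msg <- c(msg, bad("moduleRho", "must lie in [0, 1)"))
  if (object@noiseSD <= 0) msg <- c(msg, bad("noiseSD", "must be > 0"))
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nCohorts number of independent cohorts.
#' @param genesTotal size of the gene universe.
#' @param nNet,nNonNet samples per arm in each cohort.
#' @param nPlantedUp number of genes planted as upregulated in the NET arm of
#'   every cohort (includes the planted TFs).
#' @param plantedTFs gene identifiers flagged as transcription factors; the
#'   first entry is the planted master regulator.
#' @param moduleSize number of genes (master TF included) sharing the latent
#'   co-expression factor in NET samples.
#' @param effectLog2FC planted NET shift, log2 units.
#' @param moduleRho latent-factor loading in `[0, 1)`; pairwise module
#'   correlation has expectation `moduleRho^2`.
#' @param noiseSD log2-scale residual standard deviation.
#' @param seed integer RNG seed.
#' @export
simulationConfig <- function(nCohorts = 3, genesTotal = 500,
                             nNet = 20, nNonNet = 20,
                             nPlantedUp = 30,
                             plantedTFs = sprintf("TF%02d", 1:9),
                             moduleSize = 12, effectLog2FC = 2,
                             moduleRho = 0.9, noiseSD = 1, seed = 1) {
  new("SimulationConfig",
      nCohorts = as.integer(nCohorts), genesTotal = as.integer(genesTotal),
      nNet = as.integer(nNet), nNonNet = as.integer(nNonNet),
      nPlantedUp = as.integer(nPlantedUp),
      plantedTFs = as.character(plantedTFs),
      moduleSize = as.integer(moduleSize),
      effectLog2FC = as.numeric(effectLog2FC),
      moduleRho = as.numeric(moduleRho), noiseSD = as.numeric(noiseSD),
      seed = as.integer(seed))
}

#' Planted ground truth of a simulated study
#'
#' @slot perCohortUp named list of per-cohort planted upregulated gene sets.
#' @slot sharedUp cross-cohort intersection of the planted sets.
#' @slot masterTF identifier of the planted master regulator.
#' @slot moduleMembers genes sharing the latent co-expression factor
#'   (contains `masterTF`).
#' @slot cofactor the gene the three-filter cascade should recover.
#' @slot targetPeakGenes genes given a binding peak within the proximity
#'   window of their TSS.
#' @export
setClass("GroundTruth", representation(
  perCohortUp = "list", sharedUp = "character", masterTF = "character",
  moduleMembers = "character", cofactor = "character",
  targetPeakGenes = "character"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!object@masterTF %in% object@moduleMembers)
    msg <- c(msg, "masterTF must be a module member")
  ok <- vapply(object@perCohortUp,
               function(s) all(object@sharedUp %in% s), logical(1))
  if (!all(ok))
    msg <- c(msg, "sharedUp must be contained in every per-cohort up set")
  if (length(msg)) msg else TRUE
})

#' Consensus co-expression network
#'
#' Weighted undirected graph over transcription-factor (TF) and non-TF gene
#' nodes. An edge exists only between TF-gene or TF-TF pairs, and its integer
#' weight is the correlation count: the number of cohorts in which the pair's
#' Pearson correlation exceeds the threshold (signed, strict). Per-cohort r
#' values are retained alongside each edge.
#'
#' @slot nodes data.frame with columns `node` and `isTF`.
#' @slot edges data.frame with columns `nodeA`, `nodeB`, `weight`, and one
#'   `r.<cohort>` column per cohort.
#' @slot nDatasets number of cohorts the network consolidates.
#' @export
setClass("ConsensusNetwork", representation(
  nodes = "data.frame", edges = "data.frame", nDatasets = "integer"))

setValidity("ConsensusNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$weight < 1L) || any(e$weight > object@nDatasets))
      msg <- c(msg, "edge weights must lie in [1, nDatasets]")
    if (any(e$nodeA == e$nodeB)) msg <- c(msg, "self-edges are not allowed")
    tf <- object@nodes$node[object@nodes$isTF]
    if (any(!(e$nodeA %in% tf | e$nodeB %in% tf)))
      msg <- c(msg, "every edge must touch at least one TF node")
  }
  if (length(msg)) msg else TRUE
})

#' Community partition of a consensus network
#'
#' @slot membership named integer vector, one community label per node.
#' @slot modularity weighted modularity of the partition (in `[-0.5, 1]`).
#' @export
setClass("CommunityPartition", representation(
  membership = "integer", modularity = "numeric"))

#' Per-sample signature score table
#'
#' Per-sample sum of per-gene z-scores over a gene signature. When every
#' signature gene is present and non-constant, the scores sum to zero across
#' the cohort's samples by construction.
#'
#' @slot scores named numeric vector (one score per sample).
#' @slot cohortName,signatureName character scalars.
#' @slot nGenesUsed number of signature genes found in the cohort.
#' @slot missingGenes signature genes absent from the cohort.
#' @export
setClass("ScoreTable", representation(
  scores = "numeric", cohortName = "character", signatureName = "character",
  nGenesUsed = "integer", missingGenes = "character"))
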