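#' Accessors for package classes
#'
#' `cohortName()` returns the cohort label of an [ExpressionCohort-class];
#' `exprMatrix()` its expression matrix; `sampleGroups()` its two-level group
#' factor. `scores()` extracts the named per-sample score vector of a
#' [ScoreTable-class].
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cohortName", function(x) standardGeneric("cohortName"))

#' @rdname accessors
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setMethod("cohortName", "ExpressionCohort", function(x)
  S4Vectors::metadata(x)$cohortName)

#' @rdname accessors
#' @export
setMethod("exprMatrix", "ExpressionCohort", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname accessors
#' @export
setMethod("sampleGroups", "ExpressionCohort", function(x)
  SummarizedExperiment::colData(x)$group)

#' @rdname accessors
#' @export
setMethod("scores", "ScoreTable", function(x) x@scores)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nCohorts, "cohort(s),",
      object@genesTotal, "genes,", object@nNet, "+", object@nNonNet,
      "samples/arm\n")
  cat("  planted up:", object@nPlantedUp, "genes incl.",
      length(object@plantedTFs), "TFs; module size", object@moduleSize, "\n")
  cat(sprintf("  effectLog2FC = %g, moduleRho = %g, noiseSD = %g, seed = %d\n",
              object@effectLog2FC, object@moduleRho, object@noiseSD,
              object@seed))
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: master TF", object@masterTF, "|",
      length(object@moduleMembers), "module genes |",
      length(object@sharedUp), "shared upregulated genes\n")
  cat("  cofactor:", object@cofactor, "| target peak genes:",
      length(object@targetPeakGenes), "\n")
})

setMethod("show", "ConsensusNetwork", function(object) {
  cat("ConsensusNetwork:", nrow(object@nodes), "nodes (",
      sum(object@nodes$isTF), "TFs ),", nrow(object@edges), "edges over",
      object@nDatasets, "dataset(s)\n")
})

setMethod("show", "CommunityPartition", function(object) {
  cat("CommunityPartition:", length(unique(object@membership)),
      "communities over", length(object@membership), "nodes; modularity =",
      format(object@modularity, digits = 4), "\n")
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", object@signatureName, "scores for",
      length(object@scores), "samples of", object@cohortName,
      "(", object@nGenesUsed, "genes used )\n")
})
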