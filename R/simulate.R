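#' @importFrom stats rnorm runif
NULL

## Gene universe: planted TFs first, then generic gene ids.
geneUniverse <- function(config) {
  nOther <- config@genesTotal - length(config@plantedTFs)
  c(config@plantedTFs, sprintf("G%04d", seq_len(nOther)))
}

#' Simulate multi-cohort expression data with planted structure
#'
#' Generates `nCohorts` independent NET vs non-NET cohorts from a log-normal
#' model: log2 expression = per-gene baseline + planted group shift (for the
#' planted upregulated genes, NET arm only) + `moduleRho` x latent factor
#' (module genes, NET arm only) + Gaussian noise, exponentiated back to an
#' RPKM-like scale (values never exactly zero). Module genes thereby attain a
#' pairwise Pearson correlation of expectation `moduleRho^2` on the log scale
#' within the NET arm, while all other genes are exchangeable noise.
#'
#' All planted TFs are part of the planted upregulated set, mirroring a
#' cross-cancer comparison in which a handful of TFs recur among the shared
#' upregulated genes; the first TF drives the module and is the planted master
#' regulator.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `cohorts` (list of [ExpressionCohort-class])
#'   and `truth` (a [GroundTruth-class]).
#' @examples
#' sim <- simulateCohorts(simulationConfig(nCohorts = 1, genesTotal = 50,
#'                                         nPlantedUp = 12, moduleSize = 5,
#'                                         plantedTFs = c("TF01", "TF02")))
#' sim$truth
#' @export
simulateCohorts <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)

  genes <- geneUniverse(config)
  nTF <- length(config@plantedTFs)
  nonTF <- setdiff(genes, config@plantedTFs)
  upSet <- c(config@plantedTFs, nonTF[seq_len(config@nPlantedUp - nTF)])
  masterTF <- config@plantedTFs[1]
  moduleNonTF <- setdiff(upSet, config@plantedTFs)[
    seq_len(config@moduleSize - 1L)]
  module <- c(masterTF, moduleNonTF)
  cofactor <- if (length(moduleNonTF)) moduleNonTF[1] else masterTF
  ## half of the planted up genes carry a proximal peak (cofactor always does)
  targetPeakGenes <- sort(unique(c(
    cofactor, masterTF, upSet[seq(1L, length(upSet), by = 2L)])))

  baseline <- stats::runif(config@genesTotal, 3, 8)
  names(baseline) <- genes
  isUp <- genes %in% upSet
  modIdx <- match(module, genes)

  nS <- config@nNet + config@nNonNet
  group <- factor(rep(c("nonNET", "NET"), c(config@nNonNet, config@nNet)),
                  levels = c("nonNET", "NET"))
  netCols <- which(group == "NET")

  cohorts <- vector("list", config@nCohorts)
  for (k in seq_len(config@nCohorts)) {
    eps <- matrix(stats::rnorm(config@genesTotal * nS),
                  nrow = config@genesTotal)
    z <- eps
    if (config@moduleRho > 0) {
      f <- stats::rnorm(config@nNet)
      z[modIdx, netCols] <-
        config@moduleRho * matrix(f, nrow = length(modIdx),
                                  ncol = config@nNet, byrow = TRUE) +
        sqrt(1 - config@moduleRho^2) * eps[modIdx, netCols]
    }
    shift <- outer(isUp, group == "NET") * config@effectLog2FC
    logx <- baseline + shift + config@noiseSD * z
    x <- pmax(2^logx, 1e-6)
    dimnames(x) <- list(genes, sprintf("c%d_s%02d", k, seq_len(nS)))
    cohorts[[k]] <- ExpressionCohort(x, group, sprintf("cohort%d", k))
  }
  names(cohorts) <- vapply(cohorts, cohortName, character(1))

  perCohortUp <- stats::setNames(rep(list(sort(upSet)), config@nCohorts),
                                 names(cohorts))
  truth <- new("GroundTruth", perCohortUp = perCohortUp,
               sharedUp = sort(upSet), masterTF = masterTF,
               moduleMembers = module, cofactor = cofactor,
               targetPeakGenes = targetPeakGenes)
  list(cohorts = cohorts, truth = truth)
}

#' Simulate genome annotation and peak fixtures matching a ground truth
#'
#' Places one gene per 100 kb on a synthetic contig `chrS1` with alternating
#' strands, derives one TSS per gene (strand-aware), and builds two peak sets:
#' `tf` peaks whose midpoints lie within the proximity window (default sense:
#' 20 kb) of the TSSs of `targetPeakGenes`, and `control` peaks placed 30 kb
#' from the TSSs of non-target genes (hence outside any gene's window given
#' the 100 kb spacing). Motif-gene and interactor lists are constructed so
#' that their triple intersection with the planted direct targets is exactly
#' the planted cofactor.
#'
#' @param config a [SimulationConfig-class].
#' @param truth the [GroundTruth-class] produced by [simulateCohorts()] from
#'   the same config.
#' @return list with elements `genes` (stranded gene intervals, `GRanges`),
#'   `tss` (width-1 `GRanges`, one per gene), `peaks` (list of `GRanges`:
#'   `tf`, `control`), `motifGenes` and `interactors` (character vectors).
#' @export
simulateGenomeFixtures <- function(config, truth) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "GroundTruth"))
  set.seed(config@seed + 104729L)

  genes <- geneUniverse(config)
  n <- length(genes)
  start0 <- 50000 + (seq_len(n) - 1L) * 100000  # 0-based
  width <- 2000L
  strand <- rep(c("+", "-"), length.out = n)
  geneGR <- GenomicRanges::GRanges(
    "chrS1", IRanges::IRanges(start = start0 + 1L, width = width),
    strand = strand, name = genes)
  names(geneGR) <- genes
  tss <- tssFromGenes(geneGR)

  tssPos <- GenomicRanges::start(tss)
  tgt <- truth@targetPeakGenes
  offs <- sample(-15000:15000, length(tgt), replace = TRUE)
  mid <- tssPos[match(tgt, names(tss))] + offs
  tfPeaks <- GenomicRanges::GRanges(
    "chrS1", IRanges::IRanges(start = mid - 200L, end = mid + 199L),
    name = sprintf("peak_tf_%03d", seq_along(tgt)))
  names(tfPeaks) <- tfPeaks$name

  ctrlGenes <- setdiff(genes, tgt)[seq_len(min(length(tgt), n - length(tgt)))]
  cmid <- tssPos[match(ctrlGenes, names(tss))] + 30000L
  ctrlPeaks <- GenomicRanges::GRanges(
    "chrS1", IRanges::IRanges(start = cmid - 200L, end = cmid + 199L),
    name = sprintf("peak_ctrl_%03d", seq_along(ctrlGenes)))
  names(ctrlPeaks) <- ctrlPeaks$name

  ## decoys drawn outside the planted up set so the cascade pinpoints the
  ## cofactor uniquely
  nonUp <- setdiff(genes, truth@sharedUp)
  motifGenes <- sort(c(truth@cofactor, nonUp[seq_len(min(30, length(nonUp)))]))
  pool <- setdiff(nonUp, motifGenes)
  interactors <- sort(c(truth@cofactor, pool[seq_len(min(30, length(pool)))]))

  list(genes = geneGR, tss = tss,
       peaks = list(tf = tfPeaks, control = ctrlPeaks),
       motifGenes = motifGenes, interactors = interactors)
}

#' Simulate two signatures loading on a shared latent factor
#'
#' Builds a single cohort in which the genes of two disjoint signatures load
#' on one latent factor with a common loading: on the log2 scale each
#' signature gene is `baseline + loading * F + sqrt(1 - loading^2) * noise`
#' with `F` the per-sample factor, exponentiated to the expression scale. Used
#' to validate signature-score correlation recovery against the closed-form
#' factor-model expectation [factorScoreCorrelation()] (with `log2 = TRUE`
#' scoring, the factor model holds exactly on the scored values).
#'
#' An additional block of `nNoiseGenes` independent genes is appended so the
#' cohort is not purely signature genes.
#'
#' @param nSamples number of samples.
#' @param genesPerSignature genes in each of the two signatures.
#' @param loading factor loading in `[0, 1)` shared by all signature genes.
#' @param nNoiseGenes independent background genes.
#' @param seed integer RNG seed.
#' @return list with `cohort` ([ExpressionCohort-class]; the `group` factor is
#'   a nuisance split), `signatureA`, `signatureB` (character vectors).
#' @export
simulateCorrelatedSignatures <- function(nSamples = 200,
                                         genesPerSignature = 12,
                                         loading = 0.9, nNoiseGenes = 50,
                                         seed = 1) {
  stopifnot(nSamples >= 3, genesPerSignature >= 1,
            loading >= 0, loading < 1)
  set.seed(as.integer(seed))
  m <- as.integer(genesPerSignature)
  sigA <- sprintf("SA%03d", seq_len(m))
  sigB <- sprintf("SB%03d", seq_len(m))
  noise <- sprintf("BG%03d", seq_len(nNoiseGenes))
  genes <- c(sigA, sigB, noise)
  f <- stats::rnorm(nSamples)
  z <- matrix(stats::rnorm(length(genes) * nSamples), nrow = length(genes))
  sigIdx <- seq_len(2L * m)
  z[sigIdx, ] <- loading * matrix(f, nrow = 2L * m, ncol = nSamples,
                                  byrow = TRUE) +
    sqrt(1 - loading^2) * z[sigIdx, ]
  x <- 2^(6 + z)
  dimnames(x) <- list(genes, sprintf("s%03d", seq_len(nSamples)))
  grp <- factor(rep(c("A", "B"), length.out = nSamples), levels = c("A", "B"))
  list(cohort = ExpressionCohort(x, grp, "factor-sim"),
       signatureA = sigA, signatureB = sigB)
}

#' Closed-form score correlation under the shared-factor model
#'
#' For two disjoint signatures of `mA` and `mB` genes whose (z-scaled) values
#' share one latent factor with loading `lambda`, the correlation between the
#' two sum-of-z scores is
#' `mA * mB * lambda^2 / sqrt((mA + mA*(mA-1)*lambda^2) * (mB + mB*(mB-1)*lambda^2))`.
#' With one gene per signature this reduces to `lambda^2`.
#'
#' @param mA,mB signature sizes.
#' @param lambda shared factor loading.
#' @return expected Pearson correlation of the two signature scores.
#' @export
factorScoreCorrelation <- function(mA, mB, lambda) {
  vA <- mA + mA * (mA - 1) * lambda^2
  vB <- mB + mB * (mB - 1) * lambda^2
  mA * mB * lambda^2 / sqrt(vA * vB)
}
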