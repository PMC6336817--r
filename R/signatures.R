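#' Per-gene z-scores across the samples of one cohort
#'
#' For each gene, `z = (x - mu) / sigma` where `mu` and `sigma` are the mean
#' and standard deviation of that gene's expression across the cohort's
#' samples ("study mean" / "study standard deviation"). Z-scores are always
#' computed within one cohort, never pooled across cohorts. Expression enters
#' pre-normalized, i.e. as stored in the cohort; set `log2 = TRUE` to
#' z-score `log2(x + 1)` instead (useful when heavy-tailed RPKM outliers
#' would dominate).
#'
#' Zero-variance genes have undefined z-scores; their rows are returned as
#' all zeros with a warning.
#'
#' @param cohort an [ExpressionCohort-class] with at least two samples.
#' @param log2 z-score `log2(x + 1)`-transformed values (default `FALSE`).
#' @param sdType `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return numeric matrix of z-scores, same dimnames as the expression
#'   matrix; every non-constant row has mean 0 and (sample) sd 1.
#' @export
zscoreByGene <- function(cohort, log2 = FALSE,
                         sdType = c("sample", "population")) {
  stopifnot(is(cohort, "ExpressionCohort"))
  sdType <- match.arg(sdType)
  m <- exprMatrix(cohort)
  if (ncol(m) < 2L)
    stop("z-scores need at least two samples (sd undefined)")
  if (log2) m <- base::log2(m + 1)
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowSums(ctr^2) / (ncol(m) - 1L))
  if (sdType == "population") s <- s * sqrt((ncol(m) - 1L) / ncol(m))
  zero <- s == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance gene(s) set to z = 0 (e.g. %s)",
                    sum(zero), rownames(m)[which(zero)[1]]))
    s[zero] <- 1
    ctr[zero, ] <- 0
  }
  ctr / s
}

#' Sum-of-z signature score per sample
#'
#' The signature score of a sample is the sum of that sample's per-gene
#' z-scores ([zscoreByGene()]) over the signature genes present in the
#' cohort. Missing signature genes are recorded (and a warning emitted);
#' scoring fails if no signature gene is present. Because each z-score row
#' sums to zero across samples, so do the scores (when all used genes are
#' non-constant), and the scores are invariant under per-gene positive affine
#' rescaling of the expression values.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param signature character vector of signature gene identifiers.
#' @param name signature name stored in the result.
#' @param exclude genes to drop from the signature before scoring (e.g. the
#'   overlap with a second signature; see [signatureOverlap()]).
#' @inheritParams zscoreByGene
#' @return A [ScoreTable-class].
#' @examples
#' m <- rbind(HK = c(1, 2, 3))
#' colnames(m) <- c("s1", "s2", "s3")
#' ec <- ExpressionCohort(m, c("a", "a", "b"))
#' scores(signatureScore(ec, "HK"))   # -1 0 1
#' @export
signatureScore <- function(cohort, signature, name = "signature",
                           exclude = NULL, log2 = FALSE,
                           sdType = c("sample", "population")) {
  stopifnot(is(cohort, "ExpressionCohort"))
  signature <- setdiff(unique(as.character(signature)), exclude)
  present <- intersect(signature, rownames(cohort))
  missing <- setdiff(signature, present)
  if (!length(present))
    stop(sprintf("no gene of signature '%s' is present in cohort '%s'",
                 name, cohortName(cohort)))
  if (length(missing))
    warning(sprintf("signature '%s': %d gene(s) absent from cohort '%s'",
                    name, length(missing), cohortName(cohort)))
  z <- zscoreByGene(cohort[present, ], log2 = log2, sdType = sdType)
  new("ScoreTable", scores = colSums(z), cohortName = cohortName(cohort),
      signatureName = name, nGenesUsed = length(present),
      missingGenes = missing)
}

#' Overlap between two signatures
#'
#' Shared genes can bias the correlation of two signature scores; this
#' reports the overlap so it can be excluded via the `exclude` argument of
#' [signatureScore()] if desired.
#'
#' @param a,b character vectors of gene identifiers.
#' @return character vector of shared genes.
#' @export
signatureOverlap <- function(a, b) sort(intersect(a, b))

#' Correlation of two per-sample score tables
#'
#' Pearson correlation of two score vectors after aligning samples by
#' identifier. Unmatched samples are an error.
#'
#' @param a,b [ScoreTable-class] objects over the same samples.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
scoreCorrelation <- function(a, b) {
  stopifnot(is(a, "ScoreTable"), is(b, "ScoreTable"))
  sa <- scores(a); sb <- scores(b)
  unmatched <- c(setdiff(names(sa), names(sb)), setdiff(names(sb), names(sa)))
  if (length(unmatched))
    stop("sample mismatch between score tables: ",
         paste(sort(unique(unmatched)), collapse = ", "))
  stats::cor(sa, sb[names(sa)])
}

#' Normalize a cohort by a housekeeping gene
#'
#' Divides each sample's expression values by that sample's value of the
#' housekeeping gene (e.g. ACTB), so the housekeeping row becomes all ones.
#' Optional preprocessing for cross-platform comparisons of expression
#' levels; off by default everywhere else in the package.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param gene housekeeping gene identifier; must be present with a strictly
#'   positive value in every sample.
#' @return the normalized [ExpressionCohort-class].
#' @export
housekeepingNormalize <- function(cohort, gene) {
  stopifnot(is(cohort, "ExpressionCohort"))
  m <- exprMatrix(cohort)
  if (!gene %in% rownames(m))
    stop(sprintf("housekeeping gene '%s' not present in cohort '%s'",
                 gene, cohortName(cohort)))
  hk <- m[gene, ]
  if (any(hk <= 0))
    stop(sprintf("housekeeping value not positive in sample(s): %s",
                 paste(colnames(m)[hk <= 0], collapse = ", ")))
  ExpressionCohort(sweep(m, 2L, hk, "/"), sampleGroups(cohort),
                   cohortName(cohort))
}

#' Tumor-growth inhibition rate
#'
#' `IR = (volume_vehicle - volume_treated) / volume_vehicle`. Equals 0 for no
#' effect, 1 for complete suppression, and may be negative when the treated
#' volume exceeds the vehicle volume.
#'
#' @param vVehicle vehicle-arm tumor volume (> 0).
#' @param vTreated treated-arm tumor volume (>= 0).
#' @return inhibition rate (vectorized over its arguments).
#' @examples
#' inhibitionRate(100, 25)  # 0.75
#' @export
inhibitionRate <- function(vVehicle, vTreated) {
  if (any(vVehicle <= 0)) stop("vehicle volume must be positive")
  if (any(vTreated < 0)) stop("treated volume must be nonnegative")
  (vVehicle - vTreated) / vVehicle
}
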