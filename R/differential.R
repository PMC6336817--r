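#' @importFrom stats p.adjust pnorm pwilcox setNames
NULL

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact two-sided p-value (by the null distribution of the rank-sum
#' statistic) when the combined sample size is at most 12 and the pooled
#' values are tie-free; otherwise the normal approximation with tie
#' correction and continuity correction. The two-sided p is twice the smaller
#' tail, capped at 1. Fully tied input (all values identical) returns 1.
#'
#' Because the statistic depends only on ranks, the p-value is invariant
#' under any strictly increasing transform of the pooled values, and
#' symmetric in its two arguments.
#'
#' @param a,b numeric vectors (both nonempty, finite).
#' @return p-value in (0, 1].
#' @examples
#' wilcoxonRankSum(c(1, 2, 3), c(4, 5, 6))  # 0.1 (exact)
#' @export
wilcoxonRankSum <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("values must be finite")
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n1 + n2 <= 12L) {
    p <- 2 * min(stats::pwilcox(W, n1, n2),
                 stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE))
    return(min(1, p))
  }
  n <- n1 + n2
  tj <- table(r)
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(tj^3 - tj) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)       # all pooled values identical
  d <- W - n1 * n2 / 2
  z <- sign(d) * max(0, abs(d) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment, order-preserving with the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in `[0, 1]`, same order as `p`.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite numbers in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold change of group means on the linear scale
#'
#' `(mean(a) + pseudocount) / (mean(b) + pseudocount)`. The pseudocount
#' guards zero denominators on RPKM-like data; set it to 0 to get the plain
#' ratio of means (then `mean(b)` must be positive).
#'
#' @param a,b numeric vectors (case and reference group).
#' @param pseudocount nonnegative offset added to both means (default 0.1).
#' @return positive fold change.
#' @export
foldChange <- function(a, b, pseudocount = 0.1) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  mb <- mean(b)
  if (mb == 0 && pseudocount == 0)
    stop("mean of reference group is zero and pseudocount is zero")
  (mean(a) + pseudocount) / (mb + pseudocount)
}

## Shared per-gene engine: Wilcoxon p and fold change, case vs reference.
perGeneStats <- function(cohort, caseLevel, refLevel, pseudocount) {
  grp <- sampleGroups(cohort)
  lv <- levels(grp)
  if (is.null(caseLevel)) caseLevel <- lv[2]
  if (is.null(refLevel)) refLevel <- lv[1]
  if (!all(c(caseLevel, refLevel) %in% lv) || caseLevel == refLevel)
    stop("caseLevel and refLevel must be the two distinct group levels")
  m <- exprMatrix(cohort)
  ci <- which(grp == caseLevel)
  ri <- which(grp == refLevel)
  if (length(ci) < 1L || length(ri) < 1L)
    stop("each arm needs at least one sample")
  p <- apply(m, 1L, function(v) wilcoxonRankSum(v[ci], v[ri]))
  fc <- apply(m, 1L, function(v) foldChange(v[ci], v[ri], pseudocount))
  data.frame(foldChange = fc, log2FC = log2(fc), p = p,
             row.names = rownames(m))
}

#' Call genes upregulated in the case arm of one cohort
#'
#' Per-gene two-sided Wilcoxon rank-sum p-values ([wilcoxonRankSum()]) on the
#' linear expression values, Benjamini-Hochberg adjustment across all tested
#' genes of the cohort, and an up-call for genes with fold change strictly
#' above `fcThreshold` and FDR strictly below `fdrThreshold`.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param fcThreshold fold-change threshold (strict, default 2).
#' @param fdrThreshold FDR threshold (strict, default 0.05).
#' @param caseLevel,refLevel group levels compared (`case / reference`);
#'   default: second and first level of the cohort's group factor.
#' @param pseudocount passed to [foldChange()].
#' @return A [S4Vectors::DataFrame] with one row per gene and columns
#'   `foldChange`, `log2FC`, `p`, `fdr`, `calledUp`; thresholds and cohort
#'   name are kept in its `metadata()`.
#' @seealso [upGenes()], [intersectUp()]
#' @export
callUpregulated <- function(cohort, fcThreshold = 2, fdrThreshold = 0.05,
                            caseLevel = NULL, refLevel = NULL,
                            pseudocount = 0.1) {
  stopifnot(is(cohort, "ExpressionCohort"))
  st <- perGeneStats(cohort, caseLevel, refLevel, pseudocount)
  fdr <- bhAdjust(st$p)
  res <- S4Vectors::DataFrame(
    foldChange = st$foldChange, log2FC = st$log2FC, p = st$p, fdr = fdr,
    calledUp = st$foldChange > fcThreshold & fdr < fdrThreshold,
    row.names = rownames(st))
  S4Vectors::metadata(res) <- list(cohortName = cohortName(cohort),
                                   fcThreshold = fcThreshold,
                                   fdrThreshold = fdrThreshold,
                                   comparison = "upregulated")
  res
}

#' Genes called up in a differential result
#'
#' @param result a result from [callUpregulated()] or
#'   [callDysregulatedTumorNormal()] (for the latter, genes flagged in either
#'   direction).
#' @return character vector of gene identifiers.
#' @export
upGenes <- function(result) {
  col <- if ("calledUp" %in% colnames(result)) "calledUp" else "called"
  rownames(result)[result[[col]]]
}

#' Intersect upregulated gene sets across cohorts
#'
#' @param sets list of at least two character vectors of gene identifiers.
#' @return character vector: genes present in every set (sorted).
#' @export
intersectUp <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("need at least two gene sets")
  sort(Reduce(intersect, sets))
}

#' Tumor vs normal dysregulation call
#'
#' Flags genes with `|log2(fold change)| > 1` and raw Wilcoxon `p < 0.05`
#' (both strict; no multiple-testing adjustment in this screen). Cohorts with
#' fewer than `minNormal` reference (normal) samples are refused with a
#' classed error (condition class `"cohortSkipError"`) naming the cohort, so
#' callers can skip them.
#'
#' @param cohort an [ExpressionCohort-class] with tumor/normal labels (first
#'   level = normal/reference, second = tumor/case, unless overridden).
#' @param minNormal minimum number of normal samples required (default 6,
#'   i.e. more than 5).
#' @param log2fcThreshold,pThreshold strict thresholds.
#' @inheritParams callUpregulated
#' @return A [S4Vectors::DataFrame] with columns `foldChange`, `log2FC`, `p`
#'   and logical `called`.
#' @export
callDysregulatedTumorNormal <- function(cohort, minNormal = 6,
                                        log2fcThreshold = 1,
                                        pThreshold = 0.05,
                                        caseLevel = NULL, refLevel = NULL,
                                        pseudocount = 0.1) {
  stopifnot(is(cohort, "ExpressionCohort"))
  grp <- sampleGroups(cohort)
  ref <- if (is.null(refLevel)) levels(grp)[1] else refLevel
  nNormal <- sum(grp == ref)
  if (nNormal < minNormal) {
    cond <- structure(
      class = c("cohortSkipError", "error", "condition"),
      list(message = sprintf(
        "cohort '%s' skipped: %d normal samples (< %d required)",
        cohortName(cohort), nNormal, minNormal), call = sys.call()))
    stop(cond)
  }
  st <- perGeneStats(cohort, caseLevel, refLevel, pseudocount)
  res <- S4Vectors::DataFrame(
    foldChange = st$foldChange, log2FC = st$log2FC, p = st$p,
    called = abs(st$log2FC) > log2fcThreshold & st$p < pThreshold,
    row.names = rownames(st))
  S4Vectors::metadata(res) <- list(cohortName = cohortName(cohort),
                                   comparison = "tumor-vs-normal")
  res
}
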