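# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately naive (enumeration / all-pairs / direct
# definitions) so they share no code path with the implementation.

# All rank-sum statistics obtainable by assigning the pooled ranks to group a.
wilcoxEnumStats <- function(r, n1) {
  combs <- utils::combn(length(r), n1)
  apply(combs, 2L, function(ix) sum(r[ix]))
}

# Two-sided rank-sum p by exhaustive enumeration of group assignments.
wilcoxEnumP <- function(a, b) {
  r <- rank(c(a, b))
  Ws <- wilcoxEnumStats(r, length(a))
  Wobs <- sum(r[seq_along(a)])
  min(1, 2 * min(mean(Ws <= Wobs), mean(Ws >= Wobs)))
}

# Step-up BH from its definition: sort, q_(i) = min_{j >= i} p_(j) * n / j.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n))
    q[i] <- min(1, min(ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- q
  out
}

# All-pairs peak-to-TSS assignment by the midpoint rule.
assignOracle <- function(peaks, tss, window) {
  pn <- if (!is.null(peaks$name)) as.character(peaks$name) else names(peaks)
  genes <- names(tss)
  pChrom <- as.character(GenomicRanges::seqnames(peaks))
  gChrom <- as.character(GenomicRanges::seqnames(tss))
  mids <- floor((GenomicRanges::start(peaks) - 1 +
                 GenomicRanges::end(peaks)) / 2) + 1
  gPos <- GenomicRanges::start(tss)
  res <- stats::setNames(rep(list(character(0)), length(genes)), genes)
  for (i in seq_along(peaks)) {
    hit <- pChrom[i] == gChrom & abs(mids[i] - gPos) <= window
    for (j in which(hit)) res[[genes[j]]] <- c(res[[genes[j]]], pn[i])
  }
  res
}

# All-pairs >= 1 bp intersection test between two closed 1-based intervals.
overlapOracle <- function(a, b) {
  hit <- function(x, y) {
    xc <- as.character(GenomicRanges::seqnames(x))
    yc <- as.character(GenomicRanges::seqnames(y))
    xs <- GenomicRanges::start(x); xe <- GenomicRanges::end(x)
    ys <- GenomicRanges::start(y); ye <- GenomicRanges::end(y)
    vapply(seq_along(x), function(i)
      any(xc[i] == yc & xs[i] <= ye & xe[i] >= ys), logical(1))
  }
  aHit <- hit(a, b)
  bHit <- hit(b, a)
  list(nAOnly = sum(!aHit), nBOnly = sum(!bHit),
       nAOverlap = sum(aHit), nBOverlap = sum(bHit))
}

# Two-sided Fisher p by direct hypergeometric enumeration over tables with
# the observed margins.
fisherOracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Adjusted Rand index between two labelings.
adjustedRand <- function(x, y) {
  tab <- table(x, y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sumIJ <- ch2(as.vector(tab))
  sumI <- ch2(rowSums(tab))
  sumJ <- ch2(colSums(tab))
  nC2 <- ch2(sum(tab))
  exp <- sumI * sumJ / nC2
  (sumIJ - exp) / ((sumI + sumJ) / 2 - exp)
}

# Small cohort builder.
makeCohort <- function(m, group = NULL, name = "test") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  if (is.null(group))
    group <- factor(rep(c("ref", "case"), length.out = ncol(m)),
                    levels = c("ref", "case"))
  ExpressionCohort(m, group, name)
}

# Random peak / TSS fixture on two chromosomes.
randomIntervalFixture <- function(nPeaks, nGenes, seed) {
  set.seed(seed)
  chromP <- sample(c("chr1", "chr2"), nPeaks, replace = TRUE)
  s <- sample.int(2e5, nPeaks, replace = TRUE)
  w <- sample.int(2000, nPeaks, replace = TRUE)
  peaks <- GenomicRanges::GRanges(
    chromP, IRanges::IRanges(start = s, width = w),
    name = sprintf("p%04d", seq_len(nPeaks)))
  names(peaks) <- peaks$name
  chromG <- sample(c("chr1", "chr2"), nGenes, replace = TRUE)
  tpos <- sample.int(2e5, nGenes, replace = TRUE)
  tss <- GenomicRanges::GRanges(chromG, IRanges::IRanges(tpos, width = 1))
  names(tss) <- sprintf("gene%03d", seq_len(nGenes))
  list(peaks = peaks, tss = tss)
}
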