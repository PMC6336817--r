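#' @importFrom GenomicRanges GRanges start end strand seqnames findOverlaps
#'   countOverlaps resize
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats fisher.test
#' @importFrom utils read.table write.table
NULL

#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates on disk are 0-based half-open; the returned `GRanges` is
#' 1-based closed per Bioconductor convention. Malformed lines (fewer than
#' three fields, non-numeric or negative coordinates, `start >= end`) are
#' rejected with their line numbers. Interval names (column 4) become the
#' `name` metadata column and the `names()` of the result; missing names are
#' synthesized.
#'
#' @param path BED file path.
#' @return A `GRanges` with `name` (and, for BED6, `score`) metadata.
#' @seealso [writeBed()]
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", which(nf < 3L)[1],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(!is.finite(s) | !is.finite(e) | s < 0 | s >= e)
  if (length(bad))
    stop("BED parse error at line ", bad[1],
         ": require numeric 0 <= start < end")
  name <- ifelse(nf >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, character(1)),
    sprintf("peak_%d", seq_along(lines)))
  score <- ifelse(nf >= 5L, suppressWarnings(as.numeric(vapply(
    fields, function(f) if (length(f) >= 5L) f[[5L]] else "0",
    character(1)))), 0)
  strand <- vapply(fields, function(f)
    if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) f[[6L]] else "*",
    character(1))
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = s + 1, end = e), strand = strand,
    name = name, score = score)
  names(gr) <- name
  gr
}

#' Write a GRanges as BED6
#'
#' Inverse of [readBed()]: coordinates are converted back to 0-based
#' half-open. The `name` column falls back to `names(gr)`, then to
#' synthesized identifiers; `score` defaults to 0; `*` strand is written as
#' `.`.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  name <- if (!is.null(gr$name)) gr$name
          else if (!is.null(names(gr))) names(gr)
          else sprintf("peak_%d", seq_along(gr))
  score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = name, score = score, strand = strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-aware transcription start sites of gene intervals
#'
#' The TSS of a `+`-strand gene is its leftmost base, of a `-`-strand gene
#' its rightmost base (so editing the end of a `-`-strand interval moves its
#' TSS).
#'
#' @param genes stranded `GRanges` of gene intervals (names = gene ids).
#' @return width-1 `GRanges` of TSS positions, one per gene.
#' @export
tssFromGenes <- function(genes) {
  if (any(as.character(GenomicRanges::strand(genes)) == "*"))
    stop("gene intervals must be stranded (+ or -)")
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

peakMidpoints <- function(peaks) {
  ## midpoint of the 0-based half-open interval, floored, back to 1-based
  mid0 <- floor((GenomicRanges::start(peaks) - 1L +
                 GenomicRanges::end(peaks)) / 2)
  GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                         IRanges::IRanges(mid0 + 1L, width = 1L))
}

peakNames <- function(peaks) {
  if (!is.null(peaks$name)) as.character(peaks$name)
  else if (!is.null(names(peaks))) names(peaks)
  else sprintf("peak_%d", seq_along(peaks))
}

#' Assign peaks to genes by TSS proximity
#'
#' A peak is assigned to a gene iff the distance from the peak midpoint to
#' the gene's TSS is at most `window` bases (inclusive at exactly `window`)
#' on the same chromosome; strand is ignored for the distance. A peak may be
#' assigned to several genes.
#'
#' @param peaks `GRanges` of peaks.
#' @param tss width-1 `GRanges` of TSS positions, names = gene ids.
#' @param window maximum midpoint-to-TSS distance in bases (default 20000).
#' @return named list mapping every gene to the character vector of assigned
#'   peak names (possibly empty).
#' @export
assignPeaksToGenes <- function(peaks, tss, window = 20000) {
  genes <- if (!is.null(names(tss))) names(tss) else as.character(tss$name)
  if (is.null(genes)) stop("tss must carry gene identifiers")
  res <- stats::setNames(rep(list(character(0)), length(genes)), genes)
  if (!length(peaks)) return(res)
  mids <- peakMidpoints(peaks)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(start = pmax(1L, GenomicRanges::start(tss) - window),
                     end = GenomicRanges::start(tss) + window))
  ## peaks and TSSs legitimately may sit on disjoint chromosome sets
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(mids, win, ignore.strand = TRUE))
  pn <- peakNames(peaks)
  spl <- split(pn[S4Vectors::queryHits(hits)],
               genes[S4Vectors::subjectHits(hits)])
  res[names(spl)] <- spl
  res
}

#' Proximity enrichment of a gene set among peak-bearing genes
#'
#' Cross-tabulates gene-set membership against carrying at least one assigned
#' peak ([assignPeaksToGenes()]) over a gene universe, and tests association
#' with Fisher's exact test. The odds ratio reported is the sample odds ratio
#' `(a*d)/(b*c)` of the 2x2 table (possibly `Inf` under perfect association).
#'
#' @param peaks `GRanges` of peaks.
#' @param tss width-1 `GRanges` of TSSs (names = gene ids) covering the
#'   universe.
#' @param geneset character vector, subset of `universe`.
#' @param universe character vector of genes considered.
#' @param window passed to [assignPeaksToGenes()].
#' @return list with `oddsRatio`, `p` and the 2x2 `table`.
#' @export
proximityEnrichment <- function(peaks, tss, geneset, universe,
                                window = 20000) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be nonempty")
  if (!all(geneset %in% universe))
    stop("geneset must be a subset of the universe")
  tss <- tss[names(tss) %in% universe]
  assigned <- assignPeaksToGenes(peaks, tss, window)
  withPeak <- names(assigned)[lengths(assigned) > 0]
  inSet <- universe %in% geneset
  hasPeak <- universe %in% withPeak
  tab <- table(factor(inSet, c(TRUE, FALSE)), factor(hasPeak, c(TRUE, FALSE)),
               dnn = c("inGeneset", "hasPeak"))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  or <- if (b * cc == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * cc)
  list(oddsRatio = or, p = stats::fisher.test(tab)$p.value, table = tab)
}

#' Venn-style overlap counts of two peak sets
#'
#' A peak counts as overlapping iff it intersects at least `minOverlap` bases
#' of any peak in the other set. Counts are reported per input set (a peak
#' overlapping several peaks of the other set counts once), which is the
#' appropriate bookkeeping when the two sets differ in cardinality.
#'
#' @param a,b `GRanges` peak sets.
#' @param minOverlap minimum intersection width in bases (default 1).
#' @return list with `nAOnly`, `nBOnly`, `nAOverlap`, `nBOverlap`.
#' @export
overlapPeaks <- function(a, b, minOverlap = 1L) {
  aHit <- GenomicRanges::countOverlaps(a, b, minoverlap = minOverlap,
                                       ignore.strand = TRUE) > 0
  bHit <- GenomicRanges::countOverlaps(b, a, minoverlap = minOverlap,
                                       ignore.strand = TRUE) > 0
  list(nAOnly = sum(!aHit), nBOnly = sum(!bHit),
       nAOverlap = sum(aHit), nBOverlap = sum(bHit))
}

#' Fraction of re-ChIP peaks co-occupied by both single-factor cistromes
#'
#' Fraction of sequential-immunoprecipitation (re-ChIP) peaks that intersect
#' (>= `minOverlap` bp) at least one peak of `chipA` AND at least one peak of
#' `chipB`.
#'
#' @param rechip nonempty `GRanges` of re-ChIP peaks.
#' @param chipA,chipB `GRanges` of the two single-factor peak sets.
#' @param minOverlap minimum intersection width in bases (default 1).
#' @return fraction in `[0, 1]`.
#' @export
rechipCooccupancy <- function(rechip, chipA, chipB, minOverlap = 1L) {
  if (!length(rechip)) stop("re-ChIP peak set is empty")
  inA <- GenomicRanges::countOverlaps(rechip, chipA, minoverlap = minOverlap,
                                      ignore.strand = TRUE) > 0
  inB <- GenomicRanges::countOverlaps(rechip, chipB, minoverlap = minOverlap,
                                      ignore.strand = TRUE) > 0
  mean(inA & inB)
}

#' Direct targets: upregulated genes with a proximal binding peak
#'
#' Intersection of an upregulated gene set with the genes that have at least
#' one peak assigned within `window` of their TSS.
#'
#' @param deUp character vector of upregulated genes.
#' @param tfPeaks `GRanges` of the regulator's binding peaks.
#' @param tss width-1 `GRanges` of TSSs (names = gene ids).
#' @param window passed to [assignPeaksToGenes()] (default 20000).
#' @return sorted character vector of direct target genes.
#' @export
directTargets <- function(deUp, tfPeaks, tss, window = 20000) {
  assigned <- assignPeaksToGenes(tfPeaks, tss, window)
  withPeak <- names(assigned)[lengths(assigned) > 0]
  sort(intersect(deUp, withPeak))
}

#' Three-filter co-factor cascade
#'
#' Successively intersects the direct-target gene set with the motif-derived
#' gene list and the protein-interactor list, recording survivor counts per
#' stage. Adding genes to any filter set can only add survivors (monotone).
#'
#' @param direct direct target genes (see [directTargets()]).
#' @param motifGenes genes whose motifs are enriched in the partner factor's
#'   binding sites.
#' @param interactors known protein interactors of the partner factor.
#' @return list with `survivors` (sorted character) and `stages` (data.frame
#'   of `stage`, `nIn`, `nOut`).
#' @export
cofactorCascade <- function(direct, motifGenes, interactors) {
  s1 <- sort(intersect(direct, motifGenes))
  s2 <- sort(intersect(s1, interactors))
  stages <- data.frame(
    stage = c("direct_targets", "motif_filter", "interactor_filter"),
    nIn = c(length(direct), length(direct), length(s1)),
    nOut = c(length(direct), length(s1), length(s2)))
  list(survivors = s2, stages = stages)
}
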