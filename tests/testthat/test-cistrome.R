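test_that("BED round-trips through 0-based half-open coordinates", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tpkA\t5\t+",
               "chr2\t0\t100\tpkB\t0\t-",
               "chr1\t30\t31\tpkC\t0\t."), tmp)
  gr <- readBed(tmp)
  expect_equal(GenomicRanges::start(gr), c(11, 1, 31))
  expect_equal(GenomicRanges::end(gr), c(20, 100, 31))
  expect_equal(gr$name, c("pkA", "pkB", "pkC"))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-", "*"))
  out <- withr::local_tempfile(fileext = ".bed")
  writeBed(gr, out)
  gr2 <- readBed(out)
  expect_equal(GenomicRanges::start(gr2), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(gr2), GenomicRanges::end(gr))
  expect_equal(gr2$name, gr$name)
  expect_equal(as.character(GenomicRanges::strand(gr2)),
               as.character(GenomicRanges::strand(gr)))
  ## BED3 gets synthesized names
  tmp3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t5\t9", tmp3)
  expect_equal(readBed(tmp3)$name, "peak_1")
})

test_that("malformed BED lines are rejected with their line number", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20\tok", "chr1\t20\t10\tbad"), tmp)
  expect_error(readBed(tmp), "line 2")
  writeLines("chr1\t10", tmp)
  expect_error(readBed(tmp), "line 1.*fewer than 3")
  writeLines("chr1\tx\t20", tmp)
  expect_error(readBed(tmp), "line 1")
})

test_that("TSS derivation is strand-aware", {
  g <- GenomicRanges::GRanges(c("chr1", "chr1"),
                              IRanges::IRanges(c(101, 501), c(200, 700)),
                              strand = c("+", "-"))
  names(g) <- c("gp", "gm")
  tss <- tssFromGenes(g)
  expect_equal(unname(GenomicRanges::start(tss)), c(101, 700))
  expect_equal(unname(GenomicRanges::width(tss)), c(1, 1))
  gStar <- g
  GenomicRanges::strand(gStar) <- "*"
  expect_error(tssFromGenes(gStar), "strand")
})

test_that("peak assignment window is inclusive at exactly 20 kb", {
  tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100000, width = 1))
  names(tss) <- "gene1"
  at <- function(pos, nm) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pos, width = 1), name = nm)
  peaks <- c(at(100000, "atTss"), at(120000, "at20k"),
             at(120001, "at20k1"), at(80000, "minus20k"))
  asn <- assignPeaksToGenes(peaks, tss, window = 20000)
  expect_setequal(asn$gene1, c("atTss", "at20k", "minus20k"))
  ## different chromosome never assigned
  off <- GenomicRanges::GRanges("chr2", IRanges::IRanges(100000, width = 1),
                                name = "otherChrom")
  expect_length(assignPeaksToGenes(off, tss)$gene1, 0)
  ## midpoint rule: a wide peak is judged by its midpoint
  wide <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(120001, 129999),
                                 name = "wide")  # midpoint 125000
  expect_length(assignPeaksToGenes(wide, tss)$gene1, 0)
})

test_that("peak assignment agrees with the all-pairs oracle", {
  for (s in 1:20) {
    fx <- randomIntervalFixture(nPeaks = 60, nGenes = 25, seed = s)
    got <- assignPeaksToGenes(fx$peaks, fx$tss, window = 15000)
    want <- assignOracle(fx$peaks, fx$tss, window = 15000)
    expect_identical(lapply(got, sort), lapply(want, sort))
  }
})

test_that("peak-set overlap matches the quadratic oracle and is symmetric", {
  a0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 50), c(10, 60)))
  expect_equal(overlapPeaks(a0, a0),
               list(nAOnly = 0L, nBOnly = 0L, nAOverlap = 2L,
                    nBOverlap = 2L))
  b0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 120))
  expect_equal(overlapPeaks(a0, b0)$nAOverlap, 0L)
  expect_equal(overlapPeaks(a0, b0)$nAOnly, 2L)
  for (s in 21:35) {
    fx <- randomIntervalFixture(nPeaks = 50, nGenes = 5, seed = s)
    fy <- randomIntervalFixture(nPeaks = 40, nGenes = 5, seed = s + 500)
    got <- overlapPeaks(fx$peaks, fy$peaks)
    expect_equal(got, overlapOracle(fx$peaks, fy$peaks))
    swapped <- overlapPeaks(fy$peaks, fx$peaks)
    expect_equal(got$nAOverlap, swapped$nBOverlap)
    expect_equal(got$nAOnly, swapped$nBOnly)
  }
})

test_that("minimum-overlap width is honoured", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  expect_equal(overlapPeaks(a, b)$nAOverlap, 1L)       # 1 bp shared
  expect_equal(overlapPeaks(a, b, minOverlap = 2L)$nAOverlap, 0L)
})

test_that("re-ChIP co-occupancy fraction is exact on planted fixtures", {
  mk <- function(starts) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(starts, width = 100))
  chipA <- mk(seq(1000, 10000, by = 1000))
  chipB <- mk(seq(1000, 10000, by = 1000) + 50)
  expect_equal(rechipCooccupancy(mk(c(1020, 2020)), chipA, chipB), 1)
  expect_equal(rechipCooccupancy(mk(c(1e6, 2e6)), chipA, chipB), 0)
  ## 8 of 10 rechip peaks hit both cistromes -> 0.8 exactly
  rechip <- mk(c(seq(1000, 8000, by = 1000) + 25, 5e6, 6e6))
  expect_equal(rechipCooccupancy(rechip, chipA, chipB), 0.8)
  expect_error(rechipCooccupancy(GenomicRanges::GRanges(), chipA, chipB),
               "empty")
})

test_that("proximity enrichment builds the right 2x2 table", {
  ## synthetic layout: genes every 100 kb; geneset genes get a proximal peak
  n <- 100
  tss <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(50000, by = 100000, length.out = n),
                             width = 1))
  names(tss) <- sprintf("g%03d", seq_len(n))
  universe <- names(tss)
  geneset <- universe[1:15]
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(
      GenomicRanges::start(tss)[c(1:10, 16:20)] + 500, width = 200),
    name = sprintf("p%02d", 1:15))
  ## table: a=10 in-set with peak, b=5 in-set without, c=5, d=80
  enr <- proximityEnrichment(peaks, tss, geneset, universe)
  expect_equal(as.vector(enr$table), c(10, 5, 5, 80))
  expect_equal(enr$oddsRatio, 32)
  expect_equal(enr$p, fisherOracle(10, 5, 5, 80), tolerance = 1e-10)

  ## perfect association: infinite odds ratio, hypergeometric tail p
  peaksAll <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(GenomicRanges::start(tss)[1:15], width = 1),
    name = sprintf("q%02d", 1:15))
  enr2 <- proximityEnrichment(peaksAll, tss, geneset, universe)
  expect_identical(enr2$oddsRatio, Inf)
  expect_equal(enr2$p, fisherOracle(15, 0, 0, 85), tolerance = 1e-10)
  expect_error(proximityEnrichment(peaks, tss, c(geneset, "zz"), universe),
               "subset")
  expect_error(proximityEnrichment(peaks, tss, geneset, character(0)),
               "nonempty")
})

test_that("independent geneset and peaks give odds ratio near 1", {
  ors <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 200
    tss <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(seq(50000, by = 100000, length.out = n),
                               width = 1))
    names(tss) <- sprintf("g%03d", seq_len(n))
    geneset <- sample(names(tss), 60)
    withPeak <- sample(n, 100)
    peaks <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(GenomicRanges::start(tss)[withPeak] + 100,
                               width = 50),
      name = sprintf("p%03d", seq_along(withPeak)))
    proximityEnrichment(peaks, tss, geneset, names(tss))$oddsRatio
  }, numeric(1))
  expect_lt(abs(mean(log(ors))), 0.35)
})

test_that("direct targets and the cascade behave as set algebra", {
  tss <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 50000, 120000), width = 1))
  names(tss) <- c("A", "B", "C")
  noPeaks <- GenomicRanges::GRanges()
  expect_identical(directTargets(c("A", "B"), noPeaks, tss), character(0))
  atTss <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(GenomicRanges::start(tss), width = 1),
    name = c("p1", "p2", "p3"))
  expect_identical(directTargets(c("A", "B"), atTss, tss), c("A", "B"))
  expect_identical(directTargets(character(0), atTss, tss), character(0))

  casc <- cofactorCascade(c("A", "B", "C"), c("B", "C", "D"), c("C", "E"))
  expect_identical(casc$survivors, "C")
  expect_equal(casc$stages$nOut, c(3, 2, 1))
  expect_identical(cofactorCascade(c("A", "B"), c("A", "B"),
                                   character(0))$survivors, character(0))
  ## monotone: enlarging any filter never removes survivors
  casc2 <- cofactorCascade(c("A", "B", "C"), c("A", "B", "C", "D"),
                           c("C", "E", "A"))
  expect_true(all(casc$survivors %in% casc2$survivors))
})
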