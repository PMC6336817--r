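#' Write / read one cohort as expression + sample-annotation TSV
#'
#' The expression TSV has genes in rows, a header row, and a first column
#' named `gene`; the sample-annotation TSV has columns `sample`, `cohort`,
#' `group`. This is the on-disk dialect shared by the simulator and the
#' pipeline, and the one expected of user-supplied data.
#'
#' @param cohort an [ExpressionCohort-class].
#' @param exprPath,samplePath output/input paths.
#' @return `writeCohort` returns its paths invisibly; `readCohort` returns an
#'   [ExpressionCohort-class]. Group levels are restored from a `levels`
#'   comment-free convention: the reference level is the lexicographically
#'   first unless the annotation file orders otherwise (first level seen
#'   among rows after sorting by group then sample is not used — levels are
#'   taken in order of first appearance).
#' @export
writeCohort <- function(cohort, exprPath, samplePath) {
  m <- exprMatrix(cohort)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann <- data.frame(sample = colnames(m), cohort = cohortName(cohort),
                    group = as.character(sampleGroups(cohort)))
  utils::write.table(ann, samplePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(exprPath, samplePath))
}

#' @rdname writeCohort
#' @export
readCohort <- function(exprPath, samplePath) {
  df <- utils::read.table(exprPath, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ann <- utils::read.table(samplePath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(colnames(m) %in% ann$sample))
    stop("sample annotation does not cover all expression columns")
  ann <- ann[match(colnames(m), ann$sample), ]
  grp <- factor(ann$group, levels = unique(ann$group))
  ExpressionCohort(m, grp, unique(ann$cohort)[1])
}

#' Read / write gene lists (one identifier per line)
#'
#' @param path file path.
#' @param genes character vector.
#' @return `readGeneList` returns a character vector.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname readGeneList
#' @export
writeGeneList <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read / write GMT-like signature files
#'
#' Each line: signature name, description, then tab-separated gene
#' identifiers.
#'
#' @param path file path.
#' @param signatures named list of character vectors.
#' @param descriptions optional character vector parallel to `signatures`.
#' @return `readGmt` returns a named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT parse error at line ", bad[1],
         ": need name, description and at least one gene")
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[[`, character(1), 1L))
}

#' @rdname readGmt
#' @export
writeGmt <- function(signatures, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(signatures))
  lines <- mapply(function(nm, ds, genes)
    paste(c(nm, ds, genes), collapse = "\t"),
    names(signatures), descriptions, signatures)
  writeLines(unname(lines), path)
  invisible(path)
}
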