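#' @importFrom stats cor sd
NULL

#' Pearson correlation with a defined degenerate case
#'
#' Plain Pearson correlation of two equal-length vectors. If either vector
#' has zero variance the correlation is undefined and `NA` is returned (a
#' pair with undefined correlation contributes no edge to the consensus
#' network).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Correlation count across datasets
#'
#' Number of datasets in which the signed correlation strictly exceeds the
#' threshold. `NA` (undefined) correlations never count. `r = threshold`
#' exactly does not count (strict), and strongly negative correlations never
#' count (the criterion is signed, not absolute).
#'
#' @param r numeric vector of per-dataset correlations (may contain `NA`).
#' @param threshold correlation threshold (default 0.5).
#' @return integer count in `[0, length(r)]`.
#' @export
correlationCount <- function(r, threshold = 0.5) {
  sum(!is.na(r) & r > threshold)
}

#' Build the consensus co-expression network
#'
#' For every TF-gene and TF-TF pair, computes the per-cohort Pearson
#' correlation of transformed expression over the selected samples of each
#' cohort (by default `log2(x + 1)` over the case-arm, i.e. NET, samples),
#' and includes an edge iff the correlation count ([correlationCount()]) is
#' at least 1, with the count as integer edge weight. Non-TF pairs are never
#' connected. Per-cohort correlations are retained on each edge.
#'
#' @param cohorts list of [ExpressionCohort-class] objects.
#' @param tfs character: nodes flagged as transcription factors.
#' @param genes character: non-TF gene nodes.
#' @param threshold correlation-count threshold (strict, signed; default 0.5).
#' @param samples which samples of each cohort enter the correlation:
#'   `"case"` (second group level; default), `"all"`, or `"reference"`.
#' @param transform `"log2"` (default, `log2(x+1)`) or `"none"`.
#' @return A [ConsensusNetwork-class].
#' @export
buildConsensus <- function(cohorts, tfs, genes, threshold = 0.5,
                           samples = c("case", "all", "reference"),
                           transform = c("log2", "none")) {
  samples <- match.arg(samples)
  transform <- match.arg(transform)
  if (!length(cohorts)) stop("need at least one cohort")
  tfs <- sort(unique(as.character(tfs)))
  genes <- sort(unique(setdiff(as.character(genes), tfs)))
  nodes <- c(tfs, genes)
  if (!length(tfs)) stop("need at least one TF node")

  rList <- lapply(cohorts, function(ch) {
    stopifnot(is(ch, "ExpressionCohort"))
    miss <- setdiff(nodes, rownames(ch))
    if (length(miss))
      stop(sprintf("gene(s) %s missing from cohort '%s'",
                   paste(miss, collapse = ", "), cohortName(ch)))
    grp <- sampleGroups(ch)
    keep <- switch(samples,
                   all = rep(TRUE, length(grp)),
                   case = grp == levels(grp)[2],
                   reference = grp == levels(grp)[1])
    m <- exprMatrix(ch)[nodes, keep, drop = FALSE]
    if (transform == "log2") m <- log2(m + 1)
    ## rows with zero variance give NA correlations (no edge)
    suppressWarnings(stats::cor(t(m[tfs, , drop = FALSE]), t(m)))
  })

  ## candidate pairs: TF-TF (each once) plus TF-gene
  nT <- length(tfs)
  pairA <- character(0); pairB <- character(0)
  if (nT > 1L) {
    idx <- which(upper.tri(diag(nT)), arr.ind = TRUE)
    pairA <- tfs[idx[, 1L]]; pairB <- tfs[idx[, 2L]]
  }
  if (length(genes)) {
    pairA <- c(pairA, rep(tfs, each = length(genes)))
    pairB <- c(pairB, rep(genes, times = nT))
  }
  rMat <- matrix(
    unlist(lapply(rList, function(R) R[cbind(pairA, pairB)])),
    ncol = length(rList))
  w <- rowSums(!is.na(rMat) & rMat > threshold)
  keep <- w >= 1L
  edges <- data.frame(nodeA = pairA[keep], nodeB = pairB[keep],
                      weight = as.integer(w[keep]),
                      stringsAsFactors = FALSE)
  rKeep <- rMat[keep, , drop = FALSE]
  colnames(rKeep) <- sprintf("r.%d", seq_len(ncol(rKeep)))
  edges <- cbind(edges, as.data.frame(rKeep))
  rownames(edges) <- NULL
  new("ConsensusNetwork",
      nodes = data.frame(node = nodes, isTF = nodes %in% tfs,
                         stringsAsFactors = FALSE),
      edges = edges, nDatasets = length(cohorts))
}

asIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("nodeA", "nodeB", "weight")], directed = FALSE,
    vertices = data.frame(name = sort(net@nodes$node)))
  g
}

#' Weighted degree of network nodes
#'
#' Sum of incident edge weights (correlation counts). With `nodes = NULL`,
#' returns the weighted degree of every node.
#'
#' @param net a [ConsensusNetwork-class].
#' @param nodes node identifiers, or `NULL` for all nodes.
#' @return named integer vector of weighted degrees.
#' @export
weightedDegree <- function(net, nodes = NULL) {
  stopifnot(is(net, "ConsensusNetwork"))
  all <- net@nodes$node
  wd <- stats::setNames(integer(length(all)), all)
  if (nrow(net@edges)) {
    t1 <- tapply(net@edges$weight, net@edges$nodeA, sum)
    t2 <- tapply(net@edges$weight, net@edges$nodeB, sum)
    wd[names(t1)] <- wd[names(t1)] + as.integer(t1)
    wd[names(t2)] <- wd[names(t2)] + as.integer(t2)
  }
  if (is.null(nodes)) return(wd)
  miss <- setdiff(nodes, all)
  if (length(miss))
    stop("unknown node(s): ", paste(miss, collapse = ", "))
  wd[nodes]
}

#' Detect communities by greedy modularity maximization
#'
#' Deterministic greedy (agglomerative) maximization of weighted modularity
#' over the consensus network, with nodes processed in sorted identifier
#' order. Isolated nodes form singleton communities. The contract is
#' determinism given the seed plus a partition whose modularity is at least
#' that of the trivial one-community partition; the specific heuristic is
#' the fast-greedy algorithm.
#'
#' @param net a [ConsensusNetwork-class] (nonempty).
#' @param seed integer seed (the greedy procedure is itself deterministic;
#'   the seed fixes any library-internal tie-breaking).
#' @return A [CommunityPartition-class].
#' @export
detectCommunities <- function(net, seed = 1L) {
  stopifnot(is(net, "ConsensusNetwork"))
  if (!nrow(net@nodes)) stop("network has no nodes")
  g <- asIgraph(net)
  if (igraph::ecount(g) == 0L) {
    memb <- stats::setNames(seq_len(igraph::vcount(g)),
                            igraph::V(g)$name)
    return(new("CommunityPartition", membership = memb, modularity = 0))
  }
  set.seed(as.integer(seed))
  cl <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  ## the trivial one-community partition has modularity 0; never do worse
  if (q < 0) {
    memb <- stats::setNames(rep(1L, igraph::vcount(g)), igraph::V(g)$name)
    q <- 0
  }
  new("CommunityPartition",
      membership = stats::setNames(as.integer(memb), names(memb)),
      modularity = q)
}

## Largest community by node count; ties broken by total internal edge
## weight, then by smallest community label.
topCommunity <- function(net, partition) {
  memb <- partition@membership
  sizes <- table(memb)
  cand <- as.integer(names(sizes)[sizes == max(sizes)])
  if (length(cand) > 1L) {
    e <- net@edges
    internal <- vapply(cand, function(cm) {
      inC <- names(memb)[memb == cm]
      sum(e$weight[e$nodeA %in% inC & e$nodeB %in% inC])
    }, numeric(1))
    cand <- cand[internal == max(internal)]
  }
  min(cand)
}

#' Rank candidate master TFs within the top community
#'
#' Identifies the community containing the largest number of nodes (ties
#' broken by total internal edge weight, then smallest label) and returns its
#' TFs sorted by weighted degree, descending, ties broken lexicographically.
#' A top community without any TF yields an empty ranking with a warning.
#'
#' @param net a [ConsensusNetwork-class].
#' @param partition the [CommunityPartition-class] of `net`.
#' @return data.frame with columns `tf`, `community`, `weightedDegree`,
#'   ordered by decreasing weighted degree.
#' @export
rankMasterTFs <- function(net, partition) {
  stopifnot(is(net, "ConsensusNetwork"), is(partition, "CommunityPartition"))
  memb <- partition@membership
  if (!all(net@nodes$node %in% names(memb)))
    stop("partition does not cover every network node")
  top <- topCommunity(net, partition)
  inTop <- names(memb)[memb == top]
  tfs <- sort(intersect(inTop, net@nodes$node[net@nodes$isTF]))
  if (!length(tfs)) {
    warning("top community contains no TF")
    return(data.frame(tf = character(0), community = integer(0),
                      weightedDegree = integer(0)))
  }
  wd <- weightedDegree(net, tfs)
  ord <- order(-wd, tfs)
  data.frame(tf = tfs[ord], community = top,
             weightedDegree = as.integer(wd[ord]), row.names = NULL)
}
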