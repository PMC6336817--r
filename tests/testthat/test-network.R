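test_that("pearsonR matches hand-computed values and degenerate rules", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonR(x, 2 * x + 1), 1)
  expect_equal(pearsonR(x, -x), -1)
  expect_equal(pearsonR(x, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearsonR(x, rep(2, 4))))
  expect_error(pearsonR(1:3, 1:4), "equal length")
  ## invariance under positive affine transforms
  set.seed(2)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(pearsonR(3 * a + 7, b), pearsonR(a, b))
  expect_equal(pearsonR(a, 0.5 * b - 2), pearsonR(a, b))
})

test_that("correlation count is strict, signed, and ignores NA", {
  expect_equal(correlationCount(c(0.9, 0.9, 0.9)), 3)
  expect_equal(correlationCount(c(0.5, 0.4, -0.9)), 0)
  expect_equal(correlationCount(c(0.51, 0.2, 0.7)), 2)
  expect_equal(correlationCount(c(NA, 0.8)), 1)
  expect_equal(correlationCount(c(-0.99, -0.99)), 0)
})

test_that("consensus network obeys the TF-edge rule and weight bounds", {
  sim <- simulateCohorts(simulationConfig(nCohorts = 1, moduleRho = 0.95,
                                          seed = 4))
  ch <- sim$cohorts[[1]]
  tfs <- sprintf("TF%02d", 1:9)
  genes <- setdiff(sim$truth@sharedUp, tfs)
  ## three identical cohorts: every edge present must have weight 3
  net3 <- buildConsensus(list(ch, ch, ch), tfs, genes)
  expect_true(all(net3@edges$weight == 3))
  net1 <- buildConsensus(list(ch), tfs, genes)
  expect_true(all(net1@edges$weight == 1))
  ## same edges in both (consensus of identical data adds nothing)
  key <- function(e) paste(e$nodeA, e$nodeB)
  expect_setequal(key(net3@edges), key(net1@edges))
  ## module members are wired to the master TF
  moduleEdges <- net1@edges[net1@edges$nodeA == sim$truth@masterTF |
                            net1@edges$nodeB == sim$truth@masterTF, ]
  partners <- setdiff(unique(c(moduleEdges$nodeA, moduleEdges$nodeB)),
                      sim$truth@masterTF)
  expect_true(all(setdiff(sim$truth@moduleMembers,
                          sim$truth@masterTF) %in% partners))
  ## every edge touches a TF: non-TF pairs are never connected
  tfSet <- net1@nodes$node[net1@nodes$isTF]
  expect_true(all(net1@edges$nodeA %in% tfSet |
                  net1@edges$nodeB %in% tfSet))
  expect_error(buildConsensus(list(ch), tfs, c(genes, "NOPE")),
               "NOPE.*cohort1")
})

test_that("removing a cohort never increases an edge weight", {
  sims <- lapply(1:3, function(s)
    simulateCohorts(simulationConfig(nCohorts = 1, moduleRho = 0.8,
                                     seed = s)))
  cohorts <- lapply(sims, function(s) s$cohorts[[1]])
  tfs <- sprintf("TF%02d", 1:9)
  genes <- setdiff(sims[[1]]$truth@sharedUp, tfs)
  netAll <- buildConsensus(cohorts, tfs, genes)
  netTwo <- buildConsensus(cohorts[1:2], tfs, genes)
  keyAll <- paste(netAll@edges$nodeA, netAll@edges$nodeB)
  keyTwo <- paste(netTwo@edges$nodeA, netTwo@edges$nodeB)
  common <- intersect(keyAll, keyTwo)
  expect_true(all(netTwo@edges$weight[match(common, keyTwo)] <=
                  netAll@edges$weight[match(common, keyAll)]))
  ## an edge absent from the superset network cannot appear in the subset
  expect_true(all(keyTwo %in% keyAll))
  expect_true(all(netAll@edges$weight <= 3))
})

## hand-built network helper: unit-weight edges unless stated
handNet <- function(edges, tfs, nDatasets = 1L) {
  nodes <- sort(unique(c(edges$nodeA, edges$nodeB, tfs)))
  if (is.null(edges$weight)) edges$weight <- 1L
  edges$r.1 <- 0.9
  new("ConsensusNetwork",
      nodes = data.frame(node = nodes, isTF = nodes %in% tfs),
      edges = edges, nDatasets = nDatasets)
}

test_that("weighted degree sums incident edge weights", {
  net <- handNet(data.frame(nodeA = c("T1", "T1", "T1"),
                            nodeB = c("a", "b", "c"),
                            weight = c(1L, 2L, 3L)),
                 tfs = "T1", nDatasets = 3L)
  expect_equal(unname(weightedDegree(net, "T1")), 6L)
  expect_equal(unname(weightedDegree(net, "a")), 1L)
  ## isolated node
  net2 <- handNet(data.frame(nodeA = "T1", nodeB = "a", weight = 1L),
                  tfs = c("T1", "T9"))
  expect_equal(unname(weightedDegree(net2, "T9")), 0L)
  expect_error(weightedDegree(net2, "missing"), "unknown node")
})

test_that("community detection separates disconnected cliques", {
  tri <- data.frame(nodeA = c("a1", "a1", "a2", "b1", "b1", "b2"),
                    nodeB = c("a2", "a3", "a3", "b2", "b3", "b3"))
  net <- handNet(tri, tfs = unique(c(tri$nodeA, tri$nodeB)))
  part <- detectCommunities(net, seed = 1)
  memb <- part@membership
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(memb[c("b1", "b2", "b3")])), 1)
  expect_gt(part@modularity, 0)

  ## complete graph on 4 nodes collapses to a single community
  k4 <- t(utils::combn(c("n1", "n2", "n3", "n4"), 2))
  netK4 <- handNet(data.frame(nodeA = k4[, 1], nodeB = k4[, 2]),
                   tfs = c("n1", "n2", "n3", "n4"))
  partK4 <- detectCommunities(netK4, seed = 1)
  expect_equal(length(unique(partK4@membership)), 1)
  ## modularity never below the trivial one-community partition (= 0)
  expect_gte(part@modularity, 0)
  expect_gte(partK4@modularity, 0)
})

test_that("planted two-block networks are partitioned correctly", {
  set.seed(8)
  aris <- replicate(5, {
    blockA <- sprintf("a%02d", 1:6); blockB <- sprintf("b%02d", 1:6)
    clique <- function(members) {
      cmb <- t(utils::combn(members, 2))
      data.frame(nodeA = cmb[, 1], nodeB = cmb[, 2], weight = 3L)
    }
    edges <- rbind(clique(blockA)[sample(15, 10), ],
                   clique(blockB)[sample(15, 10), ])
    net <- handNet(edges, tfs = c(blockA, blockB), nDatasets = 3L)
    part <- detectCommunities(net, seed = 1)
    truth <- ifelse(startsWith(names(part@membership), "a"), 1, 2)
    adjustedRand(part@membership, truth)
  })
  expect_gte(mean(aris), 0.9)
})

test_that("master-TF ranking picks the largest community, ties by weight", {
  ## largest community holds the TFs, ranked by weighted degree then name
  edges <- data.frame(nodeA = c("T1", "T1", "T1", "T2", "T2", "T3"),
                      nodeB = c("g1", "g2", "g3", "g1", "g2", "x1"),
                      weight = c(3L, 3L, 3L, 2L, 2L, 1L))
  net <- handNet(edges, tfs = c("T1", "T2", "T3"), nDatasets = 3L)
  part <- detectCommunities(net, seed = 1)
  rk <- rankMasterTFs(net, part)
  expect_equal(rk$tf[1], "T1")
  expect_equal(rk$weightedDegree[1], 9L)
  expect_true(all(diff(rk$weightedDegree) <= 0))

  ## single node that is a TF: degree zero
  net1 <- new("ConsensusNetwork",
              nodes = data.frame(node = "T1", isTF = TRUE),
              edges = data.frame(nodeA = character(0),
                                 nodeB = character(0),
                                 weight = integer(0)),
              nDatasets = 1L)
  p1 <- detectCommunities(net1, seed = 1)
  rk1 <- rankMasterTFs(net1, p1)
  expect_equal(rk1$tf, "T1")
  expect_equal(rk1$weightedDegree, 0L)

  ## equally sized communities: larger total internal weight wins
  e2 <- data.frame(nodeA = c("T1", "T1", "T2", "T2"),
                   nodeB = c("p1", "p2", "q1", "q2"),
                   weight = c(3L, 3L, 1L, 1L))
  net2 <- handNet(e2, tfs = c("T1", "T2"), nDatasets = 3L)
  memb <- stats::setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                          c("T1", "p1", "p2", "T2", "q1", "q2"))
  part2 <- new("CommunityPartition", membership = memb, modularity = 0.3)
  rk2 <- rankMasterTFs(net2, part2)
  expect_equal(unique(rk2$community), 1L)
  expect_equal(rk2$tf, "T1")

  ## a top community without TFs warns and returns an empty ranking
  nodes3 <- c("T1", "T2", "p1", "p2", "q1", "q2")
  net3 <- new("ConsensusNetwork",
              nodes = data.frame(node = nodes3,
                                 isTF = nodes3 %in% c("T1", "T2")),
              edges = data.frame(nodeA = "T1", nodeB = "T2", weight = 1L,
                                 r.1 = 0.9),
              nDatasets = 1L)
  memb3 <- stats::setNames(c(2L, 2L, 1L, 1L, 1L, 1L), nodes3)
  part3 <- new("CommunityPartition", membership = memb3, modularity = 0.1)
  expect_warning(rk3 <- rankMasterTFs(net3, part3), "no TF")
  expect_equal(nrow(rk3), 0)
})

test_that("planted master TF attains the top weighted degree", {
  hits <- vapply(1:3, function(s) {
    sim <- simulateCohorts(simulationConfig(seed = s))
    tfs <- sprintf("TF%02d", 1:9)
    genes <- setdiff(sim$truth@sharedUp, tfs)
    net <- buildConsensus(sim$cohorts, tfs, genes)
    part <- detectCommunities(net, seed = s)
    rk <- rankMasterTFs(net, part)
    identical(rk$tf[1], sim$truth@masterTF)
  }, logical(1))
  expect_true(all(hits))
})
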