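test_that("interactome construction dedupes, drops self-pairs, keeps provenance", {
  g <- buildInteractome(list(
    intact = data.frame(a = c("A", "B", "B", "A"),
                        b = c("B", "A", "C", "A")),
    hprd = data.frame(a = "A", b = "B")))
  ig <- asIgraph(g)
  expect_equal(igraph::ecount(ig), 2)       # (A,B), (B,C)
  expect_identical(selfLoopsDropped(g), 1L)      # the (A,A) pair
  eAB <- igraph::E(ig)[igraph::V(ig)["A"] %--% igraph::V(ig)["B"]]
  expect_identical(igraph::edge_attr(ig, "sources", eAB), "hprd;intact")
  expect_error(buildInteractome(data.frame(a = character(),
                                           b = character())), "no interaction")
})

test_that("tissue subnetworks are induced subgraphs", {
  tri <- buildInteractome(data.frame(a = c("A", "B", "C"),
                                     b = c("B", "C", "A"), source = "s"))
  # identity when everything is expressed
  same <- tissueSubnetwork(tri, c("A", "B", "C"))
  expect_setequal(geneSymbols(same), c("A", "B", "C"))
  expect_equal(igraph::ecount(asIgraph(same)), 3)
  # triangle restricted to two nodes keeps the single edge between them
  sub <- tissueSubnetwork(tri, c("A", "B"))
  expect_setequal(geneSymbols(sub), c("A", "B"))
  expect_equal(igraph::ecount(asIgraph(sub)), 1)
  # empty intersection warns, does not error
  expect_warning(empty <- tissueSubnetwork(tri, "ZZZ"), "no expressed")
  expect_length(geneSymbols(empty), 0)
})

test_that("closed-form centralities: star and path", {
  star <- buildInteractome(data.frame(a = "HUB",
                                      b = paste0("L", 1:4), source = "s"))
  cp <- centralityProfile(star)
  expect_equal(cp["HUB", "connectivity"], 4)
  expect_equal(unname(cp[paste0("L", 1:4), "connectivity"]), rep(1, 4))
  expect_equal(cp["HUB", "eccentricity"], 0.5)   # ecc 1 over diameter 2
  expect_equal(cp["HUB", "betweenness"], 1)      # all leaf pairs route via hub
  expect_equal(cp["HUB", "eigenvector"], 1)

  path <- buildInteractome(data.frame(a = c("A", "B"), b = c("B", "C"),
                                      source = "s"))
  cp <- centralityProfile(path)
  expect_equal(cp["B", "eccentricity"], 0.5)
  expect_equal(unname(cp[c("A", "C"), "eccentricity"]), c(1, 1))
  expect_equal(cp["B", "betweenness"], 1)        # the single non-adjacent pair
  expect_equal(unname(cp[c("A", "C"), "betweenness"]), c(0, 0))
  expect_equal(cp["B", "closeness"], 1)          # distances 1 and 1
  expect_equal(cp["A", "closeness"], 2 / 3)
})

test_that("all five centralities match brute-force oracles on random graphs", {
  set.seed(1234)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    A <- randomAdjacency(n)
    got <- centralityProfile(adjacencyToInteractome(A))
    # buildInteractome drops isolated nodes (no edges mention them);
    # restrict the oracle to the nodes present
    keep <- rownames(got)
    ora <- oracleCentralities(A[keep, keep, drop = FALSE])
    got <- got[keep, ]
    for (m in colnames(got))
      expect_equal(got[[m]], ora[[m]], tolerance = 1e-9,
                   info = paste("measure", m, "rep", rep))
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(5)
  A <- randomAdjacency(30, p = 0.15)
  g1 <- adjacencyToInteractome(A)
  perm <- sample(nrow(A))
  B <- A[perm, perm]
  g2 <- adjacencyToInteractome(B)
  c1 <- centralityProfile(g1)
  c2 <- centralityProfile(g2)
  common <- intersect(rownames(c1), rownames(c2))
  expect_equal(c1[common, ], c2[common, ], tolerance = 1e-9)
})

test_that("isolated nodes and disconnected components are scored per component", {
  # isolated nodes never enter an edge list, so use two components
  g <- buildInteractome(data.frame(
    a = c("A", "B", "C", "X", "Y"), b = c("B", "C", "A", "Y", "X"),
    source = "s"))
  cp <- centralityProfile(g)
  # both components fully scored; eigenvector nonzero only on the larger
  expect_equal(unname(cp[c("A", "B", "C"), "eigenvector"]),
               rep(1, 3), tolerance = 1e-9)
  expect_true(all(cp[c("X", "Y"), "eigenvector"] == 0))
  expect_equal(unname(cp[c("X", "Y"), "closeness"]), c(1, 1))
  expect_equal(unname(cp[c("X", "Y"), "eccentricity"]), c(1, 1))
})

test_that("eccentricity histograms normalize and expose the modal bin", {
  profs <- list(flat = c(0.63, 0.63, 0.62, 1.0),
                unit = rep(1, 5))
  ed <- eccentricityDistribution(profs)
  expect_equal(unname(rowSums(ed$histograms)), c(1, 1))
  expect_equal(unname(ed$modal["flat"]), 0.625)
  expect_equal(unname(ed$modal["unit"]), 0.975)
  # ties resolve to the lower bin (left-closed binning)
  tie <- list(t = c(0.12, 0.9))
  expect_equal(unname(eccentricityDistribution(tie)$modal), 0.125)
  expect_error(eccentricityDistribution(list(x = numeric())), "empty")
})

test_that("tissue clustering recovers planted groups and is seeded", {
  # identical histograms per group: exact recovery
  h <- rbind(matrix(rep(c(1, 0, 0), each = 4), 4, 3, byrow = FALSE),
             matrix(rep(c(0, 0, 1), each = 4), 4, 3, byrow = FALSE))
  rownames(h) <- paste0("t", 1:8)
  cl <- clusterTissues(h, K = 2, seed = 3)
  expect_length(unique(cl$cluster[1:4]), 1)
  expect_length(unique(cl$cluster[5:8]), 1)
  expect_false(cl$cluster[1] == cl$cluster[5])
  # K = n gives singleton clusters with zero inertia
  clN <- clusterTissues(h + matrix(runif(24, 0, 1e-3), 8), K = 8, seed = 1)
  expect_equal(clN$totWithinss, 0, tolerance = 1e-12)
  expect_error(clusterTissues(h, K = 9), "exceeds")
  # determinism given the seed
  expect_identical(clusterTissues(h, 2, seed = 7),
                   clusterTissues(h, 2, seed = 7))
})

test_that("random-graph comparison is seeded and detects lattice structure", {
  ring <- igraph::make_ring(40)
  igraph::V(ring)$name <- paste0("n", 1:40)
  latt <- igraph::connect(ring, 2)     # ring lattice, neighborhood 2
  igraph::V(latt)$name <- paste0("n", 1:40)
  g <- buildInteractome(igraph::as_data_frame(latt)[, 1:2])
  ps <- vapply(1:5, function(s)
    compareToRandom(g, nRandom = 20, seed = s)$p.value, numeric(1))
  expect_true(all(ps < 0.05))          # lattices inflate eccentricity
  # reproducible given the seed
  r1 <- compareToRandom(g, nRandom = 5, seed = 11)
  r2 <- compareToRandom(g, nRandom = 5, seed = 11)
  expect_identical(r1$p.value, r2$p.value)
  expect_identical(r1$nullModel, "degree_rewire")
})

test_that("landscape surface bins genes and flags the high-high corner", {
  kl <- c(A = 20, B = 12, C = 0.5, D = 0, E = 3)
  imm <- makeRelevance(kl, "immune")
  can <- makeRelevance(c(A = 15, B = 0.2, C = 8, D = 0, E = 2), "neoplasm")
  prof <- data.frame(connectivity = c(5, 3, 2, 1, 4),
                     betweenness = 0, closeness = 0, eigenvector = 0,
                     eccentricity = 1, row.names = names(kl))
  ls <- landscapeSurface(imm, can, prof, bins = 4)
  expect_setequal(ls$table$gene[ls$table$high_high], c("A", "E"))
  expect_equal(sum(ls$count), 5)
  expect_equal(sum(ls$meanConnectivity * ls$count, na.rm = TRUE),
               sum(prof$connectivity))
  # single gene: one occupied cell holding its degree
  one <- landscapeSurface(makeRelevance(c(Z = 2)),
                          makeRelevance(c(Z = 3)),
                          data.frame(connectivity = 7, betweenness = 0,
                                     closeness = 0, eigenvector = 0,
                                     eccentricity = 1, row.names = "Z"),
                          bins = 3)
  expect_equal(sum(one$count), 1)
  expect_equal(max(one$maxConnectivity, na.rm = TRUE), 7)
})

test_that("score-centrality correlations behave at the extremes", {
  set.seed(21)
  kl <- setNames(runif(50, 0, 10), sprintf("g%02d", 1:50))
  imm <- makeRelevance(kl)
  can <- makeRelevance(kl)              # identical scores
  prof <- data.frame(connectivity = -kl + 20, betweenness = runif(50),
                     closeness = runif(50), eigenvector = runif(50),
                     eccentricity = runif(50), row.names = names(kl))
  res <- scoreCentralityCorrelation(imm, can, prof)
  expect_equal(res$spearmanImmuneCancer, 1.0)
  expect_equal(res$pearson["immune", "connectivity"], -1.0)
  # independent vectors stay weakly correlated
  set.seed(22)
  kl2 <- setNames(runif(1000), sprintf("h%04d", 1:1000))
  imm2 <- makeRelevance(kl2)
  can2 <- makeRelevance(setNames(runif(1000), names(kl2)))
  prof2 <- data.frame(connectivity = runif(1000), betweenness = runif(1000),
                      closeness = runif(1000), eigenvector = runif(1000),
                      eccentricity = runif(1000), row.names = names(kl2))
  res2 <- scoreCentralityCorrelation(imm2, can2, prof2)
  expect_true(all(abs(res2$pearson) < 0.1))
  # constant vector: undefined, reported missing
  profC <- prof; profC$closeness <- 1
  expect_true(is.na(
    scoreCentralityCorrelation(imm, can, profC)$pearson["immune",
                                                        "closeness"]))
})
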