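# Small deterministic study builder.
makeStudy <- function(m, detection = NULL, condition = NULL, ...) {
  sd <- data.frame(row.names = colnames(m), ...)
  if (!is.null(condition)) sd$condition <- condition
  ExpressionStudy(m, detection = detection, sampleData = sd)
}

test_that("quantile normalization matches the order-statistic contract", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # identical columns unchanged; column means equalized; idempotent
  set.seed(31)
  r <- matrix(rlnorm(200, 5), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  qr <- quantileNormalize(r)
  expect_equal(diff(range(colMeans(qr))), 0, tolerance = 1e-12)
  expect_equal(quantileNormalize(qr), qr, tolerance = 1e-12)
  same <- cbind(a = r[, 1], b = r[, 1])
  expect_equal(quantileNormalize(same), same, tolerance = 1e-12)

  expect_warning(one <- quantileNormalize(r[, 1, drop = FALSE]), "single")
  expect_identical(one, r[, 1, drop = FALSE])

  # the ExpressionStudy method normalizes the exprs assay in place
  st <- makeStudy(r, condition = rep(c("x", "y"), 2))
  stn <- quantileNormalize(st)
  expect_equal(intensityMatrix(stn), qr, tolerance = 1e-12)
})

test_that("detection filter applies strict 'more than' boundaries", {
  m <- matrix(100, 3, 5, dimnames = list(c("all", "atMin", "aboveMin"),
                                         paste0("s", 1:5)))
  dp <- rbind(all = rep(0.001, 5),
              atMin = c(0.001, 0.001, 0.5, 0.5, 0.5),
              aboveMin = c(0.001, 0.001, 0.001, 0.5, 0.5))
  st <- makeStudy(m, detection = dp, condition = rep("c", 5))
  suppressMessages(kept <- detectionFilter(st, alpha = 0.01,
                                           minSamples = 2))
  # significant in exactly minSamples samples -> dropped (strict)
  expect_setequal(rownames(kept), c("all", "aboveMin"))

  # alpha boundary is strict too: p exactly at alpha does not count
  dpEdge <- rbind(all = rep(0.01, 5), atMin = rep(0.001, 5),
                  aboveMin = rep(0.001, 5))
  stEdge <- makeStudy(m, detection = dpEdge, condition = rep("c", 5))
  suppressMessages(keptEdge <- detectionFilter(stEdge, alpha = 0.01,
                                               minSamples = 2))
  expect_false("all" %in% rownames(keptEdge))

  # default minSamples scales the 50-of-57 rule
  suppressMessages(k57 <- detectionFilter(st))   # ceiling(50/57*5) = 5
  expect_identical(nrow(k57), 0L)

  stNoDet <- makeStudy(m, condition = rep("c", 5))
  expect_error(detectionFilter(stNoDet), "no detection")
})

test_that("fold-change DE respects the strict threshold and symmetry", {
  m <- cbind(a1 = c(10, 10, 30, 5), a2 = c(10, 10, 30, 5),
             b1 = c(25, 20, 10, 5), b2 = c(25, 20, 10, 5))
  rownames(m) <- c("up", "edge", "down", "flat")
  st <- makeStudy(m, condition = c("a", "a", "b", "b"))
  de <- foldChangeDE(st, "a", "b", threshold = 2)
  expect_identical(upInB(de), "up")       # 25/10 = 2.5 > 2
  expect_identical(downInB(de), "down")   # 30/10 = 3 > 2
  # ratio exactly 2 ("edge") fails the strict cutoff

  # swapping conditions swaps directions exactly
  rev <- foldChangeDE(st, "b", "a", threshold = 2)
  expect_identical(upInB(rev), downInB(de))
  expect_identical(downInB(rev), upInB(de))

  # identical profiles: both sets empty
  mSame <- m[, c(1, 2, 1, 2)]
  colnames(mSame) <- paste0("s", 1:4)
  stSame <- makeStudy(mSame, condition = c("a", "a", "b", "b"))
  deSame <- foldChangeDE(stSame, "a", "b")
  expect_length(deGenes(deSame), 0)

  expect_error(foldChangeDE(st, "a", "zzz"), "no samples")
})

test_that("direction symmetry holds for random studies", {
  set.seed(77)
  for (rep in 1:10) {
    m <- matrix(rlnorm(40 * 6, 4, 1), 40, 6,
                dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:6)))
    st <- makeStudy(m, condition = rep(c("a", "b"), each = 3))
    de <- foldChangeDE(st, "a", "b")
    rev <- foldChangeDE(st, "b", "a")
    expect_identical(sort(upInB(de)), sort(downInB(rev)))
    expect_identical(sort(downInB(de)), sort(upInB(rev)))
  }
})

test_that("mean DE relevance averages the union of directions", {
  rel <- makeRelevance(c(G1 = 1, G2 = 2, G3 = 6, G4 = 0))
  de <- new("DEComparison", conditionA = "a", conditionB = "b",
            upInB = c("G1", "G2"), downInB = "G3", threshold = 2)
  expect_equal(meanImmuneOfDE(de, rel), 3)
  one <- new("DEComparison", conditionA = "a", conditionB = "b",
             upInB = "G2", downInB = character(), threshold = 2)
  expect_equal(meanImmuneOfDE(one, rel), 2)
  emptyDe <- new("DEComparison", conditionA = "a", conditionB = "b",
                 upInB = character(), downInB = character(), threshold = 2)
  expect_true(is.na(meanImmuneOfDE(emptyDe, rel)))
  # unknown genes weigh 0 bits, with a message
  unk <- new("DEComparison", conditionA = "a", conditionB = "b",
             upInB = c("G3", "NOVEL"), downInB = character(), threshold = 2)
  expect_message(v <- meanImmuneOfDE(unk, rel), "missing")
  expect_equal(v, 3)
})

test_that("pairwise immune matrix composes single comparisons symmetrically", {
  set.seed(13)
  m <- matrix(rlnorm(30 * 6, 5, 1), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:6)))
  st <- makeStudy(m, condition = c("a", "a", "b", "b", "c", "c"))
  rel <- makeRelevance(setNames(runif(30, 0, 5), rownames(m)))
  M <- suppressMessages(pairwiseImmuneMatrix(st, rel))
  expect_true(all(is.na(diag(M))))
  expect_equal(M, t(M))
  expect_equal(M["a", "b"],
               meanImmuneOfDE(foldChangeDE(st, "a", "b"), rel))
  expect_equal(M["b", "c"],
               meanImmuneOfDE(foldChangeDE(st, "b", "c"), rel))
})

test_that("ranked transition lists apply the strict KL cutoff in order", {
  rel <- makeRelevance(c(A = 12, B = 11, C = 5, D = 0.4, E = 2))
  de <- new("DEComparison", conditionA = "n", conditionB = "t",
            upInB = c("A", "C", "D"), downInB = c("B", "E"), threshold = 2)
  rt <- rankedTransitionGenes(de, rel, klMin = 1)
  expect_identical(rt$up$gene, c("A", "C"))      # D below 1 bit
  expect_identical(rt$down$gene, c("B", "E"))
  expect_true(all(diff(rt$up$kl_bits) <= 0))
  # klMin 0 keeps everything; klMin above max empties the lists
  expect_identical(nrow(rankedTransitionGenes(de, rel, 20)$up), 0L)
  all0 <- rankedTransitionGenes(de, rel, 0)
  expect_identical(all0$up$gene, c("A", "C", "D"))
})

test_that("composite W_g has the decided log-ratio-times-KL form", {
  m <- cbind(p1 = c(10, 100), p2 = c(30, 100))
  rownames(m) <- c("G1", "G2")
  st <- makeStudy(m, condition = c("x", "x"))
  rel <- makeRelevance(c(G1 = 3, G2 = 0))
  wg <- compositeGeneScore(st, rel)
  msi <- 20
  expect_equal(wg["G1", "p1"], log2(10 / msi) * 3)
  expect_equal(wg["G1", "p2"], log2(30 / msi) * 3)
  expect_equal(unname(wg["G2", ]), c(0, 0))       # zero relevance
  # S = MSI gives 0; S = 2*MSI with KL 3 gives exactly 3
  m2 <- cbind(p1 = 10, p2 = 10, p3 = 40)
  rownames(m2) <- "G"
  st2 <- makeStudy(m2, condition = rep("x", 3))
  rel2 <- makeRelevance(c(G = 3))
  wg2 <- compositeGeneScore(st2, rel2)
  expect_equal(unname(wg2["G", "p3"]), 3 * log2(2))
})

test_that("patient grades sum W_g and are linear in relevance", {
  set.seed(41)
  m <- matrix(rlnorm(20 * 8, 5, 1), 20, 8,
              dimnames = list(sprintf("g%02d", 1:20), paste0("p", 1:8)))
  st <- makeStudy(m, condition = rep("x", 8))
  kl <- setNames(runif(20, 0, 4), rownames(m))
  wg <- compositeGeneScore(st, makeRelevance(kl))
  wp <- patientScore(wg)
  expect_equal(wp, colSums(wg))
  expect_equal(unname(patientScore(wg["g01", , drop = FALSE])),
               unname(wg["g01", ]))
  # doubling every kl_bits doubles every W_p
  wp2 <- patientScore(compositeGeneScore(st, makeRelevance(2 * kl)))
  expect_equal(wp2, 2 * wp, tolerance = 1e-12)
  # all-zero relevance: all-zero grades
  wp0 <- patientScore(compositeGeneScore(st, makeRelevance(0 * kl)))
  expect_true(all(wp0 == 0))
})

test_that("binary phenotype association: direction, ties and determinism", {
  wp <- c(a1 = 0, a2 = 1, a3 = 2, b1 = 10, b2 = 11, b3 = 12)
  lab <- rep(c("a", "b"), each = 3)
  res <- phenotypeAssociation(wp, lab, nDraws = 500, seed = 9)
  # perfectly separated: no permutation strictly beats the observed split
  expect_identical(res$p.raw, 0)
  expect_equal(res$p.smoothed, 1 / 501)
  expect_identical(res$direction, "up_in_b")

  # swapping class labels flips direction, keeps the p-value
  resSwap <- phenotypeAssociation(wp, rep(c("b", "a"), each = 3),
                                  nDraws = 500, seed = 9)
  expect_identical(resSwap$direction, "down_in_b")
  expect_identical(resSwap$p.raw, res$p.raw)
  expect_equal(abs(resSwap$statistic), abs(res$statistic))

  # deterministic given the seed
  set.seed(1); w2 <- rnorm(20)
  l2 <- rep(c("x", "y"), 10)
  expect_identical(phenotypeAssociation(w2, l2, 200, seed = 4),
                   phenotypeAssociation(w2, l2, 200, seed = 4))
  expect_error(phenotypeAssociation(w2, rep("x", 20), 100), "two")
})

test_that("numeric phenotype correlation hits the exact extremes", {
  set.seed(15)
  wp <- rnorm(30)
  res <- numericPhenotypeCorrelation(wp, wp, nDraws = 200, seed = 2)
  expect_equal(res$r, 1.0)
  resNeg <- numericPhenotypeCorrelation(wp, -wp, nDraws = 200, seed = 2)
  expect_equal(resNeg$r, -1.0)
  expect_identical(res$p.raw, 0)
  # independent vectors: small r
  r2 <- numericPhenotypeCorrelation(rnorm(200), rnorm(200),
                                    nDraws = 200, seed = 3)
  expect_lt(abs(r2$r), 0.2)
  expect_gt(r2$p.smoothed, 0.01)
  expect_warning(cst <- numericPhenotypeCorrelation(rep(1, 5), 1:5, 100),
                 "constant")
  expect_true(is.na(cst$r))
  expect_error(numericPhenotypeCorrelation(1:2, 1:2), "at least 3")
})

test_that("immune subnetworks select high-relevance DE genes with attributes", {
  g <- buildInteractome(data.frame(a = c("A", "B", "C", "D"),
                                   b = c("B", "C", "A", "E"),
                                   source = "s"))
  rel <- makeRelevance(c(A = 5, B = 4, C = 3, D = 0.5, E = 2))
  de <- new("DEComparison", conditionA = "n", conditionB = "t",
            upInB = c("A", "B", "D"), downInB = "C", threshold = 2)
  sub <- immuneSubnetwork(de, rel, g, klMin = 1)
  expect_setequal(geneSymbols(sub), c("A", "B", "C"))   # triangle survives
  expect_equal(igraph::ecount(asIgraph(sub)), 3)
  ig <- asIgraph(sub)
  expect_identical(igraph::V(ig)$direction[match("C", igraph::V(ig)$name)],
                   "down")
  expect_equal(igraph::V(ig)$kl_bits[match("A", igraph::V(ig)$name)], 5)
  # nothing qualifies: empty graph with warning
  expect_warning(none <- immuneSubnetwork(de, rel, g, klMin = 100),
                 "no high-relevance")
  expect_length(geneSymbols(none), 0)
})
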