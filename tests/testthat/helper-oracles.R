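# Independent brute-force oracles. These deliberately share no code with
# the package implementation: plain dense double loops over the printed
# formulas, Floyd-Warshall distances, explicit shortest-path counting and
# power iteration.

# Naive double-loop Shannon / KL over a dense count matrix.
oracleScores <- function(counts, contextTerms) {
  counts <- as.matrix(counts)
  GS <- sum(counts)
  out <- data.frame(gene = rownames(counts),
                    shannon = 0, kl = 0, stringsAsFactors = FALSE)
  for (g in seq_len(nrow(counts))) {
    gT <- sum(counts[g, ])
    q <- if (GS > 0) gT / GS else 0
    H <- 0; KL <- 0
    for (term in contextTerms) {
      if (!term %in% colnames(counts)) next
      iT <- sum(counts[, term])
      if (iT == 0) next
      p <- counts[g, term] / iT
      if (p > 0) {
        H <- H - p * log2(p)
        KL <- KL + p * log2(p / q)
      }
    }
    out$shannon[g] <- H
    out$kl[g] <- KL
  }
  out
}

# All-pairs shortest-path distances by Floyd-Warshall on an adjacency
# matrix (Inf when unreachable).
oracleDistances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Shortest-path counts sigma[s, t] from the distance matrix by dynamic
# programming over predecessors.
oraclePathCounts <- function(adj, D) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(adj[, t] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  sigma
}

# All five centrality measures from first principles, under the package's
# stated normalizations (per component; eigenvector on the largest
# component only, ties toward the earliest-indexed node's component).
oracleCentralities <- function(adj) {
  n <- nrow(adj)
  out <- data.frame(connectivity = rowSums(adj > 0),
                    betweenness = 0, closeness = 0,
                    eigenvector = 0, eccentricity = 0,
                    row.names = rownames(adj))
  D <- oracleDistances(adj)
  # connected components from reachability
  compId <- integer(n)
  cid <- 0
  for (v in seq_len(n)) {
    if (compId[v] == 0) {
      cid <- cid + 1
      compId[is.finite(D[v, ])] <- cid
    }
  }
  sigma <- oraclePathCounts(adj, D)
  for (ci in seq_len(cid)) {
    vs <- which(compId == ci)
    nc <- length(vs)
    if (nc < 2) next
    Dc <- D[vs, vs, drop = FALSE]
    out$closeness[vs] <- (nc - 1) / rowSums(Dc)
    ecc <- apply(Dc, 1, max)
    out$eccentricity[vs] <- ecc / max(ecc)
    if (nc >= 3) {
      for (v in vs) {
        b <- 0
        for (s in vs) for (t in vs) {
          if (s >= t || s == v || t == v) next
          if (sigma[s, t] > 0 && D[s, v] + D[v, t] == D[s, t])
            b <- b + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
        out$betweenness[v] <- b / ((nc - 1) * (nc - 2) / 2)
      }
    }
  }
  sizes <- tabulate(compId, cid)
  largest <- which.max(sizes)
  vs <- which(compId == largest)
  if (length(vs) >= 2 && sum(adj[vs, vs]) > 0) {
    A <- adj[vs, vs, drop = FALSE]
    # power iteration with +I shift to dodge bipartite oscillation
    x <- rep(1, length(vs))
    for (i in 1:10000) {
      xn <- A %*% x + x
      xn <- xn / sqrt(sum(xn^2))
      if (max(abs(xn - x)) < 1e-13) { x <- xn; break }
      x <- xn
    }
    out$eigenvector[vs] <- as.numeric(x) / max(x)
  }
  out
}

# Random undirected simple graph as a 0/1 adjacency matrix with names.
randomAdjacency <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.05, 0.3)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  if (sum(A) == 0) A[1, 2] <- 1     # an edgeless graph is no interactome
  A <- A + t(A)
  dimnames(A) <- list(sprintf("v%03d", 1:n), sprintf("v%03d", 1:n))
  A
}

adjacencyToInteractome <- function(A) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  buildInteractome(data.frame(a = rownames(A)[idx[, 1]],
                              b = rownames(A)[idx[, 2]],
                              source = "sim"))
}

# A small deterministic co-citation fixture used across tests:
#   4 genes x 5 terms, context = first 2 terms.
fixtureCocitation <- function() {
  m <- matrix(c(10,  0,  5,  5,  0,
                 0,  0, 10, 10, 20,
                 5,  5,  0,  0,  0,
                 0,  2,  0,  3,  5),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("CD8A", "GAPDH", "IL2", "TP53"),
                              c("T001", "T002", "T003", "T004", "T005")))
  list(table = CoCitationTable(m),
       dictionary = TermDictionary("immune", data.frame(
         term_id = c("T001", "T002"), source = c("GO", "MeSH"),
         term_text = c("immune response", "Immunity"))),
       counts = m)
}
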