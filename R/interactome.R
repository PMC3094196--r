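#' @include AllClasses.R AllGenerics.R constructors.R
#' @importFrom igraph V E vcount ecount graph_from_data_frame
NULL

#' Build an interactome from one or more edge lists
#'
#' Integrates binary interactor pairs from one or more source databases
#' into a single undirected simple graph. Pairs are canonicalized (so
#' `(A,B)` and `(B,A)` collapse), self-pairs are dropped and counted, and
#' every deduplicated edge retains the full list of contributing sources
#' in its `sources` attribute.
#'
#' @param edges a `data.frame` with the first two columns holding symbol
#'   pairs and an optional `source` column, or a named list of such
#'   data.frames (names used as source labels).
#' @return An [InteractomeGraph-class].
#' @examples
#' g <- buildInteractome(data.frame(a = c("A", "B", "B"),
#'                                  b = c("B", "A", "C"),
#'                                  source = "demo"))
#' g
#' @export
buildInteractome <- function(edges) {
  if (is.data.frame(edges)) edges <- list(edges)
  if (!length(edges) || !sum(vapply(edges, nrow, integer(1))))
    stop("no interaction pairs supplied", call. = FALSE)
  if (is.null(names(edges)))
    names(edges) <- paste0("source", seq_along(edges))
  pieces <- lapply(names(edges), function(nm) {
    df <- edges[[nm]]
    src <- if ("source" %in% colnames(df)) as.character(df$source)
           else rep(nm, nrow(df))
    data.frame(a = as.character(df[[1L]]), b = as.character(df[[2L]]),
               source = src, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  selfLoops <- sum(df$a == df$b)
  df <- df[df$a != df$b, , drop = FALSE]
  if (!nrow(df)) stop("all supplied pairs were self-pairs", call. = FALSE)
  u <- pmin(df$a, df$b)
  v <- pmax(df$a, df$b)
  key <- paste(u, v, sep = "\r")
  srcs <- vapply(split(df$source, key), function(s)
    paste(sort(unique(s)), collapse = ";"), character(1))
  uv <- do.call(rbind, strsplit(names(srcs), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = uv[, 1L], to = uv[, 2L], sources = unname(srcs),
               stringsAsFactors = FALSE),
    directed = FALSE)
  new("InteractomeGraph", graph = g, selfLoops = as.integer(selfLoops))
}

## Internal: wrap an igraph into an InteractomeGraph.
.wrapGraph <- function(g, selfLoops = 0L)
  new("InteractomeGraph", graph = g, selfLoops = as.integer(selfLoops))

#' Tissue-specific induced subnetwork
#'
#' Restricts an interactome to the genes expressed in one tissue: the
#' induced subgraph on `expressed` intersected with the node set. Node and
#' edge retention fractions are attached as graph attributes
#' `nodeRetention` / `edgeRetention`.
#'
#' @param graph an [InteractomeGraph-class].
#' @param expressed character vector of expressed gene symbols.
#' @return An [InteractomeGraph-class]; empty (with a warning) when no
#'   expressed gene is present in the network.
#' @export
setMethod("tissueSubnetwork", "InteractomeGraph",
function(graph, expressed, ...) {
  g <- graph@graph
  keep <- intersect(as.character(expressed), igraph::V(g)$name)
  if (!length(keep))
    warning("no expressed gene present in the network; empty subnetwork",
            call. = FALSE)
  sub <- igraph::induced_subgraph(g, keep)
  sub <- igraph::set_graph_attr(sub, "nodeRetention",
                                igraph::vcount(sub) /
                                  max(igraph::vcount(g), 1L))
  sub <- igraph::set_graph_attr(sub, "edgeRetention",
                                if (igraph::ecount(g) > 0)
                                  igraph::ecount(sub) / igraph::ecount(g)
                                else NA_real_)
  .wrapGraph(sub, graph@selfLoops)
})

#' Five centrality measures for every gene of a network
#'
#' Computes connectivity (degree), betweenness, closeness, eigenvector
#' centrality and normalized eccentricity. Disconnected graphs are handled
#' per connected component:
#' * closeness(v) = (n_c - 1) / sum of distances to v's component;
#' * betweenness is normalized by `(n_c - 1)(n_c - 2) / 2` (0 when
#'   `n_c < 3`);
#' * eigenvector centrality is the principal eigenvector of the largest
#'   component's adjacency matrix scaled to maximum 1, 0 elsewhere (ties on
#'   component size resolved toward the component holding the
#'   earliest-indexed node);
#' * normalized eccentricity(v) = ecc(v) / diameter of v's component, which
#'   lies in (0, 1\] so that lower values mean shorter network reach;
#' * isolated nodes get 0 for every measure.
#'
#' @param graph an [InteractomeGraph-class].
#' @return `data.frame` with rownames = gene symbols and columns
#'   `connectivity`, `betweenness`, `closeness`, `eigenvector`,
#'   `eccentricity`.
#' @export
setMethod("centralityProfile", "InteractomeGraph", function(graph, ...) {
  g <- graph@graph
  n <- igraph::vcount(g)
  out <- data.frame(connectivity = as.numeric(igraph::degree(g)),
                    betweenness = numeric(n), closeness = numeric(n),
                    eigenvector = numeric(n), eccentricity = numeric(n),
                    row.names = igraph::V(g)$name)
  if (n == 0L) return(out)
  comp <- igraph::components(g)
  largest <- which.max(comp$csize)   # ties -> lowest component id
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    nc <- length(vs)
    if (nc < 2L) next                # isolated node: all zeros
    sub <- igraph::induced_subgraph(g, vs)
    d <- igraph::distances(sub)
    out$closeness[vs] <- (nc - 1) / rowSums(d)
    ecc <- apply(d, 1L, max)
    out$eccentricity[vs] <- ecc / max(ecc)
    if (nc >= 3L)
      out$betweenness[vs] <- igraph::betweenness(sub, directed = FALSE) /
        ((nc - 1) * (nc - 2) / 2)
    if (ci == largest && igraph::ecount(sub) > 0)
      out$eigenvector[vs] <- igraph::eigen_centrality(sub)$vector
  }
  out
})

#' Per-tissue normalized eccentricity histograms and modal values
#'
#' Converts per-tissue centrality profiles into normalized frequency
#' histograms of normalized eccentricity (each summing to 1) plus the modal
#' value -- the midpoint of the highest-frequency bin, ties resolved to the
#' lower bin. This is the summary on which tissue classes separate (immune
#' tissues showing the lowest modal values).
#'
#' @param profiles named list; each element either a numeric vector of
#'   normalized eccentricities or a profile `data.frame` from
#'   [centralityProfile()] (its `eccentricity` column is used).
#' @param binEdges bin edges over \[0, 1\]; default 20 bins of width 0.05.
#' @return list with `histograms` (tissues x bins matrix of frequencies),
#'   `modal` (named numeric) and `mids` (bin midpoints).
#' @export
eccentricityDistribution <- function(profiles,
                                     binEdges = seq(0, 1, by = 0.05)) {
  if (!is.list(profiles) || is.null(names(profiles)))
    stop("'profiles' must be a named list", call. = FALSE)
  vals <- lapply(profiles, function(p) {
    x <- if (is.data.frame(p)) p$eccentricity else as.numeric(p)
    if (!length(x)) stop("empty centrality profile", call. = FALSE)
    x
  })
  nb <- length(binEdges) - 1L
  mids <- (binEdges[-1L] + binEdges[-length(binEdges)]) / 2
  H <- t(vapply(vals, function(x) {
    idx <- findInterval(x, binEdges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = nb) / length(x)
  }, numeric(nb)))
  colnames(H) <- sprintf("bin%02d", seq_len(nb))
  modal <- apply(H, 1L, function(h) mids[which.max(h)])
  list(histograms = H, modal = modal, mids = mids)
}

#' K-means clustering of tissues on centrality histograms
#'
#' Groups tissues by the shape of their per-gene centrality distribution
#' (fixed-bin normalized histograms as feature vectors), using seeded
#' K-means with multiple restarts; the best solution by total
#' within-cluster sum of squares is kept.
#'
#' @param histograms tissues x bins numeric matrix (e.g. the `histograms`
#'   element of [eccentricityDistribution()]).
#' @param K number of clusters; must not exceed the number of tissues.
#' @param seed integer seed making the clustering deterministic.
#' @param nRestarts random restarts (default 50).
#' @return list with `cluster` (named assignment), `totWithinss` and
#'   `centers`.
#' @export
clusterTissues <- function(histograms, K, seed = 1L, nRestarts = 50L) {
  histograms <- as.matrix(histograms)
  if (K > nrow(histograms))
    stop("K exceeds the number of tissues", call. = FALSE)
  if (K == nrow(histograms)) {
    # every tissue its own cluster; stats::kmeans refuses K = n
    return(list(cluster = structure(seq_len(K),
                                    names = rownames(histograms)),
                totWithinss = 0, centers = histograms))
  }
  set.seed(seed)
  km <- stats::kmeans(histograms, centers = K, nstart = nRestarts)
  list(cluster = structure(km$cluster, names = rownames(histograms)),
       totWithinss = km$tot.withinss, centers = km$centers)
}

#' Compare a network's eccentricity distribution to degree-matched
#' random graphs
#'
#' Generates `nRandom` degree-preserving rewirings of the graph (10 x |E|
#' swap attempts each), pools their normalized eccentricities and tests the
#' observed values against the pool with a two-sided Wilcoxon rank-sum
#' test. Eccentricity is strongly degree-sequence dependent, hence the
#' rewiring null; for graphs too small to rewire a uniform random graph
#' with the same |V| and |E| is used instead and flagged.
#'
#' @param graph an [InteractomeGraph-class].
#' @param nRandom number of random replicates (>= 1).
#' @param seed integer seed.
#' @return list with `p.value`, `statistic`, `nullModel`
#'   (`"degree_rewire"` or `"gnm_fallback"`), `observed` and `random`
#'   eccentricity vectors.
#' @export
compareToRandom <- function(graph, nRandom = 20L, seed = 1L) {
  stopifnot(is(graph, "InteractomeGraph"), nRandom >= 1L)
  g <- graph@graph
  obs <- centralityProfile(graph)$eccentricity
  set.seed(seed)
  canRewire <- igraph::ecount(g) >= 2L
  rand <- unlist(lapply(seq_len(nRandom), function(i) {
    rg <- if (canRewire)
      igraph::rewire(g, igraph::keeping_degseq(
        niter = 10L * igraph::ecount(g)))
    else
      igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
    igraph::V(rg)$name <- as.character(seq_len(igraph::vcount(rg)))
    centralityProfile(.wrapGraph(rg))$eccentricity
  }))
  wt <- suppressWarnings(stats::wilcox.test(obs, rand,
                                            alternative = "two.sided"))
  list(p.value = wt$p.value, statistic = unname(wt$statistic),
       nullModel = if (canRewire) "degree_rewire" else "gnm_fallback",
       observed = obs, random = rand)
}

#' The immune x cancer x connectivity interactome landscape
#'
#' Bins every gene shared by the two relevance tables and the network into
#' a 2-D grid over log10 immune bits x log10 cancer bits, aggregating the
#' connectivity (degree) per cell, and flags "high-high" genes whose
#' immune and cancer relevance both exceed 1 bit (the level at which the
#' means of expert-curated resources start). Genes scoring 0 fall in the
#' lowest cell of their axis.
#'
#' @param immune,cancer [RelevanceTable-class] objects on a shared gene
#'   universe.
#' @param profile centrality `data.frame` from [centralityProfile()].
#' @param bins number of grid cells per axis.
#' @return list with `meanConnectivity`, `maxConnectivity`, `count`
#'   (bins x bins matrices), `xEdges`, `yEdges` (log10-bit edges) and
#'   `table`, the per-gene `data.frame` (`gene`, `immune_bits`,
#'   `cancer_bits`, `connectivity`, `high_high`).
#' @export
landscapeSurface <- function(immune, cancer, profile, bins = 20L) {
  stopifnot(is(immune, "RelevanceTable"), is(cancer, "RelevanceTable"))
  ib <- klBits(immune)
  cb <- klBits(cancer)
  genes <- intersect(intersect(names(ib), names(cb)), rownames(profile))
  tab <- data.frame(gene = genes,
                    immune_bits = unname(ib[genes]),
                    cancer_bits = unname(cb[genes]),
                    connectivity = profile[genes, "connectivity"],
                    stringsAsFactors = FALSE)
  tab$high_high <- tab$immune_bits > 1 & tab$cancer_bits > 1
  .axisBin <- function(x) {
    lx <- log10(x)
    fin <- is.finite(lx)
    if (!any(fin)) return(list(idx = rep(1L, length(x)), edges = c(0, 1)))
    edges <- seq(min(lx[fin]), max(lx[fin]), length.out = bins + 1L)
    if (edges[1] == edges[length(edges)])
      edges <- edges + seq(0, 1, length.out = bins + 1L)
    idx <- findInterval(lx, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    idx[!fin] <- 1L                     # zero scores: lowest cell
    list(idx = idx, edges = edges)
  }
  xb <- .axisBin(tab$immune_bits)
  yb <- .axisBin(tab$cancer_bits)
  agg <- function(f, init) {
    m <- matrix(init, bins, bins)
    sp <- split(tab$connectivity, list(x = xb$idx, y = yb$idx),
                drop = TRUE)
    for (nm in names(sp)) {
      ij <- as.integer(strsplit(nm, ".", fixed = TRUE)[[1L]])
      m[ij[1L], ij[2L]] <- f(sp[[nm]])
    }
    m
  }
  list(meanConnectivity = agg(mean, NA_real_),
       maxConnectivity = agg(max, NA_real_),
       count = agg(length, 0),
       xEdges = xb$edges, yEdges = yb$edges, table = tab)
}

#' Correlations between relevance scores and network centrality
#'
#' Pearson correlation of each relevance score against each of the five
#' centrality measures, plus the Spearman rank correlation between the
#' immune and cancer scores themselves. Constant vectors give `NA` (the
#' correlation is undefined) rather than an error.
#'
#' @inheritParams landscapeSurface
#' @return list with `pearson` (2 x 5 matrix, rows immune/cancer) and
#'   `spearmanImmuneCancer`.
#' @export
scoreCentralityCorrelation <- function(immune, cancer, profile) {
  ib <- klBits(immune)
  cb <- klBits(cancer)
  genes <- intersect(intersect(names(ib), names(cb)), rownames(profile))
  if (length(genes) < 3L)
    stop("need at least 3 shared genes", call. = FALSE)
  .safeCor <- function(x, y, method = "pearson") {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  meas <- c("connectivity", "betweenness", "closeness", "eigenvector",
            "eccentricity")
  pear <- rbind(
    immune = vapply(meas, function(m)
      .safeCor(ib[genes], profile[genes, m]), numeric(1)),
    cancer = vapply(meas, function(m)
      .safeCor(cb[genes], profile[genes, m]), numeric(1)))
  list(pearson = pear,
       spearmanImmuneCancer = .safeCor(ib[genes], cb[genes],
                                       method = "spearman"))
}
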