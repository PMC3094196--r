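#' @include AllClasses.R AllGenerics.R constructors.R
NULL

#' Simulate a literature co-citation corpus with planted context signal
#'
#' Emulates the statistical shape of a Medline-derived gene-by-term
#' co-citation table. Gene citation totals follow a Zipf law over a
#' randomly assigned popularity ranking (heavy-tailed literature
#' popularity); term popularity is itself mildly Zipf-distributed; each
#' gene's citations are allocated over terms by a multinomial draw. A
#' chosen number of planted genes have the odds of their context-term
#' citations multiplied by `enrichmentRatio`, creating genuine context
#' relevance; the truth set is returned for evaluation. All output is a
#' pure function of the seed.
#'
#' @param nGenes number of genes.
#' @param nTermsTotal size of the full co-citation vocabulary (GO + MeSH
#'   space).
#' @param nContextTerms number of context terms forming the dictionary
#'   (a subset of the vocabulary).
#' @param popularityExponent Zipf exponent for gene citation totals
#'   (default 1.1).
#' @param nPlanted number of context-enriched genes.
#' @param enrichmentRatio multiplier (>= 1) on the context-term citation
#'   odds of planted genes; 1 means no signal.
#' @param maxCitations,minCitations citation total of the most popular
#'   gene and the floor for the least popular one. Every gene in a curated
#'   co-citation corpus has non-trivial literature presence; the defaults
#'   span 50--10000 events.
#' @param termExponent Zipf exponent for term popularity (default 0.5).
#' @param context label for the generated dictionary.
#' @param seed integer seed.
#' @return list with `table` ([CoCitationTable-class]), `dictionary`
#'   ([TermDictionary-class]) and `planted` (character truth set).
#' @examples
#' sim <- simulateCocitationCorpus(nGenes = 100, nTermsTotal = 60,
#'                                 nContextTerms = 10, nPlanted = 10,
#'                                 seed = 7)
#' sim$table
#' @export
simulateCocitationCorpus <- function(nGenes = 1000L, nTermsTotal = 500L,
                                     nContextTerms = 50L,
                                     popularityExponent = 1.1,
                                     nPlanted = 50L, enrichmentRatio = 5,
                                     maxCitations = 10000L,
                                     minCitations = 50L,
                                     termExponent = 0.5,
                                     context = "immune", seed = 1L) {
  if (nPlanted > nGenes)
    stop("more planted genes than genes", call. = FALSE)
  if (nContextTerms > nTermsTotal)
    stop("context dictionary larger than the term vocabulary",
         call. = FALSE)
  if (enrichmentRatio < 1)
    stop("enrichmentRatio must be >= 1", call. = FALSE)
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(nGenes))
  terms <- sprintf("T%04d", seq_len(nTermsTotal))
  popRank <- sample.int(nGenes)
  gT <- pmax(minCitations, round(maxCitations / popRank^popularityExponent))
  termW <- 1 / sample.int(nTermsTotal)^termExponent
  ctxIdx <- sort(sample.int(nTermsTotal, nContextTerms))
  planted <- sort(sample(genes, nPlanted))
  counts <- matrix(0, nGenes, nTermsTotal,
                   dimnames = list(genes, terms))
  boosted <- termW
  boosted[ctxIdx] <- boosted[ctxIdx] * enrichmentRatio
  for (g in seq_len(nGenes)) {
    w <- if (genes[g] %in% planted) boosted else termW
    counts[g, ] <- stats::rmultinom(1L, gT[g], w)
  }
  dict <- TermDictionary(context, data.frame(
    term_id = terms[ctxIdx],
    source = rep_len(c("GO", "MeSH"), nContextTerms),
    term_text = paste("synthetic", context, "term", seq_len(nContextTerms)),
    stringsAsFactors = FALSE))
  list(table = CoCitationTable(counts), dictionary = dict,
       planted = planted)
}

#' Simulate a scale-free interactome with tissue expression sets
#'
#' Without tissue archetypes, grows a preferential-attachment graph
#' (`attachment` edges per new node, so `attachment = 1` yields a tree)
#' and draws each tissue's expressed gene set as a uniform sample of
#' `coverage` of the nodes. With a `tissues` data.frame carrying an
#' `archetype` column (values 1--3), the network is instead assembled
#' from three structurally distinct regions joined by a few bridge edges:
#' a dense module (Erdos-Renyi, p = 0.5; normalized eccentricity
#' concentrated at 1), a ring (eccentricities near-uniform over
#' \[0.5, 1\]) and a dense core carrying two thick antennae (bulk mass
#' near 0.5). A tissue expresses `coverage` of its archetype's region
#' plus `noiseShare` stray genes elsewhere. The archetypes therefore
#' carry distinct, sampling-stable normalized-eccentricity
#' distributions -- the planted structure used to validate tissue
#' clustering.
#'
#' @param nNodes number of genes (>= 2).
#' @param attachment preferential-attachment parameter (edges per node).
#' @param tissues either `NULL`, a character vector of tissue names, or a
#'   `data.frame` with columns `tissue` and `archetype`.
#' @param coverage fraction of the (region) nodes a tissue expresses.
#' @param noiseShare fraction of out-of-region nodes added in archetype
#'   mode.
#' @param seed integer seed.
#' @return list with `graph` ([InteractomeGraph-class]), `tissues`
#'   (named list of expressed symbol sets, possibly empty) and `regions`
#'   (archetype mode only: named list of region node sets).
#' @export
simulateInteractome <- function(nNodes = 300L, attachment = 2L,
                                tissues = NULL, coverage = 0.8,
                                noiseShare = 0.05, seed = 1L) {
  if (nNodes < 2L) stop("need at least 2 nodes", call. = FALSE)
  if (attachment < 1L) stop("attachment must be >= 1", call. = FALSE)
  if (coverage <= 0 || coverage > 1)
    stop("coverage must lie in (0, 1]", call. = FALSE)
  set.seed(seed)
  archetypeMode <- is.data.frame(tissues) &&
    "archetype" %in% colnames(tissues)
  nodeNames <- sprintf("N%04d", seq_len(nNodes))
  regions <- NULL
  if (archetypeMode) {
    sizes <- c(floor(nNodes / 3), floor(nNodes / 3), 0L)
    sizes[3L] <- nNodes - sum(sizes[1:2])
    ## dense core with two antennae of width 3; an antenna level breaks
    ## only when all three of its nodes drop out of a tissue's sample
    spider <- function(size) {
      L <- max(3L, floor(size / 10))
      coreN <- size - 6L * L
      sp <- igraph::sample_gnp(coreN, 0.5)
      for (a in 1:2) {
        prev <- sample(seq_len(coreN), 3L)
        for (lev in seq_len(L)) {
          ids <- igraph::vcount(sp) + 1:3
          sp <- igraph::add_vertices(sp, 3L)
          sp <- igraph::add_edges(sp,
            as.vector(t(as.matrix(expand.grid(prev, ids)))))
          prev <- ids
        }
      }
      sp
    }
    parts <- list(
      igraph::sample_gnp(sizes[1L], 0.5),
      igraph::make_ring(sizes[2L]),
      spider(sizes[3L]))
    g <- igraph::disjoint_union(parts)
    igraph::V(g)$name <- nodeNames
    bounds <- cumsum(sizes)
    regions <- list(dense = nodeNames[seq_len(bounds[1L])],
                    ring = nodeNames[(bounds[1L] + 1L):bounds[2L]],
                    spider = nodeNames[(bounds[2L] + 1L):bounds[3L]])
    ## a couple of bridges keep the interactome one component
    bridge <- rbind(
      c(sample(regions$dense, 1L), sample(regions$ring, 1L)),
      c(sample(regions$ring, 1L), sample(regions$spider, 1L)))
    g <- igraph::add_edges(g, t(bridge))
    g <- igraph::simplify(g)
  } else {
    g <- igraph::sample_pa(nNodes, power = 1, m = attachment,
                           directed = FALSE)
    igraph::V(g)$name <- nodeNames
    g <- igraph::simplify(g)
  }
  expressed <- list()
  if (archetypeMode) {
    for (i in seq_len(nrow(tissues))) {
      reg <- regions[[tissues$archetype[i]]]
      own <- sample(reg, max(1L, round(coverage * length(reg))))
      other <- setdiff(nodeNames, reg)
      stray <- sample(other, round(noiseShare * length(other)))
      expressed[[as.character(tissues$tissue[i])]] <- sort(c(own, stray))
    }
  } else if (!is.null(tissues)) {
    for (tn in as.character(tissues))
      expressed[[tn]] <-
        sort(sample(nodeNames, max(1L, round(coverage * nNodes))))
  }
  list(graph = .wrapGraph(g), tissues = expressed, regions = regions)
}

#' Simulate an expression cohort with a planted immune effect
#'
#' Emulates a two-group patient cohort profiled on an Illumina-like
#' platform. Baseline intensities are log-normal per gene with i.i.d.
#' log2-scale noise; in the affected (second) group the `nTop`
#' highest-relevance genes are multiplied by `2^effectSize`. Detection
#' p-values are small (`Beta(0.05, 100)`, i.e. detected at p < 0.01 in
#' ~99% of measurements, as robustly expressed array probes are) where a
#' gene is expressed, with a dropout fraction and a fraction of
#' never-expressed genes drawn uniform.
#' Sample annotations carry the planted `group` label, a pure-noise binary
#' label, a numeric phenotype tracking the planted effect and a pure-noise
#' numeric phenotype.
#'
#' @param relevance a [RelevanceTable-class] defining the gene universe and
#'   which genes count as high relevance.
#' @param nPerGroup integer vector of the two group sizes.
#' @param effectSize planted log2 fold change on the top-relevance genes.
#' @param nTop number of top-relevance genes carrying the effect.
#' @param noiseSd log2-scale noise standard deviation.
#' @param dropoutRate probability an expressed measurement loses its
#'   detection call.
#' @param lowExpressedFraction fraction of genes simulated as not
#'   expressed (background signal, uniform detection p-values).
#' @param seed integer seed.
#' @return list with `study` ([ExpressionStudy-class]), `plantedGenes`,
#'   `affectedGroup` (`"groupB"`) and `lowExpressed`.
#' @export
simulateExpressionCohort <- function(relevance, nPerGroup = c(20L, 20L),
                                     effectSize = 1, nTop = 100L,
                                     noiseSd = 0.5, dropoutRate = 0.05,
                                     lowExpressedFraction = 0.1,
                                     seed = 1L) {
  stopifnot(is(relevance, "RelevanceTable"), length(nPerGroup) == 2L,
            all(nPerGroup >= 1L), noiseSd > 0)
  set.seed(seed)
  sc <- relevanceScores(relevance)
  genes <- sc$gene
  nGenes <- length(genes)
  if (nTop > nGenes) stop("nTop exceeds the gene universe", call. = FALSE)
  planted <- sc$gene[order(sc$rank)][seq_len(nTop)]
  n <- sum(nPerGroup)
  group <- rep(c("groupA", "groupB"), nPerGroup)
  samples <- sprintf("P%03d", seq_len(n))
  lowExpressed <- sample(setdiff(genes, planted),
                         round(lowExpressedFraction * nGenes))
  baseMean <- stats::rnorm(nGenes, mean = 7, sd = 1)
  names(baseMean) <- genes
  baseMean[lowExpressed] <- stats::rnorm(length(lowExpressed), 1, 0.5)
  lg <- matrix(baseMean, nGenes, n) +
    matrix(stats::rnorm(nGenes * n, 0, noiseSd), nGenes, n)
  dimnames(lg) <- list(genes, samples)
  lg[planted, group == "groupB"] <-
    lg[planted, group == "groupB"] + effectSize
  exprs <- 2^lg
  detection <- matrix(stats::rbeta(nGenes * n, 0.05, 100), nGenes, n,
                      dimnames = dimnames(exprs))
  dropped <- matrix(stats::runif(nGenes * n) < dropoutRate, nGenes, n)
  detection[dropped] <- stats::runif(sum(dropped))
  detection[lowExpressed, ] <-
    stats::runif(length(lowExpressed) * n)
  pheno <- data.frame(
    condition = group,
    group = group,
    noise_label = sample(c("x", "y"), n, replace = TRUE),
    breslow = ifelse(group == "groupB", 2, 0) + stats::rnorm(n, 0, 1),
    noise_numeric = stats::rnorm(n),
    row.names = samples, stringsAsFactors = FALSE)
  study <- ExpressionStudy(exprs, detection = detection,
                           sampleData = pheno)
  list(study = study, plantedGenes = planted, affectedGroup = "groupB",
       lowExpressed = lowExpressed)
}
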