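#' @import methods
#' @importFrom Matrix Matrix rowSums colSums Diagonal
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' TermDictionary: a curated context vocabulary
#'
#' A set of controlled-vocabulary terms (Gene Ontology and/or MeSH) that an
#' expert has judged relevant for one biological context, e.g. "immune" or
#' "neoplasm". The dictionary is the alphabet of symbols over which a gene's
#' contextual information content is measured; its size `N` is the number of
#' terms.
#'
#' @slot context single character label for the context.
#' @slot terms `data.frame` with columns `term_id`, `source` (one of
#'   `"GO"`, `"MeSH"`) and `term_text`.
#'
#' @seealso [TermDictionary()], [readTermDictionary()]
#' @export
setClass("TermDictionary",
  representation(context = "character", terms = "data.frame"))

setValidity("TermDictionary", function(object) {
  msg <- character()
  if (length(object@context) != 1L || is.na(object@context) ||
      !nzchar(object@context))
    msg <- c(msg, "'context' must be a single non-empty string")
  tm <- object@terms
  need <- c("term_id", "source", "term_text")
  if (!all(need %in% colnames(tm)))
    msg <- c(msg, sprintf("'terms' must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(tm) == 0L)
      msg <- c(msg, "a dictionary must contain at least one term")
    if (anyDuplicated(tm$term_id))
      msg <- c(msg, "term_ids must be unique within a dictionary")
    if (!all(tm$source %in% c("GO", "MeSH")))
      msg <- c(msg, "term sources must be 'GO' or 'MeSH'")
  }
  if (length(msg)) msg else TRUE
})

#' CoCitationTable: gene-by-term literature co-citation counts
#'
#' Sparse non-negative integer counts of joint mentions of a gene and a
#' vocabulary term in article titles/abstracts. The margins used by the
#' relevance score are cached at construction and always recomputed from the
#' counts, never trusted from a file: per-term totals over all genes
#' (`iT_g`), per-gene totals over all terms (`g_T`) and the grand total
#' (`GS_T`).
#'
#' @slot counts `dgCMatrix`, genes in rows, terms in columns.
#' @slot geneTotals numeric, per-gene totals `g_T` (named by gene).
#' @slot termTotals numeric, per-term totals `iT_g` (named by term).
#' @slot grandTotal numeric scalar `GS_T`.
#'
#' @seealso [CoCitationTable()], [scoreGenome()], [readCoCitationTable()]
#' @export
setClass("CoCitationTable",
  representation(counts = "Matrix", geneTotals = "numeric",
                 termTotals = "numeric", grandTotal = "numeric"))

setValidity("CoCitationTable", function(object) {
  msg <- character()
  cts <- object@counts
  if (is.null(rownames(cts)) || is.null(colnames(cts)))
    msg <- c(msg, "counts must have gene rownames and term colnames")
  else {
    if (anyDuplicated(rownames(cts)))
      msg <- c(msg, "duplicated gene symbols in counts")
    if (anyDuplicated(colnames(cts)))
      msg <- c(msg, "duplicated term ids in counts")
  }
  x <- cts@x
  if (length(x) && (any(x < 0) || any(x != round(x))))
    msg <- c(msg, "counts must be non-negative integers")
  if (!isTRUE(all.equal(unname(object@geneTotals),
                        unname(Matrix::rowSums(cts)))) ||
      !isTRUE(all.equal(unname(object@termTotals),
                        unname(Matrix::colSums(cts)))) ||
      !isTRUE(all.equal(object@grandTotal, sum(object@geneTotals))))
    msg <- c(msg, "cached margins do not match the counts")
  if (length(msg)) msg else TRUE
})

#' RelevanceTable: per-gene context relevance scores in bits
#'
#' One row per gene of the scored universe, holding the Shannon information
#' and the popularity-corrected Kullback-Leibler relevance over a context
#' dictionary, both in bits, with a deterministic rank (1 = most relevant;
#' ties broken by gene symbol). Genes never co-cited with any term are
#' flagged rather than dropped so whole-genome scoring always succeeds.
#'
#' @slot context context label the scores refer to.
#' @slot scores `data.frame` with columns `gene`, `shannon_bits`, `kl_bits`,
#'   `rank`, `never_cocited`, ordered by rank.
#'
#' @seealso [scoreGenome()], [klBits()], [writeRelevanceTable()]
#' @export
setClass("RelevanceTable",
  representation(context = "character", scores = "data.frame"))

setValidity("RelevanceTable", function(object) {
  msg <- character()
  sc <- object@scores
  need <- c("gene", "shannon_bits", "kl_bits", "rank", "never_cocited")
  if (!all(need %in% colnames(sc)))
    msg <- c(msg, sprintf("'scores' must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(sc$gene))
      msg <- c(msg, "one score entry per gene required")
    if (nrow(sc) && !identical(sort(sc$rank), seq_len(nrow(sc))))
      msg <- c(msg, "ranks must be a permutation of 1..n_genes")
    if (any(!is.finite(sc$kl_bits)))
      msg <- c(msg, "kl_bits must be finite")
    ord <- order(sc$rank)
    kl <- sc$kl_bits[ord]
    if (nrow(sc) > 1L && any(diff(kl) > 1e-12))
      msg <- c(msg, "ranks must be consistent with descending kl_bits")
  }
  if (length(msg)) msg else TRUE
})

#' GeneSetCollection: named curated gene sets over a shared universe
#'
#' @slot sets named list of character vectors of (normalized) gene symbols.
#' @slot universe character vector of valid symbols the members resolve
#'   against.
#' @slot unresolved character vector of input symbols that could not be
#'   resolved (retained for reporting, never silently dropped).
#'
#' @seealso [GeneSetCollection()], [overlapDistribution()], [readGmt()]
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", universe = "character",
                 unresolved = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)) ||
      any(!nzchar(names(object@sets))))
    msg <- c(msg, "sets must be uniquely named")
  if (!all(vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "each set must be a character vector of symbols")
  if (length(msg)) msg else TRUE
})

#' OverlapSummary: how genes distribute across curated resources
#'
#' Counts of genes belonging to exactly k of the resources in a collection,
#' the core set shared by all resources, and the size of the union.
#'
#' @slot sharedByK integer vector, element k = number of genes in exactly k
#'   sets.
#' @slot core character vector of genes common to every set.
#' @slot unionSize integer, distinct genes across all sets.
#' @export
setClass("OverlapSummary",
  representation(sharedByK = "integer", core = "character",
                 unionSize = "integer"))

setValidity("OverlapSummary", function(object) {
  msg <- character()
  if (sum(object@sharedByK) != object@unionSize)
    msg <- c(msg, "shared_by_k counts must sum to the union size")
  if (length(object@core) !=
      object@sharedByK[length(object@sharedByK)])
    msg <- c(msg, "core size must equal shared_by_|sets|")
  if (length(msg)) msg else TRUE
})

#' InteractomeGraph: an undirected simple protein-interaction network
#'
#' Nodes are gene symbols; an edge records an experimentally supported
#' binary interaction between the protein products of two genes, with
#' per-edge provenance listing every contributing source database.
#' Self-loops and duplicate pairs are removed at construction.
#'
#' @slot graph an `igraph` object (undirected, simple) with edge attribute
#'   `sources`.
#' @slot selfLoops integer count of self-pairs dropped during construction.
#'
#' @seealso [buildInteractome()], [centralityProfile()], [tissueSubnetwork()]
#' @export
setClass("InteractomeGraph",
  representation(graph = "ANY", selfLoops = "integer"))

setValidity("InteractomeGraph", function(object) {
  g <- object@graph
  msg <- character()
  if (!igraph::is_igraph(g))
    msg <- c(msg, "'graph' must be an igraph object")
  else {
    if (igraph::is_directed(g))
      msg <- c(msg, "interactome must be undirected")
    if (!igraph::is_simple(g))
      msg <- c(msg, "interactome must be simple (no loops/multi-edges)")
    if (is.null(igraph::V(g)$name))
      msg <- c(msg, "nodes must be named by gene symbol")
  }
  if (length(msg)) msg else TRUE
})

#' DEComparison: fold-change differential expression between two conditions
#'
#' Gene sets exceeding a linear fold-change threshold between the mean
#' profiles of two conditions, split by direction.
#'
#' @slot conditionA,conditionB condition labels compared.
#' @slot upInB genes whose mean in B exceeds `threshold` times the mean in A.
#' @slot downInB genes whose mean in A exceeds `threshold` times the mean in
#'   B.
#' @slot threshold linear fold-change cutoff (default pipeline value 2).
#' @seealso [foldChangeDE()]
#' @export
setClass("DEComparison",
  representation(conditionA = "character", conditionB = "character",
                 upInB = "character", downInB = "character",
                 threshold = "numeric"))

setValidity("DEComparison", function(object) {
  msg <- character()
  if (length(intersect(object@upInB, object@downInB)))
    msg <- c(msg, "up and down sets must be disjoint")
  if (object@threshold <= 0)
    msg <- c(msg, "threshold must be positive")
  if (length(msg)) msg else TRUE
})

#' ExpressionStudy: an expression cohort with detection calls and phenotypes
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' strictly positive genes-by-samples intensity matrix in assay `exprs`
#' (values are floored at a small positive intensity so ratios and logs are
#' always defined), an optional matching matrix of detection p-values in
#' assay `detection`, and sample annotations (condition labels, categorical
#' and numeric clinical phenotypes) in `colData`.
#'
#' @seealso [ExpressionStudy()], [quantileNormalize()], [detectionFilter()],
#'   [compositeGeneScore()]
#' @export
#' @import SummarizedExperiment
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "an 'exprs' assay is required")
  else if (any(SummarizedExperiment::assay(object, "exprs") <= 0))
    msg <- c(msg, "intensities must be strictly positive after flooring")
  if ("detection" %in% SummarizedExperiment::assayNames(object)) {
    dp <- SummarizedExperiment::assay(object, "detection")
    if (any(dp < 0 | dp > 1, na.rm = TRUE))
      msg <- c(msg, "detection p-values must lie in [0,1]")
  }
  if (length(msg)) msg else TRUE
})
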