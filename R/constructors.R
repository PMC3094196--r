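#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a TermDictionary
#'
#' @param context single context label, e.g. `"immune"`.
#' @param terms `data.frame` with columns `term_id`, `source`
#'   (`"GO"`/`"MeSH"`) and `term_text`, one row per term.
#' @return A [TermDictionary-class] object.
#' @examples
#' td <- TermDictionary("immune", data.frame(
#'   term_id = c("GO:0006955", "D007109"),
#'   source = c("GO", "MeSH"),
#'   term_text = c("immune response", "Immunity")))
#' nTerms(td)
#' @export
TermDictionary <- function(context, terms) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  terms$term_id <- as.character(terms$term_id)
  new("TermDictionary", context = as.character(context), terms = terms)
}

#' Number of terms (alphabet size N) of a dictionary
#' @param x a [TermDictionary-class].
#' @return integer alphabet size.
#' @export
nTerms <- function(x) nrow(x@terms)

#' @describeIn TermDictionary context label accessor
#' @export
setMethod("contextName", "TermDictionary", function(x) x@context)

#' @describeIn TermDictionary term identifier accessor
#' @export
setMethod("termIds", "TermDictionary", function(x) x@terms$term_id)

setMethod("show", "TermDictionary", function(object) {
  cat("TermDictionary '", object@context, "' with ", nrow(object@terms),
      " terms (", sum(object@terms$source == "GO"), " GO, ",
      sum(object@terms$source == "MeSH"), " MeSH)\n", sep = "")
})

#' Construct a CoCitationTable from a counts matrix
#'
#' Margins (`g_T`, `iT_g`, `GS_T`) are recomputed from the counts.
#'
#' @param counts genes-by-terms matrix of non-negative integer co-citation
#'   counts, with gene rownames and term colnames. Dense or sparse input is
#'   accepted; the table stores a sparse matrix.
#' @return A [CoCitationTable-class] object.
#' @examples
#' m <- matrix(c(3, 0, 1, 2), 2, 2,
#'             dimnames = list(c("CD8A", "GAPDH"), c("GO:1", "D1")))
#' tab <- CoCitationTable(m)
#' grandTotal(tab)
#' @export
CoCitationTable <- function(counts) {
  cts <- if (is.matrix(counts)) {
    as(Matrix::Matrix(counts * 1.0, sparse = TRUE), "CsparseMatrix")
  } else {
    as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  }
  new("CoCitationTable", counts = cts,
      geneTotals = structure(Matrix::rowSums(cts), names = rownames(cts)),
      termTotals = structure(Matrix::colSums(cts), names = colnames(cts)),
      grandTotal = sum(cts))
}

#' @describeIn CoCitationTable gene symbols (row universe)
#' @param x,object a `CoCitationTable`.
#' @export
setMethod("geneSymbols", "CoCitationTable", function(x) rownames(x@counts))

#' @describeIn CoCitationTable term identifiers (column universe)
#' @export
setMethod("termIds", "CoCitationTable", function(x) colnames(x@counts))

#' Margin accessors for a CoCitationTable
#'
#' `geneTotals` returns the per-gene totals `g_T`, `termTotals` the
#' per-term totals `iT_g`, and `grandTotal` the corpus total `GS_T`.
#'
#' @param x a [CoCitationTable-class].
#' @return named numeric vector (or scalar for `grandTotal`).
#' @export
geneTotals <- function(x) x@geneTotals

#' @rdname geneTotals
#' @export
termTotals <- function(x) x@termTotals

#' @rdname geneTotals
#' @export
grandTotal <- function(x) x@grandTotal

#' @rdname geneTotals
#' @export
cocitationCounts <- function(x) x@counts

setMethod("show", "CoCitationTable", function(object) {
  cat("CoCitationTable:", nrow(object@counts), "genes x",
      ncol(object@counts), "terms,", object@grandTotal,
      "co-citation events\n")
})

#' @describeIn RelevanceTable ranked score table accessor
#' @param x,object a `RelevanceTable`.
#' @export
setMethod("relevanceScores", "RelevanceTable", function(x) x@scores)

#' @describeIn RelevanceTable context label accessor
#' @export
setMethod("contextName", "RelevanceTable", function(x) x@context)

#' @describeIn RelevanceTable gene symbols in rank order
#' @export
setMethod("geneSymbols", "RelevanceTable", function(x) x@scores$gene)

#' @describeIn RelevanceTable named vector of KL relevance in bits
#' @export
setMethod("klBits", "RelevanceTable", function(x)
  structure(x@scores$kl_bits, names = x@scores$gene))

#' @describeIn RelevanceTable named vector of Shannon information in bits
#' @export
setMethod("shannonBits", "RelevanceTable", function(x)
  structure(x@scores$shannon_bits, names = x@scores$gene))

setMethod("show", "RelevanceTable", function(object) {
  sc <- object@scores
  cat("RelevanceTable '", object@context, "': ", nrow(sc), " genes, ",
      "kl_bits in [", round(min(sc$kl_bits), 3), ", ",
      round(max(sc$kl_bits), 3), "]\n", sep = "")
  print(utils::head(sc, 5))
  if (nrow(sc) > 5) cat("...\n")
})

#' Construct a GeneSetCollection
#'
#' Member symbols are normalized (uppercase plus optional alias mapping)
#' with [resolveSymbols()]; unresolved symbols are retained in the sets and
#' reported in the `unresolved` slot, never silently dropped.
#'
#' @param sets named list of character vectors of gene symbols.
#' @param universe optional character vector of valid canonical symbols;
#'   defaults to the union of the normalized sets.
#' @param aliasMap optional named character vector mapping alias symbols to
#'   canonical ones.
#' @return A [GeneSetCollection-class].
#' @examples
#' gc <- GeneSetCollection(list(iris = c("CD8A", "cd4"),
#'                              immunome = c("CD4", "IL2")))
#' setUniverse(gc)
#' @export
GeneSetCollection <- function(sets, universe = NULL, aliasMap = NULL) {
  stopifnot(is.list(sets))
  if (is.null(universe)) {
    norm <- lapply(sets, function(s)
      resolveSymbols(s, aliasMap = aliasMap)$symbols)
    universe <- sort(unique(unlist(norm, use.names = FALSE)))
  }
  unresolved <- character()
  norm <- lapply(sets, function(s) {
    r <- resolveSymbols(s, aliasMap = aliasMap, universe = universe)
    unresolved <<- union(unresolved, r$unresolved)
    r$symbols
  })
  new("GeneSetCollection", sets = norm,
      universe = sort(unique(toupper(universe))),
      unresolved = unresolved)
}

#' @describeIn GeneSetCollection named list of member sets
#' @param x,object a `GeneSetCollection`.
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn GeneSetCollection symbol universe accessor
#' @export
setMethod("setUniverse", "GeneSetCollection", function(x) x@universe)

#' Union of all member sets in a collection
#' @param x a [GeneSetCollection-class].
#' @return character vector of curated symbols.
#' @export
setUnion <- function(x) sort(unique(unlist(x@sets, use.names = FALSE)))

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets,",
      length(setUnion(object)), "distinct genes,",
      length(object@universe), "universe symbols\n")
  for (nm in names(object@sets))
    cat("  ", nm, ": ", length(object@sets[[nm]]), " genes\n", sep = "")
  if (length(object@unresolved))
    cat("  (", length(object@unresolved), " unresolved symbols)\n",
        sep = "")
})

setMethod("show", "OverlapSummary", function(object) {
  cat("OverlapSummary:", object@unionSize, "distinct genes;",
      length(object@core), "core genes shared by all sets\n")
  k <- seq_along(object@sharedByK)
  cat(paste0("  in exactly ", k, " set(s): ", object@sharedByK, "\n"),
      sep = "")
})

#' Counts of genes by number of sets they belong to
#' @param x an [OverlapSummary-class].
#' @return integer vector indexed by k.
#' @export
sharedByK <- function(x) x@sharedByK

#' @rdname sharedByK
#' @export
coreGenes <- function(x) x@core

#' @rdname sharedByK
#' @export
unionSize <- function(x) x@unionSize

#' @describeIn InteractomeGraph node symbols
#' @param x,object an `InteractomeGraph`.
#' @export
setMethod("geneSymbols", "InteractomeGraph", function(x)
  igraph::V(x@graph)$name)

#' Underlying igraph object of an InteractomeGraph
#' @param x an [InteractomeGraph-class].
#' @return the wrapped `igraph` object.
#' @export
asIgraph <- function(x) x@graph

#' @rdname asIgraph
#' @export
selfLoopsDropped <- function(x) x@selfLoops

setMethod("show", "InteractomeGraph", function(object) {
  g <- object@graph
  cat("InteractomeGraph:", igraph::vcount(g), "genes,",
      igraph::ecount(g), "interactions")
  if (object@selfLoops > 0)
    cat(" (", object@selfLoops, " self-pairs dropped)", sep = "")
  cat("\n")
})

setMethod("show", "DEComparison", function(object) {
  cat("DEComparison ", object@conditionA, " -> ", object@conditionB,
      " (fold-change > ", object@threshold, "): ",
      length(object@upInB), " up, ", length(object@downInB),
      " down\n", sep = "")
})

#' Accessors for a DEComparison
#' @param x a [DEComparison-class].
#' @return character vector of gene symbols (or the union for `deGenes`).
#' @export
upInB <- function(x) x@upInB

#' @rdname upInB
#' @export
downInB <- function(x) x@downInB

#' @rdname upInB
#' @export
deGenes <- function(x) union(x@upInB, x@downInB)

#' Construct an ExpressionStudy
#'
#' Intensities are floored at `floor` (default 1 on a raw Illumina-like
#' scale) so that fold-change ratios and log transforms are always defined;
#' the floor used is recorded in `metadata()`.
#'
#' @param exprs genes-by-samples numeric matrix of signal intensities.
#' @param detection optional matrix of detection p-values, same shape.
#' @param sampleData optional `data.frame` of per-sample annotations; must
#'   contain a `condition` column for differential expression work. Row
#'   order must match the columns of `exprs`.
#' @param floor positive intensity floor.
#' @return An [ExpressionStudy-class].
#' @examples
#' m <- matrix(rlnorm(20, 5), 5, 4,
#'             dimnames = list(paste0("G", 1:5), paste0("S", 1:4)))
#' es <- ExpressionStudy(m, sampleData = data.frame(
#'   condition = rep(c("a", "b"), 2), row.names = colnames(m)))
#' conditionLabels(es)
#' @export
ExpressionStudy <- function(exprs, detection = NULL, sampleData = NULL,
                            floor = 1) {
  stopifnot(is.matrix(exprs), floor > 0)
  assays <- list(exprs = pmax(exprs, floor))
  if (!is.null(detection)) {
    stopifnot(identical(dim(detection), dim(exprs)))
    dimnames(detection) <- dimnames(exprs)
    assays$detection <- detection
  }
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(exprs))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = S4Vectors::DataFrame(sampleData))
  out <- new("ExpressionStudy", se)
  S4Vectors::metadata(out)$intensity_floor <- floor
  out
}

#' Condition labels of an ExpressionStudy
#' @param x an [ExpressionStudy-class].
#' @return character vector of per-sample condition labels.
#' @export
conditionLabels <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"condition" %in% colnames(cd))
    stop("the study has no 'condition' column in its sample annotations")
  as.character(cd$condition)
}

#' Intensity and detection matrices of an ExpressionStudy
#' @param x an [ExpressionStudy-class].
#' @return numeric matrix (or NULL when no detection assay is present).
#' @export
intensityMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @rdname intensityMatrix
#' @export
detectionPvalues <- function(x) {
  if (!"detection" %in% SummarizedExperiment::assayNames(x)) return(NULL)
  SummarizedExperiment::assay(x, "detection")
}
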