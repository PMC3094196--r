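#' @include AllClasses.R AllGenerics.R constructors.R
NULL

#' Normalize gene symbols against an alias table and universe
#'
#' Canonicalization is case-insensitive (symbols are uppercased), then an
#' optional alias map is applied (e.g. `CD45 -> PTPRC`). A symbol counts as
#' resolved when its canonical form is found in the known vocabulary: the
#' supplied `universe` plus the targets of the alias map. Unresolved
#' symbols are kept verbatim (uppercased) and reported, never silently
#' dropped -- real curation data is lossy and the loss must stay visible.
#'
#' @param raw character vector of input symbols.
#' @param aliasMap optional named character vector, `names = alias`,
#'   `values = canonical symbol` (matched case-insensitively).
#' @param universe optional character vector of valid canonical symbols.
#' @return list with `symbols` (unique canonical symbols, input order),
#'   `unresolved` (flagged symbols) and `report` (per-input data.frame).
#' @examples
#' resolveSymbols(c("cd45", "PTPRC"),
#'                aliasMap = c(CD45 = "PTPRC"),
#'                universe = "PTPRC")
#' @export
resolveSymbols <- function(raw, aliasMap = NULL, universe = NULL) {
  raw <- as.character(raw)
  up <- toupper(raw)
  canonical <- up
  if (!is.null(aliasMap)) {
    stopifnot(!is.null(names(aliasMap)))
    map <- structure(toupper(as.character(aliasMap)),
                     names = toupper(names(aliasMap)))
    hit <- match(up, names(map))
    canonical[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  }
  known <- toupper(c(universe, if (!is.null(aliasMap)) aliasMap))
  resolved <- canonical %in% known
  list(symbols = unique(canonical),
       unresolved = unique(canonical[!resolved]),
       report = data.frame(input = raw, canonical = canonical,
                           resolved = resolved,
                           stringsAsFactors = FALSE))
}

#' Distribution of genes across the sets of a collection
#'
#' Tallies, for every gene in the union, how many member sets contain it,
#' reporting the count of genes in exactly k sets and the core set common
#' to all resources. This is the resource-overlap bookkeeping behind
#' statements like "82 core genes common to all 6 resources".
#'
#' @param collection a [GeneSetCollection-class] with at least 2 sets.
#' @return An [OverlapSummary-class].
#' @examples
#' gc <- GeneSetCollection(list(a = c("A", "B", "C"),
#'                              b = c("B", "C", "D"),
#'                              c = c("C", "E")))
#' overlapDistribution(gc)
#' @export
setMethod("overlapDistribution", "GeneSetCollection", function(collection) {
  sets <- lapply(collection@sets, unique)
  if (length(sets) < 2L)
    stop("overlap distribution needs at least 2 sets", call. = FALSE)
  members <- unlist(sets, use.names = FALSE)
  tab <- table(members)
  k <- as.integer(tab)
  counts <- tabulate(k, nbins = length(sets))
  new("OverlapSummary",
      sharedByK = counts,
      core = sort(names(tab)[k == length(sets)]),
      unionSize = length(tab))
})

#' Mean KL relevance of each curated set, the core set and the non-curated
#' remainder
#'
#' Benchmarks a relevance table against a collection of curated resources:
#' for every set, the arithmetic mean of `kl_bits` over its members; plus
#' the mean over the core genes common to all sets and over the
#' "non-curated" genes (the relevance universe minus the union of all
#' sets). Members missing from the relevance table are ignored for that
#' set's mean (with a message); empty sets give `NA` with a warning.
#'
#' @param collection a [GeneSetCollection-class].
#' @param relevance a [RelevanceTable-class] covering the universe.
#' @return `data.frame` with columns `set`, `n_genes`, `mean_kl_bits`; rows
#'   for each set, `"core"` and `"non_curated"`.
#' @export
meanRelevanceBySet <- function(collection, relevance) {
  stopifnot(is(collection, "GeneSetCollection"),
            is(relevance, "RelevanceTable"))
  kl <- klBits(relevance)
  core <- if (length(collection@sets) >= 2L)
    coreGenes(overlapDistribution(collection)) else character()
  groups <- c(collection@sets,
              list(core = core,
                   non_curated = setdiff(names(kl), setUnion(collection))))
  res <- lapply(names(groups), function(nm) {
    g <- unique(groups[[nm]])
    scored <- g[g %in% names(kl)]
    if (length(scored) < length(g))
      message(length(g) - length(scored), " gene(s) of set '", nm,
              "' missing from the relevance table; ignored")
    if (!length(g)) {
      warning("set '", nm, "' is empty; mean undefined", call. = FALSE)
      m <- NA_real_
    } else if (!length(scored)) {
      m <- NA_real_
    } else m <- mean(kl[scored])
    data.frame(set = nm, n_genes = length(scored), mean_kl_bits = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Fraction of an external gene set absent from a collection's union
#'
#' Quantifies how much of an external (e.g. high-throughput) gene list is
#' not covered by the curated resources: `|external \ union| / |external|`.
#'
#' @param collection a [GeneSetCollection-class].
#' @param external non-empty character vector of gene symbols (normalized
#'   case-insensitively against the collection).
#' @return non-overlap fraction in \[0, 1\].
#' @export
externalOverlap <- function(collection, external) {
  stopifnot(is(collection, "GeneSetCollection"))
  external <- unique(toupper(as.character(external)))
  if (!length(external)) stop("empty external gene set", call. = FALSE)
  length(setdiff(external, setUnion(collection))) / length(external)
}

#' Top-ranked relevance genes outside the curated resources
#'
#' Nominates candidates for entry into curated immune resources: the
#' `topN` highest-KL genes of the relevance universe that belong to none of
#' the collection's sets, in rank order.
#'
#' @param relevance a [RelevanceTable-class].
#' @param collection a [GeneSetCollection-class].
#' @param topN number of candidates requested (>= 1). When fewer
#'   non-curated genes exist, all are returned with a message.
#' @return `data.frame` with columns `gene`, `kl_bits`, `rank`.
#' @export
noncuratedCandidates <- function(relevance, collection, topN) {
  stopifnot(is(relevance, "RelevanceTable"),
            is(collection, "GeneSetCollection"), topN >= 1)
  sc <- relevance@scores
  out <- sc[!(sc$gene %in% setUnion(collection)),
            c("gene", "kl_bits", "rank")]
  if (nrow(out) < topN)
    message("only ", nrow(out), " non-curated gene(s) available ",
            "(requested ", topN, ")")
  out <- utils::head(out[order(out$rank), , drop = FALSE], topN)
  rownames(out) <- NULL
  out
}

#' Histogram of KL relevance across the genome
#'
#' The genome-wide frequency distribution of `kl_bits` (the "sharp decline
#' from high to low relevance" view). Bins are left-closed right-open, the
#' last bin closed. Scores outside the bin range are an error unless an
#' overflow bin is requested.
#'
#' @param relevance a [RelevanceTable-class].
#' @param binEdges strictly increasing numeric vector of bin edges.
#' @param overflow if `TRUE`, add underflow/overflow bins capturing scores
#'   outside the edges.
#' @return named integer vector of counts, summing to the number of genes.
#' @export
scoreFrequencyDistribution <- function(relevance, binEdges,
                                       overflow = FALSE) {
  stopifnot(is(relevance, "RelevanceTable"))
  binEdges <- as.numeric(binEdges)
  if (length(binEdges) < 2L || any(diff(binEdges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  x <- relevance@scores$kl_bits
  lo <- x < binEdges[1L]
  hi <- x > binEdges[length(binEdges)]
  if (!overflow && any(lo | hi))
    stop(sum(lo | hi), " score(s) outside the bin range; pass ",
         "overflow = TRUE to capture them", call. = FALSE)
  inner <- x[!(lo | hi)]
  ## left-closed right-open, last bin closed
  idx <- findInterval(inner, binEdges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  counts <- tabulate(idx, nbins = length(binEdges) - 1L)
  names(counts) <- paste0("[", binEdges[-length(binEdges)], ",",
                          binEdges[-1L],
                          c(rep(")", length(binEdges) - 2L), "]"))
  if (overflow)
    counts <- c(underflow = sum(lo), counts, overflow = sum(hi))
  counts
}
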