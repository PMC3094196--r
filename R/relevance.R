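#' @include AllClasses.R AllGenerics.R constructors.R
NULL

## Internal: locate a gene/term or fail naming the missing key.
.geneRow <- function(table, gene) {
  i <- match(gene, rownames(table@counts))
  if (is.na(i)) stop("unknown gene: '", gene, "'", call. = FALSE)
  i
}

.termCol <- function(table, term) {
  j <- match(term, colnames(table@counts))
  if (is.na(j)) stop("unknown term: '", term, "'", call. = FALSE)
  j
}

#' Per-term co-citation probability p_i of a gene
#'
#' The probability that a co-citation event of context term `term` involves
#' `gene`: `p_i = g_i / iT_g`, where `g_i` is the gene-term co-citation
#' count and `iT_g` the term's co-citation total over all genes. A term
#' never co-cited with any gene has `iT_g = 0` and yields probability 0.
#'
#' @param gene gene symbol present in the table.
#' @param term term identifier present in the table.
#' @param table a [CoCitationTable-class].
#' @return probability in \[0, 1\].
#' @seealso [backgroundProbability()], [klRelevance()]
#' @export
termProbability <- function(gene, term, table) {
  stopifnot(is(table, "CoCitationTable"))
  i <- .geneRow(table, gene)
  j <- .termCol(table, term)
  tot <- table@termTotals[[j]]
  if (tot == 0) return(0)
  table@counts[i, j] / tot
}

#' Background (popularity) probability q of a gene
#'
#' The gene's probability of co-citation among all GO and MeSH terms in the
#' corpus: `q = g_T / GS_T`. This is the literature-popularity bias the KL
#' relevance corrects for.
#'
#' @inheritParams termProbability
#' @return probability in \[0, 1\]; 0 for a gene never co-cited with any
#'   term.
#' @export
backgroundProbability <- function(gene, table) {
  stopifnot(is(table, "CoCitationTable"))
  i <- .geneRow(table, gene)
  if (table@grandTotal == 0)
    stop("empty corpus: the co-citation table has no events", call. = FALSE)
  table@geneTotals[[i]] / table@grandTotal
}

## Internal: per-gene (p_i, q) pairs over dictionary terms present in the
## table. Dictionary terms absent from the table behave as all-zero columns.
.contextProbs <- function(gene, dictionary, table) {
  i <- .geneRow(table, gene)
  ids <- termIds(dictionary)
  j <- match(ids, colnames(table@counts))
  j <- j[!is.na(j)]
  if (!length(j)) return(list(p = numeric(), q = 0))
  tot <- table@termTotals[j]
  cnt <- as.numeric(table@counts[i, j])
  p <- ifelse(tot > 0, cnt / pmax(tot, 1), 0)
  q <- if (table@grandTotal > 0) table@geneTotals[[i]] / table@grandTotal
       else 0
  list(p = p, q = q)
}

#' Shannon information of a gene over a context dictionary
#'
#' `H = -sum_i p_i log2(p_i)` over the dictionary terms, with the usual
#' convention `0 log2 0 = 0`. Reported in bits.
#'
#' @param gene gene symbol.
#' @param dictionary a [TermDictionary-class]; terms absent from the table
#'   are treated as never co-cited.
#' @param table a [CoCitationTable-class].
#' @return non-negative information in bits.
#' @export
shannonInformation <- function(gene, dictionary, table) {
  pr <- .contextProbs(gene, dictionary, table)
  p <- pr$p[pr$p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

#' Popularity-corrected KL relevance of a gene, in bits
#'
#' The context relevance score: `KL = sum_i p_i log2(p_i / q)` over the
#' dictionary terms, where `p_i` is the per-term co-citation probability and
#' `q` the gene's overall popularity among all GO and MeSH terms. The
#' per-gene `p_i` are used exactly as defined -- they are not renormalized
#' to a distribution over the dictionary -- so individual terms with
#' `p_i < q` contribute negatively. Zero-count terms contribute 0; a gene
#' with no context co-citations scores exactly 0.
#'
#' @inheritParams shannonInformation
#' @return relevance in bits.
#' @export
klRelevance <- function(gene, dictionary, table) {
  pr <- .contextProbs(gene, dictionary, table)
  keep <- pr$p > 0
  if (!any(keep)) return(0)
  if (pr$q == 0)
    stop("corrupt margins: positive context probability with zero ",
         "background popularity", call. = FALSE)
  p <- pr$p[keep]
  sum(p * log2(p / pr$q))
}

#' Score every gene of a co-citation corpus against a context dictionary
#'
#' Computes the Shannon information and the popularity-corrected KL
#' relevance (both in bits) for each gene in the table and ranks the genome
#' by descending KL, ties broken by gene symbol so the ranking is
#' deterministic and invariant to input order. Genes never co-cited with
#' any term are scored 0 and flagged `never_cocited` rather than dropped.
#'
#' @param table a [CoCitationTable-class].
#' @param dictionary a [TermDictionary-class]. Terms absent from the
#'   table's co-citation space are treated as all-zero columns and reported
#'   via a message.
#' @return A [RelevanceTable-class] ordered by rank.
#' @examples
#' sim <- simulateCocitationCorpus(nGenes = 50, nTermsTotal = 40,
#'                                 nContextTerms = 8, nPlanted = 5,
#'                                 seed = 1)
#' rt <- scoreGenome(sim$table, sim$dictionary)
#' head(relevanceScores(rt))
#' @export
setMethod("scoreGenome", c("CoCitationTable", "TermDictionary"),
function(table, dictionary, ...) {
  genes <- rownames(table@counts)
  if (!length(genes)) stop("empty co-citation table", call. = FALSE)
  ids <- termIds(dictionary)
  j <- match(ids, colnames(table@counts))
  nMissing <- sum(is.na(j))
  if (nMissing > 0)
    message(nMissing, " dictionary term(s) absent from the co-citation ",
            "space; treated as never co-cited")
  j <- j[!is.na(j)]

  n <- length(genes)
  H <- numeric(n)
  KL <- numeric(n)
  if (length(j)) {
    sub <- table@counts[, j, drop = FALSE]
    tot <- table@termTotals[j]
    tr <- Matrix::mat2triplet(sub)
    keep <- tr$x > 0
    gi <- tr$i[keep]
    p <- tr$x[keep] / tot[tr$j[keep]]
    q <- if (table@grandTotal > 0) table@geneTotals / table@grandTotal
         else rep(0, n)
    if (any(q[gi] == 0))
      stop("corrupt margins: positive context probability with zero ",
           "background popularity", call. = FALSE)
    if (length(gi)) {
      contrib <- cbind(h = -p * log2(p), kl = p * log2(p / q[gi]))
      agg <- rowsum(contrib, group = gi)
      idx <- as.integer(rownames(agg))
      H[idx] <- agg[, "h"]
      KL[idx] <- agg[, "kl"]
    }
  }
  ord <- order(-KL, genes)
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  sc <- data.frame(gene = genes, shannon_bits = H, kl_bits = KL,
                   rank = rk,
                   never_cocited = unname(table@geneTotals == 0),
                   stringsAsFactors = FALSE)
  sc <- sc[ord, , drop = FALSE]
  rownames(sc) <- NULL
  new("RelevanceTable", context = contextName(dictionary), scores = sc)
})
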