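#' @include AllClasses.R AllGenerics.R constructors.R
#' @importFrom utils read.delim write.table head
NULL

#' Read / write a term dictionary
#'
#' Tab-delimited UTF-8 with columns `term_id`, `source`, `term_text`,
#' `context`; one context per file.
#'
#' @param path file path.
#' @return [TermDictionary-class] for the reader; invisible path for the
#'   writer.
#' @export
readTermDictionary <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  ctx <- unique(df$context)
  if (length(ctx) != 1L)
    stop("dictionary file must hold exactly one context", call. = FALSE)
  TermDictionary(ctx, df[, c("term_id", "source", "term_text")])
}

#' @rdname readTermDictionary
#' @param dictionary a [TermDictionary-class].
#' @export
writeTermDictionary <- function(dictionary, path) {
  df <- dictionary@terms
  df$context <- dictionary@context
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a co-citation table in long format
#'
#' Tab-delimited columns `gene_symbol`, `term_id`, `count`. Margins are
#' always recomputed on load, never trusted from the file.
#'
#' @param path file path.
#' @return [CoCitationTable-class] for the reader.
#' @export
readCoCitationTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_symbol", "term_id", "count") %in% colnames(df)))
  genes <- sort(unique(df$gene_symbol))
  terms <- sort(unique(df$term_id))
  m <- Matrix::sparseMatrix(i = match(df$gene_symbol, genes),
                            j = match(df$term_id, terms),
                            x = as.numeric(df$count),
                            dims = c(length(genes), length(terms)),
                            dimnames = list(genes, terms))
  CoCitationTable(m)
}

#' @rdname readCoCitationTable
#' @param table a [CoCitationTable-class]; zero counts are omitted.
#' @export
writeCoCitationTable <- function(table, path) {
  tr <- Matrix::mat2triplet(table@counts)
  keep <- tr$x != 0
  df <- data.frame(gene_symbol = rownames(table@counts)[tr$i[keep]],
                   term_id = colnames(table@counts)[tr$j[keep]],
                   count = tr$x[keep], stringsAsFactors = FALSE)
  df <- df[order(df$gene_symbol, df$term_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a ranked relevance table
#'
#' Tab-delimited columns `gene_symbol`, `context`, `shannon_bits`,
#' `kl_bits`, `rank`, sorted by rank.
#'
#' @param path file path.
#' @return [RelevanceTable-class] for the reader.
#' @export
readRelevanceTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ctx <- unique(df$context)
  stopifnot(length(ctx) == 1L)
  sc <- data.frame(gene = df$gene_symbol, shannon_bits = df$shannon_bits,
                   kl_bits = df$kl_bits, rank = as.integer(df$rank),
                   never_cocited = if ("never_cocited" %in% colnames(df))
                     as.logical(df$never_cocited) else FALSE,
                   stringsAsFactors = FALSE)
  sc <- sc[order(sc$rank), ]
  rownames(sc) <- NULL
  new("RelevanceTable", context = ctx, scores = sc)
}

#' @rdname readRelevanceTable
#' @param relevance a [RelevanceTable-class].
#' @export
writeRelevanceTable <- function(relevance, path) {
  sc <- relevance@scores[order(relevance@scores$rank), ]
  df <- data.frame(gene_symbol = sc$gene, context = relevance@context,
                   shannon_bits = sc$shannon_bits, kl_bits = sc$kl_bits,
                   rank = sc$rank, never_cocited = sc$never_cocited,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from GMT or one-symbol-per-line files
#'
#' `readGmt` parses the standard GMT layout (set name, description, then
#' members, tab-delimited); `readGeneList` reads a plain list of symbols.
#'
#' @param path file path.
#' @return named list of character vectors (`readGmt`) or a character
#'   vector (`readGeneList`).
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L)
      stop("malformed GMT line: need name, description, members",
           call. = FALSE)
    f[-(1:2)]
  })
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  out
}

#' @rdname readGmt
#' @export
readGeneList <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' @rdname readGmt
#' @param sets named list of character vectors or a
#'   [GeneSetCollection-class].
#' @export
writeGmt <- function(sets, path) {
  if (is(sets, "GeneSetCollection")) sets <- geneSets(sets)
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction edge list
#'
#' Tab-delimited columns `symbol_a`, `symbol_b` and optional `source`.
#'
#' @param path file path.
#' @return `data.frame` suitable for [buildInteractome()].
#' @export
readEdgeList <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(ncol(df) >= 2L)
  df
}

#' Export a network as GraphML, optionally annotated with relevance scores
#'
#' Writes the graph with whatever node attributes it carries; when
#' relevance tables are given, `immune_bits` / `cancer_bits` and the node
#' degree are attached first, matching what external viewers expect for
#' landscape-style figures.
#'
#' @param graph an [InteractomeGraph-class].
#' @param path output file.
#' @param immune,cancer optional [RelevanceTable-class] objects.
#' @export
writeGraphML <- function(graph, path, immune = NULL, cancer = NULL) {
  g <- graph@graph
  g <- igraph::set_vertex_attr(g, "degree",
                               value = igraph::degree(g))
  ann <- function(g, rt, attr) {
    kl <- klBits(rt)
    v <- ifelse(igraph::V(g)$name %in% names(kl),
                kl[igraph::V(g)$name], NA_real_)
    igraph::set_vertex_attr(g, attr, value = v)
  }
  if (!is.null(immune)) g <- ann(g, immune, "immune_bits")
  if (!is.null(cancer)) g <- ann(g, cancer, "cancer_bits")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an expression study from tab-delimited matrices
#'
#' @param exprsPath genes x samples intensity matrix, header row of sample
#'   ids, first column gene symbols.
#' @param detectionPath optional detection p-value matrix, same layout.
#' @param samplesPath optional sample annotation table with a `sample_id`
#'   column matching the matrix columns.
#' @param floor intensity floor passed to [ExpressionStudy()].
#' @return An [ExpressionStudy-class].
#' @export
readExpressionStudy <- function(exprsPath, detectionPath = NULL,
                                samplesPath = NULL, floor = 1) {
  readMat <- function(p) {
    df <- read.delim(p, row.names = 1L, check.names = FALSE)
    as.matrix(df)
  }
  exprs <- readMat(exprsPath)
  detection <- if (!is.null(detectionPath)) readMat(detectionPath)
  sampleData <- NULL
  if (!is.null(samplesPath)) {
    ann <- read.delim(samplesPath, stringsAsFactors = FALSE)
    stopifnot("sample_id" %in% colnames(ann))
    if (!setequal(ann$sample_id, colnames(exprs)))
      stop("sample annotations do not match the matrix columns",
           call. = FALSE)
    rownames(ann) <- ann$sample_id
    sampleData <- ann[colnames(exprs), setdiff(colnames(ann), "sample_id"),
                      drop = FALSE]
  }
  ExpressionStudy(exprs, detection = detection, sampleData = sampleData,
                  floor = floor)
}

#' Write a genes x samples matrix as tab-delimited text
#' @param m numeric matrix with dimnames.
#' @param path output file.
#' @export
writeMatrixTsv <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the per-gene landscape table
#'
#' Tab-delimited `gene`, `immune_bits`, `cancer_bits`, `connectivity`,
#' `high_high` -- the underlying data of the landscape surface.
#'
#' @param landscape result of [landscapeSurface()].
#' @param path output file.
#' @export
writeLandscapeTable <- function(landscape, path) {
  write.table(landscape$table, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
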