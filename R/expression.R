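#' @include AllClasses.R AllGenerics.R constructors.R
NULL

#' Quantile normalization of an intensity matrix
#'
#' Forces every sample (column) onto the identical distribution of values:
#' the cross-column mean of order statistics, with ties receiving the mean
#' of their quantile values. Idempotent. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x numeric matrix (genes x samples) or an
#'   [ExpressionStudy-class], whose `exprs` assay is normalized in place.
#' @return object of the same class as `x`.
#' @examples
#' quantileNormalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
setMethod("quantileNormalize", "matrix", function(x, ...) {
  if (ncol(x) < 2L) {
    warning("single-sample matrix: quantile normalization is the identity",
            call. = FALSE)
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
})

#' @rdname quantileNormalize
#' @export
setMethod("quantileNormalize", "ExpressionStudy", function(x, ...) {
  SummarizedExperiment::assay(x, "exprs") <-
    quantileNormalize(intensityMatrix(x))
  x
})

#' Filter probes on detection p-values
#'
#' Keeps a gene only if its signal is reliably detected above the negative
#' control background: `count(detection_p < alpha) > minSamples`, both
#' comparisons strict. The default `minSamples` scales the original
#' "more than 50 of 57 patients" criterion to the cohort at hand,
#' `ceiling(50/57 * n_samples)`.
#'
#' @param study an [ExpressionStudy-class] carrying a `detection` assay.
#' @param alpha detection p-value cutoff (default 0.01).
#' @param minSamples strict lower bound on the number of detected samples;
#'   default `ceiling(50/57 * ncol(study))`.
#' @return the filtered [ExpressionStudy-class].
#' @export
setMethod("detectionFilter", "ExpressionStudy",
function(study, alpha = 0.01, minSamples = NULL, ...) {
  dp <- detectionPvalues(study)
  if (is.null(dp))
    stop("no detection p-value matrix in this study; subset the study ",
         "yourself if you intend to skip the detection filter",
         call. = FALSE)
  if (is.null(minSamples))
    minSamples <- ceiling(50 / 57 * ncol(study))
  keep <- rowSums(dp < alpha) > minSamples
  message("detection filter: keeping ", sum(keep), " of ", length(keep),
          " genes (detected at p < ", alpha, " in more than ", minSamples,
          " samples)")
  study[keep, ]
})

## Internal: per-condition mean profiles on the linear scale.
.conditionMeans <- function(study, cond) {
  lab <- conditionLabels(study)
  idx <- which(lab == cond)
  if (!length(idx))
    stop("condition '", cond, "' has no samples", call. = FALSE)
  rowMeans(intensityMatrix(study)[, idx, drop = FALSE])
}

#' Fold-change differential expression between two conditions
#'
#' A gene is called differentially expressed when the ratio of its
#' per-condition mean intensities (linear scale, floored values) exceeds
#' `threshold` in either direction. Swapping the conditions exactly swaps
#' the up and down sets.
#'
#' @param study an [ExpressionStudy-class] with a `condition` annotation.
#' @param conditionA,conditionB condition labels to compare.
#' @param threshold linear fold-change cutoff (default 2, the pipeline's
#'   "greater than two-fold" rule; strict inequality).
#' @return A [DEComparison-class].
#' @export
foldChangeDE <- function(study, conditionA, conditionB, threshold = 2) {
  stopifnot(is(study, "ExpressionStudy"), threshold > 0)
  ma <- .conditionMeans(study, conditionA)
  mb <- .conditionMeans(study, conditionB)
  genes <- rownames(study)
  new("DEComparison", conditionA = conditionA, conditionB = conditionB,
      upInB = genes[mb / ma > threshold],
      downInB = genes[ma / mb > threshold],
      threshold = threshold)
}

#' Mean immunological relevance of a DE gene set
#'
#' The average `kl_bits` over all differentially expressed genes (union of
#' both directions). DE genes missing from the relevance table contribute
#' 0 bits (conservative) and are reported via a message. An empty DE set
#' yields `NA`, not 0 -- no evidence is not zero relevance.
#'
#' @param de a [DEComparison-class].
#' @param relevance a [RelevanceTable-class].
#' @return mean relevance in bits, or `NA` for an empty comparison.
#' @export
meanImmuneOfDE <- function(de, relevance) {
  stopifnot(is(de, "DEComparison"), is(relevance, "RelevanceTable"))
  genes <- deGenes(de)
  if (!length(genes)) return(NA_real_)
  kl <- klBits(relevance)
  missing <- setdiff(genes, names(kl))
  if (length(missing))
    message(length(missing), " DE gene(s) missing from the relevance ",
            "table; scored as 0 bits")
  vals <- ifelse(genes %in% names(kl), kl[genes], 0)
  mean(vals)
}

#' Pairwise condition-by-condition immune grade matrix
#'
#' For every ordered pair of conditions, the mean relevance of the genes
#' exceeding the fold-change threshold between them. Because the DE set is
#' the union of both directions, the matrix is symmetric; the diagonal is
#' `NA` (no self-comparison).
#'
#' @inheritParams foldChangeDE
#' @param relevance a [RelevanceTable-class].
#' @return numeric condition x condition matrix of mean `kl_bits`.
#' @export
pairwiseImmuneMatrix <- function(study, relevance, threshold = 2) {
  conds <- unique(conditionLabels(study))
  if (length(conds) < 2L)
    stop("need at least 2 conditions", call. = FALSE)
  M <- matrix(NA_real_, length(conds), length(conds),
              dimnames = list(conds, conds))
  for (i in seq_along(conds)) for (j in seq_along(conds)) {
    if (i >= j) next
    m <- meanImmuneOfDE(foldChangeDE(study, conds[i], conds[j],
                                     threshold), relevance)
    M[i, j] <- M[j, i] <- m
  }
  M
}

#' Direction-resolved high-relevance DE gene lists
#'
#' The Table-1-style view of a comparison: up and down gene lists
#' restricted to `kl_bits > klMin` and sorted by descending relevance.
#'
#' @param de a [DEComparison-class].
#' @param relevance a [RelevanceTable-class].
#' @param klMin relevance cutoff in bits (>= 0); strict inequality.
#' @return list of two `data.frame`s (`up`, `down`) with columns `gene`,
#'   `kl_bits`.
#' @export
rankedTransitionGenes <- function(de, relevance, klMin) {
  stopifnot(klMin >= 0)
  kl <- klBits(relevance)
  pick <- function(genes) {
    v <- kl[intersect(genes, names(kl))]
    v <- v[v > klMin]
    v <- sort(v, decreasing = TRUE)
    data.frame(gene = names(v), kl_bits = unname(v),
               stringsAsFactors = FALSE)
  }
  list(up = pick(de@upInB), down = pick(de@downInB))
}

#' Composite expression x relevance gene score W_g
#'
#' For every gene and patient, the log2 fold change of the patient's
#' signal relative to the gene's mean signal intensity across all patients
#' (MSI), weighted by the gene's KL relevance:
#' `W_g = log2(S / MSI) * kl_bits`. The log form makes up- and
#' down-regulation contribute symmetrically. The study is expected to be
#' quantile normalized and detection filtered first.
#'
#' @param study an [ExpressionStudy-class].
#' @param relevance a [RelevanceTable-class]; genes missing from it weigh
#'   0 bits (reported via a message).
#' @return genes x patients numeric matrix of W_g values.
#' @export
compositeGeneScore <- function(study, relevance) {
  stopifnot(is(study, "ExpressionStudy"), is(relevance, "RelevanceTable"))
  S <- intensityMatrix(study)
  msi <- rowMeans(S)
  stopifnot(all(msi > 0))              # guaranteed by the intensity floor
  kl <- klBits(relevance)
  w <- ifelse(rownames(S) %in% names(kl), kl[rownames(S)], 0)
  nMissing <- sum(!(rownames(S) %in% names(kl)))
  if (nMissing)
    message(nMissing, " gene(s) missing from the relevance table; ",
            "weighted 0 bits")
  log2(S / msi) * w
}

#' Per-patient immune grade W_p
#'
#' Sums the composite gene scores over all (filtered) genes for each
#' patient: `W_p = sum_g W_g`.
#'
#' @param wg genes x patients matrix from [compositeGeneScore()].
#' @return named numeric vector of patient grades.
#' @export
patientScore <- function(wg) colSums(wg)

## Internal: two-sided Monte-Carlo permutation p for an observed statistic
## against a null generator. Raw p counts strictly larger |null| draws so a
## configuration no permutation can beat reports 0, as clinical tables
## print it; the smoothed (k+1)/(n+1) form stays a valid p-value.
.permPvalue <- function(obs, nullDraws) {
  k <- sum(abs(nullDraws) > abs(obs))
  list(raw = k / length(nullDraws),
       smoothed = (k + 1) / (length(nullDraws) + 1))
}

#' Permutation association of patient grades with a binary phenotype
#'
#' Tests whether the immune grade `W_p` differs between two phenotype
#' classes. The statistic is the difference of class means (second factor
#' level minus first); the null distribution is built by `nDraws` random
#' label permutations. Both the raw empirical p (`k / nDraws`, which can
#' be 0) and the smoothed `(k + 1) / (nDraws + 1)` are reported, with the
#' effect direction.
#'
#' @param wp named numeric vector of patient grades.
#' @param phenotype binary labels (factor or coercible), aligned with
#'   `wp`.
#' @param nDraws Monte-Carlo draws (default 10000).
#' @param seed integer seed; results are deterministic given the seed.
#' @return list with `statistic`, `p.raw`, `p.smoothed`, `direction`
#'   (e.g. `"up_in_<level2>"`), `levels` and `nDraws`.
#' @export
phenotypeAssociation <- function(wp, phenotype, nDraws = 10000L,
                                 seed = 1L) {
  f <- factor(phenotype)
  if (nlevels(f) != 2L || any(tabulate(f, 2L) == 0L))
    stop("phenotype must have exactly two non-empty classes",
         call. = FALSE)
  stopifnot(length(wp) == length(f), nDraws >= 1L)
  wp <- as.numeric(wp)
  n <- length(wp)
  isB <- f == levels(f)[2L]
  nB <- sum(isB)
  tot <- sum(wp)
  statFromSum <- function(sB) sB / nB - (tot - sB) / (n - nB)
  obs <- statFromSum(sum(wp[isB]))
  set.seed(seed)
  nulls <- vapply(seq_len(nDraws), function(i)
    statFromSum(sum(wp[sample.int(n, nB)])), numeric(1))
  p <- .permPvalue(obs, nulls)
  list(statistic = obs, p.raw = p$raw, p.smoothed = p$smoothed,
       direction = paste0(if (obs >= 0) "up_in_" else "down_in_",
                          levels(f)[2L]),
       levels = levels(f), nDraws = nDraws)
}

#' Permutation-tested Pearson correlation with a numeric phenotype
#'
#' Pearson correlation between the patient grades and a numeric clinical
#' phenotype (e.g. Breslow thickness), with a two-sided permutation p from
#' the same Monte-Carlo machinery as [phenotypeAssociation()]. Constant
#' input makes the correlation undefined and is reported as `NA` with a
#' warning.
#'
#' @param wp named numeric vector of patient grades (>= 3 patients).
#' @param phenotype numeric vector aligned with `wp`.
#' @inheritParams phenotypeAssociation
#' @return list with `r`, `p.raw`, `p.smoothed`, `nDraws`.
#' @export
numericPhenotypeCorrelation <- function(wp, phenotype, nDraws = 10000L,
                                        seed = 1L) {
  wp <- as.numeric(wp)
  phenotype <- as.numeric(phenotype)
  stopifnot(length(wp) == length(phenotype))
  if (length(wp) < 3L)
    stop("need at least 3 patients", call. = FALSE)
  if (stats::sd(wp) == 0 || stats::sd(phenotype) == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p.raw = NA_real_, p.smoothed = NA_real_,
                nDraws = nDraws))
  }
  r <- stats::cor(wp, phenotype)
  set.seed(seed)
  nulls <- vapply(seq_len(nDraws), function(i)
    stats::cor(wp, phenotype[sample.int(length(phenotype))]), numeric(1))
  p <- .permPvalue(r, nulls)
  list(r = r, p.raw = p$raw, p.smoothed = p$smoothed, nDraws = nDraws)
}

#' High-relevance subnetwork of a differential expression comparison
#'
#' The induced interactome subgraph on the DE genes whose relevance
#' exceeds `klMin` bits, annotated per node with the regulation direction
#' and the relevance (the Figure-6-style module view; export with
#' [writeGraphML()] for external viewers, where node size conventionally
#' encodes relevance).
#'
#' @param de a [DEComparison-class].
#' @param relevance a [RelevanceTable-class].
#' @param graph an [InteractomeGraph-class].
#' @param klMin relevance cutoff in bits (strict).
#' @return An [InteractomeGraph-class] whose nodes carry `direction`
#'   (`"up"`/`"down"`) and `kl_bits` attributes; empty with a warning when
#'   no DE gene qualifies.
#' @export
immuneSubnetwork <- function(de, relevance, graph, klMin = 1) {
  stopifnot(is(de, "DEComparison"), is(graph, "InteractomeGraph"))
  kl <- klBits(relevance)
  genes <- deGenes(de)
  genes <- genes[genes %in% names(kl) & kl[genes] > klMin]
  keep <- intersect(genes, geneSymbols(graph))
  if (!length(keep))
    warning("no high-relevance DE gene present in the network",
            call. = FALSE)
  sub <- igraph::induced_subgraph(graph@graph, keep)
  if (length(keep)) {
    nm <- igraph::V(sub)$name
    sub <- igraph::set_vertex_attr(sub, "direction",
      value = ifelse(nm %in% de@upInB, "up", "down"))
    sub <- igraph::set_vertex_attr(sub, "kl_bits", value = kl[nm])
  }
  .wrapGraph(sub)
}
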