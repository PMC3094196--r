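# A relevance table with prescribed KL scores (rank by descending score,
# symbol tie-break), for tests that need exact known relevance values.
makeRelevance <- function(kl, context = "immune") {
  genes <- names(kl)
  ord <- order(-kl, genes)
  rk <- integer(length(kl)); rk[ord] <- seq_along(kl)
  sc <- data.frame(gene = genes, shannon_bits = abs(kl),
                   kl_bits = unname(kl), rank = rk, never_cocited = FALSE,
                   stringsAsFactors = FALSE)
  sc <- sc[ord, ]; rownames(sc) <- NULL
  new("RelevanceTable", context = context, scores = sc)
}
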