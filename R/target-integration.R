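#' Integration filter parameters
#'
#' `fpkm_cutoff` defaults to the six-decimal threshold 0.983129 FPKM -- the
#' GFP+ expression level of the lowest-expressed gene independently known
#' to be enriched in the sorted population -- rather than its two-decimal
#' rounding, since the six-decimal value is the operative filter.
#'
#' @param fpkm_cutoff minimum FPKM in the GFP+ sample.
#' @param fold_cutoff minimum GFP+/GFP- fold enrichment (default 1.5).
#' @param max_dist peak-to-gene association radius in bp (default 3000).
#' @param pseudocount added to both FPKM values before the fold ratio
#'   (default 0; with 0, a zero GFP- denominator counts as infinite
#'   enrichment and passes the fold test).
#' @return list of class `integration_params`.
#' @export
integration_params <- function(fpkm_cutoff = 0.983129, fold_cutoff = 1.5,
                               max_dist = 3000L, pseudocount = 0) {
  if (fpkm_cutoff < 0 || fold_cutoff < 0 || max_dist < 0 || pseudocount < 0)
    stopf("all integration parameters must be >= 0")
  structure(list(fpkm_cutoff = fpkm_cutoff, fold_cutoff = fold_cutoff,
                 max_dist = as.integer(max_dist), pseudocount = pseudocount),
            class = "integration_params")
}

#' Filter transcripts by expression and fold enrichment
#'
#' A transcript passes when it is expressed at `fpkm_cutoff` or higher in
#' the GFP+ sample *and* enriched `fold_cutoff`-fold or higher over the
#' GFP- sample. With no pseudocount, `fpkm_minus = 0` together with a
#' passing `fpkm_plus` counts as infinite enrichment and passes.
#'
#' @param records expression table (columns `transcript_id`, `gene_id`,
#'   `fpkm_plus`, `fpkm_minus`; transcript ids must be unique).
#' @param params an [integration_params()].
#' @return character vector of passing transcript ids.
#' @export
filter_expressed <- function(records, params = integration_params()) {
  need <- c("transcript_id", "gene_id", "fpkm_plus", "fpkm_minus")
  if (!all(need %in% names(records)))
    stopf("expression table must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(records$transcript_id))
    stopf("duplicate transcript_id in expression table")
  if (any(records$fpkm_plus < 0 | records$fpkm_minus < 0))
    stopf("FPKM values must be >= 0")
  plus <- records$fpkm_plus + params$pseudocount
  minus <- records$fpkm_minus + params$pseudocount
  fold <- ifelse(minus > 0, plus / minus, ifelse(plus > 0, Inf, NaN))
  pass <- records$fpkm_plus >= params$fpkm_cutoff &
    !is.nan(fold) & fold >= params$fold_cutoff
  records$transcript_id[pass]
}

#' All transcript isoforms of peak-associated genes
#'
#' @param associations output of [assign_peaks_to_genes()].
#' @param models a [gene_models()] object.
#' @return character vector of transcript ids (set semantics: each
#'   transcript once, however many peaks its gene collected).
#' @export
chip_transcript_set <- function(associations, models) {
  genes <- unique(associations$gene_id)
  tx_gene <- S4Vectors::mcols(models$transcripts)$gene_id
  sort(names(models$transcripts)[tx_gene %in% genes])
}

#' Intersect expression-passing and ChIP-associated transcripts
#'
#' @param passing transcript ids from [filter_expressed()].
#' @param chip_set transcript ids from [chip_transcript_set()].
#' @param records the expression table (used to map transcripts to genes).
#' @return list with `transcripts` (sorted overlap) and `genes` (sorted
#'   distinct gene ids of the overlap).
#' @export
intersect_and_collapse <- function(passing, chip_set, records) {
  overlap <- sort(intersect(passing, chip_set))
  genes <- sort(unique(records$gene_id[match(overlap, records$transcript_id)]))
  list(transcripts = overlap, genes = genes[!is.na(genes)])
}

#' Cumulative hypergeometric tail probability
#'
#' Probability of observing `k` or more successes when drawing `n` items
#' without replacement from a population of `N` containing `K` successes:
#' `P(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`, computed
#' by log-space summation of `lchoose` terms, exact to well beyond six
#' significant digits. `exclusive = TRUE` returns the strictly-greater tail
#' `P(X > k) = 1 - F(k)` instead, a convention some spreadsheet-era
#' analyses report under the "k or more" label.
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size.
#' @param k observed successes in the sample.
#' @param exclusive return `P(X > k)` instead of `P(X >= k)`.
#' @return tail probability.
#' @export
hypergeom_tail <- function(N, K, n, k, exclusive = FALSE) {
  for (v in list(N = N, K = K, n = n, k = k))
    if (!is_count(v)) stopf("N, K, n, k must be non-negative integers")
  if (K > N || n > N) stopf("K and n must not exceed N")
  if (k > min(K, n)) stopf("k must not exceed min(K, n)")
  k0 <- if (exclusive) k + 1 else k
  if (k0 > min(K, n)) return(0)
  i <- k0:min(K, n)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(exp(logsumexp(lt)), 1)
}
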