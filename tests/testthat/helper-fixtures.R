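# Shared fixtures, all built in code.

# a small, fast synthetic configuration used across module tests
small_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed,
               chrom_lengths = c(chrA = 120000L, chrB = 80000L),
               n_genes = 14L, n_planted_peaks = 4L, peak_width = 600L,
               n_bound_sites = 40L, n_unbound_sites = 40L)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# two genes with known anatomy:
#   gA (+): exons [1001,1200] [2001,2200] [3001,3400]
#           introns [1201,2000] (first) and [2201,3000]
#   gB (-): exons [6001,6400] [7501,7700]; intron [6401,7500] (first)
toy_models <- function() {
  gene_models(data.frame(
    chrom = "chr1",
    start = c(1001L, 2001L, 3001L, 6001L, 7501L),
    end   = c(1200L, 2200L, 3400L, 6400L, 7700L),
    strand = c("+", "+", "+", "-", "-"),
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    transcript_id = c("gA.1", "gA.1", "gA.1", "gB.1", "gB.1"),
    stringsAsFactors = FALSE))
}

# constant-value probe track on a regular grid
uniform_track <- function(chrom = "chr1", from = 1L, to = 5000L, by = 50L,
                          value = 1) {
  pos <- as.integer(seq.int(from, to, by = by))
  data.frame(chrom = chrom, pos = pos, value = value,
             stringsAsFactors = FALSE)
}

# combined-track layout (column `combined` instead of `value`)
uniform_combined <- function(..., value = 1) {
  t <- uniform_track(..., value = value)
  data.frame(chrom = t$chrom, pos = t$pos, combined = t$value,
             stringsAsFactors = FALSE)
}

# scored track with hand-placed significant probes, for call_peaks tests
scored_track <- function(pos, sig, chrom = "chr1", score = NULL) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             score = score %||% ifelse(sig, 10, 0),
             p_value = ifelse(sig, 1e-5, 1),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_genome <- function(seed, len = 1e5L, gc = 0.43, name = "chrT") {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
  })
  out <- Biostrings::DNAStringSet(s)
  names(out) <- name
  out
}

# reciprocal-overlap matching between planted and called peak sets
match_peaks <- function(planted, called, min_frac = 0.5) {
  if (length(called) == 0L)
    return(list(recalled = logical(length(planted)),
                matched_calls = logical(0)))
  ov <- GenomicRanges::findOverlaps(planted, called, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(planted[q], called[s]))
  frac <- w / pmax(GenomicRanges::width(planted[q]),
                   GenomicRanges::width(called[s]))
  good <- frac >= min_frac
  list(recalled = seq_along(planted) %in% q[good],
       matched_calls = seq_along(called) %in% s[good])
}
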