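#' Scan a genome for E-box cores
#'
#' Reports every plus-strand sliding-window match of the requested cores
#' (IUPAC ambiguity codes such as `CANNTG` are honored). The two palindromic
#' E-boxes CATATG and CAGCTG are their own reverse complements, so
#' plus-strand scanning is exhaustive for them; all occurrences are recorded
#' in plus-strand orientation. Overlapping matches are all reported.
#'
#' @param genome a [Biostrings::DNAStringSet] named by chromosome.
#' @param regions optional GRanges; only occurrences lying entirely inside a
#'   region are kept. Regions beyond chromosome ends raise an error.
#' @param cores character vector of 6-mers (IUPAC allowed).
#' @return data.frame with columns `chrom`, `start`, `end` (1-based,
#'   inclusive), `core` (matched hexamer), `core_class` (`TA`, `GC` or
#'   `other`, from the central dinucleotide), `prefix_base` (base
#'   immediately 5' of the core on the plus strand, NA at a chromosome
#'   start).
#' @export
scan_eboxes <- function(genome, regions = NULL,
                        cores = c("CATATG", "CAGCTG")) {
  if (any(nchar(cores) != 6L)) stopf("cores must be 6-mers")
  if (!is.null(regions)) {
    rc <- as.character(GenomeInfoDb::seqnames(regions))
    if (!all(rc %in% names(genome)))
      stopf("region chromosome(s) absent from genome: %s",
            paste(unique(setdiff(rc, names(genome))), collapse = ", "))
    too_far <- GenomicRanges::end(regions) > Biostrings::width(genome)[
      match(rc, names(genome))] | GenomicRanges::start(regions) < 1L
    if (any(too_far)) stopf("region(s) extend beyond chromosome bounds")
  }
  rows <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    for (core in cores) {
      m <- Biostrings::matchPattern(core, subj, fixed = FALSE)
      if (length(m) == 0L) next
      st <- Biostrings::start(m)
      hit <- as.character(m)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = st, end = st + 5L, core = hit,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), core = character(0),
                      core_class = character(0), prefix_base = character(0),
                      stringsAsFactors = FALSE))
  occ <- do.call(rbind, rows)
  occ <- occ[!duplicated(occ[, c("chrom", "start", "core")]), , drop = FALSE]
  occ <- occ[order(occ$chrom, occ$start), , drop = FALSE]
  central <- substr(occ$core, 3L, 4L)
  occ$core_class <- ifelse(central == "TA", "TA",
                           ifelse(central == "GC", "GC", "other"))
  occ$prefix_base <- NA_character_
  has_prefix <- occ$start > 1L
  if (any(has_prefix)) {
    occ$prefix_base[has_prefix] <- vapply(which(has_prefix), function(i) {
      as.character(Biostrings::subseq(genome[[occ$chrom[i]]],
                                      occ$start[i] - 1L, occ$start[i] - 1L))
    }, character(1))
  }
  if (!is.null(regions)) {
    gr <- GenomicRanges::GRanges(occ$chrom, IRanges::IRanges(occ$start, occ$end))
    keep <- IRanges::overlapsAny(gr, regions, type = "within",
                                 ignore.strand = TRUE)
    occ <- occ[keep, , drop = FALSE]
  }
  rownames(occ) <- NULL
  occ
}

occurrences_gr <- function(occurrences) {
  GenomicRanges::GRanges(occurrences$chrom,
                         IRanges::IRanges(occurrences$start, occurrences$end))
}

# peak id + offset of the occurrence center from the peak center (midpoint
# by default, summit if requested); occurrences outside any peak get NA
occurrence_offsets <- function(occurrences, peaks, center = c("midpoint", "summit")) {
  center <- match.arg(center)
  if (is.null(names(peaks))) names(peaks) <- sprintf("peak_%04d", seq_along(peaks))
  hits <- GenomicRanges::findOverlaps(occurrences_gr(occurrences), peaks,
                                      type = "within", ignore.strand = TRUE)
  peak_id <- rep(NA_character_, nrow(occurrences))
  offset <- rep(NA_real_, nrow(occurrences))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  first <- !duplicated(q)     # peaks never overlap, so at most one hit each
  q <- q[first]; s <- s[first]
  ctr <- if (center == "summit" && !is.null(S4Vectors::mcols(peaks)$summit)) {
    S4Vectors::mcols(peaks)$summit
  } else {
    (GenomicRanges::start(peaks) + GenomicRanges::end(peaks)) / 2
  }
  peak_id[q] <- names(peaks)[s]
  offset[q] <- (occurrences$start[q] + 2.5) - ctr[s]
  data.frame(peak_id = peak_id, peak_offset = offset, stringsAsFactors = FALSE)
}

#' Count E-boxes per peak
#'
#' Tallies TA/GC-class occurrences inside each peak and summarizes how many
#' peaks carry at least one, and more than one, such E-box. Peaks with no
#' occurrence are excluded from both tallies.
#'
#' @param occurrences output of [scan_eboxes()].
#' @param peaks GRanges of peaks.
#' @return list with `per_peak` (data.frame `peak_id`, `n_ebox`),
#'   `n_peaks_with_ebox` and `n_peaks_multi`.
#' @export
peak_ebox_counts <- function(occurrences, peaks) {
  if (is.null(names(peaks))) names(peaks) <- sprintf("peak_%04d", seq_along(peaks))
  keep <- occurrences$core_class %in% c("TA", "GC")
  counts <- integer(length(peaks))
  names(counts) <- names(peaks)
  if (any(keep)) {
    hits <- GenomicRanges::findOverlaps(occurrences_gr(occurrences[keep, ]),
                                        peaks, type = "within",
                                        ignore.strand = TRUE)
    tab <- table(S4Vectors::subjectHits(hits))
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  list(per_peak = data.frame(peak_id = names(counts), n_ebox = unname(counts),
                             stringsAsFactors = FALSE),
       n_peaks_with_ebox = sum(counts >= 1L),
       n_peaks_multi = sum(counts > 1L))
}

profile_bins <- function(half_extent, bin_width) {
  nb <- ceiling(half_extent / bin_width)
  mids <- seq(-nb * bin_width + bin_width / 2, nb * bin_width - bin_width / 2,
              by = bin_width)
  mids
}

#' Positional density of E-boxes within peaks
#'
#' Occurrence density as a function of distance from the peak center
#' (midpoint by default, summit on request). Because peaks have unequal
#' widths, each bin's count is normalized by the number of peaks whose
#' extent reaches that bin's midpoint.
#'
#' @param occurrences output of [scan_eboxes()].
#' @param peaks GRanges of peaks.
#' @param bin_width bin width in bp (default 50).
#' @param center `"midpoint"` (default) or `"summit"`.
#' @return data.frame with columns `offset` (bin midpoint), `count`,
#'   `n_peaks` (peaks covering the bin), `density` (count / n_peaks, NaN
#'   where no peak reaches).
#' @export
positional_profile <- function(occurrences, peaks, bin_width = 50L,
                               center = c("midpoint", "summit")) {
  center <- match.arg(center)
  half <- if (length(peaks) > 0L) max(GenomicRanges::width(peaks)) / 2 else bin_width
  mids <- profile_bins(half, bin_width)
  halfw <- GenomicRanges::width(peaks) / 2
  n_peaks <- vapply(mids, function(m) sum(halfw >= abs(m)), numeric(1))
  count <- integer(length(mids))
  if (nrow(occurrences) > 0L && length(peaks) > 0L) {
    off <- occurrence_offsets(occurrences, peaks, center)$peak_offset
    off <- off[!is.na(off)]
    if (length(off) > 0L) {
      b <- findInterval(off, c(mids - bin_width / 2, max(mids) + bin_width / 2),
                        rightmost.closed = TRUE)
      b <- b[b >= 1L & b <= length(mids)]
      tab <- table(b)
      count[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  data.frame(offset = mids, count = count, n_peaks = n_peaks,
             density = ifelse(n_peaks > 0, count / n_peaks, NaN))
}

#' Prefix-base composition of E-boxes by distance from peak center
#'
#' For every distance bin, the frequency of the base immediately 5' of the
#' core among occurrences in that bin. Frequencies in a populated bin sum
#' to 1; empty bins are reported as NaN, not 0.
#'
#' @inheritParams positional_profile
#' @return data.frame with columns `offset`, `n`, `A`, `C`, `G`, `T`.
#' @export
prefix_variant_profile <- function(occurrences, peaks, bin_width = 50L,
                                   center = c("midpoint", "summit")) {
  center <- match.arg(center)
  half <- if (length(peaks) > 0L) max(GenomicRanges::width(peaks)) / 2 else bin_width
  mids <- profile_bins(half, bin_width)
  res <- matrix(NaN, length(mids), 4L, dimnames = list(NULL, BASES))
  n <- integer(length(mids))
  if (nrow(occurrences) > 0L && length(peaks) > 0L) {
    off <- occurrence_offsets(occurrences, peaks, center)$peak_offset
    ok <- !is.na(off) & !is.na(occurrences$prefix_base)
    if (any(ok)) {
      b <- findInterval(off[ok], c(mids - bin_width / 2, max(mids) + bin_width / 2),
                        rightmost.closed = TRUE)
      pb <- occurrences$prefix_base[ok]
      for (i in unique(b[b >= 1L & b <= length(mids)])) {
        sel <- pb[b == i]
        n[i] <- length(sel)
        res[i, ] <- vapply(BASES, function(x) mean(sel == x), numeric(1))
      }
    }
  }
  cbind(data.frame(offset = mids, n = n), as.data.frame(res))
}

#' GC content by distance from peak center
#'
#' Mean GC fraction of peak sequence in distance bins from the peak center,
#' pooled across peaks (total G+C over total bases per bin).
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param peaks GRanges of peaks.
#' @param bin_width bin width in bp (default 50).
#' @return data.frame with columns `offset`, `gc`, `n_bases`.
#' @export
gc_profile <- function(genome, peaks, bin_width = 50L) {
  half <- if (length(peaks) > 0L) max(GenomicRanges::width(peaks)) / 2 else bin_width
  mids <- profile_bins(half, bin_width)
  gc_bases <- numeric(length(mids))
  n_bases <- numeric(length(mids))
  for (i in seq_along(peaks)) {
    chrom <- as.character(GenomeInfoDb::seqnames(peaks)[i])
    s <- GenomicRanges::start(peaks)[i]
    e <- GenomicRanges::end(peaks)[i]
    ctr <- (s + e) / 2
    seq <- strsplit(as.character(Biostrings::subseq(genome[[chrom]], s, e)),
                    "")[[1L]]
    off <- (s:e) - ctr
    b <- findInterval(off, c(mids - bin_width / 2, max(mids) + bin_width / 2),
                      rightmost.closed = TRUE)
    ok <- b >= 1L & b <= length(mids)
    isgc <- seq %in% c("G", "C")
    for (k in unique(b[ok])) {
      sel <- ok & b == k
      gc_bases[k] <- gc_bases[k] + sum(isgc[sel])
      n_bases[k] <- n_bases[k] + sum(sel)
    }
  }
  data.frame(offset = mids, gc = ifelse(n_bases > 0, gc_bases / n_bases, NaN),
             n_bases = n_bases)
}

#' Sample random intronic E-boxes
#'
#' Draws a uniform sample, without replacement, from all intronic
#' occurrences of a core, excluding occurrences overlapping the supplied
#' peaks, to serve as the unbound background set. If fewer than `n`
#' occurrences exist, all are returned with a warning.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param models a [gene_models()] object (introns taken across isoforms).
#' @param core core hexamer (default CATATG).
#' @param n sample size (default 800).
#' @param exclude optional GRanges (typically the called peaks).
#' @param seed integer seed; the sample is deterministic given it.
#' @return data.frame in [scan_eboxes()] layout.
#' @export
sample_random_intronic_eboxes <- function(genome, models, core = "CATATG",
                                          n = 800L, exclude = NULL,
                                          seed = 1L) {
  introns <- GenomicRanges::reduce(unlist(models$introns), ignore.strand = TRUE)
  occ <- scan_eboxes(genome, regions = introns, cores = core)
  if (!is.null(exclude) && nrow(occ) > 0L) {
    keep <- !IRanges::overlapsAny(occurrences_gr(occ), exclude,
                                  ignore.strand = TRUE)
    occ <- occ[keep, , drop = FALSE]
  }
  if (nrow(occ) <= n) {
    if (nrow(occ) < n)
      warnf("only %d intronic %s occurrences available (requested %d)",
            nrow(occ), core, n)
    return(occ)
  }
  idx <- withr::with_seed(stage_seed(seed, "sample"),
                          sort(sample.int(nrow(occ), n)))
  out <- occ[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conservation profile around E-box cores
#'
#' Mean per-base conservation at every offset relative to the core start
#' (plus-strand orientation; both cores are palindromic so this is
#' well-defined), over the core plus `flank` bp each side. Sites whose
#' window runs off a chromosome are dropped from the affected offsets only.
#'
#' @param occurrences output of [scan_eboxes()].
#' @param conservation per-base track: named list of numeric vectors, one
#'   per chromosome (see [gen_conservation()] / [read_conservation()]).
#' @param flank bp each side of the 6-bp core (default 20).
#' @return data.frame with columns `offset` (0 = core start), `mean_score`,
#'   `n_sites`.
#' @export
conservation_profile <- function(occurrences, conservation, flank = 20L) {
  offsets <- seq.int(-flank, 5L + flank)
  m <- matrix(NA_real_, nrow(occurrences), length(offsets))
  for (i in seq_len(nrow(occurrences))) {
    v <- conservation[[occurrences$chrom[i]]]
    if (is.null(v)) next
    p <- occurrences$start[i] + offsets
    ok <- p >= 1L & p <= length(v)
    m[i, ok] <- v[p[ok]]
  }
  data.frame(offset = offsets,
             mean_score = colMeans(m, na.rm = TRUE),
             n_sites = as.integer(colSums(!is.na(m))))
}
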