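#' Assign peaks to nearby genes
#'
#' A gene is associated with a peak when the gap between the peak interval
#' and the gene span is strictly less than `max_dist` bp (an overlapping
#' peak has distance 0). The "proximal endpoint" of a gene is its nearest
#' point to the peak, so the criterion is symmetric in direction. One peak
#' may map to several genes and one gene may collect several peaks.
#'
#' @param peaks GRanges of peaks (e.g. from [call_peaks()]).
#' @param models a [gene_models()] object.
#' @param max_dist association radius in bp (default 3000).
#' @return data.frame with columns `peak_id`, `gene_id`, `distance`,
#'   sorted by peak then distance.
#' @export
assign_peaks_to_genes <- function(peaks, models, max_dist = 3000L) {
  genes <- models$genes
  known <- as.character(GenomeInfoDb::seqnames(peaks)) %in%
    unique(as.character(GenomeInfoDb::seqnames(genes)))
  if (!all(known)) {
    warnf("%d peak(s) on chromosomes absent from the annotation were skipped",
          sum(!known))
    peaks <- peaks[known]
  }
  if (length(peaks) == 0L)
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  if (is.null(names(peaks))) names(peaks) <- sprintf("peak_%04d", seq_along(peaks))
  hits <- GenomicRanges::findOverlaps(peaks, genes, maxgap = max_dist,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(peak_id = character(0), gene_id = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  d <- GenomicRanges::distance(peaks[S4Vectors::queryHits(hits)],
                               genes[S4Vectors::subjectHits(hits)],
                               ignore.strand = TRUE)
  keep <- d < max_dist
  out <- data.frame(peak_id = names(peaks)[S4Vectors::queryHits(hits)][keep],
                    gene_id = names(genes)[S4Vectors::subjectHits(hits)][keep],
                    distance = as.integer(d[keep]), stringsAsFactors = FALSE)
  out[order(out$peak_id, out$distance, out$gene_id), , drop = FALSE]
}

# pool probe values into strand-oriented offset bins around anchors
pool_anchor_bins <- function(track, anchors, window, bins) {
  binwidth <- 2 * window / bins
  sums <- numeric(bins)
  cnts <- integer(bins)
  parts <- split(seq_len(nrow(track)), track$chrom)
  a_chrom <- as.character(GenomeInfoDb::seqnames(anchors))
  a_pos <- GenomicRanges::start(anchors)
  a_neg <- as.character(GenomicRanges::strand(anchors)) == "-"
  for (i in seq_along(anchors)) {
    idx <- parts[[a_chrom[i]]]
    if (is.null(idx)) next
    pos <- track$pos[idx]
    lo <- findInterval(a_pos[i] - window - 0.5, pos) + 1L
    hi <- findInterval(a_pos[i] + window, pos)
    if (hi < lo) next
    off <- pos[lo:hi] - a_pos[i]
    if (a_neg[i]) off <- -off
    b <- floor((off + window) / binwidth) + 1L
    b[b > bins] <- bins
    b <- pmax(b, 1L)
    v <- track$combined[idx][lo:hi]
    for (k in seq_along(b)) {
      sums[b[k]] <- sums[b[k]] + v[k]
      cnts[b[k]] <- cnts[b[k]] + 1L
    }
  }
  list(sums = sums, cnts = cnts, binwidth = binwidth)
}

#' Signal profile anchored on TSS/TTS-like positions
#'
#' Averages the combined signal in strand-oriented bins centered on each
#' anchor. Minus-strand anchors are mirrored so that positive offsets are
#' transcription-downstream. Anchors without probes in the window simply
#' contribute nothing.
#'
#' @param track combined track (columns `chrom`, `pos`, `combined`).
#' @param anchors GRanges of width-1 anchors with strand (see [tss()]).
#' @param window half-width of the profile in bp.
#' @param bins number of bins covering \[-window, window\].
#' @return data.frame of class `anchored_profile` with columns `bin_start`,
#'   `bin_mid`, `bin_end` (offsets in bp), `mean_signal`, `n_obs`;
#'   attribute `n_anchors`.
#' @export
anchored_profile <- function(track, anchors, window = 3000L, bins = 120L) {
  if (window <= 0 || bins < 1) stopf("window must be > 0 and bins >= 1")
  track <- track[order(track$chrom, track$pos), , drop = FALSE]
  p <- pool_anchor_bins(track, anchors, window, bins)
  edges <- seq(-window, window, length.out = bins + 1L)
  out <- data.frame(bin_start = edges[-(bins + 1L)], bin_end = edges[-1L],
                    mean_signal = ifelse(p$cnts > 0, p$sums / p$cnts, NaN),
                    n_obs = p$cnts)
  out$bin_mid <- (out$bin_start + out$bin_end) / 2
  out <- out[, c("bin_start", "bin_mid", "bin_end", "mean_signal", "n_obs")]
  attr(out, "n_anchors") <- length(anchors)
  class(out) <- c("anchored_profile", "data.frame")
  out
}

#' Metagene profile
#'
#' Every gene body is rescaled to `body_bins` equal-fraction bins
#' (strand-oriented, so bin 1 is always the 5' end of the gene), optionally
#' flanked by fixed-width upstream/downstream bins, and the combined signal
#' is averaged per bin across genes.
#'
#' @param track combined track (columns `chrom`, `pos`, `combined`).
#' @param models a [gene_models()] object.
#' @param body_bins number of gene-body bins (default 100).
#' @param flank_bp flank width in bp on each side (0 = body only).
#' @param flank_bins number of bins per flank.
#' @return data.frame of class `anchored_profile` with columns `section`
#'   (upstream/body/downstream), `bin` (1-based within the whole profile),
#'   `mean_signal`, `n_obs`.
#' @export
metagene_profile <- function(track, models, body_bins = 100L,
                             flank_bp = 1000L, flank_bins = 20L) {
  if (body_bins < 1) stopf("body_bins must be >= 1")
  if (flank_bp == 0) flank_bins <- 0L
  track <- track[order(track$chrom, track$pos), , drop = FALSE]
  parts <- split(seq_len(nrow(track)), track$chrom)
  total <- 2L * flank_bins + body_bins
  sums <- numeric(total)
  cnts <- integer(total)
  genes <- models$genes
  g_chrom <- as.character(GenomeInfoDb::seqnames(genes))
  g_start <- GenomicRanges::start(genes)
  g_end <- GenomicRanges::end(genes)
  g_neg <- as.character(GenomicRanges::strand(genes)) == "-"
  for (i in seq_along(genes)) {
    idx <- parts[[g_chrom[i]]]
    if (is.null(idx)) next
    pos <- track$pos[idx]
    lo <- findInterval(g_start[i] - flank_bp - 0.5, pos) + 1L
    hi <- findInterval(g_end[i] + flank_bp, pos)
    if (hi < lo) next
    p <- pos[lo:hi]
    v <- track$combined[idx][lo:hi]
    width <- g_end[i] - g_start[i] + 1L
    bin <- integer(length(p))
    body <- p >= g_start[i] & p <= g_end[i]
    frac <- (p[body] - g_start[i]) / width
    if (g_neg[i]) frac <- 1 - (p[body] - g_start[i] + 1L) / width
    bb <- pmin(floor(frac * body_bins) + 1L, body_bins)
    bin[body] <- flank_bins + bb
    if (flank_bins > 0L) {
      up <- p < g_start[i]
      dn <- p > g_end[i]
      ub <- pmin(floor((p[up] - (g_start[i] - flank_bp)) / (flank_bp / flank_bins)) + 1L,
                 flank_bins)
      db <- pmin(floor((p[dn] - g_end[i] - 1L) / (flank_bp / flank_bins)) + 1L,
                 flank_bins)
      if (g_neg[i]) {
        # mirrored: genomic-right flank is transcription-upstream
        bin[dn] <- flank_bins + 1L - db
        bin[up] <- flank_bins + body_bins + (flank_bins + 1L - ub)
      } else {
        bin[up] <- ub
        bin[dn] <- flank_bins + body_bins + db
      }
    }
    ok <- bin >= 1L & bin <= total
    for (k in which(ok)) {
      sums[bin[k]] <- sums[bin[k]] + v[k]
      cnts[bin[k]] <- cnts[bin[k]] + 1L
    }
  }
  section <- rep(c("upstream", "body", "downstream"),
                 c(flank_bins, body_bins, flank_bins))
  out <- data.frame(section = section, bin = seq_len(total),
                    mean_signal = ifelse(cnts > 0, sums / cnts, NaN),
                    n_obs = cnts, stringsAsFactors = FALSE)
  attr(out, "n_genes") <- length(genes)
  class(out) <- c("anchored_profile", "data.frame")
  out
}

# union category regions with priority TSS > first_intron > other_intron
category_regions <- function(models, tss_flank) {
  tssr <- GenomicRanges::reduce(
    GenomicRanges::resize(tss(models), 2L * tss_flank + 1L, fix = "center"),
    ignore.strand = TRUE)
  fi <- GenomicRanges::reduce(models$first_intron, ignore.strand = TRUE)
  all_introns <- GenomicRanges::reduce(unlist(models$introns),
                                       ignore.strand = TRUE)
  other <- GenomicRanges::setdiff(all_introns, models$first_intron,
                                  ignore.strand = TRUE)
  fi <- GenomicRanges::setdiff(fi, tssr, ignore.strand = TRUE)
  other <- GenomicRanges::setdiff(other, tssr, ignore.strand = TRUE)
  other <- GenomicRanges::setdiff(other, fi, ignore.strand = TRUE)
  list(tss = tssr, first_intron = fi, other_intron = other)
}

#' First-intron vs other-intron binding preference
#'
#' Per-bp-normalized mean signal (for a combined track) or peak coverage
#' fraction (for a peak GRanges) over three gene-anatomy categories: TSS
#' regions (TSS +/- `tss_flank`), first introns and other introns. Overlaps
#' between categories are resolved with priority TSS > first intron >
#' other intron. The ratio of first-intron to other-intron signal is
#' reported with `Inf` when the other-intron category carries none.
#'
#' @param x a combined track data.frame (`chrom`, `pos`, `combined`) or a
#'   GRanges of peaks.
#' @param models a [gene_models()] object.
#' @param tss_flank half-width of the TSS category in bp (default 500).
#' @return data.frame with one row per category: `category`, `bp`,
#'   `mean_signal`; attribute `first_over_other` carries the ratio.
#' @export
intron_preference <- function(x, models, tss_flank = 500L) {
  cats <- category_regions(models, tss_flank)
  if (is(x, "GRanges")) {
    val <- vapply(cats, function(r) {
      cov <- sum(GenomicRanges::width(GenomicRanges::intersect(
        r, GenomicRanges::reduce(x, ignore.strand = TRUE),
        ignore.strand = TRUE)))
      bp <- sum(GenomicRanges::width(r))
      if (bp > 0) cov / bp else NaN
    }, numeric(1))
  } else {
    x <- x[order(x$chrom, x$pos), , drop = FALSE]
    pr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos, width = 1L))
    val <- vapply(cats, function(r) {
      inside <- IRanges::overlapsAny(pr, r, ignore.strand = TRUE)
      if (any(inside)) mean(x$combined[inside]) else NaN
    }, numeric(1))
  }
  bp <- vapply(cats, function(r) sum(GenomicRanges::width(r)), numeric(1))
  out <- data.frame(category = names(cats), bp = bp, mean_signal = unname(val),
                    stringsAsFactors = FALSE, row.names = NULL)
  fo <- if (is.nan(val[["other_intron"]]) || val[["other_intron"]] == 0) {
    if (!is.nan(val[["first_intron"]]) && val[["first_intron"]] > 0) Inf else NaN
  } else val[["first_intron"]] / val[["other_intron"]]
  attr(out, "first_over_other") <- fo
  out
}

#' Fraction of one peak set overlapping another
#'
#' A peak in `peaks_a` counts as overlapping when it shares at least one bp
#' with any peak in `peaks_b`.
#'
#' @param peaks_a,peaks_b GRanges.
#' @return fraction in \[0, 1\] (NaN for an empty `peaks_a`).
#' @export
peak_set_overlap <- function(peaks_a, peaks_b) {
  if (length(peaks_a) == 0L) return(NaN)
  mean(IRanges::overlapsAny(peaks_a, peaks_b, ignore.strand = TRUE))
}
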