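#' Peak-caller parameters
#'
#' Defaults mirror the tiling-array analysis settings the pipeline was
#' designed around: a 300-bp smoothing bandwidth, runs of significant
#' probes merged across gaps of at most 300 bp, at least 8 significant
#' probes per peak, and a per-probe significance threshold of 1e-4.
#'
#' @param bandwidth half-width (bp) of the smoothing window.
#' @param max_gap maximum gap (bp) between consecutive significant probes
#'   merged into one peak.
#' @param min_probe minimum number of significant probes per peak; windows
#'   with fewer probes than this are never significant.
#' @param p_threshold per-probe p-value threshold.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(bandwidth = 300L, max_gap = 300L, min_probe = 8L,
                          p_threshold = 1e-4) {
  if (bandwidth <= 0 || max_gap <= 0 || min_probe <= 0 || p_threshold <= 0)
    stopf("all caller parameters must be positive")
  structure(list(bandwidth = as.integer(bandwidth),
                 max_gap = as.integer(max_gap),
                 min_probe = as.integer(min_probe),
                 p_threshold = p_threshold),
            class = "caller_params")
}

check_probe_track <- function(t, who = "track") {
  if (!is.data.frame(t) || !all(c("chrom", "pos", "value") %in% names(t)))
    stopf("%s must be a data.frame with columns chrom, pos, value", who)
  ord <- order(t$chrom, t$pos)
  t <- t[ord, , drop = FALSE]
  dup <- unlist(tapply(t$pos, t$chrom, function(p) c(FALSE, diff(p) == 0)))
  if (any(dup)) stopf("%s has duplicated probe positions", who)
  rownames(t) <- NULL
  t
}

#' Combine the four probe tracks
#'
#' The experimental ChIP sample (`t1`) is normalized against its input
#' (`t2`), the control ChIP (`t3`) against its input (`t4`), and the
#' experimental ChIP directly against the control ChIP, then combined per
#' probe as
#'
#'   C = \[(t1 - t2) - (t3 - t4)\] + (t1 - t3)
#'
#' on log2 values. Requiring signal in both the input-normalized contrast
#' and the direct ChIP-vs-ChIP contrast makes the combined score robust to
#' artifacts shared by the two ChIP samples. By default the four intensity
#' vectors are quantile-normalized jointly before combining.
#'
#' @param t1,t2,t3,t4 probe tracks (data.frames with `chrom`, `pos`,
#'   `value`): experimental ChIP, experimental input, control ChIP, control
#'   input. All four must share an identical probe grid.
#' @param quantile_normalize jointly quantile-normalize the four intensity
#'   columns first (default TRUE). Turn off when the inputs are already
#'   comparable or when exact per-probe arithmetic is wanted.
#' @return data.frame with columns `chrom`, `pos`, `combined`.
#' @export
normalize_tracks <- function(t1, t2, t3, t4, quantile_normalize = TRUE) {
  tracks <- list(t1 = check_probe_track(t1, "t1"), t2 = check_probe_track(t2, "t2"),
                 t3 = check_probe_track(t3, "t3"), t4 = check_probe_track(t4, "t4"))
  ref <- tracks[[1L]]
  for (nm in names(tracks)[-1L]) {
    t <- tracks[[nm]]
    if (nrow(t) != nrow(ref) || any(t$chrom != ref$chrom) || any(t$pos != ref$pos)) {
      bad <- if (nrow(t) != nrow(ref)) 1L else
        which(t$chrom != ref$chrom | t$pos != ref$pos)[1L]
      stopf("probe grid of %s differs from t1 starting at record %d (%s:%d)",
            nm, bad, ref$chrom[min(bad, nrow(ref))], ref$pos[min(bad, nrow(ref))])
    }
  }
  v <- cbind(tracks$t1$value, tracks$t2$value, tracks$t3$value, tracks$t4$value)
  if (quantile_normalize) v <- limma::normalizeQuantiles(v)
  combined <- ((v[, 1L] - v[, 2L]) - (v[, 3L] - v[, 4L])) + (v[, 1L] - v[, 3L])
  data.frame(chrom = ref$chrom, pos = ref$pos, combined = combined,
             stringsAsFactors = FALSE)
}

# trimmed-mean * sqrt(n) window statistic for one chromosome
smooth_chrom <- function(pos, val, bandwidth, trim) {
  n <- length(pos)
  lo <- findInterval(pos - bandwidth - 0.5, pos) + 1L
  hi <- findInterval(pos + bandwidth, pos)
  s <- numeric(n)
  nw <- hi - lo + 1L
  for (i in seq_len(n)) {
    w <- val[lo[i]:hi[i]]
    s[i] <- mean(w, trim = trim) * sqrt(nw[i])
  }
  list(score = s, n_window = nw)
}

#' Windowed smoothing with per-probe p-values
#'
#' A MAT-like windowed statistic: for every probe, the 10%-trimmed mean of
#' the combined signal over all probes within `bandwidth` bp, scaled by the
#' square root of the window's probe count. Per-probe p-values are the
#' upper-tail probability of the score under a null Gaussian calibrated
#' robustly on the genome-wide score distribution (location = median,
#' scale = 1.4826 x median absolute deviation), so that genuine peaks in
#' the upper tail do not inflate the null. Windows holding fewer than
#' `min_probe` probes are assigned p = 1.
#'
#' @param combined output of [normalize_tracks()].
#' @param params a [caller_params()].
#' @param trim fraction trimmed from each tail of the window (default 0.1).
#' @return data.frame with columns `chrom`, `pos`, `combined`, `score`,
#'   `n_window`, `p_value`.
#' @export
smooth_score <- function(combined, params = caller_params(), trim = 0.1) {
  if (nrow(combined) == 0L)
    return(cbind(combined, score = numeric(0), n_window = integer(0),
                 p_value = numeric(0)))
  combined <- combined[order(combined$chrom, combined$pos), , drop = FALSE]
  parts <- split(seq_len(nrow(combined)), combined$chrom)
  score <- numeric(nrow(combined))
  nwin <- integer(nrow(combined))
  for (idx in parts) {
    sc <- smooth_chrom(combined$pos[idx], combined$combined[idx],
                       params$bandwidth, trim)
    score[idx] <- sc$score
    nwin[idx] <- sc$n_window
  }
  med <- median(score)
  scale <- mad(score)   # already includes the 1.4826 consistency factor
  p <- if (scale > 0) {
    pnorm(score, mean = med, sd = scale, lower.tail = FALSE)
  } else {
    ifelse(score > med, 0, ifelse(score < med, 1, 0.5))
  }
  p[nwin < params$min_probe] <- 1
  out <- combined
  out$score <- score
  out$n_window <- nwin
  out$p_value <- p
  rownames(out) <- NULL
  out
}

#' Call peaks from a scored track
#'
#' Probes with `p_value <= p_threshold` are significant; consecutive
#' significant probes separated by at most `max_gap` bp form a run, and runs
#' with at least `min_probe` significant probes become peaks. A peak spans
#' from its first to its last significant probe plus one probe spacing; the
#' summit is the significant probe with the maximal smoothed score
#' (leftmost on ties). Peaks never overlap.
#'
#' @param scored output of [smooth_score()] (columns `chrom`, `pos`,
#'   `score`, `p_value`).
#' @param params a [caller_params()].
#' @param probe_spacing bp added past the last significant probe; if NULL,
#'   the median probe spacing of the track is used.
#' @return GRanges sorted by (chromosome, start) with metadata columns
#'   `summit`, `score`, `p_value`, `n_probes`, named `peak_0001`, ...
#' @export
call_peaks <- function(scored, params = caller_params(), probe_spacing = NULL) {
  need <- c("chrom", "pos", "score", "p_value")
  if (!all(need %in% names(scored)))
    stopf("scored track must have columns %s", paste(need, collapse = ", "))
  scored <- scored[order(scored$chrom, scored$pos), , drop = FALSE]
  if (is.null(probe_spacing)) {
    d <- unlist(tapply(scored$pos, scored$chrom, diff))
    probe_spacing <- if (length(d) > 0L) median(d) else 1L
  }
  res <- list()
  for (chrom in unique(scored$chrom)) {
    t <- scored[scored$chrom == chrom, , drop = FALSE]
    sig <- which(t$p_value <= params$p_threshold)
    if (length(sig) == 0L) next
    pos <- t$pos[sig]
    run <- cumsum(c(1L, as.integer(diff(pos) > params$max_gap)))
    for (r in split(seq_along(sig), run)) {
      if (length(r) < params$min_probe) next
      ii <- sig[r]
      best <- ii[which.max(t$score[ii])]
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = t$pos[ii[1L]],
        end = t$pos[ii[length(ii)]] + probe_spacing - 1L,
        summit = t$pos[best], score = max(t$score[ii]),
        p_value = min(t$p_value[ii]), n_probes = length(ii),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      summit = integer(0), score = numeric(0), p_value = numeric(0),
      n_probes = integer(0))
    return(gr)
  }
  df <- do.call(rbind, res)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    summit = as.integer(df$summit), score = df$score, p_value = df$p_value,
    n_probes = as.integer(df$n_probes))
  names(gr) <- sprintf("peak_%04d", seq_along(gr))
  gr
}
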