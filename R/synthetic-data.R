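#' Configuration for the synthetic study system
#'
#' The generator emulates the input side of a tiling-array ChIP study of a
#' bHLH factor in a fly-sized genome region: an i.i.d. background genome
#' with planted palindromic E-box cores (CATATG / CAGCTG), multi-exon gene
#' models, four probe tracks (experimental ChIP/input and control
#' ChIP/input) on a shared ~35-bp grid with Gaussian log2 noise,
#' phastCons-like per-base conservation, and a Cufflinks-style per-transcript
#' FPKM table for sorted GFP+ vs GFP- cells. Everything planted is recorded
#' in a truth registry ([synthetic_truth()]) so recovery can be scored.
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 1 Mb of genome over two chromosomes, 60 genes, 20 planted peaks of
#' 1 kb at 4-fold ChIP enrichment, 35-bp probe spacing with 0.25 log2-unit
#' noise, 500 bound / 500 unbound E-box sites, and 3-fold planted transcript
#' enrichment (the FPKM/fold filters require >= 1.5).
#'
#' @param seed integer; every generator output is a pure function of it.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param n_genes number of non-overlapping gene models to place.
#' @param n_planted_peaks peaks planted inside first introns of distinct genes.
#' @param peak_width planted peak width (bp).
#' @param enrichment_fold linear ChIP enrichment over planted peaks (>= 1);
#'   the experimental-ChIP track gains `log2(enrichment_fold)`.
#' @param probe_spacing bp between probe starts (shared across tracks).
#' @param noise_sd per-probe Gaussian noise, log2-intensity units.
#' @param baseline log2 baseline intensity of all tracks.
#' @param gc background GC fraction of the genome.
#' @param n_bound_sites,n_unbound_sites planted E-box site counts
#'   (bound sites inside peaks, unbound sites in introns of peak-free genes).
#' @param shape_effect_delta shift (Angstrom) in mean flank minor-groove
#'   width of bound-site windows produced by [gen_site_sets()]; 0 disables
#'   the bias entirely.
#' @param site_flank flank length (bp) each side of the 6-bp core in site
#'   windows.
#' @param site_core core 6-mer of generated site windows.
#' @param frac_enriched_transcripts fraction of transcripts planted as
#'   GFP+-enriched.
#' @param expr_enrichment FPKM multiplier for enriched transcripts (>= 1.5
#'   for the filters to see them).
#' @param ratio_sdlog log-normal sd of the GFP+/GFP- ratio noise.
#' @param fpkm_meanlog,fpkm_sdlog log-normal parameters of baseline FPKM.
#' @param plant_reference plant one non-enriched transcript at exactly
#'   FPKM+ = 0.983129 (the Pick1-style threshold anchor).
#' @param concordant if TRUE, transcripts of peak-hosting genes are planted
#'   enriched (ChIP/expression concordance); if FALSE the enriched set is
#'   drawn at random (null).
#' @param cons_shape1,cons_shape2 Beta parameters of background conservation.
#' @param cons_elevation amount by which conservation around bound sites is
#'   pushed toward 1 (`s + elevation * (1 - s)`).
#' @param cons_flank bp each side of a bound core that get elevated.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             chrom_lengths = c(chr2L = 500000L, chr2R = 500000L),
                             n_genes = 60L,
                             n_planted_peaks = 20L,
                             peak_width = 1000L,
                             enrichment_fold = 4,
                             probe_spacing = 35L,
                             noise_sd = 0.25,
                             baseline = 8,
                             gc = 0.43,
                             n_bound_sites = 500L,
                             n_unbound_sites = 500L,
                             shape_effect_delta = 1.0,
                             site_flank = 10L,
                             site_core = "CATATG",
                             frac_enriched_transcripts = 0.15,
                             expr_enrichment = 3,
                             ratio_sdlog = 0.25,
                             fpkm_meanlog = 1.8,
                             fpkm_sdlog = 1.1,
                             plant_reference = TRUE,
                             concordant = TRUE,
                             cons_shape1 = 1,
                             cons_shape2 = 9,
                             cons_elevation = 0.6,
                             cons_flank = 10L) {
  cfg <- as.list(environment())
  if (is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == ""))
    stopf("chrom_lengths must be a named vector")
  for (f in c("n_genes", "n_planted_peaks", "n_bound_sites", "n_unbound_sites"))
    if (!is_count(cfg[[f]])) stopf("%s must be a non-negative integer", f)
  if (cfg$probe_spacing < 1) stopf("probe_spacing must be >= 1")
  if (cfg$enrichment_fold < 1) stopf("enrichment_fold must be >= 1")
  if (cfg$frac_enriched_transcripts < 0 || cfg$frac_enriched_transcripts > 1)
    stopf("frac_enriched_transcripts must lie in [0, 1]")
  if (cfg$site_flank < 1) stopf("site_flank must be >= 1")
  if (!grepl("^CA[ACGT]{2}TG$", cfg$site_core))
    stopf("site_core must be a CANNTG hexamer")
  class(cfg) <- "synthetic_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

base_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

# Deterministic layout shared by all generators: gene scaffolds, planted
# peaks (in first introns of distinct host genes), bound/unbound core
# positions and the enriched-transcript set.
plan_layout <- function(cfg) {
  withr::with_seed(stage_seed(cfg$seed, "layout"), {
    margin <- 1500L
    exon_rows <- list()
    gene_tbl <- list()
    g <- 0L
    # spread genes over chromosomes proportionally to length
    quota <- floor(cfg$n_genes * cumsum(cfg$chrom_lengths) /
                     sum(cfg$chrom_lengths) + 0.5)
    for (ci in seq_along(cfg$chrom_lengths)) {
      chrom <- names(cfg$chrom_lengths)[ci]
      len <- cfg$chrom_lengths[[chrom]]
      cursor <- margin + 1L
      repeat {
        if (g >= quota[ci] && ci < length(cfg$chrom_lengths)) break
        if (g >= cfg$n_genes) break
        e1 <- sample(200:500, 1L)
        i1 <- sample((cfg$peak_width + 200L):(cfg$peak_width + 700L), 1L)
        e2 <- sample(200:500, 1L)
        extra <- runif(1) < 0.6
        segs_tx <- c(e1, i1, e2)
        if (extra) segs_tx <- c(segs_tx, sample(300:900, 1L), sample(200:500, 1L))
        span <- sum(segs_tx)
        if (cursor + span > len - margin) break
        g <- g + 1L
        gene_id <- sprintf("G%04d", g)
        strand <- sample(c("+", "-"), 1L)
        segs <- if (strand == "-") rev(segs_tx) else segs_tx
        starts <- cursor + cumsum(c(0L, head(segs, -1L)))
        ends <- starts + segs - 1L
        is_exon <- seq_along(segs) %% 2L == 1L
        ex_s <- starts[is_exon]; ex_e <- ends[is_exon]
        n_iso <- sample(1:3, 1L)
        for (k in seq_len(n_iso)) {
          s <- ex_s; e <- ex_e
          trim <- 60L * (k - 1L)
          if (trim > 0L) {
            if (strand == "+") {
              if (e[length(e)] - trim - s[length(s)] >= 100L)
                e[length(e)] <- e[length(e)] - trim
            } else {
              if (e[1L] - (s[1L] + trim) >= 100L) s[1L] <- s[1L] + trim
            }
          }
          exon_rows[[length(exon_rows) + 1L]] <- data.frame(
            chrom = chrom, start = s, end = e, strand = strand,
            gene_id = gene_id,
            transcript_id = sprintf("%s.%d", gene_id, k),
            stringsAsFactors = FALSE)
        }
        # genomic first intron in transcription orientation
        intron_s <- ends[!is_exon] ; intron_ss <- starts[!is_exon]
        fi_idx <- if (strand == "-") length(intron_ss) else 1L
        gene_tbl[[g]] <- data.frame(
          gene_id = gene_id, chrom = chrom, strand = strand,
          start = cursor, end = cursor + span - 1L,
          fi_start = intron_ss[fi_idx], fi_end = intron_s[fi_idx],
          n_iso = n_iso, stringsAsFactors = FALSE)
        cursor <- cursor + span + sample(1000:2500, 1L)
      }
    }
    if (g < cfg$n_genes)
      stopf("cannot place %d genes in the configured chromosomes (placed %d)",
            cfg$n_genes, g)
    genes <- do.call(rbind, gene_tbl)
    exons <- do.call(rbind, exon_rows)

    if (cfg$n_planted_peaks > nrow(genes))
      stopf("n_planted_peaks exceeds the number of genes")
    hosts <- sort(sample(genes$gene_id, cfg$n_planted_peaks))
    hg <- genes[match(hosts, genes$gene_id), ]
    pw <- pmin(cfg$peak_width, hg$fi_end - hg$fi_start + 1L - 100L)
    if (any(pw < 100L))
      stopf("planted peaks do not fit inside first introns; reduce peak_width")
    centers <- floor((hg$fi_start + hg$fi_end) / 2)
    ps <- centers - floor(pw / 2); pe <- ps + pw - 1L
    peaks <- GenomicRanges::GRanges(hg$chrom, IRanges::IRanges(ps, pe))
    names(peaks) <- sprintf("planted_%03d", seq_along(peaks))
    S4Vectors::mcols(peaks)$host_gene <- hg$gene_id

    slot_df <- function(chroms, lo, hi, tag) {
      out <- mapply(function(ch, a, b, id) {
        p <- seq.int(a + 3L, b - 8L, by = 12L)
        if (length(p) == 0L) return(NULL)
        data.frame(chrom = ch, pos = p, region = id, stringsAsFactors = FALSE)
      }, chroms, lo, hi, tag, SIMPLIFY = FALSE)
      do.call(rbind, out)
    }
    bound_slots <- slot_df(hg$chrom, ps, pe, names(peaks))
    if (is.null(bound_slots) || nrow(bound_slots) < cfg$n_bound_sites)
      stopf("not enough room in planted peaks for %d bound sites",
            cfg$n_bound_sites)
    bs <- bound_slots[sort(sample.int(nrow(bound_slots), cfg$n_bound_sites)), ]
    bs$core <- sample(c("CATATG", "CAGCTG"), nrow(bs), replace = TRUE)

    free <- genes[!(genes$gene_id %in% hosts), ]
    unb_slots <- slot_df(free$chrom, free$fi_start, free$fi_end, free$gene_id)
    if (is.null(unb_slots) || nrow(unb_slots) < cfg$n_unbound_sites)
      stopf("not enough intronic room for %d unbound sites", cfg$n_unbound_sites)
    us <- unb_slots[sort(sample.int(nrow(unb_slots), cfg$n_unbound_sites)), ]
    us$core <- sample(c("CATATG", "CAGCTG"), nrow(us), replace = TRUE)

    tx_ids <- unique(exons$transcript_id)
    tx_gene <- exons$gene_id[match(tx_ids, exons$transcript_id)]
    host_tx <- tx_ids[tx_gene %in% hosts]
    n_enr <- ceiling(cfg$frac_enriched_transcripts * length(tx_ids))
    if (cfg$concordant) {
      extra_pool <- setdiff(tx_ids, host_tx)
      n_extra <- max(0L, n_enr - length(host_tx))
      enriched <- c(host_tx, sample(extra_pool, min(n_extra, length(extra_pool))))
    } else {
      enriched <- sample(tx_ids, min(n_enr, length(tx_ids)))
    }
    non_enr <- setdiff(tx_ids, enriched)
    reference <- if (length(non_enr) > 0L) sample(non_enr, 1L) else NA_character_

    list(cfg = cfg, genes = genes, exons = exons, peaks = peaks,
         bound_sites = bs[, c("chrom", "pos", "core", "region")],
         unbound_sites = us[, c("chrom", "pos", "core", "region")],
         transcripts = data.frame(transcript_id = tx_ids, gene_id = tx_gene,
                                  stringsAsFactors = FALSE),
         enriched_transcripts = sort(enriched),
         reference_transcript = reference,
         host_genes = hosts)
  })
}

#' Planted-truth registry for a synthetic configuration
#'
#' Returns every feature the generators plant, so downstream recovery can be
#' scored: planted peak intervals (with host genes), bound and unbound E-box
#' core positions, the enriched transcript set and the reference transcript
#' pinned at the FPKM threshold.
#'
#' @param cfg a [synthetic_config()].
#' @return list of class `planted_truth` with elements `peaks` (GRanges),
#'   `bound_sites`, `unbound_sites` (data.frames with `chrom`, `pos`,
#'   `core`), `enriched_transcripts`, `reference_transcript`, `host_genes`.
#' @export
synthetic_truth <- function(cfg) {
  plan <- plan_layout(cfg)
  structure(plan[c("peaks", "bound_sites", "unbound_sites",
                   "enriched_transcripts", "reference_transcript",
                   "host_genes")],
            class = "planted_truth")
}

#' Generate the synthetic genome
#'
#' I.i.d. bases at the configured GC fraction, with planted CATATG/CAGCTG
#' cores overwritten at every registered bound and unbound site position.
#'
#' @param cfg a [synthetic_config()].
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
gen_genome <- function(cfg) {
  plan <- plan_layout(cfg)
  probs <- base_probs(cfg$gc)
  seqs <- withr::with_seed(stage_seed(cfg$seed, "genome"), {
    lapply(names(cfg$chrom_lengths), function(chrom) {
      v <- sample(BASES, cfg$chrom_lengths[[chrom]], replace = TRUE, prob = probs)
      for (df in list(plan$bound_sites, plan$unbound_sites)) {
        rows <- which(df$chrom == chrom)
        for (i in rows)
          v[df$pos[i]:(df$pos[i] + 5L)] <- strsplit(df$core[i], "")[[1L]]
      }
      paste(v, collapse = "")
    })
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(cfg$chrom_lengths)
  out
}

#' Generate synthetic gene models
#'
#' Non-overlapping multi-exon genes on both strands, each with at least one
#' intron and 1-3 isoforms differing at the TTS-side terminal exon. Planted
#' peaks (see [synthetic_truth()]) sit inside first introns of a subset of
#' these genes.
#'
#' @param cfg a [synthetic_config()].
#' @return A [gene_models()] object.
#' @export
gen_annotation <- function(cfg) {
  gene_models(plan_layout(cfg)$exons)
}

#' Generate the four probe tracks
#'
#' Probes every `probe_spacing` bp on a grid shared by all four samples.
#' Log2 intensities are `baseline + N(0, noise_sd)`; the experimental-ChIP
#' track additionally gains `log2(enrichment_fold)` over planted peak
#' intervals. Control ChIP and both inputs carry no planted signal.
#'
#' @param cfg a [synthetic_config()].
#' @return Named list of four probe-track data.frames (`exp_chip`,
#'   `exp_input`, `ctl_chip`, `ctl_input`), each with columns `chrom`,
#'   `pos` (1-based probe start), `value`.
#' @export
gen_probe_tracks <- function(cfg) {
  plan <- plan_layout(cfg)
  withr::with_seed(stage_seed(cfg$seed, "probes"), {
    per_chrom <- lapply(names(cfg$chrom_lengths), function(chrom) {
      len <- cfg$chrom_lengths[[chrom]]
      pos <- seq.int(1L, len, by = cfg$probe_spacing)
      n <- length(pos)
      vals <- matrix(cfg$baseline + rnorm(4L * n, 0, cfg$noise_sd), n, 4L)
      pk <- plan$peaks[GenomeInfoDb::seqnames(plan$peaks) == chrom]
      if (length(pk) > 0L) {
        inside <- IRanges::overlapsAny(
          IRanges::IRanges(pos, width = 1L), IRanges::ranges(pk))
        vals[inside, 1L] <- vals[inside, 1L] + log2(cfg$enrichment_fold)
      }
      list(pos = pos, chrom = rep(chrom, n), vals = vals)
    })
    chrom <- unlist(lapply(per_chrom, `[[`, "chrom"))
    pos <- unlist(lapply(per_chrom, `[[`, "pos"))
    vals <- do.call(rbind, lapply(per_chrom, `[[`, "vals"))
    mk <- function(j) data.frame(chrom = chrom, pos = pos, value = vals[, j],
                                 stringsAsFactors = FALSE)
    list(exp_chip = mk(1L), exp_input = mk(2L),
         ctl_chip = mk(3L), ctl_input = mk(4L))
  })
}

#' Generate the per-transcript expression table
#'
#' Baseline FPKM is log-normal; the GFP+ value is the GFP- value times
#' log-normal ratio noise, times `expr_enrichment` for planted-enriched
#' transcripts. One designated non-enriched reference transcript is pinned
#' at exactly FPKM+ = 0.983129 (FPKM- = 0.26) to exercise the expression
#' cutoff, unless `plant_reference` is FALSE.
#'
#' @param cfg a [synthetic_config()].
#' @return data.frame with columns `transcript_id`, `gene_id`, `fpkm_plus`,
#'   `fpkm_minus`.
#' @export
gen_expression <- function(cfg) {
  plan <- plan_layout(cfg)
  tx <- plan$transcripts
  n <- nrow(tx)
  withr::with_seed(stage_seed(cfg$seed, "expression"), {
    minus <- rlnorm(n, cfg$fpkm_meanlog, cfg$fpkm_sdlog)
    ratio <- if (cfg$ratio_sdlog > 0) rlnorm(n, 0, cfg$ratio_sdlog) else rep(1, n)
    enr <- tx$transcript_id %in% plan$enriched_transcripts
    plus <- minus * ratio * ifelse(enr, cfg$expr_enrichment, 1)
    out <- data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
                      fpkm_plus = plus, fpkm_minus = minus,
                      stringsAsFactors = FALSE)
    if (isTRUE(cfg$plant_reference) && !is.na(plan$reference_transcript)) {
      i <- match(plan$reference_transcript, out$transcript_id)
      out$fpkm_plus[i] <- 0.983129
      out$fpkm_minus[i] <- 0.26
    }
    out
  })
}

#' Generate the per-base conservation track
#'
#' Background scores are Beta-distributed (low by default); every position
#' within `cons_flank` bp of a planted bound core is pushed toward 1 by
#' `s + cons_elevation * (1 - s)`. Scores always lie in [0, 1].
#'
#' @param cfg a [synthetic_config()].
#' @return Named list (one numeric vector per chromosome, length equal to
#'   the chromosome) of class `conservation_track`.
#' @export
gen_conservation <- function(cfg) {
  plan <- plan_layout(cfg)
  out <- withr::with_seed(stage_seed(cfg$seed, "conservation"), {
    lapply(names(cfg$chrom_lengths), function(chrom) {
      len <- cfg$chrom_lengths[[chrom]]
      s <- rbeta(len, cfg$cons_shape1, cfg$cons_shape2)
      rows <- which(plan$bound_sites$chrom == chrom)
      for (i in rows) {
        p <- plan$bound_sites$pos[i]
        idx <- max(1L, p - cfg$cons_flank):min(len, p + 5L + cfg$cons_flank)
        s[idx] <- s[idx] + cfg$cons_elevation * (1 - s[idx])
      }
      pmin(pmax(s, 0), 1)
    })
  })
  names(out) <- names(cfg$chrom_lengths)
  class(out) <- "conservation_track"
  out
}

# -- aligned site windows -----------------------------------------------------

site_flank_positions <- function(flank) {
  c(seq_len(flank), (flank + 7L):(2L * flank + 6L))
}

# mean minor-groove width over the flank positions of the inner window of
# each full-length site sequence (full = 2 bp context + flank + core + flank
# + 2 bp context)
site_flank_mgw <- function(seqs, tabm, flank) {
  fp <- site_flank_positions(flank)
  acc <- matrix(0, length(seqs), length(fp))
  for (j in seq_along(fp)) {
    i <- fp[j]
    acc[, j] <- tabm[substr(seqs, i, i + 4L), "MGW"]
  }
  rowMeans(acc)
}

#' Generate aligned bound/unbound E-box site windows
#'
#' Produces `n_bound_sites` label-1 and `n_unbound_sites` label-0 sequences
#' of identical width, each carrying the identical central core hexamer and
#' 2 bp of extra context on each side (so that every inner-window position
#' has a defined pentamer shape). Flanks are drawn i.i.d. at the background
#' base composition; when `shape_effect_delta > 0` bound-site flanks are
#' rejection-sampled so their mean flank minor-groove width sits
#' `shape_effect_delta` Angstrom above the background mean. With
#' `shape_effect_delta = 0` no selection is applied and both classes are
#' exchangeable.
#'
#' @param cfg a [synthetic_config()].
#' @param shape_table pentamer shape table (see [synthetic_shape_table()]).
#' @param core core hexamer; defaults to `cfg$site_core`.
#' @return data.frame with columns `sequence`, `label` and attributes
#'   `core`, `flank`, `context` (= 2) and `window_width`
#'   (`6 + 2 * flank`).
#' @export
gen_site_sets <- function(cfg, shape_table, core = cfg$site_core) {
  tabm <- validate_shape_table(shape_table)
  f <- as.integer(cfg$site_flank)
  width <- 6L + 2L * f + 4L
  if (width < 6L + 2L + 4L) stopf("site windows too narrow")
  probs <- base_probs(cfg$gc)
  draw <- function(n) {
    if (n == 0L) return(character(0))
    left <- matrix(sample(BASES, n * (f + 2L), TRUE, prob = probs), n)
    right <- matrix(sample(BASES, n * (f + 2L), TRUE, prob = probs), n)
    paste0(do.call(paste0, as.data.frame(left)), core,
           do.call(paste0, as.data.frame(right)))
  }
  withr::with_seed(stage_seed(cfg$seed, "sites"), {
    unbound <- draw(cfg$n_unbound_sites)
    if (cfg$shape_effect_delta == 0) {
      bound <- draw(cfg$n_bound_sites)
    } else {
      ref <- site_flank_mgw(draw(1000L), tabm, f)
      target <- mean(ref) + cfg$shape_effect_delta
      tol <- max(sd(ref) / 3, 0.02)
      acc <- character(0)
      tries <- 0L
      while (length(acc) < cfg$n_bound_sites && tries < 80L) {
        cand <- draw(4000L)
        m <- site_flank_mgw(cand, tabm, f)
        acc <- c(acc, cand[abs(m - target) <= tol])
        tries <- tries + 1L
        if (tries %% 8L == 0L) tol <- tol * 1.5
      }
      if (length(acc) < cfg$n_bound_sites)
        stopf("shape_effect_delta = %.3g is unreachable for this table",
              cfg$shape_effect_delta)
      bound <- acc[seq_len(cfg$n_bound_sites)]
    }
    out <- data.frame(
      sequence = c(bound, unbound),
      label = rep(c(1L, 0L), c(length(bound), length(unbound))),
      stringsAsFactors = FALSE)
    attr(out, "core") <- core
    attr(out, "flank") <- f
    attr(out, "context") <- 2L
    attr(out, "window_width") <- 6L + 2L * f
    out
  })
}
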