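test_that("generators are pure functions of the seed", {
  cfg <- small_cfg(seed = 4L)
  expect_identical(as.character(gen_genome(cfg)), as.character(gen_genome(cfg)))
  expect_identical(gen_expression(cfg), gen_expression(cfg))
  t1 <- gen_probe_tracks(cfg)
  t2 <- gen_probe_tracks(cfg)
  expect_identical(t1, t2)
  expect_identical(synthetic_truth(cfg), synthetic_truth(cfg))
  # a different seed actually changes the data
  expect_false(identical(as.character(gen_genome(cfg)),
                         as.character(gen_genome(small_cfg(seed = 5L)))))
})

test_that("planted-truth registry is complete and consistent", {
  cfg <- small_cfg(seed = 2L, n_bound_sites = 5L)
  truth <- synthetic_truth(cfg)
  genome <- gen_genome(cfg)
  expect_identical(nrow(truth$bound_sites), 5L)
  for (i in seq_len(nrow(truth$bound_sites))) {
    b <- truth$bound_sites[i, ]
    expect_identical(
      as.character(Biostrings::subseq(genome[[b$chrom]], b$pos, b$pos + 5L)),
      b$core)
  }
  # bound sites sit inside planted peaks
  bs <- GenomicRanges::GRanges(truth$bound_sites$chrom,
                               IRanges::IRanges(truth$bound_sites$pos, width = 6L))
  expect_true(all(IRanges::overlapsAny(bs, truth$peaks, type = "within")))
  # unbound sites sit in introns of peak-free genes
  models <- gen_annotation(cfg)
  introns <- GenomicRanges::reduce(unlist(models$introns), ignore.strand = TRUE)
  us <- GenomicRanges::GRanges(truth$unbound_sites$chrom,
                               IRanges::IRanges(truth$unbound_sites$pos, width = 6L))
  expect_true(all(IRanges::overlapsAny(us, introns, type = "within")))
  expect_false(any(IRanges::overlapsAny(us, truth$peaks)))
})

test_that("degenerate GC fraction fills all non-planted bases with G/C", {
  cfg <- small_cfg(seed = 3L, gc = 1)
  genome <- gen_genome(cfg)
  truth <- synthetic_truth(cfg)
  seq <- strsplit(as.character(genome[["chrA"]]), "")[[1L]]
  planted <- rep(FALSE, length(seq))
  for (df in list(truth$bound_sites, truth$unbound_sites)) {
    rows <- df[df$chrom == "chrA", ]
    for (p in rows$pos) planted[p:(p + 5L)] <- TRUE
  }
  expect_true(all(seq[!planted] %in% c("G", "C")))
})

test_that("synthetic annotation has the requested structure", {
  cfg <- small_cfg(seed = 1L, n_genes = 10L, n_planted_peaks = 3L)
  models <- gen_annotation(cfg)
  expect_length(models$genes, 10L)
  # every isoform has at least one intron, hence a defined first intron
  expect_setequal(names(models$transcripts), names(models$first_intron))
  # minus-strand TSS is the larger genomic coordinate of the span
  neg <- as.character(GenomicRanges::strand(models$transcripts)) == "-"
  expect_true(any(neg))
  expect_identical(GenomicRanges::start(tss(models))[neg],
                   GenomicRanges::end(models$transcripts)[neg])
  # genes do not overlap
  red <- GenomicRanges::reduce(models$genes, ignore.strand = TRUE)
  expect_length(red, length(models$genes))
})

test_that("probe tracks share one grid and carry the planted enrichment", {
  cfg <- small_cfg(seed = 6L, noise_sd = 0, enrichment_fold = 1)
  tr <- gen_probe_tracks(cfg)
  expect_identical(tr$exp_chip, tr$exp_input)
  expect_identical(tr$exp_chip, tr$ctl_chip)
  expect_identical(tr$exp_chip, tr$ctl_input)

  cfg4 <- small_cfg(seed = 6L, noise_sd = 0, enrichment_fold = 4)
  tr4 <- gen_probe_tracks(cfg4)
  expect_identical(tr4$exp_chip$pos, tr4$ctl_input$pos)
  truth <- synthetic_truth(cfg4)
  d <- tr4$exp_chip$value - tr4$exp_input$value
  inside <- IRanges::overlapsAny(
    GenomicRanges::GRanges(tr4$exp_chip$chrom,
                           IRanges::IRanges(tr4$exp_chip$pos, width = 1L)),
    truth$peaks)
  expect_equal(d[inside], rep(2, sum(inside)))
  expect_equal(d[!inside], rep(0, sum(!inside)))
})

test_that("expression table honors enrichment, noise and the planted reference", {
  cfg <- small_cfg(seed = 2L, ratio_sdlog = 0, expr_enrichment = 1,
                   plant_reference = FALSE)
  expr <- gen_expression(cfg)
  expect_equal(expr$fpkm_plus, expr$fpkm_minus)

  cfgr <- small_cfg(seed = 2L)
  exprr <- gen_expression(cfgr)
  truth <- synthetic_truth(cfgr)
  ref <- exprr[exprr$transcript_id == truth$reference_transcript, ]
  expect_identical(ref$fpkm_plus, 0.983129)
  expect_true(ref$fpkm_plus >= 0.983129)
  expect_false(ref$fpkm_plus >= 0.983130)
  expect_identical(gen_expression(cfgr), exprr)
})

test_that("conservation track is bounded, elevated only around bound sites", {
  cfg <- small_cfg(seed = 5L)
  cons <- gen_conservation(cfg)
  expect_true(all(unlist(cons) >= 0 & unlist(cons) <= 1))

  cfg0 <- small_cfg(seed = 5L, cons_elevation = 0)
  cons0 <- gen_conservation(cfg0)
  truth <- synthetic_truth(cfg)
  near <- lapply(names(cons), function(chrom) {
    v <- rep(FALSE, length(cons[[chrom]]))
    rows <- truth$bound_sites[truth$bound_sites$chrom == chrom, ]
    for (p in rows$pos) {
      idx <- max(1L, p - cfg$cons_flank):min(length(v), p + 5L + cfg$cons_flank)
      v[idx] <- TRUE
    }
    v
  })
  names(near) <- names(cons)
  for (chrom in names(cons)) {
    expect_identical(cons[[chrom]][!near[[chrom]]], cons0[[chrom]][!near[[chrom]]])
    expect_true(all(cons[[chrom]][near[[chrom]]] >= cons0[[chrom]][near[[chrom]]]))
  }
  # elevation 1 pushes bound-site bases exactly to 1 whatever the background
  cons1 <- gen_conservation(small_cfg(seed = 5L, cons_elevation = 1))
  for (i in seq_len(nrow(truth$bound_sites))) {
    b <- truth$bound_sites[i, ]
    expect_equal(cons1[[b$chrom]][b$pos:(b$pos + 5L)], rep(1, 6L))
  }
})

test_that("site sets are aligned, labeled and unbiased at delta = 0", {
  tab <- synthetic_shape_table()
  cfg <- small_cfg(seed = 9L, n_bound_sites = 500L, n_unbound_sites = 500L,
                   shape_effect_delta = 0)
  sites <- gen_site_sets(cfg, tab)
  f <- attr(sites, "flank")
  expect_identical(sum(sites$label == 1L), 500L)
  expect_identical(sum(sites$label == 0L), 500L)
  core_seen <- unique(substr(sites$sequence, f + 3L, f + 8L))
  expect_identical(core_seen, attr(sites, "core"))
  expect_identical(unique(nchar(sites$sequence)), 2L * f + 10L)

  # Monte-Carlo: mean flank MGW difference is 0 in expectation; the observed
  # difference stays below 3 analytic standard errors at n = 500 per class
  tm <- dimmtargets:::validate_shape_table(tab)
  mg <- dimmtargets:::site_flank_mgw(sites$sequence, tm, f)
  d <- mean(mg[sites$label == 1L]) - mean(mg[sites$label == 0L])
  se <- sqrt(var(mg[sites$label == 1L]) / 500 + var(mg[sites$label == 0L]) / 500)
  expect_lt(abs(d), 3 * se)

  # delta > 0 shifts the bound-class mean by about delta
  cfg1 <- small_cfg(seed = 9L, n_bound_sites = 200L, n_unbound_sites = 200L,
                    shape_effect_delta = 1)
  s1 <- gen_site_sets(cfg1, tab)
  mg1 <- dimmtargets:::site_flank_mgw(s1$sequence, tm, f)
  d1 <- mean(mg1[s1$label == 1L]) - mean(mg1[s1$label == 0L])
  expect_gt(d1, 0.6)
})

test_that("impossible layouts raise sizing errors", {
  expect_error(synthetic_truth(synthetic_config(
    chrom_lengths = c(c1 = 20000L), n_genes = 50L)), "cannot place")
  expect_error(synthetic_truth(small_cfg(n_bound_sites = 100000L)),
               "bound sites")
})
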