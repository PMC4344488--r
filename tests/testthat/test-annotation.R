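test_that("peak-gene association uses the gap distance with a strict radius", {
  models <- toy_models()
  # gA span is [1001, 3400]; a peak ending 2500 bp before it associates
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1, 4500, 2101), c(100, 4600, 2160)))
  names(peaks) <- c("far", "near", "inside")
  # far: gap 1001 - 100 - 1 = 900 -> associated with gA
  # near: right of gA end 3400, gap 4500 - 3400 - 1 = 1099 -> associated
  # inside: inside gA's second intron -> distance 0
  a <- assign_peaks_to_genes(peaks, models, max_dist = 3000L)
  expect_identical(a$distance[a$peak_id == "inside" & a$gene_id == "gA"], 0L)
  expect_identical(a$distance[a$peak_id == "far" & a$gene_id == "gA"], 900L)
  expect_identical(a$distance[a$peak_id == "near" & a$gene_id == "gA"], 1099L)

  # distance 2500 associates, 3500 does not
  p <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1500))
  g <- gene_models(data.frame(chrom = "chr1", start = c(4001, 5501),
                              end = c(4500, 6000), strand = "+",
                              gene_id = "g1", transcript_id = "g1.1"))
  a1 <- assign_peaks_to_genes(p, g)
  expect_identical(a1$distance, 2500L)
  g2 <- gene_models(data.frame(chrom = "chr1", start = c(5001, 6501),
                               end = c(5500, 7000), strand = "+",
                               gene_id = "g1", transcript_id = "g1.1"))
  expect_identical(nrow(assign_peaks_to_genes(p, g2)), 0L)
})

test_that("association matches a brute-force all-pairs scan", {
  withr::with_seed(11, {
    ps <- sort(sample(1:50000, 20))
    gs <- sort(sample(1:50000, 10))
  })
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ps, ps + 499))
  names(peaks) <- sprintf("p%02d", seq_along(peaks))
  ex <- data.frame(chrom = "chr1", start = gs, end = gs + 1999, strand = "+",
                   gene_id = sprintf("g%02d", seq_along(gs)),
                   transcript_id = sprintf("g%02d.1", seq_along(gs)))
  models <- gene_models(ex)
  a <- assign_peaks_to_genes(peaks, models, max_dist = 3000L)
  got <- paste(a$peak_id, a$gene_id, a$distance)
  want <- character(0)
  for (i in seq_along(ps)) for (j in seq_along(gs)) {
    gap <- max(0L, gs[j] - (ps[i] + 499L) - 1L, ps[i] - (gs[j] + 1999L) - 1L)
    if (gap < 3000L)
      want <- c(want, paste(sprintf("p%02d", i), sprintf("g%02d", j), gap))
  }
  expect_setequal(got, want)
})

test_that("peaks on unknown chromosomes are skipped with a warning", {
  p <- GenomicRanges::GRanges(c("chr1", "chrUn"),
                              IRanges::IRanges(c(1201, 100), c(1300, 200)))
  expect_warning(a <- assign_peaks_to_genes(p, toy_models()), "skipped")
  expect_true(all(a$gene_id %in% c("gA", "gB")))
})

test_that("anchored profiles are flat on uniform signal and strand-mirrored", {
  track <- uniform_combined(from = 1, to = 20000, by = 50, value = 2)
  anchors <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 10000),
                                    strand = "+")
  prof <- anchored_profile(track, anchors, window = 3000, bins = 30)
  expect_equal(prof$mean_signal, rep(2, 30))

  # signal genomically right of a minus-strand anchor lands upstream
  tr <- track
  tr$combined <- ifelse(tr$pos > 10000, 1, 0)
  neg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10000, 10000),
                                strand = "-")
  pn <- anchored_profile(tr, neg, window = 2000, bins = 20)
  up <- pn$bin_mid < 0 & pn$n_obs > 0
  dn <- pn$bin_mid > 0 & pn$n_obs > 0
  expect_true(all(pn$mean_signal[up] == 1))
  expect_true(all(pn$mean_signal[dn] == 0))

  # one anchor, one bin: the bin mean is the window mean
  withr::with_seed(3, tr$combined <- rnorm(nrow(tr)))
  p1 <- anchored_profile(tr, anchors, window = 1000, bins = 1)
  inwin <- tr$pos >= 9000 & tr$pos <= 11000
  expect_equal(p1$mean_signal, mean(tr$combined[inwin]))
})

test_that("profiles are invariant under coordinate reflection with strand flip", {
  withr::with_seed(7, {
    track <- uniform_combined(from = 1, to = 20000, by = 50)
    track$combined <- rnorm(nrow(track))
  })
  anchors <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(5000, 12000), width = 1),
                                    strand = c("+", "-"))
  fwd <- anchored_profile(track, anchors, window = 1500, bins = 10)
  L <- 20001L
  refl <- data.frame(chrom = track$chrom, pos = L - track$pos,
                     combined = track$combined)
  refl <- refl[order(refl$pos), ]
  ranchors <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(L - c(5000, 12000), width = 1),
                                     strand = c("-", "+"))
  rev <- anchored_profile(refl, ranchors, window = 1500, bins = 10)
  expect_equal(rev$mean_signal, fwd$mean_signal)
})

test_that("metagene rescales bodies and respects strand", {
  # single 1000-bp plus-strand gene, signal 1 on its first 100 bp
  ex <- data.frame(chrom = "chr1", start = c(1, 501), end = c(400, 1000),
                   strand = "+", gene_id = "g", transcript_id = "g.1")
  models <- gene_models(ex)
  track <- uniform_combined(from = 5, to = 1000, by = 10, value = 0)
  track$combined[track$pos <= 100] <- 1
  prof <- metagene_profile(track, models, body_bins = 10, flank_bp = 0)
  expect_equal(prof$mean_signal, c(1, rep(0, 9)))

  # same geometry on the minus strand: signal at the genomic end is bin 1
  exn <- ex; exn$strand <- "-"
  trn <- uniform_combined(from = 5, to = 1000, by = 10, value = 0)
  trn$combined[trn$pos > 900] <- 1
  profn <- metagene_profile(trn, gene_models(exn), body_bins = 10, flank_bp = 0)
  expect_equal(profn$mean_signal, c(1, rep(0, 9)))

  # uniform signal gives a flat metagene including flanks
  tru <- uniform_combined(from = 1, to = 30000, by = 25, value = 3)
  exu <- data.frame(chrom = "chr1", start = c(10001, 13001),
                    end = c(11000, 15000), strand = "+",
                    gene_id = "g", transcript_id = "g.1")
  pu <- metagene_profile(tru, gene_models(exu), body_bins = 20,
                         flank_bp = 1000, flank_bins = 5)
  expect_equal(pu$mean_signal, rep(3, 30))
  expect_identical(unique(pu$section[1:5]), "upstream")
})

test_that("intron preference separates first introns from the rest", {
  models <- toy_models()
  # gA first intron [1201, 2000], other intron [2201, 3000]
  track <- uniform_combined(from = 1, to = 8000, by = 25, value = 0)
  fi <- (track$pos >= 1201 & track$pos <= 2000) |
    (track$pos >= 6401 & track$pos <= 7500)
  track$combined[fi] <- 1
  pref <- intron_preference(track, models, tss_flank = 100L)
  first <- pref$mean_signal[pref$category == "first_intron"]
  other <- pref$mean_signal[pref$category == "other_intron"]
  expect_gt(first, 0.9)
  expect_identical(other, 0)
  expect_identical(attr(pref, "first_over_other"), Inf)

  uni <- uniform_combined(from = 1, to = 8000, by = 25, value = 2)
  pu <- intron_preference(uni, models, tss_flank = 100L)
  expect_equal(pu$mean_signal, rep(2, 3))

  # peak mode: coverage fraction per category
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1201, 2000))
  pp <- intron_preference(pk, models, tss_flank = 100L)
  expect_gt(pp$mean_signal[pp$category == "first_intron"],
            pp$mean_signal[pp$category == "other_intron"])
})

test_that("peak-set overlap fraction counts any shared base", {
  a <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 201), c(100, 300)))
  expect_identical(peak_set_overlap(a, a), 1)
  b <- GenomicRanges::GRanges("c", IRanges::IRanges(251, 260))
  expect_identical(peak_set_overlap(a, b), 0.5)
  far <- GenomicRanges::GRanges("c", IRanges::IRanges(1000, 1100))
  expect_identical(peak_set_overlap(a, far), 0)
  expect_true(is.nan(peak_set_overlap(GenomicRanges::GRanges(), a)))
})
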