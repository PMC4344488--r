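dna <- function(...) {
  x <- Biostrings::DNAStringSet(c(...))
  x
}

test_that("E-box scanning reports positions, prefixes and core classes", {
  g <- dna(chrM = "GCATATGC")
  occ <- scan_eboxes(g, cores = "CATATG")
  expect_identical(nrow(occ), 1L)
  expect_identical(occ$start, 2L)
  expect_identical(occ$prefix_base, "G")
  expect_identical(occ$core_class, "TA")

  gcg <- dna(chrM = "CACGTG")
  occ2 <- scan_eboxes(gcg, cores = "CANNTG")
  expect_identical(occ2$core, "CACGTG")
  expect_identical(occ2$core_class, "other")
  expect_true(is.na(occ2$prefix_base))   # chromosome start has no prefix

  tandem <- dna(chrM = "CATATGCATATG")
  occ3 <- scan_eboxes(tandem, cores = "CATATG")
  expect_identical(occ3$start, c(1L, 7L))
})

test_that("scanning agrees with a regex oracle on random sequence", {
  g <- random_genome(41, len = 100000L)
  s <- as.character(g[[1]])
  for (core in c("CATATG", "CAGCTG", "CANNTG")) {
    occ <- scan_eboxes(g, cores = core)
    pat <- sprintf("(?=%s)", gsub("N", "[ACGT]", core))
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    want <- if (m[1] == -1L) integer(0) else as.integer(m)
    expect_identical(occ$start, want)
  }
  # overlapping ambiguity: CANNTG includes every CATATG/CAGCTG hit
  all_occ <- scan_eboxes(g, cores = c("CANNTG"))
  ta <- scan_eboxes(g, cores = "CATATG")
  expect_true(all(ta$start %in% all_occ$start))
})

test_that("palindromic occurrence sets survive reverse complementation", {
  g <- random_genome(42, len = 50000L)
  occ <- scan_eboxes(g, cores = "CATATG")
  rc <- Biostrings::reverseComplement(g[[1]])
  grc <- Biostrings::DNAStringSet(rc); names(grc) <- names(g)
  occ_rc <- scan_eboxes(grc, cores = "CATATG")
  L <- Biostrings::width(g)[1]
  expect_setequal(occ_rc$start, L - occ$start - 4L)
})

test_that("regions restrict and validate the scan", {
  g <- dna(chrM = "AACATATGAA")
  r_in <- GenomicRanges::GRanges("chrM", IRanges::IRanges(1, 10))
  expect_identical(nrow(scan_eboxes(g, r_in, "CATATG")), 1L)
  r_half <- GenomicRanges::GRanges("chrM", IRanges::IRanges(1, 5))
  expect_identical(nrow(scan_eboxes(g, r_half, "CATATG")), 0L)
  r_out <- GenomicRanges::GRanges("chrM", IRanges::IRanges(5, 200))
  expect_error(scan_eboxes(g, r_out, "CATATG"), "bounds")
})

test_that("per-peak E-box tallies match enumeration", {
  g <- dna(c1 = paste0(strrep("A", 100), "CATATG", strrep("A", 94),
                       "CATATGCCCCATATG", strrep("A", 85),
                       strrep("T", 100)))
  peaks <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    c(301, 101, 201), c(400, 200, 300)))   # counts 0, 1, 2 after sorting
  occ <- scan_eboxes(g, cores = "CATATG")
  res <- peak_ebox_counts(occ, peaks)
  expect_setequal(res$per_peak$n_ebox, c(0L, 1L, 2L))
  expect_identical(res$n_peaks_with_ebox, 2L)
  expect_identical(res$n_peaks_multi, 1L)
})

test_that("positional density is center-normalized per peak coverage", {
  peaks <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    c(1001, 3001, 5001), width = c(200, 400, 600)))
  # occurrences exactly at peak centers (core center at midpoint)
  ctr <- GenomicRanges::start(peaks) + GenomicRanges::width(peaks) / 2
  occ <- data.frame(chrom = "c1", start = as.integer(ctr - 2.5),
                    end = as.integer(ctr - 2.5) + 5L, core = "CATATG",
                    core_class = "TA", prefix_base = "A")
  prof <- positional_profile(occ, peaks, bin_width = 50)
  central <- which(prof$offset == -25 | prof$offset == 25)
  expect_identical(sum(prof$count), 3L)
  expect_identical(sum(prof$count[central]), 3L)
  # every peak reaches the central bins; only the widest reaches the edge
  expect_identical(prof$n_peaks[central], c(3, 3))
  expect_identical(prof$n_peaks[prof$offset == -275], 1)

  empty <- positional_profile(occ[0, ], peaks, bin_width = 50)
  expect_true(all(empty$count == 0))
})

test_that("prefix frequencies sum to one in populated bins, NaN elsewhere", {
  peaks <- GenomicRanges::GRanges("c1", IRanges::IRanges(1001, 1400))
  occ <- data.frame(chrom = "c1", start = c(1101L, 1201L, 1301L),
                    end = c(1106L, 1206L, 1306L), core = "CATATG",
                    core_class = "TA", prefix_base = c("C", "C", "C"))
  prof <- prefix_variant_profile(occ, peaks, bin_width = 100)
  pop <- prof$n > 0
  expect_true(all(prof$C[pop] == 1))
  expect_true(all(rowSums(prof[pop, c("A", "C", "G", "T")]) == 1))
  expect_true(all(is.nan(prof$C[!pop])))
})

test_that("GC profile reflects base composition exactly", {
  pk <- GenomicRanges::GRanges("c1", IRanges::IRanges(101, 500))
  ggc <- dna(c1 = strrep("GC", 400))
  expect_true(all(gc_profile(ggc, pk, 50)$gc[gc_profile(ggc, pk, 50)$n_bases > 0] == 1))
  gat <- dna(c1 = strrep("AT", 400))
  pat <- gc_profile(gat, pk, 50)
  expect_true(all(pat$gc[pat$n_bases > 0] == 0))
  gacgt <- dna(c1 = strrep("ACGT", 200))
  pmix <- gc_profile(gacgt, pk, 50)
  full <- pmix$n_bases == 50
  expect_true(all(pmix$gc[full] == 0.5))
})

test_that("random intronic sampling respects constraints and the seed", {
  cfg <- small_cfg(seed = 8L)
  genome <- gen_genome(cfg)
  models <- gen_annotation(cfg)
  truth <- synthetic_truth(cfg)
  s1 <- sample_random_intronic_eboxes(genome, models, "CATATG", n = 10L,
                                      exclude = truth$peaks, seed = 5L)
  s2 <- sample_random_intronic_eboxes(genome, models, "CATATG", n = 10L,
                                      exclude = truth$peaks, seed = 5L)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 10L)
  introns <- GenomicRanges::reduce(unlist(models$introns), ignore.strand = TRUE)
  gr <- GenomicRanges::GRanges(s1$chrom, IRanges::IRanges(s1$start, s1$end))
  expect_true(all(IRanges::overlapsAny(gr, introns, type = "within")))
  expect_false(any(IRanges::overlapsAny(gr, truth$peaks)))
  # asking for more than exist returns everything, flagged
  expect_warning(
    all_of_them <- sample_random_intronic_eboxes(genome, models, "CATATG",
                                                 n = 100000L, seed = 1L),
    "available")
  expect_lt(nrow(all_of_them), 100000L)
})

test_that("conservation profiles average per offset and handle single sites", {
  cons <- structure(list(c1 = rep(1, 1000)), class = "conservation_track")
  occ <- data.frame(chrom = "c1", start = c(101L, 501L), end = c(106L, 506L),
                    core = "CATATG", core_class = "TA", prefix_base = "A")
  prof <- conservation_profile(occ, cons, flank = 10)
  expect_equal(prof$mean_score, rep(1, 26))
  expect_equal(prof$n_sites, rep(2L, 26))

  v <- seq(0, 1, length.out = 1000)
  cons2 <- structure(list(c1 = v), class = "conservation_track")
  one <- conservation_profile(occ[1, ], cons2, flank = 3)
  expect_equal(one$mean_score, v[101 + (-3:8)])

  # offsets running past the chromosome are dropped from their means only
  edge <- data.frame(chrom = "c1", start = 2L, end = 7L, core = "CATATG",
                     core_class = "TA", prefix_base = NA)
  pe <- conservation_profile(edge, cons, flank = 3)
  expect_identical(pe$n_sites[pe$offset < -1], rep(0L, 2))
  expect_equal(pe$mean_score[pe$offset >= -1], rep(1, 10))
})
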