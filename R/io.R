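#' Read a probe track from bedGraph or WIG
#'
#' Accepts bedGraph (0-based half-open) and fixed/variable-step WIG
#' (1-based); each record collapses to the probe's 1-based start position.
#' Unsorted input is sorted with a warning; overlapping probe records are a
#' format error. Malformed bedGraph lines are reported with their line
#' number.
#'
#' @param path file path; format is sniffed from the content (a
#'   `fixedStep`/`variableStep` line means WIG).
#' @return probe-track data.frame (`chrom`, `pos`, `value`).
#' @export
read_probe_track <- function(path) {
  lines <- readLines(path)
  is_wig <- any(grepl("^(fixedStep|variableStep)", lines))
  if (is_wig) {
    gr <- rtracklayer::import(path, format = "wig")
  } else {
    body <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
    nf <- lengths(strsplit(trimws(lines[body]), "[ \t]+"))
    if (any(nf != 4L))
      stopf("malformed bedGraph line %d in %s",
            which(body)[which(nf != 4L)[1L]], path)
    gr <- rtracklayer::import(path, format = "bedGraph")
  }
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   pos = GenomicRanges::start(gr),
                   value = S4Vectors::mcols(gr)$score,
                   stringsAsFactors = FALSE)
  ord <- order(df$chrom, df$pos)
  if (any(ord != seq_len(nrow(df)))) {
    warnf("probe records in %s were not sorted; sorting", path)
    df <- df[ord, , drop = FALSE]
  }
  grs <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$pos, GenomicRanges::end(gr)[ord]))
  if (any(IRanges::countOverlaps(grs, grs, ignore.strand = TRUE) > 1L))
    stopf("overlapping probe records in %s", path)
  rownames(df) <- NULL
  df
}

#' Write a probe track as bedGraph
#'
#' One 1-bp record per probe, 0-based half-open as the format requires,
#' with a track line carrying the seed/provenance label. Values are
#' written with full double precision so a write/read round trip is exact.
#'
#' @param track probe-track data.frame (`chrom`, `pos`, `value`).
#' @param path output path.
#' @param name track label written into the bedGraph track line.
#' @export
write_probe_track <- function(track, path, name = "probe_track") {
  track <- check_probe_track(track)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s" description="%s"',
                     name, provenance_label()), con)
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$pos - 1L,
                     track$pos, formatC(track$value, format = "g", digits = 17)),
             con)
  invisible(path)
}

provenance_label <- function() {
  sprintf("dimmtargets %s", as.character(utils::packageVersion("dimmtargets")))
}

#' Read gene models from GTF
#'
#' GTF exon records (1-based inclusive) become a [gene_models()] object;
#' introns and per-isoform first introns are derived from the exon
#' structure.
#'
#' @param path GTF file path.
#' @return a [gene_models()] object.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stopf("no exon records in %s", path)
  gene_models(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = S4Vectors::mcols(gr)$gene_id,
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    stringsAsFactors = FALSE))
}

#' Write gene models as GTF
#'
#' @param models a [gene_models()] object.
#' @param path output path.
#' @export
write_annotation <- function(models, path) {
  ex <- unlist(models$exons)
  tx_id <- rep(names(models$exons), lengths(models$exons))
  gene_id <- S4Vectors::mcols(models$transcripts)$gene_id[
    match(tx_id, names(models$transcripts))]
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    source = "dimmtargets", type = "exon", gene_id = gene_id,
    transcript_id = tx_id)
  names(ex) <- NULL
  rtracklayer::export(ex, path, format = "gtf")
  invisible(path)
}

#' Read / write a per-base conservation track (bedGraph)
#'
#' The on-disk form is run-length bedGraph (0-based half-open); in memory
#' the track is a named list with one numeric score vector per chromosome,
#' NA where the file has no record. Scores must lie in \[0, 1\].
#'
#' @param path bedGraph path.
#' @param seqlengths named integer vector of chromosome lengths; if NULL,
#'   each vector extends to the last covered base.
#' @return named list of numeric vectors, class `conservation_track`.
#' @export
read_conservation <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  sc <- S4Vectors::mcols(gr)$score
  if (any(sc < 0 | sc > 1)) stopf("conservation scores must lie in [0, 1]")
  chroms <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  out <- lapply(chroms, function(chrom) {
    g <- gr[GenomeInfoDb::seqnames(gr) == chrom]
    len <- if (!is.null(seqlengths)) seqlengths[[chrom]] else
      max(GenomicRanges::end(g))
    v <- rep(NA_real_, len)
    for (i in seq_along(g))
      v[GenomicRanges::start(g)[i]:GenomicRanges::end(g)[i]] <-
        S4Vectors::mcols(g)$score[i]
    v
  })
  names(out) <- chroms
  class(out) <- "conservation_track"
  out
}

#' @rdname read_conservation
#' @param track named list of per-base score vectors.
#' @export
write_conservation <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="conservation" description="%s"',
                     provenance_label()), con)
  for (chrom in names(track)) {
    v <- track[[chrom]]
    r <- rle(ifelse(is.na(v), NA, round(v, 6)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- !is.na(r$values)
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[ok] - 1L, ends[ok],
                       formatC(r$values[ok], format = "g", digits = 8)), con)
  }
  invisible(path)
}

#' Read / write the per-transcript expression table (TSV)
#'
#' Columns: `transcript_id`, `gene_id`, `fpkm_plus`, `fpkm_minus`.
#'
#' @param path TSV path.
#' @return expression data.frame.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "fpkm_plus", "fpkm_minus")
  if (!all(need %in% names(df)))
    stopf("expression table %s lacks columns %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' @rdname read_expression
#' @param records expression data.frame.
#' @export
write_expression <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a pentamer shape table (TSV)
#'
#' Columns: `pentamer`, `MGW`, `ProT`, `Roll`, `HelT`.
#'
#' @param path TSV path.
#' @return shape-table data.frame.
#' @export
read_shape_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_shape_table(df)
  df
}

#' @rdname read_shape_table
#' @param table shape-table data.frame.
#' @export
write_shape_table <- function(table, path) {
  validate_shape_table(table)
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write peaks as BED6
#'
#' 0-based half-open; the BED score column is the smoothed statistic
#' rescaled to 0-1000.
#'
#' @param peaks GRanges from [call_peaks()].
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="peaks" description="%s"',
                     provenance_label()), con)
  if (length(peaks) > 0L) {
    sc <- S4Vectors::mcols(peaks)$score
    bed_score <- if (max(sc) > 0) round(1000 * pmax(sc, 0) / max(sc)) else
      rep(0L, length(sc))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.",
                       as.character(GenomeInfoDb::seqnames(peaks)),
                       GenomicRanges::start(peaks) - 1L,
                       GenomicRanges::end(peaks),
                       names(peaks) %||% sprintf("peak_%04d", seq_along(peaks)),
                       as.integer(bed_score)), con)
  }
  invisible(path)
}

#' Read a BED6 peak file
#'
#' @param path BED path.
#' @return GRanges named by the BED name column.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(S4Vectors::mcols(gr)$name)) names(gr) <- S4Vectors::mcols(gr)$name
  gr
}

#' Write the genome as FASTA
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
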