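#' Gene models with per-isoform intron structure
#'
#' Builds the package's gene-model container from an exon table. Coordinates
#' are 1-based inclusive (GRanges convention). Introns are derived per
#' transcript as the gaps between consecutive exons; the *first intron* is
#' the intron adjacent to the TSS-proximal exon in transcription
#' orientation, i.e. the leftmost genomic intron for `+` transcripts and the
#' rightmost for `-` transcripts.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id` (one row per exon).
#' @return An object of class `gene_models`: a list with elements
#'   `transcripts` (GRanges named by transcript id, with `gene_id`
#'   metadata), `genes` (GRanges named by gene id), `exons`, `introns`
#'   (GRangesList split by transcript) and `first_intron` (GRanges, named by
#'   transcript, transcripts without introns absent).
#' @export
gene_models <- function(exons) {
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  if (!is.data.frame(exons) || !all(need %in% names(exons)))
    stopf("exon table must have columns %s", paste(need, collapse = ", "))
  gr <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start, exons$end),
                               strand = exons$strand)
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id
  S4Vectors::mcols(gr)$transcript_id <- exons$transcript_id
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  exl <- GenomicRanges::split(gr, S4Vectors::mcols(gr)$transcript_id)

  ov <- vapply(seq_along(exl), function(i) {
    r <- IRanges::ranges(exl[[i]])
    length(IRanges::reduce(r, min.gapwidth = 0L)) < length(r)
  }, logical(1))
  if (any(ov))
    stopf("overlapping exons within transcript(s): %s",
          paste(head(names(exl)[ov], 3L), collapse = ", "))

  tx_gene <- vapply(exl, function(g)
    as.character(S4Vectors::mcols(g)$gene_id[1L]), character(1))
  tx <- unlist(range(exl))
  names(tx) <- names(exl)
  S4Vectors::mcols(tx)$gene_id <- tx_gene

  introns <- GenomicRanges::psetdiff(tx[names(exl)], exl)
  first_intron_list <- lapply(names(introns), function(t) {
    ir <- introns[[t]]
    if (length(ir) == 0L) return(NULL)
    if (as.character(GenomicRanges::strand(tx[t])) == "-") {
      ir[which.max(GenomicRanges::start(ir))]
    } else {
      ir[which.min(GenomicRanges::start(ir))]
    }
  })
  keep <- !vapply(first_intron_list, is.null, logical(1))
  first_intron <- if (any(keep)) {
    fi <- unlist(GenomicRanges::GRangesList(first_intron_list[keep]))
    names(fi) <- names(introns)[keep]
    fi
  } else GenomicRanges::GRanges()

  gene_split <- split(seq_along(tx), tx_gene)
  genes <- unlist(range(GenomicRanges::split(tx, tx_gene)))
  # gene span ignores strand conflicts only if isoforms agree; they do here
  structure(list(transcripts = tx, genes = genes, exons = exl,
                 introns = introns, first_intron = first_intron),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts on %d chromosome(s)\n",
              length(x$genes), length(x$transcripts),
              length(unique(as.character(GenomeInfoDb::seqnames(x$genes))))))
  invisible(x)
}

#' Transcription start and termination sites
#'
#' Strand-aware single-base anchors for every transcript: for a `-` strand
#' transcript the TSS is the larger genomic coordinate of its span.
#'
#' @param models a [gene_models()] object.
#' @return GRanges of width 1, named by transcript id.
#' @export
tss <- function(models) GenomicRanges::resize(models$transcripts, 1L, fix = "start")

#' @rdname tss
#' @export
tts <- function(models) GenomicRanges::resize(models$transcripts, 1L, fix = "end")
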