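#' Run the whole target-discovery pipeline on a synthetic dataset
#'
#' Generates the full synthetic study system from `cfg`, writes its inputs,
#' and runs every analysis stage in order: four-track normalization,
#' windowed smoothing, peak calling, peak-to-gene annotation, E-box
#' scanning with positional/prefix/GC/conservation profiles, DNA
#' sequence+shape classification of bound versus random intronic E-boxes,
#' and ChIP x expression integration with the cumulative hypergeometric
#' test. All declared artifacts are written under `out_dir` and a JSON
#' summary records every parameter, the seed and the headline numbers, so
#' a rerun with the same configuration is byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param cfg a [synthetic_config()].
#' @param caller a [caller_params()].
#' @param integration an [integration_params()].
#' @param shape_table pentamer shape table; default [synthetic_shape_table()].
#' @param n_background random intronic E-boxes sampled as the unbound set.
#' @param lambda ridge penalty for the classifier stage (fixed by default
#'   so the emitted summary is reproducible at a glance).
#' @param write_inputs also write the generated FASTA/GTF/bedGraph/TSV
#'   inputs under `out_dir/inputs` (default TRUE).
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(out_dir, cfg = synthetic_config(),
                         caller = caller_params(),
                         integration = integration_params(),
                         shape_table = synthetic_shape_table(),
                         n_background = 800L, lambda = 1,
                         write_inputs = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  genome <- stage("simulate", gen_genome(cfg))
  models <- stage("simulate", gen_annotation(cfg))
  tracks <- stage("simulate", gen_probe_tracks(cfg))
  cons <- stage("simulate", gen_conservation(cfg))
  expr_tab <- stage("simulate", gen_expression(cfg))

  if (write_inputs) {
    ind <- file.path(out_dir, "inputs")
    dir.create(ind, showWarnings = FALSE)
    write_genome(genome, file.path(ind, "genome.fa"))
    write_annotation(models, file.path(ind, "annotation.gtf"))
    for (nm in names(tracks))
      write_probe_track(tracks[[nm]], file.path(ind, paste0(nm, ".bedGraph")), nm)
    write_conservation(cons, file.path(ind, "conservation.bedGraph"))
    write_expression(expr_tab, file.path(ind, "expression.tsv"))
    write_shape_table(shape_table, file.path(ind, "shape_table.tsv"))
  }

  combined <- stage("normalize", normalize_tracks(
    tracks$exp_chip, tracks$exp_input, tracks$ctl_chip, tracks$ctl_input))
  scored <- stage("smooth", smooth_score(combined, caller))
  peaks <- stage("callpeaks", call_peaks(scored, caller,
                                         probe_spacing = cfg$probe_spacing))
  write_peaks_bed(peaks, file.path(out_dir, "peaks.bed"))

  assoc <- stage("annotate", assign_peaks_to_genes(peaks, models,
                                                   integration$max_dist))
  pref <- stage("annotate", intron_preference(combined, models))

  occ <- stage("motifs", scan_eboxes(genome))
  in_peaks <- occ[!is.na(occurrence_offsets(occ, peaks)$peak_id), , drop = FALSE]
  counts <- stage("motifs", peak_ebox_counts(occ, peaks))
  posprof <- stage("motifs", positional_profile(occ, peaks))
  background <- stage("motifs", sample_random_intronic_eboxes(
    genome, models, core = cfg$site_core, n = n_background, exclude = peaks,
    seed = cfg$seed))
  bound_occ <- in_peaks[in_peaks$core == cfg$site_core, , drop = FALSE]
  consprof_bound <- stage("motifs", conservation_profile(bound_occ, cons))
  consprof_bg <- stage("motifs", conservation_profile(background, cons))
  write.table(occ, file.path(out_dir, "eboxes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(posprof, file.path(out_dir, "positional_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(set = rep(c("bound", "background"),
                              c(nrow(consprof_bound), nrow(consprof_bg))),
                    rbind(consprof_bound, consprof_bg)),
              file.path(out_dir, "conservation_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sites <- stage("shape", extract_site_windows(genome, bound_occ, background,
                                               flank = cfg$site_flank))
  aucs <- stage("shape", compare_models(sites, shape_table, lambda = lambda,
                                        seed = cfg$seed))

  passing <- stage("integrate", filter_expressed(expr_tab, integration))
  chip_tx <- stage("integrate", chip_transcript_set(assoc, models))
  ov <- stage("integrate", intersect_and_collapse(passing, chip_tx, expr_tab))
  N <- nrow(expr_tab); K <- length(passing)
  n_s <- length(chip_tx); k_s <- length(ov$transcripts)
  pval <- stage("integrate", hypergeom_tail(N, K, n_s, k_s))
  writeLines(ov$transcripts, file.path(out_dir, "target_transcripts.tsv"))
  writeLines(ov$genes, file.path(out_dir, "target_genes.tsv"))

  summary <- list(
    seed = cfg$seed,
    params = list(caller = unclass(caller), integration = unclass(integration),
                  synthetic = unclass(cfg), lambda = lambda,
                  n_background = n_background),
    n_peaks = length(peaks),
    n_associated_genes = length(unique(assoc$gene_id)),
    ebox = list(n_occurrences = nrow(occ),
                n_in_peaks = nrow(in_peaks),
                n_peaks_with_ebox = counts$n_peaks_with_ebox,
                n_peaks_multi = counts$n_peaks_multi),
    intron_preference = setNames(as.list(pref$mean_signal), pref$category),
    classifier_auc = setNames(as.list(aucs$auc), aucs$feature_set),
    integration = list(N = N, K = K, n = n_s, k = k_s,
                       n_target_genes = length(ov$genes),
                       p_value = pval)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
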