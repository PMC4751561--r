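#' Run the full uORF analysis pipeline
#'
#' Sequences the stages over either real inputs (genome FASTA + GFF3, plus
#' an optional ortholog proteome FASTA) or a synthetic specification:
#' transcript assembly, uORF/dORF scanning and inventory, randomized
#' controls with Poisson count comparisons, Kozak matrix and score
#' populations, mixture projection of class-1 scores onto the reference and
#' random bases, the extension-conservation test, and the Bayesian
#' translation-probability table with ROC. Every table is written as TSV
#' (fits and models as JSON) under \code{outdir}, and a
#' \code{run_meta.json} records the seed and configuration. Without a
#' proteome, the conservation and Bayes stages are skipped with a notice
#' (there is then no positive training set).
#'
#' All per-stage seeds are derived from \code{seed} by fixed offsets, so a
#' given configuration and seed reproduce identical outputs.
#'
#' @param outdir Output directory (created).
#' @param seed Master seed.
#' @param fasta,gff3 Paths to real inputs (mutually exclusive with
#'   \code{spec}).
#' @param proteome Optional ortholog proteome FASTA path (real mode), or
#'   \code{TRUE} (synthetic mode) to generate one from ground truth.
#' @param spec A \code{\link{synthetic_spec}} (synthetic mode).
#' @param n_random Size of the random-context score control
#'   (default 20000).
#' @param quantile High-BLASTP quantile (default 0.25).
#' @return List with the principal stage results (invisible file side
#'   effects): \code{inventory}, \code{kozak}, \code{mixture},
#'   \code{extension} (or NULL), \code{bayes} (or NULL), \code{roc},
#'   \code{prob_table}, \code{dorfs}, \code{outdir}.
#' @export
run_all <- function(outdir, seed, fasta = NULL, gff3 = NULL,
                    proteome = NULL, spec = NULL, n_random = 20000L,
                    quantile = 0.25) {
  real_mode <- !is.null(fasta) || !is.null(gff3)
  if (real_mode && !is.null(spec)) {
    stop("give either real inputs (fasta + gff3) or a synthetic spec")
  }
  if (real_mode && (is.null(fasta) || is.null(gff3))) {
    stop("real mode needs both fasta and gff3")
  }
  if (!real_mode && is.null(spec)) stop("no inputs configured")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  orth <- NULL
  if (real_mode) {
    assembly <- load_assembly(fasta)
    models <- assemble_transcripts(assembly, gff3)
    if (!is.null(proteome) && !isFALSE(proteome)) {
      orth <- Biostrings::readAAStringSet(proteome)
    }
  } else {
    gen <- generate_genome(spec, seed, dir = file.path(outdir, "synthetic"))
    assembly <- gen$genome
    models <- assemble_transcripts(assembly,
                                   file.path(outdir, "synthetic",
                                             "annotation.gff3"))
    if (isTRUE(proteome)) {
      orth <- generate_ortholog_proteome(gen, seed = seed + 7L)
      Biostrings::writeXStringSet(orth, file.path(outdir, "synthetic",
                                                  "proteome.fasta"))
    }
  }

  message("stage orf_scan: ", nrow(models), " transcripts")
  inv <- uorf_inventory(models)
  write_orf_tsv(inv$records, file.path(outdir, "uorf_records.tsv"))
  utils::write.table(inv$partition, file.path(outdir, "uorf_partition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  utr5 <- models$utr5[nchar(models$utr5) > 0L]
  cds <- models$cds
  freq_tab <- rbind(CDS = atg_frequencies(cds, "start")[1:2],
                    UTR5 = atg_frequencies(utr5, "end")[1:2])
  utils::write.table(data.frame(set = rownames(freq_tab), freq_tab),
                     file.path(outdir, "atg_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("stage seq_controls")
  scr <- scramble_each(utr5, seed + 11L)
  # scrambled-control inventory on the same transcript frames
  scr_models <- models[nchar(models$utr5) > 0L, , drop = FALSE]
  scr_models$utr5 <- scr$sequences
  inv_scr <- uorf_inventory(scr_models)
  count_cmp <- do.call(rbind, lapply(1:3, function(cl) {
    a <- inv$class_sums[[paste0("class", cl)]]
    b <- inv_scr$class_sums[[paste0("class", cl)]]
    tt <- poisson_count_test(a, b)
    data.frame(uorf_class = cl, genome = a, scramble = b,
               z = tt$z, p = tt$p, stars = tt$stars)
  }))
  utils::write.table(count_cmp, file.path(outdir, "control_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  message("stage kozak")
  refc <- reference_contexts(models)
  km <- build_kozak_matrix(refc$contexts)
  write_kozak_tsv(km, file.path(outdir, "kozak_matrix.tsv"))
  ref_scores <- kozak_score(km, refc$contexts)
  rnd <- mono_random(nucleotide_freqs(utr5), rep(19L, n_random), seed + 13L)
  keep <- substr(rnd$sequences, 11L, 13L) == "ATG"
  # force the anchor: random contexts get ATG written at the anchor
  rnd_ctx <- paste0(substr(rnd$sequences, 1L, 10L), "ATG",
                    substr(rnd$sequences, 14L, 19L))
  rnd_scores <- kozak_score(km, rnd_ctx)

  full <- paste0(models$utr5, models$cds, models$utr3)
  names(full) <- models$transcript_id
  class_scores <- lapply(1:3, function(cl) {
    recs <- inv$records[inv$records$uorf_class == cl, , drop = FALSE]
    score_population(km, models, recs[, c("transcript_id", "atg_pos")],
                     paste0("class", cl))
  })

  message("stage distribution_fit")
  edges <- shared_edges(ref_scores, rnd_scores,
                        class_scores[[1L]]$scores$score, n_bins = 40L)
  # identical kernel smoothing of bases and target: linear, so true mixture
  # weights are preserved, while sampling noise in the empirical reference
  # basis (which attenuates its fitted weight) is suppressed
  mix <- project_mixture(
    smooth_density(hist1d(ref_scores, edges)$density),
    smooth_density(hist1d(rnd_scores, edges)$density),
    smooth_density(hist1d(class_scores[[1L]]$scores$score, edges)$density))
  jsonlite::write_json(
    list(c_reference = mix$weights[["c1"]], c_random = mix$weights[["c2"]],
         pve = mix$pve, n_bins = mix$n_bins),
    file.path(outdir, "class1_score_mixture.json"),
    digits = NA, auto_unbox = TRUE)

  ext <- NULL; bayes <- NULL; roc <- NULL; prob_tab <- NULL
  if (!is.null(orth)) {
    message("stage conservation: ", length(orth), " subjects")
    ext <- extension_test(models, inv, orth, seed = seed + 17L,
                          quantile = quantile)
    utils::write.table(ext$scores, file.path(outdir, "extension_test.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    message("stage translation_bayes")
    c1s <- class_scores[[1L]]$scores
    c1r <- inv$records[inv$records$uorf_class == 1L, , drop = FALSE]
    c1 <- merge(merge(c1s, c1r[, c("transcript_id", "length_codons")],
                      by = "transcript_id"),
                ext$scores[, c("transcript_id", "high_blastp",
                               "above_abs_cutoff")],
                by = "transcript_id")
    c2s <- class_scores[[2L]]$scores
    c2r <- inv$records[inv$records$uorf_class == 2L, , drop = FALSE]
    c2 <- merge(c2s, c2r[, c("transcript_id", "length_codons")],
                by = "transcript_id")
    # positive training set: uORFs whose extension shows sequence-specific
    # conservation by the absolute bit-score rule; unlike the top-quantile
    # rule this tracks the conserved subset whatever its true fraction
    train_pos <- c1$above_abs_cutoff
    pos <- data.frame(K = c1$score[train_pos],
                      L = pmax(c1$length_codons[train_pos], 1L))
    neg <- data.frame(K = c2$score, L = pmax(c2$length_codons, 1L))
    bayes <- fit_surfaces(pos, neg)
    write_bayes_json(bayes, file.path(outdir, "bayes_model.json"))
    roc <- model_roc(bayes, pos, neg)
    utils::write.table(roc$points, file.path(outdir, "roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prob_tab <- uorf_probability_table(
      inv$records, c1s, bayes,
      ext$scores[, c("transcript_id", "improvement", "high_blastp")])
    utils::write.table(prob_tab, file.path(outdir, "uorf_probabilities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    message("no proteome: conservation and Bayes stages skipped")
  }

  message("stage dorf_scan")
  dorfs <- do.call(rbind, mapply(scan_dorfs, models$utr3,
                                 models$transcript_id, SIMPLIFY = FALSE))
  rownames(dorfs) <- NULL
  write_orf_tsv(dorfs, file.path(outdir, "dorfs.tsv"))

  meta <- list(seed = seed, n_transcripts = nrow(models),
               mode = if (real_mode) "real" else "synthetic",
               n_random = n_random, quantile = quantile,
               kozak_window = km$window,
               kozak_excluded = refc$n_excluded + km$n_train * 0L)
  jsonlite::write_json(meta, file.path(outdir, "run_meta.json"),
                       digits = NA, auto_unbox = TRUE)

  invisible(list(models = models, inventory = inv, kozak = km,
                 ref_scores = ref_scores, rnd_scores = rnd_scores,
                 class_scores = class_scores, mixture = mix,
                 control_counts = count_cmp, extension = ext,
                 bayes = bayes, roc = roc, prob_table = prob_tab,
                 dorfs = dorfs, outdir = outdir))
}
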