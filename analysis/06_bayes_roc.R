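#!/usr/bin/env Rscript
# Bayesian translation-probability classifier: density surfaces over
# (exponentiated Kozak score, log length) trained on the conserved class-1
# subset (positive) and class-2 uORFs (negative); per-uORF posterior table
# and ROC. Requires 01_simulate.R and 05_conservation.R.
# Outputs under results/analysis/.

suppressPackageStartupMessages(library(uorfscan))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

dir <- "results/data/implanted"
asm <- load_assembly(file.path(dir, "genome.fasta"))
models <- suppressWarnings(
  assemble_transcripts(asm, file.path(dir, "annotation.gff3")))
inv <- uorf_inventory(models)
truth <- read.delim(file.path(dir, "truth.tsv"))
ext <- read.delim(file.path(out, "extension_test.tsv"))

km <- build_kozak_matrix(reference_contexts(models)$contexts)
recs <- inv$records
sc1 <- score_population(km, models,
                        recs[recs$uorf_class == 1L,
                             c("transcript_id", "atg_pos")], "class1")$scores
sc2 <- score_population(km, models,
                        recs[recs$uorf_class == 2L,
                             c("transcript_id", "atg_pos")], "class2")$scores
c1 <- merge(merge(sc1, recs[recs$uorf_class == 1L,
                            c("transcript_id", "length_codons")]),
            ext[, c("transcript_id", "above_abs_cutoff")])
c2 <- merge(sc2, recs[recs$uorf_class == 2L,
                      c("transcript_id", "length_codons")])

pos <- data.frame(K = c1$score[c1$above_abs_cutoff],
                  L = pmax(c1$length_codons[c1$above_abs_cutoff], 1L))
neg <- data.frame(K = c2$score, L = pmax(c2$length_codons, 1L))
model <- fit_surfaces(pos, neg)
write_bayes_json(model, file.path(out, "bayes_model.json"))

roc <- model_roc(model, pos, neg)
print(roc)
write.table(roc$points, file.path(out, "roc.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tab <- uorf_probability_table(
  inv$records, sc1, model,
  transform(ext, high_blastp = high_blastp)[, c("transcript_id",
                                                "improvement",
                                                "high_blastp")])
write.table(tab, file.path(out, "uorf_probabilities.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

tr <- merge(tab, truth, by = "transcript_id")
message(sprintf("mean posterior over all class-1 uORFs: %.3f (truth f = %.2f)",
                mean(tr$p_translated), mean(tr$translated)))
message(sprintf("mean posterior | translated %.3f; | untranslated %.3f",
                mean(tr$p_translated[tr$translated]),
                mean(tr$p_translated[!tr$translated])))
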