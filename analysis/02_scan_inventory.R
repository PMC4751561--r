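#!/usr/bin/env Rscript
# Re-assemble transcript models from the simulated FASTA + GFF3 and build
# the uORF inventory: per-class transcript sums, the presence-combination
# partition, and ATG frequency tables for CDS and 5'UTR sequence.
# Requires 01_simulate.R. Outputs under results/analysis/.

suppressPackageStartupMessages(library(uorfscan))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (name in c("neutral", "implanted")) {
  dir <- file.path("results/data", name)
  asm <- load_assembly(file.path(dir, "genome.fasta"))
  models <- suppressWarnings(
    assemble_transcripts(asm, file.path(dir, "annotation.gff3")))
  inv <- uorf_inventory(models)
  print(inv)

  write_orf_tsv(inv$records,
                file.path(out, paste0(name, "_uorf_records.tsv")))
  write.table(inv$partition,
              file.path(out, paste0(name, "_partition.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  utr5 <- models$utr5[nchar(models$utr5) > 0L]
  freq <- rbind(CDS = atg_frequencies(models$cds, "start")[1:2],
                UTR5 = atg_frequencies(utr5, "end")[1:2])
  write.table(data.frame(set = rownames(freq), round(freq, 4)),
              file.path(out, paste0(name, "_atg_frequencies.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: ATG freq in CDS %.3f/%.3f (in/out of frame), 5'UTR %.3f/%.3f",
    name, freq["CDS", 1], freq["CDS", 2], freq["UTR5", 1], freq["UTR5", 2]))

  # candidate-level frame symmetry: two wrong frames vs one right frame
  n1 <- inv$candidate_counts[["class1"]]
  n2 <- inv$candidate_counts[["class2"]]
  message(sprintf("%s: class-2:class-1 candidate ratio %.2f (records %.2f)",
                  name, n2 / n1,
                  inv$class_sums[["class2"]] / inv$class_sums[["class1"]]))
}
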