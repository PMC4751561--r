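# Independent oracles and tiny fixture builders used across the suite.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# Brute-force uORF classifier: enumerates every (start, frame) pair naively
# by cutting the UTR into explicit codon lists, with no shared code with
# scan_uorfs().
oracle_scan_uorfs <- function(utr5) {
  L <- nchar(utr5)
  out <- data.frame(uorf_class = integer(), atg_pos = integer(),
                    length_codons = integer())
  if (L < 3L) return(out)
  for (a in 0:(L - 3L)) {
    if (substr(utr5, a + 1L, a + 3L) != "ATG") next
    # explicit codon walk from this ATG
    codon_starts <- seq(a, L - 3L, by = 3L)
    codons <- substring(utr5, codon_starts + 1L, codon_starts + 3L)
    stop_idx <- which(codons %in% ORACLE_STOPS)
    stop_idx <- stop_idx[stop_idx > 1L]  # ATG itself is not a stop
    if (length(stop_idx) > 0L) {
      out <- rbind(out, data.frame(uorf_class = 3L, atg_pos = a,
                                   length_codons = stop_idx[1L] - 1L))
    } else {
      fo <- (L - a) %% 3L
      out <- rbind(out, data.frame(uorf_class = if (fo == 0L) 1L else 2L,
                                   atg_pos = a,
                                   length_codons = (L - a) %/% 3L))
    }
  }
  # cap classes 1 and 2 at the 5'-most record
  keep <- rep(TRUE, nrow(out))
  for (cl in c(1L, 2L)) {
    idx <- which(out$uorf_class == cl)
    if (length(idx) > 1L) keep[idx[-1L]] <- FALSE
  }
  out[keep, , drop = FALSE]
}

# Gotoh affine-gap local alignment, raw score only. Penalty convention:
# a gap of length g costs gap_open + g * gap_extend.
oracle_sw_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  x <- strsplit(a, "", fixed = TRUE)[[1L]]
  y <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(x); m <- length(y)
  open <- gap_open + gap_extend
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in x (horizontal)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in y (vertical)
  best <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      E[i, j] <- max(E[i, j - 1L] - gap_extend, H[i, j - 1L] - open)
      F[i, j] <- max(F[i - 1L, j] - gap_extend, H[i - 1L, j] - open)
      d <- H[i - 1L, j - 1L] + submat[x[i - 1L], y[j - 1L]]
      H[i, j] <- max(0, d, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

random_dna <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Write a toy genome + annotation; `loci` is a list of lists with fields
# contig, strand, exons (matrix of 1-based start/end), cds (same shape),
# id. Sequences must already be in the contigs.
write_toy_gff3 <- function(loci, path) {
  lines <- "##gff-version 3"
  for (l in loci) {
    g_start <- min(l$exons[, 1L]); g_end <- max(l$exons[, 2L])
    lines <- c(lines,
      sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s_g",
              l$contig, g_start, g_end, l$strand, l$id),
      sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s_g",
              l$contig, g_start, g_end, l$strand, l$id, l$id),
      sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              l$contig, l$exons[, 1L], l$exons[, 2L], l$strand, l$id,
              seq_len(nrow(l$exons)), l$id),
      sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
              l$contig, l$cds[, 1L], l$cds[, 2L], l$strand, l$id,
              seq_len(nrow(l$cds)), l$id))
  }
  writeLines(lines, path)
  path
}

write_toy_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  path
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Small synthetic genome scanned directly from the generator's region table.
gen_models <- function(gen) {
  m <- gen$transcripts
  class(m) <- c("transcript_models", "data.frame")
  m
}
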