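test_that("load_assembly normalizes case, keeps lengths, rejects duplicates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1 description", "acgtACGTnn", ">c2", "GGGCCC"), fa)
  asm <- load_assembly(fa)
  expect_named(asm, c("c1", "c2"))
  expect_equal(unname(Biostrings::width(asm)), c(10L, 6L))
  expect_equal(as.character(asm[["c1"]]), "ACGTACGTNN")

  writeLines(c(">dup", "ACGT", ">dup", "TTTT"), fa)
  expect_error(load_assembly(fa), "duplicate contig")
  expect_error(load_assembly(tempfile()), "not found")
})

test_that("single-exon transcript with CDS covering the whole exon has empty UTRs", {
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  cds <- "ATGAAACCCGGGTAA"
  write_toy_fasta(c(c1 = paste0("GGG", cds, "TTT")), fa)
  write_toy_gff3(list(list(contig = "c1", strand = "+", id = "t1",
                           exons = cbind(4L, 18L), cds = cbind(4L, 18L))),
                 gff)
  models <- assemble_transcripts(load_assembly(fa), gff)
  expect_equal(nrow(models), 1L)
  expect_equal(models$utr5, "")
  expect_equal(models$cds, cds)
  expect_equal(models$utr3, "")
})

test_that("minus-strand two-exon 5'UTR splices across the junction correctly", {
  # 60-nt toy locus; transcript on the minus strand. Expected regions are
  # hand-assembled here by independent substring + reverse-complement.
  set.seed(404)
  contig <- random_dna(60)
  # minus-strand transcript: genomic exons [5,30] and [41,56];
  # mRNA order: revcomp([41,56]) then revcomp([5,30]).
  ex1 <- substr(contig, 5, 30); ex2 <- substr(contig, 41, 56)
  mrna <- paste0(revcomp(ex2), revcomp(ex1))
  # CDS on genome [5,21] -> mRNA-sense CDS is revcomp of that piece,
  # the 5'UTR spans all of exon2 plus part of exon1 (splice junction).
  exp_cds <- revcomp(substr(contig, 5, 21))
  exp_utr5 <- paste0(revcomp(ex2), revcomp(substr(contig, 22, 30)))
  expect_equal(paste0(exp_utr5, exp_cds), mrna)  # no 3'UTR in this locus

  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_toy_fasta(c(chrM = contig), fa)
  write_toy_gff3(list(list(contig = "chrM", strand = "-", id = "tm",
                           exons = rbind(c(5L, 30L), c(41L, 56L)),
                           cds = cbind(5L, 21L))), gff)
  models <- assemble_transcripts(load_assembly(fa), gff)
  expect_equal(models$strand, "-")
  expect_equal(models$utr5, exp_utr5)
  expect_equal(models$cds, exp_cds)
  expect_equal(models$utr3, "")
})

test_that("region lengths sum to exon lengths and mRNAs without CDS are skipped", {
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  set.seed(7)
  contig <- random_dna(300)
  write_toy_fasta(c(c1 = contig), fa)
  loci <- list(
    list(contig = "c1", strand = "+", id = "ta",
         exons = rbind(c(11L, 100L), c(121L, 200L)),
         cds = rbind(c(41L, 100L), c(121L, 160L))),
    list(contig = "c1", strand = "-", id = "tb",
         exons = cbind(221L, 280L), cds = cbind(231L, 269L)))
  write_toy_gff3(loci, gff)
  # add an mRNA with no CDS
  cat("c1\ttest\tmRNA\t285\t295\t.\t+\t.\tID=tc;Parent=tc_g\n",
      file = gff, append = TRUE)
  expect_warning(models <- assemble_transcripts(load_assembly(fa), gff),
                 "no CDS")
  expect_equal(sort(models$transcript_id), c("ta", "tb"))
  total_regions <- nchar(models$utr5) + nchar(models$cds) + nchar(models$utr3)
  expect_equal(total_regions[models$transcript_id == "ta"], 90L + 80L)
  expect_equal(total_regions[models$transcript_id == "tb"], 60L)
})

test_that("annotation against a missing contig aborts", {
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_toy_fasta(c(c1 = "ACGTACGTACGT"), fa)
  write_toy_gff3(list(list(contig = "cX", strand = "+", id = "t1",
                           exons = cbind(1L, 12L), cds = cbind(1L, 12L))),
                 gff)
  expect_error(assemble_transcripts(load_assembly(fa), gff),
               "absent from assembly")
})

test_that("translate_cds follows the standard code, stops at stops, handles N", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(translate_cds("ATGGCT"), "MA")
  expect_equal(translate_cds("ATGAANGGG"), "MXG")
  expect_equal(translate_cds("ATGGCTAA"), "MA")  # trailing partial codon
  # 300-nt random CDS against Biostrings as the codon-table oracle
  set.seed(11)
  cds <- random_dna(300)
  exp <- sub("\\*.*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(cds))))
  expect_equal(translate_cds(cds), exp)
})

test_that("region FASTA round trip regenerates identical spliced regions", {
  spec <- synthetic_spec(n_transcripts = 30L, cds_meanlog = log(60),
                         fraction_class1_implanted = 0.5)
  gen <- generate_genome(spec, seed = 99, dir = tempfile())
  models <- suppressWarnings(
    assemble_transcripts(load_assembly(gen$paths$fasta), gen$paths$gff3))
  m <- models[match(gen$transcripts$transcript_id, models$transcript_id), ]
  expect_equal(m$utr5, gen$transcripts$utr5)
  expect_equal(m$cds, gen$transcripts$cds)
  expect_equal(m$utr3, gen$transcripts$utr3)
  # and the written region FASTA parses back to the same sequences
  rf <- tempfile(fileext = ".fa")
  write_region_fasta(models, rf)
  back <- Biostrings::readDNAStringSet(rf)
  i <- paste0(m$transcript_id[1], ".cds")
  expect_equal(as.character(back[[i]]), m$cds[1])
})
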