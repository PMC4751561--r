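adapter <- aligner_adapter()

test_that("internal aligner equals the Gotoh dynamic-programming oracle", {
  set.seed(71)
  alpha <- c("A", "R", "N", "D", "G")  # reduced alphabet
  for (i in 1:120) {
    a <- paste(sample(alpha, sample(1:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alpha, sample(1:12, 1), replace = TRUE), collapse = "")
    want_raw <- oracle_sw_score(a, b, adapter$submat)
    got <- max_score(a, b, adapter)
    want <- if (want_raw <= 0) 0 else
      max(0, (adapter$lambda * want_raw - log(adapter$K)) / log(2))
    expect_equal(got, want, tolerance = 1e-9,
                 info = paste(a, b, sep = " / "))
  }
})

test_that("max_score is the maximum over subjects and handles no-hit", {
  prot <- Biostrings::AAStringSet(c(s1 = "MKVLAWWRE", s2 = "GGGGG"))
  q <- "MKVLAWWRE"
  self_raw <- oracle_sw_score(q, q, adapter$submat)
  expect_equal(max_score(q, prot, adapter),
               (adapter$lambda * self_raw - log(adapter$K)) / log(2))
  # a query with no positive-scoring alignment
  expect_equal(max_score("PP", Biostrings::AAStringSet(c(a = "GG")),
                         adapter), 0)
  expect_error(max_score("MK", Biostrings::AAStringSet(), adapter), "empty")
})

test_that("extension queries are built by scramble-preserving concatenation", {
  q <- build_extension_queries("MAAAW", "MK", seed = 4)
  expect_equal(q$ref, "MAAAW")
  expect_equal(q$ext, "MKMAAAW")
  expect_true(q$scr1 %in% c("MKMAAAW", "KMMAAAW"))
  expect_equal(substr(q$scr1, 3, 7), "MAAAW")
  set.seed(72)
  ext <- paste(sample(c("A", "C", "D", "E", "K", "M"), 30, replace = TRUE),
               collapse = "")
  q <- build_extension_queries("MWWW", ext, seed = 9)
  expect_equal(sort(strsplit(substr(q$scr1, 1, 30), "")[[1]]),
               sort(strsplit(ext, "")[[1]]))
  expect_error(build_extension_queries("MWWW", "", seed = 1), "zero-length")
})

test_that("conserved extensions improve scores; scrambles and neutrals do not", {
  spec <- synthetic_spec(n_transcripts = 80L, cds_meanlog = log(50),
                         cds_sdlog = 0.4, fraction_class1_implanted = 1,
                         fraction_translated = 0.5)
  gen <- generate_genome(spec, seed = 30)
  models <- gen_models(gen)
  inv <- uorf_inventory(models)
  orth <- generate_ortholog_proteome(gen, seed = 31)
  ext <- extension_test(models, inv, orth, adapter, seed = 32)
  sc <- merge(ext$scores, gen$truth, by = "transcript_id")
  cons <- sc$conserved_extension
  expect_gt(median(sc$improvement[cons]), 5)
  expect_lt(abs(median(sc$improvement[!cons])), 1)
  expect_lt(abs(median(sc$delta_scr_max)), 1)
  # conserved set separates from non-conserved by ranking
  expect_gt(mean(rank(sc$improvement)[cons]), mean(rank(sc$improvement)[!cons]) + 20)
})

test_that("proteome without homologs yields zero deltas and no positive set", {
  spec <- synthetic_spec(n_transcripts = 40L, cds_meanlog = log(40),
                         fraction_class1_implanted = 1,
                         fraction_translated = 0)
  gen <- generate_genome(spec, seed = 33)
  models <- gen_models(gen)
  inv <- uorf_inventory(models)
  junk <- Biostrings::AAStringSet(
    vapply(1:40, function(i) strrep("G", 50), character(1)))
  ext <- extension_test(models, inv, junk, adapter, seed = 34)
  # spurious matches to the poly-G subjects stay tiny and below the
  # conservation cutoff for every transcript
  expect_equal(median(ext$scores$delta_real), 0)
  expect_lt(max(abs(ext$scores$improvement)), 4)
  expect_equal(sum(ext$scores$above_abs_cutoff), 0L)
})

test_that("first-vs-second ATG logic on constructed nested subjects", {
  # CDS: M ...27 codons... M(second ATG) ...30 codons...
  set.seed(73)
  mk_codons <- function(aas) {
    lut <- c(A = "GCT", W = "TGG", K = "AAA", L = "CTG", V = "GTC",
             D = "GAT", E = "GAA", R = "CGT", S = "TCT", G = "GGT")
    paste(lut[aas], collapse = "")
  }
  aa1 <- sample(c("A", "W", "K", "L", "V", "D", "E", "R", "S", "G"), 27,
                replace = TRUE)
  aa2 <- sample(c("A", "W", "K", "L", "V", "D", "E", "R", "S", "G"), 30,
                replace = TRUE)
  cds <- paste0("ATG", mk_codons(aa1), "ATG", mk_codons(aa2), "TAA")
  models <- data.frame(transcript_id = "t1", strand = "+", utr5 = "",
                       cds = cds, utr3 = "", stringsAsFactors = FALSE)
  class(models) <- c("transcript_models", "data.frame")
  full_pep <- translate_cds(cds)

  # subject covering the full peptide: s2 > s1 > s0
  r <- first_vs_second_atg_test(models,
                                Biostrings::AAStringSet(c(v = full_pep)),
                                adapter)
  expect_equal(r$n_eligible, 1L)
  expect_true(r$scores$precondition_met)
  expect_true(r$scores$first_atg_supported)
  expect_gt(r$scores$s1, r$scores$s0)

  # subject covering only the region 3' of second ATG + 25 aa: s2 == s1 == s0
  tail_pep <- substr(full_pep, 28 + 25 + 1, nchar(full_pep))
  r <- first_vs_second_atg_test(models,
                                Biostrings::AAStringSet(c(v = tail_pep)),
                                adapter)
  expect_false(r$scores$precondition_met)
  expect_equal(r$scores$s2, r$scores$s1)
  expect_equal(r$scores$s1, r$scores$s0)

  # too-short CDS is excluded and counted
  short <- models
  short$cds <- paste0("ATG", mk_codons(rep("A", 5)), "ATG",
                      mk_codons(rep("W", 10)), "TAA")
  r <- first_vs_second_atg_test(short,
                                Biostrings::AAStringSet(c(v = full_pep)),
                                adapter)
  expect_equal(r$n_eligible, 0L)
  expect_equal(r$n_excluded_short, 1L)
})

test_that("prepending residues never lowers the best local score", {
  set.seed(74)
  prot <- Biostrings::AAStringSet(c(
    a = "MKVLAWREDESTILK", b = "GGAVVLLMMKK"))
  for (i in 1:10) {
    q <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                      sample(5:15, 1), replace = TRUE), collapse = "")
    pre <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                        sample(1:8, 1), replace = TRUE), collapse = "")
    expect_gte(max_score(paste0(pre, q), prot, adapter) + 1e-9,
               max_score(q, prot, adapter))
  }
})
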