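count_nucs <- function(s) table(factor(strsplit(s, "")[[1]],
                                       levels = c("A", "C", "G", "T")))

test_that("scramble preserves per-sequence composition and is deterministic", {
  expect_equal(scramble_each("AAAA", 1)$sequences, "AAAA")
  s <- scramble_each("ACGT", 5)$sequences
  expect_equal(sort(strsplit(s, "")[[1]]), c("A", "C", "G", "T"))

  set.seed(31)
  seqs <- replicate(20, random_dna(sample(50:200, 1)))
  cs1 <- scramble_each(seqs, 42)
  cs2 <- scramble_each(seqs, 42)
  expect_identical(cs1$sequences, cs2$sequences)
  expect_false(identical(scramble_each(seqs, 43)$sequences, cs1$sequences))
  for (i in seq_along(seqs)) {
    expect_equal(count_nucs(cs1$sequences[i]), count_nucs(seqs[i]))
  }
  # positional identity with the source is at chance level on a long read
  long <- random_dna(10000)
  scr <- scramble_each(long, 9)$sequences
  match_rate <- mean(strsplit(long, "")[[1]] == strsplit(scr, "")[[1]])
  exp_rate <- sum(prop.table(count_nucs(long))^2)
  expect_lt(abs(match_rate - exp_rate), 3 * sqrt(exp_rate / 10000))
})

test_that("dinucleotide-matched generation converges to the target table", {
  set.seed(8)
  src <- replicate(30, random_dna(300, c(A = .15, C = .35, G = .30, T = .20)))
  target <- dinucleotide_freqs(src)
  cs <- random_by_dinucleotide(target, lengths = 1e6L, seed = 17)
  expect_equal(nchar(cs$sequences), 1e6L)
  got <- dinucleotide_freqs(cs$sequences)
  tv <- sum(abs(got - target)) / 2
  expect_lt(tv, 0.01)
  # length contract
  cs2 <- random_by_dinucleotide(target, c(5L, 7L), seed = 1)
  expect_equal(nchar(cs2$sequences), c(5L, 7L))
})

test_that("mono_random matches composition and the point-mass degenerate case", {
  cs <- mono_random(c(A = 1, C = 0, G = 0, T = 0), c(10L, 4L), seed = 2)
  expect_equal(cs$sequences, c("AAAAAAAAAA", "AAAA"))
  p <- c(A = 0.175, C = 0.325, G = 0.325, T = 0.175)
  cs <- mono_random(p, 200000L, seed = 3)
  got <- prop.table(count_nucs(cs$sequences))
  expect_lt(max(abs(as.numeric(got) - p)), 3 * sqrt(max(p) / 200000))
})

test_that("mutagenize hits the expected substitution fraction", {
  seqs <- c("ACGTACGTAC", "GGGGG")
  expect_equal(mutagenize(seqs, 0, c(A = .25, C = .25, G = .25, T = .25),
                          seed = 1)$sequences, seqs)
  allA <- mutagenize(seqs, 1, c(A = 1, C = 0, G = 0, T = 0), seed = 1)
  expect_equal(allA$sequences, c("AAAAAAAAAA", "AAAAA"))
  # r = 0.1 with uniform replacement: realized fraction ~ 0.1 * 3/4
  set.seed(5)
  long <- random_dna(4e5)
  cs <- mutagenize(long, 0.1, c(A = .25, C = .25, G = .25, T = .25),
                   seed = 77)
  expect_equal(nchar(cs$sequences), nchar(long))
  expect_lt(abs(cs$effective_rate - 0.075), 3 * sqrt(0.075 * 0.925 / 4e5))
})

test_that("exact dinucleotide shuffle preserves the dinucleotide multiset", {
  set.seed(12)
  for (i in 1:25) {
    s <- random_dna(sample(10:200, 1))
    sh <- dinucleotide_shuffle(s, seed = i)$sequences
    expect_equal(nchar(sh), nchar(s))
    expect_equal(sort(substring(sh, 1:(nchar(sh) - 1), 2:nchar(sh))),
                 sort(substring(s, 1:(nchar(s) - 1), 2:nchar(s))))
  }
})

test_that("replicate sets derive distinct deterministic seeds", {
  seqs <- replicate(10, random_dna(60))
  reps <- control_replicates(seqs, "scramble", seed = 10, n_rep = 3)
  expect_length(reps, 3L)
  expect_false(identical(reps[[1]]$sequences, reps[[2]]$sequences))
  again <- control_replicates(seqs, "scramble", seed = 10, n_rep = 3)
  expect_identical(lapply(reps, `[[`, "sequences"),
                   lapply(again, `[[`, "sequences"))
})

test_that("neutral 5'UTR controls show no class-1 length excess", {
  # the negative-control behavior: genome-vs-scramble class-1 lengths are
  # indistinguishable when the source sequence is itself neutral
  # (kozak_effect = 0: no initiator-consensus footprint in the UTR tails)
  spec <- synthetic_spec(n_transcripts = 800L, cds_meanlog = log(40),
                         kozak_effect = 0)
  gen <- generate_genome(spec, seed = 21)
  models <- gen_models(gen)
  inv <- uorf_inventory(models)
  scr_models <- models
  scr_models$utr5 <- scramble_each(models$utr5, 99)$sequences
  inv_scr <- uorf_inventory(scr_models)
  len1 <- inv$records$length_codons[inv$records$uorf_class == 1L]
  len1_scr <- inv_scr$records$length_codons[inv_scr$records$uorf_class == 1L]
  ks <- suppressWarnings(stats::ks.test(len1, len1_scr))
  expect_gt(ks$p.value, 0.01)
})
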