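make_ctx <- function(utr, cds) {
  # convenience: context of the reference ATG with default window
  paste0(substr(utr, nchar(utr) - 9, nchar(utr)), substr(cds, 1, 9))
}

test_that("context extraction excludes windows overrunning the sequence", {
  s <- paste0(strrep("C", 10), "ATG", strrep("G", 6))
  ex <- extract_atg_contexts(s, c(10L), up = 10L, down = 8L)
  expect_equal(ex$contexts, s)
  expect_equal(ex$n_excluded, 0L)
  # too close to the 5' end
  ex <- extract_atg_contexts(paste0("CC", "ATG", strrep("G", 8)), 2L)
  expect_equal(length(ex$contexts), 0L)
  expect_equal(ex$n_excluded, 1L)
  expect_error(extract_atg_contexts(strrep("C", 30), 15L), "non-ATG")
})

test_that("monomorphic training set gives 2 bits everywhere and maximal score", {
  ctx <- rep(paste0("GCCGCCGCCA", "ATG", "GCGGCG"), 50)
  m <- build_kozak_matrix(ctx)
  expect_equal(unname(m$info), rep(2, 19))
  # 16 scored positions at 2 bits each
  expect_equal(kozak_score(m, ctx[1]), 32)
  # any other base at a scored position contributes 0
  other <- paste0("TCCGCCGCCA", "ATG", "GCGGCG")
  expect_equal(kozak_score(m, other), 30)
})

test_that("two equiprobable bases give 1 bit; uniform training ~ 0 bits", {
  ctx <- c(rep(paste0("ACCCCCCCCC", "ATG", "CCCCCC"), 25),
           rep(paste0("GCCCCCCCCC", "ATG", "CCCCCC"), 25))
  m <- build_kozak_matrix(ctx)
  expect_equal(m$info[[1]], 1)
  # uniformly drawn contexts: information near 0 (small-sample bias only)
  set.seed(60)
  rnd <- vapply(1:2000, function(i) {
    paste0(random_dna(10), "ATG", random_dna(6))
  }, character(1))
  m2 <- build_kozak_matrix(rnd)
  expect_lt(max(m2$info[m2$scored]), 0.02)
  expect_lt(abs(mean(kozak_score(m2, rnd))), 0.2)
})

test_that("score equals hand-summed weights on a tiny matrix", {
  # window -1..+3: one scored position each side of the ATG
  ctx <- c("AATGC", "AATGC", "AATGC", "CATGG")
  m <- build_kozak_matrix(ctx, up = 1L)
  # position -1: p(A)=3/4, p(C)=1/4 -> H = 0.8113, R = 1.1887
  r1 <- 2 + 0.75 * log2(0.75) + 0.25 * log2(0.25)
  # position +3: p(C)=3/4, p(G)=1/4
  expect_equal(m$info[[1]], r1, tolerance = 1e-12)
  expect_equal(kozak_score(m, "AATGC"), r1 * 0.75 + r1 * 0.75)
  expect_equal(kozak_score(m, "CATGG"), r1 * 0.25 + r1 * 0.25)
  # N contributes nothing
  expect_equal(kozak_score(m, "NATGC"), r1 * 0.75)
  expect_error(kozak_score(m, "ATGCAratherlong"), "window")
})

test_that("reference contexts score above mono-random contexts", {
  spec <- synthetic_spec(n_transcripts = 300L, cds_meanlog = log(50))
  gen <- generate_genome(spec, seed = 14)
  models <- gen_models(gen)
  refc <- reference_contexts(models)
  m <- build_kozak_matrix(refc$contexts)
  ref_scores <- kozak_score(m, refc$contexts)
  rnd <- mono_random(nucleotide_freqs(models$utr5), rep(19L, 5000), seed = 4)
  rnd_ctx <- paste0(substr(rnd$sequences, 1, 10), "ATG",
                    substr(rnd$sequences, 14, 19))
  rnd_scores <- kozak_score(m, rnd_ctx)
  expect_gt(mean(ref_scores), mean(rnd_scores) + 2)
  # the generator was asked for ~4 bits of separation
  expect_lt(abs(mean(ref_scores) - mean(rnd_scores) - spec$kozak_effect), 1)
})

test_that("random-context score distribution is reproducible across seeds", {
  p <- c(A = 0.175, C = 0.325, G = 0.325, T = 0.175)
  ctxs <- lapply(c(101, 202), function(s) {
    r <- mono_random(p, rep(19L, 100000L), seed = s)$sequences
    paste0(substr(r, 1, 10), "ATG", substr(r, 14, 19))
  })
  set.seed(77)
  train <- vapply(1:500, function(i) {
    paste0(random_dna(10, p), "ATG", random_dna(6, p))
  }, character(1))
  m <- build_kozak_matrix(train)
  s1 <- kozak_score(m, ctxs[[1]])
  s2 <- kozak_score(m, ctxs[[2]])
  ks <- suppressWarnings(stats::ks.test(s1, s2))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("score_population labels, scores, and counts exclusions", {
  spec <- synthetic_spec(n_transcripts = 60L, cds_meanlog = log(50),
                         fraction_class1_implanted = 0.5)
  gen <- generate_genome(spec, seed = 8)
  models <- gen_models(gen)
  inv <- uorf_inventory(models)
  recs <- inv$records[inv$records$uorf_class == 1L, ]
  m <- build_kozak_matrix(reference_contexts(models)$contexts)
  ss <- score_population(m, models, recs[, c("transcript_id", "atg_pos")],
                         "class1")
  expect_equal(ss$category, "class1")
  expect_true(all(is.finite(ss$scores$score)))
  expect_equal(nrow(ss$scores) + ss$n_excluded, nrow(recs))
  # empty category
  empty <- score_population(m, models, list(), "none")
  expect_equal(nrow(empty$scores), 0L)
  # implanted strong contexts outscore the random expectation
  tr <- gen$truth
  strong <- ss$scores$transcript_id %in%
    tr$transcript_id[tr$translated]
  if (any(strong) && any(!strong)) {
    expect_gt(mean(ss$scores$score[strong]), mean(ss$scores$score[!strong]))
  }
})

test_that("matrix TSV round-trips weights", {
  ctx <- c("AATGC", "CATGG", "AATGG")
  m <- build_kozak_matrix(ctx, up = 1L)
  f <- tempfile(fileext = ".tsv")
  write_kozak_tsv(m, f)
  df <- read.delim(f)
  expect_equal(nrow(df), 4L * 5L)
  w <- df$weight[df$position == -1 & df$base == "A"]
  expect_equal(w, unname(m$weights["A", 1]))
})
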