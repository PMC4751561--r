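test_that("scan_uorfs classifies the canonical small cases", {
  # in-frame ATG, 6 nt to the CDS, no stop: class 1, two codons ("MK")
  r <- scan_uorfs("AAATGAAA", "t")
  expect_equal(r$uorf_class, 1L)
  expect_equal(r$atg_pos, 2L)
  expect_equal(r$length_codons, 2L)
  expect_equal(translate_cds(substr("AAATGAAA", 3, 8)), "MK")

  # out-of-frame ATG, 7 nt to the CDS: class 2
  r <- scan_uorfs("AATGAAAA", "t")
  expect_equal(r$uorf_class, 2L)
  expect_equal(r$atg_pos, 1L)
  expect_equal(r$frame_offset, 1L)
  expect_equal(r$length_codons, 2L)

  # ATG then stop inside the UTR: one class 3 of one codon
  r <- scan_uorfs("ATGTAAAAA", "t")
  expect_equal(r$uorf_class, 3L)
  expect_equal(r$atg_pos, 0L)
  expect_equal(r$length_codons, 1L)

  expect_equal(nrow(scan_uorfs("CCCCCCCC", "t")), 0L)
  expect_equal(nrow(scan_uorfs("", "t")), 0L)
  # ATG straddling the UTR/CDS junction is not evaluated
  expect_equal(nrow(scan_uorfs("CCCCCCAT", "t")), 0L)
})

test_that("only the 5'-most class-1/2 ATG is reported but all are candidates", {
  # two in-frame ATGs without stops: one reported class-1 record
  u <- "ATGCCCATGCCC"
  r <- scan_uorfs(u, "t")
  expect_equal(sum(r$uorf_class == 1L), 1L)
  expect_equal(r$atg_pos[r$uorf_class == 1L], 0L)
  all_r <- scan_uorfs(u, "t", keep_candidates = TRUE)
  expect_equal(sum(all_r$uorf_class == 1L), 2L)
  expect_equal(sum(all_r$reported), 1L)
})

test_that("N-containing codons are treated as neither ATG nor stop", {
  # TNA in frame after the ATG is not a stop: reaches the CDS as class 1
  r <- scan_uorfs("ATGTNACCC", "t")
  expect_equal(r$uorf_class, 1L)
  # ATN is not an initiator
  expect_equal(nrow(scan_uorfs("ATNCCCCCC", "t")), 0L)
})

test_that("scan_uorfs agrees with the brute-force enumeration oracle", {
  set.seed(2024)
  p <- c(A = 0.175, C = 0.325, G = 0.325, T = 0.175)
  for (i in 1:400) {
    u <- random_dna(sample(3:300, 1L), p)
    got <- scan_uorfs(u, "t")
    want <- oracle_scan_uorfs(u)
    expect_equal(nrow(got), nrow(want), info = u)
    if (nrow(got) > 0L) {
      o <- order(got$atg_pos, got$uorf_class)
      w <- order(want$atg_pos, want$uorf_class)
      expect_equal(got$uorf_class[o], want$uorf_class[w], info = u)
      expect_equal(got$atg_pos[o], want$atg_pos[w], info = u)
      expect_equal(got$length_codons[o], want$length_codons[w], info = u)
    }
  }
})

test_that("inventory partition sums are consistent", {
  spec <- synthetic_spec(n_transcripts = 150L, cds_meanlog = log(50),
                         fraction_class1_implanted = 0.4)
  gen <- generate_genome(spec, seed = 3)
  inv <- uorf_inventory(gen_models(gen))
  expect_equal(sum(inv$partition$n_transcripts), inv$n_transcripts)
  # per-class sums recompute from the partition rows
  for (cl in 1:3) {
    col <- paste0("class", cl)
    expect_equal(sum(inv$partition$n_transcripts[inv$partition[[col]]]),
                 unname(inv$class_sums[col]))
  }
  # every implanted uORF recovered at its recorded position as class 1
  tr <- gen$truth[gen$truth$implanted, ]
  rec1 <- inv$records[inv$records$uorf_class == 1L, ]
  hit <- merge(tr, rec1, by = "transcript_id")
  expect_equal(nrow(hit), nrow(tr))
  expect_equal(hit$atg_pos.x, hit$atg_pos.y)
  expect_equal(hit$ext_codons, hit$length_codons)
})

test_that("atg_frequencies matches hand counts", {
  # CDS anchored at start, initiator excluded: 2 in-frame ATGs over 9/3
  f <- atg_frequencies("ATGATGATG", anchor = "start")
  expect_equal(unname(f["atg_inframe_freq"]), 2 / 3)
  expect_equal(unname(f["atg_outframe_freq"]), 0)
  # 5'UTR anchored at its end (downstream CDS frame)
  f <- atg_frequencies("ATGAAA", anchor = "end")  # pos 0, (6-0)%%3==0
  expect_equal(unname(f["atg_inframe_freq"]), 1 / 2)
  f <- atg_frequencies(c("CCCCCC", "GGG"), anchor = "end")
  expect_equal(unname(f["atg_inframe_freq"]), 0)
  expect_equal(unname(f["atg_outframe_freq"]), 0)
  expect_error(atg_frequencies(character(0)), "empty")
  expect_error(atg_frequencies(c("", "")), "empty")
})

test_that("scan_dorfs finds each terminating ORF and ignores open ones", {
  r <- scan_dorfs("ATGTGA", "t")
  expect_equal(nrow(r), 1L)
  expect_equal(r$length_codons, 1L)
  expect_equal(r$atg_pos, 0L)
  # ORF running off the 3'UTR end (no stop inside) is not a dORF
  expect_equal(nrow(scan_dorfs("ATGAAAAAA", "t")), 0L)
  expect_equal(nrow(scan_dorfs("CCCCCCCC", "t")), 0L)
  # two ATGs, both reaching the same stop: two records
  r <- scan_dorfs("ATGATGTAA", "t")
  expect_equal(nrow(r), 2L)
  expect_equal(r$length_codons, c(2L, 1L))
})
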