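#' Specification for a synthetic genome
#'
#' Bundles the generation parameters with defaults emulating a compact,
#' GC-rich genome: GC 0.65, log-normal region lengths, multi-exon
#' transcripts on both strands, and (optionally) implanted class-1 uORFs of
#' which a fraction \code{fraction_translated} carry a strong initiator
#' context and an ortholog-conserved N-terminal extension. Neutral 5'UTR
#' background is a zeroth-order model at the spec GC, so uORF occurrence in
#' unimplanted transcripts is purely composition-driven.
#'
#' @param n_transcripts Number of transcripts.
#' @param gc_content Background GC fraction (default 0.65).
#' @param utr5_meanlog,utr5_sdlog Log-normal 5'UTR length (nt).
#' @param cds_meanlog,cds_sdlog Log-normal CDS length (codons; floor 30).
#' @param utr3_meanlog,utr3_sdlog Log-normal 3'UTR length (nt).
#' @param exon_count_probs Probabilities for 1..k exons per transcript.
#' @param intron_meanlog,intron_sdlog Log-normal intron length (nt).
#' @param fraction_class1_implanted Fraction of transcripts given an
#'   implanted class-1 uORF (default 0: neutral genome).
#' @param fraction_translated Of the implanted uORFs, fraction flagged
#'   translated: strong Kozak context, longer extension, conserved in the
#'   ortholog proteome (default 0.5).
#' @param kozak_effect Target mean Kozak-score separation (bits) between
#'   strong-context and background ATGs (default 4).
#' @param ext_meanlog_translated,ext_sdlog Log-normal extension length
#'   (codons; floor 2) for translated implants, which are longer than
#'   neutral expectation, mirroring the observed association of
#'   conservation with length. Untranslated implants instead get a
#'   neutrally placed ATG (uniform over in-frame 5'UTR positions), so
#'   their length distribution matches the composition-driven class-2
#'   uORFs they resemble.
#' @param ortholog_conservation Per-residue identity of ortholog peptides
#'   (default 0.7, i.e. >50 percent neutral divergence).
#' @param transcripts_per_contig Packing density (default 500).
#' @return List of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(n_transcripts = 2000L,
                           gc_content = 0.65,
                           utr5_meanlog = log(150), utr5_sdlog = 0.6,
                           cds_meanlog = log(350), cds_sdlog = 0.7,
                           utr3_meanlog = log(400), utr3_sdlog = 0.6,
                           exon_count_probs = c(0.4, 0.3, 0.2, 0.1),
                           intron_meanlog = log(200), intron_sdlog = 0.5,
                           fraction_class1_implanted = 0,
                           fraction_translated = 0.5,
                           kozak_effect = 4,
                           ext_meanlog_translated = log(45),
                           ext_sdlog = 0.4,
                           ortholog_conservation = 0.7,
                           transcripts_per_contig = 500L) {
  stopifnot(gc_content > 0, gc_content < 1,
            fraction_class1_implanted >= 0, fraction_class1_implanted <= 1,
            fraction_translated >= 0, fraction_translated <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

bg_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

bg_string <- function(n, p) {
  if (n <= 0L) return("")
  paste(sample(NUC, n, replace = TRUE, prob = p), collapse = "")
}

## n random non-stop codons from the background composition.
bg_codons <- function(n, p) {
  if (n <= 0L) return("")
  b <- matrix(sample(NUC, 3L * n, replace = TRUE, prob = p), ncol = 3L)
  cods <- paste0(b[, 1L], b[, 2L], b[, 3L])
  repeat {
    bad <- cods %in% STOP_CODONS
    if (!any(bad)) break
    nb <- sum(bad)
    rb <- matrix(sample(NUC, 3L * nb, replace = TRUE, prob = p), ncol = 3L)
    cods[bad] <- paste0(rb[, 1L], rb[, 2L], rb[, 3L])
  }
  paste(cods, collapse = "")
}

## Kozak-like consensus over the -10..+8 window (ATG positions NA).
KOZAK_CONSENSUS <- {
  x <- rep("C", 19L)
  x[8L] <- "A"                 # -3
  x[11:13] <- NA               # ATG anchor
  x[14L] <- "G"                # +3
  x
}

#' Strong-context base distributions calibrated to a bit-score effect
#'
#' Builds the per-position base distributions of the "strong" initiator
#' context model by exponentially tilting the background composition
#' toward a Kozak-like consensus, with the tilt chosen (numerically) so
#' that the expected Kozak score of strong contexts exceeds that of
#' background contexts by \code{kozak_effect} bits, under the information
#' matrix implied by the strong model itself.
#'
#' @param gc_content Background GC.
#' @param kozak_effect Target separation in bits.
#' @return List: \code{probs} (4 x 19 matrix, columns = window positions
#'   -10..+8; anchor columns are the degenerate A/T/G point masses),
#'   \code{beta} (tilt), \code{expected_effect}.
#' @export
strong_context_model <- function(gc_content = 0.65, kozak_effect = 4) {
  p_bg <- bg_probs(gc_content)
  scored <- which(!is.na(KOZAK_CONSENSUS))
  make_probs <- function(beta) {
    probs <- matrix(p_bg, 4L, 19L, dimnames = list(NUC, NULL))
    for (j in scored) {
      q <- p_bg * exp(beta * (NUC == KOZAK_CONSENSUS[j]))
      probs[, j] <- q / sum(q)
    }
    probs[, 11L] <- as.numeric(NUC == "A")
    probs[, 12L] <- as.numeric(NUC == "T")
    probs[, 13L] <- as.numeric(NUC == "G")
    probs
  }
  effect <- function(beta) {
    probs <- make_probs(beta)
    d <- 0
    for (j in scored) {
      q <- probs[, j]
      info <- 2 + sum(q[q > 0] * log2(q[q > 0]))
      w <- info * q
      d <- d + sum(q * w) - sum(p_bg * w)
    }
    d
  }
  if (kozak_effect <= 0) {
    beta <- 0
  } else {
    beta <- stats::uniroot(function(b) effect(b) - kozak_effect,
                           c(1e-6, 12), tol = 1e-6)$root
  }
  list(probs = make_probs(beta), beta = beta,
       expected_effect = effect(beta))
}

## Draw one context from the strong model; returns 19-char string.
draw_strong_context <- function(model_probs) {
  paste(vapply(seq_len(19L), function(j) {
    sample(NUC, 1L, prob = model_probs[, j])
  }, character(1)), collapse = "")
}

## Break position p ATGs in `frame_positions` (0-based) by T -> C.
disrupt_inframe_atgs <- function(utr5, before_pos, frame) {
  x <- strsplit(utr5, "", fixed = TRUE)[[1L]]
  repeat {
    changed <- FALSE
    hits <- gregexpr("ATG", paste(x, collapse = ""), fixed = TRUE)[[1L]]
    if (hits[1L] != -1L) {
      for (h in hits) {
        p <- h - 1L
        if (p < before_pos && p %% 3L == frame) {
          x[p + 2L] <- "C"   # ATG -> ACG
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  paste(x, collapse = "")
}

has_inframe_stop <- function(seq, from, to) {
  # codons starting at from, from+3, ... while codon end <= to (0-based)
  k <- from
  while (k + 2L <= to) {
    if (substr(seq, k + 1L, k + 3L) %in% STOP_CODONS) return(TRUE)
    k <- k + 3L
  }
  FALSE
}

## Build one transcript's utr5/cds/utr3 plus implant truth; bounded retries.
build_transcript_seqs <- function(spec, implant, translated, strong_probs,
                                  p) {
  for (attempt in 1:50) {
    utr5_len <- max(13L, round(stats::rlnorm(1, spec$utr5_meanlog,
                                             spec$utr5_sdlog)))
    cds_cod <- max(30L, round(stats::rlnorm(1, spec$cds_meanlog,
                                            spec$cds_sdlog)))
    utr3_len <- max(9L, round(stats::rlnorm(1, spec$utr3_meanlog,
                                            spec$utr3_sdlog)))
    ext_cod <- NA_integer_
    if (implant) {
      if (translated) {
        ext_cod <- max(2L, round(stats::rlnorm(1, spec$ext_meanlog_translated,
                                               spec$ext_sdlog)))
        utr5_len <- max(utr5_len, 3L * ext_cod + 14L)
      } else {
        # neutral placement: uniform over in-frame 5'UTR positions
        max_cod <- (utr5_len - 14L) %/% 3L
        if (max_cod < 2L) next
        ext_cod <- sample(2:max_cod, 1L)
      }
    }

    cds <- paste0("ATG", bg_codons(cds_cod - 2L, p),
                  sample(STOP_CODONS, 1L))
    utr3 <- bg_string(utr3_len, p)

    # reference initiator context: strong model at the CDS start
    ref_ctx <- draw_strong_context(strong_probs)
    # splice context into sequence: last 10 nt of utr5 + first 9 nt of cds
    utr5 <- if (implant) {
      atg_pos <- utr5_len - 3L * ext_cod
      paste0(bg_string(atg_pos, p), "ATG", bg_codons(ext_cod - 1L, p))
    } else {
      bg_string(utr5_len, p)
    }
    utr5 <- paste0(substr(utr5, 1L, utr5_len - 10L),
                   substr(ref_ctx, 1L, 10L))
    cds <- paste0("ATG", substr(ref_ctx, 14L, 19L),
                  substr(cds, 10L, nchar(cds)))
    # codons 2-3 of the CDS came from the context draw; reject stops
    if (has_inframe_stop(cds, 3L, 8L)) next

    if (implant) {
      atg_pos <- utr5_len - 3L * ext_cod
      if (translated) {
        # strong context around the implanted ATG
        ctx <- draw_strong_context(strong_probs)
        pre <- substr(ctx, 1L, 10L)
        post <- substr(ctx, 14L, 19L)
        utr5 <- paste0(substr(utr5, 1L, atg_pos - 10L), pre, "ATG", post,
                       substr(utr5, atg_pos + 10L, utr5_len))
      }
      if (nchar(utr5) != utr5_len) next
      # implant integrity after overwrites
      if (substr(utr5, atg_pos + 1L, atg_pos + 3L) != "ATG") next
      if (has_inframe_stop(utr5, atg_pos, utr5_len - 1L)) next
      # remove 5'-more in-frame competitors so the implant is the class-1
      utr5 <- disrupt_inframe_atgs(utr5, atg_pos, atg_pos %% 3L)
      if (has_inframe_stop(utr5, atg_pos, utr5_len - 1L)) next
      if (substr(utr5, atg_pos + 1L, atg_pos + 3L) != "ATG") next
      return(list(utr5 = utr5, cds = cds, utr3 = utr3,
                  atg_pos = atg_pos, ext_codons = ext_cod))
    }
    return(list(utr5 = utr5, cds = cds, utr3 = utr3,
                atg_pos = NA_integer_, ext_codons = NA_integer_))
  }
  stop("could not realize transcript under spec after 50 attempts")
}

#' Generate a synthetic genome with ground truth
#'
#' Emits a multi-contig genome (FASTA), a GFF3 annotation with
#' gene/mRNA/exon/CDS features on both strands, and a ground-truth table
#' recording, per transcript, whether a class-1 uORF was implanted, its
#' position and extension length, and its translated / conserved flags.
#' Identical \code{seed} reproduces identical files.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param seed Integer seed.
#' @param dir Optional output directory; if given, writes
#'   \code{genome.fasta}, \code{annotation.gff3}, \code{truth.tsv} and a
#'   \code{params.json} sidecar echoing all generation parameters.
#' @return List of class \code{synthetic_genome}: \code{genome}
#'   (\code{DNAStringSet}), \code{gff3} (character lines), \code{truth}
#'   (data frame), \code{transcripts} (internal region table:
#'   transcript_id, strand, utr5, cds, utr3), \code{spec}, \code{seed},
#'   \code{paths} (if written).
#' @export
generate_genome <- function(spec, seed, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  res <- with_seed(seed, generate_genome_impl(spec))
  res$spec <- spec
  res$seed <- seed
  class(res) <- "synthetic_genome"
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "genome.fasta"),
                  gff3 = file.path(dir, "annotation.gff3"),
                  truth = file.path(dir, "truth.tsv"),
                  params = file.path(dir, "params.json"))
    Biostrings::writeXStringSet(res$genome, paths$fasta)
    writeLines(res$gff3, paths$gff3)
    utils::write.table(res$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(c(unclass(spec), list(seed = seed)),
                         paths$params, digits = NA, auto_unbox = TRUE)
    res$paths <- paths
  }
  res
}

generate_genome_impl <- function(spec) {
  p <- bg_probs(spec$gc_content)
  n <- spec$n_transcripts
  strong <- strong_context_model(spec$gc_content, spec$kozak_effect)

  n_implant <- round(spec$fraction_class1_implanted * n)
  implant <- seq_len(n) <= n_implant  # deterministic assignment
  n_transl <- round(spec$fraction_translated * n_implant)
  translated <- implant & seq_len(n) <= n_transl

  strands <- rep(c("+", "-"), length.out = n)
  n_contig <- max(1L, ceiling(n / spec$transcripts_per_contig))
  contig_of <- rep(seq_len(n_contig), length.out = n)

  gff <- c("##gff-version 3")
  truth <- vector("list", n)
  tx_rows <- vector("list", n)
  contig_parts <- replicate(n_contig, list(), simplify = FALSE)
  contig_len <- integer(n_contig)

  for (i in seq_len(n)) {
    tid <- sprintf("tx%05d", i)
    gid <- sprintf("g%05d", i)
    sq <- build_transcript_seqs(spec, implant[i], translated[i],
                                strong$probs, p)
    tr_seq <- paste0(sq$utr5, sq$cds, sq$utr3)
    tlen <- nchar(tr_seq)

    # exon structure: split transcript at interior breakpoints
    k_max <- length(spec$exon_count_probs)
    n_ex <- sample.int(k_max, 1L, prob = spec$exon_count_probs)
    n_ex <- min(n_ex, max(1L, tlen %/% 60L))
    bp <- sort(sample(seq(30L, tlen - 30L), n_ex - 1L))
    ex_t_start <- c(0L, bp)                  # 0-based transcript coords
    ex_t_end <- c(bp, tlen)                  # exclusive
    introns <- if (n_ex > 1L) {
      pmax(30L, round(stats::rlnorm(n_ex - 1L, spec$intron_meanlog,
                                    spec$intron_sdlog)))
    } else integer(0)

    # pre-mRNA (transcript sense, introns inserted)
    pieces <- substring(tr_seq, ex_t_start + 1L, ex_t_end)
    pre <- pieces[1L]
    ex_p_start <- integer(n_ex); ex_p_start[1L] <- 0L
    for (k in seq_len(n_ex - 1L)) {
      pre <- paste0(pre, bg_string(introns[k], p), pieces[k + 1L])
      ex_p_start[k + 1L] <- ex_p_start[k] +
        (ex_t_end[k] - ex_t_start[k]) + introns[k]
    }
    ex_p_end <- ex_p_start + (ex_t_end - ex_t_start)
    seg_len <- nchar(pre)

    strand <- strands[i]
    ci <- contig_of[i]
    spacer <- sample(100:300, 1L)
    offset <- contig_len[ci] + spacer      # 0-based start of segment
    contig_parts[[ci]] <- c(contig_parts[[ci]],
                            bg_string(spacer, p),
                            if (strand == "+") pre else
                              as.character(Biostrings::reverseComplement(
                                Biostrings::DNAString(pre))))
    contig_len[ci] <- offset + seg_len

    # map pre-mRNA [s, e) (0-based) to 1-based genomic interval
    p2g <- function(s, e) {
      if (strand == "+") c(offset + s + 1L, offset + e)
      else c(offset + seg_len - e + 1L, offset + seg_len - s)
    }
    ex_g <- t(mapply(p2g, ex_p_start, ex_p_end))

    # CDS transcript range [cs, ce) -> per-exon genomic pieces
    cs <- nchar(sq$utr5); ce <- cs + nchar(sq$cds)
    cds_g <- NULL; cds_phase <- integer(0); done <- 0L
    for (k in seq_len(n_ex)) {
      s <- max(cs, ex_t_start[k]); e <- min(ce, ex_t_end[k])
      if (s >= e) next
      ps <- ex_p_start[k] + (s - ex_t_start[k])
      pe <- ex_p_start[k] + (e - ex_t_start[k])
      cds_g <- rbind(cds_g, p2g(ps, pe))
      cds_phase <- c(cds_phase, (3L - done %% 3L) %% 3L)
      done <- done + (e - s)
    }

    contig_name <- sprintf("chr%02d", ci)
    g_start <- min(ex_g[, 1L]); g_end <- max(ex_g[, 2L])
    lines <- c(
      sprintf("%s\tuorfscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              contig_name, g_start, g_end, strand, gid),
      sprintf("%s\tuorfscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              contig_name, g_start, g_end, strand, tid, gid),
      sprintf("%s\tuorfscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              contig_name, ex_g[, 1L], ex_g[, 2L], strand, tid,
              seq_len(n_ex), tid),
      sprintf("%s\tuorfscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds%d;Parent=%s",
              contig_name, cds_g[, 1L], cds_g[, 2L], strand, cds_phase,
              tid, seq_len(nrow(cds_g)), tid))
    gff <- c(gff, lines)

    truth[[i]] <- data.frame(
      transcript_id = tid, contig = contig_name, strand = strand,
      implanted = implant[i], translated = translated[i],
      conserved_extension = translated[i],
      atg_pos = sq$atg_pos, ext_codons = sq$ext_codons,
      utr5_len = nchar(sq$utr5), cds_codons = nchar(sq$cds) %/% 3L,
      stringsAsFactors = FALSE)
    tx_rows[[i]] <- data.frame(
      transcript_id = tid, strand = strand,
      utr5 = sq$utr5, cds = sq$cds, utr3 = sq$utr3,
      stringsAsFactors = FALSE)
  }

  genome <- Biostrings::DNAStringSet(vapply(
    seq_len(n_contig),
    function(ci) paste0(paste(unlist(contig_parts[[ci]]), collapse = ""),
                        bg_string(150L, p)),
    character(1)))
  names(genome) <- sprintf("chr%02d", seq_len(n_contig))

  list(genome = genome, gff3 = gff,
       truth = do.call(rbind, truth),
       transcripts = do.call(rbind, tx_rows),
       strong_model = strong)
}

#' Generate an ortholog proteome for a synthetic genome
#'
#' One ortholog peptide per transcript: the reference peptide mutated at a
#' per-residue rate of \code{1 - identity} (substitutions drawn uniformly
#' from the other 19 residues). Transcripts whose ground truth flags a
#' conserved extension additionally carry the (equally diverged) extension
#' peptide at the ortholog's N-terminus; non-conserved extensions are
#' absent from the orthologs.
#'
#' @param gen A \code{synthetic_genome} from \code{\link{generate_genome}}.
#' @param identity Per-residue identity (default from the spec).
#' @param seed Integer seed.
#' @return \code{AAStringSet}, one ortholog per transcript.
#' @export
generate_ortholog_proteome <- function(gen, identity = NULL, seed = 1L) {
  stopifnot(inherits(gen, "synthetic_genome"))
  if (is.null(identity)) identity <- gen$spec$ortholog_conservation
  AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  mutate_pep <- function(pep, rate) {
    if (nchar(pep) == 0L) return(pep)
    x <- strsplit(pep, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(x)) < rate)
    if (length(hit) > 0L) {
      repl <- AA20[sample.int(20L, length(hit), replace = TRUE)]
      while (any(same <- repl == x[hit])) {  # substitution must change
        repl[same] <- AA20[sample.int(20L, sum(same), replace = TRUE)]
      }
      x[hit] <- repl
    }
    paste(x, collapse = "")
  }
  with_seed(seed, {
    tx <- gen$transcripts
    tr <- gen$truth
    peps <- character(nrow(tx))
    for (i in seq_len(nrow(tx))) {
      ref <- translate_cds(tx$cds[i])
      orth <- mutate_pep(ref, 1 - identity)
      if (isTRUE(tr$conserved_extension[i])) {
        ext_nt <- substr(tx$utr5[i], tr$atg_pos[i] + 1L, nchar(tx$utr5[i]))
        ext <- translate_cds(ext_nt)
        orth <- paste0(mutate_pep(ext, 1 - identity), orth)
      }
      peps[i] <- orth
    }
    ss <- Biostrings::AAStringSet(peps)
    names(ss) <- paste0("orth_", tx$transcript_id)
    ss
  })
}
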