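#' Configure the protein aligner
#'
#' The internal backend is Smith–Waterman local alignment
#' (\code{Biostrings::pairwiseAlignment}, \code{type = "local"}) with
#' BLOSUM62 and affine gaps (open 11, extend 1), the standard protein
#' search parameterization. Raw scores are converted to bits with the
#' gapped Karlin–Altschul parameters for that matrix
#' (\eqn{\lambda = 0.267}, \eqn{K = 0.041}):
#' \eqn{S' = (\lambda S - \ln K)/\ln 2}. An external \code{blastp} backend
#' can be named for full-proteome-scale runs; all desk-scale analyses and
#' tests use the internal backend.
#'
#' @param backend \code{"internal"} (Smith–Waterman) only; the slot exists
#'   so a driver can record an external engine.
#' @param matrix Substitution matrix name (in \code{Biostrings}).
#' @param gap_open,gap_extend Gap penalties (positive).
#' @param lambda,K Karlin–Altschul parameters for the bit conversion.
#' @return List of class \code{aligner_adapter}.
#' @export
aligner_adapter <- function(backend = "internal", matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1,
                            lambda = 0.267, K = 0.041) {
  submat <- get(utils::data(list = matrix, package = "Biostrings",
                            envir = environment()))
  structure(list(backend = backend, matrix_name = matrix, submat = submat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K),
            class = "aligner_adapter")
}

raw_to_bits <- function(raw, adapter) {
  (adapter$lambda * raw - log(adapter$K)) / log(2)
}

#' Maximum alignment bit score of a query against a proteome
#'
#' Smith–Waterman local alignment of the query against every subject;
#' returns the maximum bit score, or 0 when no subject aligns with a
#' positive raw score (no hit).
#'
#' @param query Peptide string.
#' @param proteome \code{AAStringSet} (or character vector) of subjects.
#' @param adapter An \code{\link{aligner_adapter}}.
#' @return Maximum bit score (>= 0).
#' @export
max_score <- function(query, proteome, adapter = aligner_adapter()) {
  if (length(proteome) == 0L) stop("empty proteome")
  if (nchar(query) == 0L) return(0)
  if (!methods::is(proteome, "AAStringSet")) {
    proteome <- Biostrings::AAStringSet(proteome)
  }
  raw <- Biostrings::pairwiseAlignment(
    pattern = rep(Biostrings::AAStringSet(query), length(proteome)),
    subject = proteome,
    type = "local", substitutionMatrix = adapter$submat,
    gapOpening = adapter$gap_open, gapExtension = adapter$gap_extend,
    scoreOnly = TRUE)
  best <- max(raw)
  if (best <= 0) return(0)
  max(0, raw_to_bits(best, adapter))
}

#' Build the four extension-test queries for one class-1 uORF
#'
#' Returns the reference peptide; the reference N-terminally extended by
#' the uORF peptide; and two controls in which the extension is scrambled
#' at the peptide level (residue multiset preserved) before prepending,
#' leaving the reference part untouched.
#'
#' @param reference_pep Reference peptide (annotated CDS product).
#' @param extension_pep uORF extension peptide (first residue M).
#' @param seed Integer seed for the two scrambles.
#' @return Named list: \code{ref}, \code{ext}, \code{scr1}, \code{scr2}.
#' @export
build_extension_queries <- function(reference_pep, extension_pep, seed) {
  if (nchar(extension_pep) == 0L) stop("zero-length extension")
  scr <- with_seed(seed, replicate(2L, paste(
    sample(strsplit(extension_pep, "", fixed = TRUE)[[1L]]),
    collapse = "")))
  list(ref = reference_pep,
       ext = paste0(extension_pep, reference_pep),
       scr1 = paste0(scr[1L], reference_pep),
       scr2 = paste0(scr[2L], reference_pep))
}

#' N-terminal-extension conservation test over all class-1 uORFs
#'
#' For every class-1 uORF: aligns the reference peptide, the uORF-extended
#' peptide and two scrambled-extension controls against the ortholog
#' proteome, taking the maximum bit score of each. The test statistic per
#' transcript is \code{improvement = delta_real - max(delta_scr, 0)} where
#' \code{delta_real = s_ext - s_ref} and \code{delta_scr} is the larger of
#' the two scrambled-control deltas (the mean is also reported). The
#' "high-BLASTP" positive set is the top \code{quantile} fraction by
#' improvement; the absolute rule \code{improvement > abs_cutoff} bits is
#' reported in parallel.
#'
#' @param models A \code{transcript_models} data frame.
#' @param inventory An \code{orf_inventory}.
#' @param proteome \code{AAStringSet} ortholog proteome.
#' @param adapter An \code{\link{aligner_adapter}}.
#' @param seed Integer seed (extension scrambles).
#' @param quantile Top fraction by improvement called high-BLASTP
#'   (default 0.25).
#' @param abs_cutoff Bits for the alternative absolute rule (default 4).
#' @return Object of class \code{extension_test}: data frame \code{scores}
#'   (per transcript: s_ref, s_ext, s_scr1, s_scr2, delta_real,
#'   delta_scr_max, delta_scr_mean, improvement, high_blastp,
#'   above_abs_cutoff), \code{quantile}, \code{abs_cutoff},
#'   \code{n_skipped} (zero-length extensions).
#' @export
extension_test <- function(models, inventory, proteome,
                           adapter = aligner_adapter(), seed = 1L,
                           quantile = 0.25, abs_cutoff = 4) {
  recs <- inventory$records
  c1 <- recs[recs$uorf_class == 1L, , drop = FALSE]
  rows <- list(); n_skipped <- 0L
  for (i in seq_len(nrow(c1))) {
    tid <- c1$transcript_id[i]
    mrow <- match(tid, models$transcript_id)
    utr5 <- models$utr5[mrow]
    ext_nt <- substr(utr5, c1$atg_pos[i] + 1L, nchar(utr5))
    if (c1$length_codons[i] < 1L) { n_skipped <- n_skipped + 1L; next }
    ext_pep <- translate_cds(ext_nt)
    if (nchar(ext_pep) == 0L) { n_skipped <- n_skipped + 1L; next }
    ref_pep <- translate_cds(models$cds[mrow])
    q <- build_extension_queries(ref_pep, ext_pep, seed + i)
    s <- vapply(q, max_score, numeric(1), proteome = proteome,
                adapter = adapter)
    rows[[tid]] <- data.frame(
      transcript_id = tid, uorf_length_codons = c1$length_codons[i],
      s_ref = s[["ref"]], s_ext = s[["ext"]],
      s_scr1 = s[["scr1"]], s_scr2 = s[["scr2"]],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no class-1 uORFs with nonzero extension")
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$delta_real <- df$s_ext - df$s_ref
  df$delta_scr_max <- pmax(df$s_scr1, df$s_scr2) - df$s_ref
  df$delta_scr_mean <- (df$s_scr1 + df$s_scr2) / 2 - df$s_ref
  df$improvement <- df$delta_real - pmax(df$delta_scr_max, 0)
  cut <- stats::quantile(df$improvement, 1 - quantile, names = FALSE)
  df$high_blastp <- df$improvement >= cut & df$improvement > 0
  df$above_abs_cutoff <- df$improvement > abs_cutoff
  structure(list(scores = df, quantile = quantile, abs_cutoff = abs_cutoff,
                 n_skipped = n_skipped),
            class = "extension_test")
}

#' First-vs-second-ATG CDS-membership test
#'
#' For transcripts whose CDS contains an in-frame internal ATG ("second"
#' ATG) with at least \code{offset_aa} codons following it, aligns three
#' nested queries against the ortholog proteome: from \code{offset_aa}
#' residues C-terminal to the second ATG (score s0), from the second ATG
#' (s1), and from the first (reference) ATG (s2). Transcripts with s1 > s0
#' meet the precondition that the region just 3' of the second ATG carries
#' alignable signal; among those, s2 > s1 supports the first ATG being
#' genuinely within the CDS.
#'
#' @param models A \code{transcript_models} data frame.
#' @param proteome \code{AAStringSet}.
#' @param adapter An \code{\link{aligner_adapter}}.
#' @param offset_aa Offset (default 25 aa) defining the s0 query start.
#' @return Object of class \code{atg_order_test}: data frame \code{scores}
#'   (transcript_id, second_atg_codon, s0, s1, s2, precondition_met,
#'   first_atg_supported), \code{n_eligible}, \code{n_excluded_short},
#'   \code{n_precondition}, \code{fraction_first_supported}.
#' @export
first_vs_second_atg_test <- function(models, proteome,
                                     adapter = aligner_adapter(),
                                     offset_aa = 25L) {
  rows <- list(); n_short <- 0L
  for (i in seq_len(nrow(models))) {
    cds <- models$cds[i]
    n_cod <- nchar(cds) %/% 3L
    second <- NA_integer_
    if (n_cod >= 2L) {
      for (k in 1L:(n_cod - 1L)) {
        if (substr(cds, 3L * k + 1L, 3L * k + 3L) == "ATG") {
          second <- k; break
        }
      }
    }
    if (is.na(second)) next
    if (n_cod - second < offset_aa + 2L) { n_short <- n_short + 1L; next }
    q2 <- translate_cds(cds)
    q1 <- translate_cds(substr(cds, 3L * second + 1L, nchar(cds)))
    q0 <- translate_cds(substr(cds, 3L * (second + offset_aa) + 1L,
                               nchar(cds)))
    if (nchar(q0) < 2L) { n_short <- n_short + 1L; next }
    s0 <- max_score(q0, proteome, adapter)
    s1 <- max_score(q1, proteome, adapter)
    s2 <- max_score(q2, proteome, adapter)
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = models$transcript_id[i], second_atg_codon = second,
      s0 = s0, s1 = s1, s2 = s2,
      precondition_met = s1 > s0,
      first_atg_supported = s2 > s1,
      stringsAsFactors = FALSE)
  }
  scores <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(transcript_id = character(), second_atg_codon = integer(),
               s0 = numeric(), s1 = numeric(), s2 = numeric(),
               precondition_met = logical(), first_atg_supported = logical(),
               stringsAsFactors = FALSE)
  pre <- scores$precondition_met
  structure(list(scores = scores,
                 n_eligible = nrow(scores),
                 n_excluded_short = n_short,
                 n_precondition = sum(pre),
                 fraction_first_supported =
                   if (sum(pre) > 0) mean(scores$first_atg_supported[pre])
                   else NA_real_),
            class = "atg_order_test")
}

#' @export
print.extension_test <- function(x, ...) {
  cat("extension conservation test over", nrow(x$scores), "class-1 uORFs\n")
  cat(sprintf("  median improvement %.2f bits; high-BLASTP (top %.0f%%): %d; > %g bits: %d\n",
              stats::median(x$scores$improvement), 100 * x$quantile,
              sum(x$scores$high_blastp), x$abs_cutoff,
              sum(x$scores$above_abs_cutoff)))
  invisible(x)
}

#' @export
print.atg_order_test <- function(x, ...) {
  cat("first-vs-second ATG test:", x$n_eligible, "eligible transcripts,",
      x$n_precondition, "meet s1 > s0\n")
  if (!is.na(x$fraction_first_supported)) {
    cat(sprintf("  fraction with s2 > s1 among them: %.3f\n",
                x$fraction_first_supported))
  }
  invisible(x)
}
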