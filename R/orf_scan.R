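STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan a transcript's 5'UTR for upstream ORFs
#'
#' Evaluates every ATG whose three bases lie wholly within the 5'UTR and
#' classifies it relative to the reference CDS start:
#' \describe{
#'   \item{class 1}{in frame with the CDS, no in-frame stop codon wholly
#'     within the 5'UTR — a potential N-terminal extension;}
#'   \item{class 2}{out of frame, no in-frame stop wholly within the 5'UTR;}
#'   \item{class 3}{in-frame stop codon entirely within the 5'UTR.}
#' }
#' Every class-3 ORF is reported individually; for classes 1 and 2 only the
#' 5'-most qualifying ATG is reported (at most one record of each), though
#' more 3' candidates still seed class-3 records when they terminate in the
#' UTR. Codons containing \code{N} are treated as neither ATG nor stop.
#'
#' Length is in complete codons: to the first in-frame stop (excluded) for
#' class 3, to the beginning of the CDS for classes 1 and 2.
#'
#' @param utr5 5'UTR sequence, mRNA sense (may be empty).
#' @param transcript_id Optional id copied into the result.
#' @param keep_candidates If \code{TRUE}, also return the unreported class-1/2
#'   candidate ATGs (3'-of-the-chosen ones) with \code{reported = FALSE};
#'   the two-wrong-frames count expectation is exact only at candidate level.
#' @return Data frame with one row per record: \code{transcript_id},
#'   \code{uorf_class}, \code{atg_pos} (0-based transcript-relative position
#'   of the A), \code{frame_offset}, \code{length_codons},
#'   \code{terminates_in_utr5}, \code{reported}.
#' @export
scan_uorfs <- function(utr5, transcript_id = NA_character_,
                       keep_candidates = FALSE) {
  empty <- data.frame(
    transcript_id = character(), uorf_class = integer(),
    atg_pos = integer(), frame_offset = integer(),
    length_codons = integer(), terminates_in_utr5 = logical(),
    reported = logical(), stringsAsFactors = FALSE)
  L <- nchar(utr5)
  if (L < 3L) return(empty)
  atgs <- gregexpr("ATG", utr5, fixed = TRUE)[[1]]
  if (atgs[1] == -1L) return(empty)

  rows <- lapply(atgs, function(a1) {
    a <- a1 - 1L                       # 0-based position of the A
    d <- L - a                         # nt from ATG to CDS start
    m <- d %/% 3L                      # complete codons wholly within UTR
    fo <- d %% 3L
    stop_at <- NA_integer_
    if (m >= 2L) {
      for (k in 1L:(m - 1L)) {
        cod <- substr(utr5, a + 3L * k + 1L, a + 3L * k + 3L)
        if (cod %in% STOP_CODONS) { stop_at <- k; break }
      }
    }
    if (!is.na(stop_at)) {
      data.frame(transcript_id = transcript_id, uorf_class = 3L,
                 atg_pos = a, frame_offset = fo,
                 length_codons = stop_at, terminates_in_utr5 = TRUE,
                 reported = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(transcript_id = transcript_id,
                 uorf_class = if (fo == 0L) 1L else 2L,
                 atg_pos = a, frame_offset = fo,
                 length_codons = m, terminates_in_utr5 = FALSE,
                 reported = FALSE, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  for (cl in c(1L, 2L)) {
    idx <- which(res$uorf_class == cl)
    if (length(idx) > 0L) res$reported[idx[1L]] <- TRUE  # 5'-most
  }
  if (!keep_candidates) res <- res[res$reported, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan all transcripts and build the uORF inventory
#'
#' Runs \code{\link{scan_uorfs}} over every transcript and aggregates:
#' per-class transcript sums, the 8-row presence-combination partition
#' (which classes co-occur per transcript), and uncapped candidate counts
#' for classes 1 and 2.
#'
#' @param models A \code{transcript_models} data frame.
#' @return List of class \code{orf_inventory}: \code{records} (all reported
#'   uORF records, row-bound), \code{candidates} (including unreported
#'   class-1/2 candidates), \code{class_sums} (named vector, transcripts
#'   containing >= 1 of each class), \code{partition} (data frame of the 8
#'   presence combinations with transcript counts), \code{candidate_counts}
#'   (total class-1 and class-2 candidate ATGs genome-wide),
#'   \code{n_transcripts}.
#' @export
uorf_inventory <- function(models) {
  recs <- mapply(scan_uorfs, models$utr5, models$transcript_id,
                 MoreArgs = list(keep_candidates = TRUE), SIMPLIFY = FALSE)
  cand <- do.call(rbind, recs)
  rownames(cand) <- NULL
  records <- cand[cand$reported, , drop = FALSE]

  has <- matrix(FALSE, nrow(models), 3L,
                dimnames = list(models$transcript_id, paste0("class", 1:3)))
  if (nrow(records) > 0L) {
    for (cl in 1:3) {
      tid <- unique(records$transcript_id[records$uorf_class == cl])
      has[tid, cl] <- TRUE
    }
  }
  combo <- interaction(has[, 1], has[, 2], has[, 3], drop = FALSE)
  grid <- expand.grid(class1 = c(FALSE, TRUE), class2 = c(FALSE, TRUE),
                      class3 = c(FALSE, TRUE))
  key <- interaction(grid$class1, grid$class2, grid$class3)
  partition <- cbind(grid, n_transcripts = as.integer(table(combo)[as.character(key)]))
  partition$n_transcripts[is.na(partition$n_transcripts)] <- 0L

  structure(list(
    records = records,
    candidates = cand,
    class_sums = colSums(has),
    partition = partition,
    candidate_counts = c(
      class1 = sum(cand$uorf_class == 1L),
      class2 = sum(cand$uorf_class == 2L)),
    n_transcripts = nrow(models)
  ), class = "orf_inventory")
}

#' @export
print.orf_inventory <- function(x, ...) {
  cat("uORF inventory over", x$n_transcripts, "transcripts\n")
  cat("  transcripts with class 1:", x$class_sums[["class1"]],
      " class 2:", x$class_sums[["class2"]],
      " class 3:", x$class_sums[["class3"]], "\n")
  cat("  none:", x$partition$n_transcripts[1], "\n")
  cat("  candidate ATGs  class 1:", x$candidate_counts[["class1"]],
      " class 2:", x$candidate_counts[["class2"]], "\n")
  invisible(x)
}

#' ATG frequency table for a sequence set
#'
#' Counts ATGs in frame and out of frame with an anchor, each divided by
#' (total sequence length)/3, the per-codon-equivalent normalization. For a
#' CDS set the anchor is position 0 and the initiator ATG itself is excluded;
#' for a 5'UTR set the anchor is the downstream CDS start, i.e. the sequence
#' end, so "in frame" means in frame with the CDS that follows.
#'
#' @param seqs Character vector of sequences.
#' @param anchor \code{"start"} (CDS-style, initiator excluded) or
#'   \code{"end"} (5'UTR-style, frame anchored at the downstream CDS).
#' @return Named numeric vector: \code{atg_inframe_freq},
#'   \code{atg_outframe_freq}, plus counts and the denominator.
#' @export
atg_frequencies <- function(seqs, anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  total <- sum(nchar(seqs))
  if (length(seqs) == 0L || total == 0L) stop("empty sequence set")
  n_in <- 0L; n_out <- 0L
  for (s in seqs) {
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    pos <- hits - 1L                    # 0-based
    if (anchor == "start") pos <- pos[pos != 0L]  # drop the initiator
    if (length(pos) == 0L) next
    fo <- if (anchor == "start") pos %% 3L else (nchar(s) - pos) %% 3L
    n_in <- n_in + sum(fo == 0L)
    n_out <- n_out + sum(fo != 0L)
  }
  denom <- total / 3
  c(atg_inframe_freq = n_in / denom, atg_outframe_freq = n_out / denom,
    n_inframe = n_in, n_outframe = n_out, denom = denom)
}

#' Scan a 3'UTR for downstream ORFs (dORFs)
#'
#' Reports every ATG-initiated ORF that terminates at a stop codon wholly
#' within the 3'UTR, in any frame, each ATG counted separately. Length in
#' codons excludes the stop.
#'
#' @param utr3 3'UTR sequence, mRNA sense.
#' @param transcript_id Optional id copied into the result.
#' @return Data frame: \code{transcript_id}, \code{atg_pos} (0-based within
#'   the 3'UTR), \code{length_codons}.
#' @export
scan_dorfs <- function(utr3, transcript_id = NA_character_) {
  empty <- data.frame(transcript_id = character(), atg_pos = integer(),
                      length_codons = integer(), stringsAsFactors = FALSE)
  L <- nchar(utr3)
  if (L < 6L) return(empty)
  atgs <- gregexpr("ATG", utr3, fixed = TRUE)[[1]]
  if (atgs[1] == -1L) return(empty)
  rows <- lapply(atgs, function(a1) {
    a <- a1 - 1L
    m <- (L - a) %/% 3L
    if (m < 2L) return(NULL)
    for (k in 1L:(m - 1L)) {
      cod <- substr(utr3, a + 3L * k + 1L, a + 3L * k + 3L)
      if (cod %in% STOP_CODONS) {
        return(data.frame(transcript_id = transcript_id, atg_pos = a,
                          length_codons = k, stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Write uORF/dORF records as TSV
#'
#' @param records A record data frame from \code{\link{scan_uorfs}},
#'   \code{\link{uorf_inventory}} or \code{\link{scan_dorfs}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_orf_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
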