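#' Extract fixed-window contexts around ATGs
#'
#' Pulls the window \code{-up..+down} (relative to the A of the ATG, which
#' sits at relative position 0) out of a transcript-sense sequence for each
#' given ATG position. Contexts that would overrun either end of the
#' sequence are excluded and counted rather than padded.
#'
#' @param seq Full mRNA-sense sequence (e.g. \code{paste0(utr5, cds, utr3)}).
#' @param atg_positions 0-based positions of the A of each ATG.
#' @param up,down Window extent upstream/downstream of the A (defaults 10
#'   and 8, i.e. positions -10..+8).
#' @return List: \code{contexts} (character vector, width
#'   \code{up + down + 1}), \code{positions} (their ATG positions),
#'   \code{n_excluded}.
#' @export
extract_atg_contexts <- function(seq, atg_positions, up = 10L, down = 8L) {
  L <- nchar(seq)
  start <- atg_positions - up          # 0-based
  end <- atg_positions + down
  ok <- start >= 0L & end <= L - 1L
  ctx <- if (any(ok)) substring(seq, start[ok] + 1L, end[ok] + 1L)
         else character(0)
  bad_atg <- substr(ctx, up + 1L, up + 3L) != "ATG"
  if (any(bad_atg)) stop("non-ATG at anchor for position(s) ",
                         paste(atg_positions[ok][bad_atg], collapse = ", "))
  list(contexts = ctx, positions = atg_positions[ok],
       n_excluded = sum(!ok))
}

#' Build a Kozak-style position-information matrix
#'
#' From aligned fixed-window initiator contexts, computes per-position
#' nucleotide frequencies \eqn{p_i(n)}, information content
#' \eqn{R_i = 2 - H_i} bits (Shannon entropy in bits over A,C,G,T), and
#' weights \eqn{w_i(n) = R_i p_i(n)} — the bits a context earns for showing
#' base \eqn{n} at position \eqn{i}. The three ATG anchor positions are
#' retained in the matrix but flagged unscored: they are invariant across
#' contexts and would only add a constant. \code{N}s are ignored in the
#' frequency counts.
#'
#' @param contexts Character vector of equal-width context strings with ATG
#'   at the anchor (as from \code{\link{extract_atg_contexts}}).
#' @param up Window extent upstream of the A (defines the anchor column).
#' @param small_sample_correction Apply the small-sample entropy correction
#'   \eqn{e(n) = 3/(2 n \ln 2)} subtracted from \eqn{R_i} (negligible at
#'   large n; off by default).
#' @return Object of class \code{kozak_matrix}: \code{freqs}, \code{info},
#'   \code{weights} (4 x width), \code{positions} (relative coordinates),
#'   \code{scored} (logical), \code{n_train}, \code{window}.
#' @export
build_kozak_matrix <- function(contexts, up = 10L,
                               small_sample_correction = FALSE) {
  if (length(contexts) == 0L) stop("empty training set")
  w <- unique(nchar(contexts))
  if (length(w) != 1L) stop("contexts differ in width")
  m <- do.call(rbind, strsplit(contexts, "", fixed = TRUE))
  freqs <- vapply(seq_len(w), function(j) {
    col <- m[, j]
    counts <- tabulate(match(col, NUC), nbins = 4L)
    tot <- sum(counts)
    if (tot == 0L) rep(0.25, 4) else counts / tot
  }, numeric(4))
  rownames(freqs) <- NUC
  h <- apply(freqs, 2L, function(p) {
    nz <- p[p > 0]
    -sum(nz * log2(nz))
  })
  info <- 2 - h
  if (small_sample_correction) {
    info <- pmax(0, info - 3 / (2 * length(contexts) * log(2)))
  }
  weights <- sweep(freqs, 2L, info, "*")
  positions <- seq_len(w) - 1L - up
  scored <- !(positions %in% 0:2)
  structure(list(freqs = freqs, info = info, weights = weights,
                 positions = positions, scored = scored,
                 n_train = length(contexts),
                 window = c(up = up, down = w - up - 1L)),
            class = "kozak_matrix")
}

#' @export
print.kozak_matrix <- function(x, ...) {
  cat("Kozak matrix: window ", -x$window[["up"]], "..+", x$window[["down"]],
      " (ATG anchor unscored), trained on ", x$n_train, " contexts\n",
      sep = "")
  cat("  total information over scored positions:",
      round(sum(x$info[x$scored]), 3), "bits\n")
  invisible(x)
}

#' Kozak score of one or more ATG contexts
#'
#' The score is the sum over scored window positions of the weight (bits)
#' of the observed base: \eqn{K = \sum_i w_i(b_i)}. Positions showing
#' \code{N} contribute 0 bits.
#'
#' @param m A \code{kozak_matrix}.
#' @param contexts Character vector of context strings covering the full
#'   window (same width as the training contexts).
#' @return Numeric vector of scores in bits.
#' @export
kozak_score <- function(m, contexts) {
  w <- ncol(m$weights)
  bad <- nchar(contexts) != w
  if (any(bad)) {
    stop("context width ", nchar(contexts)[bad][1L], " does not cover the ",
         -m$window[["up"]], "..+", m$window[["down"]], " window (need ", w,
         " nt)")
  }
  if (length(contexts) == 0L) return(numeric(0))
  cm <- do.call(rbind, strsplit(contexts, "", fixed = TRUE))
  cols <- which(m$scored)
  scores <- numeric(length(contexts))
  for (j in cols) {
    idx <- match(cm[, j], NUC)
    contrib <- unname(m$weights[, j])[idx]
    contrib[is.na(contrib)] <- 0  # N or other unknowns
    scores <- scores + contrib
  }
  scores
}

#' Score a categorized ATG population
#'
#' Extracts contexts for the given ATG positions on each transcript's full
#' mRNA sequence, scores them, and labels the result. ATGs too close to the
#' transcript ends to fill the window are excluded and counted.
#'
#' @param m A \code{kozak_matrix}.
#' @param models A \code{transcript_models} data frame.
#' @param atg_positions Named list mapping \code{transcript_id} to 0-based
#'   ATG positions in the full transcript sequence (utr5+cds+utr3), or a
#'   data frame with columns \code{transcript_id}, \code{atg_pos}.
#' @param category Label stored with every score.
#' @return Object of class \code{context_score_set}: data frame
#'   \code{scores} (\code{transcript_id}, \code{atg_pos}, \code{score}),
#'   \code{category}, \code{n_excluded}.
#' @export
score_population <- function(m, models, atg_positions, category) {
  if (is.data.frame(atg_positions)) {
    atg_positions <- split(atg_positions$atg_pos,
                           atg_positions$transcript_id)
  }
  up <- m$window[["up"]]; down <- m$window[["down"]]
  full <- paste0(models$utr5, models$cds, models$utr3)
  names(full) <- models$transcript_id
  rows <- list(); n_excl <- 0L
  for (tid in names(atg_positions)) {
    pos <- atg_positions[[tid]]
    if (length(pos) == 0L || !tid %in% names(full)) next
    ex <- extract_atg_contexts(full[[tid]], pos, up, down)
    n_excl <- n_excl + ex$n_excluded
    if (length(ex$contexts) == 0L) next
    rows[[tid]] <- data.frame(
      transcript_id = tid, atg_pos = ex$positions,
      score = kozak_score(m, ex$contexts), stringsAsFactors = FALSE)
  }
  scores <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(transcript_id = character(), atg_pos = integer(),
               score = numeric(), stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(scores = scores, category = category,
                 n_excluded = n_excl),
            class = "context_score_set")
}

#' Reference-initiator contexts of a transcript set
#'
#' The reference initiator is the annotated CDS start; its context window
#' reaches \code{up} nt into the 5'UTR and \code{down - 2} nt past the ATG
#' into the CDS. Transcripts whose 5'UTR is shorter than \code{up} (or CDS
#' shorter than \code{down + 1}) are excluded and counted.
#'
#' @param models A \code{transcript_models} data frame.
#' @param up,down Window extents.
#' @return As \code{\link{extract_atg_contexts}}, plus
#'   \code{transcript_ids}.
#' @export
reference_contexts <- function(models, up = 10L, down = 8L) {
  ok <- nchar(models$utr5) >= up & nchar(models$cds) >= down + 1L
  ctx <- paste0(
    substr(models$utr5[ok], nchar(models$utr5[ok]) - up + 1L,
           nchar(models$utr5[ok])),
    substr(models$cds[ok], 1L, down + 1L))
  bad <- substr(ctx, up + 1L, up + 3L) != "ATG"
  if (any(bad)) {
    warning(sum(bad), " reference CDS not starting with ATG excluded")
    ctx <- ctx[!bad]
  }
  list(contexts = ctx,
       transcript_ids = models$transcript_id[ok][if (any(bad)) !bad else TRUE],
       n_excluded = sum(!ok) + sum(bad))
}

#' Serialize a Kozak matrix as TSV
#'
#' Long format: position, base, frequency, information (bits), weight
#' (bits), scored flag.
#'
#' @param m A \code{kozak_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_kozak_tsv <- function(m, path) {
  df <- expand.grid(base = NUC, position = m$positions,
                    stringsAsFactors = FALSE)
  df$freq <- as.vector(m$freqs)
  df$info <- rep(m$info, each = 4L)
  df$weight <- as.vector(m$weights)
  df$scored <- rep(m$scored, each = 4L)
  df <- df[, c("position", "base", "freq", "info", "weight", "scored")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
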