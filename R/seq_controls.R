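NUC <- c("A", "C", "G", "T")

## Run `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_control_set <- function(kind, sequences, seed, rate = NA_real_,
                            replicate_index = 1L) {
  structure(list(kind = kind, rate = rate, replicate_index = replicate_index,
                 sequences = sequences, seed = seed),
            class = "control_set")
}

#' Scramble each sequence individually
#'
#' Permutes the bases of every sequence independently, preserving each
#' sequence's nucleotide multiset (composition) and length exactly while
#' destroying sequence order.
#'
#' @param seqs Character vector of sequences.
#' @param seed Integer seed; identical seed gives identical output.
#' @param replicate_index Replicate label stored in the result.
#' @return A \code{control_set} (kind \code{"scramble"}).
#' @export
scramble_each <- function(seqs, seed, replicate_index = 1L) {
  out <- with_seed(seed, vapply(seqs, function(s) {
    paste(sample(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
  new_control_set("scramble", out, seed, replicate_index = replicate_index)
}

#' Dinucleotide frequencies of a sequence set
#'
#' @param seqs Character vector.
#' @return 4x4 matrix (rows: first base, columns: second base) of pooled
#'   dinucleotide frequencies, summing to 1.
#' @export
dinucleotide_freqs <- function(seqs) {
  counts <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (s in seqs) {
    if (nchar(s) < 2L) next
    d <- Biostrings::dinucleotideFrequency(Biostrings::DNAString(s))
    counts <- counts + matrix(d, 4, 4, byrow = TRUE,
                              dimnames = list(NUC, NUC))
  }
  counts / sum(counts)
}

#' Mononucleotide frequencies of a sequence set
#'
#' @param seqs Character vector.
#' @return Named numeric vector over A,C,G,T summing to 1.
#' @export
nucleotide_freqs <- function(seqs) {
  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(seqs))[, NUC, drop = FALSE])
  counts / sum(counts)
}

## First-order Markov chain sampler: one sequence of length n.
markov_seq <- function(n, start_p, trans_cum) {
  if (n == 0L) return("")
  idx <- integer(n)
  idx[1L] <- sample.int(4L, 1L, prob = start_p)
  if (n > 1L) {
    u <- stats::runif(n - 1L)
    for (i in 2L:n) {
      idx[i] <- findInterval(u[i - 1L], trans_cum[idx[i - 1L], ]) + 1L
    }
  }
  paste(NUC[idx], collapse = "")
}

#' Random sequences matched to target dinucleotide frequencies
#'
#' Generates new sequences from a first-order Markov chain whose transition
#' matrix is derived from the target dinucleotide frequency table (row-wise
#' normalization), with initial state drawn from the implied marginal.
#' Lengths are copied from \code{lengths} so the length distribution matches
#' the source set exactly.
#'
#' @param target_dinuc_freqs 4x4 dinucleotide frequency matrix
#'   (e.g. from \code{\link{dinucleotide_freqs}}).
#' @param lengths Integer vector of sequence lengths to generate.
#' @param seed Integer seed.
#' @param replicate_index Replicate label.
#' @return A \code{control_set} (kind \code{"dinuc_random"}).
#' @export
random_by_dinucleotide <- function(target_dinuc_freqs, lengths, seed,
                                   replicate_index = 1L) {
  f <- target_dinuc_freqs / sum(target_dinuc_freqs)
  marg <- rowSums(f)
  trans <- f / ifelse(rowSums(f) > 0, rowSums(f), 1)
  zero <- rowSums(f) == 0
  if (any(zero)) {
    warning("zero-probability row(s) in dinucleotide table; uniform fallback")
    trans[zero, ] <- 0.25
  }
  trans_cum <- t(apply(trans, 1L, cumsum))
  trans_cum[, 4L] <- 1  # guard rounding
  out <- with_seed(seed, vapply(lengths, markov_seq, character(1),
                                start_p = marg, trans_cum = trans_cum))
  new_control_set("dinuc_random", out, seed, replicate_index = replicate_index)
}

#' Random sequences from mononucleotide frequencies
#'
#' Zeroth-order analogue of \code{\link{random_by_dinucleotide}}: i.i.d.
#' bases at the target composition, lengths copied from \code{lengths}.
#'
#' @param target_nuc_freqs Named frequency vector over A,C,G,T.
#' @param lengths Integer vector of lengths.
#' @param seed Integer seed.
#' @param replicate_index Replicate label.
#' @return A \code{control_set} (kind \code{"mono_random"}).
#' @export
mono_random <- function(target_nuc_freqs, lengths, seed,
                        replicate_index = 1L) {
  p <- target_nuc_freqs[NUC] / sum(target_nuc_freqs)
  out <- with_seed(seed, {
    total <- sum(lengths)
    bases <- sample(NUC, total, replace = TRUE, prob = p)
    ends <- cumsum(lengths)
    starts <- ends - lengths + 1L
    vapply(seq_along(lengths), function(i) {
      if (lengths[i] == 0L) "" else
        paste(bases[starts[i]:ends[i]], collapse = "")
    }, character(1))
  })
  new_control_set("mono_random", out, seed, replicate_index = replicate_index)
}

#' Mutagenize sequences at a fixed per-position rate
#'
#' Each position is independently selected with probability \code{rate};
#' selected positions are resampled from \code{overall_nuc_freqs}.
#' Resampling may regenerate the original base, so the realized substitution
#' fraction is about \code{rate * (1 - sum(p^2))}; it is returned as
#' \code{effective_rate}.
#'
#' @param seqs Character vector.
#' @param rate Per-position resampling probability in [0, 1]; the
#'   mutagenesis series uses 0.1, 0.2 and 0.5.
#' @param overall_nuc_freqs Named frequency vector over A,C,G,T used for
#'   replacement draws.
#' @param seed Integer seed.
#' @param replicate_index Replicate label.
#' @return A \code{control_set} (kind \code{"mutagenized"}) with extra
#'   fields \code{effective_rate} (realized substituted fraction).
#' @export
mutagenize <- function(seqs, rate, overall_nuc_freqs, seed,
                       replicate_index = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  p <- overall_nuc_freqs[NUC] / sum(overall_nuc_freqs)
  n_sub <- 0L; n_tot <- 0L
  out <- with_seed(seed, vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    x <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- stats::runif(n) < rate
    if (any(hit)) {
      repl <- sample(NUC, sum(hit), replace = TRUE, prob = p)
      n_sub <<- n_sub + sum(repl != x[hit])
      x[hit] <- repl
    }
    n_tot <<- n_tot + n
    paste(x, collapse = "")
  }, character(1), USE.NAMES = FALSE))
  cs <- new_control_set("mutagenized", out, seed, rate = rate,
                        replicate_index = replicate_index)
  cs$effective_rate <- if (n_tot > 0) n_sub / n_tot else 0
  cs
}

#' Exact dinucleotide-preserving shuffle of each sequence
#'
#' Altschul–Erickson shuffling: each sequence is rewritten as a random
#' Eulerian walk over its own dinucleotide multigraph, preserving the exact
#' dinucleotide counts (and hence composition, length, first and last base)
#' of that sequence. Offered as the exact-shuffle alternative to the
#' generative \code{\link{random_by_dinucleotide}} mode.
#'
#' @param seqs Character vector.
#' @param seed Integer seed.
#' @param replicate_index Replicate label.
#' @return A \code{control_set} (kind \code{"dinuc_shuffle"}).
#' @export
dinucleotide_shuffle <- function(seqs, seed, replicate_index = 1L) {
  out <- with_seed(seed, vapply(seqs, shuffle_one_euler, character(1),
                                USE.NAMES = FALSE))
  new_control_set("dinuc_shuffle", out, seed,
                  replicate_index = replicate_index)
}

## One Altschul-Erickson shuffle. Edges out of each vertex are permuted,
## then the "last exit" edges are re-chosen to form an arborescence into the
## final vertex (guaranteeing the walk is Eulerian), by rejection.
shuffle_one_euler <- function(s) {
  n <- nchar(s)
  if (n <= 2L) return(s)
  x <- match(strsplit(s, "", fixed = TRUE)[[1L]], NUC)
  if (anyNA(x)) return(s)  # N-containing sequences returned unshuffled
  from <- x[-n]; to <- x[-1L]
  final <- x[n]
  adj <- lapply(1:4, function(v) to[from == v])
  present <- which(vapply(adj, length, integer(1)) > 0L | seq_len(4) == final)
  for (attempt in 1:200) {
    perm <- lapply(adj, function(e) if (length(e) > 1L) sample(e) else e)
    # walk greedily; Eulerian iff all edges consumed
    ptr <- rep(1L, 4)
    path <- integer(n); path[1L] <- x[1L]
    v <- x[1L]; ok <- TRUE
    for (i in 2:n) {
      if (ptr[v] > length(perm[[v]])) { ok <- FALSE; break }
      nxt <- perm[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      path[i] <- nxt
      v <- nxt
    }
    if (ok && all(ptr - 1L == vapply(perm, length, integer(1)))) {
      return(paste(NUC[path], collapse = ""))
    }
  }
  stop("Eulerian shuffle failed after 200 attempts (length ", n, ")")
}

#' Build replicate control sets
#'
#' Convenience wrapper producing \code{n_rep} replicates of one control
#' kind, with per-replicate seeds derived from a master seed by fixed
#' offsets.
#'
#' @param seqs Source sequences.
#' @param kind One of \code{"scramble"}, \code{"dinuc_random"},
#'   \code{"mono_random"}, \code{"mutagenized"}, \code{"dinuc_shuffle"}.
#' @param seed Master seed.
#' @param n_rep Number of replicates (default 3).
#' @param rate Mutagenesis rate (mutagenized only).
#' @return List of \code{control_set}s.
#' @export
control_replicates <- function(seqs, kind, seed, n_rep = 3L, rate = 0.1) {
  dn <- if (kind == "dinuc_random") dinucleotide_freqs(seqs)
  mn <- if (kind %in% c("mono_random", "mutagenized")) nucleotide_freqs(seqs)
  lens <- nchar(seqs)
  lapply(seq_len(n_rep), function(r) {
    s <- seed + 1000L * r
    switch(kind,
      scramble = scramble_each(seqs, s, r),
      dinuc_random = random_by_dinucleotide(dn, lens, s, r),
      mono_random = mono_random(mn, lens, s, r),
      mutagenized = mutagenize(seqs, rate, mn, s, r),
      dinuc_shuffle = dinucleotide_shuffle(seqs, s, r),
      stop("unknown control kind: ", kind))
  })
}

#' Write a control set as FASTA
#'
#' Headers encode kind, replicate and source index, e.g.
#' \code{scramble_rep1_seq00042}.
#'
#' @param cs A \code{control_set}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_control_fasta <- function(cs, path) {
  ss <- Biostrings::DNAStringSet(cs$sequences)
  names(ss) <- sprintf("%s_rep%d_seq%05d", cs$kind, cs$replicate_index,
                       seq_along(cs$sequences))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
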