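## Gaussian blur of a matrix (separable, reflected edges).
gauss_blur <- function(mat, bandwidth) {
  if (bandwidth <= 0) return(mat)
  half <- max(1L, ceiling(3 * bandwidth))
  k <- stats::dnorm(-half:half, sd = bandwidth)
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    idx <- seq_len(n)
    out <- numeric(n)
    for (j in -half:half) {
      src <- idx + j
      src[src < 1L] <- 1L - (src[src < 1L] - 1L)   # reflect
      src[src > n] <- 2L * n - src[src > n] + 1L
      out <- out + k[j + half + 1L] * v[src]
    }
    out
  }
  mat <- apply(mat, 2L, blur1)
  t(apply(mat, 1L, blur1))
}

#' Fit the two training density surfaces for the Bayes classifier
#'
#' Bins positive (high-BLASTP class-1) and negative (class-2) training
#' points on a shared 2D grid of exponentiated Kozak score \eqn{u = 2^K}
#' and \eqn{\log_{10}} length in codons, Gaussian-smooths each histogram,
#' adds a pseudocount floor, and normalizes to densities. The prior on
#' translation is fixed at 0.5 (an assumed 50:50 split of translated and
#' untranslated class-1 uORFs), so the posterior reduces to the density
#' ratio cell-wise.
#'
#' @param positive,negative Data frames (or 2-column matrices) with
#'   columns \code{K} (Kozak score, bits) and \code{L} (length, codons);
#'   each needs >= 20 points.
#' @param n_bins Grid resolution per axis (default 30).
#' @param bandwidth Gaussian smoothing bandwidth in cells (default 0.75;
#'   0 = raw histogram).
#' @param pseudocount Common density floor added per cell after
#'   normalization (then renormalized); default one pseudo-observation
#'   over the pooled training sets spread across the grid,
#'   \code{1/((n_pos + n_neg) * n_bins^2)}. A common floor makes cells
#'   with no training evidence return the prior.
#' @param prior Prior probability of translation (default 0.5).
#' @return Object of class \code{bayes_model}: \code{u_edges},
#'   \code{l_edges}, \code{pos_density}, \code{neg_density},
#'   \code{posterior_grid}, \code{prior}, \code{config}.
#' @export
fit_surfaces <- function(positive, negative, n_bins = 30L, bandwidth = 0.75,
                         pseudocount = NULL, prior = 0.5) {
  positive <- as.data.frame(positive); negative <- as.data.frame(negative)
  if (nrow(positive) < 20L || nrow(negative) < 20L) {
    stop("each training set needs >= 20 points")
  }
  tx <- function(df) data.frame(u = 2^df$K, l = log10(df$L))
  tp <- tx(positive); tn <- tx(negative)
  u_edges <- shared_edges(tp$u, tn$u, n_bins = n_bins)
  l_edges <- shared_edges(tp$l, tn$l, n_bins = n_bins)

  # common pseudocount floor on the normalized-density scale, so that grid
  # cells without training evidence return the prior rather than an
  # artifact of unequal training-set sizes
  pc <- if (is.null(pseudocount)) {
    1 / ((nrow(positive) + nrow(negative)) * n_bins^2)
  } else pseudocount
  surface <- function(t2) {
    iu <- findInterval(pmin(pmax(t2$u, u_edges[1L]), u_edges[n_bins + 1L]),
                       u_edges, rightmost.closed = TRUE, all.inside = TRUE)
    il <- findInterval(pmin(pmax(t2$l, l_edges[1L]), l_edges[n_bins + 1L]),
                       l_edges, rightmost.closed = TRUE, all.inside = TRUE)
    h <- matrix(0, n_bins, n_bins)
    for (i in seq_len(nrow(t2))) h[iu[i], il[i]] <- h[iu[i], il[i]] + 1
    h <- gauss_blur(h, bandwidth)
    (h / sum(h) + pc) / (1 + n_bins^2 * pc)
  }
  pos_d <- surface(tp)
  neg_d <- surface(tn)
  post <- (prior * pos_d) / (prior * pos_d + (1 - prior) * neg_d)
  structure(list(u_edges = u_edges, l_edges = l_edges,
                 pos_density = pos_d, neg_density = neg_d,
                 posterior_grid = post, prior = prior,
                 config = list(n_bins = n_bins, bandwidth = bandwidth,
                               pseudocount = pc,
                               n_pos = nrow(positive),
                               n_neg = nrow(negative))),
            class = "bayes_model")
}

#' Posterior translation probability for (K, L) points
#'
#' Maps each point into the model grid (clamping out-of-grid points to the
#' boundary cells so every uORF receives a probability) and reads off the
#' cell-wise density-ratio posterior.
#'
#' @param model A \code{bayes_model}.
#' @param K Kozak scores (bits).
#' @param L Lengths (codons).
#' @return Numeric vector of posterior probabilities in [0, 1].
#' @export
posterior_translated <- function(model, K, L) {
  n_bins <- model$config$n_bins
  u <- pmin(pmax(2^K, model$u_edges[1L]), model$u_edges[n_bins + 1L])
  l <- pmin(pmax(log10(L), model$l_edges[1L]), model$l_edges[n_bins + 1L])
  iu <- findInterval(u, model$u_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  il <- findInterval(l, model$l_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  model$posterior_grid[cbind(iu, il)]
}

#' ROC curve from positive and negative scores
#'
#' Sweeps the cutoff over all distinct score values, accumulating
#' (FPR, TPR) pairs from (0,0) to (1,1); AUC by the trapezoid rule. Ties
#' are handled by grouping equal scores into one step.
#'
#' @param scores_pos,scores_neg Numeric score vectors (higher = more
#'   positive).
#' @return Object of class \code{roc_curve}: data frame \code{points}
#'   (cutoff, fpr, tpr), \code{auc}.
#' @export
roc_curve <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("both score sets must be non-empty")
  }
  cuts <- sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) mean(scores_pos >= c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(scores_neg >= c), numeric(1))
  pts <- data.frame(cutoff = c(Inf, cuts), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  pts <- rbind(pts, data.frame(cutoff = -Inf, fpr = 1, tpr = 1))
  pts <- pts[!duplicated(pts[, c("fpr", "tpr")]), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' ROC of a fitted Bayes model on labelled (K, L) sets
#'
#' @param model A \code{bayes_model}.
#' @param positive,negative Data frames with columns \code{K}, \code{L}.
#' @return A \code{\link{roc_curve}} over the model's posterior scores.
#' @export
model_roc <- function(model, positive, negative) {
  roc_curve(posterior_translated(model, positive$K, positive$L),
            posterior_translated(model, negative$K, negative$L))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Per-uORF probability table
#'
#' Combines class-1 uORF records, Kozak scores, optional conservation
#' improvements, and Bayesian posteriors into the per-transcript summary
#' table written by the pipeline.
#'
#' @param records Class-1 records (from \code{\link{uorf_inventory}}).
#' @param kozak_scores Data frame \code{transcript_id}, \code{score}.
#' @param model A \code{bayes_model}.
#' @param improvements Optional data frame \code{transcript_id},
#'   \code{improvement}, \code{high_blastp}.
#' @return Data frame: transcript_id, atg_pos, length_codons, kozak_score,
#'   improvement, high_blastp, p_translated.
#' @export
uorf_probability_table <- function(records, kozak_scores, model,
                                   improvements = NULL) {
  c1 <- records[records$uorf_class == 1L, , drop = FALSE]
  df <- merge(c1[, c("transcript_id", "atg_pos", "length_codons")],
              kozak_scores[, c("transcript_id", "score")],
              by = "transcript_id")
  names(df)[names(df) == "score"] <- "kozak_score"
  if (!is.null(improvements)) {
    df <- merge(df, improvements[, c("transcript_id", "improvement",
                                     "high_blastp")],
                by = "transcript_id", all.x = TRUE)
  } else {
    df$improvement <- NA_real_; df$high_blastp <- NA
  }
  df$p_translated <- posterior_translated(model, df$kozak_score,
                                          pmax(df$length_codons, 1L))
  df[order(df$transcript_id), ]
}

#' Serialize a Bayes model as JSON
#'
#' @param model A \code{bayes_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_bayes_json <- function(model, path) {
  jsonlite::write_json(
    list(u_edges = model$u_edges, l_edges = model$l_edges,
         pos_density = model$pos_density, neg_density = model$neg_density,
         posterior = model$posterior_grid, prior = model$prior,
         config = model$config),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
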