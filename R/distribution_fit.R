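#' Histogram a sample on shared bin edges
#'
#' @param values Numeric vector.
#' @param edges Strictly increasing bin edges; values outside are clamped
#'   into the first/last bin so densities always sum to 1.
#' @return List of class \code{hist1d}: \code{edges}, \code{counts},
#'   \code{density} (normalized to sum 1), \code{n}.
#' @export
hist1d <- function(values, edges) {
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  if (length(values) == 0L) stop("empty sample")
  v <- pmin(pmax(values, edges[1L]), edges[length(edges)])
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  structure(list(edges = edges, counts = counts,
                 density = counts / sum(counts), n = length(values)),
            class = "hist1d")
}

#' Shared equal-width bin edges over pooled samples
#'
#' @param ... Numeric vectors pooled to define the range.
#' @param n_bins Number of bins (default 40).
#' @return Numeric vector of \code{n_bins + 1} edges.
#' @export
shared_edges <- function(..., n_bins = 40L) {
  pooled <- unlist(list(...))
  r <- range(pooled, finite = TRUE)
  if (r[1L] == r[2L]) r <- r + c(-0.5, 0.5)
  seq(r[1L], r[2L], length.out = n_bins + 1L)
}

#' Gaussian smoothing of a binned density vector
#'
#' Kernel smoothing in bin units with reflected edges. Because smoothing is
#' linear, applying the same kernel to the two basis vectors and the target
#' of a mixture projection leaves the true mixture weights unchanged while
#' reducing the sampling noise in empirical bases (which otherwise
#' attenuates fitted weights).
#'
#' @param density Numeric vector (histogram density or counts).
#' @param bandwidth Kernel standard deviation in bins.
#' @return Smoothed vector of the same sum.
#' @export
smooth_density <- function(density, bandwidth = 2) {
  if (bandwidth <= 0) return(density)
  half <- max(1L, ceiling(3 * bandwidth))
  k <- stats::dnorm(-half:half, sd = bandwidth)
  k <- k / sum(k)
  n <- length(density)
  idx <- seq_len(n)
  out <- numeric(n)
  for (j in -half:half) {
    src <- idx + j
    src[src < 1L] <- 1L - (src[src < 1L] - 1L)   # reflect
    src[src > n] <- 2L * n - src[src > n] + 1L
    out <- out + k[j + half + 1L] * density[src]
  }
  out
}

#' Least-squares mixture projection of a distribution onto two bases
#'
#' Solves the normal equations for the unconstrained least-squares weights
#' \eqn{(c_1, c_2)} such that \eqn{c_1 b_1 + c_2 b_2 \approx t}:
#' \eqn{c = (A^T A)^{-1} A^T t} with \eqn{A = [b_1\; b_2]}. Weights are not
#' constrained to the simplex (set \code{constrained = TRUE} for a bounded
#' fit used in sensitivity analyses). The proportion of variance explained
#' is computed about the target mean.
#'
#' @param basis1,basis2 Density (or count) vectors on identical bins.
#' @param target Density vector on the same bins.
#' @param constrained If \code{TRUE}, weights are optimized within [0,1]^2.
#' @return Object of class \code{mixture_fit}: \code{weights} (c1, c2),
#'   \code{fitted}, \code{pve}, \code{condition_number}, \code{n_bins},
#'   \code{constrained}.
#' @export
project_mixture <- function(basis1, basis2, target, constrained = FALSE) {
  if (length(basis1) != length(basis2) ||
      length(basis1) != length(target)) {
    stop("basis and target vectors must share binning")
  }
  A <- cbind(b1 = basis1, b2 = basis2)
  kappa_A <- kappa(A, exact = TRUE)
  if (!is.finite(kappa_A) || kappa_A > 1e10) {
    stop("collinear bases: condition number ", format(kappa_A))
  }
  if (constrained) {
    obj <- function(c12) sum((A %*% c12 - target)^2)
    fit <- stats::optim(c(0.5, 0.5), obj, method = "L-BFGS-B",
                        lower = c(0, 0), upper = c(1, 1))
    cc <- fit$par
  } else {
    cc <- drop(solve(crossprod(A), crossprod(A, target)))
  }
  fitted <- drop(A %*% cc)
  ss_res <- sum((target - fitted)^2)
  ss_tot <- sum((target - mean(target))^2)
  pve <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  out <- structure(list(weights = stats::setNames(cc, c("c1", "c2")),
                        fitted = fitted, pve = pve,
                        condition_number = kappa_A,
                        n_bins = length(target),
                        constrained = constrained),
                   class = "mixture_fit")
  if (!constrained && (any(cc < 0) || any(cc > 1))) {
    out$outside_simplex <- TRUE
  }
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("mixture fit: c1 = %.4f, c2 = %.4f, PVE = %.4f (%d bins%s)\n",
              x$weights[["c1"]], x$weights[["c2"]], x$pve, x$n_bins,
              if (isTRUE(x$outside_simplex)) "; weights outside [0,1]" else ""))
  invisible(x)
}

#' Poisson-error comparison of two category counts
#'
#' Treats each count as Poisson with standard deviation \eqn{\sqrt{n}} and
#' compares them by the normal-approximation z statistic
#' \eqn{z = (a - b)/\sqrt{a + b}}, two-sided. Significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @param count_a,count_b Non-negative counts.
#' @return List: \code{z}, \code{p}, \code{stars}.
#' @export
poisson_count_test <- function(count_a, count_b) {
  stopifnot(count_a >= 0, count_b >= 0)
  if (count_a + count_b == 0) {
    return(list(z = 0, p = 1, stars = ""))
  }
  z <- (count_a - count_b) / sqrt(count_a + count_b)
  p <- 2 * stats::pnorm(-abs(z))
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(z = z, p = p, stars = stars)
}

#' Welch unequal-variance t test
#'
#' Thin wrapper over \code{stats::t.test} with explicit handling of
#' degenerate (zero-variance) inputs, where the Welch statistic is
#' undefined: identical constant samples give p = 1; otherwise the tie is
#' resolved by direction of the mean difference (p = 0 or 1 for one-sided
#' alternatives, 0 for two-sided).
#'
#' @param scores_a,scores_b Numeric vectors, each of length >= 2.
#' @param alternative \code{"two.sided"}, \code{"less"} or
#'   \code{"greater"} (a vs b).
#' @return List: \code{statistic}, \code{p}, \code{mean_a}, \code{mean_b}.
#' @export
welch_t <- function(scores_a, scores_b,
                    alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(scores_a) >= 2L, length(scores_b) >= 2L)
  ma <- mean(scores_a); mb <- mean(scores_b)
  if (stats::var(scores_a) == 0 && stats::var(scores_b) == 0) {
    d <- ma - mb
    p <- if (d == 0) 1 else switch(alternative,
      two.sided = 0,
      less = if (d < 0) 0 else 1,
      greater = if (d > 0) 0 else 1)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf, p = p,
                mean_a = ma, mean_b = mb))
  }
  tt <- stats::t.test(scores_a, scores_b, alternative = alternative,
                      var.equal = FALSE)
  list(statistic = unname(tt$statistic), p = tt$p.value,
       mean_a = ma, mean_b = mb)
}

#' Empirical cumulative distribution for plotting
#'
#' @param values Non-empty numeric vector.
#' @return Data frame with \code{x} (sorted values) and \code{cum}
#'   (cumulative proportion, reaching 1 at the maximum).
#' @export
cumulative_curve <- function(values) {
  if (length(values) == 0L) stop("empty sample")
  x <- sort(values)
  data.frame(x = x, cum = seq_along(x) / length(x))
}

#' Divergence point of two empirical CDFs
#'
#' Finds the smallest x at which the absolute difference of the two
#' empirical CDFs first exceeds \code{threshold}, and reports the CDF level
#' (fraction of sample 1 at or below that point). Used to locate where a
#' real score distribution peels away from its scrambled control.
#'
#' @param values1,values2 Numeric vectors.
#' @param threshold CDF-difference threshold (default 0.02).
#' @return List: \code{x} (divergence abscissa, NA if never exceeded),
#'   \code{fraction} (CDF of sample 1 at the divergence point),
#'   \code{threshold}.
#' @export
cdf_divergence <- function(values1, values2, threshold = 0.02) {
  grid <- sort(unique(c(values1, values2)))
  f1 <- stats::ecdf(values1)(grid)
  f2 <- stats::ecdf(values2)(grid)
  over <- which(abs(f1 - f2) > threshold)
  if (length(over) == 0L) {
    return(list(x = NA_real_, fraction = NA_real_, threshold = threshold))
  }
  i <- over[1L]
  list(x = grid[i], fraction = f1[i], threshold = threshold)
}
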