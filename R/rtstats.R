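#' Screen reaction times for outliers
#'
#' Removes reaction times below 100 ms or above the sample mean plus three
#' standard deviations. Mean and SD are computed on the full input sample
#' in a single pass; the rule is not iterated.
#'
#' @param rts Numeric vector of reaction times in ms (nonempty).
#' @param floor_ms Lower cutoff in ms (default 100).
#' @param sd_mult Upper cutoff multiplier (default 3: mean + 3 SD).
#' @return A list with `kept` and `removed` (both numeric vectors) and the
#'   applied `ceiling` value.
#' @examples
#' screen_outliers(c(90, 300, 310))
#' @export
screen_outliers <- function(rts, floor_ms = 100, sd_mult = 3) {
  if (length(rts) == 0) stop("empty reaction-time sample")
  m <- mean(rts)
  s <- stats::sd(rts)
  if (is.na(s)) s <- 0  # single observation
  ceiling_ms <- m + sd_mult * s
  keep <- rts >= floor_ms & rts <= ceiling_ms
  list(kept = rts[keep], removed = rts[!keep], ceiling = ceiling_ms)
}

#' Empirical reaction-time quantiles
#'
#' Linear interpolation of the order statistics (the standard
#' `type = 7` estimator), guaranteed nondecreasing in `p`.
#'
#' @param rts Numeric vector, length >= `length(probs)`.
#' @param probs Probabilities strictly inside (0, 1).
#' @return Named numeric vector of quantiles.
#' @export
rt_quantiles <- function(rts, probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie strictly in (0, 1)")
  if (length(rts) < length(probs))
    stop("sample smaller than the number of requested quantiles")
  stats::quantile(rts, probs = probs, type = 7, names = TRUE)
}

#' Delta plot of a congruency effect
#'
#' Computes quantile-wise differences between the incongruent and congruent
#' reaction-time distributions, plotted against the pairwise quantile
#' means, together with the orthogonal-polynomial coefficients `c0` (level),
#' `c1` (slope) and `c2` (curvature) of the difference-vs-mean curve.
#'
#' @param congruent,incongruent Numeric vectors of correct-response RTs
#'   (ms), each at least as long as `probs`.
#' @param probs Quantile probabilities.
#' @return An object of class `"delta_plot"`: a list with `probs`, `deltas`
#'   (incongruent - congruent, ms), `means` (pairwise quantile means, ms),
#'   and coefficients `c0`, `c1`, `c2` (all `NA` with fewer than three
#'   quantiles).
#' @examples
#' set.seed(1)
#' dp <- delta_plot(rnorm(500, 400, 50), rnorm(500, 425, 55))
#' dp$c1
#' @export
delta_plot <- function(congruent, incongruent,
                       probs = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  qc <- rt_quantiles(congruent, probs)
  qi <- rt_quantiles(incongruent, probs)
  deltas <- unname(qi - qc)
  means <- unname((qi + qc) / 2)
  coefs <- if (length(probs) >= 3) {
    fit_orthogonal_polys(means, deltas, max_order = 2)$coefficients
  } else c(c0 = NA_real_, c1 = NA_real_, c2 = NA_real_)
  out <- list(probs = probs, deltas = deltas, means = means,
              c0 = unname(coefs[1]), c1 = unname(coefs[2]),
              c2 = unname(coefs[3]))
  class(out) <- "delta_plot"
  out
}

#' @export
print.delta_plot <- function(x, ...) {
  cat("<delta_plot>\n")
  print(data.frame(p = x$probs, mean_ms = round(x$means, 1),
                   delta_ms = round(x$deltas, 2)))
  cat(sprintf("  c0 = %.3f  c1 = %.3f  c2 = %.3f\n", x$c0, x$c1, x$c2))
  invisible(x)
}

#' Orthogonal-polynomial coefficients on arbitrarily spaced points
#'
#' Builds an orthonormal polynomial basis on the (generally unequally
#' spaced) abscissae `x` by the three-term recurrence, and returns the
#' coefficients of `y` in that basis: the inner products of `y` with the
#' degree-0, 1, 2, ... basis polynomials. The basis is normalized to unit
#' Euclidean norm, so `c0 = mean(y) * sqrt(n)` and the reconstruction
#' `sum_j c_j * phi_j(x)` equals the least-squares polynomial fit of degree
#' `max_order`.
#'
#' @param x Abscissae, length >= `max_order + 1`, not all equal.
#' @param y Ordinates, same length as `x`.
#' @param max_order Highest polynomial degree (default 2).
#' @return A list with `coefficients` (named `c0`, `c1`, ...), `basis` (an
#'   `n x (max_order+1)` matrix of orthonormal basis values), and `fitted`
#'   (the reconstruction).
#' @export
fit_orthogonal_polys <- function(x, y, max_order = 2) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < max_order + 1) stop("need at least max_order + 1 points")
  if (length(unique(x)) < max_order + 1)
    stop("degenerate abscissae: fewer than max_order + 1 distinct x values")
  basis <- matrix(0, n, max_order + 1)
  basis[, 1] <- 1 / sqrt(n)
  if (max_order >= 1) {
    for (j in 2:(max_order + 1)) {
      v <- x * basis[, j - 1]
      # subtract projections on all previous basis vectors (modified
      # Gram-Schmidt over the full history for numerical safety; for
      # polynomials only the last two projections are nonzero in exact
      # arithmetic)
      for (i in 1:(j - 1)) v <- v - sum(v * basis[, i]) * basis[, i]
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12 * sqrt(sum((x * basis[, j - 1])^2)))
        stop("collinear abscissae: cannot build degree ", j - 1, " basis")
      basis[, j] <- v / nv
    }
  }
  coefs <- drop(crossprod(basis, y))
  names(coefs) <- paste0("c", 0:max_order)
  list(coefficients = coefs, basis = basis,
       fitted = drop(basis %*% coefs))
}

#' Robust scale estimate from pairwise absolute differences
#'
#' Qn-type estimator: the k-th order statistic of the n(n-1)/2 pairwise
#' absolute differences, with `k = choose(h, 2)`, `h = floor(n/2) + 1`,
#' multiplied by the consistency constant 2.2219 (for the normal
#' distribution, without finite-sample correction). Translation invariant
#' and scale equivariant; zero only when all values coincide.
#'
#' @param x Numeric vector, length >= 2.
#' @param constant Consistency constant (default 2.2219).
#' @return The scale estimate (same units as `x`).
#' @examples
#' robust_scale(c(1, 2, 3))  # 1 * 2.2219
#' @export
robust_scale <- function(x, constant = 2.2219) {
  n <- length(x)
  if (n < 2) stop("robust_scale needs at least 2 observations")
  d <- abs(outer(x, x, "-"))
  d <- d[lower.tri(d)]
  h <- floor(n / 2) + 1
  k <- choose(h, 2)
  constant * sort(d, partial = k)[k]
}

#' Pool reaction-time samples across participants
#'
#' Aligns each participant's distribution in location and scale before
#' combining: participant i's reaction time x_ij becomes
#' `y_ij = m. + (x_ij - m_i) * q. / q_i`, where `m_i` is the participant
#' mean, `q_i` the participant's robust scale ([robust_scale()]), and
#' `m.`, `q.` are the means of those individual values. The pooled sample
#' keeps every trial (no quantile averaging), preserves each participant's
#' within-sample rank order, and has grand mean exactly `m.`.
#'
#' @param samples A named list of numeric vectors, one per participant,
#'   each with at least 2 correct-response RTs (ms).
#' @return An object of class `"pooling_summary"`: a list with `m_i`, `q_i`
#'   (per-participant vectors), `m_dot`, `q_dot`, `pooled` (all transformed
#'   RTs in input order) and `transformed` (the per-participant list).
#' @examples
#' pool_participants(list(a = c(300, 350, 400), b = c(500, 560, 620)))
#' @export
pool_participants <- function(samples) {
  if (!is.list(samples) || length(samples) < 1)
    stop("samples must be a nonempty list of numeric vectors")
  if (is.null(names(samples)))
    names(samples) <- paste0("P", seq_along(samples))
  if (any(vapply(samples, length, 1L) < 2))
    stop("every participant needs at least 2 reaction times")
  m_i <- vapply(samples, mean, numeric(1))
  q_i <- vapply(samples, robust_scale, numeric(1))
  zero <- q_i == 0
  if (any(zero))
    stop("zero robust scale for participant(s): ",
         paste(names(samples)[zero], collapse = ", "))
  m_dot <- mean(m_i)
  q_dot <- mean(q_i)
  transformed <- Map(function(x, m, q) m_dot + (x - m) * q_dot / q,
                     samples, m_i, q_i)
  out <- list(m_i = m_i, q_i = q_i, m_dot = m_dot, q_dot = q_dot,
              pooled = unlist(transformed, use.names = FALSE),
              transformed = transformed)
  class(out) <- "pooling_summary"
  out
}

#' @export
print.pooling_summary <- function(x, ...) {
  cat(sprintf("<pooling_summary> %d participants, %d pooled trials, m. = %.1f ms, q. = %.1f ms\n",
              length(x$m_i), length(x$pooled), x$m_dot, x$q_dot))
  invisible(x)
}
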