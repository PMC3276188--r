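#' Maximum-likelihood Poisson intensity of a recombination spectrum
#'
#' The Poisson intensity lambda — the expected number of recombinations
#' accumulated per transmitted lineage since founding — is estimated by its
#' MLE, the mean of the spectrum: lambda_hat = sum(k * n_k) / n.
#'
#' @param spectrum a [recomb_spectrum()] or a plain vector of counts for
#'   k = 0, 1, ...
#' @return The intensity estimate (numeric scalar).
#' @examples
#' fit_lambda(c(1030, 382, 74, 14))  # 0.3813...
#' @export
fit_lambda <- function(spectrum) {
  sp <- as_spectrum(spectrum)
  sum(sp$k * sp$counts) / sp$n
}

as_spectrum <- function(x) {
  if (inherits(x, "recomb_spectrum")) x else recomb_spectrum(x)
}

#' Normal-approximation confidence interval for the Poisson intensity
#'
#' By asymptotic normality of the MLE (Slutsky's theorem), a level-(1 - alpha)
#' interval is lambda_hat -/+ u_{alpha/2} * sqrt(lambda_hat / n), where
#' u_{alpha/2} is the standard-normal fractile. The lower bound is floored
#' at 0.
#'
#' @param lambda_hat fitted intensity.
#' @param n number of haplotypes behind the estimate.
#' @param alpha risk level in (0, 1); default 0.05.
#' @return Numeric vector `c(low, high)`.
#' @export
lambda_ci <- function(lambda_hat, n, alpha = 0.05) {
  if (n <= 0) stop("'n' must be positive")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single value in (0, 1)")
  if (lambda_hat < 0) stop("'lambda_hat' must be non-negative")
  u <- stats::qnorm(1 - alpha / 2)
  half <- u * sqrt(lambda_hat / n)
  c(low = max(0, lambda_hat - half), high = lambda_hat + half)
}

#' Fit the Poisson intensity with its confidence interval
#'
#' Convenience wrapper combining [fit_lambda()] and [lambda_ci()].
#'
#' @inheritParams fit_lambda
#' @inheritParams lambda_ci
#' @return Object of class `poisson_fit` with `lambda_hat`, `n`, `ci_low`,
#'   `ci_high`, `alpha`.
#' @examples
#' poisson_fit(recomb_spectrum(c(1030, 382, 74, 14)))
#' @export
poisson_fit <- function(spectrum, alpha = 0.05) {
  sp <- as_spectrum(spectrum)
  lam <- fit_lambda(sp)
  ci <- lambda_ci(lam, sp$n, alpha)
  structure(list(lambda_hat = lam, n = sp$n,
                 ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                 alpha = alpha, spectrum = sp),
            class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf(
    "Poisson intensity: lambda_hat = %.3f (%d%% CI %.3f-%.3f), n = %d\n",
    x$lambda_hat, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Expected class counts under a Poisson intensity
#'
#' Expected number of haplotypes with k recombinations out of n, i.e.
#' n * exp(-lambda) * lambda^k / k!. With `tail = "open"` the final entry is
#' the open-ended bin n * P(K >= k_max), so the vector sums exactly to n.
#'
#' @param lambda Poisson intensity (>= 0).
#' @param n number of haplotypes.
#' @param k_max largest class reported.
#' @param tail "none" for pure point probabilities at k = 0..k_max, "open"
#'   to close with the tail bin at k_max.
#' @return Numeric vector of length k_max + 1.
#' @examples
#' round(expected_counts(0.381, 1500, 5), 2)
#' # 1024.77 390.44 74.38 9.45 0.90 0.07
#' @export
expected_counts <- function(lambda, n, k_max, tail = c("none", "open")) {
  tail <- match.arg(tail)
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (n <= 0) stop("'n' must be positive")
  if (k_max < 0) stop("'k_max' must be non-negative")
  if (tail == "none") {
    n * stats::dpois(0:k_max, lambda)
  } else if (k_max == 0) {
    n
  } else {
    c(n * stats::dpois(0:(k_max - 1), lambda),
      n * stats::ppois(k_max - 1, lambda, lower.tail = FALSE))
  }
}

#' Merge sparse tail bins for the chi-squared test
#'
#' The Pearson test requires every expected bin count to reach
#' `min_expected` (classically 5). Bins are merged from the upper tail
#' downward: the last bin absorbs k-classes until its expected total reaches
#' the threshold and every remaining lower bin is individually above it; the
#' final bin is open-ended (K >= k_last). Observed and expected totals are
#' preserved.
#'
#' @param observed observed counts for k = 0, 1, ...
#' @param expected expected counts, same length.
#' @param min_expected threshold (default 5).
#' @return data.frame with columns `k_lo`, `k_hi` (Inf for the open tail
#'   bin when merging occurred), `observed`, `expected`.
#' @export
merge_bins <- function(observed, expected, min_expected = 5) {
  if (length(observed) != length(expected))
    stop("'observed' and 'expected' must have the same length")
  if (min_expected < 0) stop("'min_expected' must be non-negative")
  K <- length(expected)
  if (sum(expected) < min_expected)
    stop("total expected count ", format(sum(expected)),
         " is below 'min_expected'; cannot form a valid bin")
  # smallest tail merge such that the merged tail and all lower bins pass
  cut <- K
  repeat {
    tail_ok <- sum(expected[cut:K]) >= min_expected
    below_ok <- cut == 1L || all(expected[seq_len(cut - 1L)] >= min_expected)
    if (tail_ok && below_ok) break
    cut <- cut - 1L
  }
  if (cut == K) {
    data.frame(k_lo = 0:(K - 1), k_hi = 0:(K - 1),
               observed = observed, expected = expected)
  } else {
    data.frame(
      k_lo = 0:(cut - 1),
      k_hi = c(seq_len(cut - 1L) - 1, Inf),
      observed = c(observed[seq_len(cut - 1L)], sum(observed[cut:K])),
      expected = c(expected[seq_len(cut - 1L)], sum(expected[cut:K])))
  }
}

#' Chi-squared goodness of fit of the spectrum to a Poisson distribution
#'
#' Tests whether the recombination-count spectrum is consistent with a
#' Poisson distribution. Expected counts are computed over the observed
#' k-range with an open-ended final bin (so they total n), sparse tail bins
#' are merged via [merge_bins()], and the Pearson statistic is referred to a
#' chi-squared distribution with df = (number of bins) - 2: one lost for the
#' fixed total and one for the estimated intensity.
#'
#' @param spectrum a [recomb_spectrum()] or counts vector.
#' @param lambda intensity to test against; `NULL` (default) fits the MLE
#'   from the spectrum. df uses bins - 2 in both modes.
#' @param min_expected bin-merging threshold (default 5).
#' @return Object of class `gof_result` with `statistic`, `df`, `p_value`,
#'   `merged_bins`, `lambda` and `lambda_fitted`.
#' @examples
#' gof_test(c(1030, 382, 74, 14))  # statistic ~1.44, df 2, p ~0.49
#' @export
gof_test <- function(spectrum, lambda = NULL, min_expected = 5) {
  sp <- as_spectrum(spectrum)
  fitted <- is.null(lambda)
  if (fitted) lambda <- fit_lambda(sp)
  if (lambda < 0) stop("'lambda' must be non-negative")
  kmax <- max(sp$k)
  expected <- expected_counts(lambda, sp$n, kmax, tail = "open")
  bins <- merge_bins(sp$counts, expected, min_expected)
  bins$k_hi[nrow(bins)] <- Inf  # expected was built with an open tail
  df <- nrow(bins) - 2L
  if (df <= 0L)
    stop("spectrum too coarse after bin merging (", nrow(bins),
         " bin(s)): no degrees of freedom left for the test")
  statistic <- sum((bins$observed - bins$expected)^2 / bins$expected)
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 merged_bins = bins, lambda = lambda, lambda_fitted = fitted,
                 min_expected = min_expected),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf(
    "Poisson goodness of fit: chi-squared = %.3f, df = %d, p = %.3f\n",
    x$statistic, x$df, x$p_value))
  cat(sprintf("  lambda = %.4f (%s), bins:\n", x$lambda,
              if (x$lambda_fitted) "fitted" else "fixed"))
  b <- x$merged_bins
  lab <- ifelse(is.finite(b$k_hi) & b$k_hi == b$k_lo, b$k_lo,
                paste0(">=", b$k_lo))
  print(data.frame(k = lab, observed = b$observed,
                   expected = round(b$expected, 2)), row.names = FALSE)
  invisible(x)
}

#' Per-generation recombination rate from the accumulated intensity
#'
#' The intensity counts recombinations accumulated over
#' G = elapsed_years / generation_time generations, so the per-generation
#' rate is lambda_hat / G.
#'
#' @param lambda_hat accumulated intensity (>= 0).
#' @param elapsed_years time since the founding event, in years.
#' @param generation_time mean generation time in years (may be a vector to
#'   explore several assumptions).
#' @return Rate(s) per generation, same length as `generation_time`.
#' @examples
#' per_generation_rate(0.381, 400, c(4, 8))  # ~0.0038, ~0.0076
#' @export
per_generation_rate <- function(lambda_hat, elapsed_years, generation_time) {
  if (lambda_hat < 0) stop("'lambda_hat' must be non-negative")
  if (elapsed_years <= 0 || any(generation_time <= 0))
    stop("'elapsed_years' and 'generation_time' must be positive")
  lambda_hat / (elapsed_years / generation_time)
}

#' Correct a detectable rate for founder homozygosity
#'
#' Crossovers occurring in animals homozygous for a founder haplotype (or in
#' regions where the two haplotypes share alleles) produce no detectable
#' mosaic, so the parsimony-based rate underestimates the total rate. Dividing
#' by the heterozygote frequency recovers an estimate of all recombination
#' events, detectable or not.
#'
#' @param rate detectable per-generation rate.
#' @param het_freq frequency of heterozygotes, in (0, 1].
#' @return Corrected rate(s).
#' @examples
#' homozygosity_correction(0.0038, 0.90)
#' @export
homozygosity_correction <- function(rate, het_freq) {
  if (any(rate < 0)) stop("'rate' must be non-negative")
  if (length(het_freq) != 1L || het_freq <= 0 || het_freq > 1)
    stop("'het_freq' must be a single value in (0, 1]")
  rate / het_freq
}

#' Per-generation rate estimates across generation-time assumptions
#'
#' Combines [per_generation_rate()] and [homozygosity_correction()] for a
#' fitted intensity, propagating the confidence bounds.
#'
#' @param fit a [poisson_fit()].
#' @param elapsed_years years since founding (default 400).
#' @param generation_times vector of generation times in years (default 4, 8).
#' @param het_freq heterozygote frequency for the correction (default 0.90).
#' @return data.frame with one row per generation time: `generation_time`,
#'   `generations`, `rate` (detectable), `rate_low`, `rate_high` (CI bounds
#'   scaled the same way) and `rate_corrected`.
#' @export
estimate_rates <- function(fit, elapsed_years = 400,
                           generation_times = c(4, 8), het_freq = 0.90) {
  stopifnot(inherits(fit, "poisson_fit"))
  g <- elapsed_years / generation_times
  rate <- per_generation_rate(fit$lambda_hat, elapsed_years, generation_times)
  data.frame(
    generation_time = generation_times,
    generations = g,
    rate = rate,
    rate_low = fit$ci_low / g,
    rate_high = fit$ci_high / g,
    rate_corrected = homozygosity_correction(rate, het_freq))
}
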