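# Shuffle-based null distribution of alignment scores, Gumbel moment fit,
# tail p-values and the four-way outcome classification.

.euler_gamma <- 0.57721566490153286

#' Null alignment scores by sequence shuffling
#'
#' Estimates the null distribution of alignment scores for unrelated
#' sequences of the same base composition: on each of `n` iterations both
#' input strings are independently permuted (composition-preserving), one
#' offset is drawn uniformly from all enumerable offsets, and that offset is
#' scored under the chosen scheme.
#'
#' @inheritParams rank_offsets
#' @param n Number of shuffle iterations (default 2000).
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @return Numeric vector of `n` null scores.
#' @export
#' @examples
#' s <- shuffle_null_scores("ACGTACGTAC", "TGCATGCATG", n = 100, seed = 1)
#' length(s)
shuffle_null_scores <- function(fwd, rev, scheme = "ambiguity_corrected",
                                n = 2000L, seed, min_overlap = 1L) {
  scheme <- match_scheme(scheme)
  if (missing(seed)) abort("`seed` is required: the null draw must be reproducible.")
  stopifnot(n >= 2)
  fm <- as_mask(fwd, "fwd")
  rm <- as_mask(rev, "rev")
  offs <- enumerate_offsets(length(fm), length(rm), min_overlap)
  if (length(offs) == 0L) abort("No offset reaches the requested minimum overlap.")
  withr::with_seed(as.integer(seed), {
    vapply(seq_len(n), function(k) {
      fs <- fm[sample.int(length(fm))]
      rs <- rm[sample.int(length(rm))]
      o <- offs[sample.int(length(offs), 1L)]
      score_one(fs, rs, o, scheme)$score
    }, numeric(1))
  })
}

#' Fit a Gumbel distribution to null scores by moment matching
#'
#' The distribution of optimal ungapped alignment scores between random
#' sequences is classically extreme-value type I (Gumbel). The fit matches
#' moments: scale `beta = sd * sqrt(6) / pi`, location
#' `mu = mean - gamma * beta` with `gamma` the Euler–Mascheroni constant.
#'
#' @param samples Numeric vector of at least two null scores with nonzero
#'   variance (see [shuffle_null_scores()]).
#' @return An object of class `"gumbel_fit"`: a list with `mu`, `beta`,
#'   `sample_mean`, `sample_sd`, `n_samples` and the samples themselves.
#' @export
#' @examples
#' fit <- fit_gumbel(rnorm(500))
#' tidy(fit)
fit_gumbel <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) abort("At least two null scores are required.")
  m <- mean(samples)
  s <- sd(samples)
  if (!is.finite(s) || s == 0) abort("Degenerate null (constant scores): cannot fit a Gumbel distribution.")
  beta <- s * sqrt(6) / pi
  structure(
    list(mu = m - .euler_gamma * beta, beta = beta,
         sample_mean = m, sample_sd = s,
         n_samples = length(samples), samples = samples),
    class = "gumbel_fit")
}

#' @export
print.gumbel_fit <- function(x, ...) {
  cat(sprintf("Gumbel null fit (moment-matched, n = %d)\n", x$n_samples))
  cat(sprintf("  location mu = %.4f, scale beta = %.4f\n", x$mu, x$beta))
  cat(sprintf("  sample mean = %.4f, sd = %.4f\n", x$sample_mean, x$sample_sd))
  invisible(x)
}

#' @export
tidy.gumbel_fit <- function(x, ...) {
  tibble(term = c("mu", "beta"), estimate = c(x$mu, x$beta))
}

#' @export
glance.gumbel_fit <- function(x, ...) {
  tibble(mu = x$mu, beta = x$beta, sample_mean = x$sample_mean,
         sample_sd = x$sample_sd, n_samples = x$n_samples)
}

#' Gumbel upper-tail probability of an alignment score
#'
#' The probability, under the fitted null, of observing a score higher than
#' the one given: `1 - exp(-exp(-(score - mu)/beta))`. Strictly decreasing in
#' the score; used as the p-value of an offset.
#'
#' @param fit A [fit_gumbel()] object.
#' @param score Numeric vector of scores.
#' @return Numeric vector of tail probabilities in (0, 1).
#' @export
#' @examples
#' fit <- fit_gumbel(c(0, 1, 2, 1, 0.5))
#' tail_p(fit, fit$mu) # 1 - exp(-1)
tail_p <- function(fit, score) {
  stopifnot(inherits(fit, "gumbel_fit"))
  -expm1(-exp(-(score - fit$mu) / fit$beta))
}

#' Classify the offset-score distribution into the four outcomes
#'
#' Annotates every ranked offset with its Gumbel tail p-value and counts the
#' significant outliers at a Bonferroni-corrected threshold
#' `alpha / n_offsets`. The count determines the biological reading:
#'
#' * 0 outliers — `no_signal`: forward and reverse do not align better than
#'   random sequences of the same composition (probably mismatched inputs);
#' * 1 — `single_offset`: a homozygote, or a heterozygote without an indel;
#' * 2 — `two_offsets`: the expected outcome for a length-variant
#'   heterozygote, whose two haplotypes can now be reconstructed;
#' * more — `multi_template`: more than two templates in the mixture
#'   (copy-number variation, contamination, PCR recombination, ...).
#'
#' @param ranked A [rank_offsets()] tibble.
#' @param fit A [fit_gumbel()] object for the matching scheme.
#' @param alpha Familywise significance level before Bonferroni correction.
#' @return An object of class `"offset_outcome"`: list with `category`,
#'   `n_outliers`, `significant_offsets`, the annotated `offsets` tibble,
#'   `alpha`, `p_threshold` and the `fit`.
#' @export
classify_outliers <- function(ranked, fit, alpha = 0.05) {
  stopifnot(inherits(fit, "gumbel_fit"), nrow(ranked) >= 1, alpha > 0, alpha < 1)
  ranked$p_value <- tail_p(fit, ranked$score)
  thr <- alpha / nrow(ranked)
  sig <- ranked[ranked$p_value < thr, ]
  n <- nrow(sig)
  category <- if (n == 0L) "no_signal" else if (n == 1L) "single_offset"
    else if (n == 2L) "two_offsets" else "multi_template"
  structure(
    list(category = category, n_outliers = n,
         significant_offsets = sig, offsets = ranked,
         alpha = alpha, p_threshold = thr, fit = fit),
    class = "offset_outcome")
}

#' @export
print.offset_outcome <- function(x, ...) {
  cat(sprintf("Offset significance: %d outlier(s) at p < %.3g -> %s\n",
              x$n_outliers, x$p_threshold, x$category))
  if (x$n_outliers > 0) {
    print(as_tibble(x$significant_offsets))
  }
  invisible(x)
}

#' Binned null-score histogram with fitted density and tail curves
#'
#' Tidies the shuffle null for plotting or export: one row per histogram bin
#' with the observed count and, at the bin midpoint, the fitted Gumbel
#' density and upper-tail probability.
#'
#' @param fit A [fit_gumbel()] object (carries its samples).
#' @param bins Number of histogram bins.
#' @return A tibble with columns `mid`, `lower`, `upper`, `count`, `density`,
#'   `fit_density`, `fit_tail`.
#' @export
null_histogram <- function(fit, bins = 30L) {
  stopifnot(inherits(fit, "gumbel_fit"))
  h <- graphics::hist(fit$samples, breaks = bins, plot = FALSE)
  z <- (h$mids - fit$mu) / fit$beta
  tibble(
    mid = h$mids, lower = h$breaks[-length(h$breaks)], upper = h$breaks[-1],
    count = h$counts, density = h$density,
    fit_density = exp(-z - exp(-z)) / fit$beta,
    fit_tail = -expm1(-exp(-z)))
}
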