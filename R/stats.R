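#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the z-transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe-Glynn 1983) into the K-squared statistic, referred to a
#' chi-squared distribution with 2 degrees of freedom. The skewness
#' transform is undefined below n = 8, so at least 8 observations are
#' required.
#'
#' @param x Numeric vector, `length(x) >= 8`.
#' @return Tibble with `statistic` (K-squared), `p.value`, `z_skew`,
#'   `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) abort("the omnibus normality test requires at least 8 values.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) abort("zero variance; normality test undefined.")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  a <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / a + sqrt((y / a)^2 + 1))

  # kurtosis z (Anscombe-Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a2 <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z_kurt <- ((1 - 2 / (9 * a2)) -
               ((1 - 2 / a2) / (1 + xk * sqrt(2 / (a2 - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a2))

  k2 <- z_skew^2 + z_kurt^2
  tibble::tibble(statistic = k2, p.value = 1 - pchisq(k2, df = 2),
                 z_skew = z_skew, z_kurt = z_kurt, n = n)
}

#' Paired effect sizes
#'
#' `cohens_d_paired()` is the mean paired difference divided by the SD of
#' the differences. `cles()` is the common-language effect size: the
#' fraction of pairs with `early > late`, ties counted one half.
#'
#' @param early,late Paired numeric vectors.
#' @return A single number.
#' @export
cohens_d_paired <- function(early, late) {
  d <- early - late
  mean(d) / sd(d)
}

#' @rdname cohens_d_paired
#' @export
cles <- function(early, late) {
  mean((early > late) + 0.5 * (early == late))
}

#' Early-versus-late paired comparison
#'
#' The block-adaptation contrast: subject summaries from early blocks (1-2)
#' are compared against late blocks (5-6) with a paired test whose type is
#' gated on a D'Agostino-Pearson normality test of the paired differences
#' at the 0.05 level: a paired t-test with Cohen's d when the differences
#' look normal, a Wilcoxon signed-rank test with the common-language effect
#' size otherwise. Identical samples (all differences zero) are reported as
#' a degenerate null result (p = 1, CLES 0.5).
#'
#' @param early,late Paired per-subject summaries (same length, `n >= 8`).
#' @param normality_alpha Gate level for the normality test (default 0.05).
#' @return One-row tibble: `test`, `statistic`, `p.value`, `effect_size`,
#'   `effect_name`, `normality_p`, `n`.
#' @export
early_late_comparison <- function(early, late, normality_alpha = 0.05) {
  early <- as.numeric(early); late <- as.numeric(late)
  if (length(early) != length(late)) abort("`early` and `late` must be paired.")
  n <- length(early)
  d <- early - late
  if (all(d == 0)) {
    return(tibble::tibble(test = "wilcoxon", statistic = NA_real_,
                          p.value = 1, effect_size = 0.5,
                          effect_name = "cles", normality_p = NA_real_,
                          n = n))
  }
  norm <- dagostino_pearson(d)
  if (norm$p.value > normality_alpha) {
    ht <- t.test(early, late, paired = TRUE)
    tibble::tibble(test = "paired_t", statistic = unname(ht$statistic),
                   p.value = ht$p.value,
                   effect_size = cohens_d_paired(early, late),
                   effect_name = "cohens_d", normality_p = norm$p.value,
                   n = n)
  } else {
    ht <- suppressWarnings(wilcox.test(early, late, paired = TRUE,
                                       exact = FALSE, correct = TRUE))
    tibble::tibble(test = "wilcoxon", statistic = unname(ht$statistic),
                   p.value = ht$p.value,
                   effect_size = cles(early, late),
                   effect_name = "cles", normality_p = norm$p.value, n = n)
  }
}

#' Per-subject early/late block summaries from a session log
#'
#' Pools a subject's trials and summarizes early (1-2) and late (5-6)
#' blocks with the mean or median, gated on a normality test of the trial
#' distribution when `n >= 8` trials are available (means for normal-looking
#' samples, medians otherwise); the chosen statistic is recorded.
#'
#' @param log A `session_log`.
#' @param value Column of the trials table to summarize (default `"mae"`).
#' @param early_blocks,late_blocks Block indices (defaults 1-2 and 5-6).
#' @return One-row tibble with `early`, `late`, and `summary_stat`.
#' @export
early_late_summary <- function(log, value = "mae", early_blocks = c(1L, 2L),
                               late_blocks = c(5L, 6L)) {
  trials <- log$trials
  v <- trials[[value]]
  stat <- "median"
  if (length(v) >= 8L && var(v) > 0 &&
      dagostino_pearson(v)$p.value > 0.05) {
    stat <- "mean"
  }
  f <- if (stat == "mean") mean else median
  tibble::tibble(
    early = f(v[trials$block %in% early_blocks]),
    late = f(v[trials$block %in% late_blocks]),
    summary_stat = stat
  )
}

#' Correlation between offline accuracy and real-time performance
#'
#' Pearson correlation between per-subject offline multivariate R-squared
#' and per-subject average real-time MAE, with a two-sided p-value and a
#' percentile bootstrap confidence interval (1,000 iterations by default).
#'
#' @param offline_r2 Per-subject offline reconstruction accuracies.
#' @param realtime_mae Per-subject average real-time MAEs (same order).
#' @param n_boot Bootstrap iterations.
#' @param conf_level Confidence level (default 0.95).
#' @param seed Seed for the bootstrap resampling.
#' @return One-row tibble: `r`, `p.value`, `conf.low`, `conf.high`, `n`.
#' @export
offline_realtime_correlation <- function(offline_r2, realtime_mae,
                                         n_boot = 1000, conf_level = 0.95,
                                         seed = 1) {
  x <- as.numeric(offline_r2); y <- as.numeric(realtime_mae)
  if (length(x) != length(y) || length(x) < 3L) {
    abort("need at least 3 paired values.")
  }
  if (var(x) == 0 || var(y) == 0) abort("zero variance in the inputs.")
  ht <- cor.test(x, y, method = "pearson")
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(x), replace = TRUE)
      if (var(x[idx]) == 0 || var(y[idx]) == 0) return(NA_real_)
      stats::cor(x[idx], y[idx])
    }, numeric(1L))
  })
  qs <- quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                 na.rm = TRUE, names = FALSE)
  tibble::tibble(r = unname(ht$estimate), p.value = ht$p.value,
                 conf.low = qs[1L], conf.high = qs[2L], n = length(x))
}
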