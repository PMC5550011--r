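# Resampling statistics: nonparametric bootstrap hypothesis tests,
# percentile confidence intervals, Holm-Bonferroni adjustment and the
# common-language effect size.

# Residuals scaled to unbias the bootstrap variance: resampling from n
# values underestimates the sampling variance of the mean by (n-1)/n, which
# makes the plain recentred bootstrap anticonservative in small samples.
.null_sample <- function(x, center) {
  n <- length(x)
  center + (x - mean(x)) * if (n > 1) sqrt(n / (n - 1)) else 1
}

# Bootstrap means of a sample, computed in chunks to bound memory.
.boot_means <- function(x, B) {
  n <- length(x)
  chunk <- max(1L, min(B, floor(5e6 / n)))
  out <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    m <- matrix(x[sample.int(n, n * b, replace = TRUE)], nrow = b)
    out[done + seq_len(b)] <- rowMeans(m)
    done <- done + b
  }
  out
}

#' Nonparametric bootstrap hypothesis test on means
#'
#' Resampling test of a mean (one-sample), a difference of means
#' (two-sample) or a mean paired difference. The null distribution is built
#' by resampling data shifted to satisfy the null: the one-sample variant
#' recenters the sample on the null value; the two-sample variant recenters
#' both groups on the pooled mean (`null_method = "recenter"`, the default)
#' or permutes group labels (`null_method = "permutation"`). Recentred
#' residuals are scaled by sqrt(n / (n - 1)) so the bootstrap variance of
#' the mean is unbiased; without this the test is anticonservative in small
#' samples. The p-value is
#' the proportion of null statistics at least as extreme as the observed
#' one: two-tailed compares absolute values; one-tailed counts extremeness
#' in the direction of the observed effect.
#'
#' @param a numeric sample.
#' @param b second sample (two-sample, paired) or `NULL` (one-sample).
#' @param kind `"two_sample"`, `"one_sample"` or `"paired"`.
#' @param null_value null mean (one-sample) or null mean difference
#'   (paired); default 0.
#' @param tails `"two"` or `"one"`.
#' @param n_resamples bootstrap replicates (default 1e6, matching the
#'   analyses this implements; reduce for speed).
#' @param seed integer seed; results are reproducible for a fixed seed.
#' @param null_method two-sample null construction: `"recenter"` or
#'   `"permutation"`.
#' @param ci_resamples replicates for the percentile CI of the observed
#'   statistic (resampled from the uncentred data).
#' @return Object of class `bootstrap_result`: `p_value`, `statistic`
#'   (observed mean / mean difference), `ci_95`, `n_resamples`, `tails`,
#'   `kind`, `seed`.
#' @examples
#' bootstrap_test(rnorm(20, 1), kind = "one_sample", n_resamples = 2000,
#'                seed = 7)
#' @export
bootstrap_test <- function(a, b = NULL,
                           kind = c("two_sample", "one_sample", "paired"),
                           null_value = 0,
                           tails = c("two", "one"),
                           n_resamples = 1e6, seed = 1L,
                           null_method = c("recenter", "permutation"),
                           ci_resamples = 1e4) {
  kind <- match.arg(kind)
  tails <- match.arg(tails)
  null_method <- match.arg(null_method)
  stopifnot(is.numeric(a), length(a) >= 1L)
  if (kind != "one_sample") {
    stopifnot(is.numeric(b), length(b) >= 1L)
    if (kind == "paired" && length(a) != length(b))
      stop("paired test requires equal-length samples")
  }
  if (n_resamples < 1000)
    warning("fewer than 1000 resamples gives unstable p-values")
  B <- as.integer(n_resamples)

  if (kind == "paired") {
    a <- a - b
    b <- NULL
    kind <- "one_sample"
  }

  res <- withr::with_seed(seed, {
    if (kind == "one_sample") {
      obs <- mean(a) - null_value
      null_boot <- .boot_means(.null_sample(a, null_value), B) - null_value
      ci <- stats::quantile(.boot_means(a, min(B, ci_resamples)),
                            c(0.025, 0.975), names = FALSE)
      list(obs = obs, boot = null_boot, ci = ci)
    } else {
      obs <- mean(a) - mean(b)
      if (null_method == "recenter") {
        g <- mean(c(a, b))
        boot <- .boot_means(.null_sample(a, g), B) -
          .boot_means(.null_sample(b, g), B)
      } else {
        pool <- c(a, b)
        na <- length(a)
        boot <- vapply(seq_len(B), function(i) {
          idx <- sample.int(length(pool), na)
          mean(pool[idx]) - mean(pool[-idx])
        }, numeric(1L))
      }
      Bc <- min(B, ci_resamples)
      ci <- stats::quantile(.boot_means(a, Bc) - .boot_means(b, Bc),
                            c(0.025, 0.975), names = FALSE)
      list(obs = obs, boot = boot, ci = ci)
    }
  })

  eps <- 1e-12
  p <- if (tails == "two") {
    mean(abs(res$boot) >= abs(res$obs) - eps)
  } else if (res$obs >= 0) {
    mean(res$boot >= res$obs - eps)
  } else {
    mean(res$boot <= res$obs + eps)
  }
  structure(list(p_value = p, statistic = res$obs, ci_95 = res$ci,
                 n_resamples = B, tails = tails, kind = kind, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap %s test (%s-tailed, %d resamples): statistic = %.4g, p = %.4g\n",
    x$kind, x$tails, x$n_resamples, x$statistic, x$p_value))
  cat(sprintf("95%% percentile CI of the statistic: [%.4g, %.4g]\n",
              x$ci_95[1L], x$ci_95[2L]))
  invisible(x)
}

#' Holm-Bonferroni adjusted p-values
#'
#' Step-down multiple-comparison adjustment; output order matches input
#' order. Delegates to [stats::p.adjust()].
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, each at least the raw value, capped at 1.
#' @export
holm_bonferroni <- function(p_values) {
  stopifnot(is.numeric(p_values), all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm")
}

#' Common-language effect size
#'
#' Percentage of cross-sample pairs (x from `a`, y from `b`) with x > y,
#' counting ties as half. Exact pairwise enumeration when the number of
#' pairs is at most 1e7, else seeded Monte Carlo.
#'
#' @param a,b numeric samples.
#' @param n_mc Monte Carlo pairs when enumeration is infeasible.
#' @param seed seed for the Monte Carlo path.
#' @return Effect size as a percentage in `[0, 100]`.
#' @examples
#' common_language_effect(c(1, 2, 3), c(2, 3, 4)) # 33.33: 2 wins + 2 ties / 9
#' @export
common_language_effect <- function(a, b, n_mc = 1e6, seed = 1L) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 1L, length(b) >= 1L)
  if (as.double(length(a)) * length(b) <= 1e7) {
    d <- outer(a, b, "-")
    100 * (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
  } else {
    withr::with_seed(seed, {
      x <- a[sample.int(length(a), n_mc, replace = TRUE)]
      y <- b[sample.int(length(b), n_mc, replace = TRUE)]
    })
    100 * (sum(x > y) + 0.5 * sum(x == y)) / n_mc
  }
}

#' Bootstrap percentile confidence interval for a mean
#'
#' @param x numeric sample of size at least 2.
#' @param level confidence level in percent (default 95).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param keep_resamples attach the resampled means as attribute
#'   `"resamples"`.
#' @return Named numeric `c(lower, upper)` with attribute `"level"`.
#' @export
percentile_ci <- function(x, level = 95, n_boot = 1e4, seed = 1L,
                          keep_resamples = FALSE) {
  stopifnot(is.numeric(x), length(x) >= 2L, level > 0, level < 100)
  means <- withr::with_seed(seed, .boot_means(x, as.integer(n_boot)))
  alpha <- (100 - level) / 200
  out <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  names(out) <- c("lower", "upper")
  attr(out, "level") <- level
  if (keep_resamples) attr(out, "resamples") <- means
  out
}
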