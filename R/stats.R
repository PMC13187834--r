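# Closed-form two-sample statistics. Welch's t handles the degenerate
# zero-variance case that arises for rare mutation classes; the
# Mann-Whitney U uses the exact null distribution for small samples.

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided, with Welch-Satterthwaite degrees of freedom. When both
#' groups have zero variance the test is degenerate: equal constants give
#' p = 1, unequal constants give p = 0, and the `degenerate` flag is set.
#' Groups with fewer than two observations give NA.
#'
#' @param x,y numeric vectors (per-isolate counts of one mutation class).
#' @return one-row tibble: `statistic`, `df`, `p_value`, `mean_x`,
#'   `mean_y`, `degenerate`.
#' @export
welch_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  if (n1 < 2 || n2 < 2) {
    return(tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                  mean_x = m1, mean_y = m2, degenerate = FALSE))
  }
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    equal <- isTRUE(all.equal(m1, m2))
    return(tibble(statistic = if (equal) 0 else sign(m1 - m2) * Inf,
                  df = NA_real_,
                  p_value = if (equal) 1 else 0,
                  mean_x = m1, mean_y = m2, degenerate = TRUE))
  }
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tibble(statistic = tstat, df = df,
         p_value = 2 * stats::pt(-abs(tstat), df),
         mean_x = m1, mean_y = m2, degenerate = FALSE)
}

#' Two-sided Mann-Whitney U test
#'
#' Uses the exact null distribution of U when the combined sample size is
#' at most `exact_limit` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors.
#' @param exact_limit largest combined n for which the exact distribution
#'   is used (default 20).
#' @return one-row tibble: `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 20) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("both groups must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && (n1 + n2) <= exact_limit) {
    p <- if (u > n1 * n2 / 2) {
      2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n1, n2)
    }
    method <- "exact"
  } else {
    z <- u - n1 * n2 / 2
    sigma <- sqrt((n1 * n2 / 12) *
                    ((n1 + n2 + 1) -
                       sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))))
    z <- (z - sign(z) * 0.5) / sigma  # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  tibble(statistic = u, p_value = min(1, p), method = method)
}
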