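#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' For small samples (both `n <= exact_max`) the null distribution of U is
#' obtained by exhaustive enumeration of all group assignments of the
#' pooled values, so ties are handled exactly; otherwise the tie-corrected
#' normal approximation with continuity correction is used. The two-tailed
#' p-value is `2 * min(P(U <= u), P(U >= u))`, capped at 1.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_max largest per-group size at which exact enumeration is
#'   used (default 8).
#' @return A list with `statistic` (U of `x`), `p_two_tailed`, `method`,
#'   `n` (c(n_x, n_y)).
#' @examples
#' mann_whitney_test(c(1, 2), c(3, 4))$p_two_tailed # 1/3
#' @export
mann_whitney_test <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n, n1)
    u_null <- colSums(matrix(rk[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_null <= u_obs + eps), mean(u_null >= u_obs - eps))
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) return(list(statistic = u_obs, p_two_tailed = 1,
                               method = "degenerate", n = c(n1, n2)))
    z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = u_obs, p_two_tailed = min(1, p), method = method,
       n = c(n1, n2))
}

#' Two-tailed Wilcoxon signed-rank test
#'
#' Paired-sample rank test on the differences `x - y` (or on `x` directly
#' when `y` is `NULL`). Zero differences are dropped, following the
#' classical treatment. For `n <= exact_max` non-zero pairs the null
#' distribution of the positive-rank sum W is enumerated over all `2^n`
#' sign patterns (midranks make this exact under ties); otherwise the
#' tie-corrected normal approximation with continuity correction is used.
#' If every difference is zero the result is `p = 1` with `n_pairs = 0` and
#' a warning.
#'
#' @param x numeric vector of first measurements, or differences.
#' @param y optional paired second measurements.
#' @param exact_max largest number of non-zero pairs at which enumeration
#'   is used (default 15).
#' @return A list with `n_pairs` (non-zero pairs used), `statistic` (W, the
#'   positive-rank sum), `p_two_tailed`, `method`.
#' @examples
#' wilcoxon_signed_rank_test(c(1, 2, 3))$p_two_tailed # 0.25
#' @export
wilcoxon_signed_rank_test <- function(x, y = NULL, exact_max = 15) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    x - y
  }
  if (!length(d)) stop("no pairs supplied")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero")
    return(list(n_pairs = 0L, statistic = 0, p_two_tailed = 1,
                method = "degenerate"))
  }
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  if (n <= exact_max) {
    w_null <- vapply(0:(2^n - 1), function(mask) {
      sum(rk[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0])
    }, 1.0)
    eps <- 1e-9
    p <- 2 * min(mean(w_null <= w_obs + eps), mean(w_null >= w_obs - eps))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(n_pairs = n, statistic = w_obs, p_two_tailed = min(1, p),
       method = method)
}

#' Pairwise group comparison with Bonferroni correction
#'
#' Runs a two-tailed Mann-Whitney U test ([mann_whitney_test()]) for every
#' pair of groups and applies a Bonferroni correction
#' (`p_adjusted = min(1, p * n_comparisons)`).
#'
#' @param values_by_group a named list of at least two numeric vectors.
#' @param n_comparisons number of comparisons for the Bonferroni factor;
#'   defaults to the number of pairs tested.
#' @return A data frame of class `group_comparison` with one row per pair:
#'   `group_a, group_b, n_a, n_b, median_a, median_b, statistic,
#'   p_two_tailed, p_adjusted`.
#' @export
compare_groups <- function(values_by_group, n_comparisons = NULL) {
  if (length(values_by_group) < 2) stop("need at least two groups")
  if (is.null(names(values_by_group)))
    names(values_by_group) <- paste0("group", seq_along(values_by_group))
  if (any(!vapply(values_by_group, length, 1L)))
    stop("every group must contain at least one value")
  pairs <- utils::combn(names(values_by_group), 2)
  if (is.null(n_comparisons)) n_comparisons <- ncol(pairs)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values_by_group[[pairs[1, i]]]
    b <- values_by_group[[pairs[2, i]]]
    mw <- mann_whitney_test(a, b)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               n_a = length(a), n_b = length(b),
               median_a = stats::median(a), median_b = stats::median(b),
               statistic = mw$statistic, p_two_tailed = mw$p_two_tailed,
               p_adjusted = min(1, mw$p_two_tailed * n_comparisons),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("group_comparison", "data.frame"))
}
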