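# Nonparametric rank tests with fully specified small-sample behaviour.
# Self-contained so that the exact-p regime, tie handling and the continuity
# correction are pinned down rather than inherited from another library.

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test for a location difference between two independent samples.
#' The U statistic is computed from midranks. When both samples are free of
#' ties and the smaller sample has at most `exact_threshold` observations,
#' the p value is exact: the null distribution of U is built by the standard
#' counting recursion over all \eqn{\binom{n+m}{n}} labelings. Otherwise a
#' normal approximation with tie correction and (by default) a continuity
#' correction is used.
#'
#' The two-sided exact p value is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#' When every value in the two samples is identical the test is degenerate
#' and `p = 1` by convention.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param exact_threshold Largest `min(length(x), length(y))` for which the
#'   exact enumeration is used (default 8); ties always force the
#'   approximation.
#' @param correct Apply the continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return An object of class `"rank_test"`: a list with `statistic` (U for
#'   the first sample), `p.value`, `method` (`"exact"` or `"normal_approx"`),
#'   `n_per_group`, and `test` (`"mann_whitney_u"`).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 8L, correct = TRUE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n <- length(x); m <- length(y)
  combined <- c(x, y)
  if (length(unique(combined)) == 1L) {
    return(new_rank_test(n * m / 2, 1, "degenerate", c(n, m),
                         "mann_whitney_u"))
  }
  r <- rank(combined)                       # midranks
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2 # U for x
  has_ties <- anyDuplicated(combined) > 0L
  if (!has_ties && min(n, m) <= exact_threshold) {
    counts <- u_null_counts(n, m)           # counts of U = 0..nm
    total <- sum(counts)
    p_le <- sum(counts[seq_len(u + 1)]) / total
    p_ge <- sum(counts[(u + 1):(n * m + 1)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- n + m
    tie_tab <- table(combined)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- n * m / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) return(new_rank_test(u, 1, "degenerate", c(n, m),
                                          "mann_whitney_u"))
    z <- u - n * m / 2
    if (correct) z <- sign(z) * max(0, abs(z) - 0.5)
    p <- min(1, 2 * pnorm(-abs(z) / sqrt(sigma2)))
    method <- "normal_approx"
  }
  new_rank_test(u, p, method, c(n, m), "mann_whitney_u")
}

# Null distribution of U for sample sizes n, m without ties: counts[u + 1] is
# the number of labelings (out of choose(n + m, n)) with statistic u.
# Lattice-path dynamic program: walk the combined order from smallest to
# largest, at each step appending either an x (which adds the number of y's
# already placed to U) or a y.
u_null_counts <- function(n, m) {
  len <- n * m + 1
  zero <- numeric(len)
  dp <- vector("list", n + 1)
  for (i in 0:n) dp[[i + 1]] <- vector("list", m + 1)
  start <- zero; start[1] <- 1
  dp[[1]][[1]] <- start
  for (i in 0:n) {
    for (j in 0:m) {
      if (i == 0 && j == 0) next
      v <- zero
      if (i > 0) {                        # last element placed was an x
        prev <- dp[[i]][[j + 1]]
        if (j > 0) v[(j + 1):len] <- v[(j + 1):len] + prev[1:(len - j)]
        else v <- v + prev
      }
      if (j > 0) v <- v + dp[[i + 1]][[j]]  # last element placed was a y
      dp[[i + 1]][[j + 1]] <- v
    }
  }
  dp[[n + 1]][[m + 1]]
}

#' Kruskal-Wallis rank test
#'
#' One-way rank-based test across `k >= 2` groups. The H statistic uses
#' midranks and the standard tie correction; the p value comes from the
#' chi-square distribution with `k - 1` degrees of freedom. If every value
#' in every group is identical, `H = 0` and `p = 1`.
#'
#' @param groups A list of at least two non-empty numeric vectors.
#' @return A `"rank_test"` object with `statistic` (H), `p.value`,
#'   `method = "chisq_approx"`, `n_per_group`, and `test = "kruskal_wallis"`.
#' @examples
#' kruskal_wallis(list(rnorm(8), rnorm(8), rnorm(8) + 2))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty")
  values <- as.numeric(unlist(groups, use.names = FALSE))
  if (anyNA(values)) stop("samples must not contain NA")
  N <- length(values)
  r <- rank(values)
  grp <- rep(seq_along(groups), sizes)
  rank_sums <- tapply(r, grp, sum)
  h <- 12 / (N * (N + 1)) * sum(rank_sums^2 / sizes) - 3 * (N + 1)
  tie_tab <- table(values)
  cor_fac <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  if (cor_fac <= 0) {
    h <- 0; p <- 1
  } else {
    h <- h / cor_fac
    h <- max(h, 0)                         # guard tiny negative rounding
    p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  }
  new_rank_test(h, p, "chisq_approx", as.integer(sizes), "kruskal_wallis")
}

#' Conservative p value (max rule)
#'
#' Returns the numerically greatest of a set of pairwise p values — the
#' reporting convention for experiments compared against two genetic
#' controls, where only the least significant comparison is quoted.
#'
#' @param pairwise_ps Non-empty numeric vector of p values in (0, 1].
#' @return The maximum p value.
#' @export
conservative_p <- function(pairwise_ps) {
  pairwise_ps <- as.numeric(pairwise_ps)
  if (length(pairwise_ps) == 0L) stop("need at least one p value")
  if (anyNA(pairwise_ps) || any(pairwise_ps <= 0) || any(pairwise_ps > 1))
    stop("p values must lie in (0, 1]")
  max(pairwise_ps)
}

#' Mean and standard error of the mean
#'
#' @param values Numeric vector, `n >= 1`.
#' @return Named numeric vector `c(mean = , sem = )`; `sem` is the sample
#'   standard deviation (n - 1 denominator) divided by `sqrt(n)`, and is `NA`
#'   when `n = 1`.
#' @examples
#' mean_sem(c(0, 2))  # mean 1, sem 1
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) return(c(mean = NA_real_, sem = NA_real_))
  c(mean = mean(values),
    sem = if (n == 1L) NA_real_ else sd(values) / sqrt(n))
}

new_rank_test <- function(statistic, p, method, sizes, test) {
  structure(list(statistic = as.numeric(statistic),
                 p.value = as.numeric(p),
                 method = method,
                 n_per_group = as.integer(sizes),
                 test = test),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  lab <- switch(x$test, mann_whitney_u = "Mann-Whitney U",
                kruskal_wallis = "Kruskal-Wallis H", x$test)
  cat(sprintf("%s test (%s)\n", lab, x$method))
  cat(sprintf("  statistic = %g, p = %.4g, n = [%s]\n",
              x$statistic, x$p.value,
              paste(x$n_per_group, collapse = ", ")))
  invisible(x)
}
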