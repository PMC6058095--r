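# Effect sizes and rank-based significance tests for open-ocean vs
# coastal nitrogen-content contrasts.

#' Relative difference in mean nitrogen content
#'
#' `100 * (mean_open - mean_coastal) / mean_coastal`, in percent;
#' negative when the open-ocean group is nitrogen-poorer.
#'
#' @param mean_open,mean_coastal group means (Nc units);
#'   `mean_coastal > 0`.
#' @return Percent relative difference.
#' @export
relative_difference <- function(mean_open, mean_coastal) {
  if (mean_coastal == 0) stop("coastal mean is zero; relative difference undefined")
  100 * (mean_open - mean_coastal) / mean_coastal
}

#' Standard error of the mean
#'
#' Sample standard deviation (n-1 denominator) over the square root of
#' the sample size.
#'
#' @param values numeric vector, `n >= 2`.
#' @return SEM.
#' @export
sem <- function(values) {
  n <- length(values)
  if (n < 2L) stop("sem() needs at least 2 values")
  sd(values) / sqrt(n)
}

# Rank-sum statistic of x within the pooled sample (midranks for ties).
.rank_sum <- function(x, y) sum(rank(c(x, y))[seq_along(x)])

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum test with three inference methods:
#' * `exact`: full enumeration of the `choose(m+n, m)` assignments of
#'   pooled (mid)ranks to the first group; intended for combined
#'   `n <= 20` (without ties it reproduces the classical exact test).
#' * `normal_approx`: standard normal approximation with tie correction
#'   and continuity correction.
#' * `monte_carlo`: label permutation of the rank-sum statistic;
#'   `p = (1 + #extreme) / (1 + n_permutations)` (add-one estimator,
#'   never exactly zero).
#'
#' Alternatives are relative to the first sample: `"less"` tests for a
#' downward location shift of `x`.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"less"`, `"greater"` or `"two_sided"`.
#' @param method `"exact"`, `"normal_approx"` or `"monte_carlo"`.
#' @param n_permutations Monte-Carlo permutation count; default 10000.
#' @param seed optional seed for the Monte-Carlo draw.
#' @return List with `statistic` (rank sum of `x`), `p_value`, `method`,
#'   `alternative`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("less", "greater", "two_sided"),
                              method = c("exact", "normal_approx",
                                         "monte_carlo"),
                              n_permutations = 10000, seed = NULL) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  w <- sum(r[seq_len(m)])
  p <- switch(method,
    exact = {
      if (N > 20L)
        stop("exact enumeration restricted to combined n <= 20")
      sums <- combn(N, m, function(ix) sum(r[ix]))
      eps <- 1e-9
      switch(alternative,
        less = mean(sums <= w + eps),
        greater = mean(sums >= w - eps),
        two_sided = {
          mu <- m * (N + 1) / 2
          mean(abs(sums - mu) >= abs(w - mu) - eps)
        })
    },
    normal_approx = {
      mu <- m * (N + 1) / 2
      ties <- table(r)
      sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      if (sigma2 <= 0) return(list(statistic = w, p_value = 1,
                                   method = method,
                                   alternative = alternative))
      s <- sqrt(sigma2)
      switch(alternative,
        less = pnorm((w - mu + 0.5) / s),
        greater = pnorm((w - mu - 0.5) / s, lower.tail = FALSE),
        two_sided = {
          z <- (abs(w - mu) - 0.5) / s
          2 * pnorm(max(z, 0), lower.tail = FALSE)
        })
    },
    monte_carlo = {
      B <- as.integer(n_permutations)
      mu <- m * (N + 1) / 2
      perm <- with_seed(seed, {
        vapply(seq_len(B), function(b) sum(sample(r, m)), numeric(1))
      })
      eps <- 1e-9
      extreme <- switch(alternative,
        less = sum(perm <= w + eps),
        greater = sum(perm >= w - eps),
        two_sided = sum(abs(perm - mu) >= abs(w - mu) - eps))
      (1 + extreme) / (1 + B)
    })
  list(statistic = w, p_value = min(p, 1), method = method,
       alternative = alternative)
}

#' Open-ocean vs coastal group comparison
#'
#' The test unit is the per-sequence nitrogen content (possibly masked
#' to a topological domain or rate class upstream). The default
#' alternative is one-sided, "open ocean is nitrogen-poorer than
#' coastal"; the two-sided variant serves pathway-wide scans.
#'
#' @param values data frame with columns `nc` and `habitat`
#'   (`open_ocean` / `coastal`), at least 2 sequences per group.
#' @param stratum label describing the stratum compared.
#' @param alternative,method,n_permutations,seed see
#'   [wilcoxon_rank_sum()].
#' @param n_sites optional number of sites behind a masked Nc (reported,
#'   not used in the test).
#' @return One-row data frame of class `"group_comparison"`: `stratum`,
#'   `N_open`, `N_coastal`, `mean_open`, `mean_coastal`, `sem_open`,
#'   `sem_coastal`, `rel_diff_percent`, `p_value`, `test`,
#'   `alternative`, `n_sites`.
#' @export
compare_groups <- function(values, stratum = "all",
                           alternative = "less", method = "normal_approx",
                           n_permutations = 10000, seed = NULL,
                           n_sites = NA_integer_) {
  stopifnot(is.data.frame(values), all(c("nc", "habitat") %in% names(values)))
  x <- values$nc[values$habitat == "open_ocean"]
  y <- values$nc[values$habitat == "coastal"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least 2 sequences per habitat group in stratum '",
         stratum, "'")
  test <- wilcoxon_rank_sum(x, y, alternative = alternative, method = method,
                            n_permutations = n_permutations, seed = seed)
  structure(data.frame(
    stratum = stratum, N_open = length(x), N_coastal = length(y),
    mean_open = mean(x), mean_coastal = mean(y),
    sem_open = sem(x), sem_coastal = sem(y),
    rel_diff_percent = relative_difference(mean(x), mean(y)),
    p_value = test$p_value, test = method, alternative = alternative,
    n_sites = n_sites, row.names = NULL),
    class = c("group_comparison", "data.frame"))
}
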