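#' Exact rank tests with ties (Mann-Whitney-Wilcoxon and signed-rank)
#'
#' Permutation-exact p-values for the two-sample Mann-Whitney-Wilcoxon rank
#' sum test (`paired = FALSE`) and the one-sample / paired Wilcoxon
#' signed-rank test (`paired = TRUE`). Ties are handled with midranks, and
#' the null distribution is computed exactly, conditional on the observed
#' (mid)rank configuration, by a counted-shift convolution over all
#' `choose(n, nx)` group labelings (rank sum) or all `2^n` sign assignments
#' (signed rank). Doubled midranks keep the convolution on integers.
#'
#' One-tailed alternatives are with respect to `x`: `"greater"` means `x`
#' tends to exceed `y` (or paired differences tend to be positive);
#' `"two.sided"` doubles the smaller tail (capped at 1). Zero paired
#' differences are dropped; if all differences are zero the p-value is 1
#' with a warning.
#'
#' @param x Numeric sample (or paired differences when `paired = TRUE` and
#'   `y` is `NULL`).
#' @param y Second sample (unpaired) or paired counterpart of `x`.
#' @param alternative `"two.sided"`, `"less"`, or `"greater"`.
#' @param paired Signed-rank test on `x - y` (or on `x` directly).
#' @return List of class `herv_rank_test`: `p_value`, `statistic` (rank sum
#'   of `x` / positive-rank sum, on the midrank scale), `alternative`,
#'   `method`, `n`.
#' @export
#' @examples
#' exact_rank_test(c(1, 2), c(3, 4), alternative = "less")$p_value  # 1/6
#' exact_rank_test(c(1, 2, 3), paired = TRUE,
#'                 alternative = "greater")$p_value                 # 1/8
exact_rank_test <- function(x, y = NULL,
                            alternative = c("two.sided", "less", "greater"),
                            paired = FALSE) {
  alternative <- match.arg(alternative)
  if (paired) {
    d <- if (is.null(y)) x else {
      stopifnot(length(x) == length(y))
      x - y
    }
    stopifnot(length(d) >= 1L)
    d <- d[!is.na(d)]
    nz <- d[d != 0]
    if (length(nz) == 0L) {
      warning("all paired differences are zero; p = 1")
      return(structure(list(p_value = 1, statistic = 0,
                            alternative = alternative,
                            method = "exact Wilcoxon signed-rank",
                            n = length(d)), class = "herv_rank_test"))
    }
    r2 <- round(2 * rank(abs(nz)))           # doubled midranks: integers
    v_obs <- sum(r2[nz > 0])
    dist <- .signed_rank_dist(r2)            # counts over 2^n assignments
    p <- .tail_p(dist$support, dist$count, v_obs, alternative,
                 total = 2^length(r2))
    return(structure(list(p_value = p, statistic = v_obs / 2,
                          alternative = alternative,
                          method = "exact Wilcoxon signed-rank",
                          n = length(nz)), class = "herv_rank_test"))
  }
  stopifnot(!is.null(y), length(x) >= 1L, length(y) >= 1L)
  pooled <- c(x, y)
  r2 <- round(2 * rank(pooled))
  nx <- length(x)
  w_obs <- sum(r2[seq_len(nx)])
  dist <- .rank_sum_dist(r2, nx)
  p <- .tail_p(dist$support, dist$count, w_obs, alternative,
               total = choose(length(pooled), nx))
  structure(list(p_value = p, statistic = w_obs / 2,
                 alternative = alternative,
                 method = "exact Mann-Whitney-Wilcoxon",
                 n = c(nx = nx, ny = length(y))),
            class = "herv_rank_test")
}

#' @export
print.herv_rank_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", x$statistic,
      " alternative =", x$alternative, " p =", format(x$p_value), "\n")
  invisible(x)
}

# Distribution of the sum of nx doubled ranks chosen from r2: DP over items,
# count[k + 1, s + 1] = number of k-subsets summing to s. Counts stay exact
# in doubles for all n this package meets (< 2^53).
.rank_sum_dist <- function(r2, nx) {
  total <- sum(r2)
  counts <- matrix(0, nrow = nx + 1L, ncol = total + 1L)
  counts[1L, 1L] <- 1
  for (r in r2) {
    for (k in rev(seq_len(nx))) {
      nzc <- which(counts[k, ] > 0)
      if (length(nzc)) {
        counts[k + 1L, nzc + r] <- counts[k + 1L, nzc + r] + counts[k, nzc]
      }
    }
  }
  sup <- which(counts[nx + 1L, ] > 0) - 1L
  list(support = sup, count = counts[nx + 1L, sup + 1L])
}

# Distribution of the positive-part sum over all 2^n sign assignments:
# polynomial product of (1 + z^r) over doubled ranks.
.signed_rank_dist <- function(r2) {
  total <- sum(r2)
  cnt <- numeric(total + 1L)
  cnt[1L] <- 1
  for (r in r2) {
    nzc <- which(cnt > 0)
    new <- cnt
    new[nzc + r] <- new[nzc + r] + cnt[nzc]
    cnt <- new
  }
  sup <- which(cnt > 0) - 1L
  list(support = sup, count = cnt[sup + 1L])
}

.tail_p <- function(support, count, obs, alternative, total) {
  p_le <- sum(count[support <= obs + 1e-9]) / total
  p_ge <- sum(count[support >= obs - 1e-9]) / total
  switch(alternative,
         less = p_le,
         greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}
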