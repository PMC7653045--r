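#' MCMC configuration
#'
#' @param chains Number of independent chains (default 3).
#' @param iterations Total iterations per chain (default 10000).
#' @param warmup Warm-up iterations discarded per chain (default 5000), so
#'   the default posterior sample is 3 x 5000 = 15000 draws.
#' @param seed Integer seed driving every chain's RNG.
#' @param rhat_tol Convergence is flagged when any split-Rhat exceeds this
#'   (default 1.01).
#' @param min_ess Convergence is flagged when any ESS falls below this.
#' @return A validated list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, iterations = 10000L, warmup = 5000L,
                        seed = 1L, rhat_tol = 1.01, min_ess = 400) {
  stopifnot(chains >= 1L, iterations >= 2L, warmup >= 0L,
            warmup < iterations)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 rhat_tol = rhat_tol, min_ess = min_ess),
            class = "mcmc_config")
}

# draws: array [iteration, chain, parameter] -> flat matrix [draw, parameter]
flatten_draws <- function(draws) {
  stopifnot(length(dim(draws)) == 3L)
  out <- apply(draws, 3L, as.vector)
  if (is.null(dim(out))) out <- matrix(out, ncol = dim(draws)[3])
  colnames(out) <- dimnames(draws)[[3]]
  out
}

#' Split-Rhat and effective sample size per parameter
#'
#' Split-chain potential scale reduction factor (each chain halved, so m
#' chains give 2m sequences) and effective sample size from the combined
#' autocorrelation estimate with Geyer's initial positive sequence
#' truncation.
#'
#' @param draws Array `[iteration, chain, parameter]` of post-warmup draws
#'   (a single matrix `[iteration, chain]` is treated as one parameter).
#' @param rhat_tol,min_ess Flag thresholds (see [mcmc_config()]).
#' @return data.frame `parameter`, `rhat`, `ess`, plus attribute
#'   `converged` (logical scalar).
#' @export
mcmc_diagnostics <- function(draws, rhat_tol = 1.01, min_ess = 400) {
  if (length(dim(draws)) == 2L) {
    draws <- array(draws, dim = c(dim(draws), 1L),
                   dimnames = c(dimnames(draws), list("par")))
  }
  stopifnot(length(dim(draws)) == 3L)
  if (dim(draws)[2] < 2L) {
    stop("diagnostics need at least 2 chains", call. = FALSE)
  }
  pars <- dimnames(draws)[[3]] %||% paste0("par", seq_len(dim(draws)[3]))
  out <- data.frame(parameter = pars,
                    rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_along(pars)) {
    ch <- draws[, , j, drop = FALSE][, , 1]
    d <- .split_chains(ch)
    out$rhat[j] <- .rhat(d)
    out$ess[j] <- .ess(d)
  }
  attr(out, "converged") <- all(out$rhat < rhat_tol, na.rm = TRUE) &&
    all(out$ess > min_ess, na.rm = TRUE)
  out
}

.split_chains <- function(ch) {
  n <- nrow(ch)
  h <- n %/% 2L
  cbind(ch[seq_len(h), , drop = FALSE],
        ch[(n - h + 1L):n, , drop = FALSE])
}

.rhat <- function(d) {
  n <- nrow(d)
  mu <- colMeans(d)
  W <- mean(apply(d, 2, var))
  B <- n * var(mu)
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.ess <- function(d) {
  n <- nrow(d)
  m <- ncol(d)
  W <- mean(apply(d, 2, var))
  B <- n * var(colMeans(d))
  varplus <- (n - 1) / n * W + B / n
  if (varplus == 0) return(NA_real_)
  # mean per-chain autocovariance at each lag
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(d[, j], lag.max = n - 1L, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / varplus
  rho[1] <- 1
  # Geyer initial positive sequence on paired sums
  tau <- 0
  t <- 2L
  while (t + 1L <= length(rho)) {
    p <- rho[t] + rho[t + 1L]
    if (p < 0) break
    tau <- tau + p
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n * 1.5)
}

#' Summarize posterior draws
#'
#' Posterior median and equal-tailed 50% and 90% credible intervals per
#' parameter.
#'
#' @param draws Matrix `[draw, parameter]` or 3D array
#'   `[iteration, chain, parameter]`.
#' @return data.frame `parameter`, `median`, `ci50_lo`, `ci50_hi`,
#'   `ci90_lo`, `ci90_hi`.
#' @export
posterior_summary <- function(draws) {
  if (length(dim(draws)) == 3L) draws <- flatten_draws(draws)
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L)
  q <- t(apply(draws, 2, quantile,
               probs = c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE))
  data.frame(parameter = colnames(draws) %||%
               paste0("par", seq_len(ncol(draws))),
             median = q[, 3], ci50_lo = q[, 2], ci50_hi = q[, 4],
             ci90_lo = q[, 1], ci90_hi = q[, 5],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Posterior-median shift across a grid of prior scales
#'
#' Refits a model under each prior scale and reports the maximum absolute
#' shift of any posterior median across the grid — the prior-robustness
#' check reported alongside the cohort models.
#'
#' @param fit_fun Function taking a prior scale and returning a named
#'   numeric vector of posterior medians.
#' @param prior_scales Numeric vector of at least 2 scales.
#' @return List with `medians` (parameters x scales matrix) and
#'   `max_shift`.
#' @export
prior_sensitivity <- function(fit_fun, prior_scales) {
  stopifnot(length(prior_scales) >= 2L)
  meds <- sapply(prior_scales, fit_fun)
  if (is.null(dim(meds))) meds <- matrix(meds, nrow = 1L)
  colnames(meds) <- as.character(prior_scales)
  list(medians = meds,
       max_shift = max(apply(meds, 1, function(r) diff(range(r)))))
}
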