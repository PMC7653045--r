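# Independent oracles used to freeze expected values; they never share code
# with the implementation paths they check.

# Exact Mann-Whitney p by full enumeration of all choose(n, nx) labelings.
enum_rank_sum_p <- function(x, y, alternative) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(length(pooled), nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  switch(alternative, less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Exact signed-rank p by full enumeration of all 2^n sign assignments.
enum_signed_p <- function(d, alternative) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- signs %*% r
  p_le <- mean(vs <= v_obs + 1e-9)
  p_ge <- mean(vs >= v_obs - 1e-9)
  switch(alternative, less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Upper-tail NB probability by direct pmf summation.
nb_tail_oracle <- function(c_obs, mu, dispersion, upper = 100000L) {
  size <- 1 / dispersion
  sum(dnbinom(c_obs:upper, size = size, mu = mu))
}

# Spearman rho with midranks, computed from first principles.
spearman_brute <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small, fast simulation configuration for unit tests.
tiny_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, n_loci = 6, n_healthy = 3, n_pre = 2, n_post = 3,
             transcript_length_range = c(200, 600), binder_rate = 0.05,
             n_viral = 4, ...)
}

# Short chains for test-time fits; the ESS flag threshold is scaled down
# to match the reduced draw count (it is a diagnostic, not an inference
# tolerance).
fast_mcmc <- function(seed = 1, chains = 2, iterations = 1500,
                      warmup = 500) {
  mcmc_config(chains = chains, iterations = iterations, warmup = warmup,
              seed = seed, min_ess = 50)
}

# Minimal single-experiment counts_table from a 4-column matrix.
toy_counts <- function(m, experiment = "S1") {
  colnames(m) <- c(paste0(experiment, "_baseline_", 1:3), experiment)
  if (is.null(rownames(m))) rownames(m) <- paste0("b", seq_len(nrow(m)))
  counts_table(m, data.frame(
    column = colnames(m), experiment = experiment,
    role = c("baseline", "baseline", "baseline", "sorted"),
    stringsAsFactors = FALSE))
}
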