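#' Bayesian model of per-group responder proportions
#'
#' Each group's responder count is binomial with an unknown population
#' proportion under a conjugate `Beta(a, b)` prior (default the
#' non-informative `Beta(1, 1)`), so the posterior is exactly
#' `Beta(k + a, n - k + b)` and is sampled directly (conjugate sampling),
#' organized into chains for the standard diagnostics. Pairwise contrast
#' probabilities `P(p_a > p_b)` are computed on draws paired by index.
#'
#' @param k Named integer vector of responder counts per group.
#' @param n Group sizes (same names/order).
#' @param cfg An [mcmc_config()].
#' @param prior Length-2 beta prior parameters.
#' @return Object of class `herv_prop_fit`: `draws` (array iteration x
#'   chain x group), `summary`, `contrasts` (`pair`, `p_greater`),
#'   `diagnostics`, `converged`.
#' @export
#' @examples
#' fit <- fit_proportion_model(c(hd = 4, pre = 17), c(hd = 27, pre = 34),
#'                             mcmc_config(iterations = 2000, warmup = 1000))
#' fit$summary
fit_proportion_model <- function(k, n, cfg = mcmc_config(),
                                 prior = c(1, 1)) {
  stopifnot(length(k) == length(n), all(k >= 0), all(n >= 1))
  if (any(k > n)) stop("input error: k > n", call. = FALSE)
  groups <- names(k) %||% paste0("group", seq_along(k))
  n_draw <- cfg$iterations - cfg$warmup
  draws <- array(NA_real_, dim = c(n_draw, cfg$chains, length(k)),
                 dimnames = list(NULL, NULL, groups))
  with_seed(cfg$seed, {
    for (g in seq_along(k)) {
      for (ch in seq_len(cfg$chains)) {
        draws[, ch, g] <- rbeta(n_draw, k[g] + prior[1],
                                n[g] - k[g] + prior[2])
      }
    }
  })
  flat <- flatten_draws(draws)
  contrasts <- .pair_contrasts(flat, transform = identity)
  diag <- mcmc_diagnostics(draws, cfg$rhat_tol, cfg$min_ess)
  structure(list(draws = draws, summary = posterior_summary(draws),
                 contrasts = contrasts, diagnostics = diag,
                 converged = attr(diag, "converged"),
                 data = list(k = k, n = n), config = cfg),
            class = c("herv_prop_fit", "herv_fit"))
}

# all ordered pairs: P(a > b) plus the log fold change posterior
.pair_contrasts <- function(flat, transform = log) {
  gs <- colnames(flat)
  if (length(gs) < 2L) return(NULL)
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- flat[, pr[1]]; b <- flat[, pr[2]]
    lfc <- log(a / b)
    qs <- quantile(lfc, c(0.05, 0.5, 0.95), names = FALSE)
    data.frame(pair = paste(pr[1], "vs", pr[2]),
               p_greater = mean(a > b),
               lfc_median = qs[2], lfc_ci90_lo = qs[1],
               lfc_ci90_hi = qs[3], p_lfc_gt0 = mean(lfc > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.herv_fit <- function(x, ...) {
  cat("Bayesian fit (", class(x)[1], "), ",
      prod(dim(x$draws)[1:2]), " post-warmup draws",
      if (!isTRUE(x$converged)) "  [convergence flagged]", "\n", sep = "")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$contrasts)) {
    cat("\nContrasts:\n")
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.herv_fit <- function(object, ...) object$summary

#' @export
coef.herv_fit <- function(object, ...) {
  stats::setNames(object$summary$median, object$summary$parameter)
}

.jags_inits <- function(cfg) {
  lapply(seq_len(cfg$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (cfg$seed + 1000L * ch) %% .Machine$integer.max)
  })
}

.jags_draws <- function(model_string, data, monitor, cfg) {
  m <- rjags::jags.model(textConnection(model_string), data = data,
                         n.chains = cfg$chains, inits = .jags_inits(cfg),
                         quiet = TRUE)
  if (cfg$warmup > 0) update(m, cfg$warmup, progress.bar = "none")
  s <- rjags::coda.samples(m, monitor, n.iter = cfg$iterations - cfg$warmup,
                           progress.bar = "none")
  pars <- colnames(s[[1]])
  draws <- array(NA_real_,
                 dim = c(nrow(s[[1]]), length(s), length(pars)),
                 dimnames = list(NULL, NULL, pars))
  for (ch in seq_along(s)) draws[, ch, ] <- as.matrix(s[[ch]])
  draws
}

#' HLA-corrected Bayesian logistic regression of peptide recognition
#'
#' Models the number of recognized peptides per (individual, allele)
#' observation as binomial with
#' `logit(p_i) = beta0 + beta_hla[HLA_i] + beta_class[class_i]`,
#' where both coefficient blocks satisfy exact sum-to-zero constraints
#' (K - 1 free coefficients, the last the negative sum). Posterior draws of
#' the HLA-corrected class proportions
#' `p_class = logistic(beta0 + beta_class)` and of all pairwise log fold
#' changes `log(p_1 / p_2)` are derived per draw, propagating uncertainty.
#'
#' @param data data.frame with columns `n_pos`, `n_tested`, `hla`, `class`
#'   (see [response_counts()]).
#' @param cfg An [mcmc_config()].
#' @param prior_sd Normal prior s.d. on the intercept and free
#'   coefficients.
#' @return Object of class `herv_hla_fit`: coefficient `draws`,
#'   `p_class` draw matrix, `summary`, `contrasts`, `diagnostics`,
#'   `converged`.
#' @export
fit_hla_model <- function(data, cfg = mcmc_config(), prior_sd = 2.5) {
  stopifnot(all(c("n_pos", "n_tested", "hla", "class") %in% names(data)))
  if (any(data$n_pos > data$n_tested)) {
    stop("input error: n_pos > n_tested", call. = FALSE)
  }
  data <- data[data$n_tested > 0, , drop = FALSE]
  hla_lv <- sort(unique(data$hla))
  cls_lv <- unique(data$class)
  if (length(cls_lv) < 2L) {
    stop("need at least 2 classes", call. = FALSE)
  }
  jd <- list(npos = as.integer(data$n_pos),
             Ntest = as.integer(data$n_tested),
             hla = match(data$hla, hla_lv),
             cls = match(data$class, cls_lv),
             Nobs = nrow(data), Kh = length(hla_lv), Kc = length(cls_lv),
             prec = 1 / prior_sd^2)
  # exact sum-to-zero: K - 1 free coefficients, last = -sum; a block with
  # a single level degenerates to the constant 0
  szb <- function(v, K) {
    if (K == 1L) return(sprintf("    %s[1] <- 0\n", v))
    paste0(sprintf("    for (k in 1:(%d - 1)) { %sf[k] ~ dnorm(0, prec) }\n",
                   K, v),
           sprintf("    for (k in 1:(%d - 1)) { %s[k] <- %sf[k] }\n",
                   K, v, v),
           sprintf("    %s[%d] <- -sum(%sf)\n", v, K, v))
  }
  model <- paste0("model {
    for (i in 1:Nobs) {
      npos[i] ~ dbin(p[i], Ntest[i])
      logit(p[i]) <- b0 + bh[hla[i]] + bc[cls[i]]
    }
    b0 ~ dnorm(0, prec)\n",
    szb("bh", jd$Kh), szb("bc", jd$Kc), "  }")
  jd$Kh <- NULL
  jd$Kc <- NULL
  draws <- .jags_draws(model, jd, c("b0", "bh", "bc"), cfg)
  pars <- dimnames(draws)[[3]]
  nice <- pars
  nice[pars == "b0"] <- "beta0"
  for (i in seq_along(hla_lv)) {
    nice[pars == sprintf("bh[%d]", i)] <- paste0("beta_hla.", hla_lv[i])
  }
  for (i in seq_along(cls_lv)) {
    nice[pars == sprintf("bc[%d]", i)] <- paste0("beta_class.", cls_lv[i])
  }
  dimnames(draws)[[3]] <- nice
  flat <- flatten_draws(draws)
  p_class <- sapply(cls_lv, function(cl) {
    stats::plogis(flat[, "beta0"] + flat[, paste0("beta_class.", cl)])
  })
  colnames(p_class) <- cls_lv
  contrasts <- .pair_contrasts(p_class)
  diag <- mcmc_diagnostics(draws, cfg$rhat_tol, cfg$min_ess)
  conv <- attr(diag, "converged")
  if (!conv) {
    warning("MCMC convergence flagged (split-Rhat or ESS outside ",
            "tolerance); inspect $diagnostics")
  }
  structure(list(draws = draws, p_class = p_class,
                 summary = posterior_summary(draws),
                 p_class_summary = posterior_summary(p_class),
                 contrasts = contrasts, diagnostics = diag,
                 converged = conv, data = data, config = cfg),
            class = c("herv_hla_fit", "herv_fit"))
}

#' Normalize HERV response posteriors to the viral internal control
#'
#' Divides, draw by draw, the HLA-corrected class proportions of HERV
#' peptide recognition by the class proportions of viral peptide
#' recognition (the internal control for overall T cell reactivity), then
#' summarizes the normalized ratios and their between-class log fold
#' changes.
#'
#' @param herv_p_class Draw matrix of HERV class proportions (columns =
#'   classes), e.g. `fit$p_class` from [fit_hla_model()].
#' @param viral_p_class Draw matrix of viral class proportions with the
#'   same classes and draw count, e.g. `fit$draws` flattened from
#'   [fit_proportion_model()].
#' @return List of class `herv_norm_fit`: `ratio` draw matrix, `summary`,
#'   `contrasts`, `n_dropped` (draws removed for zero viral proportion).
#' @export
normalize_to_viral <- function(herv_p_class, viral_p_class) {
  if (length(dim(viral_p_class)) == 3L) {
    viral_p_class <- flatten_draws(viral_p_class)
  }
  stopifnot(nrow(herv_p_class) == nrow(viral_p_class))
  cls <- colnames(herv_p_class)
  stopifnot(all(cls %in% colnames(viral_p_class)))
  viral_p_class <- viral_p_class[, cls, drop = FALSE]
  bad <- rowSums(viral_p_class == 0) > 0
  if (any(bad)) {
    message(sum(bad), " draw(s) with zero viral proportion excluded")
  }
  ratio <- herv_p_class[!bad, , drop = FALSE] /
    viral_p_class[!bad, , drop = FALSE]
  structure(list(ratio = ratio, summary = posterior_summary(ratio),
                 contrasts = .pair_contrasts(ratio),
                 n_dropped = sum(bad)),
            class = "herv_norm_fit")
}

#' @export
print.herv_norm_fit <- function(x, ...) {
  cat("Viral-normalized HERV response ratios\n")
  print(x$summary, row.names = FALSE)
  cat("\nContrasts:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Bayesian logistic regression of clinical outcome
#'
#' Models the probability that a patient is a treatment responder as
#' `logistic(beta0 + beta_hla . x_hla + beta_herv x_herv + beta_vir x_vir +
#' beta_hxv x_herv x_vir)`, with indicator covariates for the four HLA
#' alleles and for any HERV / any viral T cell response. The three antigen
#' coefficients (`beta_herv`, `beta_vir`, `beta_hxv`) share a hierarchical
#' `Normal(0, tau)` prior with `tau ~ half-Normal(tau_scale)`, which
#' regularizes the fit and keeps posteriors finite under separation.
#'
#' @param data data.frame with columns `outcome` (`"responder"` /
#'   `"non-responder"` or 0/1), `herv`, `viral` (0/1 indicators), and one
#'   0/1 column per HLA allele whose names are given in `hla_cols`.
#' @param cfg An [mcmc_config()].
#' @param hla_cols Names of the HLA indicator columns (default: columns
#'   starting with `"hla"`).
#' @param prior_sd Normal prior s.d. on intercept and HLA coefficients.
#' @param tau_scale Scale of the half-normal hyperprior.
#' @return Object of class `herv_outcome_fit` with `draws`, `summary`,
#'   `ci_includes_zero` (named logical over coefficients, 90% CI),
#'   `diagnostics`, `converged`.
#' @export
fit_outcome_model <- function(data, cfg = mcmc_config(), hla_cols = NULL,
                              prior_sd = 2.5, tau_scale = 1) {
  stopifnot(all(c("outcome", "herv", "viral") %in% names(data)))
  hla_cols <- hla_cols %||% grep("^hla", names(data), value = TRUE)
  stopifnot(length(hla_cols) >= 1L)
  y <- data$outcome
  if (!is.numeric(y)) y <- as.integer(y == "responder")
  stopifnot(all(y %in% c(0L, 1L)))
  X <- as.matrix(data[hla_cols])
  jd <- list(y = y, X = X, xh = as.numeric(data$herv),
             xv = as.numeric(data$viral), Nobs = nrow(data),
             Ka = ncol(X), prec = 1 / prior_sd^2,
             tau_prec = 1 / tau_scale^2)
  model <- "model {
    for (i in 1:Nobs) {
      y[i] ~ dbern(p[i])
      logit(p[i]) <- b0 + inprod(bhla[1:Ka], X[i, 1:Ka]) +
        bherv * xh[i] + bvir * xv[i] + bhxv * xh[i] * xv[i]
    }
    b0 ~ dnorm(0, prec)
    for (a in 1:Ka) { bhla[a] ~ dnorm(0, prec) }
    tau ~ dnorm(0, tau_prec) T(0,)
    cprec <- 1 / (tau * tau + 1.0E-9)
    bherv ~ dnorm(0, cprec)
    bvir ~ dnorm(0, cprec)
    bhxv ~ dnorm(0, cprec)
  }"
  draws <- .jags_draws(model, jd,
                       c("b0", "bhla", "bherv", "bvir", "bhxv", "tau"), cfg)
  pars <- dimnames(draws)[[3]]
  nice <- pars
  nice[pars == "b0"] <- "beta0"
  for (i in seq_along(hla_cols)) {
    nice[pars == sprintf("bhla[%d]", i)] <- paste0("beta_", hla_cols[i])
  }
  nice[pars == "bherv"] <- "beta_herv"
  nice[pars == "bvir"] <- "beta_vir"
  nice[pars == "bhxv"] <- "beta_hxv"
  dimnames(draws)[[3]] <- nice
  summ <- posterior_summary(draws)
  coefs <- setdiff(summ$parameter, "tau")
  inc0 <- stats::setNames(summ$ci90_lo <= 0 & summ$ci90_hi >= 0,
                          summ$parameter)[coefs]
  diag <- mcmc_diagnostics(draws, cfg$rhat_tol, cfg$min_ess)
  structure(list(draws = draws, summary = summ, ci_includes_zero = inc0,
                 diagnostics = diag, converged = attr(diag, "converged"),
                 data = data, config = cfg),
            class = c("herv_outcome_fit", "herv_fit"))
}

#' Per-(individual, allele) response counts from a responder matrix
#'
#' The observation unit of the HLA-corrected model: for every
#' individual-class row and every allele the individual carries, the number
#' of tested peptides of that allele (`n_tested`) and the number positive
#' (`n_pos`).
#'
#' @param matrix A [aggregate_responses()] result.
#' @param antigen_class Restrict to this antigen class when the library is
#'   annotated (default `"HERV"`).
#' @return data.frame `individual`, `class`, `hla`, `n_pos`, `n_tested`.
#' @export
response_counts <- function(matrix, antigen_class = "HERV") {
  stopifnot(inherits(matrix, "responder_matrix"))
  ent <- matrix$entries
  keep <- if ("antigen_class" %in% names(ent)) {
    ent$antigen_class == antigen_class
  } else rep(TRUE, nrow(ent))
  out <- list()
  for (r in seq_len(nrow(matrix$rows))) {
    st <- matrix$status[r, keep]
    al <- ent$allele[keep]
    for (a in unique(al)) {
      tested <- !is.na(st) & al == a
      if (!any(tested)) next
      out[[length(out) + 1L]] <- data.frame(
        individual = matrix$rows$individual_id[r],
        class = matrix$rows$class[r], hla = a,
        n_pos = sum(st[tested] == 1L), n_tested = sum(tested),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-class pooled peptide-recognition counts
#'
#' Pools tested / positive peptide observations over individuals within
#' each class — the data of the proportion-of-peptides model used for the
#' viral internal control.
#'
#' @inheritParams response_counts
#' @return data.frame `class`, `k` (positive), `n` (tested).
#' @export
class_peptide_counts <- function(matrix, antigen_class = "viral") {
  rc <- response_counts(matrix, antigen_class = antigen_class)
  agg <- stats::aggregate(rc[c("n_pos", "n_tested")],
                          by = list(class = rc$class), FUN = sum)
  data.frame(class = agg$class, k = agg$n_pos, n = agg$n_tested,
             stringsAsFactors = FALSE)
}

#' Per-patient outcome-model covariates
#'
#' Builds the clinical-outcome regression data: per patient, the outcome
#' label, indicators for any HERV and any viral T cell response (over all
#' of the patient's rows), and HLA-allele indicators.
#'
#' @param matrix A [aggregate_responses()] result.
#' @param sample_sheet Sample sheet with `individual_id`, `class`,
#'   `alleles`, `outcome`.
#' @return data.frame `individual`, `outcome`, `herv`, `viral`, plus one
#'   `hlaN` indicator column per allele in the pool.
#' @export
outcome_data <- function(matrix, sample_sheet) {
  pats <- unique(sample_sheet$individual_id[
    .is_patient_class(sample_sheet$class)])
  pool <- sort(unique(unlist(strsplit(sample_sheet$alleles, ";",
                                      fixed = TRUE))))
  ent <- matrix$entries
  ag <- if ("antigen_class" %in% names(ent)) ent$antigen_class
        else rep("HERV", nrow(ent))
  out <- lapply(pats, function(p) {
    rws <- matrix$rows$individual_id == p
    st <- matrix$status[rws, , drop = FALSE]
    alleles <- unique(unlist(strsplit(
      sample_sheet$alleles[sample_sheet$individual_id == p], ";",
      fixed = TRUE)))
    oc <- sample_sheet$outcome[sample_sheet$individual_id == p][1]
    row <- data.frame(individual = p, outcome = oc,
                      herv = as.integer(any(st[, ag == "HERV"] == 1L,
                                            na.rm = TRUE)),
                      viral = as.integer(any(st[, ag == "viral"] == 1L,
                                             na.rm = TRUE)),
                      stringsAsFactors = FALSE)
    for (i in seq_along(pool)) {
      row[[paste0("hla", i)]] <- as.integer(pool[i] %in% alleles)
    }
    row
  })
  do.call(rbind, out)
}
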