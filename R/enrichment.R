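#' Barcode read-count container for a multimer screen
#'
#' A barcode x column count matrix plus column metadata grouping columns
#' into experiments: each sorted sample column is paired with exactly three
#' baseline replicate columns (the unsorted pMHC pool). `NA` counts mark
#' barcodes outside a sample's HLA-matched panel.
#'
#' @param counts Numeric matrix, barcodes in rows (unique rownames),
#'   columns named as in `columns$column`; non-negative integers or `NA`.
#' @param columns data.frame with `column`, `experiment`, `role`
#'   (`"baseline"` or `"sorted"`).
#' @param annotation Optional data.frame mapping `barcode` to `peptide`,
#'   `allele`, `antigen_class`, `source_loci`.
#' @return An object of class `counts_table`.
#' @export
counts_table <- function(counts, columns, annotation = NULL) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            all(c("column", "experiment", "role") %in% names(columns)))
  if (anyDuplicated(rownames(counts))) {
    stop("barcode IDs must be unique", call. = FALSE)
  }
  if (!setequal(colnames(counts), columns$column)) {
    stop("count columns and column metadata disagree", call. = FALSE)
  }
  if (any(counts < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  for (e in unique(columns$experiment)) {
    sub <- columns[columns$experiment == e, ]
    if (sum(sub$role == "baseline") != 3L || sum(sub$role == "sorted") != 1L) {
      stop("experiment '", e, "' must have exactly 3 baseline replicates ",
           "and 1 sorted sample", call. = FALSE)
    }
  }
  structure(list(counts = counts, columns = columns,
                 annotation = annotation),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat("counts_table:", nrow(x$counts), "barcodes x", ncol(x$counts),
      "columns (", length(unique(x$columns$experiment)), "experiments )\n")
  invisible(x)
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-sample TMM scaling factors for a count matrix. The
#' reference column is the sample whose 75th-percentile count fraction is
#' closest to the mean of those quantiles across samples. For each sample,
#' log2 count-fraction ratios to the reference (M) are doubly trimmed — the
#' top and bottom `trim_m` by M and `trim_a` by average log intensity A —
#' and averaged with inverse asymptotic binomial-variance weights; the
#' factor is 2 to that mean. Factors are rescaled to geometric mean 1.
#' Only barcodes with positive counts in both the sample and the reference
#' enter the trimmed mean.
#'
#' @param counts Numeric count matrix (features x samples), or a
#'   [counts_table()] (one experiment's columns are normalized together by
#'   [detect_responses()]).
#' @param trim_m,trim_a Trim fractions for M and A (defaults 0.3 / 0.05).
#' @return Named numeric vector of factors, one per column.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  if (inherits(counts, "counts_table")) counts <- counts$counts
  stopifnot(is.matrix(counts))
  lib <- colSums(counts)
  zero <- lib == 0 | apply(counts, 2, function(v) all(v == 0))
  if (any(zero)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  }
  frac <- sweep(counts, 2, lib, "/")
  q75 <- apply(frac, 2, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(q75 - mean(q75)))

  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    obs <- counts[, j]; rf <- counts[, ref]
    ok <- obs > 0 & rf > 0
    obs <- obs[ok]; rf <- rf[ok]
    M <- log2((obs / lib[j]) / (rf / lib[ref]))
    A <- 0.5 * log2((obs / lib[j]) * (rf / lib[ref]))
    w <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - rf) / (lib[ref] * rf)
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    n <- length(M)
    if (n == 0L) return(1)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Effective per-column library sizes and pseudo-fraction for one
# experiment's 4-column submatrix (NA rows already dropped).
.norm_fractions <- function(counts, factors) {
  lib <- colSums(counts)
  eff <- lib * factors[colnames(counts)]
  sweep(counts, 2, eff, "/")
}

#' log2 fold change of sorted-sample barcode fractions vs baseline
#'
#' For each barcode, the log2 ratio of the TMM-normalized count fraction in
#' the sorted sample to the mean normalized fraction across the three
#' baseline replicates. A pseudo-fraction `0.5 / median(effective library
#' size)` is added to numerator and denominator so zero counts give finite
#' fold changes.
#'
#' @param counts Count matrix of one experiment: three baseline columns and
#'   one sorted column.
#' @param factors TMM factors named by column (see [tmm_factors()]).
#' @param baseline_cols,sorted_col Column names; by default inferred from
#'   the `_baseline_` naming convention.
#' @param pseudo Pseudo-fraction; `NULL` for the default above.
#' @return Named numeric vector of log2 fold changes, one per barcode.
#' @export
log2fc_vs_baseline <- function(counts, factors, baseline_cols = NULL,
                               sorted_col = NULL, pseudo = NULL) {
  cols <- .experiment_cols(counts, baseline_cols, sorted_col)
  fr <- .norm_fractions(counts, factors)
  eff <- colSums(counts) * factors[colnames(counts)]
  pseudo <- pseudo %||% (0.5 / median(eff))
  base_mean <- rowMeans(fr[, cols$baseline, drop = FALSE])
  lfc <- log2((fr[, cols$sorted] + pseudo) / (base_mean + pseudo))
  stats::setNames(lfc, rownames(counts))
}

.experiment_cols <- function(counts, baseline_cols, sorted_col) {
  if (is.null(baseline_cols)) {
    baseline_cols <- grep("_baseline_", colnames(counts), value = TRUE)
  }
  if (is.null(sorted_col)) {
    sorted_col <- setdiff(colnames(counts), baseline_cols)
  }
  if (length(baseline_cols) != 3L || length(sorted_col) != 1L) {
    stop("an experiment needs exactly 3 baseline columns and 1 sorted ",
         "column", call. = FALSE)
  }
  list(baseline = baseline_cols, sorted = sorted_col)
}

#' One-sided negative-binomial enrichment p-values at fixed dispersion
#'
#' Tests each barcode's sorted-sample count against the normalized mean of
#' the triplicate baselines: the null mean is the baseline mean fraction
#' rescaled to the sorted sample's effective library size, and the p-value
#' is the upper tail `P(X >= c_obs)` under `X ~ NB(mu, mu + phi * mu^2)`
#' with dispersion `phi` fixed (default 0.1, i.e. size `1 / phi`). A zero
#' observed count gives p = 1; a zero baseline mean with a positive
#' observed count uses a floor of 0.5 reads so p stays positive.
#'
#' @inheritParams log2fc_vs_baseline
#' @param dispersion NB dispersion phi > 0.
#' @return Named numeric vector of p-values in (0, 1].
#' @export
nb_pvalues <- function(counts, factors, dispersion = 0.1,
                       baseline_cols = NULL, sorted_col = NULL) {
  if (dispersion <= 0) {
    stop("configuration error: dispersion must be > 0", call. = FALSE)
  }
  cols <- .experiment_cols(counts, baseline_cols, sorted_col)
  fr <- .norm_fractions(counts, factors)
  eff <- colSums(counts) * factors[colnames(counts)]
  mu <- rowMeans(fr[, cols$baseline, drop = FALSE]) * eff[cols$sorted]
  obs <- counts[, cols$sorted]
  mu[mu == 0 & obs > 0] <- 0.5
  p <- ifelse(obs == 0, 1,
              pnbinom(obs - 1, size = 1 / dispersion, mu = mu,
                      lower.tail = FALSE))
  # guard against exact-zero tail probabilities from extreme counts
  p <- pmax(p, .Machine$double.xmin)
  stats::setNames(pmin(p, 1), rownames(counts))
}

#' Benjamini-Hochberg false-discovery rates
#'
#' Step-up BH q-values (`stats::p.adjust(method = "BH")`), capped at 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values in the input order; empty input gives empty output.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Run the full barcode-enrichment detection pipeline
#'
#' Per experiment: TMM factors over its four columns, log2 fold changes and
#' one-sided NB p-values of the sorted sample vs the baseline mean, BH FDR
#' within the experiment, the raw read fraction of each barcode in the
#' sorted sample, and the dual significance call
#' `fdr < fdr_threshold & read_fraction >= min_fraction`.
#'
#' @param counts A [counts_table()].
#' @param fdr_threshold FDR cutoff (default 0.001, i.e. FDR < 0.1%).
#' @param min_fraction Minimum raw read fraction of a barcode among all
#'   barcode reads of its sorted sample (default 1/1000).
#' @param dispersion NB dispersion (default 0.1).
#' @param trim_m,trim_a TMM trim fractions.
#' @return data.frame with one row per (sorted sample, tested barcode):
#'   `sample`, `barcode`, `log2_fc`, `p`, `fdr`, `read_fraction`,
#'   `significant`, plus the pMHC annotation columns when the table carries
#'   an annotation.
#' @export
detect_responses <- function(counts, fdr_threshold = 0.001,
                             min_fraction = 0.001, dispersion = 0.1,
                             trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(counts, "counts_table"))
  res <- list()
  for (e in unique(counts$columns$experiment)) {
    cc <- counts$columns[counts$columns$experiment == e, ]
    bcols <- cc$column[cc$role == "baseline"]
    scol <- cc$column[cc$role == "sorted"]
    m <- counts$counts[, c(bcols, scol), drop = FALSE]
    tested <- rowSums(is.na(m)) == 0L
    m <- m[tested, , drop = FALSE]
    if (nrow(m) == 0L) next
    f <- tmm_factors(m, trim_m = trim_m, trim_a = trim_a)
    lfc <- log2fc_vs_baseline(m, f, bcols, scol)
    p <- nb_pvalues(m, f, dispersion, bcols, scol)
    q <- bh_fdr(p)
    frac <- m[, scol] / sum(m[, scol])
    res[[e]] <- data.frame(sample = e, barcode = rownames(m),
                           log2_fc = unname(lfc), p = unname(p),
                           fdr = unname(q), read_fraction = unname(frac),
                           significant = unname(q < fdr_threshold &
                                                  frac >= min_fraction),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!is.null(counts$annotation)) {
    out <- merge(out, counts$annotation, by = "barcode", sort = FALSE)
    out <- out[order(match(out$sample, unique(counts$columns$experiment))), ]
    rownames(out) <- NULL
  }
  out
}

#' Apply the dual significance filter to enrichment results
#'
#' A (sample, barcode) pair is a detection iff its FDR is below
#' `fdr_threshold` and its raw read fraction is at least `min_fraction`.
#'
#' @param results data.frame with columns `fdr` and `read_fraction` (as
#'   returned by [detect_responses()]).
#' @inheritParams detect_responses
#' @return The input with a recomputed logical `significant` column.
#' @export
call_detections <- function(results, fdr_threshold = 0.001,
                            min_fraction = 0.001) {
  stopifnot(all(c("fdr", "read_fraction") %in% names(results)))
  results$significant <- results$fdr < fdr_threshold &
    results$read_fraction >= min_fraction
  results
}

#' Clonally reduce barcode reads via molecule tags
#'
#' Collapses reads sharing a molecule tag: the clonally reduced count of a
#' barcode in a sample is its number of distinct tags. Input without a
#' `tag` column passes through unchanged with a notice.
#'
#' @param reads data.frame of read records with columns `barcode`,
#'   `sample`, and optionally `tag`.
#' @return data.frame `barcode`, `sample`, `count`.
#' @export
clonal_reduce <- function(reads) {
  stopifnot(all(c("barcode", "sample") %in% names(reads)))
  if (!"tag" %in% names(reads)) {
    message("no molecule-tag column; returning raw read counts")
    agg <- stats::aggregate(list(count = rep(1L, nrow(reads))),
                            by = reads[c("barcode", "sample")], FUN = sum)
    return(agg)
  }
  agg <- stats::aggregate(list(count = reads$tag),
                          by = reads[c("barcode", "sample")],
                          FUN = function(t) length(unique(t)))
  agg
}
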