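#' Floor TPM values
#'
#' Replaces expression values below `floor` by `floor` (default 0.05 TPM)
#' so downstream log fold changes stay finite and the scale is not skewed
#' by near-zero values. Idempotent; negative input is rejected.
#'
#' @param x Numeric vector or matrix of TPM values.
#' @param floor Positive floor (default 0.05).
#' @return `x` with values below `floor` replaced.
#' @export
floor_tpm <- function(x, floor = 0.05) {
  stopifnot(floor > 0)
  if (any(x < 0, na.rm = TRUE)) {
    stop("input error: negative expression value", call. = FALSE)
  }
  x[x < floor] <- floor
  x
}

#' log2 fold change of floored expression values
#'
#' `log2(x) - log2(y)`; both inputs must already be floored (strictly
#' positive), so the result is always finite and antisymmetric in its
#' arguments.
#'
#' @param x,y Positive numeric vectors (recycled).
#' @return `log2(x) - log2(y)`.
#' @export
log2_fold_change <- function(x, y) {
  if (any(x <= 0) || any(y <= 0)) {
    stop("zero or negative expression: apply floor_tpm() first",
         call. = FALSE)
  }
  log2(x) - log2(y)
}

#' Per-patient log2 fold-change tables of HERV expression
#'
#' Two comparison modes. `"vs-healthy"`: each patient column against the
#' per-locus mean of the (floored) healthy-donor columns. `"paired"`: each
#' individual's post-treatment column against their pre-treatment column;
#' individuals lacking either timepoint are dropped with a message.
#' Flooring is applied to every value before any log or mean.
#'
#' @param tpm Numeric matrix (locus x sample).
#' @param samples data.frame `sample_id`, `individual_id`, `class`
#'   (defaults to `attr(tpm, "samples")`).
#' @param mode `"vs-healthy"` or `"paired"`.
#' @param floor TPM floor applied first.
#' @return Numeric matrix of log2 fold changes: loci x patient samples
#'   (mode `"vs-healthy"`) or loci x paired individuals (mode `"paired"`).
#' @export
group_fold_changes <- function(tpm, samples = NULL,
                               mode = c("vs-healthy", "paired"),
                               floor = 0.05) {
  mode <- match.arg(mode)
  samples <- samples %||% attr(tpm, "samples")
  stopifnot(!is.null(samples),
            all(c("sample_id", "individual_id", "class") %in%
                  names(samples)))
  m <- floor_tpm(tpm, floor)
  if (mode == "vs-healthy") {
    hcols <- samples$sample_id[samples$class == "healthy"]
    if (length(hcols) == 0L) {
      stop("no healthy samples for mode 'vs-healthy'", call. = FALSE)
    }
    hmean <- rowMeans(m[, hcols, drop = FALSE])
    pcols <- samples$sample_id[samples$class != "healthy"]
    out <- sapply(pcols, function(s) log2_fold_change(m[, s], hmean))
    if (is.null(dim(out))) out <- matrix(out, ncol = length(pcols),
                                         dimnames = list(rownames(m), pcols))
    return(out)
  }
  pre <- samples[samples$class == "pre-AZA", ]
  post <- samples[samples$class == "post-AZA", ]
  both <- intersect(pre$individual_id, post$individual_id)
  dropped <- length(unique(c(pre$individual_id, post$individual_id))) -
    length(both)
  if (dropped > 0) {
    message(dropped, " unpaired patient(s) dropped from paired comparison")
  }
  if (length(both) == 0L) {
    stop("no paired pre/post samples", call. = FALSE)
  }
  out <- sapply(both, function(i) {
    log2_fold_change(m[, post$sample_id[post$individual_id == i][1]],
                     m[, pre$sample_id[pre$individual_id == i][1]])
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = length(both),
                                       dimnames = list(rownames(m), both))
  colnames(out) <- both
  out
}

#' Clamp fold changes for heatmap display
#'
#' Values outside `[-bound, bound]` are shown at the scale limit.
#'
#' @param values Numeric vector or matrix.
#' @param bound Positive bound (default 6).
#' @return Clamped values.
#' @export
clip_for_heatmap <- function(values, bound = 6) {
  stopifnot(bound > 0)
  pmin(pmax(values, -bound), bound)
}

#' Spearman correlation between HERV expression and T cell recognition
#'
#' Correlates per-locus mean patient expression with the per-locus
#' proportion of predicted epitopes detected. Ties are handled by
#' midranks. The two-tailed p-value uses the t approximation
#' `t = r sqrt((n - 2) / (1 - r^2))` by default, or full permutation
#' enumeration for small inputs (`method = "exact"`, n <= 8).
#'
#' @param mean_expression Named numeric vector, per-locus mean TPM.
#' @param epitope_prop Named numeric vector, per-locus detected/predicted
#'   proportion (see [epitope_proportion()]); matched to
#'   `mean_expression` by name.
#' @param method `"approx"` (t approximation) or `"exact"`.
#' @return List `r`, `p`, `n`, `method`.
#' @export
expression_vs_recognition <- function(mean_expression, epitope_prop,
                                      method = c("approx", "exact")) {
  method <- match.arg(method)
  if (!is.null(names(mean_expression)) && !is.null(names(epitope_prop))) {
    common <- intersect(names(mean_expression), names(epitope_prop))
    mean_expression <- mean_expression[common]
    epitope_prop <- epitope_prop[common]
  }
  ok <- !is.na(mean_expression) & !is.na(epitope_prop)
  x <- mean_expression[ok]; y <- epitope_prop[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 loci", call. = FALSE)
  r <- cor(rank(x), rank(y))
  if (method == "exact") {
    if (n > 8L) stop("exact permutation p-value limited to n <= 8",
                     call. = FALSE)
    rx <- rank(x); ry <- rank(y)
    perms <- .permutations(seq_len(n))
    rs <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rs) >= abs(r) - 1e-12)
  } else {
    if (abs(r) >= 1 - 1e-12) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  list(r = r, p = p, n = n, method = method)
}

.permutations <- function(v) {
  n <- length(v)
  if (n <= 1L) return(matrix(v, nrow = 1L))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- .permutations(v[-i])
    out[[i]] <- cbind(v[i], rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Compare expression of immunogenic vs non-immunogenic HERVs
#'
#' Per-group medians of per-locus mean expression, and the exact two-tailed
#' Mann-Whitney-Wilcoxon p-value ([exact_rank_test()]) for the difference
#' between loci recognized by T cells and loci never recognized.
#'
#' @param mean_expression Named numeric vector, per-locus mean TPM.
#' @param immunogenic Logical vector (same order/names), whether the locus
#'   yielded at least one T cell response.
#' @return List `median_immunogenic`, `median_non_immunogenic`, `p`,
#'   `n_immunogenic`, `n_non_immunogenic`.
#' @export
immunogenic_group_compare <- function(mean_expression, immunogenic) {
  stopifnot(length(mean_expression) == length(immunogenic))
  pos <- mean_expression[immunogenic]
  neg <- mean_expression[!immunogenic]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  tt <- exact_rank_test(pos, neg, alternative = "two.sided")
  list(median_immunogenic = median(pos),
       median_non_immunogenic = median(neg),
       p = tt$p_value, n_immunogenic = length(pos),
       n_non_immunogenic = length(neg))
}
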