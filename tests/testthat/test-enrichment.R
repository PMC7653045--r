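test_that("TMM factors: identity, scale invariance, row permutation", {
  set.seed(3)
  base <- rnbinom(200, size = 10, mu = 100) + 1
  m <- cbind(s1 = base, s2 = base, s3 = base, s4 = base)
  rownames(m) <- paste0("b", 1:200)
  expect_equal(unname(tmm_factors(m)), rep(1, 4), tolerance = 1e-12)

  # doubling a column with identical composition: equal normalized totals
  m2 <- cbind(s1 = base, s2 = 2 * base, s3 = base)
  rownames(m2) <- paste0("b", 1:200)
  f <- tmm_factors(m2)
  normed <- colSums(m2) * f
  expect_equal(normed[["s2"]] / normed[["s1"]], 2, tolerance = 1e-8)
  frac_before <- m2[, "s2"] / sum(m2[, "s2"])
  frac_after <- m2[, "s2"] / (sum(m2[, "s2"]) * f[["s2"]])
  expect_equal(frac_before / sum(frac_before),
               frac_after / sum(frac_after), tolerance = 1e-12)

  # row permutation leaves factors unchanged
  set.seed(4)
  m3 <- matrix(rnbinom(300 * 3, size = 5, mu = 80) + 1, ncol = 3,
               dimnames = list(paste0("b", 1:300), paste0("s", 1:3)))
  perm <- sample(300)
  expect_equal(unname(tmm_factors(m3)), unname(tmm_factors(m3[perm, ])))
})

test_that("TMM matches the reference implementation", {
  skip_if_not_installed("edgeR")
  for (seed in c(7, 8, 9)) {
    set.seed(seed)
    m <- matrix(rnbinom(400 * 4, size = 8,
                        mu = rep(c(50, 120, 200, 80), each = 400)),
                ncol = 4, dimnames = list(paste0("b", 1:400),
                                          paste0("s", 1:4)))
    f_ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = m),
                                    method = "TMM")$samples$norm.factors
    expect_equal(unname(tmm_factors(m)), f_ref, tolerance = 1e-10)
  }
})

test_that("TMM rejects all-zero samples by name", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(0, 0, 0))
  rownames(m) <- paste0("b", 1:3)
  expect_error(tmm_factors(m), "s2")
})

test_that("log2 fold change vs baseline matches hand computation", {
  # identical composition -> 0 everywhere
  m <- matrix(c(100, 100, 100, 100,
                900, 900, 900, 900), nrow = 2, byrow = TRUE,
              dimnames = list(c("b1", "b2"),
                              c("S1_baseline_1", "S1_baseline_2",
                                "S1_baseline_3", "S1")))
  f <- stats::setNames(rep(1, 4), colnames(m))
  expect_equal(unname(log2fc_vs_baseline(m, f)), c(0, 0), tolerance = 1e-9)

  # sorted fraction 4x the baseline mean -> ~2 (pseudo-fraction is small)
  m4 <- matrix(c(100, 100, 100, 400,
                 900, 900, 900, 600), nrow = 2, byrow = TRUE,
               dimnames = dimnames(m))
  lfc <- log2fc_vs_baseline(m4, f)
  expect_equal(unname(lfc[1]), 2, tolerance = 0.02)

  # hand-worked toy with unequal library sizes, pseudo-fraction exact
  counts <- matrix(c(10, 20, 30,
                     20, 40, 60,
                     10, 20, 30,
                     5, 10, 85), ncol = 4,
                   dimnames = list(paste0("b", 1:3),
                                   c("E_baseline_1", "E_baseline_2",
                                     "E_baseline_3", "E")))
  f1 <- stats::setNames(rep(1, 4), colnames(counts))
  lib <- colSums(counts)
  pseudo <- 0.5 / median(lib)
  base_mean <- rowMeans(sweep(counts[, 1:3], 2, lib[1:3], "/"))
  expected <- log2((counts[, 4] / lib[4] + pseudo) / (base_mean + pseudo))
  expect_equal(unname(log2fc_vs_baseline(counts, f1)), unname(expected))
})

test_that("NB p-values match a pmf-summation oracle", {
  # baseline fraction 0.1 at library size 100 -> mu = 10 (size 10), obs 40
  m <- matrix(c(10, 10, 10, 40,
                90, 90, 90, 60), nrow = 2, byrow = TRUE,
              dimnames = list(c("b1", "b2"),
                              c("E_baseline_1", "E_baseline_2",
                                "E_baseline_3", "E")))
  f <- stats::setNames(rep(1, 4), colnames(m))
  p <- nb_pvalues(m, f, dispersion = 0.1)
  expect_equal(unname(p[1]), nb_tail_oracle(40, 10, 0.1),
               tolerance = 1e-12)
  expect_error(nb_pvalues(m, f, dispersion = 0), "dispersion")

  # direct check of the distributional quantity itself
  expect_equal(pnbinom(39, size = 10, mu = 10, lower.tail = FALSE),
               nb_tail_oracle(40, 10, 0.1), tolerance = 1e-12)
})

test_that("zero observed count gives p = 1; zero baseline floored", {
  m <- matrix(c(50, 50, 50, 0,
                0, 0, 0, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("b1", "b2"),
                              c("E_baseline_1", "E_baseline_2",
                                "E_baseline_3", "E")))
  f <- stats::setNames(rep(1, 4), colnames(m))
  p <- nb_pvalues(m, f)
  expect_identical(unname(p[1]), 1)
  expect_gt(p[2], 0)
  expect_lt(p[2], 0.01)
})

test_that("NB test is calibrated on null draws", {
  # baselines pinned at the true mean so the draws follow the test's own
  # null NB(100, 0.1) exactly; the estimated-baseline case is covered by
  # the dual-filter error-control tests
  set.seed(11)
  n <- 10000
  m <- cbind(rep(100, n), rep(100, n), rep(100, n),
             rnbinom(n, size = 10, mu = 100))
  dimnames(m) <- list(paste0("b", 1:n),
                      c("E_baseline_1", "E_baseline_2", "E_baseline_3",
                        "E"))
  f <- stats::setNames(rep(1, 4), colnames(m))
  p <- nb_pvalues(m, f, dispersion = 0.1)
  rej <- mean(p <= 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("BH q-values follow the step-up formula", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(21)
  p <- runif(50)^2
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("dual detection filter applies both thresholds", {
  res <- data.frame(fdr = c(0.0009, 0.0009, 0.002),
                    read_fraction = c(0.002, 0.0005, 0.01))
  out <- call_detections(res)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))
})

test_that("clonal reduction counts distinct molecule tags", {
  reads <- data.frame(barcode = rep("b1", 5), sample = "s1",
                      tag = c("t1", "t1", "t2", "t2", "t2"))
  expect_identical(clonal_reduce(reads)$count, 2L)
  reads$tag <- paste0("t", 1:5)
  expect_identical(clonal_reduce(reads)$count, 5L)
  expect_message(out <- clonal_reduce(reads[c("barcode", "sample")]),
                 "raw read")
  expect_identical(out$count, 5L)
})

test_that("null experiments stay below the expected false-call rate", {
  cfg <- sim_config(seed = 31, n_loci = 6, n_healthy = 20, n_pre = 1,
                    n_post = 1, enrichment_fold = 1,
                    transcript_length_range = c(200, 600),
                    response_prob_by_class = c(healthy = 0.5, pre = 0.5,
                                               post = 0.5),
                    n_viral = 0)
  lib <- data.frame(peptide = sprintf("P%03d", 1:400),
                    allele = rep(cfg$hla_pool, each = 100))
  co <- sim_cohort(cfg, lib)
  ct <- sim_barcode_counts(cfg, co$truth, lib, co$sample_sheet)
  det <- detect_responses(ct)
  expect_lte(mean(det$significant), 0.002)
})

test_that("planted 50-fold responders are detected with high sensitivity", {
  cfg <- sim_config(seed = 41, n_loci = 6, n_healthy = 8, n_pre = 1,
                    n_post = 1, enrichment_fold = 50, baseline_depth = 100,
                    response_prob_by_class = c(healthy = 0.05, pre = 0.05,
                                               post = 0.05),
                    transcript_length_range = c(200, 600), n_viral = 0)
  lib <- data.frame(peptide = sprintf("P%03d", 1:300),
                    allele = rep(cfg$hla_pool, each = 75))
  co <- sim_cohort(cfg, lib)
  ct <- sim_barcode_counts(cfg, co$truth, lib, co$sample_sheet)
  det <- detect_responses(ct)
  key_det <- paste(det$sample, det$barcode)
  truth_pairs <- which(co$truth, arr.ind = TRUE)
  key_true <- paste(rownames(co$truth)[truth_pairs[, 1]],
                    ct$annotation$barcode[truth_pairs[, 2]])
  sens <- mean(key_true %in% key_det[det$significant])
  expect_gt(sens, 0.95)
  # and every detection satisfies both filters by construction
  sig <- det[det$significant, ]
  expect_true(all(sig$fdr < 0.001 & sig$read_fraction >= 0.001))
})

test_that("counts tables round-trip through TSV", {
  cfg <- tiny_cfg(seed = 51)
  lib <- data.frame(peptide = sprintf("P%02d", 1:8),
                    allele = rep(cfg$hla_pool, 2))
  co <- sim_cohort(cfg, lib)
  ct <- sim_barcode_counts(cfg, co$truth, lib, co$sample_sheet)
  path <- tempfile(fileext = ".tsv")
  write_counts_tsv(ct, path)
  back <- read_counts_tsv(path, annotation = ct$annotation)
  expect_equal(back$counts, ct$counts)
  expect_identical(back$columns[order(back$columns$column), ],
                   ct$columns[order(ct$columns$column), ],
                   ignore_attr = TRUE)
})
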