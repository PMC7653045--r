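make_sheet <- function() {
  data.frame(
    sample_id = c("H1", "P1_pre", "P1_c1", "P1_c6", "P2_pre", "P2_post"),
    individual_id = c("H1", "P1", "P1", "P1", "P2", "P2"),
    class = c("healthy", "pre-AZA", "post-AZA", "post-AZA", "pre-AZA",
              "post-AZA"),
    alleles = c("HLA-A*02:01", "HLA-A*02:01;HLA-B*07:02",
                "HLA-A*02:01;HLA-B*07:02", "HLA-A*02:01;HLA-B*07:02",
                "HLA-A*02:01", "HLA-A*02:01"),
    outcome = c(NA, "responder", "responder", "responder",
                "non-responder", "non-responder"),
    stringsAsFactors = FALSE)
}

make_lib <- function() {
  data.frame(peptide = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
             allele = c("HLA-A*02:01", "HLA-B*07:02", "HLA-A*02:01"),
             source_loci = c("ERVX-1", "ERVX-1;ERVX-2", "ERVX-2"),
             antigen_class = "HERV", stringsAsFactors = FALSE)
}

test_that("detections aggregate with any-timepoint OR over samples", {
  det <- data.frame(sample = c("P1_c1", "P1_c6"),
                    peptide = "AAAAAAAAA", allele = "HLA-A*02:01",
                    significant = TRUE, stringsAsFactors = FALSE)
  rm_ <- aggregate_responses(det, make_sheet(), make_lib())
  # both post-treatment detections collapse into one positive cell
  expect_identical(sum(rm_$status == 1L, na.rm = TRUE), 1L)
  post_row <- rm_$rows$individual_id == "P1" & rm_$rows$class == "post-AZA"
  expect_identical(unname(rm_$status[post_row, 1]), 1L)
  # the same peptide in P1's pre row is tested but negative
  pre_row <- rm_$rows$individual_id == "P1" & rm_$rows$class == "pre-AZA"
  expect_identical(unname(rm_$status[pre_row, 1]), 0L)
})

test_that("cells for uncarried alleles are not-tested", {
  rm_ <- aggregate_responses(data.frame(), make_sheet(), make_lib())
  # H1 and P2 lack HLA-B*07:02: its column is NA for them
  b7 <- 2L
  expect_true(is.na(rm_$status[rm_$rows$individual_id == "H1", b7]))
  expect_true(all(is.na(
    rm_$status[rm_$rows$individual_id == "P2", b7])))
  expect_true(all(rm_$status[rm_$rows$individual_id == "P1", b7] == 0L))
  # empty detections: nothing positive, tested cells all 0
  expect_identical(sum(rm_$status == 1L, na.rm = TRUE), 0L)
})

test_that("detections referencing unknown samples error", {
  det <- data.frame(sample = "NOPE", peptide = "AAAAAAAAA",
                    allele = "HLA-A*02:01", significant = TRUE)
  expect_error(aggregate_responses(det, make_sheet(), make_lib()), "NOPE")
})

test_that("epitope classification splits patient / healthy / shared", {
  det <- data.frame(
    sample = c("H1", "P1_pre", "P2_pre"),
    peptide = c("AAAAAAAAA", "AAAAAAAAA", "DDDDDDDDD"),
    allele = c("HLA-A*02:01", "HLA-A*02:01", "HLA-A*02:01"),
    significant = TRUE, stringsAsFactors = FALSE)
  rm_ <- aggregate_responses(det, make_sheet(), make_lib())
  cl <- classify_epitopes(rm_)
  expect_identical(unname(cl$counts),
                   c(1L, 0L, 1L))  # patient-only, healthy-only, shared
  expect_identical(
    cl$catalog$cohort_label[cl$catalog$peptide == "AAAAAAAAA"],
    "patient and healthy donor")
  # no positives -> all zero
  rm0 <- aggregate_responses(data.frame(), make_sheet(), make_lib())
  expect_identical(unname(classify_epitopes(rm0)$counts), c(0L, 0L, 0L))
})

test_that("the packaged epitope catalog reproduces the published counts", {
  cat29 <- load_epitope_catalog()
  expect_identical(nrow(cat29), 29L)
  s <- summarize_catalog(cat29)
  expect_identical(s$distinct_peptides, 29L)
  expect_identical(s$per_allele[["HLA-A*01:01"]], 4L)
  expect_identical(s$per_allele[["HLA-A*02:01"]], 10L)
  expect_identical(s$per_allele[["HLA-B*07:02"]], 10L)
  expect_identical(s$per_allele[["HLA-B*08:01"]], 5L)
  expect_identical(unname(count_cohort_labels(cat29)), c(23L, 5L, 1L))
  # classification recomputed from a responder matrix agrees
  cl <- classify_epitopes(catalog_to_matrix(cat29))
  expect_identical(unname(cl$counts), c(23L, 5L, 1L))
  expect_identical(sum(cl$counts), 29L)
})

test_that("reactivity score follows the positive/tested definition", {
  # 2 patient rows each testing 10 peptides of one locus, 1 positive
  lib <- data.frame(peptide = sprintf("P%02d", 1:10),
                    allele = "HLA-A*02:01",
                    source_loci = "ERVH-5", antigen_class = "HERV",
                    stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = c("P1_pre", "P2_pre"),
                      individual_id = c("P1", "P2"),
                      class = "pre-AZA", alleles = "HLA-A*02:01",
                      outcome = "responder", stringsAsFactors = FALSE)
  det <- data.frame(sample = "P1_pre", peptide = "P03",
                    allele = "HLA-A*02:01", significant = TRUE)
  rm_ <- aggregate_responses(det, sheet, lib)
  expect_equal(unname(reactivity_score(rm_)[["ERVH-5"]]), 1 / 20)
  # no positives -> 0
  rm0 <- aggregate_responses(data.frame(), sheet, lib)
  expect_equal(unname(reactivity_score(rm0)[["ERVH-5"]]), 0)
})

test_that("multi-locus peptides credit every source locus", {
  rm_ <- aggregate_responses(
    data.frame(sample = "P1_pre", peptide = "CCCCCCCCC",
               allele = "HLA-B*07:02", significant = TRUE),
    make_sheet(), make_lib())
  rs <- reactivity_score(rm_)
  expect_gt(rs[["ERVX-1"]], 0)
  expect_gt(rs[["ERVX-2"]], 0)
  ep <- epitope_proportion(rm_)
  # ERVX-1 has 2 predicted entries, 1 detected; ERVX-2 has 2, 1 detected
  expect_equal(unname(ep[["ERVX-1"]]), 0.5)
  expect_equal(unname(ep[["ERVX-2"]]), 0.5)
  expect_true(all(ep <= 1))
})

test_that("scores match a hand enumeration on a 3-locus toy matrix", {
  lib <- data.frame(
    peptide = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD", "EEEEEEEEE"),
    allele = "HLA-A*02:01",
    source_loci = c("L1", "L1;L2", "L2", "L3"),
    antigen_class = "HERV", stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = c("H1", "P1_pre", "P2_pre"),
                      individual_id = c("H1", "P1", "P2"),
                      class = c("healthy", "pre-AZA", "pre-AZA"),
                      alleles = "HLA-A*02:01", outcome = NA,
                      stringsAsFactors = FALSE)
  det <- data.frame(sample = c("P1_pre", "P1_pre", "H1"),
                    peptide = c("AAAAAAAAA", "CCCCCCCCC", "EEEEEEEEE"),
                    allele = "HLA-A*02:01", significant = TRUE)
  rm_ <- aggregate_responses(det, sheet, lib)
  rs <- reactivity_score(rm_)
  # L1: entries A, C; patient rows P1 (A+, C+), P2 (both neg):
  # positives 2, tested 4
  expect_equal(unname(rs[["L1"]]), 2 / 4)
  # L2: entries C, D; positives 1 (C in P1), tested 4
  expect_equal(unname(rs[["L2"]]), 1 / 4)
  # L3: only healthy positive; patient positives 0, tested 2
  expect_equal(unname(rs[["L3"]]), 0)
  ep <- epitope_proportion(rm_)
  expect_equal(unname(ep[c("L1", "L2", "L3")]), c(1, 0.5, 0))
})

test_that("scores are invariant to row order and duplicate samples", {
  lib <- make_lib()
  sheet <- make_sheet()
  det <- data.frame(sample = c("P1_c1", "P1_c6", "P2_pre"),
                    peptide = c("AAAAAAAAA", "AAAAAAAAA", "DDDDDDDDD"),
                    allele = "HLA-A*02:01", significant = TRUE)
  rm1 <- aggregate_responses(det, sheet, lib)
  # reversing sheet rows must not change scores (P1_c1/P1_c6 collapse)
  rm2 <- aggregate_responses(det, sheet[rev(seq_len(nrow(sheet))), ], lib)
  expect_equal(reactivity_score(rm1)[sort(names(reactivity_score(rm1)))],
               reactivity_score(rm2)[sort(names(reactivity_score(rm2)))])
  expect_equal(epitope_proportion(rm1)[c("ERVX-1", "ERVX-2")],
               epitope_proportion(rm2)[c("ERVX-1", "ERVX-2")])
})

test_that("recovered reactivity ranks track configured response rates", {
  # per-locus response probability increases L1 < L2 < L3; the recovered
  # reactivity scores should correlate positively with them
  set.seed(5)
  probs <- c(L1 = 0.02, L2 = 0.1, L3 = 0.3)
  lib <- data.frame(peptide = sprintf("P%02d", 1:30),
                    allele = "HLA-A*02:01",
                    source_loci = rep(names(probs), each = 10),
                    antigen_class = "HERV", stringsAsFactors = FALSE)
  sheet <- data.frame(sample_id = sprintf("P%02d_pre", 1:20),
                      individual_id = sprintf("P%02d", 1:20),
                      class = "pre-AZA", alleles = "HLA-A*02:01",
                      outcome = NA, stringsAsFactors = FALSE)
  det <- do.call(rbind, lapply(sheet$sample_id, function(s) {
    hit <- runif(30) < probs[lib$source_loci]
    if (!any(hit)) return(NULL)
    data.frame(sample = s, peptide = lib$peptide[hit],
               allele = "HLA-A*02:01", significant = TRUE)
  }))
  rm_ <- aggregate_responses(det, sheet, lib)
  rs <- reactivity_score(rm_)[names(probs)]
  expect_gt(cor(rs, probs, method = "spearman"), 0)
  expect_true(all(diff(rs) > 0))
})
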