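#' Aggregate detections into an individual-level responder matrix
#'
#' Collapses per-sample detections over timepoints: one row per individual
#' per class (healthy / pre-AZA / post-AZA; a patient's pre and post rows
#' are distinct but share the individual ID), one column per (peptide,
#' allele) library entry. Cells are tri-state: `1` positive (a detection in
#' any of that individual's samples of the class), `0` tested but negative,
#' `NA` not tested (the individual lacks the restricting allele, or the
#' entry was absent from every panel of those samples).
#'
#' @param detections data.frame from [detect_responses()] (only rows with
#'   `significant == TRUE` count as detections) with columns `sample`,
#'   `peptide`, `allele`; or an already-filtered detection set.
#' @param sample_sheet data.frame with `sample_id`, `individual_id`,
#'   `class`, `alleles` (semicolon-separated).
#' @param library Library data.frame (`peptide`, `allele`, optionally
#'   `source_loci`, `antigen_class`) defining the columns.
#' @return An object of class `responder_matrix`: list with `status`
#'   (integer matrix rows x columns with NA), `rows` (individual, class),
#'   `entries` (the library), and `tested` (logical matrix).
#' @export
aggregate_responses <- function(detections, sample_sheet, library) {
  stopifnot(all(c("sample_id", "individual_id", "class", "alleles") %in%
                  names(sample_sheet)),
            all(c("peptide", "allele") %in% names(library)))
  if (nrow(detections) > 0 &&
      !all(detections$sample %in% sample_sheet$sample_id)) {
    bad <- setdiff(unique(detections$sample), sample_sheet$sample_id)
    stop("detections reference unknown sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("significant" %in% names(detections)) {
    detections <- detections[detections$significant, , drop = FALSE]
  }
  rows <- unique(sample_sheet[c("individual_id", "class")])
  rownames(rows) <- NULL
  row_key <- paste(rows$individual_id, rows$class, sep = "|")
  ekey <- paste(library$peptide, library$allele, sep = "|")

  status <- matrix(NA_integer_, nrow(rows), nrow(library),
                   dimnames = list(row_key, ekey))
  for (r in seq_len(nrow(rows))) {
    sub <- sample_sheet[sample_sheet$individual_id == rows$individual_id[r] &
                          sample_sheet$class == rows$class[r], ]
    al <- unique(unlist(strsplit(sub$alleles, ";", fixed = TRUE)))
    tested <- library$allele %in% al
    status[r, tested] <- 0L
    det <- detections[detections$sample %in% sub$sample_id, , drop = FALSE]
    if (nrow(det) > 0) {
      dkey <- unique(paste(det$peptide, det$allele, sep = "|"))
      hit <- tested & ekey %in% dkey
      status[r, hit] <- 1L
    }
  }
  structure(list(status = status, rows = rows, entries = library),
            class = "responder_matrix")
}

#' @export
print.responder_matrix <- function(x, ...) {
  cat("responder_matrix:", nrow(x$status), "individual-class rows x",
      ncol(x$status), "pMHC entries;",
      sum(x$status == 1L, na.rm = TRUE), "positive cells\n")
  invisible(x)
}

.is_patient_class <- function(class) class %in% c("pre-AZA", "post-AZA")

#' Classify recognized epitopes by cohort
#'
#' Labels every (peptide, allele) entry positive in at least one row as
#' `patient` (positive only in pre-/post-treatment patient rows),
#' `healthy donor` (only in healthy rows), or
#' `patient and healthy donor` (shared).
#'
#' @param matrix A [aggregate_responses()] result.
#' @param antigen_class Restrict to entries of this antigen class
#'   (default `"HERV"`; ignored when the library has no `antigen_class`).
#' @return A list with `catalog` (data.frame `peptide`, `allele`,
#'   `source_loci`, `cohort_label`) and `counts` (named vector
#'   `patient_only`, `healthy_only`, `shared`).
#' @export
classify_epitopes <- function(matrix, antigen_class = "HERV") {
  stopifnot(inherits(matrix, "responder_matrix"))
  ent <- matrix$entries
  keep <- if ("antigen_class" %in% names(ent)) {
    ent$antigen_class == antigen_class
  } else {
    rep(TRUE, nrow(ent))
  }
  pat <- .is_patient_class(matrix$rows$class)
  pos_pat <- colSums(matrix$status[pat, , drop = FALSE] == 1L,
                     na.rm = TRUE) > 0
  pos_hd <- colSums(matrix$status[!pat, , drop = FALSE] == 1L,
                    na.rm = TRUE) > 0
  rec <- keep & (pos_pat | pos_hd)
  label <- ifelse(pos_pat & pos_hd, "patient and healthy donor",
                  ifelse(pos_pat, "patient", "healthy donor"))
  catalog <- data.frame(
    peptide = ent$peptide[rec], allele = ent$allele[rec],
    source_loci = if ("source_loci" %in% names(ent)) ent$source_loci[rec]
      else NA_character_,
    cohort_label = label[rec], stringsAsFactors = FALSE)
  rownames(catalog) <- NULL
  list(catalog = catalog, counts = count_cohort_labels(catalog))
}

#' Tally cohort labels of an epitope catalog
#'
#' @param catalog data.frame with a `cohort_label` column (`patient`,
#'   `healthy donor`, or `patient and healthy donor`).
#' @return Named integer vector `patient_only`, `healthy_only`, `shared`.
#' @export
count_cohort_labels <- function(catalog) {
  c(patient_only = sum(catalog$cohort_label == "patient"),
    healthy_only = sum(catalog$cohort_label == "healthy donor"),
    shared = sum(catalog$cohort_label == "patient and healthy donor"))
}

#' Summarize an epitope catalog
#'
#' Counts catalog entries per HLA allele, total entries, and distinct
#' peptide sequences (a peptide restricted by two alleles is two entries
#' but one distinct peptide).
#'
#' @param catalog data.frame with `peptide` and `allele` columns.
#' @return List with `per_allele` (named integer vector), `total_entries`,
#'   `distinct_peptides`.
#' @export
summarize_catalog <- function(catalog) {
  stopifnot(all(c("peptide", "allele") %in% names(catalog)))
  per <- table(catalog$allele)
  list(per_allele = stats::setNames(as.integer(per), names(per)),
       total_entries = nrow(catalog),
       distinct_peptides = length(unique(catalog$peptide)))
}

# peptide-entry -> loci list helper
.entry_loci <- function(entries) {
  strsplit(ifelse(is.na(entries$source_loci), "", entries$source_loci),
           ";", fixed = TRUE)
}

#' Per-HERV T cell reactivity score
#'
#' For each locus, the number of positive peptide observations summed over
#' patient rows divided by the number of tested peptide observations summed
#' over the same rows (a score in `[0, 1]`). Multi-locus peptides credit
#' every listed source locus. Loci never tested in any patient row get
#' `NA`.
#'
#' @param matrix A [aggregate_responses()] result.
#' @param library Optional library defining loci (defaults to the matrix's
#'   entries).
#' @return Named numeric vector of scores per locus.
#' @export
reactivity_score <- function(matrix, library = NULL) {
  stopifnot(inherits(matrix, "responder_matrix"))
  ent <- library %||% matrix$entries
  loci_list <- .entry_loci(matrix$entries)
  loci <- sort(unique(unlist(.entry_loci(ent))))
  pat <- .is_patient_class(matrix$rows$class)
  st <- matrix$status[pat, , drop = FALSE]
  pos <- colSums(st == 1L, na.rm = TRUE)
  tested <- colSums(!is.na(st))
  vapply(stats::setNames(loci, loci), function(l) {
    in_l <- vapply(loci_list, function(s) l %in% s, logical(1))
    denom <- sum(tested[in_l])
    if (denom == 0) return(NA_real_)
    sum(pos[in_l]) / denom
  }, numeric(1))
}

#' Per-HERV proportion of predicted epitopes ever detected
#'
#' For each locus, the number of distinct (peptide, allele) entries of that
#' locus positive in at least one patient row, divided by the number of
#' predicted entries of the locus in the library.
#'
#' @inheritParams reactivity_score
#' @return Named numeric vector of proportions per locus.
#' @export
epitope_proportion <- function(matrix, library = NULL) {
  stopifnot(inherits(matrix, "responder_matrix"))
  ent <- library %||% matrix$entries
  loci_list <- .entry_loci(matrix$entries)
  loci <- sort(unique(unlist(.entry_loci(ent))))
  pat <- .is_patient_class(matrix$rows$class)
  pos <- colSums(matrix$status[pat, , drop = FALSE] == 1L, na.rm = TRUE) > 0
  vapply(stats::setNames(loci, loci), function(l) {
    in_l <- vapply(loci_list, function(s) l %in% s, logical(1))
    if (!any(in_l)) return(NA_real_)
    sum(pos[in_l]) / sum(in_l)
  }, numeric(1))
}

#' Published catalog of 29 HERV-derived CD8+ T cell epitopes
#'
#' Loads the packaged catalog of HERV-derived T cell epitopes identified by
#' DNA-barcoded pMHC multimer screening of myeloid-malignancy patients and
#' healthy donors: 29 distinct 9-11mer peptides restricted by HLA-A*01:01
#' (4), HLA-A*02:01 (10), HLA-B*07:02 (10), and HLA-B*08:01 (5); 23 seen
#' only in patients, 5 only in healthy donors, and 1 shared. Multi-locus
#' peptides keep their full semicolon-joined source-locus list in a single
#' row.
#'
#' @return data.frame `peptide`, `allele`, `source_loci`, `cohort_label`.
#' @export
load_epitope_catalog <- function() {
  path <- system.file("extdata", "herv_epitopes.tsv",
                      package = "hervscreen", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Rebuild a minimal responder matrix from an epitope catalog
#'
#' Inverts a cohort-labelled catalog into the smallest responder matrix
#' consistent with it (one patient row, one healthy-donor row; every entry
#' tested in both), so matrix-level operations such as
#' [classify_epitopes()] can be exercised against a published catalog.
#'
#' @param catalog data.frame `peptide`, `allele`, `source_loci`,
#'   `cohort_label`.
#' @return A `responder_matrix`.
#' @export
catalog_to_matrix <- function(catalog) {
  rows <- data.frame(individual_id = c("P1", "H1"),
                     class = c("pre-AZA", "healthy"),
                     stringsAsFactors = FALSE)
  pat <- catalog$cohort_label %in% c("patient", "patient and healthy donor")
  hd <- catalog$cohort_label %in% c("healthy donor",
                                    "patient and healthy donor")
  status <- rbind(as.integer(pat), as.integer(hd))
  dimnames(status) <- list(paste(rows$individual_id, rows$class, sep = "|"),
                           paste(catalog$peptide, catalog$allele, sep = "|"))
  entries <- catalog[c("peptide", "allele", "source_loci")]
  entries$antigen_class <- "HERV"
  structure(list(status = status, rows = rows, entries = entries),
            class = "responder_matrix")
}
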