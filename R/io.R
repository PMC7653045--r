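#' Read HERV transcripts from FASTA
#'
#' Header convention: `>locus|accession`. A header without `|` uses the
#' full header as both locus and accession.
#'
#' @param path FASTA file.
#' @return data.frame `locus`, `accession`, `sequence`.
#' @export
read_transcripts <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  parts <- strsplit(hdr, "|", fixed = TRUE)
  data.frame(locus = vapply(parts, `[`, character(1), 1L),
             accession = vapply(parts, function(p) {
               if (length(p) >= 2L) p[2] else p[1]
             }, character(1)),
             sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write HERV transcripts to FASTA
#'
#' @param transcripts data.frame `locus`, `accession`, `sequence`.
#' @param path Output FASTA path.
#' @export
write_transcripts <- function(transcripts, path) {
  ss <- Biostrings::DNAStringSet(transcripts$sequence)
  names(ss) <- paste(transcripts$locus, transcripts$accession, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write a counts table to TSV
#'
#' Wide format: first column `barcode`, one column per sample; baseline
#' replicates follow the `<experiment>_baseline_{1,2,3}` naming convention
#' from which roles are recovered on read.
#'
#' @param counts A [counts_table()].
#' @param path Output TSV path.
#' @export
write_counts_tsv <- function(counts, path) {
  stopifnot(inherits(counts, "counts_table"))
  df <- data.frame(barcode = rownames(counts$counts), counts$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts table from TSV
#'
#' @param path TSV written by [write_counts_tsv()] (or following the same
#'   column naming convention).
#' @param annotation Optional pMHC annotation data.frame
#'   (`barcode`, `peptide`, `allele`, ...).
#' @return A [counts_table()].
#' @export
read_counts_tsv <- function(path, annotation = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$barcode
  cols <- colnames(m)
  is_base <- grepl("_baseline_[0-9]+$", cols)
  columns <- data.frame(
    column = cols,
    experiment = ifelse(is_base, sub("_baseline_[0-9]+$", "", cols), cols),
    role = ifelse(is_base, "baseline", "sorted"),
    stringsAsFactors = FALSE)
  counts_table(m, columns, annotation = annotation)
}

#' Read / write a sample sheet
#'
#' CSV with columns `sample_id`, `individual_id`, `class`, `timepoint`,
#' `alleles` (semicolon-separated), `outcome`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet data.frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a TPM expression matrix
#'
#' TSV, first column `locus`, one column per sample.
#'
#' @param path TSV path.
#' @return Numeric matrix (locus x sample).
#' @export
read_tpm <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_tpm
#' @param tpm Numeric matrix (locus x sample).
#' @export
write_tpm <- function(tpm, path) {
  df <- data.frame(locus = rownames(tpm), tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
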