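#' Translate a transcript from its first start codon
#'
#' Locates the first `ATG` anywhere on the given (sense) strand, which fixes
#' the reading frame, and translates consecutive codons until the first stop
#' codon (TAA/TAG/TGA), exclusive. If no stop codon is reached, translation
#' runs to the last complete codon; a trailing incomplete codon is dropped.
#' Codons containing characters outside `{A, C, G, T}` translate to `X`.
#' A sequence without any `ATG` translates to the empty string.
#'
#' @param sequence A single nucleotide string (IUPAC alphabet, case
#'   insensitive).
#' @return An amino-acid string (possibly empty).
#' @export
#' @examples
#' translate_first_orf("ATGAAATAA")   # "MK"
#' translate_first_orf("CCATGGCCTGA") # "MA"
translate_first_orf <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  start <- regexpr("ATG", s, fixed = TRUE)[1]
  if (start < 0L) return("")
  s <- substr(s, start, nchar(s))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) return("")
  codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- character(n_codon)
  code <- Biostrings::GENETIC_CODE
  for (i in seq_len(n_codon)) {
    cd <- codons[i]
    if (cd %in% STOP_CODONS) {
      aa <- aa[seq_len(i - 1L)]
      return(paste(aa, collapse = ""))
    }
    aa[i] <- if (grepl("[^ACGT]", cd)) "X" else unname(code[cd])
  }
  paste(aa, collapse = "")
}

#' Enumerate overlapping peptides of the requested lengths
#'
#' All substrings of each requested length, in order of start position, one
#' block per length. The count is `sum_L max(0, nchar(aa) - L + 1)`, so a
#' protein shorter than 9 residues yields no peptides (the "long enough"
#' exclusion).
#'
#' @param aa Amino-acid string.
#' @param lengths Integer vector of peptide lengths (default 9:11).
#' @return data.frame with columns `peptide`, `start`, `length`.
#' @export
#' @examples
#' nrow(chop_peptides(strrep("A", 11))) # 3 + 2 + 1 = 6
chop_peptides <- function(aa, lengths = 9:11) {
  stopifnot(is.character(aa), length(aa) == 1L, length(lengths) >= 1L)
  n <- nchar(aa)
  out <- lapply(sort(unique(as.integer(lengths))), function(L) {
    k <- n - L + 1L
    if (k <= 0L) return(NULL)
    data.frame(peptide = substring(aa, seq_len(k), seq_len(k) + L - 1L),
               start = seq_len(k), length = L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), start = integer(0),
                      length = integer(0), stringsAsFactors = FALSE)
  }
  out
}

#' Build the candidate epitope library from HERV transcripts
#'
#' Translates each transcript from its first ORF, enumerates 9-11mers,
#' drops peptides containing ambiguous residues (`X`), queries the binding
#' rank provider for every (peptide, allele) pair, keeps pairs with
#' percentile rank `<= threshold`, and merges records across transcripts and
#' loci via [merge_annotate()]. A peptide passing the threshold for several
#' alleles yields one record per allele.
#'
#' @param transcripts data.frame with columns `locus`, `accession`,
#'   `sequence` (see [read_transcripts()] / [sim_transcripts()]).
#' @param provider A rank provider: function `(peptide, allele) -> rank in
#'   (0, 100]`, deterministic per pair (see [sim_rank_provider()],
#'   [rank_table_provider()]).
#' @param alleles Character vector of HLA alleles to predict against.
#' @param threshold Inclusion threshold on the percentile rank; the
#'   comparison is `<=`, so a rank of exactly `threshold` is included.
#' @return A deduplicated library data.frame: `peptide`, `allele`, `rank`,
#'   `affinity`, `source_loci` (semicolon-joined), `occurrences`.
#' @export
build_library <- function(transcripts, provider, alleles, threshold = 2) {
  stopifnot(threshold > 0, is.function(provider),
            all(c("locus", "sequence") %in% names(transcripts)))
  recs <- list()
  for (i in seq_len(nrow(transcripts))) {
    aa <- translate_first_orf(transcripts$sequence[i])
    pep <- chop_peptides(aa)
    if (nrow(pep) == 0L) next
    keep <- !grepl("X", pep$peptide, fixed = TRUE)
    if (!any(keep)) next
    recs[[length(recs) + 1L]] <- data.frame(
      peptide = pep$peptide[keep], locus = transcripts$locus[i],
      stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) return(empty_library())
  pep_loci <- unique(do.call(rbind, recs))

  peptides <- unique(pep_loci$peptide)
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      stringsAsFactors = FALSE)
  rank <- tryCatch(provider(grid$peptide, grid$allele), error = function(e) {
    stop("rank provider failed: ", conditionMessage(e), call. = FALSE)
  })
  if (length(rank) != nrow(grid) || anyNA(rank)) {
    bad <- if (anyNA(rank)) which(is.na(rank))[1] else 1L
    stop(sprintf("rank provider failed on (%s, %s)",
                 grid$peptide[bad], grid$allele[bad]), call. = FALSE)
  }
  hit <- rank <= threshold
  if (!any(hit)) return(empty_library())
  hits <- data.frame(peptide = grid$peptide[hit], allele = grid$allele[hit],
                     rank = rank[hit], affinity = NA_real_,
                     stringsAsFactors = FALSE)
  # expand each hit once per source locus, then deduplicate
  loci_of <- split(pep_loci$locus, pep_loci$peptide)
  expanded <- hits[rep(seq_len(nrow(hits)),
                       lengths(loci_of[hits$peptide])), ]
  expanded$source_loci <- unlist(loci_of[hits$peptide], use.names = FALSE)
  merge_annotate(expanded)
}

empty_library <- function() {
  data.frame(peptide = character(0), allele = character(0),
             rank = numeric(0), affinity = numeric(0),
             source_loci = character(0), occurrences = integer(0),
             stringsAsFactors = FALSE)
}

#' Deduplicate library records and annotate multi-locus origin
#'
#' Collapses records to one row per (peptide, allele). `source_loci` becomes
#' the union of contributing loci (semicolon-joined, sorted) and
#' `occurrences` the number of distinct loci; duplicates arising from
#' several transcripts of the same locus count that locus once. Conflicting
#' ranks for an identical (peptide, allele) pair abort, since the rank
#' provider must be deterministic.
#'
#' @param records data.frame with columns `peptide`, `allele`, `rank`,
#'   optionally `affinity`, and `source_loci` (one locus per row, or
#'   semicolon-joined).
#' @return One record per (peptide, allele) with updated `source_loci` and
#'   `occurrences`.
#' @export
merge_annotate <- function(records) {
  stopifnot(all(c("peptide", "allele", "rank", "source_loci") %in%
                  names(records)))
  if (nrow(records) == 0L) return(empty_library())
  key <- paste(records$peptide, records$allele, sep = "\r")
  rank_by_key <- tapply(records$rank, key, function(r) length(unique(r)))
  if (any(rank_by_key > 1L)) {
    k <- names(rank_by_key)[rank_by_key > 1L][1]
    stop("conflicting ranks for (",
         gsub("\r", ", ", k, fixed = TRUE),
         "): rank provider must be deterministic", call. = FALSE)
  }
  first <- !duplicated(key)
  out <- records[first, c("peptide", "allele", "rank")]
  out$affinity <- if ("affinity" %in% names(records)) {
    records$affinity[first]
  } else {
    NA_real_
  }
  loci <- tapply(records$source_loci, key, function(s) {
    sort(unique(unlist(strsplit(s, ";", fixed = TRUE))))
  })
  out$source_loci <- vapply(loci[key[first]], paste, character(1),
                            collapse = ";")
  out$occurrences <- lengths(loci[key[first]])
  rownames(out) <- NULL
  out
}

#' Use a precomputed rank table in place of a live predictor
#'
#' Wraps a (peptide, allele, rank) table — e.g. an exported run of an
#' external MHC binding predictor — as a rank provider for
#' [build_library()]. Pairs absent from the table raise an error, matching
#' the abort-on-provider-failure contract.
#'
#' @param table data.frame with columns `peptide`, `allele`, `rank`, and
#'   optionally `affinity`.
#' @return A vectorized function `(peptide, allele) -> rank`.
#' @export
rank_table_provider <- function(table) {
  stopifnot(all(c("peptide", "allele", "rank") %in% names(table)))
  key <- paste(table$peptide, table$allele, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    r <- tapply(table$rank, key, function(x) length(unique(x)))
    if (any(r[dup] > 1L)) {
      stop("rank table has conflicting entries for the same (peptide, ",
           "allele) pair", call. = FALSE)
    }
  }
  lookup <- stats::setNames(table$rank, key)
  function(peptide, allele) {
    q <- paste(peptide, allele, sep = "\r")
    r <- lookup[q]
    if (anyNA(r)) {
      i <- which(is.na(r))[1]
      stop(sprintf("no rank for (%s, %s)", peptide[i], allele[i]),
           call. = FALSE)
    }
    unname(r)
  }
}
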