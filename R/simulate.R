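#' Simulation configuration for a synthetic HERV multimer screen
#'
#' Bundles every tunable of the synthetic-data generators. Defaults mirror the
#' study design the pipeline targets: 66 HERV loci, the four most common
#' Caucasian HLA class I alleles, 27 healthy donors and 34 patients sampled
#' before (33) and after (34) hypomethylating therapy, a binder-calling rate
#' near 1.9% of (peptide, allele) pairs, triplicate baseline barcode samples
#' with negative-binomial noise at dispersion 0.1, and log-normal TPM with a
#' disease-driven upshift.
#'
#' @param seed Integer seed; identical seeds give byte-identical outputs.
#' @param n_loci Number of HERV loci to simulate.
#' @param transcript_length_range Length-2 integer vector, nucleotides.
#' @param orf_fraction Fraction of loci carrying a translatable ORF long
#'   enough to yield 9-11mer peptides; the remainder either lack a start
#'   codon or carry an ORF shorter than 27 nt.
#' @param binder_rate Marginal probability that a random (peptide, allele)
#'   pair is predicted a binder (percentile rank <= 2).
#' @param n_healthy,n_pre,n_post Cohort sizes (healthy donors, patients with
#'   a pre-treatment sample, patients with a post-treatment sample).
#' @param hla_pool Character vector of 4 HLA allele names.
#' @param response_prob_by_class Named numeric, per-peptide recognition
#'   probability for classes `healthy`, `pre`, `post` (HERV antigens).
#' @param viral_response_prob_by_class Same, for the viral control antigens.
#' @param post_gain_prob Probability that a patient gains a response
#'   post-treatment that was absent pre-treatment (default 0: pre and post
#'   share the individual's truth).
#' @param n_viral Number of viral control pMHCs included in every panel.
#' @param enrichment_fold Mean fold enrichment of a true responder's barcode
#'   in the sorted sample relative to baseline; must be >= 1.
#' @param baseline_depth Mean reads per barcode in baseline samples.
#' @param nb_dispersion Negative-binomial dispersion phi
#'   (variance = mu + phi * mu^2).
#' @param tpm_disease_effect log2-scale expression shift of disease-
#'   upregulated loci in patients.
#' @param tpm_noise_sd log2-scale s.d. of per-sample expression noise.
#' @param post_shift_sd log2-scale s.d. of the heterogeneous per-patient
#'   post-treatment expression shift (0 disables it).
#' @param n_expr_healthy,n_expr_pre,n_expr_post Expression-matrix sample
#'   sizes.
#'
#' @return An object of class `herv_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_loci = 8)
#' cfg$binder_rate
sim_config <- function(seed = 1L,
                       n_loci = 66L,
                       transcript_length_range = c(400L, 2500L),
                       orf_fraction = 57 / 66,
                       binder_rate = 0.019,
                       n_healthy = 27L,
                       n_pre = 33L,
                       n_post = 34L,
                       hla_pool = c("HLA-A*01:01", "HLA-A*02:01",
                                    "HLA-B*07:02", "HLA-B*08:01"),
                       response_prob_by_class = c(healthy = 1e-4,
                                                  pre = 8e-4,
                                                  post = 8e-4),
                       viral_response_prob_by_class = c(healthy = 0.25,
                                                        pre = 0.135,
                                                        post = 0.18),
                       post_gain_prob = 0,
                       n_viral = 19L,
                       enrichment_fold = 50,
                       baseline_depth = 100,
                       nb_dispersion = 0.1,
                       tpm_disease_effect = 2,
                       tpm_noise_sd = 0.5,
                       post_shift_sd = 0,
                       n_expr_healthy = 14L,
                       n_expr_pre = 18L,
                       n_expr_post = 16L) {
  cfg <- list(seed = as.integer(seed), n_loci = as.integer(n_loci),
              transcript_length_range = as.integer(transcript_length_range),
              orf_fraction = orf_fraction, binder_rate = binder_rate,
              n_healthy = as.integer(n_healthy), n_pre = as.integer(n_pre),
              n_post = as.integer(n_post), hla_pool = hla_pool,
              response_prob_by_class = response_prob_by_class,
              viral_response_prob_by_class = viral_response_prob_by_class,
              post_gain_prob = post_gain_prob, n_viral = as.integer(n_viral),
              enrichment_fold = enrichment_fold,
              baseline_depth = baseline_depth, nb_dispersion = nb_dispersion,
              tpm_disease_effect = tpm_disease_effect,
              tpm_noise_sd = tpm_noise_sd, post_shift_sd = post_shift_sd,
              n_expr_healthy = as.integer(n_expr_healthy),
              n_expr_pre = as.integer(n_expr_pre),
              n_expr_post = as.integer(n_expr_post))
  validate_sim_config(cfg)
  structure(cfg, class = "herv_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  if (cfg$n_loci < 1L) {
    stop("configuration error: n_loci must be >= 1", call. = FALSE)
  }
  r <- cfg$transcript_length_range
  if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < 120L) {
    stop("configuration error: invalid transcript_length_range ",
         "(need min <= max and min >= 120 nt)", call. = FALSE)
  }
  if (!(cfg$binder_rate > 0 && cfg$binder_rate < 1)) {
    stop("configuration error: binder_rate must lie in (0, 1)", call. = FALSE)
  }
  probs <- c(cfg$orf_fraction, cfg$response_prob_by_class,
             cfg$viral_response_prob_by_class, cfg$post_gain_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: all probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (!all(c("healthy", "pre", "post") %in%
             names(cfg$response_prob_by_class))) {
    stop("configuration error: response_prob_by_class needs entries ",
         "'healthy', 'pre', 'post'", call. = FALSE)
  }
  if (cfg$enrichment_fold < 1) {
    stop("configuration error: enrichment_fold must be >= 1", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) {
    stop("configuration error: nb_dispersion must be > 0", call. = FALSE)
  }
  if (length(cfg$hla_pool) != 4L) {
    stop("configuration error: hla_pool must name 4 alleles", call. = FALSE)
  }
  invisible(cfg)
}

# Sub-generator seeds are derived with distinct small offsets so each
# generator is deterministic regardless of call order.
sim_seed <- function(cfg, stage) {
  off <- c(transcripts = 101L, ranks = 202L, cohort = 303L,
           counts = 404L, expression = 505L)[[stage]]
  (cfg$seed + off) %% .Machine$integer.max
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# n random codons avoiding stop codons (keeps a planted reading frame open)
# and optionally ATG.
random_codons <- function(n, avoid_atg = FALSE) {
  pool <- setdiff(all_codons(), STOP_CODONS)
  if (avoid_atg) pool <- setdiff(pool, "ATG")
  if (n == 0L) return(character(0))
  sample(pool, n, replace = TRUE)
}

# Random nucleotide string of length n guaranteed to contain no ATG in any
# frame or offset.
random_seq_no_atg <- function(n) {
  if (n <= 0L) return("")
  s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  while (grepl("ATG", s, fixed = TRUE)) {
    s <- gsub("ATG", "ATC", s, fixed = TRUE)
  }
  s
}

#' Simulate HERV transcript sequences with planted open reading frames
#'
#' Generates one or two transcript variants per locus. A configurable
#' fraction of loci carry a planted ORF (first ATG anywhere in the sequence,
#' in-frame stop, >= 33 nt) whose translation yields 9-11mer peptides; the
#' remaining loci either contain no ATG at all or an ORF shorter than 27 nt,
#' so they drop out at the "long enough to include 9-11mers" step.
#' Transcripts of the same locus share the planted ORF (they model accession
#' variants of one gene), which exercises same-locus peptide deduplication
#' downstream.
#'
#' @param cfg A [sim_config()].
#' @return A data.frame with columns `locus`, `accession`, `sequence`, plus
#'   attributes `has_orf` (named logical per locus) and `orf_aa` (named
#'   character, the planted protein per ORF-bearing locus).
#' @export
sim_transcripts <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(sim_seed(cfg, "transcripts"), {
    n <- cfg$n_loci
    loci <- sprintf("ERVSIM-%d", seq_len(n))
    n_orf <- round(cfg$orf_fraction * n)
    has_orf <- seq_len(n) <= n_orf
    # non-ORF loci alternate between "no ATG anywhere" and "ORF < 27 nt"
    short_orf <- !has_orf & (seq_len(n) %% 2L == 0L)

    rows <- list()
    orf_aa <- character(0)
    for (i in seq_len(n)) {
      len <- sample(seq(cfg$transcript_length_range[1],
                        cfg$transcript_length_range[2]), 1L)
      if (has_orf[i]) {
        max_aa <- min(150L, (len - 60L) %/% 3L)
        aa_len <- sample(30:max(30L, max_aa), 1L)
        body <- random_codons(aa_len - 1L)          # codons after ATG
        cassette <- paste0("ATG", paste(body, collapse = ""),
                           sample(STOP_CODONS, 1L))
        orf_aa[loci[i]] <- translate_first_orf(cassette)
      } else if (short_orf[i]) {
        k <- sample(0:6, 1L)                        # aa length k+1 <= 7 < 9
        cassette <- paste0("ATG",
                           paste(random_codons(k, avoid_atg = TRUE),
                                 collapse = ""),
                           sample(STOP_CODONS, 1L))
      } else {
        cassette <- ""
      }
      n_tx <- if (runif(1) < 0.25) 2L else 1L
      for (t in seq_len(n_tx)) {
        pre_len <- if (nzchar(cassette)) {
          sample(0:max(0L, len - nchar(cassette) - 30L), 1L)
        } else 0L
        prefix <- random_seq_no_atg(pre_len)
        suf_len <- max(0L, len - nchar(cassette) - pre_len)
        suffix <- if (nzchar(cassette)) {
          paste(sample(c("A", "C", "G", "T"), suf_len, replace = TRUE),
                collapse = "")
        } else {
          random_seq_no_atg(len)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          locus = loci[i],
          accession = sprintf("SIM%05d.%d", i, t),
          sequence = paste0(prefix, cassette, suffix),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "has_orf") <- stats::setNames(has_orf, loci)
    attr(out, "orf_aa") <- orf_aa
    out
  })
}

# 32-bit-safe rolling string hash (values stay below 2^53 in double space).
.str_hash <- function(s) {
  m <- 2147483563
  vapply(s, function(x) {
    h <- 17
    for (c in utf8ToInt(x)) h <- (h * 131 + c) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Deterministic mock MHC binding-rank predictor
#'
#' Returns a rank-provider closure `f(peptide, allele)` standing in for an
#' external MHC class I binding predictor. Ranks are percentile scores in
#' (0, 100], deterministic per (peptide, allele, seed), and calibrated so
#' that the marginal probability of `rank <= 2` equals `binder_rate`.
#' Peptides containing residues outside the 20 standard amino acids get the
#' sentinel rank 100 (never a binder).
#'
#' @param cfg A [sim_config()]; uses `seed` and `binder_rate`.
#' @return A vectorized function `(peptide, allele) -> rank`.
#' @export
#' @examples
#' f <- sim_rank_provider(sim_config(seed = 1))
#' f("SLYNTVATL", "HLA-A*02:01")
sim_rank_provider <- function(cfg) {
  validate_sim_config(cfg)
  base_seed <- sim_seed(cfg, "ranks")
  br <- cfg$binder_rate
  function(peptide, allele) {
    stopifnot(length(peptide) == length(allele) || length(allele) == 1L)
    if (length(allele) == 1L) allele <- rep(allele, length(peptide))
    hp <- .str_hash(peptide)
    ha <- .str_hash(allele)
    seeds <- (hp * 69069 + ha * 37 + base_seed) %% 2147483647
    u <- vapply(seeds, function(s) with_seed(s, runif(1)), numeric(1))
    rank <- ifelse(u <= br, pmax(u / br * 2, 1e-9),
                   2 + (u - br) / (1 - br) * 98)
    bad <- vapply(strsplit(peptide, ""), function(ch) {
      any(!ch %in% STANDARD_AA)
    }, logical(1))
    rank[bad] <- 100
    rank
  }
}

#' Simulate a screening cohort and its ground-truth responder table
#'
#' Builds the sample sheet (healthy donors plus patients with paired pre-
#' and post-treatment samples) and, for a given pMHC library, the true
#' per-sample recognition table. Each individual carries 1-4 HLA alleles
#' drawn uniformly from the pool; a peptide can only be truly recognized by
#' an individual carrying its restricting allele. Patients' pre and post
#' samples share the individual's truth; post samples may add responses with
#' probability `post_gain_prob`.
#'
#' @param cfg A [sim_config()].
#' @param library A peptide library data.frame with columns `peptide`,
#'   `allele` and optionally `antigen_class` (entries labelled `"viral"` use
#'   the viral response probabilities).
#' @return A list with `sample_sheet` (sample_id, individual_id, class,
#'   timepoint, alleles, outcome) and `truth` (logical matrix, sample x
#'   library entry).
#' @export
sim_cohort <- function(cfg, library) {
  validate_sim_config(cfg)
  stopifnot(all(c("peptide", "allele") %in% names(library)))
  with_seed(sim_seed(cfg, "cohort"), {
    n_pat <- max(cfg$n_pre, cfg$n_post)
    ind <- c(sprintf("H%02d", seq_len(cfg$n_healthy)),
             sprintf("P%02d", seq_len(n_pat)))
    cls0 <- c(rep("healthy", cfg$n_healthy), rep("patient", n_pat))
    alleles <- vapply(ind, function(i) {
      paste(sample(cfg$hla_pool, sample(1:4, 1L)), collapse = ";")
    }, character(1))
    outcome <- ifelse(cls0 == "patient",
                      sample(c("responder", "non-responder"), length(ind),
                             replace = TRUE), NA_character_)

    pats <- ind[cls0 == "patient"]
    sheet <- rbind(
      data.frame(sample_id = ind[cls0 == "healthy"],
                 individual_id = ind[cls0 == "healthy"],
                 class = "healthy", timepoint = NA_integer_,
                 alleles = alleles[cls0 == "healthy"],
                 outcome = NA_character_, stringsAsFactors = FALSE),
      data.frame(sample_id = paste0(pats[seq_len(cfg$n_pre)], "_pre"),
                 individual_id = pats[seq_len(cfg$n_pre)],
                 class = "pre-AZA", timepoint = 0L,
                 alleles = alleles[pats[seq_len(cfg$n_pre)]],
                 outcome = outcome[match(pats[seq_len(cfg$n_pre)], ind)],
                 stringsAsFactors = FALSE),
      data.frame(sample_id = paste0(pats[seq_len(cfg$n_post)], "_post"),
                 individual_id = pats[seq_len(cfg$n_post)],
                 class = "post-AZA", timepoint = 6L,
                 alleles = alleles[pats[seq_len(cfg$n_post)]],
                 outcome = outcome[match(pats[seq_len(cfg$n_post)], ind)],
                 stringsAsFactors = FALSE))
    rownames(sheet) <- NULL

    ag <- if ("antigen_class" %in% names(library)) {
      library$antigen_class
    } else {
      rep("HERV", nrow(library))
    }
    prob_for <- function(class_key, ag_class) {
      p <- ifelse(ag_class == "viral",
                  cfg$viral_response_prob_by_class[[class_key]],
                  cfg$response_prob_by_class[[class_key]])
      p
    }
    carries <- function(id, al) {
      al %in% strsplit(alleles[[id]], ";", fixed = TRUE)[[1]]
    }

    # individual-level base truth ("pre" probability for patients)
    base_truth <- matrix(FALSE, length(ind), nrow(library),
                         dimnames = list(ind, NULL))
    gain <- matrix(FALSE, length(ind), nrow(library),
                   dimnames = list(ind, NULL))
    for (i in ind) {
      key <- if (cls0[match(i, ind)] == "healthy") "healthy" else "pre"
      ok <- vapply(library$allele, carries, logical(1), id = i)
      p <- prob_for(key, ag)
      base_truth[i, ] <- ok & (runif(nrow(library)) < p)
      if (cls0[match(i, ind)] == "patient" && cfg$post_gain_prob > 0) {
        gain[i, ] <- ok & (runif(nrow(library)) < cfg$post_gain_prob)
      }
    }

    truth <- matrix(FALSE, nrow(sheet), nrow(library),
                    dimnames = list(sheet$sample_id, NULL))
    for (r in seq_len(nrow(sheet))) {
      i <- sheet$individual_id[r]
      truth[r, ] <- if (sheet$class[r] == "post-AZA") {
        base_truth[i, ] | gain[i, ]
      } else {
        base_truth[i, ]
      }
    }
    list(sample_sheet = sheet, truth = truth)
  })
}

#' Simulate DNA-barcode read counts for a multimer screen
#'
#' For every sample in the sheet, emits one experiment: three baseline
#' replicate columns (the unsorted pMHC pool, negative-binomial counts with
#' mean `baseline_depth` and dispersion `nb_dispersion`) and one sorted
#' column where barcodes of truly recognized pMHCs are enriched
#' `enrichment_fold`-fold while the rest follow the baseline null. Only
#' HLA-matched library entries are in a sample's panel; counts outside the
#' panel are `NA`.
#'
#' @param cfg A [sim_config()].
#' @param truth Logical truth matrix from [sim_cohort()].
#' @param library Peptide library with `peptide`, `allele`, and optionally
#'   `antigen_class`, `source_loci`.
#' @param sample_sheet Sample sheet from [sim_cohort()].
#' @return A [counts_table()].
#' @export
sim_barcode_counts <- function(cfg, truth, library, sample_sheet) {
  validate_sim_config(cfg)
  if (nrow(library) != ncol(truth)) {
    stop("truth and library refer to different peptide sets", call. = FALSE)
  }
  if (cfg$enrichment_fold < 1) {
    stop("configuration error: enrichment_fold must be >= 1", call. = FALSE)
  }
  with_seed(sim_seed(cfg, "counts"), {
    nb <- nrow(library)
    barcodes <- sprintf("BC%04d", seq_len(nb))
    size <- 1 / cfg$nb_dispersion
    cols <- list()
    meta <- list()
    for (r in seq_len(nrow(sample_sheet))) {
      sid <- sample_sheet$sample_id[r]
      al <- strsplit(sample_sheet$alleles[r], ";", fixed = TRUE)[[1]]
      panel <- library$allele %in% al
      for (b in 1:3) {
        v <- rep(NA_real_, nb)
        v[panel] <- rnbinom(sum(panel), size = size, mu = cfg$baseline_depth)
        cols[[paste0(sid, "_baseline_", b)]] <- v
        meta[[length(meta) + 1L]] <- data.frame(
          column = paste0(sid, "_baseline_", b), experiment = sid,
          role = "baseline", stringsAsFactors = FALSE)
      }
      mu <- ifelse(truth[sid, ], cfg$enrichment_fold * cfg$baseline_depth,
                   cfg$baseline_depth)
      v <- rep(NA_real_, nb)
      v[panel] <- rnbinom(sum(panel), size = size, mu = mu[panel])
      cols[[sid]] <- v
      meta[[length(meta) + 1L]] <- data.frame(
        column = sid, experiment = sid, role = "sorted",
        stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- barcodes
    ann <- data.frame(barcode = barcodes, peptide = library$peptide,
                      allele = library$allele,
                      antigen_class = if ("antigen_class" %in% names(library))
                        library$antigen_class else "HERV",
                      source_loci = if ("source_loci" %in% names(library))
                        library$source_loci else NA_character_,
                      stringsAsFactors = FALSE)
    counts_table(counts, do.call(rbind, meta), annotation = ann)
  })
}

#' Simulate a HERV TPM expression matrix
#'
#' Log-normal TPM per locus and sample: each locus gets a baseline log2
#' level, patient samples of disease-upregulated loci are shifted by
#' `tpm_disease_effect` on the log2 scale, and post-treatment columns can
#' receive an additional heterogeneous per-patient shift
#' (`post_shift_sd > 0`).
#'
#' @param cfg A [sim_config()].
#' @param loci Character vector of locus names.
#' @param upregulated Logical vector, which loci carry the disease effect;
#'   defaults to all.
#' @return A numeric matrix (locus x sample) with attribute `samples`, a
#'   data.frame of `sample_id`, `individual_id`, `class`.
#' @export
sim_expression <- function(cfg, loci, upregulated = NULL) {
  validate_sim_config(cfg)
  if (is.null(upregulated)) upregulated <- rep(TRUE, length(loci))
  stopifnot(length(upregulated) == length(loci))
  with_seed(sim_seed(cfg, "expression"), {
    base <- rnorm(length(loci), mean = 0, sd = 1)
    ids <- c(sprintf("EH%02d", seq_len(cfg$n_expr_healthy)),
             sprintf("EP%02d", seq_len(cfg$n_expr_pre)))
    samples <- rbind(
      data.frame(sample_id = sprintf("EH%02d", seq_len(cfg$n_expr_healthy)),
                 individual_id = sprintf("EH%02d",
                                         seq_len(cfg$n_expr_healthy)),
                 class = "healthy", stringsAsFactors = FALSE),
      data.frame(sample_id = sprintf("EP%02d_pre", seq_len(cfg$n_expr_pre)),
                 individual_id = sprintf("EP%02d", seq_len(cfg$n_expr_pre)),
                 class = "pre-AZA", stringsAsFactors = FALSE),
      data.frame(sample_id = sprintf("EP%02d_post",
                                     seq_len(cfg$n_expr_post)),
                 individual_id = sprintf("EP%02d", seq_len(cfg$n_expr_post)),
                 class = "post-AZA", stringsAsFactors = FALSE))
    post_shift <- rnorm(cfg$n_expr_pre, 0, cfg$post_shift_sd)
    m <- matrix(NA_real_, length(loci), nrow(samples),
                dimnames = list(loci, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- base
      if (samples$class[j] != "healthy") {
        mu <- mu + ifelse(upregulated, cfg$tpm_disease_effect, 0)
      }
      if (samples$class[j] == "post-AZA") {
        k <- match(samples$individual_id[j],
                   sprintf("EP%02d", seq_len(cfg$n_expr_pre)))
        mu <- mu + post_shift[k]
      }
      m[, j] <- 2^(mu + rnorm(length(loci), 0, cfg$tpm_noise_sd))
    }
    attr(m, "samples") <- samples
    m
  })
}

#' Simulate a complete screen end-to-end
#'
#' Convenience orchestrator: transcripts -> mock rank predictor -> peptide
#' library (HERV plus a viral control panel) -> cohort and ground truth ->
#' barcode counts -> expression matrix.
#'
#' @param cfg A [sim_config()].
#' @param threshold Binding-rank inclusion threshold for the library.
#' @return A list with elements `transcripts`, `provider`, `library`,
#'   `cohort` (sample sheet + truth), `counts`, `expression`,
#'   `immunogenic_truth` (per-locus logical: any truly recognized peptide).
#' @export
sim_screen <- function(cfg, threshold = 2) {
  tx <- sim_transcripts(cfg)
  provider <- sim_rank_provider(cfg)
  lib <- build_library(tx, provider, cfg$hla_pool, threshold = threshold)
  lib$antigen_class <- "HERV"
  viral <- viral_control_panel(cfg)
  lib <- rbind(lib, viral)
  cohort <- sim_cohort(cfg, lib)
  counts <- sim_barcode_counts(cfg, cohort$truth, lib, cohort$sample_sheet)
  herv_idx <- lib$antigen_class == "HERV"
  imm <- vapply(unique(tx$locus), function(l) {
    in_locus <- herv_idx & vapply(strsplit(lib$source_loci, ";"),
                                  function(s) l %in% s, logical(1))
    pat <- grepl("^P", rownames(cohort$truth))
    any(cohort$truth[pat, in_locus, drop = FALSE])
  }, logical(1))
  expr <- sim_expression(cfg, unique(tx$locus))
  list(transcripts = tx, provider = provider, library = lib,
       cohort = cohort, counts = counts, expression = expr,
       immunogenic_truth = imm)
}

# Fixed-size synthetic viral control panel (CMV/EBV/Flu stand-ins): random
# 9mers, alleles round-robin over the pool, rank 0.5 (always included).
viral_control_panel <- function(cfg) {
  with_seed(sim_seed(cfg, "ranks") + 7L, {
    pep <- vapply(seq_len(cfg$n_viral), function(i) {
      paste(sample(STANDARD_AA, 9, replace = TRUE), collapse = "")
    }, character(1))
    data.frame(peptide = pep,
               allele = rep(cfg$hla_pool, length.out = cfg$n_viral),
               rank = 0.5, affinity = NA_real_,
               source_loci = "VIRAL-CTRL", occurrences = 1L,
               antigen_class = "viral", stringsAsFactors = FALSE)
  })
}
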