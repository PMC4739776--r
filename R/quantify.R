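#' Poisson expression test with Benjamini-Hochberg correction
#'
#' Tests each transcript's RNA-seq read count against a null in which the
#' library is spread over the tested transcripts in proportion to length:
#' `lambda_t = library_size * length_t / sum(length)`. The p-value is the
#' upper Poisson tail `P(X >= observed)`; q-values are BH-adjusted across
#' all tested transcripts. A transcript is called expressed when `q < 1e-3`
#' and it has more than `reads_min` reads, or when it encodes a called
#' peptide (pass ids via `called_ids`).
#'
#' @param counts tibble with `transcript_id` and `n_reads`.
#' @param lengths named vector of transcript lengths (nt), or a transcript
#'   tibble.
#' @param library_size total reads; defaults to `sum(counts$n_reads)`.
#' @param q_max,reads_min expression thresholds.
#' @param called_ids transcripts encoding a called peptide (always
#'   expressed).
#' @return Tibble with `lambda`, `p`, `q` and `expressed`.
#' @export
test_expression <- function(counts, lengths, library_size = NULL,
                            q_max = 1e-3, reads_min = 10L,
                            called_ids = character()) {
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$transcript_id)
  }
  library_size <- library_size %||% sum(counts$n_reads)
  if (is.null(library_size) || library_size <= 0) {
    abort("library size must be positive")
  }
  len <- lengths[counts$transcript_id]
  if (any(is.na(len))) abort("transcript length missing for some counts")
  lambda <- library_size * len / sum(len)
  p <- ppois(counts$n_reads - 1L, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  mutate(counts,
         lambda = unname(lambda), p = unname(p), q = unname(q),
         expressed = (.data$q < q_max & .data$n_reads > reads_min) |
           .data$transcript_id %in% called_ids)
}

#' Translation efficiency per ORF
#'
#' TE is the log2 ratio of ribosome-profiling RPKM to RNA-seq RPKM over the
#' same ORF span. An ORF is eligible only when both libraries give it more
#' than `reads_min` reads and when at most `max_masked` of its span is
#' overlapped by called ORFs of a different type (pass the overlapped
#' fraction via `masked_fraction`; it defaults to 0). Eligible ORFs with a
#' zero RNA-seq RPKM are flagged infinite and excluded from summaries.
#'
#' @param orfs tibble with `orf_id`, `start`, `stop`.
#' @param ribo_reads,rna_reads named vectors of read counts per `orf_id`.
#' @param ribo_library,rna_library library sizes.
#' @param reads_min both counts must exceed this (default 10).
#' @param masked_fraction named vector in `[0,1]`: fraction of each ORF's
#'   span overlapped by other ORF types.
#' @param max_masked eligibility ceiling on `masked_fraction`.
#' @return Tibble with `ribo_rpkm`, `rna_rpkm`, `log2_te`, `eligible`.
#' @export
translation_efficiency <- function(orfs, ribo_reads, rna_reads,
                                   ribo_library, rna_library,
                                   reads_min = 10L,
                                   masked_fraction = NULL,
                                   max_masked = 0.5) {
  nr <- unname(ribo_reads[orfs$orf_id]); nr[is.na(nr)] <- 0
  na <- unname(rna_reads[orfs$orf_id]); na[is.na(na)] <- 0
  len <- orfs$stop - orfs$start
  mf <- if (is.null(masked_fraction)) rep(0, nrow(orfs)) else
    unname(masked_fraction[orfs$orf_id])
  mf[is.na(mf)] <- 0
  ribo_rpkm <- rpkm(nr, len, ribo_library)
  rna_rpkm <- rpkm(na, len, rna_library)
  infinite <- nr > reads_min & mf < max_masked & rna_rpkm == 0
  eligible <- nr > reads_min & na > reads_min & mf < max_masked &
    rna_rpkm > 0
  log2_te <- ifelse(eligible, log2(ribo_rpkm / rna_rpkm), NA_real_)
  tibble(orf_id = orfs$orf_id,
         ribo_reads = nr, rna_reads = na,
         ribo_rpkm = ribo_rpkm, rna_rpkm = rna_rpkm,
         log2_te = log2_te, eligible = eligible, infinite = infinite)
}

#' Fraction of each ORF overlapped by other ORF types
#'
#' Per-nucleotide mask used for translation-efficiency eligibility: for
#' each ORF, the fraction of its span covered by (called) ORFs of a
#' different `orf_type` on the same transcript.
#'
#' @param orfs tibble with `orf_id`, `transcript_id`, `start`, `stop`,
#'   `orf_type`.
#' @return Named numeric vector of masked fractions per `orf_id`.
#' @export
orf_overlap_mask <- function(orfs) {
  out <- numeric(nrow(orfs))
  for (tx in unique(orfs$transcript_id)) {
    d <- orfs[orfs$transcript_id == tx, ]
    L <- max(d$stop)
    for (i in seq_len(nrow(d))) {
      others <- d[d$orf_type != d$orf_type[i], ]
      if (nrow(others) == 0) next
      cov <- logical(L)
      for (j in seq_len(nrow(others))) {
        cov[(others$start[j] + 1L):others$stop[j]] <- TRUE
      }
      span <- (d$start[i] + 1L):d$stop[i]
      out[match(d$orf_id[i], orfs$orf_id)] <- mean(cov[span])
    }
  }
  setNames(out, orfs$orf_id)
}

#' Relative translation efficiency class
#'
#' Compares a non-canonical ORF's TE to the canonical ORF of the same gene:
#' `high` when more than three-fold higher, `low` when more than three-fold
#' lower, otherwise `neither`.
#'
#' @param te_noncanonical,te_canonical log2 TE values (vectorised).
#' @return Character vector in `{high, low, neither}`.
#' @export
relative_te_class <- function(te_noncanonical, te_canonical) {
  ratio <- 2^(te_noncanonical - te_canonical)
  dplyr::case_when(
    ratio > 3 ~ "high",
    ratio < 1 / 3 ~ "low",
    TRUE ~ "neither"
  )
}

#' Cytosol:nucleus RNA localisation ratio
#'
#' log2 ratio of cytosolic to nuclear RPKM per transcript. Transcripts with
#' `min_total_reads` or fewer combined reads are excluded (`NA`), as are
#' zero denominators when `epsilon = 0`.
#'
#' @param cyt_rpkm,nuc_rpkm RPKM vectors from matched fractions.
#' @param total_reads combined RNA-seq read count per transcript.
#' @param min_total_reads exclusion floor (the rule is strictly more than
#'   50 combined reads).
#' @param epsilon optional pseudocount added to both RPKMs.
#' @return Numeric vector of log2 C:N ratios (`NA` when excluded).
#' @export
cn_ratio <- function(cyt_rpkm, nuc_rpkm, total_reads,
                     min_total_reads = 50L, epsilon = 0) {
  ok <- total_reads > min_total_reads & (nuc_rpkm + epsilon) > 0
  ifelse(ok, log2((cyt_rpkm + epsilon) / (nuc_rpkm + epsilon)), NA_real_)
}
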