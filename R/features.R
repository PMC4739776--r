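#' Percentage of maximum entropy (PME)
#'
#' Measures uniformity of A-site read coverage across an ORF. With `N`
#' total reads over `L` codons, the ORF is divided into regions: one codon
#' per region when `N > L`, otherwise regions of `floor(L/N)` codons with
#' the remainder appended to the last region. With region read fractions
#' `p_i = N_i / N`, `PME = H / max(H)` where `H = -sum(p_i log2 p_i)` and
#' `max(H) = log2(n_regions)`, the entropy of perfectly even coverage. A
#' value of 1 indicates uniform coverage (active translation); 0 indicates
#' all reads at a single location, as for footprints protected by
#' non-ribosomal complexes. Degenerate inputs (`N = 0`, or a single region)
#' return 0.
#'
#' @param codon_counts integer vector of A-site reads per codon (stop codon
#'   excluded).
#' @return PME value in `[0, 1]`.
#' @export
pme <- function(codon_counts) {
  L <- length(codon_counts)
  N <- sum(codon_counts)
  if (N == 0 || L == 0) return(0)
  if (N > L) {
    region <- codon_counts
  } else {
    rl <- L %/% N
    n_regions <- L %/% rl
    grp <- pmin((seq_len(L) - 1L) %/% rl + 1L, n_regions)
    region <- as.numeric(tapply(codon_counts, grp, sum))
  }
  k <- length(region)
  if (k < 2) return(0)
  p <- region / N
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  h / log2(k) + 0   # + 0 normalises IEEE negative zero
}

#' Codon-position read fractions
#'
#' Fractions of A-site reads at the 1st, 2nd and 3rd nucleotide of codons
#' across an ORF (stop codon excluded). Actively translated ORFs show
#' strong 3-nt periodicity, with roughly 65/24/11% of reads at the three
#' positions.
#'
#' @param counts integer vector of per-nucleotide A-site counts over the
#'   ORF's coding span (length divisible by 3, stop codon excluded).
#' @return Named numeric vector `c(f1, f2, f3)`; zeros when there are no
#'   reads.
#' @export
codon_fractions <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(c(f1 = 0, f2 = 0, f3 = 0))
  ph <- (seq_along(counts) - 1L) %% 3L
  c(f1 = sum(counts[ph == 0L]) / n,
    f2 = sum(counts[ph == 1L]) / n,
    f3 = sum(counts[ph == 2L]) / n)
}

#' Reads per kilobase per million mapped reads
#'
#' @param n_reads read count over the region.
#' @param length_nt region length in nt (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @return RPKM value.
#' @export
rpkm <- function(n_reads, length_nt, library_size) {
  if (any(length_nt <= 0)) abort("rpkm: region length must be positive")
  if (any(library_size <= 0)) abort("rpkm: library size must be positive")
  n_reads / (length_nt / 1000) / (library_size / 1e6)
}

#' Feature vectors for candidate ORFs
#'
#' Computes, for every candidate ORF, the classifier features and
#' expression measures: codon-position fractions `f1`/`f2`/`f3`, `pme`,
#' `n_reads` (A-site reads over the coding span, stop codon excluded),
#' `n_codons` and `rpkm`. ORFs with no reads are flagged `expressed_orf =
#' FALSE` (they carry zero fractions and PME 0).
#'
#' @param orfs candidate-ORF tibble (needs `orf_id`, `transcript_id`,
#'   `start`, `stop`).
#' @param profiles A-site profile tibble from [assign_asites()].
#' @param library_size total A-site-assigned reads; defaults to the sum
#'   over `profiles`.
#' @return `orfs` with feature columns appended.
#' @export
orf_features <- function(orfs, profiles, library_size = NULL) {
  library_size <- library_size %||% sum(profiles$n_reads)
  if (library_size <= 0) library_size <- 1
  pm <- setNames(profiles$profile, profiles$transcript_id)
  feats <- lapply(seq_len(nrow(orfs)), function(i) {
    o <- orfs[i, ]
    p <- pm[[o$transcript_id]]
    span_len <- o$stop - o$start
    if (is.null(p)) {
      cnt <- integer(span_len - 3L)
    } else {
      cnt <- p[(o$start + 1L):(o$stop - 3L)]  # stop codon excluded
    }
    fr <- codon_fractions(cnt)
    per_codon <- colSums(matrix(cnt, nrow = 3L))
    n <- sum(cnt)
    tibble(f1 = fr[[1]], f2 = fr[[2]], f3 = fr[[3]],
           pme = pme(per_codon),
           n_reads = as.integer(n),
           n_codons = as.integer(length(per_codon)),
           rpkm = rpkm(n, span_len, library_size))
  })
  out <- dplyr::bind_cols(orfs, bind_rows(feats))
  mutate(out, expressed_orf = .data$n_reads > 0L)
}
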