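genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

codon_aa <- function(codon, code) {
  aa <- code[codon]
  ifelse(is.na(aa), NA_character_, unname(aa))
}

# Per-codon synonymous site count: at each of the 3 positions, the fraction
# of the 3 possible point mutations that preserve the amino acid. Mutations
# creating a stop codon count as nonsynonymous (NG86 convention).
ng_codon_sites <- function(codon, code = genetic_code()) {
  bases <- c("A", "C", "G", "T")
  aa0 <- code[codon]
  if (is.na(aa0) || aa0 == "*") abort(paste0("invalid codon: ", codon))
  s <- 0
  for (p in 1:3) {
    orig <- substr(codon, p, p)
    for (b in setdiff(bases, orig)) {
      mut <- codon
      substr(mut, p, p) <- b
      aa1 <- code[mut]
      if (!is.na(aa1) && aa1 != "*" && aa1 == aa0) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

split_codons <- function(seq) {
  seq <- norm_dna(seq)
  n <- nchar(seq)
  if (n %% 3L != 0L) abort("coding sequence length not divisible by 3")
  if (n == 0) return(character(0))
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Synonymous and nonsynonymous site counts (NG86)
#'
#' Counts synonymous (`S`) and nonsynonymous (`N`) sites for a coding
#' sequence following Nei and Gojobori's approximate method: each codon
#' position contributes the fraction of its three possible point mutations
#' that are synonymous; mutations creating stop codons are counted
#' nonsynonymous. `S + N` equals the sequence length. Codons containing
#' ambiguous bases are skipped with a warning.
#'
#' @param seq coding sequence (DNA or RNA alphabet), no internal stops.
#' @param code named genetic-code vector (default: standard code).
#' @return Named numeric vector `c(S, N)`.
#' @export
ng_sites <- function(seq, code = genetic_code()) {
  codons <- split_codons(seq)
  if (length(codons) == 0) return(c(S = 0, N = 0))
  known <- codons %in% names(code)
  if (any(known & code[codons] == "*")) {
    abort("internal stop codon in coding sequence")
  }
  if (any(!known)) {
    warn(paste0(sum(!known), " codon(s) with ambiguous bases skipped"))
    codons <- codons[known]
  }
  tab <- table(codons)
  per <- vapply(names(tab), ng_codon_sites, numeric(2), code = code)
  tot <- per %*% as.numeric(tab)
  c(S = tot[1], N = tot[2])
}

# Classify the differences between two codons, averaging over all minimal
# mutational pathways (1, 2 or 6 orderings for 1, 2, 3 differences).
# Pathways passing through a stop-codon intermediate are excluded; if every
# pathway is blocked, all pathways are used.
ng_codon_differences <- function(a, b, code = genetic_code()) {
  dpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(dpos)
  if (k == 0) return(c(Sd = 0, Nd = 0))
  paths <- if (k == 1) matrix(dpos, 1) else
    t(apply(gtools_permutations(k), 1, function(i) dpos[i]))
  score_path <- function(ord) {
    cur <- a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      aa_cur <- code[cur]; aa_nxt <- code[nxt]
      if (is.na(aa_nxt) || aa_nxt == "*") blocked <- TRUE
      if (identical(unname(aa_cur), unname(aa_nxt))) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  }
  sc <- t(apply(paths, 1, score_path))
  ok <- sc[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(sc))
  c(Sd = mean(sc[ok, 1]), Nd = mean(sc[ok, 2]))
}

# Minimal permutation generator (avoids depending on gtools).
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Pathway-averaged substitution counts (NG86)
#'
#' Classifies the nucleotide differences between two codon-aligned coding
#' sequences as synonymous (`Sd`) or nonsynonymous (`Nd`), averaging over
#' all minimal mutational pathways within each codon. Pathways through
#' stop-codon intermediates are excluded from the average.
#'
#' @param a,b codon-aligned, gapless coding sequences of equal length.
#' @param code genetic-code vector.
#' @return Named numeric vector `c(Sd, Nd)`.
#' @export
ng_differences <- function(a, b, code = genetic_code()) {
  ca <- split_codons(a); cb <- split_codons(b)
  if (length(ca) != length(cb)) {
    abort("aligned sequences must have equal length")
  }
  tot <- c(Sd = 0, Nd = 0)
  for (i in seq_along(ca)) {
    if (!ca[i] %in% names(code) || !cb[i] %in% names(code)) next
    tot <- tot + ng_codon_differences(ca[i], cb[i], code)
  }
  tot
}

#' Nei-Gojobori Ka/Ks for a homologous coding pair
#'
#' Computes the approximate-method ("NG") nonsynonymous and synonymous
#' substitution rates for two pre-aligned, gapless coding sequences. Site
#' counts are averaged over the two sequences; proportions `pN = Nd/N` and
#' `pS = Sd/S` receive the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)`. The ratio `Ka/Ks` carries an `undefined`
#' flag when `Ks = 0`. A proportion at or above 3/4 is saturated and raises
#' an error.
#'
#' @param a,b codon-aligned coding sequences (equal length, divisible by 3,
#'   no internal stops).
#' @param code genetic-code vector.
#' @return One-row tibble: `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`,
#'   `Ks`, `Ka`, `ka_ks`, `undefined`.
#' @export
kaks_ng <- function(a, b, code = genetic_code()) {
  sa <- ng_sites(a, code); sb <- ng_sites(b, code)
  S <- unname(sa["S"] + sb["S"]) / 2
  N <- unname(sa["N"] + sb["N"]) / 2
  d <- ng_differences(a, b, code)
  pS <- if (S > 0) d[["Sd"]] / S else 0
  pN <- if (N > 0) d[["Nd"]] / N else 0
  if (pS >= 0.75 || pN >= 0.75) {
    abort("substitution proportion saturated (p >= 3/4); correction undefined")
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS); Ka <- jc(pN)
  undefined <- Ks == 0
  tibble(S_sites = unname(S), N_sites = unname(N),
         Sd = d[["Sd"]], Nd = d[["Nd"]],
         pS = unname(pS), pN = unname(pN),
         Ks = Ks, Ka = Ka,
         ka_ks = ifelse(undefined, NA_real_, Ka / Ks),
         undefined = undefined)
}

#' Ka/Ks over a table of homologous pairs
#'
#' @param pairs tibble with columns `pair_id`, `seq_a`, `seq_b`, or a path
#'   to a paired FASTA file in which consecutive records `<id>_A`, `<id>_B`
#'   form a pair.
#' @param code genetic-code vector.
#' @return Tibble with one [kaks_ng()] row per pair.
#' @export
kaks_pairs <- function(pairs, code = genetic_code()) {
  if (is.character(pairs) && length(pairs) == 1) {
    ss <- Biostrings::readDNAStringSet(pairs)
    if (length(ss) %% 2L != 0L) abort("paired FASTA must have even records")
    ids <- sub("_[AB]$", "", names(ss))
    pairs <- tibble(
      pair_id = ids[seq(1, length(ss), 2)],
      seq_a = as.character(ss[seq(1, length(ss), 2)]),
      seq_b = as.character(ss[seq(2, length(ss), 2)])
    )
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    kaks_ng(pairs$seq_a[i], pairs$seq_b[i], code)
  })
  dplyr::bind_cols(tibble(pair_id = pairs$pair_id), bind_rows(res))
}
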