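# Shared fixture builders. All fixtures are constructed in code; nothing is
# read from disk except files the tests themselves write to tempdir().

toy_tx <- function(id = "tx1", chrom = "chr1", strand = "+",
                   exon_start = list(100L), exon_end = list(200L),
                   cds_start = NA_integer_, cds_end = NA_integer_) {
  transcript_table(
    transcript_id = id, chrom = chrom, strand = strand,
    exon_start = exon_start, exon_end = exon_end,
    cds_start = cds_start, cds_end = cds_end
  )
}

# profile tibble for one transcript from a sparse position->count spec
toy_profile <- function(id, len, at = integer(), counts = integer()) {
  p <- integer(len)
  p[at + 1L] <- counts
  tibble::tibble(transcript_id = id, n_reads = sum(p), profile = list(p))
}

# brute-force PME: explicit region partition and direct entropy sum,
# independent of the package implementation
pme_oracle <- function(codon_counts) {
  L <- length(codon_counts)
  N <- sum(codon_counts)
  if (N == 0 || L == 0) return(0)
  if (N > L) {
    regions <- as.list(seq_len(L))
  } else {
    rl <- floor(L / N)
    n_regions <- floor(L / rl)
    regions <- vector("list", n_regions)
    for (r in seq_len(n_regions)) {
      lo <- (r - 1) * rl + 1
      hi <- if (r == n_regions) L else r * rl
      regions[[r]] <- lo:hi
    }
  }
  if (length(regions) < 2) return(0)
  h <- 0
  for (r in regions) {
    p <- sum(codon_counts[r]) / N
    if (p > 0) h <- h - p * log2(p)
  }
  h / log2(length(regions))
}

# brute-force three-frame ORF scanner, position-by-position
orf_scanner_oracle <- function(seq, starts = c("ATG", "CTG", "GTG", "TTG"),
                               min_len_aa = 1L) {
  seq <- toupper(chartr("U", "T", seq))
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  for (i in seq_len(max(n - 5, 0))) {          # 1-based start of codon
    cod <- substr(seq, i, i + 2)
    if (!cod %in% starts) next
    j <- i + 3
    while (j + 2 <= n) {
      cj <- substr(seq, j, j + 2)
      if (cj %in% stops) {
        pep <- (j + 3 - i) / 3 - 1
        if (pep >= min_len_aa) {
          out[[length(out) + 1]] <-
            data.frame(start = i - 1L, stop = j + 2L,
                       start_codon = chartr("T", "U", cod),
                       peptide_length = pep)
        }
        break
      }
      j <- j + 3
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), stop = integer(),
                      start_codon = character(), peptide_length = integer()))
  }
  do.call(rbind, out)
}

# enumeration oracle for NG86 site counts of a single codon
ng_sites_oracle <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (code[[mut]] != "*" && code[[mut]] == code[[codon]]) s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small deterministic simulation shared by several tests
small_sim <- function(seed = 42L, ...) {
  cfg <- sim_config(n_mrna = 30L, n_lncrna = 6L, n_contaminant = 10L,
                    n_pseudogene = 2L, seed = seed, ...)
  simulate_transcriptome(cfg)
}
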