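#' Simulation configuration
#'
#' Defines the generative conditions for the synthetic ribosome-profiling
#' benchmark. Defaults reflect the empirical features the package targets:
#' codon-phase probabilities 0.65/0.24/0.11, footprint lengths 24-31 nt
#' with length-dependent 5'-end to A-site offsets, near-uniform per-codon
#' coverage on translated ORFs with a mild (3x) initiation peak, and
#' narrow single-position pileups on short non-coding RNA contaminants.
#' The default transcriptome carries 200 truly translated ORFs (170
#' canonical mRNA ORFs plus 30 translated lncRNA ORFs) and 200 truly
#' untranslated ones (30 lncRNA ORFs, 150 contaminant ORFs, 20 pseudogene
#' ORFs); off-frame AUG ORFs inside coding regions supply further
#' classifier negatives.
#'
#' @param n_mrna,n_lncrna,n_contaminant,n_pseudogene transcript counts per
#'   class.
#' @param lncrna_translated_fraction fraction of lncRNAs with a translated
#'   planted ORF.
#' @param uorf_rate,dorf_rate probability that an mRNA carries a planted
#'   translated uORF / dORF.
#' @param phase_probs codon-position probabilities of A-site reads.
#' @param read_lengths,length_probs footprint length distribution (nt).
#' @param true_offsets 5'-end to A-site offset per read length (nt).
#' @param orf_depth_mean,orf_depth_size negative-binomial read depth per
#'   translated ORF.
#' @param uorf_depth_mean mean depth for planted uORFs/dORFs.
#' @param untranslated_depth_mean mean sparse phase-random depth on
#'   untranslated ORFs.
#' @param contaminant_depth_mean mean pileup depth on contaminants.
#' @param init_peak weight multiplier on the start codon (initiation
#'   pausing).
#' @param rna_depth_mean mean RNA-seq reads per transcript.
#' @param rna_read_length RNA-seq read length (nt).
#' @param seed mandatory RNG seed; every stochastic step derives from it.
#' @return List of class `ribocall_sim_config`.
#' @export
sim_config <- function(n_mrna = 170L, n_lncrna = 60L, n_contaminant = 150L,
                       n_pseudogene = 20L,
                       lncrna_translated_fraction = 0.5,
                       uorf_rate = 0.25, dorf_rate = 0.1,
                       phase_probs = c(0.65, 0.24, 0.11),
                       read_lengths = 24:31,
                       length_probs = c(0.04, 0.07, 0.12, 0.18,
                                        0.22, 0.18, 0.12, 0.07),
                       true_offsets = c(12L, 13L, 14L, 15L,
                                        15L, 16L, 17L, 18L),
                       orf_depth_mean = 300, orf_depth_size = 8,
                       uorf_depth_mean = 80,
                       untranslated_depth_mean = 25,
                       contaminant_depth_mean = 150,
                       init_peak = 3,
                       rna_depth_mean = 200, rna_read_length = 30L,
                       seed) {
  if (missing(seed)) abort("sim_config: a seed is mandatory")
  stopifnot(abs(sum(phase_probs) - 1) < 1e-8,
            length(read_lengths) == length(length_probs),
            length(read_lengths) == length(true_offsets))
  structure(as.list(environment()), class = "ribocall_sim_config")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

# coding block of `aa` residues plus stop: 3*(aa+1) nt
coding_block <- function(aa) {
  paste0("ATG",
         paste(sample(setdiff(NONSTOP_CODONS, "ATG"), aa - 1L,
                      replace = TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}

#' Simulate an annotated transcriptome with known truth
#'
#' Generates a genome, a transcript annotation and a truth set: multi-exon
#' mRNAs with a canonical CDS (optionally with planted translated
#' uORFs/dORFs), lncRNAs with planted translated or untranslated ORFs,
#' pseudogene-like transcripts, and short non-coding contaminant
#' transcripts. Deterministic for a given config seed.
#'
#' @param cfg a [sim_config()].
#' @return List of class `ribocall_sim` with `genome` (DNAStringSet),
#'   `transcripts` (transcript tibble, biotypes assigned), `seqs`,
#'   and `truth` (translated/untranslated ORF tables, contaminant ids,
#'   true offset table).
#' @export
simulate_transcriptome <- function(cfg) {
  set.seed(cfg$seed)
  entries <- list()
  add <- function(kind, n) {
    if (n > 0) lapply(seq_len(n), function(i) list(kind = kind, i = i))
    else list()
  }
  entries <- c(add("mrna", cfg$n_mrna), add("lncrna", cfg$n_lncrna),
               add("contaminant", cfg$n_contaminant),
               add("pseudogene", cfg$n_pseudogene))
  n_tx <- length(entries)
  if (n_tx == 0L) {
    empty_orfs <- tibble(transcript_id = character(), start = integer(),
                         stop = integer(), kind = character(),
                         orf_id = character())
    return(structure(list(
      genome = Biostrings::DNAStringSet(),
      transcripts = transcript_table(character(), character(), character(),
                                     character(), list(), list()),
      seqs = setNames(character(), character()),
      truth = list(translated_orfs = empty_orfs,
                   untranslated_orfs = empty_orfs,
                   contaminant_ids = character(),
                   offsets = tibble(length = as.integer(cfg$read_lengths),
                                    offset = as.integer(cfg$true_offsets))),
      config = cfg
    ), class = "ribocall_sim"))
  }
  tx_rows <- list(); chrom_seqs <- list(); truth_tr <- list(); truth_un <- list()
  contaminant_ids <- character(); pseudo_ids <- character()
  cur_chrom <- 0L; cur_pos <- 0L; per_chrom <- 60L
  chrom_parts <- list()

  for (t in seq_along(entries)) {
    e <- entries[[t]]
    if ((t - 1L) %% per_chrom == 0L) {
      if (cur_chrom > 0L) {
        chrom_seqs[[paste0("chr", cur_chrom)]] <-
          paste(unlist(chrom_parts), collapse = "")
      }
      cur_chrom <- cur_chrom + 1L; cur_pos <- 0L; chrom_parts <- list()
    }
    id <- paste0(e$kind, "_", e$i)
    cds <- c(NA_integer_, NA_integer_)
    orfs_tr <- NULL; orfs_un <- NULL

    if (e$kind == "mrna") {
      utr5 <- sample(60:120, 1); n_aa <- sample(60:150, 1)
      utr3 <- sample(60:150, 1)
      cds_block <- coding_block(n_aa)
      seq5 <- random_seq(utr5); seq3 <- random_seq(utr3)
      if (runif(1) < cfg$uorf_rate && utr5 >= 60) {
        aa_u <- sample(8:12, 1); span <- 3L * (aa_u + 1L)
        off <- sample(0:(utr5 - span - 6L), 1)
        substr(seq5, off + 1L, off + span) <- coding_block(aa_u)
        orfs_tr <- bind_rows(orfs_tr,
          tibble(start = off, stop = off + span, kind = "uORF"))
      }
      if (runif(1) < cfg$dorf_rate && utr3 >= 60) {
        aa_d <- sample(8:12, 1); span <- 3L * (aa_d + 1L)
        off <- sample(3:(utr3 - span - 3L), 1)
        base <- utr5 + nchar(cds_block)
        substr(seq3, off + 1L, off + span) <- coding_block(aa_d)
        orfs_tr <- bind_rows(orfs_tr,
          tibble(start = base + off, stop = base + off + span, kind = "dORF"))
      }
      tseq <- paste0(seq5, cds_block, seq3)
      cds <- c(utr5, utr5 + nchar(cds_block))
      orfs_tr <- bind_rows(
        tibble(start = cds[1], stop = cds[2], kind = "canonical"), orfs_tr)
      n_exons <- sample(2:4, 1)
    } else if (e$kind == "lncrna") {
      len <- sample(400:700, 1); aa <- sample(20:60, 1)
      span <- 3L * (aa + 1L)
      off <- sample(10:(len - span - 10L), 1)
      tseq <- random_seq(len)
      substr(tseq, off + 1L, off + span) <- coding_block(aa)
      translated <- e$i <= round(cfg$n_lncrna * cfg$lncrna_translated_fraction)
      if (translated) {
        orfs_tr <- tibble(start = off, stop = off + span, kind = "lncRNA_ORF")
      } else {
        orfs_un <- tibble(start = off, stop = off + span, kind = "lncRNA_ORF")
      }
      n_exons <- 2L
    } else if (e$kind == "contaminant") {
      len <- sample(120:180, 1); aa <- sample(8:20, 1)
      span <- 3L * (aa + 1L)
      off <- sample(3:(len - span - 3L), 1)
      tseq <- random_seq(len)
      substr(tseq, off + 1L, off + span) <- coding_block(aa)
      contaminant_ids <- c(contaminant_ids, id)
      orfs_un <- tibble(start = off, stop = off + span, kind = "contaminant_ORF")
      n_exons <- 1L
    } else {
      len <- 600L; aa <- sample(40:80, 1)
      span <- 3L * (aa + 1L)
      off <- sample(10:(len - span - 10L), 1)
      tseq <- random_seq(len)
      substr(tseq, off + 1L, off + span) <- coding_block(aa)
      pseudo_ids <- c(pseudo_ids, id)
      orfs_un <- tibble(start = off, stop = off + span, kind = "pseudogene_ORF")
      n_exons <- 1L
    }

    tlen <- nchar(tseq)
    # split into exons at random interior cut points
    if (n_exons > 1L) {
      cuts <- sort(sample(30:(tlen - 30L), n_exons - 1L))
      while (any(diff(c(0L, cuts, tlen)) < 20L)) {
        cuts <- sort(sample(30:(tlen - 30L), n_exons - 1L))
      }
    } else cuts <- integer(0)
    ex_len <- diff(c(0L, cuts, tlen))
    intron_len <- if (n_exons > 1L) sample(60:200, n_exons - 1L,
                                           replace = TRUE) else integer(0)
    # sense-strand layout: exon/intron alternation
    parts <- character(0); s_start <- integer(0); pos <- 0L
    for (j in seq_len(n_exons)) {
      s_start <- c(s_start, pos)
      parts <- c(parts, substr(tseq, sum(ex_len[seq_len(j - 1L)]) + 1L,
                               sum(ex_len[seq_len(j)])))
      pos <- pos + ex_len[j]
      if (j < n_exons) {
        parts <- c(parts, random_seq(intron_len[j]))
        pos <- pos + intron_len[j]
      }
    }
    layout <- paste(parts, collapse = "")
    L <- nchar(layout)
    strand <- sample(c("+", "-"), 1)
    locus_seq <- if (strand == "+") layout else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(layout)))
    gap <- 100L
    locus_start <- cur_pos + gap
    chrom_parts[[length(chrom_parts) + 1L]] <- paste0(random_seq(gap), locus_seq)
    cur_pos <- locus_start + L
    # exon genome intervals
    if (strand == "+") {
      ges <- locus_start + s_start
      gee <- ges + ex_len
    } else {
      ges <- locus_start + (L - (s_start + ex_len))
      gee <- locus_start + (L - s_start)
      o <- order(ges); ges <- ges[o]; gee <- gee[o]
    }
    tx_rows[[t]] <- tibble(
      transcript_id = id, gene_id = id, chrom = paste0("chr", cur_chrom),
      strand = strand, exon_start = list(as.integer(ges)),
      exon_end = list(as.integer(gee)),
      cds_start = cds[1], cds_end = cds[2], tseq = tseq,
      orfs_tr = list(orfs_tr), orfs_un = list(orfs_un)
    )
  }
  chrom_seqs[[paste0("chr", cur_chrom)]] <-
    paste(unlist(chrom_parts), collapse = "")

  rows <- bind_rows(tx_rows)
  transcripts <- transcript_table(
    transcript_id = rows$transcript_id, gene_id = rows$gene_id,
    chrom = rows$chrom, strand = rows$strand,
    exon_start = rows$exon_start, exon_end = rows$exon_end,
    cds_start = rows$cds_start, cds_end = rows$cds_end
  )
  transcripts <- assign_biotypes(transcripts, pseudogene_ids = pseudo_ids)
  genome <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  seqs <- setNames(rows$tseq, rows$transcript_id)

  pack_orfs <- function(col) {
    d <- list_rbind(imap(setNames(rows[[col]], rows$transcript_id),
                         function(o, id) {
                           if (is.null(o)) NULL else mutate(o, transcript_id = id)
                         }))
    if (is.null(d) || nrow(d) == 0) {
      return(tibble(transcript_id = character(), start = integer(),
                    stop = integer(), kind = character(), orf_id = character()))
    }
    d$orf_id <- paste0(d$transcript_id, ":", d$start, "-", d$stop)
    select(d, "orf_id", "transcript_id", "start", "stop", "kind")
  }

  structure(list(
    genome = genome, transcripts = transcripts, seqs = seqs,
    truth = list(
      translated_orfs = pack_orfs("orfs_tr"),
      untranslated_orfs = pack_orfs("orfs_un"),
      contaminant_ids = contaminant_ids,
      offsets = tibble(length = as.integer(cfg$read_lengths),
                       offset = as.integer(cfg$true_offsets))
    ),
    config = cfg
  ), class = "ribocall_sim")
}

sample_lengths <- function(n, cfg) {
  cfg$read_lengths[sample.int(length(cfg$read_lengths), n, replace = TRUE,
                              prob = cfg$length_probs)]
}

reads_to_genome <- function(sim, tx_id, t5, len) {
  tx <- sim$transcripts[match(tx_id, sim$transcripts$transcript_id), ]
  out <- vector("list", length(unique(tx_id)))
  fpe <- integer(length(t5)); chrom <- character(length(t5))
  strand <- character(length(t5))
  for (id in unique(tx_id)) {
    i <- which(tx_id == id)
    tr <- sim$transcripts[match(id, sim$transcripts$transcript_id), ]
    fpe[i] <- transcript_to_genome(tr, t5[i])
    chrom[i] <- tr$chrom; strand[i] <- tr$strand
  }
  tibble(chrom = chrom, strand = strand, five_prime_end = fpe,
         length = as.integer(len), transcript_id = tx_id, t5 = as.integer(t5))
}

#' Simulate ribosome footprints
#'
#' Draws A-site positions per truth ORF (codon sampled near-uniformly with
#' a mild initiation peak, codon phase from the configured probabilities),
#' assigns read lengths and places the 5' end `offset(length)` nt upstream
#' of the A-site in transcript space, then projects to genome coordinates
#' across splice junctions. Untranslated ORFs receive sparse phase-random
#' reads; contaminant transcripts receive narrow single-position pileups.
#'
#' @param sim a `ribocall_sim` from [simulate_transcriptome()].
#' @param cfg config; defaults to the one inside `sim`.
#' @return Read tibble (`chrom`, `strand`, `five_prime_end`, `length`, plus
#'   `transcript_id` and `t5` provenance columns).
#' @export
simulate_footprints <- function(sim, cfg = sim$config) {
  set.seed(cfg$seed + 1L)
  off_by_len <- setNames(cfg$true_offsets, cfg$read_lengths)
  tx_len <- setNames(sim$transcripts$length, sim$transcripts$transcript_id)
  out <- list()

  tr_orfs <- sim$truth$translated_orfs
  for (i in seq_len(nrow(tr_orfs))) {
    o <- tr_orfs[i, ]
    depth_mean <- if (o$kind %in% c("uORF", "dORF")) cfg$uorf_depth_mean
                  else cfg$orf_depth_mean
    n <- rnbinom(1, size = cfg$orf_depth_size, mu = depth_mean)
    if (n == 0) next
    L <- (o$stop - o$start) / 3L - 1L     # coding codons, stop excluded
    w <- c(cfg$init_peak, rep(1, L - 1L))
    codon <- sample.int(L, n, replace = TRUE, prob = w) - 1L
    phase <- sample(0:2, n, replace = TRUE, prob = cfg$phase_probs)
    len <- sample_lengths(n, cfg)
    a <- o$start + 3L * codon + phase
    t5 <- a - off_by_len[as.character(len)]
    keep <- t5 >= 0L & (t5 + len) <= tx_len[o$transcript_id]
    if (!any(keep)) next
    out[[length(out) + 1L]] <-
      reads_to_genome(sim, rep(o$transcript_id, sum(keep)),
                      t5[keep], len[keep])
  }

  un_orfs <- sim$truth$untranslated_orfs
  contam <- un_orfs$transcript_id %in% sim$truth$contaminant_ids
  sparse <- un_orfs[!contam, ]
  for (i in seq_len(nrow(sparse))) {
    o <- sparse[i, ]
    n <- stats::rpois(1, cfg$untranslated_depth_mean)
    if (n == 0) next
    a <- o$start + sample.int(o$stop - o$start - 3L, n, replace = TRUE) - 1L
    len <- sample_lengths(n, cfg)
    t5 <- a - off_by_len[as.character(len)]
    keep <- t5 >= 0L & (t5 + len) <= tx_len[o$transcript_id]
    if (!any(keep)) next
    out[[length(out) + 1L]] <-
      reads_to_genome(sim, rep(o$transcript_id, sum(keep)),
                      t5[keep], len[keep])
  }

  piles <- un_orfs[contam, ]
  for (i in seq_len(nrow(piles))) {
    o <- piles[i, ]
    n <- stats::rpois(1, cfg$contaminant_depth_mean)
    if (n == 0) next
    p0 <- o$start + sample.int(o$stop - o$start - 4L, 1) - 1L
    a <- p0 + rbinom(n, 1, 0.1)           # 90% at one nucleotide
    len <- sample_lengths(n, cfg)
    t5 <- a - off_by_len[as.character(len)]
    keep <- t5 >= 0L & (t5 + len) <= tx_len[o$transcript_id]
    if (!any(keep)) next
    out[[length(out) + 1L]] <-
      reads_to_genome(sim, rep(o$transcript_id, sum(keep)),
                      t5[keep], len[keep])
  }
  bind_rows(out)
}

#' Simulate RNA-seq reads
#'
#' Phase-free uniform coverage along each transcript, with expected depth
#' proportional to `abundance` (relative weights per transcript, default
#' equal).
#'
#' @param sim a `ribocall_sim`.
#' @param cfg config; defaults to the one inside `sim`.
#' @param abundance named numeric vector of relative abundances.
#' @return Read tibble as in [simulate_footprints()].
#' @export
simulate_rnaseq <- function(sim, cfg = sim$config, abundance = NULL) {
  set.seed(cfg$seed + 2L)
  tx <- sim$transcripts
  ab <- rep(1, nrow(tx))
  if (!is.null(abundance)) {
    ab <- unname(abundance[tx$transcript_id])
    ab[is.na(ab)] <- 0
  }
  out <- list()
  for (i in seq_len(nrow(tx))) {
    if (ab[i] <= 0) next
    usable <- tx$length[i] - cfg$rna_read_length
    if (usable < 1L) next
    n <- stats::rpois(1, cfg$rna_depth_mean * ab[i])
    if (n == 0) next
    t5 <- sample.int(usable, n, replace = TRUE) - 1L
    out[[length(out) + 1L]] <-
      reads_to_genome(sim, rep(tx$transcript_id[i], n), t5,
                      rep(cfg$rna_read_length, n))
  }
  bind_rows(out)
}

#' Count reads per ORF span
#'
#' Maps read 5' ends to transcript coordinates (no offset shift) and counts
#' those falling within each ORF span; used for RNA-seq quantification.
#'
#' @param reads read tibble with genome coordinates.
#' @param transcripts transcript tibble.
#' @param orfs tibble with `orf_id`, `transcript_id`, `start`, `stop`.
#' @return Named integer vector of counts per `orf_id`.
#' @export
orf_read_counts <- function(reads, transcripts, orfs) {
  m <- map_reads_to_transcripts(reads, transcripts)
  out <- integer(nrow(orfs))
  by_tx <- split(m$tpos, m$transcript_id)
  for (i in seq_len(nrow(orfs))) {
    p <- by_tx[[orfs$transcript_id[i]]]
    if (is.null(p)) next
    out[i] <- sum(p >= orfs$start[i] & p < orfs$stop[i])
  }
  setNames(out, orfs$orf_id)
}
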