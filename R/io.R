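#' Write a transcript table as extended genePred
#'
#' Emits the 15-column extended genePred dialect (gene symbol in column
#' 12). Round-trips with [read_genepred()].
#'
#' @param transcripts transcript tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genepred <- function(transcripts, path) {
  lines <- vapply(seq_len(nrow(transcripts)), function(i) {
    tr <- transcripts[i, ]
    es <- tr$exon_start[[1]]; ee <- tr$exon_end[[1]]
    tx_s <- min(es); tx_e <- max(ee)
    if (is.na(tr$cds_start)) {
      cs <- tx_e; ce <- tx_e
    } else {
      g1 <- transcript_to_genome(tr, tr$cds_start)
      g2 <- transcript_to_genome(tr, tr$cds_end - 1L)
      cs <- min(g1, g2); ce <- max(g1, g2) + 1L
    }
    paste(tr$transcript_id, tr$chrom, tr$strand, tx_s, tx_e, cs, ce,
          length(es),
          paste0(paste(es, collapse = ","), ","),
          paste0(paste(ee, collapse = ","), ","),
          0, tr$gene_id, "none", "none",
          paste0(paste(rep(-1, length(es)), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome to FASTA with an index
#'
#' @param genome named DNAStringSet or named character vector.
#' @param path output FASTA path; a `.fai` index is created alongside.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path, width = 70L)
  Rsamtools::indexFa(path)
  invisible(path)
}

# genomic alignment blocks (ascending) for transcript interval [t5, t5+len)
tx_interval_blocks <- function(tx_row, t5, len) {
  es <- tx_row$exon_start[[1]]; ee <- tx_row$exon_end[[1]]
  w <- ee - es
  if (tx_row$strand == "+") {
    off <- c(0L, cumsum(w))[seq_along(w)]
    ord <- seq_along(w)
  } else {
    off <- rev(c(0L, cumsum(rev(w)))[seq_along(w)])
    ord <- rev(seq_along(w))
  }
  lo <- t5; hi <- t5 + len
  blocks <- list()
  for (j in ord) {
    a <- max(lo, off[j]); b <- min(hi, off[j] + w[j])
    if (a >= b) next
    if (tx_row$strand == "+") {
      gs <- es[j] + (a - off[j]); ge <- gs + (b - a)
    } else {
      ge <- ee[j] - (a - off[j]); gs <- ge - (b - a)
    }
    blocks[[length(blocks) + 1L]] <- c(gs, ge)
  }
  m <- do.call(rbind, blocks)
  m[order(m[, 1]), , drop = FALSE]
}

#' Write simulated reads as SAM
#'
#' Emits one primary alignment per read with splice-aware CIGAR (`M`/`N`
#' operations) and sequence taken from the genome's plus strand. The file
#' converts cleanly with `Rsamtools::asBam()` and round-trips through
#' [load_alignments()].
#'
#' @param reads tibble from [simulate_footprints()] / [simulate_rnaseq()]
#'   (needs `transcript_id` and `t5` provenance columns).
#' @param sim the `ribocall_sim` the reads came from.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(reads, sim, path) {
  genome <- sim$genome
  header <- c("@HD\tVN:1.6\tSO:unknown",
              paste0("@SQ\tSN:", names(genome), "\tLN:",
                     Biostrings::width(genome)))
  tx_index <- setNames(seq_len(nrow(sim$transcripts)),
                       sim$transcripts$transcript_id)
  recs <- vapply(seq_len(nrow(reads)), function(i) {
    r <- reads[i, ]
    tr <- sim$transcripts[tx_index[[r$transcript_id]], ]
    m <- tx_interval_blocks(tr, r$t5, r$length)
    gaps <- if (nrow(m) > 1) m[-1, 1] - m[-nrow(m), 2] else integer(0)
    cig <- paste0(m[1, 2] - m[1, 1], "M")
    if (nrow(m) > 1) {
      for (j in 2:nrow(m)) {
        cig <- paste0(cig, gaps[j - 1], "N", m[j, 2] - m[j, 1], "M")
      }
    }
    seq <- paste(vapply(seq_len(nrow(m)), function(j) {
      as.character(Biostrings::subseq(genome[[r$chrom]],
                                      start = m[j, 1] + 1L, end = m[j, 2]))
    }, character(1)), collapse = "")
    flag <- if (r$strand == "-") 16L else 0L
    paste(paste0("read", i), flag, r$chrom, m[1, 1] + 1L, 255L, cig,
          "*", 0L, 0L, seq, "*", sep = "\t")
  }, character(1))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Run the calibration, discovery and feature stages
#'
#' Convenience wrapper: calibrates offsets, builds A-site profiles,
#' enumerates and classifies candidate ORFs, and computes feature vectors.
#'
#' @param reads alignment tibble (e.g. [load_alignments()] output).
#' @param transcripts transcript tibble with biotypes.
#' @param seqs named character vector of transcript sequences.
#' @param min_len_aa minimum peptide length for candidate ORFs.
#' @param offsets optional pre-computed offset table; calibrated from the
#'   data when `NULL`.
#' @return List with `offsets`, `profiles`, `orfs` and `features`.
#' @export
ribocall_pipeline <- function(reads, transcripts, seqs, min_len_aa = 6L,
                              offsets = NULL) {
  offsets <- offsets %||% calibrate_offsets(reads, transcripts)
  profiles <- assign_asites(reads, offsets, transcripts)
  orfs <- find_orfs_all(seqs, min_len_aa = min_len_aa)
  orfs <- classify_orfs(orfs, transcripts)
  features <- orf_features(orfs, profiles)
  features <- label_training_pools(features, transcripts)
  list(offsets = offsets, profiles = profiles, orfs = orfs,
       features = features)
}
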