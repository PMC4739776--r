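#' Transcript tables
#'
#' `ribocall` represents a transcriptome as an ordinary tibble with one row
#' per transcript. Exon blocks are stored in genomic order as list-columns of
#' 0-based half-open intervals; all transcript-space coordinates (including
#' `cds_start`/`cds_end`) run 5' to 3' of the RNA regardless of genomic
#' strand, so downstream ORF logic is strand-free.
#'
#' Columns: `transcript_id`, `gene_id`, `chrom`, `strand` (`"+"`/`"-"`),
#' `exon_start`, `exon_end` (integer list-columns, sorted by genome
#' coordinate, non-overlapping), `length` (sum of exon widths), `cds_start`,
#' `cds_end` (transcript-space, `NA` when non-coding), `cds_ok` (FALSE when
#' an annotated CDS length is not divisible by 3; the record is kept but
#' flagged), `biotype`.
#'
#' @param transcript_id,gene_id character vectors.
#' @param chrom,strand character vectors.
#' @param exon_start,exon_end lists of integer vectors (0-based half-open
#'   genome coordinates, ascending).
#' @param cds_start,cds_end optional transcript-space CDS offsets.
#' @param biotype optional biotype labels.
#' @return A tibble of transcripts.
#' @export
transcript_table <- function(transcript_id, gene_id = transcript_id,
                             chrom, strand, exon_start, exon_end,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             biotype = NA_character_) {
  stopifnot(all(strand %in% c("+", "-")))
  exon_start <- lapply(exon_start, as.integer)
  exon_end <- lapply(exon_end, as.integer)
  bad <- mapply(function(s, e) {
    length(s) != length(e) || any(e <= s) || is.unsorted(s, strictly = TRUE) ||
      (length(s) > 1 && any(s[-1] < e[-length(e)]))
  }, exon_start, exon_end)
  if (any(bad)) {
    abort(paste0("malformed exon blocks for: ",
                 paste(transcript_id[bad], collapse = ", ")))
  }
  len <- mapply(function(s, e) sum(e - s), exon_start, exon_end)
  tx <- tibble(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    chrom = as.character(chrom), strand = strand,
    exon_start = exon_start, exon_end = exon_end,
    length = as.integer(len),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    biotype = as.character(biotype)
  )
  tx$cds_ok <- is.na(tx$cds_start) |
    ((tx$cds_end - tx$cds_start) %% 3L == 0L)
  bad_span <- !is.na(tx$cds_start) &
    (tx$cds_start < 0L | tx$cds_end > tx$length | tx$cds_start >= tx$cds_end)
  if (any(bad_span)) {
    abort(paste0("CDS outside transcript bounds for: ",
                 paste(tx$transcript_id[bad_span], collapse = ", ")))
  }
  tx
}

#' Read transcript models from a genePred file
#'
#' Accepts plain 10-column genePred and the extended 12/15-column dialect
#' (gene symbol in column 12). Coordinates are kept 0-based half-open, the
#' file's native convention. Genomic CDS bounds are converted to
#' transcript-space offsets; a CDS whose spliced length is not divisible by
#' 3 is flagged via `cds_ok = FALSE` rather than dropped.
#'
#' @param path file path, or a character vector of genePred lines.
#' @return A transcript tibble (see [transcript_table()]).
#' @export
read_genepred <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(transcript_table(character(), character(), character(),
                            character(), list(), list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10)) {
    abort(paste0("malformed genePred line ", which(nf < 10)[1],
                 ": expected >= 10 tab-separated fields, got ", nf[nf < 10][1]))
  }
  parse_block <- function(x) as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    es <- parse_block(f[9]); ee <- parse_block(f[10])
    n_ex <- suppressWarnings(as.integer(f[8]))
    if (is.na(n_ex) || length(es) != n_ex || length(ee) != n_ex) {
      abort(paste0("malformed genePred line ", i,
                   ": exon block count disagrees with exonCount"))
    }
    list(id = f[1], chrom = f[2], strand = f[3],
         cds_g_start = as.integer(f[6]), cds_g_end = as.integer(f[7]),
         es = es, ee = ee,
         gene = if (length(f) >= 12 && nzchar(f[12])) f[12] else f[1])
  })
  tx <- transcript_table(
    transcript_id = map_chr(rows, "id"),
    gene_id = map_chr(rows, "gene"),
    chrom = map_chr(rows, "chrom"),
    strand = map_chr(rows, "strand"),
    exon_start = map(rows, "es"),
    exon_end = map(rows, "ee")
  )
  cds <- t(mapply(function(r, i) {
    if (r$cds_g_start >= r$cds_g_end) return(c(NA_integer_, NA_integer_))
    cds_genome_to_tx(tx[i, ], r$cds_g_start, r$cds_g_end)
  }, rows, seq_along(rows)))
  tx$cds_start <- as.integer(cds[, 1])
  tx$cds_end <- as.integer(cds[, 2])
  tx$cds_ok <- is.na(tx$cds_start) | ((tx$cds_end - tx$cds_start) %% 3L == 0L)
  tx
}

# genomic [gstart, gend) CDS -> transcript-space [start, end)
cds_genome_to_tx <- function(tx_row, gstart, gend) {
  if (tx_row$strand == "+") {
    a <- genome_to_transcript(tx_row, gstart)
    b <- genome_to_transcript(tx_row, gend - 1L) + 1L
  } else {
    a <- genome_to_transcript(tx_row, gend - 1L)
    b <- genome_to_transcript(tx_row, gstart) + 1L
  }
  c(a, b)
}

#' Read transcript models from a GTF file
#'
#' Thin wrapper over `rtracklayer::import()`; exon and CDS features are
#' grouped by `transcript_id` and converted to the package's 0-based
#' half-open transcript tibble.
#'
#' @param path path to a GTF (GTF2.2) file.
#' @return A transcript tibble.
#' @export
read_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to read GTF")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as_tibble(as.data.frame(gr))
  ex <- df[df$type == "exon", ]
  if (nrow(ex) == 0) abort("GTF contains no exon features")
  ex$start0 <- ex$start - 1L
  byx <- split(ex, ex$transcript_id)
  tx <- transcript_table(
    transcript_id = names(byx),
    gene_id = map_chr(byx, function(d) as.character(d$gene_id[1])),
    chrom = map_chr(byx, function(d) as.character(d$seqnames[1])),
    strand = map_chr(byx, function(d) as.character(d$strand[1])),
    exon_start = map(byx, function(d) sort(d$start0)),
    exon_end = map(byx, function(d) sort(d$end))
  )
  cds <- df[df$type == "CDS", ]
  if (nrow(cds) > 0) {
    byc <- split(cds, cds$transcript_id)
    for (id in names(byc)) {
      i <- match(id, tx$transcript_id)
      if (is.na(i)) next
      gs <- min(byc[[id]]$start) - 1L
      # include the stop codon when annotated separately
      ge <- max(byc[[id]]$end)
      sc <- df[df$type == "stop_codon" & df$transcript_id == id, ]
      if (nrow(sc) > 0) {
        gs <- min(gs, min(sc$start) - 1L)
        ge <- max(ge, max(sc$end))
      }
      b <- cds_genome_to_tx(tx[i, ], as.integer(gs), as.integer(ge))
      tx$cds_start[i] <- b[1]; tx$cds_end[i] <- b[2]
    }
    tx$cds_ok <- is.na(tx$cds_start) |
      ((tx$cds_end - tx$cds_start) %% 3L == 0L)
  }
  tx
}

#' Map transcript coordinates to genome coordinates
#'
#' Positions are 0-based; transcript positions run 5'->3' of the RNA, so on
#' the minus strand position 0 is the highest genomic coordinate of the last
#' exon. The map is a bijection over `[0, length)`;
#' [genome_to_transcript()] is its inverse.
#'
#' @param tx_row a single-row transcript tibble.
#' @param pos integer vector of transcript positions.
#' @return Integer vector of genome coordinates (same chrom as `tx_row`).
#' @export
transcript_to_genome <- function(tx_row, pos) {
  pos <- as.integer(pos)
  if (any(pos < 0L | pos >= tx_row$length)) {
    abort("transcript position out of range")
  }
  es <- tx_row$exon_start[[1]]; ee <- tx_row$exon_end[[1]]
  w <- ee - es
  if (tx_row$strand == "+") {
    off <- c(0L, cumsum(w))[-(length(w) + 1L)]
    i <- findInterval(pos, off)
    es[i] + (pos - off[i])
  } else {
    wr <- rev(w)
    offr <- c(0L, cumsum(wr))[-(length(wr) + 1L)]
    i <- findInterval(pos, offr)        # i-th exon from the 3'-genomic end
    j <- length(w) - i + 1L
    ee[j] - 1L - (pos - offr[i])
  }
}

#' @rdname transcript_to_genome
#' @param gpos integer vector of genome coordinates; must be exonic.
#' @export
genome_to_transcript <- function(tx_row, gpos) {
  gpos <- as.integer(gpos)
  es <- tx_row$exon_start[[1]]; ee <- tx_row$exon_end[[1]]
  w <- ee - es
  i <- findInterval(gpos, es)
  if (any(i == 0L | gpos >= ee[pmax(i, 1L)])) {
    abort("genome position not exonic for this transcript")
  }
  if (tx_row$strand == "+") {
    off <- c(0L, cumsum(w))[-(length(w) + 1L)]
    off[i] + (gpos - es[i])
  } else {
    wr <- rev(w)
    offr <- c(0L, cumsum(wr))[-(length(wr) + 1L)]
    j <- length(w) - i + 1L
    offr[j] + (ee[i] - 1L - gpos)
  }
}

#' Extract spliced transcript sequences
#'
#' Concatenates exon sequences in transcript order, reverse-complementing on
#' the minus strand. Sequences are stored in the DNA alphabet (`T`, not `U`).
#'
#' @param transcripts a transcript tibble.
#' @param genome a named [Biostrings::DNAStringSet] or a path to a FASTA
#'   file (read with `Biostrings::readDNAStringSet`).
#' @return Named character vector of spliced sequences, one per transcript.
#' @export
extract_transcript_seqs <- function(transcripts, genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  missing <- setdiff(unique(transcripts$chrom), names(genome))
  if (length(missing) > 0) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(missing, collapse = ", ")))
  }
  out <- vapply(seq_len(nrow(transcripts)), function(i) {
    tr <- transcripts[i, ]
    chrseq <- genome[[tr$chrom]]
    parts <- Biostrings::extractAt(
      chrseq,
      IRanges::IRanges(start = tr$exon_start[[1]] + 1L, end = tr$exon_end[[1]])
    )
    s <- Biostrings::DNAString(paste(as.character(parts), collapse = ""))
    if (tr$strand == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1))
  setNames(out, transcripts$transcript_id)
}

#' Biotype assignment rules
#'
#' Defaults follow the annotation filters used throughout the package: a
#' long non-coding RNA must have introns or exceed 500 nt and must not share
#' exonic sequence on the same strand with a coding gene or pseudogene;
#' short non-coding RNAs are under 200 nt.
#'
#' @param lncrna_min_monoexonic_length minimum length (nt) for a
#'   single-exon lncRNA.
#' @param short_ncrna_max_length transcripts shorter than this (nt) with no
#'   CDS are short non-coding RNAs.
#' @return A list of rules for [assign_biotypes()].
#' @export
biotype_rules <- function(lncrna_min_monoexonic_length = 500L,
                          short_ncrna_max_length = 200L) {
  stopifnot(lncrna_min_monoexonic_length > 0, short_ncrna_max_length > 0)
  list(lncrna_min_monoexonic_length = as.integer(lncrna_min_monoexonic_length),
       short_ncrna_max_length = as.integer(short_ncrna_max_length))
}

exon_granges <- function(transcripts) {
  n_ex <- lengths(transcripts$exon_start)
  GenomicRanges::GRanges(
    seqnames = rep(transcripts$chrom, n_ex),
    ranges = IRanges::IRanges(
      start = unlist(transcripts$exon_start) + 1L,
      end = unlist(transcripts$exon_end)
    ),
    strand = rep(transcripts$strand, n_ex),
    transcript_id = rep(transcripts$transcript_id, n_ex)
  )
}

#' Assign transcript biotypes
#'
#' Classifies each transcript as `mRNA`, `short_ncRNA`, `pseudogene`,
#' `lncRNA`, or `unclassified`. A transcript with an annotated CDS in the
#' coding set is `mRNA`. A declared pseudogene keeps that label only when it
#' shares no same-strand exonic base with a coding gene. A non-coding
#' transcript is `lncRNA` only if it has introns or exceeds the monoexonic
#' length floor and does not overlap (same-strand, exonic) a coding gene or
#' retained pseudogene; short transcripts (< 200 nt) are `short_ncRNA`.
#' The function is total and order-independent.
#'
#' @param transcripts a transcript tibble.
#' @param coding_ids transcript ids regarded as protein-coding; defaults to
#'   every transcript with an annotated CDS.
#' @param pseudogene_ids transcript ids declared pseudogenes by the source
#'   annotation.
#' @param rules a [biotype_rules()] list.
#' @return The transcript tibble with `biotype` filled in.
#' @export
assign_biotypes <- function(transcripts, coding_ids = NULL,
                            pseudogene_ids = character(),
                            rules = biotype_rules()) {
  if (nrow(transcripts) == 0) return(transcripts)
  if (is.null(coding_ids)) {
    coding_ids <- transcripts$transcript_id[!is.na(transcripts$cds_start)]
  }
  is_coding <- transcripts$transcript_id %in% coding_ids &
    !is.na(transcripts$cds_start)
  is_pseudo_src <- transcripts$transcript_id %in% pseudogene_ids & !is_coding

  overlaps_set <- function(query_idx, subject_idx) {
    if (!any(query_idx) || !any(subject_idx)) {
      return(rep(FALSE, sum(query_idx)))
    }
    q <- exon_granges(transcripts[query_idx, , drop = FALSE])
    s <- exon_granges(transcripts[subject_idx, , drop = FALSE])
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(q, s, ignore.strand = FALSE))
    # self-overlap does not count
    hit_q <- S4Vectors::mcols(q)$transcript_id[S4Vectors::queryHits(hits)]
    hit_s <- S4Vectors::mcols(s)$transcript_id[S4Vectors::subjectHits(hits)]
    keep <- hit_q != hit_s
    ov_ids <- unique(hit_q[keep])
    transcripts$transcript_id[query_idx] %in% ov_ids
  }

  noncoding <- !is_coding
  ov_coding <- rep(FALSE, nrow(transcripts))
  ov_coding[noncoding] <- overlaps_set(noncoding, is_coding)

  pseudo <- is_pseudo_src & !ov_coding
  ov_pseudo <- rep(FALSE, nrow(transcripts))
  test_lnc <- noncoding & !is_pseudo_src
  ov_pseudo[test_lnc] <- overlaps_set(test_lnc, pseudo)

  n_ex <- lengths(transcripts$exon_start)
  long_enough <- n_ex > 1L |
    transcripts$length > rules$lncrna_min_monoexonic_length
  short <- noncoding & transcripts$length < rules$short_ncrna_max_length

  biotype <- rep("unclassified", nrow(transcripts))
  biotype[is_coding] <- "mRNA"
  biotype[pseudo] <- "pseudogene"
  biotype[noncoding & !is_pseudo_src & short] <- "short_ncRNA"
  lnc <- noncoding & !is_pseudo_src & !short &
    long_enough & !ov_coding & !ov_pseudo
  biotype[lnc] <- "lncRNA"
  transcripts$biotype <- biotype
  transcripts
}

#' Summarise a transcript table
#'
#' @param transcripts a transcript tibble.
#' @return Tibble with id, biotype, length and exon count, suitable for TSV
#'   export.
#' @export
biotype_summary <- function(transcripts) {
  tibble(
    transcript_id = transcripts$transcript_id,
    biotype = transcripts$biotype,
    length = transcripts$length,
    n_exons = lengths(transcripts$exon_start)
  )
}
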