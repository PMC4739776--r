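#' Load aligned ribosome-profiling reads
#'
#' Reads a SAM or BAM file of uniquely mapped ribosome-protected fragments
#' and returns one row per usable alignment. Unmapped, secondary and
#' supplementary records are skipped. The 5' end is strand-aware: for a
#' minus-strand alignment it is the highest reference coordinate covered.
#' Reads outside `[min_len, max_len]` are dropped; ribosome-protected
#' fragments are typically 24-31 nt.
#'
#' @param path SAM or BAM file. SAM input is converted on the fly with
#'   `Rsamtools::asBam()`.
#' @param min_len,max_len read-length window in nt.
#' @return Tibble with columns `chrom`, `strand`, `five_prime_end` (0-based
#'   genome coordinate) and `length`.
#' @export
load_alignments <- function(path, min_len = 24L, max_len = 31L) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    flag = flags, what = c("rname", "strand", "pos", "cigar", "qwidth"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  if (length(b$pos) == 0) {
    return(tibble(chrom = character(), strand = character(),
                  five_prime_end = integer(), length = integer()))
  }
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar)
  start0 <- b$pos - 1L
  minus <- as.character(b$strand) == "-"
  fpe <- ifelse(minus, start0 + ref_w - 1L, start0)
  out <- tibble(
    chrom = as.character(b$rname),
    strand = ifelse(minus, "-", "+"),
    five_prime_end = as.integer(fpe),
    length = as.integer(b$qwidth)
  )
  filter(out, .data$length >= min_len, .data$length <= max_len)
}

# Map read 5' ends onto transcript coordinates. Returns one row per
# (read, transcript) combination whose 5' end falls in an exon of that
# transcript on the same strand.
map_reads_to_transcripts <- function(reads, transcripts) {
  if (nrow(reads) == 0 || nrow(transcripts) == 0) {
    return(tibble(transcript_id = character(), tpos = integer(),
                  length = integer(), read_idx = integer()))
  }
  ex <- exon_granges(transcripts)
  # transcript-space offset of each exon's 5'-most base
  tx_off <- function(tr) {
    w <- tr$exon_end[[1]] - tr$exon_start[[1]]
    if (tr$strand == "+") c(0L, cumsum(w))[seq_along(w)]
    else rev(c(0L, cumsum(rev(w)))[seq_along(w)])
  }
  offs <- unlist(lapply(seq_len(nrow(transcripts)),
                        function(i) tx_off(transcripts[i, ])))
  rg <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$five_prime_end + 1L, width = 1L),
    strand = reads$strand
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(rg, ex, ignore.strand = FALSE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) {
    return(tibble(transcript_id = character(), tpos = integer(),
                  length = integer(), read_idx = integer()))
  }
  ex_start0 <- GenomicRanges::start(ex) - 1L
  ex_end <- GenomicRanges::end(ex)
  ex_strand <- as.character(GenomicRanges::strand(ex))
  g <- reads$five_prime_end[qi]
  tpos <- ifelse(ex_strand[si] == "+",
                 offs[si] + (g - ex_start0[si]),
                 offs[si] + (ex_end[si] - 1L - g))
  tibble(
    transcript_id = S4Vectors::mcols(ex)$transcript_id[si],
    tpos = as.integer(tpos),
    length = reads$length[qi],
    read_idx = qi
  )
}

#' Calibrate read-length dependent A-site offsets
#'
#' Ribosome-protected fragments of different lengths place their 5' ends at
#' different distances from the ribosomal A-site. For each read length this
#' routine scores candidate offsets against canonical coding regions using
#' two signals: the in-frame fraction of shifted read positions over CDS
#' interiors (first/last 15 nt of each ORF excluded, to avoid initiation and
#' termination pileups) selects the frame; the count of 5' ends landing
#' exactly `offset` nt upstream of annotated start codons selects the offset
#' within the frame family. Ties go to the smaller offset. Lengths with
#' fewer than `support_min` usable reads, or whose best in-frame fraction
#' falls below `frame_min`, are excluded from the table.
#'
#' @param reads tibble from [load_alignments()] (or the same columns).
#' @param transcripts transcript tibble; only rows with an in-frame CDS are
#'   used.
#' @param offset_range integer vector of candidate offsets (nt).
#' @param support_min minimum usable reads per length.
#' @param frame_min minimum in-frame fraction for a length to be calibrated.
#' @param interior_trim nt trimmed from each CDS end for frame scoring.
#' @return Offset table: tibble with `length`, `offset`, `n_reads`,
#'   `inframe_fraction`.
#' @export
calibrate_offsets <- function(reads, transcripts, offset_range = 0:24,
                              support_min = 100L, frame_min = 0.5,
                              interior_trim = 15L) {
  canon <- filter(transcripts, !is.na(.data$cds_start), .data$cds_ok)
  if (nrow(reads) == 0 || nrow(canon) == 0) {
    abort(paste0("offset calibration requires reads over canonical coding ",
                 "transcripts; none available. Supply a default offset ",
                 "table instead."))
  }
  m <- map_reads_to_transcripts(reads, canon)
  if (nrow(m) == 0) {
    abort(paste0("no reads map to canonical coding transcripts; offset ",
                 "calibration impossible. Supply a default offset table."))
  }
  m <- left_join(m,
                 select(canon, "transcript_id", "cds_start", "cds_end",
                        tx_len = "length"),
                 by = "transcript_id")
  res <- lapply(split(m, m$length), function(d) {
    if (nrow(d) < support_min) return(NULL)
    inframe <- vapply(offset_range, function(off) {
      a <- d$tpos + off
      int <- a >= d$cds_start + interior_trim & a < d$cds_end - interior_trim
      if (!any(int)) return(NA_real_)
      mean((a[int] - d$cds_start[int]) %% 3L == 0L)
    }, numeric(1))
    if (all(is.na(inframe))) return(NULL)
    best <- offset_range[which.max(inframe)]
    fam <- offset_range[!is.na(inframe) &
                          (offset_range %% 3L == best %% 3L)]
    start_peak <- vapply(fam, function(off) {
      sum(d$tpos == d$cds_start - off)
    }, numeric(1))
    off <- fam[order(-start_peak, fam)][1]
    frac <- inframe[match(off, offset_range)]
    if (is.na(frac) || frac < frame_min) return(NULL)
    tibble(length = d$length[1], offset = as.integer(off),
           n_reads = nrow(d), inframe_fraction = frac)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    abort("no read length passed offset calibration thresholds")
  }
  arrange(out, .data$length)
}

#' A-site profiles per transcript
#'
#' Shifts each read's 5' end by its length-specific offset along the
#' transcript (across splice junctions, since the shift is applied in
#' transcript space) and accumulates one count per read at the resulting
#' A-site nucleotide. Reads whose length has no calibrated offset, or whose
#' shifted position falls outside the transcript, are discarded. A read
#' overlapping several transcripts contributes to each.
#'
#' @param reads alignment tibble.
#' @param offsets offset table from [calibrate_offsets()].
#' @param transcripts transcript tibble.
#' @return Tibble with `transcript_id`, `n_reads`, and a `profile`
#'   list-column of integer count vectors (length = transcript length).
#' @export
assign_asites <- function(reads, offsets, transcripts) {
  m <- map_reads_to_transcripts(reads, transcripts)
  m <- inner_join(m, select(offsets, "length", "offset"), by = "length")
  m <- left_join(m, select(transcripts, "transcript_id", tx_len = "length"),
                 by = "transcript_id")
  m$asite <- m$tpos + m$offset
  m <- filter(m, .data$asite >= 0L, .data$asite < .data$tx_len)
  by_tx <- split(m$asite, factor(m$transcript_id,
                                 levels = transcripts$transcript_id))
  prof <- lapply(seq_len(nrow(transcripts)), function(i) {
    tabulate(by_tx[[i]] + 1L, nbins = transcripts$length[i])
  })
  tibble(
    transcript_id = transcripts$transcript_id,
    n_reads = map_int(prof, sum),
    profile = prof
  )
}

#' Metagene profile around start or stop codons
#'
#' Averages A-site read density (reads per million assigned reads) across
#' transcripts in a window centred on the annotated start or stop codon.
#' Window positions falling outside an individual transcript are skipped
#' for that transcript.
#'
#' @param profiles tibble from [assign_asites()].
#' @param transcripts transcript tibble (rows with CDS are used).
#' @param anchor `"start"` or `"stop"`.
#' @param window half-width in nt.
#' @param library_size reads used for the RPM scale; defaults to the total
#'   assigned reads in `profiles`.
#' @return Tibble with `position` (nt relative to anchor) and `rpm`.
#' @export
metagene_profile <- function(profiles, transcripts, anchor = c("start", "stop"),
                             window = 30L, library_size = NULL) {
  anchor <- match.arg(anchor)
  canon <- filter(transcripts, !is.na(.data$cds_start), .data$cds_ok)
  if (nrow(canon) == 0) abort("metagene requires transcripts with a CDS")
  library_size <- library_size %||% sum(profiles$n_reads)
  if (library_size <= 0) library_size <- 1
  pos <- seq.int(-window, window)
  acc <- numeric(length(pos)); cnt <- numeric(length(pos))
  pm <- setNames(profiles$profile, profiles$transcript_id)
  for (i in seq_len(nrow(canon))) {
    tr <- canon[i, ]
    p <- pm[[tr$transcript_id]]
    if (is.null(p)) next
    a <- if (anchor == "start") tr$cds_start else tr$cds_end - 3L
    idx <- a + pos
    ok <- idx >= 0L & idx < tr$length
    acc[ok] <- acc[ok] + p[idx[ok] + 1L]
    cnt[ok] <- cnt[ok] + 1
  }
  rpm <- ifelse(cnt > 0, acc / cnt / (library_size / 1e6), 0)
  tibble(position = pos, rpm = rpm)
}
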