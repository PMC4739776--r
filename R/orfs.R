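STOP_CODONS <- c("TAA", "TAG", "TGA")
NEAR_COGNATE_STARTS <- c("ATG", "CTG", "GTG", "TTG")

norm_dna <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

#' Enumerate candidate ORFs in a transcript sequence
#'
#' Scans all three frames for AUG or near-cognate (CUG/GUG/UUG) start codons
#' and extends each to the first in-frame stop codon (UAA/UAG/UGA). ORFs
#' lacking an in-frame stop are not reported. Coordinates are 0-based
#' transcript positions; `stop` points one past the final base of the stop
#' codon, so `(stop - start)` is divisible by 3 and the encoded peptide has
#' `(stop - start)/3 - 1` residues.
#'
#' @param seq a single transcript sequence (DNA or RNA alphabet).
#' @param starts allowed start codons (DNA alphabet).
#' @param min_len_aa minimum peptide length (aa) to report.
#' @return Tibble with `start`, `stop`, `start_codon` (RNA alphabet),
#'   `frame` (start mod 3) and `peptide_length`.
#' @export
find_orfs <- function(seq, starts = NEAR_COGNATE_STARTS, min_len_aa = 6L) {
  seq <- norm_dna(seq)
  n <- nchar(seq)
  empty <- tibble(start = integer(), stop = integer(),
                  start_codon = character(), frame = integer(),
                  peptide_length = integer())
  if (n < 6) return(empty)
  codon_at <- substring(seq, 1:(n - 2), 3:n)  # codon starting at 0-based i-1
  rows <- list()
  for (f in 0:2) {
    idx <- seq.int(f + 1L, n - 2L, by = 3L)   # 1-based codon starts, frame f
    codons <- codon_at[idx]
    start_i <- which(codons %in% starts)
    stop_i <- which(codons %in% STOP_CODONS)
    if (length(start_i) == 0 || length(stop_i) == 0) next
    nxt <- stop_i[findInterval(start_i, stop_i) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    s0 <- idx[start_i[ok]] - 1L
    e0 <- idx[nxt[ok]] + 2L
    rows[[length(rows) + 1L]] <- tibble(
      start = as.integer(s0), stop = as.integer(e0),
      start_codon = chartr("T", "U", codons[start_i[ok]]),
      frame = as.integer(s0 %% 3L),
      peptide_length = as.integer((e0 - s0) / 3L - 1L)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out <- filter(out, .data$peptide_length >= min_len_aa)
  arrange(out, .data$start)
}

#' Enumerate candidate ORFs across a transcriptome
#'
#' @param seqs named character vector of transcript sequences (e.g. from
#'   [extract_transcript_seqs()]).
#' @inheritParams find_orfs
#' @return Tibble of candidate ORFs with a `transcript_id` column and an
#'   `orf_id` of the form `transcript:start-stop`.
#' @export
find_orfs_all <- function(seqs, starts = NEAR_COGNATE_STARTS,
                          min_len_aa = 6L) {
  out <- list_rbind(imap(as.list(seqs), function(s, id) {
    o <- find_orfs(s, starts = starts, min_len_aa = min_len_aa)
    if (nrow(o) > 0) mutate(o, transcript_id = id) else NULL
  }))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(transcript_id = character(), start = integer(),
                  stop = integer(), start_codon = character(),
                  frame = integer(), peptide_length = integer(),
                  orf_id = character()))
  }
  out$orf_id <- paste0(out$transcript_id, ":", out$start, "-", out$stop)
  select(out, "orf_id", "transcript_id", "start", "stop", "start_codon",
         "frame", "peptide_length")
}

classify_one <- function(start, stop, frame, cds_start, cds_end) {
  if (is.na(cds_start)) return("noncoding_ORF")
  cds_frame <- cds_start %% 3L
  if (stop == cds_end && frame == cds_frame) {
    if (start == cds_start) return("canonical")
    if (start < cds_start) return("extended")
    return("truncated")
  }
  if (stop <= cds_start) return("uORF")
  if (start >= cds_end) return("dORF")
  if (start < cds_start) return("overlapping_uORF")
  "internal"
}

#' Classify ORFs relative to the canonical CDS
#'
#' Adds an `orf_type` column: `canonical`, `truncated`, `extended` (same
#' stop as the CDS), `uORF` (entirely 5' of the CDS), `overlapping_uORF`
#' (starts in the 5'UTR, ends off-frame inside the CDS), `internal`
#' (off-frame start within the CDS), `dORF` (entirely 3' of the CDS), or
#' `noncoding_ORF` on transcripts without a CDS.
#'
#' @param orfs candidate-ORF tibble from [find_orfs_all()].
#' @param transcripts transcript tibble supplying `cds_start`/`cds_end`.
#' @return `orfs` with an `orf_type` column.
#' @export
classify_orfs <- function(orfs, transcripts) {
  d <- left_join(orfs,
                 select(transcripts, "transcript_id", "cds_start", "cds_end"),
                 by = "transcript_id")
  d$orf_type <- mapply(classify_one, d$start, d$stop, d$frame,
                       d$cds_start, d$cds_end)
  select(d, -"cds_start", -"cds_end")
}

#' Representative start among ORFs sharing a stop codon
#'
#' When several candidate starts share one stop codon, the representative
#' is chosen by the rule: restrict to AUG starts when any exist; take the
#' 5'-most; if no A-site read falls strictly between the chosen start and
#' the next downstream candidate start, advance to that candidate and
#' repeat. The result is always a member of the input group and the rule is
#' idempotent.
#'
#' @param group tibble of ORFs sharing `transcript_id` and `stop` (columns
#'   `start`, `start_codon` required).
#' @param profile integer vector of per-nucleotide A-site counts for the
#'   transcript.
#' @return The selected row of `group`.
#' @export
select_representative <- function(group, profile) {
  stopifnot(nrow(group) > 0)
  g <- arrange(group, .data$start)
  if (any(g$start_codon %in% c("AUG", "ATG"))) {
    g <- filter(g, .data$start_codon %in% c("AUG", "ATG"))
  }
  i <- 1L
  while (i < nrow(g)) {
    lo <- g$start[i]; hi <- g$start[i + 1L]
    between <- if (hi > lo) sum(profile[(lo + 1L):hi]) else 0L
    if (between == 0L) i <- i + 1L else break
  }
  g[i, ]
}

#' Collapse called ORFs to one representative per stop group
#'
#' Applies [select_representative()] within each (transcript, stop) group.
#'
#' @param orfs tibble of (called) ORFs.
#' @param profiles A-site profile tibble from [assign_asites()].
#' @return Subset of `orfs`, one row per stop group.
#' @export
collapse_stop_groups <- function(orfs, profiles) {
  if (nrow(orfs) == 0) return(orfs)
  pm <- setNames(profiles$profile, profiles$transcript_id)
  keys <- split(seq_len(nrow(orfs)),
                paste(orfs$transcript_id, orfs$stop, sep = "\r"))
  picked <- lapply(keys, function(idx) {
    g <- orfs[idx, ]
    p <- pm[[g$transcript_id[1]]]
    if (is.null(p)) p <- integer(max(g$stop))
    select_representative(g, p)
  })
  arrange(bind_rows(picked), .data$transcript_id, .data$start)
}
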