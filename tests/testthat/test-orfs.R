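test_that("ORF enumeration finds canonical and near-cognate starts", {
  o <- find_orfs("ATGAAATAA", starts = "ATG", min_len_aa = 1L)
  expect_equal(nrow(o), 1L)
  expect_equal(o$start, 0L)
  expect_equal(o$stop, 9L)
  expect_equal(o$peptide_length, 2L)
  # near-cognate CUG start
  o2 <- find_orfs("CTGAAATAA", min_len_aa = 1L)
  expect_equal(o2$start_codon, "CUG")
  # no in-frame stop: not reported
  expect_equal(nrow(find_orfs("ATGAAAAAA", min_len_aa = 1L)), 0L)
  # RNA alphabet accepted
  expect_equal(nrow(find_orfs("AUGAAAUAA", starts = "ATG", min_len_aa = 1L)),
               1L)
})

test_that("enumeration matches a brute-force scanner on random sequences", {
  set.seed(23)
  for (i in 1:50) {
    s <- random_dna(300)
    got <- find_orfs(s, min_len_aa = 1L)
    want <- orf_scanner_oracle(s, min_len_aa = 1L)
    key <- function(d) sort(paste(d$start, d$stop, d$start_codon))
    expect_equal(key(got), key(want))
  }
})

test_that("emitted ORFs satisfy the stop-codon invariants", {
  set.seed(29)
  stops <- c("UAA", "UAG", "UGA")
  for (i in 1:25) {
    s <- random_dna(250)
    o <- find_orfs(s, min_len_aa = 1L)
    if (nrow(o) == 0) next
    expect_true(all((o$stop - o$start) %% 3 == 0))
    expect_equal(o$peptide_length, (o$stop - o$start) / 3 - 1)
    rna <- chartr("T", "U", s)
    for (j in seq_len(nrow(o))) {
      codons <- substring(rna, seq(o$start[j] + 1, o$stop[j] - 2, 3),
                          seq(o$start[j] + 3, o$stop[j], 3))
      expect_true(tail(codons, 1) %in% stops)
      expect_false(any(head(codons, -1) %in% stops))
    }
  }
})

test_that("ORF classification covers every positional class", {
  tx <- toy_tx(exon_start = list(0L), exon_end = list(500L),
               cds_start = 50L, cds_end = 350L)
  mk <- function(start, stop) tibble::tibble(
    orf_id = "o", transcript_id = "tx1", start = start, stop = stop,
    start_codon = "AUG", frame = start %% 3L,
    peptide_length = (stop - start) / 3L - 1L)
  cls <- function(start, stop) classify_orfs(mk(start, stop), tx)$orf_type
  expect_equal(cls(50L, 350L), "canonical")
  expect_equal(cls(5L, 35L), "uORF")
  expect_equal(cls(40L, 80L), "overlapping_uORF")   # off-frame, ends in CDS
  expect_equal(cls(360L, 420L), "dORF")
  expect_equal(cls(100L, 160L), "internal")         # off-frame inside CDS
  expect_equal(cls(20L, 350L), "extended")
  expect_equal(cls(80L, 350L), "truncated")
  # off-frame start inside the CDS running past cds_end stays internal
  expect_equal(cls(340L, 400L), "internal")
  # no CDS at all
  nc <- toy_tx(exon_start = list(0L), exon_end = list(500L))
  expect_equal(classify_orfs(mk(10L, 40L), nc)$orf_type, "noncoding_ORF")
})

test_that("internal and overlapping uORFs never share the CDS frame", {
  sim <- small_sim(31L)
  orfs <- classify_orfs(find_orfs_all(sim$seqs), sim$transcripts)
  d <- dplyr::inner_join(
    orfs, dplyr::select(sim$transcripts, transcript_id, cds_start),
    by = "transcript_id")
  off <- dplyr::filter(d, orf_type %in% c("internal", "overlapping_uORF"))
  expect_true(nrow(off) > 0)
  expect_true(all(off$frame != off$cds_start %% 3L))
})

test_that("representative start selection follows the published rule", {
  grp <- function(starts, codons) tibble::tibble(
    transcript_id = "t", start = starts, stop = 200L,
    start_codon = codons)
  prof <- function(at) { p <- integer(250); p[at + 1L] <- 1L; p }
  # AUG present: restrict to AUGs, take the 5'-most (reads in [40,70))
  g <- grp(c(10L, 40L, 70L), c("CUG", "AUG", "AUG"))
  expect_equal(select_representative(g, prof(50:60))$start, 40L)
  # zero reads in [40,70), reads downstream: advance to 70
  expect_equal(select_representative(g, prof(80:90))$start, 70L)
  # no AUG at all: 5'-most near-cognate kept when reads lie in [10,25)
  g2 <- grp(c(10L, 25L), c("CUG", "GUG"))
  expect_equal(select_representative(g2, prof(15:20))$start, 10L)
  # output is always a member; the rule is idempotent
  pick <- select_representative(g, prof(80:90))
  expect_true(pick$start %in% g$start)
  expect_equal(select_representative(pick, prof(80:90))$start, pick$start)
})

test_that("stop-group collapse picks one representative per stop", {
  sim <- small_sim(37L)
  reads <- simulate_footprints(sim)
  prof <- assign_asites(reads, sim$truth$offsets, sim$transcripts)
  orfs <- classify_orfs(find_orfs_all(sim$seqs), sim$transcripts)
  rep <- collapse_stop_groups(orfs, prof)
  expect_equal(anyDuplicated(paste(rep$transcript_id, rep$stop)), 0L)
  expect_true(all(rep$orf_id %in% orfs$orf_id))
})
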