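test_that("genePred records convert CDS to transcript space", {
  line <- paste("nm1", "chr1", "+", 100, 200, 130, 190, 1,
                "100,", "200,", 0, "geneA", "none", "none", "-1,",
                sep = "\t")
  tx <- read_genepred(line)
  expect_equal(tx$length, 100L)
  expect_equal(tx$cds_start, 30L)
  expect_equal(tx$cds_end, 90L)
  expect_equal(tx$gene_id, "geneA")
  expect_true(tx$cds_ok)
})

test_that("minus-strand exons are ordered 5'->3' in transcript space", {
  # two-exon minus-strand record: transcript position 0 is genome 249
  line <- paste("nm2", "chr1", "-", 100, 250, 100, 250, 2,
                "100,200,", "150,250,", sep = "\t")
  tx <- read_genepred(line)
  expect_equal(tx$length, 100L)
  expect_equal(transcript_to_genome(tx[1, ], 0L), 249L)
  expect_equal(transcript_to_genome(tx[1, ], 49L), 200L)
  expect_equal(transcript_to_genome(tx[1, ], 50L), 149L)
  expect_equal(genome_to_transcript(tx[1, ], 249L), 0L)
})

test_that("empty and malformed genePred input are handled", {
  expect_equal(nrow(read_genepred(character())), 0L)
  expect_error(read_genepred("nm1\tchr1\t+"), "malformed genePred line 1")
  # CDS not divisible by 3 is flagged, not dropped
  line <- paste("nm3", "chr1", "+", 0, 100, 10, 21, 1, "0,", "100,",
                sep = "\t")
  tx <- read_genepred(line)
  expect_equal(nrow(tx), 1L)
  expect_false(tx$cds_ok)
})

test_that("coordinate map round-trips over every base of a 3-exon toy", {
  for (strand in c("+", "-")) {
    tx <- toy_tx(strand = strand,
                 exon_start = list(c(10L, 50L, 90L)),
                 exon_end = list(c(30L, 70L, 120L)))
    n <- tx$length
    g <- transcript_to_genome(tx[1, ], 0:(n - 1L))
    expect_equal(length(unique(g)), n)           # bijective
    expect_equal(genome_to_transcript(tx[1, ], g), 0:(n - 1L))
    # every exonic base is hit
    expect_setequal(g, c(10:29, 50:69, 90:119))
  }
  expect_error(transcript_to_genome(toy_tx()[1, ], 100L), "out of range")
  expect_error(genome_to_transcript(toy_tx()[1, ], 50L), "not exonic")
})

test_that("spliced sequence extraction is strand-aware", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATGAAACCCGGG"))
  plus <- toy_tx(exon_start = list(0L), exon_end = list(6L))
  expect_equal(unname(extract_transcript_seqs(plus, genome)), "ATGAAA")
  minus <- toy_tx(strand = "-", exon_start = list(0L), exon_end = list(6L))
  expect_equal(unname(extract_transcript_seqs(minus, genome)), "TTTCAT")
  # two-exon splice on a hand-spliced 12-nt toy: exons [0,4) + [8,12)
  spliced <- toy_tx(exon_start = list(c(0L, 8L)), exon_end = list(c(4L, 12L)))
  expect_equal(unname(extract_transcript_seqs(spliced, genome)), "ATGACGGG")
  expect_error(extract_transcript_seqs(
    toy_tx(chrom = "chrX", exon_start = list(0L), exon_end = list(6L)),
    genome), "absent")
})

test_that("sequence length always equals the sum of exon widths", {
  set.seed(11)
  genome <- Biostrings::DNAStringSet(c(chr1 = random_dna(2000)))
  for (i in 1:20) {
    k <- sample(1:4, 1)
    es <- sort(sample(seq(0, 1900, by = 10), k))
    ee <- es + sample(5:9, k, replace = TRUE)
    tx <- toy_tx(strand = sample(c("+", "-"), 1),
                 exon_start = list(es), exon_end = list(ee))
    s <- extract_transcript_seqs(tx, genome)
    expect_equal(unname(nchar(s)), sum(ee - es))
  }
})

test_that("biotype rules follow the lncRNA/pseudogene definitions", {
  tx <- transcript_table(
    transcript_id = c("coding", "mono400", "mono600ov", "twoexon300",
                      "mono600", "short150", "pseudo"),
    chrom = "chr1", strand = "+",
    exon_start = list(1000L, 5000L, 1100L, c(8000L, 8500L),
                      10000L, 20000L, 30000L),
    exon_end = list(2000L, 5400L, 1700L, c(8100L, 8700L),
                    10600L, 20150L, 30500L),
    cds_start = c(0L, NA, NA, NA, NA, NA, NA),
    cds_end = c(900L, NA, NA, NA, NA, NA, NA)
  )
  out <- assign_biotypes(tx, pseudogene_ids = "pseudo")
  bt <- setNames(out$biotype, out$transcript_id)
  expect_equal(bt[["coding"]], "mRNA")
  # 400-nt single-exon, no overlap: fails the "introns or > 500 nt" rule
  expect_equal(bt[["mono400"]], "unclassified")
  # 600-nt single-exon overlapping a coding gene on the same strand
  expect_equal(bt[["mono600ov"]], "unclassified")
  # 2-exon 300-nt transcript, no overlaps: introns satisfy the rule
  expect_equal(bt[["twoexon300"]], "lncRNA")
  expect_equal(bt[["mono600"]], "lncRNA")
  expect_equal(bt[["short150"]], "short_ncRNA")
  expect_equal(bt[["pseudo"]], "pseudogene")
})

test_that("biotype assignment is order-independent", {
  sim <- small_sim(7L)
  tx <- sim$transcripts
  perm <- sample(nrow(tx))
  out1 <- assign_biotypes(tx[perm, ],
                          pseudogene_ids = sim$truth$contaminant_ids)
  out2 <- assign_biotypes(tx, pseudogene_ids = sim$truth$contaminant_ids)
  m <- match(out1$transcript_id, out2$transcript_id)
  expect_equal(out1$biotype, out2$biotype[m])
})

test_that("genePred writer round-trips through the reader", {
  sim <- small_sim(3L)
  path <- tempfile(fileext = ".gp")
  write_genepred(sim$transcripts, path)
  back <- read_genepred(path)
  m <- match(sim$transcripts$transcript_id, back$transcript_id)
  expect_equal(back$length[m], sim$transcripts$length)
  expect_equal(back$cds_start[m], sim$transcripts$cds_start)
  expect_equal(back$cds_end[m], sim$transcripts$cds_end)
  expect_equal(back$exon_start[m], sim$transcripts$exon_start)
})
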