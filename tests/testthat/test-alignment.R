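test_that("SAM ingest computes strand-aware 5' ends and filters by length", {
  sam <- c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chr1\tLN:5000",
    # plus-strand, pos 1001 (1-based) -> 5' end 1000, length 28
    paste("r1", 0, "chr1", 1001, 255, "28M", "*", 0, 0,
          strrep("A", 28), "*", sep = "\t"),
    # minus-strand spanning 1000..1027 (0-based) -> 5' end 1027
    paste("r2", 16, "chr1", 1001, 255, "28M", "*", 0, 0,
          strrep("A", 28), "*", sep = "\t"),
    # length 20: below the default window
    paste("r3", 0, "chr1", 1001, 255, "20M", "*", 0, 0,
          strrep("A", 20), "*", sep = "\t"),
    # unmapped: skipped
    paste("r4", 4, "*", 0, 0, "*", "*", 0, 0, strrep("A", 28), "*",
          sep = "\t")
  )
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  reads <- load_alignments(path)
  expect_equal(nrow(reads), 2L)
  expect_equal(reads$five_prime_end[reads$strand == "+"], 1000L)
  expect_equal(reads$five_prime_end[reads$strand == "-"], 1027L)
})

test_that("simulated SAM round-trips through load_alignments", {
  sim <- small_sim(5L)
  reads <- simulate_footprints(sim)
  path <- tempfile(fileext = ".sam")
  write_sim_sam(head(reads, 500), sim, path)
  back <- load_alignments(path)
  expect_equal(nrow(back), 500L)
  orig <- head(reads, 500)
  o1 <- order(orig$chrom, orig$five_prime_end, orig$length)
  o2 <- order(back$chrom, back$five_prime_end, back$length)
  expect_equal(back$five_prime_end[o2], orig$five_prime_end[o1])
  expect_equal(back$strand[o2], orig$strand[o1])
  expect_equal(back$length[o2], orig$length[o1])
})

test_that("A-site assignment shifts by offset and respects bounds", {
  tx <- toy_tx(exon_start = list(0L), exon_end = list(100L))
  offsets <- tibble::tibble(length = 28L, offset = 15L)
  mk_read <- function(fpe) tibble::tibble(
    chrom = "chr1", strand = "+", five_prime_end = fpe, length = 28L)
  # 5' end at transcript position 10, offset 15 -> A-site at 25
  prof <- assign_asites(mk_read(10L), offsets, tx)
  expect_equal(which(prof$profile[[1]] > 0) - 1L, 25L)
  expect_equal(prof$n_reads, 1L)
  # 5' end 10 nt before the 3' end: shifted position out of bounds
  prof2 <- assign_asites(mk_read(95L), offsets, tx)
  expect_equal(prof2$n_reads, 0L)
  # read length without calibrated offset is discarded
  prof3 <- assign_asites(
    tibble::tibble(chrom = "chr1", strand = "+",
                   five_prime_end = 10L, length = 30L), offsets, tx)
  expect_equal(prof3$n_reads, 0L)
})

test_that("A-site shift crosses splice junctions in transcript space", {
  # two exons [0,50) and [80,130); 5' end 3 nt before the junction
  tx <- toy_tx(exon_start = list(c(0L, 80L)), exon_end = list(c(50L, 130L)))
  offsets <- tibble::tibble(length = 28L, offset = 15L)
  read <- tibble::tibble(chrom = "chr1", strand = "+",
                         five_prime_end = 47L, length = 28L)
  prof <- assign_asites(read, offsets, tx)
  # transcript pos of 5' end = 47; A-site = 62 = 12 nt into exon 2
  expect_equal(which(prof$profile[[1]] > 0) - 1L, 62L)
})

test_that("profile sums equal the number of assigned reads", {
  sim <- small_sim(9L)
  reads <- simulate_footprints(sim)
  off <- sim$truth$offsets
  prof <- assign_asites(reads, off, sim$transcripts)
  expect_true(all(purrr::map_int(prof$profile, sum) == prof$n_reads))
  # every simulated read lands inside its transcript, so totals match
  expect_equal(sum(prof$n_reads), nrow(reads))
})

test_that("offset calibration recovers the simulator's true offsets", {
  sim <- small_sim(13L)
  reads <- simulate_footprints(sim)
  off <- calibrate_offsets(reads, sim$transcripts)
  truth <- sim$truth$offsets
  m <- match(off$length, truth$length)
  expect_equal(off$offset, truth$offset[m])
  expect_true(all(off$inframe_fraction > 0.5))
})

test_that("uncalibratable input raises calibration errors", {
  tx <- toy_tx(cds_start = 0L, cds_end = 60L,
               exon_start = list(0L), exon_end = list(100L))
  empty <- tibble::tibble(chrom = character(), strand = character(),
                          five_prime_end = integer(), length = integer())
  expect_error(calibrate_offsets(empty, tx), "default offset table")
  # phase-random reads never reach the in-frame threshold
  set.seed(1)
  reads <- tibble::tibble(chrom = "chr1", strand = "+",
                          five_prime_end = sample(0:70, 400, replace = TRUE),
                          length = 24L)
  expect_error(calibrate_offsets(reads, tx, support_min = 100L),
               "thresholds")
})

test_that("metagene profile shows the simulated periodicity", {
  sim <- small_sim(17L)
  reads <- simulate_footprints(sim)
  prof <- assign_asites(reads, sim$truth$offsets, sim$transcripts)
  mg <- metagene_profile(prof, sim$transcripts, anchor = "start",
                         window = 30L)
  expect_equal(nrow(mg), 61L)
  inside <- dplyr::filter(mg, position >= 0)
  frame_means <- tapply(inside$rpm, inside$position %% 3, mean)
  # frame 1 dominates frames 2 and 3 (sawtooth with period 3)
  expect_gt(frame_means[["0"]], frame_means[["1"]])
  expect_gt(frame_means[["1"]], frame_means[["2"]])
  # all-zero profiles give a zero vector
  zero <- prof
  zero$profile <- lapply(zero$profile, function(p) 0L * p)
  zero$n_reads <- 0L
  mg0 <- metagene_profile(zero, sim$transcripts, window = 9L)
  expect_true(all(mg0$rpm == 0))
})
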