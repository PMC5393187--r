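test_that("load_transcriptome applies the stop-inclusive convention", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", paste0(strrep("ATG", 9), "TAA")), fa)
  tx <- load_transcriptome(fa, quiet = TRUE)
  expect_length(tx, 1L)
  expect_equal(tx$t1$n_codons, 10L)
  expect_equal(nchar(tx$t1$protein), 9L)
  expect_equal(tx$t1$protein, strrep("M", 9))
})

test_that("invalid records are skipped with logged reasons", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(
    ">bad_len", strrep("A", 31),
    ">internal_stop", "ATGTAAATGTAA",
    ">no_stop", "ATGATGATG",
    ">bad_chars", "ATGNNNTAA",
    ">ok", "ATGAAACGTTAA"), fa)
  tx <- load_transcriptome(fa, quiet = TRUE)
  expect_length(tx, 1L)
  expect_named(tx, "ok")
  sk <- attr(tx, "skipped")
  expect_equal(nrow(sk), 4L)
  expect_setequal(sk$id, c("bad_len", "internal_stop", "no_stop", "bad_chars"))
  expect_error(load_transcriptome(tempfile()), "not found")
})

test_that("generated transcriptomes round-trip through FASTA losslessly", {
  g <- make_transcriptome(60, len_range = c(100, 200), seed = 11)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_transcriptome(g$transcripts, fa)
  back <- load_transcriptome(fa, quiet = TRUE)
  expect_equal(nrow(attr(back, "skipped")), 0L)
  expect_identical(names(back), names(g$transcripts))
  for (id in names(back))
    expect_identical(back[[id]], g$transcripts[[id]])
  fa2 <- withr::local_tempfile(fileext = ".fa")
  write_transcriptome(back, fa2)
  expect_identical(readLines(fa), readLines(fa2))
})

make_tiny_tx <- function(n_sense = 40L) {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tx1", paste0(strrep("GCT", n_sense), "TAA")), fa)
  on.exit(unlink(fa))
  load_transcriptome(fa, quiet = TRUE)
}

test_that("footprint loading assigns the P-site at 5' end + offset", {
  tx <- make_tiny_tx()
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("tx1\t0\t28\tfp1\t0\t+", bed)
  tracks <- load_footprints(bed, tx, analysis_params(psite_offset = 15))
  expect_equal(tracks$tx1$counts[16], 1L)   # 0-based position 15
  expect_equal(tracks$tx1$total_reads, 1L)
  expect_equal(tracks$tx1$library_total, 1)
})

test_that("empty BED yields all-zero tracks and zero library total", {
  tx <- make_tiny_tx()
  bed <- withr::local_tempfile(fileext = ".bed")
  file.create(bed)
  tracks <- load_footprints(bed, tx, analysis_params())
  expect_true(all(tracks$tx1$counts == 0L))
  expect_equal(tracks$tx1$library_total, 0)
})

test_that("footprint tally matches a brute-force count and conserves reads", {
  g <- make_transcriptome(5, len_range = c(100, 150), seed = 3)
  params <- analysis_params()
  bed <- withr::local_tempfile(fileext = ".bed")
  gr <- simulate_footprints(g$transcripts, g$truth, stall_model(),
                            depth = 0.5, params, seed = 5, bed_path = bed)
  tracks <- load_footprints(bed, g$transcripts, params)
  # independent tally straight from the BED text
  bed_dt <- read.table(bed, sep = "\t")
  for (id in names(g$transcripts)) {
    expected <- integer(g$transcripts[[id]]$n_nt)
    rows <- bed_dt[bed_dt$V1 == id, ]
    for (s in rows$V2) {
      p <- s + params$psite_offset
      expected[p + 1L] <- expected[p + 1L] + 1L
    }
    expect_equal(tracks[[id]]$counts, expected)
  }
  expect_equal(tracks[[1]]$library_total + sum(attr(tracks, "dropped")),
               length(gr))
})

test_that("unknown transcripts are dropped with warning; negatives fatal", {
  tx <- make_tiny_tx()
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("tx1\t0\t28\tfp1\t0\t+", "ghost\t0\t28\tfp2\t0\t+"), bed)
  expect_warning(tracks <- load_footprints(bed, tx, analysis_params()),
                 "unknown")
  expect_equal(unname(attr(tracks, "dropped")["unknown_transcript"]), 1)
  expect_equal(tracks$tx1$library_total, 1)
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines("tx1\t-3\t25\tfp1\t0\t+", bed2)
  expect_error(load_footprints(bed2, tx, analysis_params()), "negative")
})

test_that("pool_tracks sums counts and library totals", {
  a <- coverage_track("t", c(1L, 2L), library_total = 10)
  b <- coverage_track("t", c(3L, 4L), library_total = 5)
  z <- coverage_track("t", c(0L, 0L), library_total = 0)
  pooled <- pool_tracks(a, b)
  expect_equal(pooled$counts, c(4L, 6L))
  expect_equal(pooled$library_total, 15)
  expect_equal(pool_tracks(a, z)$counts, a$counts)
  expect_error(pool_tracks(a, coverage_track("t", c(1L, 2L, 3L))),
               "different lengths")
  expect_error(pool_tracks(a, coverage_track("u", c(1L, 2L))),
               "different transcripts")
})

test_that("pooling simulated replicates conserves totals", {
  g <- make_transcriptome(3, len_range = c(100, 120), seed = 2)
  p <- analysis_params()
  bed1 <- withr::local_tempfile(fileext = ".bed")
  bed2 <- withr::local_tempfile(fileext = ".bed")
  simulate_footprints(g$transcripts, g$truth, stall_model(), 0.3, p,
                      seed = 1, bed_path = bed1)
  simulate_footprints(g$transcripts, g$truth, stall_model(), 0.3, p,
                      seed = 2, bed_path = bed2)
  t1 <- load_footprints(bed1, g$transcripts, p)
  t2 <- load_footprints(bed2, g$transcripts, p)
  pooled <- pool_tracks(t1, t2)
  for (id in names(pooled))
    expect_equal(pooled[[id]]$total_reads,
                 t1[[id]]$total_reads + t2[[id]]$total_reads)
})

test_that("rpkm_track matches the definitional example and scales", {
  tr <- coverage_track("t", rep(1L, 1000), library_total = 1e6)
  r <- rpkm_track(tr)
  expect_equal(mean(r), 1000)             # 1000 reads / (1 kb x 1 M)
  expect_equal(rpkm_track(coverage_track("t", rep(0L, 50),
                                         library_total = 100)),
               rep(0, 50))
  tr2 <- coverage_track("t", rep(1L, 1000), library_total = 2e6)
  expect_equal(rpkm_track(tr2), r / 2)
  expect_error(rpkm_track(coverage_track("t", rep(0L, 10),
                                         library_total = 0)), "empty library")
})

test_that("coverage TSV round-trips", {
  g <- make_transcriptome(4, len_range = c(100, 130), seed = 9)
  tracks <- simulate_rnaseq(g$transcripts, depth = 0.3, seed = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_coverage_tsv(tracks, tsv)
  back <- read_coverage_tsv(tsv, g$transcripts)
  for (id in names(tracks))
    expect_equal(back[[id]]$counts, tracks[[id]]$counts)
})

test_that("codon/nt mapping is self-inverse", {
  i <- 0:100
  expect_equal(nt_to_codon(codon_to_nt(i)), i)
  expect_equal(nt_to_codon(codon_to_nt(i) + 2L), i)
})

test_that("params JSON round-trips and validates", {
  p <- analysis_params(tract_min_basic = 8, psite_offset = 12)
  f <- withr::local_tempfile(fileext = ".json")
  write_params(p, f)
  expect_equal(read_params(f), p)
  expect_error(analysis_params(terminal_fraction = 0.6), "terminal_fraction")
  expect_error(analysis_params(flank = 0), "flank")
})
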