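# fabricate a transcript of n sense codons without sequence content
blank_transcript <- function(id, n_sense) {
  structure(list(id = id, cds_nt = NULL, protein = NULL,
                 n_codons = n_sense + 1L, n_nt = 3L * (n_sense + 1L)),
            class = "transcript")
}

win_row <- function(id, start, last, width = 10L, cls = "basic",
                    wclass = "tract") {
  data.table::data.table(transcript_id = id, start_res = start,
                         width = width, n_target = 8L,
                         last_target_res = last, residue_class = cls,
                         window_class = wclass)
}

test_that("define_regions follows the stated codon arithmetic", {
  params <- analysis_params()
  tx <- blank_transcript("t", 500L)
  reg <- define_regions(win_row("t", 195L, 199L), tx, params)
  expect_true(reg$analyzable)
  expect_equal(reg$post, 3L * c(240L, 480L))
  expect_equal(reg$pre, 3L * c(20L, 240L))
  # pre always ends where post begins
  expect_equal(reg$pre[2], reg$post[1])

  # tract too close to the stop: post start beyond post end
  reg2 <- define_regions(win_row("t", 430L, 439L), tx, params)
  expect_false(reg2$analyzable)
})

test_that("occupancy_ratio is densities post over pre", {
  params <- analysis_params()
  tx <- blank_transcript("t", 500L)
  reg <- define_regions(win_row("t", 195L, 199L), tx, params)

  occ <- occupancy_ratio(uniform_track("t", 500L, per_nt = 2L), reg)
  expect_equal(occ$ratio, 1.0)

  counts <- rep(4L, tx$n_nt)
  counts[(reg$post[1] + 1L):reg$post[2]] <- 1L
  occ2 <- occupancy_ratio(coverage_track("t", counts), reg)
  expect_equal(occ2$ratio, 0.25)

  counts[(reg$post[1] + 1L):reg$post[2]] <- 0L
  expect_equal(occupancy_ratio(coverage_track("t", counts), reg)$ratio, 0)

  counts0 <- rep(0L, tx$n_nt)
  counts0[(reg$post[1] + 1L):reg$post[2]] <- 1L
  occ3 <- occupancy_ratio(coverage_track("t", counts0), reg)
  expect_true(is.na(occ3$ratio))
  expect_equal(occ3$excluded_reason, "zero_pre")
})

test_that("occupancy_ratio is invariant to uniform count scaling", {
  params <- analysis_params()
  tx <- blank_transcript("t", 300L)
  reg <- define_regions(win_row("t", 100L, 107L), tx, params)
  set.seed(1)
  counts <- rpois(tx$n_nt, 2) + 1L
  r1 <- occupancy_ratio(coverage_track("t", counts), reg)$ratio
  r2 <- occupancy_ratio(coverage_track("t", counts * 7L), reg)$ratio
  expect_equal(r1, r2)
})

test_that("the wt read filter uses the stated 25-read boundary", {
  params <- analysis_params()
  txs <- structure(list(a = blank_transcript("a", 400L),
                        b = blank_transcript("b", 400L)),
                   class = "transcriptome")
  tracks <- list(a = uniform_track("a", 400L, 1L),
                 b = uniform_track("b", 400L, 1L))
  recs <- occupancy_records(
    rbind(win_row("a", 100L, 105L), win_row("b", 100L, 105L)),
    txs, tracks, params = params)
  wt <- list(a = coverage_track("a", c(rep(1L, 24), rep(0L, 3 * 401 - 24))),
             b = coverage_track("b", c(rep(1L, 25), rep(0L, 3 * 401 - 25))))
  out <- suppressMessages(apply_filters(recs, wt, txs, params))
  expect_equal(out$f_min_reads_wt, c(FALSE, TRUE))
  expect_equal(out$included, c(FALSE, TRUE))
  # missing wt track fails closed
  out2 <- suppressMessages(apply_filters(recs, wt["b"], txs, params))
  expect_equal(out2$f_min_reads_wt, c(FALSE, TRUE))
})

test_that("terminal-5% and distance-to-stop filters use the stated rules", {
  params <- analysis_params()
  txs <- structure(list(t = blank_transcript("t", 100L)),
                   class = "transcriptome")
  tracks <- list(t = uniform_track("t", 100L, 5L))
  # start 2 overlaps residues 0-4 (first 5% of 100)
  recs <- occupancy_records(win_row("t", 2L, 9L), txs, tracks,
                            params = params)
  out <- suppressMessages(apply_filters(recs, tracks, txs, params))
  expect_false(out$f_terminal[1])
  # a 500-codon transcript, tract at 25: fine terminally, check stop rule
  txs2 <- structure(list(t = blank_transcript("t", 500L)),
                    class = "transcriptome")
  tracks2 <- list(t = uniform_track("t", 500L, 5L))
  # 29 codons between the last target residue (470) and the stop -> excluded;
  # exactly 30 codons (last target 469) -> kept
  near_stop <- win_row("t", 461L, 470L)
  boundary <- win_row("t", 460L, 469L)
  mid <- win_row("t", 250L, 259L)
  recs2 <- occupancy_records(rbind(mid, boundary, near_stop), txs2, tracks2,
                             params = params)
  out2 <- suppressMessages(apply_filters(recs2, tracks2, txs2, params))
  expect_equal(out2$f_dist_stop, c(TRUE, TRUE, FALSE))
})

test_that("SD outlier filter cuts at control mean + 2 SD", {
  params <- analysis_params()
  txs <- structure(list(t = blank_transcript("t", 500L)),
                   class = "transcriptome")
  tracks <- list(t = uniform_track("t", 500L, 5L))
  tract <- occupancy_records(win_row("t", 200L, 207L), txs, tracks,
                             params = params)
  # synthetic control distribution: mean 1, sd 0.2
  ctrl <- do.call(rbind, lapply(1:11, function(i)
    occupancy_records(win_row("t", 200L, 207L, wclass = "control"),
                      txs, tracks, params = params)))
  ctrl$ratio <- seq(0.7, 1.3, length.out = 11)   # sd .2007, mean 1
  s <- sd(ctrl$ratio); m <- mean(ctrl$ratio)
  for (r in c(1.3, 1.5)) {
    tr <- data.table::copy(tract); tr$ratio <- r
    out <- apply_filters(tr, tracks, txs, params, control_records = ctrl)
    expect_equal(out$f_sd_outlier[1], r <= m + 2 * s)
  }
})

test_that("metaprofile normalizes, excludes, and averages as stated", {
  params <- analysis_params()
  n_sense <- 300L
  tr <- win_row("t", 100L, 107L)
  center <- 3L * (100L + 5L)
  # delta fixture: all reads at the center
  counts <- rep(0L, 3L * (n_sense + 1L))
  counts[center + 1L] <- 50L
  mp <- metaprofile(list(t = coverage_track("t", counts)), tr, params)
  expect_equal(mp$n_windows, 1L)
  expect_equal(mp$mean_frequency[mp$offsets == 0], 1)
  expect_equal(sum(mp$mean_frequency), 1)

  # a window with 9 reads is excluded
  counts9 <- rep(0L, 3L * (n_sense + 1L)); counts9[center + 1L] <- 9L
  expect_error(metaprofile(list(t = coverage_track("t", counts9)), tr,
                           params), "low-read")

  # two uniform windows give a flat profile at 1/301
  two <- rbind(win_row("t", 60L, 67L), win_row("t", 160L, 167L))
  mp2 <- metaprofile(list(t = uniform_track("t", n_sense, 2L)), two, params)
  expect_equal(mp2$n_windows, 2L)
  expect_equal(mp2$mean_frequency, rep(1 / 301, 301))

  # window extending past the transcript end is dropped
  edge <- win_row("t", 2L, 9L)
  mp3 <- metaprofile(list(t = uniform_track("t", n_sense, 2L)),
                     rbind(two, edge), params)
  expect_equal(mp3$n_windows, 2L)
  expect_equal(mp3$n_out_of_bounds, 1L)
})

test_that("matched-control sampling reproduces and matches features", {
  set.seed(99)
  tracts <- data.table::data.table(
    relative_position = rbeta(1000, 2, 6),
    transcript_length = exp(rnorm(1000, 7, 0.3)),
    window_reads = rpois(1000, 60))
  pool <- data.table::data.table(
    relative_position = runif(20000),
    transcript_length = exp(rnorm(20000, 7.4, 0.5)),
    window_reads = rpois(20000, 40))
  s1 <- sample_matched_controls(tracts, pool, n = 300, seed = 11)
  s2 <- sample_matched_controls(tracts, pool, n = 300, seed = 11)
  expect_identical(s1, s2)
  s3 <- sample_matched_controls(tracts, pool, n = 300, seed = 12)
  expect_false(identical(s1, s3))
  for (f in names(tracts))
    expect_lt(ks_distance(s1[[f]], tracts[[f]]),
              ks_distance(pool[[f]], tracts[[f]]) + 1e-12)
  # identity case: pool = tracts themselves
  s4 <- sample_matched_controls(tracts, tracts, n = nrow(tracts), seed = 1)
  for (f in names(tracts))
    expect_lt(ks_distance(s4[[f]], tracts[[f]]), 0.05)
})

test_that("compare_occupancy is a pooled t-test with symmetric sign", {
  g1 <- c(0.1, 0.2, 0.15); g2 <- c(0.9, 1.0, 1.1)
  res <- compare_occupancy(g1, g2)
  orc <- oracle_t_test(g1, g2)
  expect_equal(res$t, orc$t, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)
  flip <- compare_occupancy(g2, g1)
  expect_equal(flip$t, -res$t)
  expect_equal(flip$p, res$p)
  expect_warning(same <- compare_occupancy(c(1, 1), c(1, 1)), "constant")
  expect_equal(same$t, 0); expect_equal(same$p, 1)
})

test_that("dropoff_report arithmetic and counts", {
  mk <- function(ratios, ids, wclass, genotype = "g1") {
    data.table::data.table(
      transcript_id = ids, ratio = ratios,
      pre_density = 1, post_density = ratios,
      window_class = wclass, included = TRUE, genotype = genotype)
  }
  tr <- mk(c(0.25, 0.25, 0.25), c("a", "a", "b"), "tract")
  cr <- mk(rep(1, 4), c("c", "d", "e", "f"), "control")
  rep1 <- dropoff_report(tr, cr)
  pooled <- rep1[rep1$group == "pooled", ]
  expect_equal(pooled$n_windows, 3L)
  expect_equal(pooled$n_genes, 2L)
  expect_equal(pooled$percent_drop, 75)
  expect_equal(pooled$percent_drop_rom, 75)
  # equal groups: zero drop
  rep2 <- dropoff_report(mk(rep(1, 3), c("a", "b", "c"), "tract"), cr)
  expect_equal(rep2[rep2$group == "pooled", ]$percent_drop, 0)
})
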