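# End-to-end recovery pipeline on synthetic data: plant tracts with a known
# read-through fraction f, simulate footprints through the BED round-trip,
# run discovery -> occupancy -> filters -> matched controls -> report.
# Tract transcripts get the stall model; transcripts without a planted tract
# have uniform coverage and act as the control-transcript pool (two or fewer
# basic residues in every window -- here zero, by construction).
run_recovery <- function(f, seed, n_tract = 320L, n_ctrl = 320L,
                         len_range = c(250L, 350L), lambda = 0.25,
                         n_matched = 300L, pool_per_tx = 3L,
                         params = analysis_params(tract_min_basic = 8L)) {
  g <- make_transcriptome(
    n_tract + n_ctrl, len_range = len_range,
    tract_count = rep(c(8L, 0L), c(n_tract, n_ctrl)),
    tract_position = c(0.15, 0.6), seed = seed)
  bed <- tempfile(fileext = ".bed")
  on.exit(unlink(bed))
  simulate_footprints(
    g$transcripts, g$truth,
    stall_model(lambda_pre = lambda, dip_factor = 1, pileup_amplitude = 1,
                readthrough = f),
    depth = 1, params = params, seed = seed + 1L, bed_path = bed)
  tracks <- load_footprints(bed, g$transcripts, params)

  wins <- scan_transcriptome(g$transcripts, params, min_count = 8L)
  ctrl_ids <- setdiff(names(g$transcripts), g$truth$transcript_id)
  ctrl_tx <- structure(g$transcripts[ctrl_ids], class = "transcriptome")
  pool <- scan_transcriptome(ctrl_tx, params, what = "control")
  # thin the (huge) all-positions pool to a workable per-transcript sample
  pool <- stallscan:::with_seed(seed + 2L, {
    idx <- unlist(lapply(split(seq_len(nrow(pool)), pool$transcript_id),
                         function(ii) ii[sample.int(length(ii),
                                                    min(pool_per_tx,
                                                        length(ii)))]))
    pool[sort(idx), ]
  })

  recs_t <- occupancy_records(wins, g$transcripts, tracks, params = params)
  recs_c <- occupancy_records(pool, g$transcripts, tracks, params = params)
  recs_t <- add_match_features(recs_t, g$transcripts, tracks, params)
  recs_c <- add_match_features(recs_c, g$transcripts, tracks, params)
  recs_c <- apply_filters(recs_c, tracks, g$transcripts, params,
                          control_records = recs_c)
  recs_t <- apply_filters(recs_t, tracks, g$transcripts, params,
                          control_records = recs_c)
  matched <- sample_matched_controls(recs_t[recs_t$included, ],
                                     recs_c[recs_c$included, ],
                                     n = n_matched, seed = seed + 3L)
  report <- dropoff_report(recs_t, matched)
  pooled <- report[report$group == "pooled", ]
  test <- compare_occupancy(recs_t$ratio[recs_t$included], matched$ratio)
  list(report = report, drop = pooled$percent_drop,
       n_windows = pooled$n_windows, p = test$p,
       tract_records = recs_t, matched = matched)
}
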