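#' Pre/post region definitions around a tract
#'
#' The post-tract region runs from `post_offset` (default 40) codons past the
#' tract's last target residue — skipping the cycloheximide pile-up zone — to
#' `stop_trim` (default 20) codons before the stop codon. The pre-tract
#' region runs from `start_trim` (default 20) codons after the start to the
#' beginning of the post region, and so includes the tract itself and the
#' pile-up zone. Intervals are 0-based half-open in transcript nt.
#'
#' @param tract One window row as returned by [find_tracts()] (a list or
#'   one-row data.table with `last_target_res`).
#' @param transcript A `transcript`.
#' @param params An [analysis_params()].
#' @return A list with nt intervals `pre = c(start, end)`,
#'   `post = c(start, end)` and flag `analyzable` (FALSE when either region
#'   is empty; such tracts are flagged, never an error).
#' @export
define_regions <- function(tract, transcript, params = analysis_params()) {
  L <- transcript$n_codons - 1L               # sense codons
  post_start <- as.integer(tract$last_target_res) + 1L + params$post_offset
  post_end <- L - params$stop_trim
  pre_start <- params$start_trim
  pre_end <- post_start
  analyzable <- (post_start < post_end) && (pre_start < pre_end) &&
    post_end <= L && pre_start >= 0L
  list(pre = codon_to_nt(c(pre_start, pre_end)),
       post = codon_to_nt(c(post_start, post_end)),
       analyzable = analyzable)
}

#' Post/pre occupancy ratio for one tract
#'
#' Length-normalized reads past the tract divided by length-normalized reads
#' from before the tract.
#'
#' @param track A `coverage_track`.
#' @param regions Output of [define_regions()].
#' @return A list with `pre_density`, `post_density` (reads/nt), `ratio`
#'   (`NA` with `excluded_reason = "zero_pre"` when the pre region has no
#'   reads) and `analyzable`.
#' @export
occupancy_ratio <- function(track, regions) {
  if (!isTRUE(regions$analyzable))
    return(list(pre_density = NA_real_, post_density = NA_real_,
                ratio = NA_real_, analyzable = FALSE,
                excluded_reason = "unanalyzable_regions"))
  pre <- region_density(track$counts, regions$pre)
  post <- region_density(track$counts, regions$post)
  if (pre == 0)
    return(list(pre_density = pre, post_density = post, ratio = NA_real_,
                analyzable = TRUE, excluded_reason = "zero_pre"))
  list(pre_density = pre, post_density = post, ratio = post / pre,
       analyzable = TRUE, excluded_reason = NA_character_)
}

# mean reads/nt over a 0-based half-open nt interval
region_density <- function(counts, iv) {
  sum(counts[(iv[1] + 1L):iv[2]]) / (iv[2] - iv[1])
}

#' Build occupancy records for a table of windows
#'
#' Applies [define_regions()] and [occupancy_ratio()] to every window,
#' producing the per-window record table the filter and report stages
#' consume.
#'
#' @param windows Window `data.table` from [scan_transcriptome()] (or
#'   [find_tracts()] with `transcript_id` set).
#' @param transcripts A `transcriptome`.
#' @param tracks A `coverage_set` for the analysis sample.
#' @param genotype Optional label stored in a `genotype` column.
#' @param params An [analysis_params()].
#' @return The window table with added columns `pre_start`, `pre_end`,
#'   `post_start`, `post_end` (nt), `pre_density`, `post_density`, `ratio`,
#'   `analyzable`, `excluded_reason`.
#' @export
occupancy_records <- function(windows, transcripts, tracks,
                              genotype = NA_character_,
                              params = analysis_params()) {
  recs <- data.table::copy(windows)
  n <- nrow(recs)
  cols <- list(pre_start = integer(n), pre_end = integer(n),
               post_start = integer(n), post_end = integer(n),
               pre_density = numeric(n), post_density = numeric(n),
               ratio = numeric(n), analyzable = logical(n),
               excluded_reason = character(n))
  tx_id <- recs$transcript_id
  last_tr <- recs$last_target_res
  for (i in seq_len(n)) {
    tx <- transcripts[[tx_id[i]]]
    if (is.null(tx)) stop("window on unknown transcript: ",
                          tx_id[i], call. = FALSE)
    reg <- define_regions(list(last_target_res = last_tr[i]), tx, params)
    occ <- occupancy_ratio(tracks[[tx$id]], reg)
    cols$pre_start[i] <- reg$pre[1]; cols$pre_end[i] <- reg$pre[2]
    cols$post_start[i] <- reg$post[1]; cols$post_end[i] <- reg$post[2]
    cols$pre_density[i] <- occ$pre_density
    cols$post_density[i] <- occ$post_density
    cols$ratio[i] <- occ$ratio
    cols$analyzable[i] <- occ$analyzable
    cols$excluded_reason[i] <- occ$excluded_reason
  }
  for (nm in names(cols)) data.table::set(recs, j = nm, value = cols[[nm]])
  data.table::set(recs, j = "genotype", value = genotype)
  recs
}

#' Apply the transcript-level exclusion filters
#'
#' Four named filters are evaluated in order: `min_reads_wt` (transcript
#' received at least `min_transcript_reads_wt` footprints in the wild-type
#' reference sample), `terminal_5pct` (tract window does not overlap the
#' first or last `terminal_fraction` of the transcript), `dist_to_stop` (at
#' least `min_codons_to_stop` codons between the last target residue and the
#' stop codon), and `control_sd_outlier` (ratio not more than `outlier_sd`
#' standard deviations above the mean of the control-tract ratio
#' distribution, computed on records surviving the earlier filters). Records
#' that fail remain in the table with their flags for audit; `included` is
#' TRUE only when the record is analyzable, has a defined ratio and passes
#' every filter.
#'
#' @param records Record table from [occupancy_records()]; may mix tract and
#'   control windows.
#' @param wt_tracks `coverage_set` of the wild-type reference sample. A
#'   missing track fails the read filter closed.
#' @param transcripts A `transcriptome`.
#' @param params An [analysis_params()].
#' @param control_records Records supplying the control ratio distribution
#'   for the outlier filter. Defaults to the `window_class == "control"`
#'   rows of `records`; when neither yields any control record the outlier
#'   filter passes trivially (with a message).
#' @return `records` with logical columns `f_min_reads_wt`, `f_terminal`,
#'   `f_dist_stop`, `f_sd_outlier` and `included`.
#' @export
apply_filters <- function(records, wt_tracks, transcripts,
                          params = analysis_params(),
                          control_records = NULL) {
  recs <- data.table::copy(records)
  n <- nrow(recs)
  wt_total <- vapply(recs$transcript_id, function(id) {
    tr <- wt_tracks[[id]]
    if (is.null(tr)) NA_real_ else tr$total_reads
  }, 0)
  f_reads <- !is.na(wt_total) & wt_total >= params$min_transcript_reads_wt

  L <- vapply(recs$transcript_id,
              function(id) transcripts[[id]]$n_codons - 1L, 0L)
  zone <- params$terminal_fraction * L
  f_term <- !(recs$start_res < zone |
                (recs$start_res + recs$width) > (L - zone))

  f_stop <- (L - 1L - recs$last_target_res) >= params$min_codons_to_stop

  base_ok <- recs$analyzable & !is.na(recs$ratio) & f_reads & f_term & f_stop

  if (is.null(control_records))
    control_records <- recs[recs$window_class == "control", ]
  ctrl <- control_filter_stats(control_records, wt_tracks, transcripts, params)
  if (is.null(ctrl)) {
    message("no control records available: SD outlier filter not applied")
    f_sd <- rep(TRUE, n)
  } else {
    f_sd <- recs$ratio <= ctrl$mean + params$outlier_sd * ctrl$sd
    f_sd[is.na(f_sd)] <- FALSE
  }
  data.table::set(recs, j = "f_min_reads_wt", value = f_reads)
  data.table::set(recs, j = "f_terminal", value = f_term)
  data.table::set(recs, j = "f_dist_stop", value = f_stop)
  data.table::set(recs, j = "f_sd_outlier", value = f_sd)
  data.table::set(recs, j = "included", value = base_ok & f_sd)
  recs
}

# Mean/SD of the control ratio distribution after the three deterministic
# filters (the SD filter is defined to run last). NULL when no usable
# control record exists or the SD is degenerate.
control_filter_stats <- function(control_records, wt_tracks, transcripts,
                                 params) {
  if (is.null(control_records) || !nrow(control_records)) return(NULL)
  cr <- control_records
  wt_total <- vapply(cr$transcript_id, function(id) {
    tr <- wt_tracks[[id]]
    if (is.null(tr)) NA_real_ else tr$total_reads
  }, 0)
  L <- vapply(cr$transcript_id,
              function(id) transcripts[[id]]$n_codons - 1L, 0L)
  zone <- params$terminal_fraction * L
  ok <- cr$analyzable & !is.na(cr$ratio) &
    !is.na(wt_total) & wt_total >= params$min_transcript_reads_wt &
    !(cr$start_res < zone | (cr$start_res + cr$width) > (L - zone)) &
    (L - 1L - cr$last_target_res) >= params$min_codons_to_stop
  r <- cr$ratio[ok]
  if (length(r) < 2L) return(NULL)
  s <- stats::sd(r)
  if (!is.finite(s)) return(NULL)
  list(mean = mean(r), sd = s, n = length(r))
}

#' Read-frequency metaprofile around tract centers
#'
#' For each window, footprint counts over the tract center plus and minus
#' `flank` nt are normalized to sum 1 and averaged across windows. The
#' center is the first nt of codon `start_res + width/2`. Windows with fewer
#' than `min_window_reads` footprints, or extending past the transcript
#' ends, are excluded.
#'
#' @param tracks A `coverage_set`.
#' @param tracts Window `data.table` (see [scan_transcriptome()]).
#' @param params An [analysis_params()].
#' @return A list of class `metaprofile`: `offsets` (-flank..flank),
#'   `mean_frequency`, `n_windows`, and exclusion tallies `n_low_reads`,
#'   `n_out_of_bounds`.
#' @export
metaprofile <- function(tracks, tracts, params = analysis_params()) {
  flank <- params$flank
  acc <- numeric(2L * flank + 1L)
  n_used <- 0L; n_low <- 0L; n_oob <- 0L
  for (i in seq_len(nrow(tracts))) {
    tr <- tracks[[tracts$transcript_id[i]]]
    if (is.null(tr)) stop("no track for transcript ",
                          tracts$transcript_id[i], call. = FALSE)
    center <- codon_to_nt(tracts$start_res[i] + tracts$width[i] %/% 2L)
    lo <- center - flank; hi <- center + flank
    if (lo < 0L || hi >= length(tr$counts)) { n_oob <- n_oob + 1L; next }
    v <- tr$counts[(lo + 1L):(hi + 1L)]
    s <- sum(v)
    if (s < params$min_window_reads) { n_low <- n_low + 1L; next }
    acc <- acc + v / s
    n_used <- n_used + 1L
  }
  if (n_used == 0L)
    stop("no windows survive metaprofile exclusions (",
         n_low, " low-read, ", n_oob, " out-of-bounds)", call. = FALSE)
  structure(list(offsets = seq(-flank, flank),
                 mean_frequency = acc / n_used, n_windows = n_used,
                 n_low_reads = n_low, n_out_of_bounds = n_oob),
            class = "metaprofile")
}

#' @export
print.metaprofile <- function(x, ...) {
  cat("metaprofile over", x$n_windows, "windows, offsets",
      min(x$offsets), "..", max(x$offsets), "nt\n")
  invisible(x)
}

#' Add matching features to occupancy records
#'
#' Computes the three features used to match control tracts to polybasic
#' tracts: `relative_position` (window start over protein length),
#' `transcript_length` (nt) and `window_reads` (footprints in the
#' metaprofile window around the tract center, clipped to the transcript).
#'
#' @param records Record table.
#' @param transcripts A `transcriptome`.
#' @param tracks A `coverage_set`.
#' @param params An [analysis_params()].
#' @return `records` with the three feature columns added.
#' @export
add_match_features <- function(records, transcripts, tracks,
                               params = analysis_params()) {
  recs <- data.table::copy(records)
  n <- nrow(recs)
  relpos <- numeric(n); len <- numeric(n); wreads <- numeric(n)
  for (i in seq_len(n)) {
    tx <- transcripts[[recs$transcript_id[i]]]
    relpos[i] <- recs$start_res[i] / (tx$n_codons - 1L)
    len[i] <- tx$n_nt
    tr <- tracks[[tx$id]]
    center <- codon_to_nt(recs$start_res[i] + recs$width[i] %/% 2L)
    lo <- max(0L, center - params$flank)
    hi <- min(tx$n_nt - 1L, center + params$flank)
    wreads[i] <- sum(tr$counts[(lo + 1L):(hi + 1L)])
  }
  data.table::set(recs, j = "relative_position", value = relpos)
  data.table::set(recs, j = "transcript_length", value = len)
  data.table::set(recs, j = "window_reads", value = wreads)
  recs
}

#' Sample control tracts matched to the tract feature distributions
#'
#' Stratified resampling of the control pool so that the sampled controls
#' follow the tracts' distributions of position along the transcript,
#' transcript length and window read number. Each feature is binned into
#' deciles of the tract distribution (marginal bins applied as a product of
#' per-feature weights rather than joint bins, which would be mostly empty
#' at small n); every control is weighted by how over- or under-represented
#' its bins are relative to the tracts, and `n` controls are drawn with
#' those weights. Sampling is seeded and bit-reproducible.
#'
#' @param tract_records,control_records Record tables carrying the feature
#'   columns (see [add_match_features()]).
#' @param features Feature column names to match on.
#' @param n Number of controls to draw.
#' @param seed Integer seed.
#' @param n_bins Quantile bins per feature (default deciles).
#' @return The sampled subset of `control_records` (n rows).
#' @export
sample_matched_controls <- function(tract_records, control_records,
                                    features = c("relative_position",
                                                 "transcript_length",
                                                 "window_reads"),
                                    n, seed = 1L, n_bins = 10L) {
  stopifnot(nrow(tract_records) > 0L, nrow(control_records) > 0L)
  missing_f <- setdiff(features, intersect(names(tract_records),
                                           names(control_records)))
  if (length(missing_f))
    stop("missing feature column(s): ", paste(missing_f, collapse = ", "),
         " — run add_match_features() first", call. = FALSE)
  # per-feature decile bins of the tract distribution
  bins <- list(); masses <- list()
  for (f in features) {
    tv <- tract_records[[f]]
    edges <- unique(stats::quantile(tv, probs = seq(0, 1, length.out = n_bins + 1L),
                                    names = FALSE, type = 7))
    if (length(edges) < 2L) next                      # feature degenerate
    k <- length(edges) - 1L
    tb <- cut_bins(tv, edges)
    cb <- cut_bins(control_records[[f]], edges)
    pt <- tabulate(tb, nbins = k) / length(tb)
    starved <- pt > 0 & tabulate(cb, nbins = k) == 0
    if (any(starved))
      message("feature '", f, "': ", sum(starved),
              " tract bin(s) empty in the control pool; ",
              "weight mass redistributed to neighbouring bins")
    bins[[f]] <- cb
    masses[[f]] <- pt
  }
  # sequential marginal adjustment (raking): repeatedly rescale weights so
  # each feature's weighted bin masses match the tract masses
  w <- rep(1, nrow(control_records))
  for (f in names(bins)) w[bins[[f]] == 0L] <- 0   # out of tract range
  if (all(w == 0))
    stop("no control falls inside the tract feature ranges", call. = FALSE)
  for (pass in seq_len(if (length(bins) > 1L) 10L else 1L)) {
    for (f in names(bins)) {
      k <- length(masses[[f]])
      pw <- vapply(seq_len(k),
                   function(b) sum(w[bins[[f]] == b]), 0)
      pw <- pw / sum(w)
      ratio <- c(0, ifelse(pw > 0, masses[[f]] / pw, 0))
      w <- w * ratio[bins[[f]] + 1L]
    }
  }
  if (all(w == 0)) w <- rep(1, length(w))
  replace <- n > sum(w > 0)
  if (replace)
    message("control pool smaller than n after weighting; ",
            "sampling with replacement")
  idx <- with_seed(seed, sample.int(nrow(control_records), size = n,
                                    replace = replace, prob = w))
  control_records[idx, ]
}

# assign values to bins from edge vector; values outside the edge range get
# bin 0 (unmatchable: a control far outside the tract feature range must
# never be clamped into an edge decile)
cut_bins <- function(x, edges) {
  b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  b[x < edges[1] | x > edges[length(edges)]] <- 0L
  b
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Compare tract and control occupancy-ratio distributions
#'
#' Two-sided two-sample Student's t-test (pooled variance by default; set
#' `welch = TRUE` for the unequal-variance form).
#'
#' @param tract_ratios,control_ratios Numeric vectors (length >= 2 each).
#' @param welch Use the Welch test instead of pooled variance.
#' @return List with `t`, `p`, `df`, `mean_tract`, `mean_control`.
#' @export
compare_occupancy <- function(tract_ratios, control_ratios, welch = FALSE) {
  stopifnot(length(tract_ratios) >= 2L, length(control_ratios) >= 2L)
  if (stats::sd(tract_ratios) == 0 && stats::sd(control_ratios) == 0 &&
      mean(tract_ratios) == mean(control_ratios)) {
    warning("both groups constant and identical; returning t = 0, p = 1")
    return(list(t = 0, p = 1, df = length(tract_ratios) +
                  length(control_ratios) - 2L,
                mean_tract = mean(tract_ratios),
                mean_control = mean(control_ratios)))
  }
  tt <- tryCatch(
    stats::t.test(tract_ratios, control_ratios, var.equal = !welch),
    error = function(e) {
      # both groups (essentially) constant but with different means: the
      # pooled SE is ~0, so the statistic diverges
      warning("groups essentially constant; returning infinite t, p = 0")
      list(statistic = sign(mean(tract_ratios) - mean(control_ratios)) * Inf,
           p.value = 0,
           parameter = length(tract_ratios) + length(control_ratios) - 2L)
    })
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_tract = mean(tract_ratios), mean_control = mean(control_ratios))
}

#' Drop-off report: mean occupancy ratios by group
#'
#' Summarizes filtered tract records against control records, per genotype
#' and pooled across genotypes. The headline percent drop is
#' `100 * (1 - mean(tract ratios) / mean(control ratios))`; the
#' ratio-of-means variant (group post density sums over pre density sums) is
#' reported alongside, since the two conventions differ on skewed data.
#'
#' @param tract_records,control_records Filtered record tables (rows with
#'   `included == TRUE` are used); a `genotype` column defines the groups.
#' @param pooled Also emit a row pooling all genotypes.
#' @return A `data.table` with columns `group`, `n_windows`, `n_genes`,
#'   `mean_ratio`, `mean_ratio_control`, `percent_drop`, `percent_drop_rom`,
#'   `t`, `p`.
#' @export
dropoff_report <- function(tract_records, control_records, pooled = TRUE) {
  tr <- tract_records[tract_records$included, ]
  cr <- control_records[control_records$included, ]
  groups <- unique(stats::na.omit(tr$genotype))
  rows <- list()
  one_row <- function(label, t_sub, c_sub) {
    if (!nrow(t_sub))
      return(data.table::data.table(
        group = label, n_windows = 0L, n_genes = 0L, mean_ratio = NA_real_,
        mean_ratio_control = NA_real_, percent_drop = NA_real_,
        percent_drop_rom = NA_real_, t = NA_real_, p = NA_real_))
    mt <- mean(t_sub$ratio)
    mc <- if (nrow(c_sub)) mean(c_sub$ratio) else NA_real_
    rom_t <- mean(t_sub$post_density) / mean(t_sub$pre_density)
    rom_c <- if (nrow(c_sub))
      mean(c_sub$post_density) / mean(c_sub$pre_density) else NA_real_
    test <- if (nrow(t_sub) >= 2L && nrow(c_sub) >= 2L)
      suppressWarnings(compare_occupancy(t_sub$ratio, c_sub$ratio))
    else list(t = NA_real_, p = NA_real_)
    data.table::data.table(
      group = label, n_windows = nrow(t_sub),
      n_genes = length(unique(t_sub$transcript_id)),
      mean_ratio = mt, mean_ratio_control = mc,
      percent_drop = 100 * (1 - mt / mc),
      percent_drop_rom = 100 * (1 - rom_t / rom_c),
      t = test$t, p = test$p)
  }
  for (g in groups)
    rows[[g]] <- one_row(g, tr[tr$genotype %in% g, ],
                         cr[cr$genotype %in% g | is.na(cr$genotype), ])
  if (pooled || !length(groups))
    rows[["pooled"]] <- one_row("pooled", tr, cr)
  data.table::rbindlist(rows)
}
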