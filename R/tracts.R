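#' Sliding-window residue-class counts
#'
#' For every window start `s`, the number of target-class residues in
#' `protein[s, s + width)` (0-based).
#'
#' @param protein Amino-acid string.
#' @param width Window width in residues.
#' @param cls A [residue_class()].
#' @return Integer vector of length `nchar(protein) - width + 1` (empty when
#'   the protein is shorter than the window).
#' @examples
#' window_counts("KKKKKAAAAAKK", 10, residue_class("basic"))
#' @export
window_counts <- function(protein, width, cls) {
  n <- nchar(protein)
  if (n < width) return(integer(0))
  hit <- strsplit(protein, "", fixed = TRUE)[[1]] %in% cls$members
  cs <- c(0L, cumsum(hit))
  as.integer(cs[(width + 1L):(n + 1L)] - cs[1L:(n - width + 1L)])
}

# data.table schema shared by all window tables
empty_windows <- function() {
  data.table::data.table(
    transcript_id = character(), start_res = integer(), width = integer(),
    n_target = integer(), last_target_res = integer(),
    residue_class = character(), window_class = character())
}

# Last target residue (transcript coords) inside each window; windows with no
# target residue anchor on their own last residue.
last_target_in_window <- function(protein, starts, width, cls) {
  hit <- strsplit(protein, "", fixed = TRUE)[[1]] %in% cls$members
  # running maximum of 1-based target positions up to each residue
  run_last <- cummax(ifelse(hit, seq_along(hit), 0L))
  cand <- run_last[starts + width] - 1L           # 0-based, may precede start
  ifelse(cand >= starts, cand, starts + width - 1L)
}

#' Find tract windows with greedy non-overlap selection
#'
#' Candidate windows are those with at least `min_count` target-class
#' residues. To avoid overlapping windows within `nonoverlap_distance`
#' residues of each other, selection is greedy: repeatedly keep the
#' candidate with the highest count (ties to the smallest start) and discard
#' all candidates whose starts lie within the distance of it.
#'
#' @param protein Amino-acid string.
#' @param params An [analysis_params()].
#' @param cls A [residue_class()].
#' @param min_count Minimum target residues per window; defaults to
#'   `params$tract_min_basic`.
#' @param transcript_id Optional id recorded in the output.
#' @return A `data.table` of windows with columns `transcript_id`,
#'   `start_res`, `width`, `n_target`, `last_target_res`, `residue_class`,
#'   `window_class` (`"tract"`), ordered by `start_res`.
#' @examples
#' p <- paste0(strrep("A", 10), strrep("K", 10), strrep("A", 10))
#' find_tracts(p, analysis_params(), residue_class("basic"), min_count = 8)
#' @export
find_tracts <- function(protein, params = analysis_params(),
                        cls = residue_class("basic"),
                        min_count = params$tract_min_basic,
                        transcript_id = NA_character_) {
  w <- params$window_width
  if (min_count < 1L || min_count > w)
    stop("min_count must lie in [1, window_width]", call. = FALSE)
  counts <- window_counts(protein, w, cls)
  cand <- which(counts >= min_count) - 1L      # 0-based starts
  kept <- integer(0)
  while (length(cand)) {
    cc <- counts[cand + 1L]
    best <- cand[which.max(cc)]                # which.max: first max = smallest start
    kept <- c(kept, best)
    cand <- cand[abs(cand - best) > params$nonoverlap_distance]
  }
  if (!length(kept)) return(empty_windows())
  kept <- sort(kept)
  data.table::data.table(
    transcript_id = transcript_id, start_res = kept, width = w,
    n_target = counts[kept + 1L],
    last_target_res = last_target_in_window(protein, kept, w, cls),
    residue_class = cls$name, window_class = "tract")
}

#' Enumerate control windows
#'
#' Every window position with at most `control_max_basic` target-class
#' residues is a control window; no non-overlap thinning is applied, so
#' overlapping windows all appear.
#'
#' @inheritParams find_tracts
#' @return A `data.table` as in [find_tracts()], `window_class = "control"`.
#' @export
find_control_windows <- function(protein, params = analysis_params(),
                                 cls = residue_class("basic"),
                                 transcript_id = NA_character_) {
  w <- params$window_width
  counts <- window_counts(protein, w, cls)
  keep <- which(counts <= params$control_max_basic) - 1L
  if (!length(keep)) return(empty_windows())
  data.table::data.table(
    transcript_id = transcript_id, start_res = keep, width = w,
    n_target = counts[keep + 1L],
    last_target_res = last_target_in_window(protein, keep, w, cls),
    residue_class = cls$name, window_class = "control")
}

#' Scan a whole transcriptome for tract or control windows
#'
#' @param transcripts A `transcriptome`.
#' @param params An [analysis_params()].
#' @param cls A [residue_class()].
#' @param min_count Tract threshold (ignored for `what = "control"`).
#' @param what `"tract"` or `"control"`.
#' @return A `data.table` of windows over all transcripts.
#' @export
scan_transcriptome <- function(transcripts, params = analysis_params(),
                               cls = residue_class("basic"),
                               min_count = params$tract_min_basic,
                               what = c("tract", "control")) {
  what <- match.arg(what)
  out <- lapply(transcripts, function(tx) {
    if (what == "tract")
      find_tracts(tx$protein, params, cls, min_count, transcript_id = tx$id)
    else
      find_control_windows(tx$protein, params, cls, transcript_id = tx$id)
  })
  data.table::rbindlist(out)
}

#' Dose-response series of occupancy ratios over tract thresholds
#'
#' Reruns tract discovery and the occupancy-ratio analysis at each threshold
#' and reports the mean post/pre ratio, quantifying the effect of increased
#' dosage of encoded residues on ribosome drop-off.
#'
#' @param transcripts A `transcriptome`.
#' @param tracks A `coverage_set` (analysis sample).
#' @param wt_tracks Reference (wild-type) `coverage_set` for the read filter;
#'   defaults to `tracks`.
#' @param params An [analysis_params()].
#' @param cls A [residue_class()].
#' @param thresholds Ascending integer thresholds within
#'   `[1, window_width]`.
#' @param apply_sd_filter Apply the control-distribution outlier filter
#'   (needs control records); disabled by default because the series is
#'   computed per class without a control sample.
#' @return A `data.table` with one row per threshold: `threshold`,
#'   `mean_ratio`, `n_windows`.
#' @export
dose_series <- function(transcripts, tracks, wt_tracks = tracks,
                        params = analysis_params(),
                        cls = residue_class("basic"),
                        thresholds = 6:10,
                        apply_sd_filter = FALSE) {
  if (any(diff(thresholds) <= 0)) stop("thresholds must be ascending",
                                       call. = FALSE)
  if (any(thresholds < 1L | thresholds > params$window_width))
    stop("thresholds must lie in [1, window_width]", call. = FALSE)
  rows <- lapply(thresholds, function(th) {
    wins <- scan_transcriptome(transcripts, params, cls, min_count = th,
                               what = "tract")
    recs <- occupancy_records(wins, transcripts, tracks, params = params)
    recs <- apply_filters(recs, wt_tracks, transcripts, params,
                          control_records = if (apply_sd_filter) recs else NULL)
    inc <- recs[recs$included, ]
    data.table::data.table(threshold = as.integer(th),
                           mean_ratio = if (nrow(inc)) mean(inc$ratio) else NA_real_,
                           n_windows = nrow(inc))
  })
  data.table::rbindlist(rows)
}
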