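#' Analysis parameters for the stalling pipeline
#'
#' Bundles every numeric constant of the occupancy analysis: window geometry,
#' tract thresholds, the non-overlap radius, metaprofile flank, read-count
#' exclusions, region trims, the outlier rule and the footprint/P-site model.
#' All coordinates in the package are 0-based, half-open; codon index `i`
#' covers nucleotides `[3i, 3i + 3)`.
#'
#' @param window_width Tract window width in residues.
#' @param tract_min_basic Minimum number of target-class residues in a window
#'   for it to count as a tract (analyses use 6, 7 or 8).
#' @param control_max_basic Maximum number of target-class residues for a
#'   window to count as a control window.
#' @param nonoverlap_distance Minimum start-to-start distance (residues)
#'   between two kept tract windows; among closer candidates only the
#'   highest-count window is kept.
#' @param flank Metaprofile half-width in nt around the tract center.
#' @param min_window_reads Metaprofile windows with fewer reads are excluded.
#' @param min_transcript_reads_wt Transcripts with fewer footprints in the
#'   wild-type reference sample are excluded from ratio analysis.
#' @param terminal_fraction Tracts overlapping the first or last
#'   `terminal_fraction` of the transcript length are excluded.
#' @param min_codons_to_stop Minimum number of sense codons between the end of
#'   the tract (its last target residue) and the stop codon.
#' @param post_offset Post-tract region starts this many codons past the last
#'   target residue (skips the cycloheximide pile-up zone).
#' @param stop_trim Codons trimmed before the stop codon.
#' @param start_trim Codons trimmed after the start codon.
#' @param outlier_sd Records whose ratio exceeds the control mean by more than
#'   `outlier_sd` control standard deviations are excluded.
#' @param footprint_len Footprint length in nt.
#' @param psite_offset P-site offset in nt from the footprint 5' end. The
#'   source protocol states only the footprint size (a band centered at
#'   28 bp); 15 nt is the standard offset for 28-mers and region-level
#'   densities are insensitive to small changes here.
#'
#' @return An object of class `analysis_params` (a validated list).
#' @examples
#' p <- analysis_params(tract_min_basic = 8)
#' p$post_offset
#' @export
analysis_params <- function(window_width = 10L,
                            tract_min_basic = 6L,
                            control_max_basic = 2L,
                            nonoverlap_distance = 50L,
                            flank = 150L,
                            min_window_reads = 10L,
                            min_transcript_reads_wt = 25L,
                            terminal_fraction = 0.05,
                            min_codons_to_stop = 30L,
                            post_offset = 40L,
                            stop_trim = 20L,
                            start_trim = 20L,
                            outlier_sd = 2,
                            footprint_len = 28L,
                            psite_offset = 15L) {
  p <- list(
    window_width = as.integer(window_width),
    tract_min_basic = as.integer(tract_min_basic),
    control_max_basic = as.integer(control_max_basic),
    nonoverlap_distance = as.integer(nonoverlap_distance),
    flank = as.integer(flank),
    min_window_reads = as.integer(min_window_reads),
    min_transcript_reads_wt = as.integer(min_transcript_reads_wt),
    terminal_fraction = as.numeric(terminal_fraction),
    min_codons_to_stop = as.integer(min_codons_to_stop),
    post_offset = as.integer(post_offset),
    stop_trim = as.integer(stop_trim),
    start_trim = as.integer(start_trim),
    outlier_sd = as.numeric(outlier_sd),
    footprint_len = as.integer(footprint_len),
    psite_offset = as.integer(psite_offset)
  )
  class(p) <- "analysis_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "analysis_params"))
  pos <- c("window_width", "tract_min_basic", "nonoverlap_distance", "flank",
           "min_window_reads", "min_transcript_reads_wt", "min_codons_to_stop",
           "post_offset", "stop_trim", "start_trim", "outlier_sd",
           "footprint_len")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  }
  if (p$control_max_basic < 0)
    stop("control_max_basic must be non-negative", call. = FALSE)
  if (p$terminal_fraction <= 0 || p$terminal_fraction >= 0.5)
    stop("terminal_fraction must lie in (0, 0.5)", call. = FALSE)
  if (p$psite_offset < 0 || p$psite_offset >= p$footprint_len)
    stop("psite_offset must lie in [0, footprint_len)", call. = FALSE)
  invisible(p)
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("analysis_params:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read/write analysis parameters as JSON
#'
#' A JSON config file materializes [analysis_params()]; missing fields take
#' their defaults, unknown fields are an error.
#'
#' @param path JSON file path.
#' @param params For writing, an `analysis_params` object.
#' @return `read_params` returns an `analysis_params`; `write_params`
#'   invisibly returns `path`.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_params))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown parameter(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(analysis_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Residue class specification
#'
#' The tract analyses are residue-class based: basic means lysine or arginine
#' (histidine is deliberately excluded), acidic means aspartate or glutamate.
#'
#' @param name `"basic"` or `"acidic"`, or `"custom"` with explicit `members`.
#' @param members Character vector of one-letter residue codes; required for
#'   `"custom"`, ignored otherwise.
#' @return An object of class `residue_class` with fields `name` and `members`.
#' @examples
#' residue_class("basic")$members
#' @export
residue_class <- function(name = c("basic", "acidic", "custom"),
                          members = NULL) {
  name <- match.arg(name)
  members <- switch(name,
    basic = c("K", "R"),
    acidic = c("D", "E"),
    custom = {
      if (is.null(members) || !length(members))
        stop("custom residue_class needs non-empty 'members'", call. = FALSE)
      unique(toupper(members))
    }
  )
  structure(list(name = name, members = members), class = "residue_class")
}

AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
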