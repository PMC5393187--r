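#' Reporter layout
#'
#' Describes a GFP-(stall)-RFP fusion reporter on one transcript: disjoint,
#' ordered codon intervals (0-based half-open) for the GFP segment, the
#' stall sequence and the RFP segment.
#'
#' @param transcript_id Transcript id of the reporter CDS.
#' @param gfp_region,stall_region,rfp_region Codon intervals `c(start, end)`.
#' @param n_codons Optional total codon count (stop included) for bounds
#'   checking.
#' @return An object of class `reporter_layout`.
#' @export
reporter_layout <- function(transcript_id, gfp_region, stall_region,
                            rfp_region, n_codons = NULL) {
  regs <- list(gfp = as.integer(gfp_region), stall = as.integer(stall_region),
               rfp = as.integer(rfp_region))
  for (nm in names(regs)) {
    r <- regs[[nm]]
    if (length(r) != 2L || r[1] < 0L || r[2] <= r[1])
      stop("invalid ", nm, " region", call. = FALSE)
  }
  if (!(regs$gfp[2] <= regs$stall[1] && regs$stall[2] <= regs$rfp[1]))
    stop("regions must be disjoint and ordered gfp < stall < rfp",
         call. = FALSE)
  if (!is.null(n_codons) && regs$rfp[2] > n_codons)
    stop("rfp region extends past the transcript", call. = FALSE)
  structure(list(transcript_id = transcript_id, gfp_region = regs$gfp,
                 stall_region = regs$stall, rfp_region = regs$rfp),
            class = "reporter_layout")
}

#' Read/write a reporter layout as JSON
#' @param path JSON path.
#' @param layout A `reporter_layout` (for writing).
#' @return `read_reporter_layout` returns a `reporter_layout`.
#' @export
read_reporter_layout <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reporter_layout(x$transcript_id, x$gfp_region, x$stall_region, x$rfp_region)
}

#' @rdname read_reporter_layout
#' @export
write_reporter_layout <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Relative post-stall occupancy of a reporter
#'
#' Footprint density (reads per base) over the actively-translated part of
#' the RFP region divided by density over the whole ORF, both with the first
#' and last `stop_trim`/`start_trim` codons excluded. The `post_offset`
#' (default 40) codons past the stall are excluded from the RFP numerator:
#' density there reflects ribosomes queued by cycloheximide, not
#' read-through.
#'
#' @param track `coverage_track` of the reporter transcript.
#' @param layout A [reporter_layout()].
#' @param params An [analysis_params()].
#' @return A single number; 1 for uniform coverage.
#' @export
relative_post_stall_occupancy <- function(track, layout,
                                          params = analysis_params()) {
  L <- length(track$counts) %/% 3L - 1L        # sense codons
  num_start <- max(layout$rfp_region[1], layout$stall_region[2] +
                     params$post_offset)
  num_end <- min(layout$rfp_region[2], L - params$stop_trim)
  den_start <- params$start_trim
  den_end <- L - params$stop_trim
  if (num_start >= num_end)
    stop("empty post-stall RFP region for this layout", call. = FALSE)
  if (den_start >= den_end)
    stop("empty denominator region", call. = FALSE)
  den <- region_density(track$counts, codon_to_nt(c(den_start, den_end)))
  if (den == 0)
    stop("no reads in the reporter ORF (empty track)", call. = FALSE)
  num <- region_density(track$counts, codon_to_nt(c(num_start, num_end)))
  num / den
}

#' Percent drop in post-stall density between two reporters
#'
#' @param stall_value,nonstall_value Relative post-stall occupancy of the
#'   stalling and matched nonstalling reporters.
#' @return `100 * (1 - stall_value / nonstall_value)`.
#' @export
post_stall_drop <- function(stall_value, nonstall_value) {
  if (nonstall_value <= 0)
    stop("nonstall_value must be > 0", call. = FALSE)
  100 * (1 - stall_value / nonstall_value)
}

#' Reporter mRNA abundance relative to the transcriptome median
#'
#' Length-normalized RNA-seq reads over the reporter CDS divided by the
#' median length-normalized reads across all coding sequences.
#'
#' @param reporter_track RNA-seq `coverage_track` of the reporter.
#' @param transcriptome_tracks `coverage_set` over the transcriptome.
#' @param min_expressed Minimum number of CDS with nonzero reads required
#'   for a stable median.
#' @return A single number (1 when the reporter sits at the median).
#' @export
reporter_mrna_abundance <- function(reporter_track, transcriptome_tracks,
                                    min_expressed = 100L) {
  dens <- vapply(transcriptome_tracks,
                 function(tr) tr$total_reads / length(tr$counts), 0)
  if (sum(dens > 0) < min_expressed)
    stop("fewer than ", min_expressed,
         " transcripts with nonzero reads", call. = FALSE)
  med <- stats::median(dens)
  if (med == 0) stop("median transcript density is zero", call. = FALSE)
  (reporter_track$total_reads / length(reporter_track$counts)) / med
}
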