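#' Coverage track constructor
#'
#' A coverage track holds per-nucleotide footprint counts for one transcript,
#' its read total and the library total (all retained footprints in the
#' sample, used for RPKM scaling).
#'
#' @param transcript_id Transcript id.
#' @param counts Non-negative integer vector, one entry per nucleotide.
#' @param library_total All mapped/retained footprints in the sample.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(transcript_id, counts, library_total = sum(counts)) {
  counts <- as.integer(counts)
  if (any(counts < 0L)) stop("negative counts", call. = FALSE)
  structure(list(transcript_id = transcript_id, counts = counts,
                 total_reads = sum(counts),
                 library_total = as.numeric(library_total)),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track '", x$transcript_id, "': ", length(x$counts),
      " nt, ", x$total_reads, " reads (library ", x$library_total, ")\n",
      sep = "")
  invisible(x)
}

#' Load ribosome footprints from BED into coverage tracks
#'
#' BED intervals are on transcript coordinates (0-based, half-open) with the
#' chrom field equal to the transcript id. Each footprint contributes one
#' count at its P-site position, `start + psite_offset`. Footprints on
#' unknown transcripts, or whose assigned position falls outside the CDS,
#' are dropped and tallied.
#'
#' @param bed_path Path to a BED file.
#' @param transcripts A `transcriptome` from [load_transcriptome()].
#' @param params An [analysis_params()] (supplies `psite_offset`).
#' @return A named list of `coverage_track` (class `coverage_set`), one per
#'   transcript (all-zero tracks for transcripts without footprints), with a
#'   `dropped` attribute tallying `unknown_transcript` and `outside_cds`.
#'   Every track's `library_total` equals the number of retained footprints.
#' @export
load_footprints <- function(bed_path, transcripts, params = analysis_params()) {
  if (!file.exists(bed_path))
    stop("BED file not found: ", bed_path, call. = FALSE)
  gr <- rtracklayer::import(bed_path, format = "BED")
  start0 <- GenomicRanges::start(gr) - 1L  # GRanges is 1-based
  if (length(start0) && min(start0) < 0L)
    stop("negative BED coordinates", call. = FALSE)
  ids <- as.character(GenomicRanges::seqnames(gr))
  known <- ids %in% names(transcripts)
  n_unknown <- sum(!known)
  if (n_unknown)
    warning(n_unknown, " footprint(s) on unknown transcripts dropped")
  ids <- ids[known]
  pos <- start0[known] + params$psite_offset
  n_nt <- vapply(transcripts, `[[`, 0L, "n_nt")
  inside <- pos >= 0L & pos < n_nt[ids]
  n_outside <- sum(!inside)
  ids <- ids[inside]
  pos <- pos[inside]
  lib_total <- length(pos)
  by_tx <- split(pos, factor(ids, levels = names(transcripts)))
  tracks <- lapply(names(transcripts), function(id) {
    counts <- tabulate(by_tx[[id]] + 1L, nbins = n_nt[[id]])
    coverage_track(id, counts, library_total = lib_total)
  })
  names(tracks) <- names(transcripts)
  structure(tracks, class = "coverage_set",
            dropped = c(unknown_transcript = n_unknown,
                        outside_cds = n_outside))
}

#' Pool coverage tracks from replicate samples
#'
#' Position-wise sum of counts over samples; library totals add. Used to pool
#' the two profiling replicates per genotype.
#'
#' @param ... Two or more `coverage_track`s on the same transcript, or
#'   `coverage_set`s over the same transcriptome.
#' @return A pooled `coverage_track` (or `coverage_set`).
#' @export
pool_tracks <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) &&
      !inherits(xs[[1]], c("coverage_track", "coverage_set")))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L)
  if (inherits(xs[[1]], "coverage_set")) {
    ids <- names(xs[[1]])
    for (x in xs) stopifnot(identical(names(x), ids))
    out <- lapply(ids, function(id)
      do.call(pool_tracks, lapply(xs, `[[`, id)))
    names(out) <- ids
    return(structure(out, class = "coverage_set"))
  }
  t1 <- xs[[1]]
  for (x in xs[-1]) {
    if (!identical(x$transcript_id, t1$transcript_id))
      stop("cannot pool tracks from different transcripts", call. = FALSE)
    if (length(x$counts) != length(t1$counts))
      stop("cannot pool tracks of different lengths", call. = FALSE)
  }
  coverage_track(
    t1$transcript_id,
    Reduce(`+`, lapply(xs, `[[`, "counts")),
    library_total = sum(vapply(xs, `[[`, 0, "library_total"))
  )
}

#' Per-nucleotide RPKM values
#'
#' Reads per kilobase per million mapped reads, at single-nucleotide
#' resolution: each position's count is divided by (1 nt in kb) x (library
#' total in millions), so the mean over any region equals that region's
#' RPKM and the mean over the whole transcript equals the transcript RPKM.
#'
#' @param track A `coverage_track` with `library_total > 0`.
#' @return Numeric vector of per-position RPKM values.
#' @examples
#' tr <- coverage_track("t", rep(1L, 1000), library_total = 1e6)
#' mean(rpkm_track(tr))  # 1000
#' @export
rpkm_track <- function(track) {
  if (track$library_total <= 0)
    stop("empty library: library_total must be > 0", call. = FALSE)
  track$counts / ((1 / 1000) * (track$library_total / 1e6))
}

#' Read/write per-nucleotide coverage as TSV
#'
#' Columns `transcript_id`, `pos` (0-based nt) and `count`; zero positions
#' are omitted on write and implied on read.
#'
#' @param tracks A `coverage_set`.
#' @param path TSV path.
#' @param transcripts A `transcriptome` (supplies lengths on read).
#' @param library_total Optional library total on read; defaults to the sum
#'   of counts in the file.
#' @return `write_coverage_tsv` invisibly returns `path`;
#'   `read_coverage_tsv` returns a `coverage_set`.
#' @export
write_coverage_tsv <- function(tracks, path) {
  dt <- data.table::rbindlist(lapply(tracks, function(tr) {
    nz <- which(tr$counts > 0L)
    data.table::data.table(transcript_id = tr$transcript_id, pos = nz - 1L,
                           count = tr$counts[nz])
  }))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(path, transcripts, library_total = NULL) {
  dt <- data.table::fread(path, sep = "\t",
                          colClasses = list(character = "transcript_id"))
  stopifnot(all(c("transcript_id", "pos", "count") %in% names(dt)))
  unknown <- setdiff(unique(dt$transcript_id), names(transcripts))
  if (length(unknown))
    stop("coverage for unknown transcript(s): ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  if (is.null(library_total)) library_total <- sum(dt$count)
  tracks <- lapply(names(transcripts), function(id) {
    n <- transcripts[[id]]$n_nt
    counts <- integer(n)
    sub <- dt[dt$transcript_id == id, ]
    if (nrow(sub)) {
      if (any(sub$pos < 0L | sub$pos >= n))
        stop("coverage position outside CDS for ", id, call. = FALSE)
      counts[sub$pos + 1L] <- sub$count
    }
    coverage_track(id, counts, library_total = library_total)
  })
  names(tracks) <- names(transcripts)
  structure(tracks, class = "coverage_set")
}
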