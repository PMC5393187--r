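#' Spectral-count table for IP-MS enrichment
#'
#' Protein-by-sample peptide spectral counts with per-sample totals. Roles
#' are two bait replicates and one untagged-control IP. Totals supplied by
#' the caller are validated against column sums; on disagreement the column
#' sums win with a warning (totals are then no longer independent of the
#' table, so supply them only when they really are the run totals).
#'
#' @param counts Integer matrix, rownames = protein ids, columns
#'   `bait_rep1`, `bait_rep2`, `control`.
#' @param sample_totals Optional named totals per column.
#' @return An object of class `spectral_counts`.
#' @export
spectral_counts <- function(counts, sample_totals = NULL) {
  counts <- as.matrix(counts)
  need <- c("bait_rep1", "bait_rep2", "control")
  if (!all(need %in% colnames(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  counts <- counts[, need, drop = FALSE]
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  csums <- colSums(counts)
  if (is.null(sample_totals)) {
    sample_totals <- csums
  } else {
    sample_totals <- sample_totals[need]
    bad <- which(sample_totals != csums)
    if (length(bad)) {
      warning("sample_totals disagree with column sums for: ",
              paste(need[bad], collapse = ", "), "; using column sums")
      sample_totals[bad] <- csums[bad]
    }
  }
  if (any(sample_totals <= 0))
    stop("every sample must have a positive total", call. = FALSE)
  structure(list(counts = counts, sample_totals = sample_totals),
            class = "spectral_counts")
}

#' Read a spectral-count TSV
#'
#' Columns `protein`, `bait_rep1`, `bait_rep2`, `control`.
#'
#' @param path TSV path.
#' @param sample_totals Optional named totals (see [spectral_counts()]).
#' @return A `spectral_counts` object.
#' @export
read_spectral_counts <- function(path, sample_totals = NULL) {
  dt <- data.table::fread(path, sep = "\t")
  need <- c("protein", "bait_rep1", "bait_rep2", "control")
  if (!all(need %in% names(dt)))
    stop("spectral-count table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  m <- as.matrix(dt[, c("bait_rep1", "bait_rep2", "control")])
  rownames(m) <- dt$protein
  spectral_counts(m, sample_totals)
}

#' IP-MS enrichment score for one protein
#'
#' The protein's spectral counts (+1 pseudocount, making log-scale data
#' rational) are normalized by the per-sample total spectral counts,
#' averaged over the two bait replicates, and divided by the same
#' pseudocounted, total-normalized value in the untagged-control IP:
#' `mean((c1+1)/T1, (c2+1)/T2) / ((c0+1)/T0)`.
#'
#' @param table A `spectral_counts`.
#' @param protein Protein id; a protein absent from the table has zero
#'   counts everywhere.
#' @return A single positive number; 1 means no enrichment over control.
#' @examples
#' m <- matrix(c(4, 6, 1), 1, dimnames = list("p",
#'   c("bait_rep1", "bait_rep2", "control")))
#' tab <- spectral_counts(m, c(bait_rep1 = 100, bait_rep2 = 200, control = 100))
#' enrichment(tab, "p")  # 2.125
#' @export
enrichment <- function(table, protein) {
  stopifnot(inherits(table, "spectral_counts"))
  tt <- table$sample_totals
  cc <- if (protein %in% rownames(table$counts))
    table$counts[protein, ] else c(bait_rep1 = 0, bait_rep2 = 0, control = 0)
  bait <- mean(c((cc[["bait_rep1"]] + 1) / tt[["bait_rep1"]],
                 (cc[["bait_rep2"]] + 1) / tt[["bait_rep2"]]))
  ctrl <- (cc[["control"]] + 1) / tt[["control"]]
  bait / ctrl
}

#' Rank all detected proteins by IP-MS enrichment
#'
#' @param table A `spectral_counts`.
#' @return A `data.table` of `(protein, enrichment)` sorted by decreasing
#'   enrichment, ties broken by protein id.
#' @export
rank_interactors <- function(table) {
  stopifnot(inherits(table, "spectral_counts"))
  prot <- rownames(table$counts)
  e <- vapply(prot, function(p) enrichment(table, p), 0)
  out <- data.table::data.table(protein = prot, enrichment = unname(e))
  data.table::setorderv(out, c("enrichment", "protein"), order = c(-1L, 1L))
  out[]
}
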