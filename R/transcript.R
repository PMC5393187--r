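#' Load a transcriptome of coding sequences from FASTA
#'
#' Each FASTA record is one CDS on transcript coordinates, stop codon
#' included. Records are validated and invalid ones skipped with a logged
#' reason: length not a multiple of 3, shorter than two codons, non-ACGT
#' characters, missing terminal stop, internal stop, or a derived protein
#' containing non-canonical residues.
#'
#' @param fasta_path Path to a (possibly multi-record) nucleotide FASTA.
#' @param quiet Suppress the per-record skip messages.
#' @return A `transcriptome`: a named list of `transcript` objects in record
#'   order, each with fields `id`, `cds_nt`, `protein`, `n_codons`
#'   (`n_nt / 3`, stop codon included) and `n_nt`. Skip tallies are attached
#'   as attribute `skipped` (a data.frame of id and reason).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1", "ATGAAAAAGCGTAGACGCAAAAAGAGATAA"), fa)
#' tx <- load_transcriptome(fa)
#' tx$t1$protein
#' @export
load_transcriptome <- function(fasta_path, quiet = FALSE) {
  if (!file.exists(fasta_path))
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- vector("list", length(seqs))
  skipped <- list()
  kept <- 0L
  for (i in seq_along(seqs)) {
    nt <- as.character(seqs[[i]])
    rec <- make_transcript(ids[i], nt)
    if (is.character(rec)) {
      skipped[[length(skipped) + 1L]] <- data.frame(id = ids[i], reason = rec)
      if (!quiet) message("skipping '", ids[i], "': ", rec)
    } else {
      kept <- kept + 1L
      out[[kept]] <- rec
    }
  }
  out <- out[seq_len(kept)]
  names(out) <- vapply(out, `[[`, "", "id")
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(id = character(), reason = character())
  structure(out, class = "transcriptome", skipped = skipped)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Returns a transcript object, or a character scalar naming the skip reason.
make_transcript <- function(id, cds_nt) {
  cds_nt <- toupper(cds_nt)
  n_nt <- nchar(cds_nt)
  if (n_nt %% 3L != 0L) return("length not a multiple of 3")
  if (n_nt < 6L) return("shorter than two codons")
  if (grepl("[^ACGT]", cds_nt)) return("non-ACGT characters")
  last_codon <- substr(cds_nt, n_nt - 2L, n_nt)
  if (!last_codon %in% STOP_CODONS) return("no terminal stop codon")
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds_nt, 1L, n_nt - 3L)),
    no.init.codon = TRUE))
  if (grepl("\\*", prot)) return("internal stop codon")
  if (!all(strsplit(prot, "")[[1]] %in% AA_CANONICAL))
    return("non-canonical residues in protein")
  structure(list(id = id, cds_nt = cds_nt, protein = prot,
                 n_codons = n_nt %/% 3L, n_nt = n_nt),
            class = "transcript")
}

#' @export
print.transcriptome <- function(x, ...) {
  sk <- attr(x, "skipped")
  cat("transcriptome:", length(x), "transcripts",
      if (nrow(sk)) paste0("(", nrow(sk), " records skipped)") else "", "\n")
  invisible(x)
}

#' Write a transcriptome back to FASTA
#'
#' Round-trips losslessly with [load_transcriptome()] for valid records.
#'
#' @param transcripts A `transcriptome`.
#' @param fasta_path Output path.
#' @return Invisibly, `fasta_path`.
#' @export
write_transcriptome <- function(transcripts, fasta_path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "cds_nt"))
  names(seqs) <- vapply(transcripts, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta_path, width = 60L)
  invisible(fasta_path)
}

#' Codon/nucleotide coordinate conversion
#'
#' All coordinates are 0-based; codon `i` covers nucleotides `[3i, 3i + 3)`.
#'
#' @param codon,nt 0-based codon or nucleotide indices.
#' @return `codon_to_nt` gives the first nt of each codon; `nt_to_codon` the
#'   codon containing each nt.
#' @export
codon_to_nt <- function(codon) 3L * as.integer(codon)

#' @rdname codon_to_nt
#' @export
nt_to_codon <- function(nt) as.integer(nt) %/% 3L
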