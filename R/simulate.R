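#' Stall model for the footprint simulator
#'
#' Parameterizes the per-nucleotide footprint rate profile around a planted
#' stalling tract: a uniform upstream rate, a dip over the tract window
#' itself, a boxcar pile-up over the `pileup_len` codons downstream of the
#' last target residue (emulating ribosomes queued by cycloheximide), and a
#' reduced rate thereafter set by the fraction of ribosomes reading through
#' the stall (`post rate = readthrough * lambda_pre`; percent drop =
#' `100 * (1 - readthrough)`).
#'
#' @param lambda_pre Expected footprints per nt upstream of the tract.
#' @param dip_factor Rate multiplier over the tract window (<= 1).
#' @param pileup_amplitude Rate multiplier over the pile-up zone (>= 1).
#' @param pileup_len Pile-up zone length in codons.
#' @param readthrough Fraction of ribosomes continuing past the stall,
#'   in [0, 1].
#' @return An object of class `stall_model`.
#' @export
stall_model <- function(lambda_pre = 0.5, dip_factor = 0.5,
                        pileup_amplitude = 2, pileup_len = 40L,
                        readthrough = 0.1) {
  stopifnot(lambda_pre >= 0, dip_factor >= 0, pileup_amplitude >= 0,
            pileup_len >= 0, readthrough >= 0, readthrough <= 1)
  structure(list(lambda_pre = lambda_pre, dip_factor = dip_factor,
                 pileup_amplitude = pileup_amplitude,
                 pileup_len = as.integer(pileup_len),
                 readthrough = readthrough),
            class = "stall_model")
}

# inverted genetic code, stops removed
codon_choices <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA_CANONICAL]
}

# Background residues exclude basic (K/R) and acidic (D/E) residues so no
# accidental tract or non-zero control count can arise outside planted runs.
BACKGROUND_AA <- setdiff(AA_CANONICAL, c("K", "R", "D", "E"))

# codon lookup matrix: one row per residue, synonymous codons recycled
# across columns so a uniform column draw is a (near-)uniform codon draw
codon_matrix <- function(codons) {
  k <- max(lengths(codons))
  t(vapply(codons, function(ch) rep_len(ch, k), character(k)))
}

random_cds <- function(protein, codons, cmat = codon_matrix(codons)) {
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  col <- sample.int(ncol(cmat), length(aas), replace = TRUE)
  picked <- cmat[cbind(match(aas, rownames(cmat)), col)]
  paste0(paste(picked, collapse = ""), "TAA")
}

#' Generate a synthetic transcriptome with planted tracts
#'
#' Random coding sequences whose background residue usage contains no basic
#' or acidic residues, with an optional planted run of target-class residues
#' inside a 10-residue window per transcript. The ground truth (planted
#' window coordinates and residue counts) is returned alongside, so every
#' downstream estimand can be computed exactly.
#'
#' @param n_transcripts Number of CDS.
#' @param len_range Range of protein lengths (sense codons), sampled
#'   uniformly; must be >= 100.
#' @param tract_class `"basic"`, `"acidic"` or `"none"`.
#' @param tract_count Target residues planted per window (recycled across
#'   transcripts; 0 plants nothing in that transcript). Planted as a
#'   contiguous run at the window start.
#' @param tract_position Relative-position range (of protein length) in
#'   which the planted window start is drawn uniformly.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param id_prefix Transcript id prefix (ids are `<prefix>0001` ...); set
#'   distinct prefixes when merging several generated transcriptomes.
#' @param fasta_path,truth_path Optional output files (FASTA / TSV).
#' @return A list: `transcripts` (a `transcriptome`), `truth` (a
#'   `data.table` with `transcript_id`, `class`, `window_start`, `n_target`,
#'   `last_target_res`, `protein_len`).
#' @export
make_transcriptome <- function(n_transcripts, len_range = c(300L, 800L),
                               tract_class = "basic", tract_count = 8L,
                               tract_position = c(0.2, 0.7), seed = 1L,
                               id_prefix = "synthetic_tx",
                               fasta_path = NULL, truth_path = NULL) {
  if (min(len_range) < 100L)
    stop("protein lengths must be >= 100 codons", call. = FALSE)
  width <- 10L
  tract_count <- rep_len(as.integer(tract_count), n_transcripts)
  if (any(tract_count > width))
    stop("tract_count cannot exceed the window width (", width, ")",
         call. = FALSE)
  plant <- tract_class != "none" & tract_count > 0L
  target <- switch(tract_class, basic = c("K", "R"), acidic = c("D", "E"),
                   none = character(0))
  codons <- codon_choices()
  res <- with_seed(seed, {
    len_vals <- seq.int(len_range[1], len_range[2])
    lens <- len_vals[sample.int(length(len_vals), n_transcripts,
                                replace = TRUE)]
    txs <- vector("list", n_transcripts)
    truth <- vector("list", n_transcripts)
    for (i in seq_len(n_transcripts)) {
      id <- sprintf("%s%04d", id_prefix, i)
      L <- lens[i]
      prot <- sample(BACKGROUND_AA, L, replace = TRUE)
      if (plant[i]) {
        k <- tract_count[i]
        lo <- max(0L, floor(tract_position[1] * L))
        hi <- min(L - width, floor(tract_position[2] * L))
        if (hi < lo) stop("infeasible tract position range for length ", L,
                          call. = FALSE)
        ws <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        prot[(ws + 1L):(ws + k)] <- sample(target, k, replace = TRUE)
        truth[[i]] <- data.table::data.table(
          transcript_id = id, class = tract_class, window_start = ws,
          n_target = k, last_target_res = ws + k - 1L, protein_len = L)
      }
      # the protein is known by construction; build the record directly
      # rather than re-translating (validated by loader round-trip tests)
      cds <- random_cds(paste(prot, collapse = ""), codons)
      txs[[i]] <- structure(
        list(id = id, cds_nt = cds, protein = paste(prot, collapse = ""),
             n_codons = L + 1L, n_nt = 3L * (L + 1L)),
        class = "transcript")
    }
    list(txs = txs, truth = data.table::rbindlist(truth))
  })
  transcripts <- res$txs
  names(transcripts) <- vapply(transcripts, `[[`, "", "id")
  transcripts <- structure(transcripts, class = "transcriptome",
                           skipped = data.frame(id = character(),
                                                reason = character()))
  if (!is.null(fasta_path)) write_transcriptome(transcripts, fasta_path)
  if (!is.null(truth_path)) data.table::fwrite(res$truth, truth_path,
                                               sep = "\t")
  list(transcripts = transcripts, truth = res$truth)
}

# Per-nt Poisson rate vector for one transcript under a stall model.
# Footprints must fit inside the transcript, so rates are zeroed where the
# P-site position cannot be produced by a fully contained 28-mer.
rate_vector <- function(n_nt, truth_row, model, depth, params) {
  lam <- rep(model$lambda_pre * depth, n_nt)
  if (!is.null(truth_row)) {
    win_nt <- codon_to_nt(c(truth_row$window_start,
                            truth_row$window_start + 10L))
    lam[(win_nt[1] + 1L):win_nt[2]] <- lam[(win_nt[1] + 1L):win_nt[2]] *
      model$dip_factor
    pile_start <- truth_row$last_target_res + 1L
    pile_end <- min(pile_start + model$pileup_len, n_nt %/% 3L)
    if (pile_end > pile_start) {
      iv <- codon_to_nt(c(pile_start, pile_end))
      lam[(iv[1] + 1L):iv[2]] <- model$lambda_pre * depth *
        model$pileup_amplitude
    }
    if (pile_end < n_nt %/% 3L) {
      iv <- codon_to_nt(c(pile_end, n_nt %/% 3L))
      lam[(iv[1] + 1L):iv[2]] <- model$lambda_pre * depth * model$readthrough
    }
  }
  lo <- params$psite_offset                     # first feasible P-site (0-based)
  hi <- n_nt - (params$footprint_len - params$psite_offset)  # one past last
  if (lo > 0L) lam[seq_len(lo)] <- 0
  if (hi < n_nt) lam[(hi + 1L):n_nt] <- 0
  lam
}

#' Simulate ribosome footprints as a BED file
#'
#' Per-nucleotide Poisson counts under the [stall_model()] rate profile
#' (uniform upstream, dip over the tract, pile-up downstream of the last
#' target residue, reduced read-through rate thereafter), expanded to 28-nt
#' footprint intervals positioned so that P-site assignment by
#' [load_footprints()] recovers the sampled nucleotide exactly.
#'
#' @param transcripts A `transcriptome`.
#' @param truth Truth table from [make_transcriptome()] (may be empty).
#' @param model A `stall_model`, or a function of one truth row returning
#'   one (to vary, e.g., read-through with planted residue count).
#' @param depth Depth multiplier applied to all rates.
#' @param params An [analysis_params()] (footprint length, P-site offset).
#' @param seed Integer seed.
#' @param bed_path Optional BED output path.
#' @return A `GRanges` of footprints (exported to `bed_path` if given).
#' @export
simulate_footprints <- function(transcripts, truth = NULL,
                                model = stall_model(), depth = 1,
                                params = analysis_params(), seed = 1L,
                                bed_path = NULL) {
  truth_by_id <- if (!is.null(truth) && nrow(truth))
    split(truth, truth$transcript_id) else list()
  res <- with_seed(seed, {
    ids_l <- vector("list", length(transcripts))
    pos_l <- vector("list", length(transcripts))
    for (k in seq_along(transcripts)) {
      tx <- transcripts[[k]]
      tr <- truth_by_id[[tx$id]]
      tr <- if (is.null(tr)) NULL else tr[1L, ]
      m <- if (is.function(model)) model(tr) else model
      lam <- rate_vector(tx$n_nt, tr, m, depth, params)
      counts <- stats::rpois(tx$n_nt, lam)
      nz <- which(counts > 0L)
      if (length(nz)) {
        p <- rep.int(nz - 1L, counts[nz])
        ids_l[[k]] <- rep.int(tx$id, length(p))
        pos_l[[k]] <- p
      }
    }
    list(ids = unlist(ids_l, use.names = FALSE),
         pos = as.integer(unlist(pos_l, use.names = FALSE)))
  })
  gr <- GenomicRanges::GRanges(
    seqnames = if (length(res$ids)) res$ids else character(0),
    ranges = IRanges::IRanges(start = res$pos - params$psite_offset + 1L,
                              width = params$footprint_len),
    strand = "+")
  S4Vectors::mcols(gr)$name <- if (length(gr))
    sprintf("fp%07d", seq_along(gr)) else character(0)
  S4Vectors::mcols(gr)$score <- rep(0L, length(gr))
  if (!is.null(bed_path)) rtracklayer::export(gr, bed_path, format = "BED")
  gr
}

#' Simulate a GFP-(stall)-RFP reporter
#'
#' Builds a single reporter transcript matching a [reporter_layout()] (the
#' stall region is planted as polyarginine) and simulates footprints with
#' the upstream rate over GFP, a pile-up for `pileup_len` codons past the
#' stall, and the read-through rate over the remaining RFP region.
#'
#' @param layout A [reporter_layout()].
#' @param model A `stall_model` (`readthrough = 1` gives a nonstalling
#'   reporter).
#' @param n_codons Protein length (sense codons); defaults to 20 codons past
#'   the RFP region end.
#' @param depth,params,seed As in [simulate_footprints()].
#' @param bed_path,layout_path Optional output files (BED / JSON).
#' @return A list: `transcripts` (a one-record `transcriptome`),
#'   `footprints` (`GRanges`), `layout`.
#' @export
simulate_reporter <- function(layout, model = stall_model(),
                              n_codons = layout$rfp_region[2] + 20L,
                              depth = 1, params = analysis_params(),
                              seed = 1L, bed_path = NULL,
                              layout_path = NULL) {
  stopifnot(inherits(layout, "reporter_layout"))
  if (layout$rfp_region[2] > n_codons)
    stop("layout does not fit in n_codons", call. = FALSE)
  codons <- codon_choices()
  tx <- with_seed(seed + 1L, {
    prot <- sample(BACKGROUND_AA, n_codons, replace = TRUE)
    prot[(layout$stall_region[1] + 1L):layout$stall_region[2]] <- "R"
    make_transcript(layout$transcript_id,
                    random_cds(paste(prot, collapse = ""), codons))
  })
  transcripts <- structure(stats::setNames(list(tx), tx$id),
                           class = "transcriptome",
                           skipped = data.frame(id = character(),
                                                reason = character()))
  truth <- data.table::data.table(
    transcript_id = tx$id, class = "basic",
    window_start = layout$stall_region[2] - 10L,
    n_target = min(10L, layout$stall_region[2] - layout$stall_region[1]),
    last_target_res = layout$stall_region[2] - 1L,
    protein_len = n_codons)
  gr <- simulate_footprints(transcripts, truth, model, depth, params, seed,
                            bed_path)
  if (!is.null(layout_path)) write_reporter_layout(layout, layout_path)
  list(transcripts = transcripts, footprints = gr, layout = layout,
       truth = truth)
}

#' Simulate RNA-seq coverage
#'
#' Uniform per-nucleotide Poisson coverage per transcript, rate proportional
#' to an abundance multiplier (so reads scale with abundance x length).
#'
#' @param transcripts A `transcriptome`.
#' @param multipliers Named abundance multipliers (default 1 for all);
#'   e.g. set the reporter to 5 for a fivefold-over-median reporter.
#' @param depth Mean reads per nt at multiplier 1.
#' @param seed Integer seed.
#' @param tsv_path Optional coverage-TSV output (see
#'   [write_coverage_tsv()]).
#' @return A `coverage_set`.
#' @export
simulate_rnaseq <- function(transcripts, multipliers = NULL, depth = 0.5,
                            seed = 1L, tsv_path = NULL) {
  mult <- stats::setNames(rep(1, length(transcripts)), names(transcripts))
  if (!is.null(multipliers)) mult[names(multipliers)] <- multipliers
  tracks <- with_seed(seed, {
    lapply(names(transcripts), function(id) {
      n <- transcripts[[id]]$n_nt
      coverage_track(id, stats::rpois(n, depth * mult[[id]]))
    })
  })
  names(tracks) <- names(transcripts)
  lib <- sum(vapply(tracks, `[[`, 0, "total_reads"))
  for (id in names(tracks)) tracks[[id]]$library_total <- lib
  tracks <- structure(tracks, class = "coverage_set")
  if (!is.null(tsv_path)) write_coverage_tsv(tracks, tsv_path)
  tracks
}

#' Simulate flow-cytometry event tables
#'
#' Log-normal GFP/RFP/SSC channels per strain with the requested means
#' (channel CV sets the log-normal shape), biological replicates, and an
#' optional blank strain carrying no reporter.
#'
#' @param strain_specs `data.frame` with columns `strain`, `gfp`, `rfp`,
#'   `ssc` (channel means in arbitrary units).
#' @param n_events Events per (strain, replicate).
#' @param replicates Biological replicates per strain.
#' @param cv Coefficient of variation of each channel.
#' @param seed Integer seed.
#' @param tsv_path Optional TSV output.
#' @return A `data.table` of events: `sample`, `replicate`, `gfp`, `rfp`,
#'   `ssc`.
#' @export
simulate_flow <- function(strain_specs, n_events = 5000L, replicates = 3L,
                          cv = 0.25, seed = 1L, tsv_path = NULL) {
  specs <- as.data.frame(strain_specs)
  stopifnot(all(c("strain", "gfp", "rfp", "ssc") %in% names(specs)))
  sdlog <- sqrt(log(1 + cv^2))
  draw <- function(mu, n) stats::rlnorm(n, log(mu) - sdlog^2 / 2, sdlog)
  out <- with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(specs))) for (r in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        sample = specs$strain[i], replicate = r,
        gfp = draw(specs$gfp[i], n_events),
        rfp = draw(specs$rfp[i], n_events),
        ssc = draw(specs$ssc[i], n_events))
    }
    data.table::rbindlist(rows)
  })
  if (!is.null(tsv_path)) data.table::fwrite(out, tsv_path, sep = "\t")
  out
}

#' Simulate an IP-MS spectral-count table
#'
#' Multinomial spectral counts per sample: control probabilities come from
#' baseline weights, bait probabilities from baseline weights tilted by the
#' true enrichment vector.
#'
#' @param proteins Protein ids.
#' @param true_enrichment Positive tilt per protein (1 = unenriched).
#' @param totals Named totals `bait_rep1`, `bait_rep2`, `control`.
#' @param baseline Baseline weights per protein (default uniform).
#' @param seed Integer seed.
#' @param tsv_path Optional TSV output.
#' @return A `spectral_counts` object.
#' @export
simulate_ipms <- function(proteins, true_enrichment = 1,
                          totals = c(bait_rep1 = 3000L, bait_rep2 = 3000L,
                                     control = 3000L),
                          baseline = NULL, seed = 1L, tsv_path = NULL) {
  k <- length(proteins)
  tilt <- rep_len(true_enrichment, k)
  if (is.null(baseline)) baseline <- rep(1, k)
  stopifnot(all(tilt > 0), all(baseline > 0))
  p_ctrl <- baseline / sum(baseline)
  p_bait <- baseline * tilt / sum(baseline * tilt)
  m <- with_seed(seed, cbind(
    bait_rep1 = as.integer(stats::rmultinom(1, totals[["bait_rep1"]], p_bait)),
    bait_rep2 = as.integer(stats::rmultinom(1, totals[["bait_rep2"]], p_bait)),
    control = as.integer(stats::rmultinom(1, totals[["control"]], p_ctrl))))
  rownames(m) <- proteins
  tab <- spectral_counts(m)
  if (!is.null(tsv_path)) {
    dt <- data.table::data.table(protein = proteins)
    for (cn in colnames(m)) dt[[cn]] <- m[, cn]
    data.table::fwrite(dt, tsv_path, sep = "\t")
  }
  tab
}
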