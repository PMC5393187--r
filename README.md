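# stallscan

Quantifying translation arrest at polybasic-encoding tracts from ribosome
profiling data.

## What this package is for

Runs of lysine/arginine codons stall the elongating ribosome. In ribosome
profiling (ribo-seq) this produces a recognizable density signature on a
transcript: altered footprint density at the tract, an artifactual pile-up
over the ~40 codons downstream (ribosomes queued by cycloheximide added
before lysis), and reduced density further downstream reflecting the
fraction of ribosomes that read through the stall. `stallscan` is for
researchers who want to quantify that signature transcriptome-wide and on
GFP–stall–RFP reporters:

* **Tract discovery** — 10-residue windows with ≥ *k* basic (K/R) or
  acidic (D/E) residues, with greedy non-overlap selection (one window per
  50 residues, highest count wins, ties to the smallest start), and dense
  control windows (≤ 2 target residues).
* **Occupancy analysis** — per-tract post/pre density ratios with the
  operational region geometry (post: 40 codons past the last basic residue
  to 20 codons before the stop; pre: 20 codons after the start to the post
  region), four audit-friendly exclusion filters (≥ 25 wild-type reads,
  no terminal-5% tracts, ≥ 30 codons to the stop, 2-SD control-distribution
  outliers), ±150 nt read-frequency metaprofiles, matched-control
  resampling (position / length / read-depth deciles), pooled-variance
  Student's *t*, and drop-off reports.
* **Reporter metrics** — relative post-stall occupancy, reporter mRNA
  abundance against the transcriptome median, side-scatter- and
  blank-normalized flow-cytometry RFP/GFP read-through ratios, ANOVA +
  Tukey HSD group statistics.
* **IP-MS enrichment** — pseudocounted, total-normalized spectral-count
  enrichment against an untagged control:
  `mean((c1+1)/T1, (c2+1)/T2) / ((c0+1)/T0)`.
* **Synthetic data** — seeded generators for every input (CDS FASTA,
  footprint BED, coverage TSV, flow event tables, spectral-count tables)
  with recorded ground truth, so the whole pipeline is testable without
  downloads.

The core statistic is the occupancy ratio
`rho = (post-tract reads/nt) / (pre-tract reads/nt)`, and the headline
drop-off is `100 * (1 - mean(rho_tract) / mean(rho_control))`.

## Worked example

Simulate a transcriptome in which 60 transcripts carry a planted tract of
8 basic residues with 10% ribosome read-through, plus 60 tract-free
control transcripts; then recover the drop from the BED/FASTA round trip:

```r
library(stallscan)
params <- analysis_params(tract_min_basic = 8)

g <- make_transcriptome(120, len_range = c(250, 350),
                        tract_count = rep(c(8L, 0L), c(60L, 60L)),
                        tract_position = c(0.15, 0.6), seed = 42)

bed <- tempfile(fileext = ".bed")
simulate_footprints(g$transcripts, g$truth,
  stall_model(lambda_pre = 0.25, dip_factor = 1, pileup_amplitude = 1,
              readthrough = 0.1),
  params = params, seed = 43, bed_path = bed)
tracks <- load_footprints(bed, g$transcripts, params)

wins   <- scan_transcriptome(g$transcripts, params, min_count = 8)
recs   <- occupancy_records(wins, g$transcripts, tracks, params = params)
ctrl_tx <- structure(g$transcripts[setdiff(names(g$transcripts),
                                           g$truth$transcript_id)],
                     class = "transcriptome")
pool   <- scan_transcriptome(ctrl_tx, params, what = "control")
pool   <- pool[seq(1, nrow(pool), by = 100), ]
recs_c <- occupancy_records(pool, g$transcripts, tracks, params = params)
recs_c <- apply_filters(recs_c, tracks, g$transcripts, params,
                        control_records = recs_c)
recs   <- apply_filters(recs, tracks, g$transcripts, params,
                        control_records = recs_c)
dropoff_report(recs, recs_c)
```

Output (seed 42/43):

```
    group n_windows n_genes mean_ratio mean_ratio_control percent_drop            p
1: pooled        60      60  0.1016516          0.9763677      89.5888 6.320741e-83
```

All 60 planted tracts are recovered; the mean tract ratio (0.102) matches
the planted read-through fraction (0.1), control windows sit at ~1 as they
should, and the measured drop (89.6%) recovers the planted 90% drop. The
*t*-test *p*-value compares the tract and control ratio distributions.

## Command line

```sh
Rscript inst/cli/stallscan tracts --fasta cds.fa --class basic \
    --min-count 8 --out tracts.tsv
Rscript inst/cli/stallscan io validate --fasta cds.fa --bed footprints.bed
Rscript inst/cli/stallscan ipms --table counts.tsv --out ranked.tsv
Rscript inst/cli/stallscan flow --events events.tsv --blank-sample blank \
    --out summary.tsv
```

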