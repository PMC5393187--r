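---
title: "Quantifying ribosome stalling at polybasic tracts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ribosome stalling at polybasic tracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Stretches of lysine and arginine codons slow or arrest the elongating
ribosome. In ribosome profiling data this leaves a characteristic signature
on a transcript: a change in footprint density at the tract, an artifactual
pile-up of density immediately downstream when cells were treated with
cycloheximide before lysis (ribosomes keep translating slowly in the drug
and queue up behind the stall), and a reduced density further downstream
that reflects the fraction of ribosomes that actually read through the
stall. `stallscan` turns this signature into numbers: where are the
polybasic-encoding tracts, how does mean occupancy drop past them, and how
does that drop compare to matched control positions?

## Tract discovery

A *tract window* is a 10-residue window of the protein containing at least
`tract_min_basic` target-class residues (basic = K/R; histidine is
excluded because the operative definition is lysines-or-arginines; acidic
= D/E serves as a negative-control class). Windows whose starts lie within
50 residues of each other would double-count the same biological feature,
so selection is greedy: repeatedly keep the candidate window with the most
target residues, break ties toward the smallest start, and discard
candidates within the exclusion radius. The tie-break makes the output a
deterministic function of the sequence. *Control windows* are every
position with two or fewer target residues, with no thinning — control
windows are a dense population to resample from, not features.

Two genuinely open readings were settled as follows: the 50-residue
non-overlap rule is applied per transcript (windows live on a single
protein), and distance is measured start-to-start, the simplest testable
reading. Both are parameters, not constants, so either choice can be
revisited by configuration.

## Occupancy ratios and region geometry

All coordinates are 0-based and half-open; codon `i` covers nucleotides
`[3i, 3i+3)`. The CDS includes its stop codon; the protein does not. For a
transcript with `L` sense codons and a tract whose last target residue is
`r`, the regions are

* post-tract: codons `[r + 1 + 40, L - 20)` — starting 40 codons past the
  last target residue to skip the cycloheximide pile-up zone, ending 20
  codons before the stop to avoid termination effects;
* pre-tract: codons `[20, r + 41)` — from 20 codons after the start to the
  beginning of the post region. The pre region deliberately contains the
  tract and the pile-up zone; no carve-out is invented beyond what the
  operational definition states.

The occupancy ratio is post-region density over pre-region density
(reads/nt each), a scale-free quantity. Tracts whose post region is empty
are flagged unanalyzable rather than erroring, and records with a zero
pre-region density are excluded with an audit reason instead of producing
an infinite ratio.

Because the pre region contains the tract dip and the pile-up, the ratio
is an *operational* read-through estimate, not the model parameter itself:
when a simulation plants dip or pile-up amplitudes different from 1, the
pre-region density is biased away from the upstream rate and the ratio
under-estimates the true read-through fraction. The recovery tests
therefore isolate the read-through parameter with dip and pile-up set to 1;
with the default artifact amplitudes the bias is a property of the region
definitions, which we reproduce faithfully rather than correct.

## Filters

Four named filters run in order, and excluded records keep their flags for
audit: (1) the transcript must have at least 25 footprints in the
wild-type reference sample; (2) the tract window must not overlap the
first or last 5% of the coding region; (3) at least 30 codons must
separate the last target residue from the stop codon; (4) records whose
ratio exceeds the control-distribution mean by more than two control
standard deviations are dropped. The outlier rule is one-sided (above the
mean): drops below the control mean are the biological signal being
measured, and the filter's purpose is noise removal. The control mean and
SD are computed on control records that survive the first three filters,
so the SD filter is well-defined to run last; the other three are
order-independent.

## Metaprofiles

Around each tract center — defined at codon granularity as the first
nucleotide of codon `start + width/2`, since finer placement is arbitrary
for a 10-residue feature — footprint counts over ±150 nt are normalized
to sum to 1 and averaged across windows. Windows with fewer than 10 reads
carry mostly sampling noise and are excluded, as are windows that extend
past either transcript end (they would need padding conventions that
change the profile's meaning). Each contributing vector sums to one, so
excluding one window never perturbs another's contribution.

## Matched controls

Control positions differ systematically from tract positions (in location
along the transcript, transcript length, and local read depth), so raw
control ratios are not a fair baseline. `sample_matched_controls()`
resamples the control pool to match the tract distributions of three
features: relative position, transcript length, and window read count.
Each feature is binned into deciles of the tract distribution and every
control is weighted by the product of per-feature tract/control bin-mass
ratios; `n` controls are then drawn with those weights under a fixed seed.
Marginal (product) weighting was chosen over joint decile bins because
joint bins (10^3 cells) are mostly empty at realistic tract counts; the
product form matches each marginal in expectation and degrades gracefully.
Empty or starved bins are reported via messages, never skipped silently.

## Group statistics

Tract-versus-control ratio distributions are compared with a two-sided
pooled-variance Student's t-test (Welch behind a flag; the pooled form is
the named test). The headline drop is
`100 * (1 - mean(tract ratios) / mean(control ratios))`; since
mean-of-ratios and ratio-of-means differ on skewed data and neither
convention is canonical, the ratio-of-means variant is reported alongside
in every `dropoff_report()`. Flow-cytometry summaries use one-way ANOVA
followed by Tukey's HSD on per-replicate values, with SEM computed across
biological replicates (not events). Degenerate inputs (all groups
identical constants) return F = 0, p = 1 rather than NaN.

## Reporter metrics

For a GFP–stall–RFP reporter, the relative post-stall occupancy divides
reads/base in the actively translated part of the RFP region (excluding
the 40 codons past the stall, which hold queued ribosomes) by reads/base
over the whole ORF with 20-codon end trims. The flow-cytometry
read-through ratio is `100 * (RFP/GFP)_stall / (RFP/GFP)_nonstall` on
side-scatter-normalized, blank-referenced channel means; per-event
channel/SSC division was chosen over regression compensation as the
simplest reading of "side-scatter normalized". The two metrics are
consistent by construction: percent drop equals 100 minus the ratio on the
same pair of values.

## IP-MS enrichment

Enrichment for a protein is `mean((c1+1)/T1, (c2+1)/T2) / ((c0+1)/T0)` over
two bait replicates against a single untagged-control IP, where `T` are
per-sample total spectral counts. The +1 pseudocount keeps absent proteins
finite but breaks exact invariance under joint rescaling of counts and
totals: `(s*c+1)/(s*T) = (c + 1/s)/T`. The invariance holds within an
analytic bound of order one over the smallest pseudocounted count, and
exactly in the large-count limit; the tests assert that bound rather than
a fictitious exact identity. Supplied sample totals are validated against
column sums and column sums win on disagreement, with a warning.

## The synthetic-data generator: what it emulates and what it does not

No accession is stated for the study's raw data, so every pipeline input
is emulated by a seeded generator with recorded ground truth:

* **Transcriptome** — random CDS (100–2000 codons; default 300–800) whose
  background residue usage contains *no* basic or acidic residues, with a
  contiguous run of K/R (or D/E) planted inside a 10-residue window at a
  recorded position. Excluding target residues from the background is a
  deliberate idealization: planted windows are the only windows of their
  class, so recovery tests have exact truth. Real proteomes have diffuse
  basic residues and near-threshold windows; a green recovery test says
  the pipeline arithmetic is right, not that tract discovery is robust to
  borderline compositions.
* **Footprints** — per-nucleotide Poisson counts with rate `lambda_pre`
  upstream, `x dip_factor` over the tract, `x pileup_amplitude` for a
  40-codon boxcar past the last target residue, and
  `x readthrough` thereafter; each count becomes one 28-nt BED interval
  placed so that P-site assignment recovers the sampled nucleotide. The
  defaults (`lambda_pre = 0.5`/nt, `dip_factor = 0.5`,
  `pileup_amplitude = 2`, `readthrough = 0.1`) state a strong stall with
  the drug artifact present, matching the qualitative picture of a dip at
  the tract, a 40-codon pile-up, and a ~90% drop beyond. Poisson (not
  negative-binomial) noise reflects the absence of any overdispersion
  model in the source analysis; real libraries are overdispersed and
  sequence-biased, which the generator does not emulate.
* **RNA-seq** — uniform Poisson coverage proportional to abundance ×
  length; no positional bias.
* **Flow events** — log-normal channels with specified means and CV
  (mean-preserving parameterization), biological replicates, and a blank
  strain; no autofluorescence structure or channel spillover.
* **Spectral counts** — multinomial draws per sample with bait
  probabilities tilted by a true enrichment vector; no peptide-level
  structure.

Every generator is a pure function of its specification and seed; the same
seed yields byte-identical files.

## Numerical and edge-case choices

* P-site offset: 5' end + 15 nt for 28-mers, configurable; the source
  protocol states only the footprint size, and region-level densities are
  insensitive to small offsets.
* `sample()`-style index pitfalls are avoided by explicit index vectors;
  all seeded code paths save and restore the caller's RNG state.
* The distance-to-stop rule counts sense codons strictly between the last
  target residue and the stop codon; exactly 30 passes, 29 fails.
* The terminal-5% rule uses real-valued zone boundaries
  (`start < 0.05 L` or `start + width > 0.95 L`), so no rounding choice
  can silently shift a boundary case.
* Per-position RPKM is scaled so that the mean over any region equals that
  region's RPKM (count per nt divided by nt-in-kb × library-in-millions);
  this keeps trace plots and region statistics in the same units.
* `compare_occupancy` returns t = 0, p = 1 for identical constant groups
  and ±Inf, p = 0 for distinct constant groups, both with warnings,
  instead of erroring mid-pipeline.

## Known limitations

* Residue-based only: codon identity effects (e.g. CGA decoding) are out
  of scope by design.
* The wild-type read filter interprets "<25 reads" as the transcript total
  in the wild-type sample; tract-vicinity alternatives would need a window
  convention the operational definition does not give.
* Gene-level aggregation before group statistics is available but not the
  default; records are per window, gene counts deduplicate transcript ids.
* The simulator's boxcar pile-up and uniform elongation are idealizations;
  recovery bounds quoted in the tests hold under this stated world, not
  under arbitrary real-data pathologies.
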