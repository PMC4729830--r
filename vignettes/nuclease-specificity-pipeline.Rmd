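---
title: "Profiling the activity and genome-wide specificity of dimeric nucleases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the activity and genome-wide specificity of dimeric nucleases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucspec)
```

## Scope

`nucspec` implements the computational side of a nuclease engineering and
validation campaign for sequence-discriminating, dimeric designer nucleases
(zinc-finger nucleases being the motivating platform). Four analysis stages
are covered, together with a synthetic-data module that generates every
input with planted ground truth:

1. **Dual-reporter gating** — classifying GFP/mCherry flow events against
   background gates derived from a negative control, quadrant fractions and
   fold enrichment, plus growth-curve doubling times for the liquid
   selection assay.
2. **SELEX profiling** — strict filtering of selection reads against the
   library design, seeded subsampling, a flank-anchored position frequency
   matrix (PFM), two-strand alignment of the matrix to the intended target,
   and per-position discrimination percentages.
3. **Amplicon indel quantification** — per-read global alignment, lesion
   calls restricted to a padded cut window, one-sided Fisher exact tests
   against cognate controls, Bonferroni correction, on:off specificity
   ratios and aggregate off-target activity.
4. **IDLV-capture off-target discovery** — integrase-defective lentiviral
   vectors integrate preferentially at double-strand breaks, so clustered
   integration sites flag candidate cut loci. The module deduplicates
   junction coordinates, merges them into 1-kb single-linkage clusters,
   filters by replicate support, ranks candidates, and annotates paired
   half-site (dimer) binding-site matches.

`run_full()` ties discovery to validation: the ranked candidate loci are
re-sequenced (in simulation mode, re-simulated from planted truth),
compared with controls, and summarized in a specificity report.

## The discovery model

An integration table holds 0-based coordinates labelled by sample,
replicate and group (`treated`/`control`). Discovery proceeds:

* **Deduplication.** Reads identical in (chromosome, position, strand,
  sample) collapse to one *unique integration*; read multiplicity is kept
  as metadata only. Coordinate-level deduplication was chosen over
  read-level deduplication because amplification duplicates collapse to a
  coordinate anyway, and replicate structure is preserved by scoping the
  collapse per sample.
* **Clustering.** Two integrations join one cluster iff they are chained by
  pairwise gaps of at most 1,000 bp on the same chromosome (strand
  ignored, since a vector can capture in either orientation at one break).
  This is single-linkage (transitive) merging — the literal reading of
  "within 1 kb of each other" — rather than fixed windows; cluster count is
  therefore monotonically non-increasing in the merge distance, a property
  the tests exercise against a brute-force transitive-closure oracle.
* **Replicate filter.** A candidate must contain integrations from at least
  2 treated replicates and at most 1 control replicate (both
  configurable). This suppresses capture into spontaneous, cell-cycle or
  environmentally induced breaks, which replicate poorly and appear in
  controls. Every dropped cluster carries a machine-readable reason.
* **Ranking.** Candidates sort by total unique treated integrations
  (descending), then treated replicates present, then the treated:control
  ratio (a zero control count ranks as infinite ratio), then coordinates —
  making the order a deterministic total order. The ratio is used as a sort
  key, not a filter; the replicate thresholds do the filtering. The top 20
  are reported by default, mirroring the number of loci a validation PCR
  panel typically covers.
* **Annotation.** A window of cluster span ± 250 bp is scanned exhaustively
  for half-site A + spacer + half-site B on opposite strands, with the two
  half-site identities in either order and Hamming mismatches counted per
  half-site. The spacer range defaults to 4–7 bp, the usual geometry for
  obligate-dimer nucleases whose cleavage domains meet across the spacer;
  both the range and the per-half mismatch cap are configurable.

## The validation model

A lesion call is an alignment gap overlapping the cut interval padded by
10 bp on each side — NHEJ lesions center on the double-strand break, and
the pad absorbs alignment jitter without picking up distal polymorphisms.
Alignment is global with affine gaps (match +1, mismatch −2, gap open −6,
extend −1); reads below 60% identity over non-gap columns are discarded as
failed amplicons rather than scored. Substitution-only reads never gain a
gap under this scoring (for equal-length sequences a compensating
insertion–deletion pair costs at least 14 against at most 6 for two
mismatches), so a zero-rate, zero-error input yields exactly 0%.

Treated and control counts are compared with a one-sided Fisher exact test
(the upper hypergeometric tail of the 2×2 table). The count-comparison
test in the original protocol is cited but not reproduced in the sources
available to us, so the exact test was adopted as the assumption-free
choice for 2×2 counts; the implementation is validated against complete
hypergeometric enumeration for every table with margins up to 50.
P-values are Bonferroni-adjusted over the candidate batch (`m` = number of
loci amplified in the run). A locus is *active* when its adjusted p-value
is below α = 0.05 **and** its treated frequency exceeds its control
frequency. Aggregate off-target activity is the sum of active off-target
frequencies; fold change against a comparator aggregate is reported
rounded to the nearest integer. An on:off ratio with a zero off-target
frequency is censored against the batch background floor (default 0.1%,
the scale of a GFP-control lesion frequency) and reported as a lower
bound; frequencies are used raw, without background subtraction.

## The SELEX model

The selection oligo is `flank5 (24 nt) + N22 + flank3 (24 nt)`; reads are
kept only at the exact 70-nt length with both flanks matching exactly.
Because the fixed flanks pin the register of the variable region, the PFM
is built directly from the filtered, subsampled (n = 200, seeded) variable
regions — de novo motif discovery would rediscover a register that is
already known, so it is deliberately replaced by this flank-anchored
builder, and equivalence with any particular motif-discovery program is
not claimed. Columns get a pseudocount of 0.5 per base.

The matrix is aligned to the intended target by scoring every offset on
both strands as the summed per-column frequency of the target base (the
simplest monotone match score), reverse-complementing when the reverse
strand wins, and trimming to the target-length columns of the best
placement; ties prefer the forward strand, then the smallest offset.
Discrimination at a critical position is the percentage of reads carrying
the intended base versus the counter-selected homologue's base.

## The gating model

Channel thresholds are the 99.5th empirical percentile (inverse-ECDF order
statistic) of a negative control that expresses neither reporter — the
conventional background cut for a 0.5% false-positive gate; events are
positive only strictly above threshold. Quadrants follow the dot-plot
convention (Q2 double-positive, Q4 GFP-positive/mCherry-negative), and the
per-experiment gate derivation means thresholds are not assumed constant
across panels. Fold enrichment is the ratio of quadrant fractions, with a
zero reference fraction flagged undefined rather than infinite. Channel
means are arithmetic means of linear-scale intensities. Doubling time fits
log2(blanked OD) against time over a fixed log-phase band (blanked OD
0.02–0.4, below the assay's 0.8 culture cap and above lag-phase noise); a
non-positive slope is flagged as no growth. The band is absolute, so the
estimate is invariant to time shifts always, and to OD rescaling whenever
the rescaling keeps the same points inside the band.

## What the simulator emulates — and what it does not

* **Integrations** are placed at planted cut-site centers plus a signed
  geometric offset with a 50-bp scale — capture concentrates within tens
  of base pairs of the break with occasional distal events — over a
  uniform background (default 1 per Mb per replicate, both groups).
  Control replicates never receive site integrations.
* **Amplicon reads** carry at most one indel each (lesions are scored per
  read as indel-positive or not, so multi-indel alleles add nothing at
  desk scale), anchored inside the cut interval, with uniform per-base
  substitution noise. No per-cycle quality model, PCR duplication or
  paired-end structure is simulated.
* **SELEX pools** draw variable regions column-wise from a generating
  matrix between the fixed flanks; a configurable contaminant fraction
  receives length or flank defects to exercise the filter. Multi-round
  enrichment dynamics and binding-energy models are not simulated.
* **Flow events** come from a mixture of bivariate log-normal populations
  (20,000 events by default, the conventional acquisition floor); no
  spillover/compensation or scatter gating is modeled.

Passing tests on these inputs demonstrate the correctness of the
algorithms under idealized noise, not performance on real sequencer
artifacts (chimeras, index hopping, context-dependent error) or real
cytometer effects.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; BED on disk.
* All generators are deterministic given a `sim_config` (each derives its
  stream from the config seed), and pipeline outputs embed the config
  hash and seed so a bundle can be reproduced byte for byte.
* One-sided Fisher p-values are computed with the vectorised
  hypergeometric tail, enabling exhaustive validation across all small
  tables in seconds.
* The planted-recovery study in the tests uses 3+3 replicates, five sites
  at Poisson mean 5 integrations per treated replicate, and background 10
  integrations/Mb/replicate on a 100-Mb genome (≈1,000 background
  integrations per replicate); validation depth is 5,000 reads per locus,
  at which a 0.4% lesion is detected against a clean control with
  probability ≈0.9995 after Bonferroni correction over a 2-locus batch.
  These sizes keep the complete suite within a few minutes on one CPU.
* At 10 background integrations/Mb/replicate, the probability that two or
  more control replicates each deposit a background integration within
  chaining distance of a planted cluster is ≈0.13% per site — the filter
  then (correctly) discards the cluster. Recovery is therefore expected at
  99.9%, not exactly 100%, per site over many seeds; this is the method's
  inherent false-negative mode, not an implementation artifact.

## Known limitations

* Junction mapping is exact-match on toy genomes; real libraries should be
  mapped with a production aligner and imported as BED.
* The indel caller assumes merged single-end amplicon reads spanning the
  cut site and does not quantify HDR or phase multi-allelic outcomes.
* Binding-site annotation reports Hamming-mismatch matches only; no
  binding-energy or position-weight scoring of half-sites.
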