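# nucspec

Quantifying the activity and genome-wide specificity of engineered,
dimeric nucleases (zinc-finger nucleases and kin) from the data types a
nuclease engineering campaign produces: dual-reporter flow cytometry,
SELEX selection reads, amplicon deep sequencing, and integrase-defective
lentiviral vector (IDLV) capture of integration sites at double-strand
breaks. The package is aimed at genome-editing groups validating
sequence-discriminating nucleases — for example a pair engineered to cut
*CCR5* while sparing its close homologue *CCR2*.

## What it computes

**Off-target discovery from IDLV capture.** IDLV integrations mark
double-strand breaks genome-wide. Given per-replicate integration
coordinates (BED) for treated and control samples, unique integrations
(distinct chromosome/position/strand per sample) are merged into
single-linkage clusters chained at gaps ≤ 1 kb, filtered to clusters with
integrations from ≥ 2 of 3 treated and ≤ 1 of 3 control replicates, and
ranked by total unique treated integrations (ties: replicates present,
treated:control ratio, coordinates). The top 20 candidates are reported
and annotated with paired half-site matches (half-site + 4–7 bp spacer +
opposite-strand half-site, Hamming mismatches per half).

**Indel quantification.** Reads are globally aligned to each locus
reference (match +1, mismatch −2, gap open −6, extend −1); a read is
indel-positive iff a gap overlaps the cut interval ± 10 bp. For locus *i*
with treated counts (k, n) and control counts (k₀, n₀), the indel
frequency is f = 100·k/n and treated-vs-control significance is the
one-sided Fisher exact p (upper hypergeometric tail of the 2×2 table),
Bonferroni-adjusted over the candidate batch. A locus is *active* when
adjusted p < 0.05 and f > f₀. Headline summaries: the on:off specificity
ratio f_on/f_off (censored against a background floor when f_off = 0),
the aggregate off-target activity Σ f over active off-target loci, and
the fold decrease comparator/aggregate versus a reference nuclease.

**SELEX profiling.** Selection reads matching the library design exactly
(70 nt; both 24-nt flanks exact) contribute their 22-nt variable region;
200 sampled regions build a position frequency matrix
PFM[b, i] = (count + 0.5) / (n + 2), which is aligned to the intended
target over all offsets on both strands (score = Σᵢ PFM[targetᵢ, offset+i]),
reverse-complemented if needed and trimmed to the target. Discrimination
at a critical position is the percentage of reads carrying the intended
base versus the homologue's base.

**Reporter assays.** Background gates at the 99.5th percentile of a
negative control per channel; quadrant fractions (Q2 = GFP+/mCherry+,
Q4 = GFP+/mCherry−); fold enrichment between conditions; and log-phase
doubling times from OD600 curves.

A synthetic-data module (`sim_config()` and the `simulate_*` generators)
produces every input with planted ground truth, so the full pipeline runs
and is tested end to end without external data.

## Worked example

Simulate a capture experiment with one on-target site (30% lesion rate)
and one genuine low-frequency off-target (0.4%), discover candidate loci,
and validate them by simulated amplicon sequencing at 5,000 reads per
locus against a comparator aggregate of 33.3%:

```r
library(nucspec)

config <- list(
  seed = 42, outdir = "nucspec_demo",
  simulate = list(
    genome_length = 1e6, n_chromosomes = 2,
    sites = list(
      list(chrom = "chr1", position = 2e5, kind = "on_target",
           intensity = 20, indel_rate = 0.30, name = "on"),
      list(chrom = "chr2", position = 1e5, kind = "off_target",
           intensity = 8, indel_rate = 0.004, name = "off1")
    )
  ),
  validation = list(comparator_aggregate = 33.3)
)
res <- run_full(config)
str(res$report[c("n_candidates", "n_active_offtarget",
                 "aggregate_offtarget", "fold_vs_comparator")])
res$report$ratios
```

```
List of 4
 $ n_candidates       : int 2
 $ n_active_offtarget : int 1
 $ aggregate_offtarget: num 0.34
 $ fold_vs_comparator : num 98
       off_locus ratio_label
1 cluster_rank02        91.2
```

Both planted loci are discovered (the on-target ranks first); the
off-target is called active at 0.34% measured frequency (truth 0.4%,
within binomial error at 5,000 reads), the aggregate off-target activity
is that single active locus, and the report expresses it as a ~98-fold
decrease relative to the 33.3% comparator and an on:off modification
ratio of ~91. The output directory
holds the candidate table, per-locus results, the JSON report, and a
manifest keyed by the config hash and seed.

(Numbers above are from this exact configuration; rerunning it
reproduces them byte for byte.)

## Layout

```
R/                      implementation (simulation, gating, SELEX,
                        indels, discovery, config/pipeline)
tests/testthat/         unit, property and acceptance suites with
                        independent brute-force oracles
vignettes/              methods vignette (models, parameters, limits)
scripts/acceptance.R    headline-quantity reproduction script
```
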