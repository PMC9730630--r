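---
title: "Detecting and profiling A-to-I RNA editing from paired DNA/RNA base counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and profiling A-to-I RNA editing from paired DNA/RNA base counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaeditr)
library(dplyr)
```

## The model

A-to-I editing deaminates adenosine to inosine in double-stranded RNA;
inosine base-pairs like guanosine, so an edited transcript position
appears in RNA-seq as an A>G mismatch on the transcribed strand. On the
reference-forward orientation that is A>G for plus-strand genes and T>C
for minus-strand genes. The *editing level* at a site is the variant
allele frequency, alt/(ref+alt), among reads overlapping the position.

Editing detection is therefore a differential variant-calling problem:
an RNA variant with no DNA-level counterpart in the same patient. The
confounders are germline SNPs (present in DNA of both tissues), somatic
SNVs (present in tumor DNA), sequencing error, alignment artifacts in
low-complexity sequence, and multi-mapping in near-duplicated regions.
The pipeline addresses each confounder with a dedicated stage, and
Alu-element variants — where inverted-repeat double-stranded RNA makes
editing biologically expected and dense — are exempted from the two most
aggressive artifact filters.

## The procedure and its thresholds

`call_variants()` emits a candidate per (site, sample, material, tissue,
alternate allele) when all four constraints hold. Comparisons are
inclusive exactly as the thresholds are written: depth 8 passes a
"&ge; 8x" rule and VAF 0.05 passes "&ge; 5%".

| parameter | default | units | role |
|---|---|---|---|
| `min_depth` | 8 | reads (all 8 stranded counts) | minimum site depth |
| `min_vaf` | 0.05 | proportion | discovery allele-frequency floor |
| `min_baseq` | 20 | Phred | minimum mean alternate base quality |
| `strand_bias_alpha` | 0.05 | probability | Fisher-exact rejection level |
| `non_alu_min_vaf` | 0.10 | proportion | stringent non-Alu floor |
| `flank_k` | 50 | bases | uniqueness flank width |
| `maf_threshold` | 0.001 | allele frequency | strict `>` bound for SNP removal |
| `delta` (over-editing) | 0.10 | level difference | strict `>` bound per site/patient |

Design choices where the procedure was genuinely open:

* **Strand bias.** No specific test is mandated by the filtering rule
  "no strand bias"; we use the two-sided Fisher exact test on the 2x2
  table {ref, alt} x {forward, reverse}, the field convention. With
  fewer than 2 alternate reads the test has no power and is skipped
  (treated as unbiased); `strand_bias_alpha = NULL` disables the stage.
* **Base quality.** Base-count tables carry per-allele mean qualities,
  not per-read qualities, so "base quality &ge; 20" is applied to the
  mean quality of alternate-supporting bases.
* **DNA subtraction.** "Remove what the exome shows" needs a support
  threshold; DNA evidence counts when the same (site, allele) has
  &ge; 2 alternate reads or DNA VAF &ge; 0.02 in either tissue of the
  same patient, and the evidence is gathered with a permissive caller so
  weak DNA support is visible. Both knobs are arguments.
* **Genome uniqueness.** Alignment-similarity screening (classically
  done with BLAT) is implemented as an exact flanking k-mer multiplicity
  check: the 50-mer centered on the site must occur exactly once in the
  reference counting both orientations. This is deterministic,
  self-contained, and catches duplicated segments at desk scale; it is
  not a sequence-similarity search, and for real genomes an external
  mappability track can replace it (`uniqueness_check = FALSE`).
* **Recurrence.** Counted over patients by default (a site seen in tumor
  and normal of one patient is a singleton);
  `recurrence_unit = "sample"` counts patient-tissue samples instead.
* **VAF with third alleles.** VAF is alt/(ref+alt), ignoring other
  non-reference alleles; a site with two alternate alleles above
  threshold yields two candidate records.

## Cohort statistics

`recurrence_summary()` and `spectrum_fractions()` report raw
numerators/denominators next to percentages so the arithmetic stays
auditable; printed-style percentages use one decimal and round half
away from zero (91.15 -> 91.2), not banker's rounding.

`patient_overediting()` classifies each (site, patient) with levels in
both tissues: over-edited if tumor - normal > 0.10, under-edited if
normal - tumor > 0.10, strictly — a difference of exactly 10 points is
neither. Site-patient pairs missing a level in either tissue (depth
below `min_depth`) are excluded for that patient; a patient with no
evaluable pair leaves the cohort denominator with a message. The
statistic takes an explicit `site_subset` argument rather than
hard-coding a validated panel, since the panel is a study input.

`motif_profile()` builds the ±10 nt neighbor-preference matrix on the
transcribed strand (minus-strand contexts reverse-complemented), each
row normalised to 1 with the center degenerate at A.

`spearman_assoc()` mid-ranks ties and, for n &le; 9, enumerates all n!
permutations for the two-sided p-value — the cohort sizes this package
targets (15–26 patients) straddle the validity of the t approximation,
so both routes exist and the switch point `exact_max` is an argument.
For larger n it uses `t = rho * sqrt((n-2)/(1-rho^2))`. No
multiple-testing correction is applied by default; the association
functions report nominal p-values.

`paired_tissue_test()` guards the degenerate inputs a paired t test
cannot handle: identical vectors give t = 0, p = 1; a constant non-zero
shift gives p = 0 (the zero-variance guard triggers at
`sd(diff) <= 1e-10 * (|mean| + 1)` to absorb floating-point residue).
An optional natural-log transform of strictly positive values mirrors
the convention of log-transforming skewed measurements before t tests.

## Chromatogram quantification

Editing from Sanger traces is the baseline-subtracted peak-height ratio
`100 * G/(A+G)` at the expected adenosine: for each channel, the maximum
intensity within ±4 scan points of the basecall minus the channel median
over the trace, floored at zero. Vendor trace-quantification tools do
not document their internals, so this standard surrogate is the
definition here; a peak-*area* mode (`mode = "area"`) is available
because height versus area differs between tools. Reverse-strand
reads complement-swap channels (A/T, C/G) before the ratio. A combined
A+G signal below `signal_floor` (default 50, i.e. 5% of the nominal
1000-unit amplitude) is flagged `"no-signal"` instead of quantified.
The estimate is scale-invariant by construction.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` reproduces the *structure* of a paired
tumor/normal, DNA+RNA cohort of 15 patients, not the content of any
real dataset. Defaults, chosen once as the study conditions:

* 200 planted A-to-I sites in a 200 kb, 60-gene reference; 500 SNPs with
  MAFs spanning the 0.001 threshold (20% at or below it); 50 somatic
  SNVs; 1000 unedited background positions.
* Depth ~ Poisson(50) per site for both materials — the simplest
  overdispersion-free model that exercises the 8x floor. Per-base error
  1e-3, uniform over the three other bases.
* Editing levels Beta(2, 6) per site/patient/tissue (mean 0.25, typical
  of protein-coding sites); tumor levels additionally shifted by
  `adar_coupling` (default 0.08) times the patient's standardised log
  ADAR1-p110 tumor expression, coupling burden to ADAR1 the way
  amplification-driven over-editing would. Setting the coupling to 0
  yields a null cohort.
* Recurrence profile 90% singletons, with 2/3/5/15-patient tails —
  singleton-dominated, as exome-scale editing discovery is.
* Expression in FPKM-like units: ADAR1-p110 around 22 in normal tissue
  with a 1.8-fold tumor shift, ADAR2 around 2 in both (a ~20-fold
  abundance gap), lognormal spread 0.15. Only ranks matter downstream.
* 5' neighbor preference 0.7 for C/T on the transcribed strand, so the
  motif profiler has a real signal to find.
* Base qualities ~ N(35, 3) truncated to [2, 41], leaving headroom
  around the Phred-20 threshold. Minus-strand edits are planted as T>C
  reference-forward so strand collapse is genuinely exercised. Read
  strands split 50/50 unless `alt_fwd_prob` injects a strand artifact.

Coordinates follow the two conventions of the field: interval tables
(genes, Alu, repeats) are 0-based half-open (BED), site tables are
1-based (VCF); `point_in_intervals()` is the only crossing point, and
boundary tests pin its behaviour (position `end` is inside, `start` is
not).

What the generator does **not** model: read-level data (no FASTQ/SAM —
the pipeline starts at base counts, as real workflows do after
alignment), alignment error and mapping bias (errors are independent
per base), depth overdispersion, hyper-editing clusters, multi-exon
gene models, and inter-site level correlation beyond the shared patient
shift. Passing tests on this cohort therefore demonstrate the logic of
every stage and the calibration of the statistics, not robustness to
alignment artifacts in real genomes — that is what the external
mappability hook and the documented thresholds are for.

## Problem sizes and runtime choices

The shipped checks use the default cohort (15 patients, 200 sites, ~10^5
base-count rows; a few seconds to simulate and call), a 200-cohort null
calibration with 25 shared sites per cohort, 60 chromatograms for the
round-trip error, and cascades of at most 500 calls for the exhaustive
set-algebra comparison — sizes picked so the whole suite runs in about a
minute while every stage still sees non-trivial input.

## Known limitations

* Single-contig references and single-CDS gene models; multi-exon
  splicing and junction-spanning codons are out of scope.
* The k-mer uniqueness check is exact-match only; diverged duplications
  that BLAT would flag are not caught.
* DARNED/RADAR-style catalogues are consumed as plain site lists; no
  download or liftover machinery is included.
* Editing-level inference is a plain binomial proportion; no shrinkage
  across sites or patients.
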