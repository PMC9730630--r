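# rnaeditr

Exome-wide detection and profiling of A-to-I RNA editing from paired
tumor/normal DNA and RNA base counts.

## The problem

Adenosine deaminases acting on RNA (ADAR1, ADAR2) convert adenosine to
inosine in double-stranded RNA. Sequencers read inosine as guanosine, so
editing shows up in RNA-seq as an A>G mismatch against the genome (T>C on
the reference-forward strand of minus-strand genes). Telling genuine
editing apart from germline SNPs, somatic mutations and alignment
artifacts requires matched DNA, careful per-site filtering, and
Alu-stratified thresholds — Alu elements form the inverted repeats ADARs
prefer, so variants there are trusted at a lower allele frequency than
variants elsewhere.

`rnaeditr` implements that workflow for cohorts of paired tumor and
non-tumor tissue with both whole-exome (DNA) and RNA-seq material,
starting from per-site stranded base-count tables ("pileup TSV"):

1. **Candidate calling** — a transparent threshold caller per sample and
   material: depth >= 8x, variant allele frequency (VAF = alt/(ref+alt))
   >= 5%, mean alternate base quality >= Phred 20, and no strand bias
   (two-sided Fisher exact test on the ref/alt x fwd/rev table).
2. **Filter cascade** — remove RNA calls with DNA-level support in the
   same patient (somatic SNVs, residual germline), known SNPs with
   MAF > 0.001, and calls in simple repeats; partition into Alu and
   non-Alu; non-Alu calls additionally need VAF >= 10% and a flanking
   50-mer that is unique in the genome (both orientations).
3. **Annotation** — strand-collapsed mismatch type (one of 12),
   recurrence across patients, known-editing-catalogue membership,
   conservation, and the recoding consequence: CDS position, codon index
   `floor((cds_pos-1)/3)+1`, and the amino-acid substitution (e.g. an A>G
   at CDS position 22 of a Met-initiated frame recodes codon 8 from Met
   to Val, "p.M8V").
4. **Cohort statistics** — singleton/recurrent fractions, mismatch
   spectrum, +/-10 nt neighbor-preference motif, per-patient over-/
   under-editing (sites whose tumor level differs from the matched
   normal level by strictly more than 10 percentage points), Spearman
   correlation of over-editing burden with ADAR1-p110 expression (exact
   permutation p for n <= 9), paired tumor/normal t tests, and
   expression fold changes.
5. **Sanger quantification** — editing percentage from chromatogram peak
   heights as baseline-subtracted `100*G/(A+G)`, so trace-based levels
   merge with the sequencing-based level matrix.

A fully seeded synthetic cohort generator (`cohort_config()`,
`generate_reference()`, `simulate_cohort()`, `simulate_chromatogram()`)
produces reference, annotations, base counts, expression and traces with
known ground truth, so the whole pipeline is testable end to end without
any controlled-access data.

## Worked example

```r
library(rnaeditr)

cohort <- simulate_cohort(cohort_config(seed = 1))
result <- detect_editing_sites(cohort)
result
#> <editing_result>
#>   188 putative editing sites from 372 surviving calls
#> # A tibble: 4 × 4
#>   stage              n_in n_out n_removed
#>   <chr>             <int> <int>     <int>
#> 1 dna_subtraction    5471   423      5048
#> 2 known_snps          423   423         0
#> 3 simple_repeats      423   422         1
#> 4 non_alu_stringent   301   251        50

score_against_truth(result, cohort)
#> # A tibble: 1 × 7
#>   n_truth n_called n_recovered sensitivity precision n_snp_leaked ...
#> 1     200      188         186        0.93     0.989            0
```

The default configuration plants 200 A-to-I sites, 500 germline SNPs and
50 somatic SNVs in 15 patients at 50x mean depth with a 1e-3 per-base
error rate. The cascade recovers 186 of the 200 planted sites (93%
sensitivity), 98.9% of what it reports is a planted edit, and no SNP or
somatic SNV survives — the `dna_subtraction` row shows the germline
heterozygotes (RNA VAF ~50%) being removed wholesale by their own DNA
support.

Downstream, burden and expression connect in two lines:

```r
levels <- editing_level_matrix(cohort$counts, tidy(result))
burden <- patient_overediting(levels)
burden_expression_correlation(burden, cohort$expression)
#> <edit_assoc> spearman: estimate = 0.7746, p = 0.0006969, n = 15 (t approximation)
```

The generator couples each patient's tumor editing shift to its
ADAR1-p110 expression (`adar_coupling`, default 0.08), and the
correlation recovers it. `plot_mismatch_spectrum()`, `plot_motif()`,
`plot_overediting()` and `autoplot()` methods draw the matching figures.

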