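test_that("generation is bit-identical under the same seed and refuses to run unseeded", {
  cfg <- small_config(42)
  expect_identical(generate_reference(cfg), generate_reference(cfg))

  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$counts, co2$counts)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$expression, co2$expression)

  unseeded <- small_config(1)
  unseeded$seed <- NULL
  expect_error(simulate_cohort(unseeded), class = "rnaeditr_seed_error")
  expect_error(generate_reference(unseeded), class = "rnaeditr_seed_error")
})

test_that("impossible geometry is a configuration error", {
  expect_error(
    cohort_config(genome_length = 1000, n_genes = 10, gene_length = 2000,
                  seed = 1),
    class = "rnaeditr_config_error"
  )
})

test_that("planted site classes are disjoint and edits are transcribed-strand adenosines in genes", {
  co <- simulate_cohort(small_config(7))
  all_pos <- c(co$truth$edits$pos, unique(co$truth$snps$pos),
               co$truth$somatic$pos)
  expect_equal(anyDuplicated(all_pos), 0)

  ed <- co$truth$edits
  ref_chars <- strsplit(co$ref$reference, "")[[1]]
  expect_true(all(ref_chars[ed$pos] == ifelse(ed$strand == "+", "A", "T")))
  expect_true(all(ed$ref == ifelse(ed$strand == "+", "A", "T")))
  expect_true(all(ed$alt == ifelse(ed$strand == "+", "G", "C")))

  genes <- co$ref$genes
  in_gene <- vapply(ed$pos, function(p) {
    any(p > genes$start & p <= genes$end)
  }, logical(1))
  expect_true(all(in_gene))

  # annotation closure: every planted edit resolves to gene, strand, and a
  # codon when in CDS, with no unannotated failures
  ann <- annotate_consequence(ed[, c("chrom", "pos", "ref", "alt")],
                              genes, co$ref$reference)
  expect_equal(nrow(ann), nrow(ed))
  expect_true(all(!is.na(ann$gene_id)))
  expect_true(all(!is.na(ann$codon_index[ann$region == "CDS"])))

  # conservation covers all planted sites after cohort simulation
  expect_true(all(ed$pos %in% co$ref$conservation$pos))
})

test_that("alu_fraction controls the planted-edit Alu fraction", {
  co <- default_cohort() # 200 sites, alu_fraction 0.30
  frac <- mean(co$truth$edits$is_alu)
  expect_lt(abs(frac - 0.30), 0.10)

  co0 <- simulate_cohort(small_config(5, alu_fraction = 0))
  expect_equal(nrow(co0$ref$alu), 0)
  expect_false(any(co0$truth$edits$is_alu))
  res0 <- detect_editing_sites(co0)
  expect_false(any(res0$sites$is_alu))
})

test_that("observed RNA VAF at planted sites matches the planted level (no sequencing error)", {
  # near-degenerate Beta at level 0.30, depth 1000: binomial sampling alone
  cfg <- small_config(
    13, n_edit_sites = 5, n_snps = 0, n_somatic = 0, n_background = 0,
    depth_mean_rna = 1000, seq_error_rate = 0,
    edit_level_normal = c(3e4, 7e4), edit_level_tumor = c(3e4, 7e4),
    adar_coupling = 0,
    recurrence_profile = c("1" = 1)
  )
  co <- simulate_cohort(cfg)
  lv <- editing_level_matrix(co$counts, co$truth$edits, min_depth = 8)
  carried <- dplyr::inner_join(
    lv, co$truth$edit_levels,
    by = c("chrom", "pos", sample = "patient", "tissue")
  )
  expect_gt(nrow(carried), 0)
  expect_true(all(abs(carried$level.x - 0.30) < 0.05))
})

test_that("symmetric tumor/normal level distributions give balanced over/under counts", {
  # same Beta in both tissues, no ADAR coupling: over and under events are
  # exchangeable, so pooled counts should not be grossly asymmetric
  overs <- unders <- 0
  for (s in 1:4) {
    co <- simulate_cohort(small_config(
      100 + s, n_edit_sites = 40, adar_coupling = 0,
      recurrence_profile = c("8" = 1), n_snps = 0, n_somatic = 0,
      n_background = 0
    ))
    lv <- editing_level_matrix(co$counts, co$truth$edits)
    ov <- patient_overediting(lv)
    overs <- overs + sum(ov$patients$n_over)
    unders <- unders + sum(ov$patients$n_under)
  }
  total <- overs + unders
  expect_gt(total, 100)
  # two-sided binomial 4-sigma band around 1/2
  expect_lt(abs(overs / total - 0.5), 4 * sqrt(0.25 / total))
})

test_that("a strand-bias artifact in edit-supporting reads is rejected by the caller", {
  co <- simulate_cohort(small_config(21, seq_error_rate = 0),
                        alt_fwd_prob = 1)
  res <- detect_editing_sites(co)
  sc <- score_against_truth(res, co)
  # with all alt reads on one strand, most edits are lost to the
  # strand-bias filter (low-level sites with few alt reads escape the
  # Fisher test's power)
  expect_lt(sc$sensitivity, 0.5)

  co_ok <- simulate_cohort(small_config(21, seq_error_rate = 0))
  sc_ok <- score_against_truth(detect_editing_sites(co_ok), co_ok)
  expect_gt(sc_ok$sensitivity, 0.85)
  expect_gt(sc_ok$sensitivity - sc$sensitivity, 0.3)
})

test_that("chromatogram simulation honours level, symmetry and argument checks", {
  expect_error(simulate_chromatogram(0.3, noise_sd = -1), "noise_sd")
  expect_error(simulate_chromatogram(1.3), "true_level")
  expect_error(simulate_chromatogram(0.3, context = "CTGACCGTTGA"),
               "centered on an A")

  # true_level 0, no noise: only the tail of the neighboring G peak
  # (~1% of full amplitude) reaches the center window
  tr0 <- simulate_chromatogram(0, noise_sd = 0, seed = 1)
  g_at_center <- peak_height(tr0, tr0$center_index, "G")
  expect_lt(g_at_center, 10)

  # 50/50 editing, no noise: A and G center peaks equal up to neighbor tails
  tr5 <- simulate_chromatogram(0.5, noise_sd = 0, seed = 1)
  expect_lt(
    abs(peak_height(tr5, tr5$center_index, "A") -
          peak_height(tr5, tr5$center_index, "G")),
    10
  )
})

test_that("cohort round-trips through the plain-text writers", {
  co <- simulate_cohort(small_config(3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  counts2 <- read_base_counts(file.path(dir, "base_counts.tsv"))
  expect_equal(nrow(counts2), nrow(co$counts))
  expect_equal(counts2$A_fwd, as.numeric(co$counts$A_fwd))

  tr <- simulate_chromatogram(0.3, noise_sd = 5, seed = 2)
  f <- file.path(dir, "trace.tsv")
  write_trace_tsv(tr, f)
  tr2 <- read_trace_tsv(f)
  expect_equal(tr2$basecalls$base, tr$basecalls$base)
  est1 <- estimate_editing(tr, tr$center_index)
  est2 <- estimate_editing(tr2, tr$center_index)
  expect_equal(est2$estimate, est1$estimate, tolerance = 1e-6)
})
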