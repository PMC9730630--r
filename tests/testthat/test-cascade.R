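make_call <- function(pos, alt = "G", ref = "A", sample = "P01",
                      tissue = "tumor", material = "RNA", vaf = 0.3,
                      alt_count = 10L) {
  tibble::tibble(
    chrom = "chr1", pos = as.integer(pos), ref = ref, alt = alt,
    sample = sample, material = material, tissue = tissue,
    depth = 50L, ref_count = 35L, alt_count = as.integer(alt_count),
    alt_fwd = as.integer(alt_count %/% 2),
    alt_rev = as.integer(alt_count - alt_count %/% 2),
    vaf = vaf, mean_alt_qual = 35, strand_bias_p = 1, filter_status = "PASS"
  )
}

test_that("DNA subtraction removes DNA-supported RNA calls per patient", {
  rna <- dplyr::bind_rows(
    make_call(100),
    make_call(200),
    make_call(100, sample = "P02")
  )
  # P01 tumor DNA supports pos 100 A>G; P02 DNA is clean at 100
  dna <- dplyr::bind_rows(
    make_call(100, material = "DNA", vaf = 0.4, alt_count = 20L),
    make_call(500, material = "DNA", sample = "P02")
  )
  out <- subtract_dna_variants(rna, dna)
  expect_equal(nrow(out), 2)
  expect_false(any(out$sample == "P01" & out$pos == 100))
  expect_equal(removed_calls(out)$pos, 100L)
  expect_equal(removed_calls(out)$removal_reason, "dna_support")

  # weak DNA support below both thresholds does not subtract
  weak_dna <- dplyr::bind_rows(
    make_call(100, material = "DNA", vaf = 0.01, alt_count = 1L),
    make_call(1, material = "DNA", sample = "P02", vaf = 0, alt_count = 0L)
  )
  expect_equal(nrow(subtract_dna_variants(rna, weak_dna)), 3)

  # empty DNA evidence: identity under allow_missing_dna, error otherwise
  expect_error(subtract_dna_variants(rna, dna[0, ]), "no DNA evidence")
  expect_equal(
    nrow(subtract_dna_variants(rna, dna[0, ], allow_missing_dna = TRUE)), 3
  )
})

test_that("known-SNP filter uses a strict MAF threshold and matches the alt allele", {
  calls <- dplyr::bind_rows(
    make_call(100),          # common SNP -> removed
    make_call(200),          # rare catalogue entry -> retained
    make_call(300, alt = "T") # catalogue has G at 300 -> retained
  )
  catalogue <- tibble::tibble(
    chrom = "chr1", pos = c(100L, 200L, 300L), ref = "A",
    alt = c("G", "G", "G"), maf = c(0.10, 0.0005, 0.10)
  )
  out <- filter_known_snps(calls, catalogue)
  expect_equal(sort(out$pos), c(200L, 300L))
  expect_equal(removed_calls(out)$pos, 100L)

  # MAF exactly at the threshold is NOT removed (strict >)
  at <- filter_known_snps(
    make_call(100),
    tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                   maf = 0.001)
  )
  expect_equal(nrow(at), 1)

  # empty catalogue is the identity; malformed MAF rows are skipped
  expect_equal(nrow(filter_known_snps(calls, catalogue[0, ])), 3)
  expect_warning(
    out2 <- filter_known_snps(
      make_call(100),
      tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
                     maf = NA_real_)
    ),
    "malformed MAF"
  )
  expect_equal(nrow(out2), 1)
})

test_that("repeat filtering respects half-open interval boundaries", {
  reps <- tibble::tibble(chrom = "chr1", start = 90L, end = 110L)
  # 1-based point 100 is inside [90, 110); 110 is inside; 90 and 111 are not
  expect_equal(nrow(filter_simple_repeats(make_call(100), reps)), 0)
  expect_equal(nrow(filter_simple_repeats(make_call(110), reps)), 0)
  expect_equal(nrow(filter_simple_repeats(make_call(90), reps)), 1)
  expect_equal(nrow(filter_simple_repeats(make_call(111), reps)), 1)

  # removal fraction equals interval overlap fraction by direct counting
  withr::local_seed(8)
  calls <- make_call(1)[rep(1, 500), ]
  calls$pos <- sample.int(10000, 500)
  reps2 <- tibble::tibble(chrom = "chr1", start = seq(0, 9000, 1000),
                          end = seq(0, 9000, 1000) + 250L)
  out <- filter_simple_repeats(calls, reps2)
  inside <- vapply(calls$pos, function(p) {
    any(p > reps2$start & p <= reps2$end)
  }, logical(1))
  expect_equal(nrow(out), sum(!inside))
})

test_that("Alu partition is exhaustive and non-Alu calls face the dual threshold", {
  alu <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  calls <- dplyr::bind_rows(
    make_call(500, vaf = 0.07),   # Alu, 7%: kept without further filtering
    make_call(1500, vaf = 0.07),  # non-Alu, 7%: removed by the 10% rule
    make_call(1600, vaf = 0.10)   # non-Alu, 10%: kept (inclusive)
  )
  parts <- partition_alu(calls, alu)
  expect_equal(nrow(parts$alu) + nrow(parts$non_alu), nrow(calls))
  expect_equal(parts$alu$pos, 500L)

  withr::local_seed(3)
  reference <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  refined <- filter_non_alu(parts$non_alu, reference)
  expect_equal(refined$pos, 1600L)
  expect_equal(removed_calls(refined)$removal_reason, "non_alu_vaf")
})

test_that("flanking k-mer multiplicity removes sites in duplicated segments", {
  withr::local_seed(14)
  base <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  block <- substring(base, 401, 520) # 120 bp segment
  dup_ref <- paste0(base, block)     # duplicated at the end

  inside_dup <- make_call(460, vaf = 0.5)   # flank wholly inside the segment
  unique_site <- make_call(1000, vaf = 0.5)
  out <- filter_non_alu(dplyr::bind_rows(inside_dup, unique_site), dup_ref)
  expect_equal(out$pos, 1000L)
  expect_equal(removed_calls(out)$removal_reason, "flank_multiplicity")

  # same site against the non-duplicated reference is retained
  out2 <- filter_non_alu(inside_dup, base)
  expect_equal(out2$pos, 460L)

  # sites whose flank runs past the contig end are retained with a warning
  expect_warning(
    out3 <- filter_non_alu(make_call(5, vaf = 0.5), base),
    "contig end"
  )
  expect_equal(nrow(out3), 1)
})

test_that("mismatch classification collapses to the transcribed strand", {
  expect_equal(classify_mismatch("A", "G", "+"), "A-to-G")
  expect_equal(classify_mismatch("T", "C", "-"), "A-to-G")
  expect_equal(classify_mismatch("T", "C", "+"), "T-to-C")
  expect_equal(classify_mismatch("C", "T", "-"), "G-to-A")

  # exhaustive: all 12 ordered pairs x 2 strands map into the 12 types,
  # bijectively per strand
  grid <- tidyr::expand_grid(
    ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
    strand = c("+", "-")
  )
  grid <- grid[grid$ref != grid$alt, ]
  types <- classify_mismatch(grid$ref, grid$alt, grid$strand)
  expect_true(all(types %in% mismatch_types()))
  expect_equal(sort(unique(types[grid$strand == "+"])), sort(mismatch_types()))
  expect_equal(sort(unique(types[grid$strand == "-"])), sort(mismatch_types()))

  # strand involution: complementing both alleles and flipping the strand
  # reproduces the same type
  flipped <- classify_mismatch(
    complement_base(grid$ref), complement_base(grid$alt),
    ifelse(grid$strand == "+", "-", "+")
  )
  expect_equal(flipped, types)
})

test_that("recoding annotation computes codon arithmetic and amino acids", {
  # plus strand: CDS = (ATG)x10, edit at CDS position 22 -> codon 8 M>V
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 0L, end = 60L, strand = "+",
    cds_start = 2L, cds_end = 32L
  )
  reference <- paste0("GG", strrep("ATG", 10), strrep("C", 28))
  ann <- annotate_consequence(
    tibble::tibble(chrom = "chr1", pos = 24L, ref = "A", alt = "G"),
    genes, reference
  )
  expect_equal(ann$region, "CDS")
  expect_equal(ann$cds_pos, 22L)
  expect_equal(ann$codon_index, 8L)
  expect_equal(ann$ref_aa, "M")
  expect_equal(ann$alt_aa, "V")
  expect_false(ann$synonymous)

  # CDS position 1 -> codon 1
  ann1 <- annotate_consequence(
    tibble::tibble(chrom = "chr1", pos = 3L, ref = "A", alt = "G"),
    genes, reference
  )
  expect_equal(ann1$codon_index, 1L)

  # UTR position: region only, no codon fields
  utr <- annotate_consequence(
    tibble::tibble(chrom = "chr1", pos = 2L, ref = "G", alt = "A"),
    genes, reference
  )
  expect_equal(utr$region, "UTR")
  expect_true(is.na(utr$codon_index))

  # minus strand: transcript (ATG)x10 encoded in reverse complement;
  # transcript CDS position 22 -> codon 8, Met -> Val again
  tx <- strrep("ATG", 10)
  ref_minus <- paste0("GG", revcomp(tx), strrep("C", 28))
  genes_m <- dplyr::mutate(genes, strand = "-")
  pos_m <- 32L - 22L + 1L # cds_end - cds_pos + 1
  ann_m <- annotate_consequence(
    tibble::tibble(chrom = "chr1", pos = pos_m, ref = "T", alt = "C"),
    genes_m, ref_minus
  )
  expect_equal(ann_m$codon_index, 8L)
  expect_equal(ann_m$ref_aa, "M")
  expect_equal(ann_m$alt_aa, "V")

  # larger arithmetic: CDS position 1099 -> codon 367
  big_genes <- tibble::tibble(
    gene_id = "g2", chrom = "chr1", start = 0L, end = 1300L, strand = "+",
    cds_start = 10L, cds_end = 1210L
  )
  withr::local_seed(5)
  big_ref <- paste(sample(c("A", "C", "G", "T"), 1400, TRUE), collapse = "")
  ann_big <- annotate_consequence(
    tibble::tibble(chrom = "chr1", pos = 10L + 1099L, ref = "A", alt = "G"),
    big_genes, big_ref
  )
  expect_equal(ann_big$cds_pos, 1099L)
  expect_equal(ann_big$codon_index, 367L)
})

test_that("recurrence counting matches a brute-force tally and supports both units", {
  withr::local_seed(23)
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", start = 0L, end = 5000L, strand = "+",
    cds_start = 100L, cds_end = 4600L
  )
  reference <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  calls <- purrr::map(1:120, function(i) {
    make_call(
      pos = sample(c(500L, 600L, 700L, 800L, 900L), 1),
      sample = sample(sprintf("P%02d", 1:6), 1),
      tissue = sample(c("tumor", "normal"), 1)
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::distinct(pos, sample, tissue, .keep_all = TRUE)

  sites <- assemble_editing_sites(calls, genes, reference)
  brute <- tapply(calls$sample, calls$pos, function(s) length(unique(s)))
  expect_equal(sites$recurrence, as.integer(brute[as.character(sites$pos)]),
               ignore_attr = TRUE)

  sites_sm <- assemble_editing_sites(calls, genes, reference,
                                     recurrence_unit = "sample")
  brute_sm <- tapply(paste(calls$sample, calls$tissue), calls$pos,
                     function(s) length(unique(s)))
  expect_equal(sites_sm$recurrence,
               as.integer(brute_sm[as.character(sites_sm$pos)]),
               ignore_attr = TRUE)
  expect_true(all(sites_sm$recurrence >= sites$recurrence))
})

test_that("with no sequencing error the cascade removes all planted SNVs/SNPs and keeps all planted edits", {
  co <- clean_cohort()
  res <- detect_editing_sites(co)
  sc <- score_against_truth(res, co)
  expect_equal(sc$n_snp_leaked, 0L)
  expect_equal(sc$n_somatic_leaked, 0L)

  # somatic SNVs that were callable in RNA are all removed by the DNA
  # subtraction stage, and no planted edit is removed by it
  rna_calls <- call_variants(
    dplyr::filter(co$counts, material == "RNA"), genes = co$ref$genes
  )
  dna_ev <- call_variants(
    dplyr::filter(co$counts, material == "DNA"), genes = co$ref$genes,
    min_depth = 1, min_vaf = 0, min_baseq = 0, strand_bias_alpha = NULL,
    keep_filtered = TRUE
  )
  surv <- subtract_dna_variants(rna_calls, dna_ev)
  som_keys <- paste(co$truth$somatic$patient, co$truth$somatic$pos,
                    co$truth$somatic$alt)
  expect_false(any(paste(surv$sample, surv$pos, surv$alt) %in% som_keys))
  removed <- removed_calls(surv)
  edit_keys <- paste(co$truth$edits$pos, co$truth$edits$alt)
  expect_false(any(paste(removed$pos, removed$alt) %in% edit_keys))
})
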