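# shared fixtures and independent oracles for the suite

# one base-count row; counts default to 0, mean qualities to 35 where the
# base has reads (override by passing meanQ_* explicitly)
bc_row <- function(ref = "A", ..., chrom = "chr1", pos = 100L,
                   sample = "P01", material = "RNA", tissue = "tumor") {
  vals <- list(...)
  row <- as.list(setNames(rep(0L, 8), rnaeditr:::COUNT_COLS))
  quals <- as.list(setNames(rep(NA_real_, 4), rnaeditr:::QUAL_COLS))
  for (nm in names(vals)) {
    if (nm %in% names(row)) row[[nm]] <- vals[[nm]]
    if (nm %in% names(quals)) quals[[nm]] <- vals[[nm]]
  }
  for (b in c("A", "C", "G", "T")) {
    qn <- paste0("meanQ_", b)
    if (is.na(quals[[qn]]) &&
        (row[[paste0(b, "_fwd")]] + row[[paste0(b, "_rev")]]) > 0) {
      quals[[qn]] <- 35
    }
  }
  tibble::as_tibble(c(
    list(chrom = chrom, pos = pos, ref = ref, sample = sample,
         material = material, tissue = tissue),
    row, quals
  ))
}

# a small, fast cohort configuration used across tests
small_config <- function(seed, ...) {
  args <- list(
    genome_length = 40000, n_genes = 12, n_edit_sites = 30, n_snps = 60,
    n_somatic = 10, n_background = 100, seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# cached expensive fixtures (built once per test run)
.fixture_env <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(cohort_config(seed = 1))
  }
  .fixture_env$cohort
}

default_result <- function() {
  if (is.null(.fixture_env$result)) {
    .fixture_env$result <- detect_editing_sites(default_cohort())
  }
  .fixture_env$result
}

# error-free small cohort for leakage / truth-set checks
clean_cohort <- function() {
  if (is.null(.fixture_env$clean)) {
    .fixture_env$clean <- simulate_cohort(small_config(11, seq_error_rate = 0))
  }
  .fixture_env$clean
}

# ---- independent oracles ------------------------------------------------

# two-sided Fisher exact p for the 2x2 strand table, by direct
# hypergeometric summation (sum of all tables no more probable than the
# observed one, at fixed margins)
fisher_p_enum <- function(ref_f, ref_r, alt_f, alt_r) {
  m <- ref_f + ref_r
  n <- alt_f + alt_r
  k <- ref_f + alt_f
  x <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(ref_f, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force re-check of the four calling constraints, site by site
brute_force_calls <- function(counts, min_depth = 8, min_vaf = 0.05,
                              min_baseq = 20, alpha = 0.05) {
  keys <- character(0)
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    depth <- sum(vapply(rnaeditr:::COUNT_COLS, function(cn) row[[cn]],
                        numeric(1)))
    for (alt in setdiff(c("A", "C", "G", "T"), row$ref)) {
      af <- row[[paste0(alt, "_fwd")]]
      ar <- row[[paste0(alt, "_rev")]]
      ac <- af + ar
      if (ac == 0) next
      rf <- row[[paste0(row$ref, "_fwd")]]
      rr <- row[[paste0(row$ref, "_rev")]]
      vaf <- ac / (rf + rr + ac)
      q <- row[[paste0("meanQ_", alt)]]
      ok <- depth >= min_depth && vaf >= min_vaf && !is.na(q) && q >= min_baseq
      if (ok && ac >= 2) {
        ok <- fisher_p_enum(rf, rr, af, ar) >= alpha
      }
      if (ok) {
        keys <- c(keys, paste(row$chrom, row$pos, row$sample, row$material,
                              row$tissue, alt))
      }
    }
  }
  sort(keys)
}

call_keys <- function(calls) {
  sort(paste(calls$chrom, calls$pos, calls$sample, calls$material,
             calls$tissue, calls$alt))
}

# independent set-algebra recomputation of the whole cascade, base R only
oracle_cascade_keys <- function(rna_calls, dna_evidence, snps, repeats, alu,
                                reference, min_alt_reads = 2,
                                min_dna_vaf = 0.02, maf_threshold = 0.001,
                                non_alu_min_vaf = 0.10, k = 50) {
  key <- function(df) paste(df$sample, df$chrom, df$pos, df$alt)
  dna_keep <- dna_evidence$alt_count >= min_alt_reads |
    dna_evidence$vaf >= min_dna_vaf
  dna_keys <- unique(key(dna_evidence[dna_keep, ]))
  snp_keys <- unique(paste(snps$chrom[snps$maf > maf_threshold],
                           snps$pos[snps$maf > maf_threshold],
                           snps$alt[snps$maf > maf_threshold]))
  in_iv <- function(pos, iv) {
    any(pos > iv$start & pos <= iv$end)
  }
  # exhaustive k-mer table of the reference, both orientations
  L <- nchar(reference)
  starts <- 1:(L - k + 1)
  kmers <- substring(reference, starts, starts + k - 1)
  kmer_count <- function(pat) {
    sum(kmers == pat) + sum(kmers == rnaeditr::revcomp(pat))
  }
  out <- character(0)
  for (i in seq_len(nrow(rna_calls))) {
    cl <- rna_calls[i, ]
    if (key(cl) %in% dna_keys) next
    if (paste(cl$chrom, cl$pos, cl$alt) %in% snp_keys) next
    if (nrow(repeats) > 0 && in_iv(cl$pos, repeats)) next
    is_alu <- nrow(alu) > 0 && in_iv(cl$pos, alu)
    if (!is_alu) {
      if (cl$vaf < non_alu_min_vaf) next
      st <- cl$pos - k %/% 2 + 1
      if (st >= 1 && st + k - 1 <= L) {
        if (kmer_count(substring(reference, st, st + k - 1)) > 1) next
      }
    }
    out <- c(out, paste(cl$sample, cl$chrom, cl$pos, cl$alt, cl$tissue))
  }
  sort(out)
}
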