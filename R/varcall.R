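#' Two-sided Fisher exact test for allele strand bias
#'
#' Tests whether alternate-supporting reads are distributed across forward
#' and reverse strands differently from reference reads, using the exact
#' two-sided Fisher test on the 2x2 table \{ref, alt\} x \{fwd, rev\}.
#' Vectorised over the rows of a base-count table. Sites with no alternate
#' reads return 1 (no evidence of bias).
#'
#' @param counts Base-count tibble (see [simulate_cohort()] for the column
#'   dialect: `A_fwd..T_fwd`, `A_rev..T_rev`, `ref`).
#' @param alt Character vector of alternate bases, recycled to
#'   `nrow(counts)`.
#' @return Numeric vector of two-sided p-values.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   ref = "A", A_fwd = 20, C_fwd = 0, G_fwd = 10, T_fwd = 0,
#'   A_rev = 20, C_rev = 0, G_rev = 0, T_rev = 0,
#'   meanQ_A = 35, meanQ_C = NA, meanQ_G = 35, meanQ_T = NA
#' )
#' strand_bias_test(tbl, "G")
strand_bias_test <- function(counts, alt) {
  n <- nrow(counts)
  alt <- rep_len(alt, n)
  ref_f <- count_at(counts, counts$ref, "fwd")
  ref_r <- count_at(counts, counts$ref, "rev")
  alt_f <- count_at(counts, alt, "fwd")
  alt_r <- count_at(counts, alt, "rev")
  vapply(seq_len(n), function(i) {
    if (alt_f[i] + alt_r[i] == 0) return(1)
    if (ref_f[i] + ref_r[i] + alt_f[i] + alt_r[i] == 0) return(1)
    fisher.test(matrix(c(ref_f[i], ref_r[i], alt_f[i], alt_r[i]), 2,
                       byrow = TRUE))$p.value
  }, numeric(1))
}

count_at <- function(counts, base, strand) {
  m <- as.matrix(counts[paste0(BASES, "_", strand)])
  m[cbind(seq_len(nrow(counts)), match(base, BASES))]
}

qual_at <- function(counts, base) {
  m <- as.matrix(counts[paste0("meanQ_", BASES)])
  m[cbind(seq_len(nrow(counts)), match(base, BASES))]
}

#' Call candidate variants from per-site base counts
#'
#' A transparent threshold caller over stranded base counts, applying the
#' four detection constraints used for putative RNA-variant discovery:
#' total depth of at least `min_depth` (8x), variant allele frequency of at
#' least `min_vaf` (5%), mean alternate base quality of at least
#' `min_baseq` (Phred 20), and no strand bias (two-sided Fisher exact
#' p >= `strand_bias_alpha` on the ref/alt x fwd/rev table; the test is
#' skipped when fewer than 2 alternate reads are present). Calling is
#' restricted to annotated gene territory when `genes` is supplied. VAF is
#' defined as alt/(ref+alt); a site with several non-reference alleles is
#' evaluated once per allele. All comparisons are inclusive (VAF exactly
#' 0.05 passes, depth exactly 8 passes).
#'
#' @param counts Base-count tibble; rows with negative counts are an
#'   error, rows with a `ref` outside A/C/G/T are skipped with a warning.
#' @param genes Optional gene tibble (`chrom, start, end` 0-based
#'   half-open); rows outside all genes are dropped before calling.
#' @param min_depth,min_vaf,min_baseq Detection thresholds.
#' @param strand_bias_alpha Significance level for the strand-bias
#'   rejection; `NULL` disables the test (and skips computing it).
#' @param keep_filtered Keep failing candidate alleles with a
#'   `filter_status` reason instead of dropping them.
#' @return Tibble of calls: `chrom, pos, ref, alt, sample, material,
#'   tissue, depth, ref_count, alt_count, alt_fwd, alt_rev, vaf,
#'   mean_alt_qual, strand_bias_p, filter_status`.
#' @export
call_variants <- function(counts, genes = NULL,
                          min_depth = 8, min_vaf = 0.05, min_baseq = 20,
                          strand_bias_alpha = 0.05,
                          keep_filtered = FALSE) {
  cnt_mat <- as.matrix(counts[COUNT_COLS])
  if (any(cnt_mat < 0, na.rm = TRUE)) abort("negative base counts")
  bad_ref <- !counts$ref %in% BASES
  if (any(bad_ref)) {
    warn(sprintf("skipping %d records with unknown reference base", sum(bad_ref)))
    counts <- counts[!bad_ref, ]
  }
  if (!is.null(genes)) {
    keep <- point_in_intervals(counts$chrom, counts$pos, genes)
    counts <- counts[keep, ]
  }
  if (nrow(counts) == 0) return(empty_calls())

  depth <- rowSums(as.matrix(counts[COUNT_COLS]))

  # one candidate row per (site record, non-reference allele with >0 reads)
  cand <- map(BASES, function(b) {
    alt_count <- count_at(counts, rep(b, nrow(counts)), "fwd") +
      count_at(counts, rep(b, nrow(counts)), "rev")
    idx <- which(counts$ref != b & alt_count > 0)
    if (length(idx) == 0) return(NULL)
    tibble(row = idx, alt = b)
  }) |>
    bind_rows()
  if (is.null(cand) || nrow(cand) == 0) return(empty_calls())

  sub <- counts[cand$row, ]
  ref_count <- count_at(sub, sub$ref, "fwd") + count_at(sub, sub$ref, "rev")
  alt_fwd <- count_at(sub, cand$alt, "fwd")
  alt_rev <- count_at(sub, cand$alt, "rev")
  alt_count <- alt_fwd + alt_rev
  vaf <- alt_count / (ref_count + alt_count)
  mean_alt_qual <- qual_at(sub, cand$alt)
  d <- depth[cand$row]

  status <- rep("PASS", nrow(sub))
  fail <- function(cond, reason) {
    status <<- ifelse(cond & status == "PASS", reason, status)
  }
  fail(d < min_depth, "min_depth")
  fail(vaf < min_vaf, "min_vaf")
  fail(is.na(mean_alt_qual) | mean_alt_qual < min_baseq, "min_baseq")

  sb_p <- rep(NA_real_, nrow(sub))
  if (!is.null(strand_bias_alpha)) {
    # only test candidates still alive with >=2 alt reads (cheap + per design)
    need <- which(status == "PASS" & alt_count >= 2)
    if (length(need) > 0) {
      sb_p[need] <- strand_bias_test(sub[need, ], cand$alt[need])
    }
    fail(!is.na(sb_p) & sb_p < strand_bias_alpha, "strand_bias")
  }

  out <- tibble(
    chrom = sub$chrom, pos = sub$pos, ref = sub$ref, alt = cand$alt,
    sample = sub$sample, material = sub$material, tissue = sub$tissue,
    depth = as.integer(d), ref_count = as.integer(ref_count),
    alt_count = as.integer(alt_count),
    alt_fwd = as.integer(alt_fwd), alt_rev = as.integer(alt_rev),
    vaf = vaf, mean_alt_qual = mean_alt_qual, strand_bias_p = sb_p,
    filter_status = status
  )
  if (!keep_filtered) out <- filter(out, .data$filter_status == "PASS")
  arrange(out, .data$pos, .data$sample, .data$tissue, .data$alt)
}

empty_calls <- function() {
  tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), sample = character(), material = character(),
    tissue = character(), depth = integer(), ref_count = integer(),
    alt_count = integer(), alt_fwd = integer(), alt_rev = integer(),
    vaf = numeric(), mean_alt_qual = numeric(), strand_bias_p = numeric(),
    filter_status = character()
  )
}
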