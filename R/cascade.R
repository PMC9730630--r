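#' Editing filter cascade
#'
#' After candidate RNA variants are called, a multi-stage cascade removes
#' everything with a DNA-level explanation or an artifact signature:
#' DNA-supported variants (somatic SNVs and residual germline), known SNPs
#' above an MAF threshold, simple-repeat variants, and — for variants
#' outside Alu elements — a stricter VAF threshold plus a
#' flanking-sequence uniqueness check. Each stage returns the surviving
#' calls and records what it removed in a `removed` attribute retrievable
#' with [removed_calls()].
#'
#' @name cascade
NULL

with_removed <- function(kept, removed, reason) {
  if (nrow(removed) > 0) removed$removal_reason <- reason
  attr(kept, "removed") <- removed
  kept
}

#' Retrieve the calls removed by a cascade stage
#'
#' @param calls The tibble returned by a cascade filter.
#' @return Tibble of removed calls with a `removal_reason` column (empty
#'   when nothing was removed).
#' @export
removed_calls <- function(calls) {
  attr(calls, "removed") %||% tibble()
}

#' Remove RNA calls with DNA-level support in the same patient
#'
#' Drops every RNA call whose (site, alt allele) shows alternate support
#' in that patient's DNA — in either tissue — thereby removing somatic
#' SNVs (tumor DNA) and residual germline variants (both DNAs). DNA
#' support means at least `min_alt_reads` alternate reads or a DNA VAF of
#' at least `min_dna_vaf`; pass the permissively-called DNA evidence (e.g.
#' `call_variants(..., min_vaf = 0, min_baseq = 0, keep_filtered = TRUE)`)
#' so weakly supported DNA alleles are visible to the subtraction.
#'
#' @param rna_calls,dna_calls Call tibbles from [call_variants()]; both
#'   keyed by `sample`, `chrom`, `pos`, `alt`.
#' @param min_alt_reads,min_dna_vaf DNA support thresholds.
#' @param allow_missing_dna If `FALSE` (default), a patient with RNA calls
#'   but no DNA rows at all is an error.
#' @return Surviving RNA calls (removed set in `removed_calls()`).
#' @export
subtract_dna_variants <- function(rna_calls, dna_calls,
                                  min_alt_reads = 2, min_dna_vaf = 0.02,
                                  allow_missing_dna = FALSE) {
  if (!allow_missing_dna) {
    missing <- setdiff(unique(rna_calls$sample), unique(dna_calls$sample))
    if (length(missing) > 0 && nrow(rna_calls) > 0) {
      abort(paste0(
        "patients with RNA calls but no DNA evidence: ",
        paste(missing, collapse = ", "),
        " (use `allow_missing_dna = TRUE` to override)"
      ))
    }
  }
  support <- dna_calls |>
    filter(.data$alt_count >= min_alt_reads | .data$vaf >= min_dna_vaf) |>
    distinct(.data$sample, .data$chrom, .data$pos, .data$alt)
  hit <- rna_calls |>
    semi_join(support, by = c("sample", "chrom", "pos", "alt"))
  kept <- rna_calls |>
    anti_join(support, by = c("sample", "chrom", "pos", "alt"))
  with_removed(kept, hit, "dna_support")
}

#' Remove calls at known SNP positions above an MAF threshold
#'
#' Calls whose (position, alt allele) matches a catalogue entry with minor
#' allele frequency strictly greater than `maf_threshold` are removed;
#' entries at or below the threshold do not remove anything. Catalogue
#' rows with malformed (non-finite) MAF are skipped with a warning.
#'
#' @param calls Call tibble.
#' @param snp_catalogue Tibble `chrom, pos, ref, alt, maf`.
#' @param maf_threshold Strict lower MAF bound for removal (default
#'   0.001).
#' @return Surviving calls (removed set in `removed_calls()`).
#' @export
filter_known_snps <- function(calls, snp_catalogue, maf_threshold = 0.001) {
  if (is.null(snp_catalogue) || nrow(snp_catalogue) == 0) {
    return(with_removed(calls, calls[0, ], "known_snp"))
  }
  bad <- !is.finite(snp_catalogue$maf)
  if (any(bad)) {
    warn(sprintf("skipping %d catalogue entries with malformed MAF", sum(bad)))
    snp_catalogue <- snp_catalogue[!bad, ]
  }
  hot <- snp_catalogue |>
    filter(.data$maf > maf_threshold) |>
    distinct(.data$chrom, .data$pos, .data$alt)
  hit <- semi_join(calls, hot, by = c("chrom", "pos", "alt"))
  kept <- anti_join(calls, hot, by = c("chrom", "pos", "alt"))
  with_removed(kept, hit, "known_snp")
}

#' Remove calls inside simple-repeat intervals
#'
#' @param calls Call tibble (1-based positions).
#' @param repeat_intervals Tibble `chrom, start, end`, 0-based half-open.
#' @return Surviving calls (removed set in `removed_calls()`).
#' @export
filter_simple_repeats <- function(calls, repeat_intervals) {
  inside <- point_in_intervals(calls$chrom, calls$pos, repeat_intervals)
  with_removed(calls[!inside, ], calls[inside, ], "simple_repeat")
}

#' Partition calls into Alu and non-Alu groups
#'
#' The partition is exact and exhaustive: every input call lands in
#' exactly one group. Variants in Alu elements receive no further
#' stringent filtering; the non-Alu group goes through
#' [filter_non_alu()].
#'
#' @param calls Call tibble.
#' @param alu_intervals Tibble `chrom, start, end`, 0-based half-open.
#' @return List with tibbles `alu` and `non_alu`.
#' @export
partition_alu <- function(calls, alu_intervals) {
  inside <- point_in_intervals(calls$chrom, calls$pos, alu_intervals)
  list(alu = calls[inside, ], non_alu = calls[!inside, ])
}

#' Stringent refinement of non-Alu calls
#'
#' Non-Alu candidates must clear a higher VAF threshold (10% rather than
#' the 5% used at calling) and must not sit in a region similar to other
#' parts of the genome. Similarity is assessed by an exact flanking k-mer
#' multiplicity check: the `k`-mer centered on the site must occur exactly
#' once in the reference (counting both orientations). Sites whose flank
#' extends past a contig end are retained with a warning.
#'
#' @param calls Non-Alu call tibble.
#' @param reference Reference sequence (character scalar or
#'   `Biostrings::DNAString`), single contig.
#' @param min_vaf Stringent VAF threshold (default 0.10).
#' @param k Flank width in bases (default 50, centered on the site).
#' @param uniqueness_check Set `FALSE` to skip the k-mer stage (e.g. when
#'   an external mappability track is applied instead).
#' @return Surviving calls (removed set in `removed_calls()`).
#' @export
filter_non_alu <- function(calls, reference, min_vaf = 0.10, k = 50,
                           uniqueness_check = TRUE) {
  low <- calls$vaf < min_vaf
  kept <- calls[!low, ]
  removed <- calls[low, ]
  if (nrow(removed) > 0) removed$removal_reason <- "non_alu_vaf"

  if (uniqueness_check && nrow(kept) > 0) {
    dup <- flank_is_duplicated(kept$chrom, kept$pos, reference, k)
    rem2 <- kept[dup, ]
    if (nrow(rem2) > 0) rem2$removal_reason <- "flank_multiplicity"
    kept <- kept[!dup, ]
    removed <- bind_rows(removed, rem2)
  }
  attr(kept, "removed") <- removed
  kept
}

# TRUE when the k-mer centered at pos occurs more than once in the
# reference, counting forward hits and reverse-complement hits
flank_is_duplicated <- function(chrom, pos, reference, k) {
  ref_chr <- as.character(reference)
  ref_dna <- Biostrings::DNAString(ref_chr)
  L <- length(ref_dna)
  if (k > L) {
    warn("flank width exceeds contig length; uniqueness check skipped")
    return(rep(FALSE, length(pos)))
  }
  start <- pos - k %/% 2 + 1L
  end <- start + k - 1L
  in_range <- start >= 1L & end <= L
  if (any(!in_range)) {
    warn(sprintf(
      "%d sites too close to a contig end for a %d-bp flank; retained",
      sum(!in_range), k
    ))
  }
  out <- rep(FALSE, length(pos))
  idx <- which(in_range)
  if (length(idx) == 0) return(out)
  u <- !duplicated(start[idx])
  ustart <- start[idx][u]
  uend <- end[idx][u]
  pats <- Biostrings::DNAStringSet(substring(ref_chr, ustart, uend))
  fwd_hits <- Biostrings::countPDict(Biostrings::PDict(pats), ref_dna)
  rc_hits <- Biostrings::countPDict(
    Biostrings::PDict(Biostrings::reverseComplement(pats)), ref_dna
  )
  dup_u <- (as.integer(fwd_hits) + as.integer(rc_hits)) > 1
  names(dup_u) <- as.character(ustart)
  out[idx] <- dup_u[as.character(start[idx])]
  out
}
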