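#' Run the full editing-site discovery pipeline on a cohort
#'
#' End-to-end wrapper: calls RNA variants with the discovery thresholds
#' (depth >= 8, VAF >= 5%, base quality >= 20, no strand bias), gathers
#' permissive DNA evidence, then applies the cascade — DNA subtraction,
#' known-SNP filter, simple-repeat filter, Alu partition, stringent
#' non-Alu refinement (VAF >= 10% plus flanking-sequence uniqueness) —
#' and assembles cohort-level editing sites with recurrence, mismatch
#' type, recoding consequence, Alu/repeat/catalogue flags and conservation
#' scores.
#'
#' @param counts Base-count tibble holding both materials (`material`
#'   column with `"DNA"` and `"RNA"` rows), or a `synthetic_cohort` (its
#'   counts, bundle and catalogue are then used directly).
#' @param ref Reference bundle from [generate_reference()] (ignored when
#'   `counts` is a `synthetic_cohort`).
#' @param db_sites Known-editing catalogue tibble (optional).
#' @param min_depth,min_vaf,min_baseq,strand_bias_alpha RNA calling
#'   thresholds (see [call_variants()]).
#' @param non_alu_min_vaf,flank_k Stringent non-Alu thresholds (see
#'   [filter_non_alu()]).
#' @param maf_threshold Known-SNP MAF threshold.
#' @param recurrence_unit Passed to [assemble_editing_sites()].
#' @return A list of class `editing_result` with `sites` (the
#'   [assemble_editing_sites()] table), `calls` (surviving per-sample
#'   calls), and `log` (tibble of per-stage removal counts).
#' @export
#' @examples
#' cfg <- cohort_config(
#'   genome_length = 30000, n_genes = 8, n_edit_sites = 12, n_snps = 20,
#'   n_somatic = 5, n_background = 40, seed = 3
#' )
#' res <- detect_editing_sites(simulate_cohort(cfg))
#' res$log
detect_editing_sites <- function(counts, ref = NULL, db_sites = NULL,
                                 min_depth = 8, min_vaf = 0.05,
                                 min_baseq = 20, strand_bias_alpha = 0.05,
                                 non_alu_min_vaf = 0.10, flank_k = 50,
                                 maf_threshold = 0.001,
                                 recurrence_unit = "patient") {
  if (inherits(counts, "synthetic_cohort")) {
    ref <- counts$ref
    db_sites <- db_sites %||% counts$db_sites
    counts <- counts$counts
  }
  if (is.null(ref)) abort("a reference bundle is required")

  rna <- filter(counts, .data$material == "RNA")
  dna <- filter(counts, .data$material == "DNA")

  rna_calls <- call_variants(
    rna, genes = ref$genes,
    min_depth = min_depth, min_vaf = min_vaf, min_baseq = min_baseq,
    strand_bias_alpha = strand_bias_alpha
  )
  dna_evidence <- call_variants(
    dna, genes = ref$genes,
    min_depth = 1, min_vaf = 0, min_baseq = 0,
    strand_bias_alpha = NULL, keep_filtered = TRUE
  )

  log <- list()
  note <- function(stage, before, after) {
    log[[length(log) + 1]] <<- tibble(
      stage = stage, n_in = nrow(before), n_out = nrow(after),
      n_removed = nrow(before) - nrow(after)
    )
  }

  s1 <- subtract_dna_variants(rna_calls, dna_evidence)
  note("dna_subtraction", rna_calls, s1)
  s2 <- filter_known_snps(s1, ref$snps, maf_threshold)
  note("known_snps", s1, s2)
  s3 <- filter_simple_repeats(s2, ref$repeats)
  note("simple_repeats", s2, s3)
  parts <- partition_alu(s3, ref$alu)
  s4 <- filter_non_alu(
    parts$non_alu, ref$reference, min_vaf = non_alu_min_vaf, k = flank_k
  )
  note("non_alu_stringent", parts$non_alu, s4)
  surviving <- bind_rows(parts$alu, s4) |>
    arrange(.data$pos, .data$sample, .data$tissue)

  sites <- assemble_editing_sites(
    surviving, ref$genes, ref$reference,
    alu = ref$alu, repeats = ref$repeats,
    db_sites = db_sites, conservation = ref$conservation,
    recurrence_unit = recurrence_unit
  )

  structure(
    list(sites = sites, calls = surviving, log = bind_rows(log)),
    class = "editing_result"
  )
}

#' @export
print.editing_result <- function(x, ...) {
  cat("<editing_result>\n")
  cat(sprintf(
    "  %d putative editing sites from %d surviving calls\n",
    nrow(x$sites), nrow(x$calls)
  ))
  print(x$log)
  invisible(x)
}

#' @rdname detect_editing_sites
#' @param x An `editing_result`.
#' @param ... Unused.
#' @method tidy editing_result
#' @export
tidy.editing_result <- function(x, ...) {
  out <- x$sites
  attr(out, "calls") <- NULL
  class(out) <- setdiff(class(out), "editing_sites")
  out
}

#' @rdname detect_editing_sites
#' @method glance editing_result
#' @export
glance.editing_result <- function(x, ...) {
  s <- x$sites
  tibble(
    n_sites = nrow(s),
    n_singleton = sum(s$recurrence == 1),
    n_recurrent = sum(s$recurrence >= 2),
    n_a_to_g = sum(s$mismatch_type == "A-to-G", na.rm = TRUE),
    n_alu = sum(s$is_alu),
    n_db_known = sum(s$db_known)
  )
}

#' Compare a detection result with the planted truth of a synthetic cohort
#'
#' @param result An `editing_result`.
#' @param cohort The `synthetic_cohort` it was computed from.
#' @return One-row tibble with `n_truth, n_called, n_recovered,
#'   sensitivity, precision, n_snp_leaked, n_somatic_leaked`.
#' @export
score_against_truth <- function(result, cohort) {
  truth <- cohort$truth
  called <- site_key(result$sites$chrom, result$sites$pos, result$sites$alt)
  planted <- site_key(truth$edits$chrom, truth$edits$pos, truth$edits$alt)
  snp_keys <- site_key(truth$snps$chrom, truth$snps$pos, truth$snps$alt)
  som_keys <- site_key(truth$somatic$chrom, truth$somatic$pos,
                       truth$somatic$alt)
  tibble(
    n_truth = length(planted),
    n_called = length(called),
    n_recovered = sum(planted %in% called),
    sensitivity = sum(planted %in% called) / length(planted),
    precision = if (length(called) > 0) {
      sum(called %in% planted) / length(called)
    } else {
      NA_real_
    },
    n_snp_leaked = sum(called %in% snp_keys),
    n_somatic_leaked = sum(called %in% som_keys)
  )
}
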