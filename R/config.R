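#' Configuration for a synthetic paired tumor/normal editing cohort
#'
#' Bundles every knob of the synthetic cohort generator. The defaults
#' describe the emulated study design: 15 patients with paired tumor and
#' non-tumor tissue, whole-exome-like DNA and RNA-seq-like base counts at
#' mean 50x Poisson depth, a per-base sequencing error of 1e-3, 200 planted
#' A-to-I sites (90% singletons), 500 germline SNPs spanning the 0.001 MAF
#' threshold, and 50 somatic SNVs.
#'
#' Editing levels are drawn per site/patient from Beta distributions
#' (`edit_level_normal`, `edit_level_tumor` are `c(shape1, shape2)` pairs;
#' the default Beta(2, 6) has mean 0.25, typical of protein-coding A-to-I
#' sites). A patient's tumor level is additionally shifted by
#' `adar_coupling` times the patient's standardised log ADAR1-p110 tumor
#' expression, which couples editing burden to ADAR1 the way over-editing
#' couples to ADAR1 amplification; set `adar_coupling = 0` for a null
#' cohort.
#'
#' @param n_patients Number of patients (each contributes tumor + normal
#'   tissue, DNA + RNA material).
#' @param genome_length Reference length in bases (single contig).
#' @param n_genes,gene_length,cds_length Gene-model geometry; CDS length
#'   must be a multiple of 3 and fit inside the gene with UTR margin.
#' @param alu_fraction Fraction of gene territory covered by Alu intervals.
#' @param repeat_fraction Fraction covered by simple repeats.
#' @param n_edit_sites,n_snps,n_somatic Planted event counts.
#' @param depth_mean_dna,depth_mean_rna Poisson mean per-site depths.
#' @param seq_error_rate Per-base probability a read reports a wrong base.
#' @param edit_level_normal,edit_level_tumor Beta shape pairs for true
#'   editing levels in normal and tumor tissue.
#' @param adar_coupling Slope linking standardised log ADAR1-p110 tumor
#'   expression to the patient's tumor editing-level shift.
#' @param recurrence_profile Named probability vector; names are numbers of
#'   carrier patients, values the probability a planted site has that many
#'   carriers (clamped to `n_patients`).
#' @param utr_edit_fraction Fraction of planted edits placed in UTRs rather
#'   than CDS.
#' @param neighbor_ct_bias Probability that a planted site's 5' neighbor
#'   (transcribed strand) is C or T, emulating the ADAR sequence preference
#'   in which CAG/TAG contexts predominate.
#' @param db_rate_singleton,db_rate_recurrent Probability a planted
#'   singleton / recurrent site is listed in the known-editing catalogue.
#' @param n_background Number of additional unedited gene positions with
#'   error-only base counts (false-positive fodder).
#' @param seed Integer seed; required by the generator functions
#'   (reproducibility contract).
#'
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_patients
cohort_config <- function(n_patients = 15,
                          genome_length = 200000L,
                          n_genes = 60L,
                          gene_length = 2000L,
                          cds_length = 1500L,
                          alu_fraction = 0.30,
                          repeat_fraction = 0.05,
                          n_edit_sites = 200L,
                          n_snps = 500L,
                          n_somatic = 50L,
                          depth_mean_dna = 50,
                          depth_mean_rna = 50,
                          seq_error_rate = 1e-3,
                          edit_level_normal = c(2, 6),
                          edit_level_tumor = c(2, 6),
                          adar_coupling = 0.08,
                          recurrence_profile = c(
                            "1" = 0.90, "2" = 0.05, "3" = 0.03,
                            "5" = 0.01, "15" = 0.01
                          ),
                          utr_edit_fraction = 0.10,
                          neighbor_ct_bias = 0.70,
                          db_rate_singleton = 0.12,
                          db_rate_recurrent = 0.60,
                          n_background = 1000L,
                          seed = NULL) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    genome_length = as.integer(genome_length),
    n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length),
    cds_length = as.integer(cds_length),
    alu_fraction = alu_fraction,
    repeat_fraction = repeat_fraction,
    n_edit_sites = as.integer(n_edit_sites),
    n_snps = as.integer(n_snps),
    n_somatic = as.integer(n_somatic),
    depth_mean_dna = depth_mean_dna,
    depth_mean_rna = depth_mean_rna,
    seq_error_rate = seq_error_rate,
    edit_level_normal = edit_level_normal,
    edit_level_tumor = edit_level_tumor,
    adar_coupling = adar_coupling,
    recurrence_profile = recurrence_profile,
    utr_edit_fraction = utr_edit_fraction,
    neighbor_ct_bias = neighbor_ct_bias,
    db_rate_singleton = db_rate_singleton,
    db_rate_recurrent = db_rate_recurrent,
    n_background = as.integer(n_background),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  counts <- c(
    "n_patients", "genome_length", "n_genes", "gene_length", "cds_length",
    "n_edit_sites", "n_snps", "n_somatic", "n_background"
  )
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0) {
      abort(paste0("`", f, "` must be a single non-negative count"))
    }
  }
  probs <- c(
    "alu_fraction", "repeat_fraction", "seq_error_rate",
    "utr_edit_fraction", "neighbor_ct_bias",
    "db_rate_singleton", "db_rate_recurrent"
  )
  for (f in probs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("`", f, "` must lie in [0, 1]"))
    }
  }
  if (cfg$depth_mean_dna <= 0 || cfg$depth_mean_rna <= 0) {
    abort("mean depths must be positive")
  }
  if (cfg$cds_length %% 3L != 0L) {
    abort("`cds_length` must be a multiple of 3")
  }
  if (cfg$cds_length + 60L > cfg$gene_length) {
    abort("`gene_length` must exceed `cds_length` by at least 60 (UTR margin)")
  }
  if (cfg$n_genes * cfg$gene_length > cfg$genome_length) {
    abort(
      "impossible geometry: gene territory exceeds genome length",
      class = "rnaeditr_config_error"
    )
  }
  if (any(cfg$edit_level_normal <= 0) || any(cfg$edit_level_tumor <= 0) ||
      length(cfg$edit_level_normal) != 2 || length(cfg$edit_level_tumor) != 2) {
    abort("editing-level Beta parameters must be positive shape pairs")
  }
  rp <- cfg$recurrence_profile
  if (is.null(names(rp)) || any(is.na(suppressWarnings(as.integer(names(rp))))) ||
      any(rp < 0) || abs(sum(rp) - 1) > 1e-8) {
    abort("`recurrence_profile` must be a named probability vector summing to 1")
  }
  invisible(cfg)
}

require_seed <- function(cfg) {
  if (is.null(cfg$seed)) {
    abort(
      "a `seed` is required in the cohort configuration (reproducibility contract)",
      class = "rnaeditr_seed_error"
    )
  }
  invisible(cfg$seed)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf(
    "  %d patients, genome %s bp, %d genes\n",
    x$n_patients, format(x$genome_length, big.mark = ","), x$n_genes
  ))
  cat(sprintf(
    "  planted: %d edits, %d SNPs, %d somatic; depth %g/%gx; error %g\n",
    x$n_edit_sites, x$n_snps, x$n_somatic,
    x$depth_mean_dna, x$depth_mean_rna, x$seq_error_rate
  ))
  cat(sprintf(
    "  adar_coupling %g; seed %s\n", x$adar_coupling,
    if (is.null(x$seed)) "<unset>" else x$seed
  ))
  invisible(x)
}
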