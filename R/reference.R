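#' Generate a synthetic reference genome and annotation bundle
#'
#' Builds the static scaffolding a cohort simulation needs: a random
#' single-contig reference sequence, single-exon gene models with stranded
#' CDS coordinates, Alu and simple-repeat interval tracks, a germline SNP
#' catalogue whose minor allele frequencies span the 0.001 filter
#' threshold, and a conservation (PhyloP-like) score table for the
#' catalogue positions. `simulate_cohort()` later appends conservation
#' scores for the edit sites it plants, so after cohort simulation the
#' table covers every planted site.
#'
#' All interval tables use 0-based half-open coordinates (BED convention);
#' site tables use 1-based positions (VCF convention). Identical
#' configurations (including seed) produce identical bundles.
#'
#' @param config A [cohort_config()]; its `seed` must be set.
#' @return A list of class `reference_bundle` with elements `reference`
#'   (character scalar), `genes`, `alu`, `repeats`, `snps`, `conservation`
#'   (tibbles) and `config`.
#' @export
#' @examples
#' ref <- generate_reference(cohort_config(
#'   genome_length = 20000, n_genes = 6, n_snps = 20, seed = 1
#' ))
#' ref$genes
generate_reference <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  require_seed(config)
  local_seed(config$seed)

  L <- config$genome_length
  ref_chars <- sample(BASES, L, replace = TRUE)
  reference <- paste(ref_chars, collapse = "")

  # genes: one per equal-width slot, jittered, so they never overlap
  slot <- L %/% config$n_genes
  if (slot <= config$gene_length) {
    abort(
      "impossible geometry: gene territory exceeds genome length",
      class = "rnaeditr_config_error"
    )
  }
  jitter <- sample.int(slot - config$gene_length, config$n_genes, replace = TRUE) - 1L
  gene_start <- (seq_len(config$n_genes) - 1L) * slot + jitter
  utr_margin <- config$gene_length - config$cds_length
  utr5 <- sample.int(utr_margin - 30L, config$n_genes, replace = TRUE) + 15L
  genes <- tibble(
    gene_id = sprintf("gene%03d", seq_len(config$n_genes)),
    chrom = "chr1",
    start = gene_start,
    end = gene_start + config$gene_length,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    cds_start = gene_start + utr5,
    cds_end = gene_start + utr5 + config$cds_length
  )

  alu <- tile_intervals(genes, width = 300L, fraction = config$alu_fraction)
  reps <- tile_intervals(genes, width = 60L, fraction = config$repeat_fraction)

  # SNP catalogue: 80% common (MAF 0.005-0.5), 20% at or below the 0.001
  # threshold, so the MAF filter boundary is genuinely exercised
  gene_pos <- unlist(map2(genes$start + 1L, genes$end, seq.int))
  snp_pos <- sort(sample(gene_pos, min(config$n_snps, length(gene_pos))))
  snp_ref <- ref_chars[snp_pos]
  snp_alt <- map_chr(snp_ref, function(r) sample(setdiff(BASES, r), 1))
  n_snp <- length(snp_pos)
  rare <- runif(n_snp) < 0.2
  maf <- ifelse(rare, runif(n_snp, 1e-4, 1e-3), runif(n_snp, 0.005, 0.5))
  snps <- tibble(
    chrom = "chr1", pos = snp_pos, ref = snp_ref, alt = snp_alt, maf = maf
  )

  conservation <- tibble(
    chrom = "chr1", pos = snp_pos,
    score = rnorm(n_snp, 0.2, 1)
  )

  structure(
    list(
      reference = reference, genes = genes, alu = alu, repeats = reps,
      snps = snps, conservation = conservation, config = config
    ),
    class = "reference_bundle"
  )
}

# carve each gene into `width`-bp blocks and mark blocks as covered with a
# probability that makes the expected covered fraction of the *whole* gene
# equal `fraction` (blocks do not tile the gene remainder)
tile_intervals <- function(genes, width, fraction) {
  if (fraction == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer()
    ))
  }
  out <- pmap(
    list(genes$chrom, genes$start, genes$end),
    function(chrom, start, end) {
      len <- end - start
      n_blocks <- len %/% width
      if (n_blocks == 0) return(NULL)
      p <- min(1, fraction * len / (n_blocks * width))
      keep <- which(runif(n_blocks) < p)
      if (length(keep) == 0) return(NULL)
      block_start <- start + (keep - 1L) * width
      tibble(chrom = chrom, start = block_start, end = block_start + width)
    }
  )
  bind_rows(out)
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle>\n")
  cat(sprintf(
    "  %s bp reference; %d genes; %d Alu / %d repeat intervals; %d SNPs\n",
    format(nchar(x$reference), big.mark = ","), nrow(x$genes),
    nrow(x$alu), nrow(x$repeats), nrow(x$snps)
  ))
  invisible(x)
}
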