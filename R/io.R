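#' Write a synthetic cohort to plain-text files
#'
#' Serialises a cohort to the standard on-disk dialects: the reference as
#' FASTA; gene models, Alu and simple-repeat intervals as BED (0-based
#' half-open; genes carry strand in column 6 and CDS bounds in the
#' thickStart/thickEnd columns); the SNP catalogue as a VCF-like TSV with
#' `MAF=` in the INFO column; base counts, expression, conservation,
#' known-editing catalogue and truth tables as TSV.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- cohort$ref

  dna <- Biostrings::DNAStringSet(ref$reference)
  names(dna) <- "chr1"
  Biostrings::writeXStringSet(dna, file.path(dir, "reference.fa"))

  genes_bed <- ref$genes |>
    transmute(
      .data$chrom, .data$start, .data$end, name = .data$gene_id,
      score = 0L, .data$strand,
      thickStart = .data$cds_start, thickEnd = .data$cds_end
    )
  readr::write_tsv(genes_bed, file.path(dir, "genes.bed"), col_names = FALSE)
  readr::write_tsv(ref$alu, file.path(dir, "alu.bed"), col_names = FALSE)
  readr::write_tsv(ref$repeats, file.path(dir, "simple_repeats.bed"),
                   col_names = FALSE)

  vcf <- ref$snps |>
    transmute(
      `#CHROM` = .data$chrom, POS = .data$pos, ID = ".",
      REF = .data$ref, ALT = .data$alt, QUAL = ".", FILTER = ".",
      INFO = sprintf("MAF=%g", .data$maf)
    )
  readr::write_tsv(vcf, file.path(dir, "snp_catalogue.vcf"))

  readr::write_tsv(cohort$counts, file.path(dir, "base_counts.tsv"))
  readr::write_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  readr::write_tsv(ref$conservation, file.path(dir, "conservation.tsv"))
  readr::write_tsv(cohort$db_sites, file.path(dir, "editing_db_sites.tsv"))
  readr::write_tsv(cohort$truth$edits, file.path(dir, "truth_edits.tsv"))
  readr::write_tsv(cohort$truth$edit_levels,
                   file.path(dir, "truth_edit_levels.tsv"))
  readr::write_tsv(cohort$truth$snps, file.path(dir, "truth_snps.tsv"))
  readr::write_tsv(cohort$truth$somatic, file.path(dir, "truth_somatic.tsv"))
  invisible(dir)
}

#' Read and write base-count tables
#'
#' The base-count TSV dialect has one row per (position, sample,
#' material, tissue) with stranded per-base counts and per-base mean
#' qualities.
#'
#' @param path File path.
#' @return A base-count tibble.
#' @export
read_base_counts <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = "c", pos = "i", ref = "c", sample = "c", material = "c",
      tissue = "c", .default = "d"
    ),
    progress = FALSE
  )
}

#' @rdname read_base_counts
#' @param counts Base-count tibble.
#' @export
write_base_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read and write chromatogram traces as TSV
#'
#' Trace files have columns `index, basecall, chanA, chanC, chanG,
#' chanT`; `basecall` is empty except at basecalled scan points.
#'
#' @param path File path.
#' @return A `chromatogram_trace`.
#' @export
read_trace_tsv <- function(path) {
  tr <- readr::read_tsv(
    path,
    col_types = readr::cols(
      index = "i", basecall = "c", .default = "d"
    ),
    progress = FALSE
  )
  called <- which(!is.na(tr$basecall) & tr$basecall != "")
  if (length(called) == 0) abort("trace has no basecalls")
  if (any(diff(called) <= 0)) abort("basecall indices must strictly increase")
  structure(
    list(
      trace = tr,
      basecalls = tibble(
        base = tr$basecall[called],
        call_index = seq_along(called),
        scan_index = tr$index[called]
      ),
      center_index = NA_integer_
    ),
    class = "chromatogram_trace"
  )
}

#' @rdname read_trace_tsv
#' @param trace A `chromatogram_trace`.
#' @export
write_trace_tsv <- function(trace, path) {
  readr::write_tsv(trace$trace, path)
  invisible(path)
}
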