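#' Classify a mismatch strand-aware into one of the 12 substitution types
#'
#' Mismatch types are the 12 ordered reference-to-alternate base pairs
#' after collapsing to the transcribed strand: for a gene on the minus
#' strand both bases are complemented, so a reference-forward T>C variant
#' in a minus-strand gene is classified "A-to-G" — which is how A-to-I
#' editing (read as G by sequencers) appears.
#'
#' @param ref,alt Reference and alternate bases (reference-forward
#'   orientation), vectorised.
#' @param gene_strand `"+"` or `"-"`, vectorised.
#' @return Character vector of types such as `"A-to-G"`.
#' @export
#' @examples
#' classify_mismatch("A", "G", "+")
#' classify_mismatch("T", "C", "-")
classify_mismatch <- function(ref, alt, gene_strand) {
  stopifnot(all(ref %in% BASES), all(alt %in% BASES),
            all(gene_strand %in% c("+", "-")))
  if (any(ref == alt)) abort("ref and alt must differ")
  r <- ifelse(gene_strand == "-", complement_base(ref), ref)
  a <- ifelse(gene_strand == "-", complement_base(alt), alt)
  paste0(r, "-to-", a)
}

#' All 12 mismatch-type labels
#' @return Character vector of the 12 ordered substitution labels.
#' @export
mismatch_types <- function() {
  grid <- expand_grid(ref = BASES, alt = BASES) |> filter(ref != alt)
  paste0(grid$ref, "-to-", grid$alt)
}

#' Annotate the coding consequence of a variant
#'
#' Maps each variant position onto its gene model: positions inside the
#' CDS get a codon index (`floor((cds_pos - 1)/3) + 1`), the reference and
#' edited codons, the translated amino acids (standard genetic code) and a
#' synonymous flag; positions inside the gene but outside the CDS are
#' `"UTR"` with no codon fields. For minus-strand genes CDS positions
#' count from the CDS 3' genomic end and codons are reverse-complemented
#' before translation.
#'
#' @param sites Tibble with `chrom, pos, ref, alt` (reference-forward).
#' @param genes Gene tibble `gene_id, chrom, start, end, strand,
#'   cds_start, cds_end` (0-based half-open intervals).
#' @param reference Reference sequence (character scalar).
#' @return `sites` with added columns `gene_id, strand, region, cds_pos,
#'   codon_index, ref_codon, alt_codon, ref_aa, alt_aa, synonymous`.
#' @export
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = "g1", chrom = "chr1", start = 0L, end = 40L,
#'   strand = "+", cds_start = 2L, cds_end = 32L
#' )
#' ref <- paste0("GG", strrep("ATG", 10), "CCCCCCCC")
#' # CDS position 22 -> codon 8, ATG (Met) edited to GTG (Val)
#' annotate_consequence(
#'   tibble::tibble(chrom = "chr1", pos = 24L, ref = "A", alt = "G"),
#'   genes, ref
#' )
annotate_consequence <- function(sites, genes, reference) {
  joined <- sites |>
    left_join(genes, by = "chrom", relationship = "many-to-many",
              suffix = c("", ".gene")) |>
    filter(.data$pos > .data$start, .data$pos <= .data$end) |>
    select(-"start", -"end")
  unmatched <- anti_join(
    sites, joined, by = intersect(names(sites), c("chrom", "pos", "ref", "alt"))
  )
  if (nrow(unmatched) > 0) {
    warn(sprintf("%d sites outside annotated genes left unannotated",
                 nrow(unmatched)))
  }

  gc <- Biostrings::GENETIC_CODE
  out <- joined |>
    mutate(
      in_cds = .data$pos > .data$cds_start & .data$pos <= .data$cds_end,
      region = ifelse(.data$in_cds, "CDS", "UTR"),
      cds_pos = ifelse(
        .data$in_cds,
        ifelse(.data$strand == "+",
               .data$pos - .data$cds_start,
               .data$cds_end - .data$pos + 1L),
        NA_integer_
      ),
      codon_index = ifelse(.data$in_cds, (.data$cds_pos - 1L) %/% 3L + 1L,
                           NA_integer_),
      codon_offset = ifelse(.data$in_cds, (.data$cds_pos - 1L) %% 3L + 1L,
                            NA_integer_)
    )

  cds_rows <- which(out$in_cds)
  ref_codon <- alt_codon <- rep(NA_character_, nrow(out))
  if (length(cds_rows) > 0) {
    g_start <- ifelse(
      out$strand[cds_rows] == "+",
      out$cds_start[cds_rows] + (out$codon_index[cds_rows] - 1L) * 3L + 1L,
      out$cds_end[cds_rows] - out$codon_index[cds_rows] * 3L + 1L
    )
    codon_fwd <- substring(reference, g_start, g_start + 2L)
    rc <- out$strand[cds_rows] == "-"
    codon_tx <- codon_fwd
    codon_tx[rc] <- revcomp(codon_fwd[rc])
    alt_tx <- ifelse(rc, complement_base(out$alt[cds_rows]), out$alt[cds_rows])
    edited <- codon_tx
    substr(edited, out$codon_offset[cds_rows], out$codon_offset[cds_rows]) <- alt_tx
    ref_codon[cds_rows] <- codon_tx
    alt_codon[cds_rows] <- edited
  }
  out |>
    mutate(
      ref_codon = ref_codon,
      alt_codon = alt_codon,
      ref_aa = unname(gc[.data$ref_codon]),
      alt_aa = unname(gc[.data$alt_codon]),
      synonymous = ifelse(.data$in_cds, .data$ref_aa == .data$alt_aa, NA)
    ) |>
    select(-"in_cds", -"codon_offset", -"cds_start", -"cds_end")
}

#' Assemble cohort-level putative editing sites from surviving calls
#'
#' Collapses per-sample surviving RNA calls to one record per (position,
#' alternate allele): counts recurrence (distinct patients by default, or
#' distinct patient-tissue samples with `recurrence_unit = "sample"`),
#' classifies the strand-collapsed mismatch type, annotates the coding
#' consequence, and joins Alu / simple-repeat membership, known-editing
#' catalogue membership and conservation scores.
#'
#' @param calls Surviving call tibble (cascade output).
#' @param genes,reference As in [annotate_consequence()].
#' @param alu,repeats Interval tibbles (may be `NULL`).
#' @param db_sites Known-editing catalogue tibble `chrom, pos` (strand
#'   column ignored for membership); may be `NULL`.
#' @param conservation Tibble `chrom, pos, score`; may be `NULL`.
#' @param recurrence_unit `"patient"` (default) or `"sample"`.
#' @return Tibble of class `editing_sites`, one row per site, with the
#'   per-sample calls kept in attribute `"calls"`.
#' @export
assemble_editing_sites <- function(calls, genes, reference,
                                   alu = NULL, repeats = NULL,
                                   db_sites = NULL, conservation = NULL,
                                   recurrence_unit = c("patient", "sample")) {
  recurrence_unit <- match.arg(recurrence_unit)
  if (nrow(calls) == 0) {
    out <- tibble(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), recurrence = integer()
    )
    class(out) <- c("editing_sites", class(out))
    return(out)
  }
  rec <- calls |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(
      recurrence = if (recurrence_unit == "patient") {
        n_distinct(.data$sample)
      } else {
        n_distinct(paste(.data$sample, .data$tissue))
      },
      mean_vaf = mean(.data$vaf),
      .groups = "drop"
    )

  ann <- annotate_consequence(
    select(rec, "chrom", "pos", "ref", "alt"), genes, reference
  )
  out <- rec |>
    left_join(
      select(ann, "chrom", "pos", "ref", "alt", "gene_id", "strand",
             "region", "cds_pos", "codon_index", "ref_codon", "alt_codon",
             "ref_aa", "alt_aa", "synonymous"),
      by = c("chrom", "pos", "ref", "alt")
    ) |>
    mutate(
      mismatch_type = ifelse(
        is.na(.data$strand), NA_character_,
        classify_mismatch(.data$ref, .data$alt, .data$strand)
      ),
      is_alu = point_in_intervals(.data$chrom, .data$pos, alu),
      in_simple_repeat = point_in_intervals(.data$chrom, .data$pos, repeats),
      db_known = if (is.null(db_sites) || nrow(db_sites) == 0) {
        FALSE
      } else {
        paste(.data$chrom, .data$pos) %in% paste(db_sites$chrom, db_sites$pos)
      }
    )
  if (!is.null(conservation) && nrow(conservation) > 0) {
    out <- left_join(
      out, rename(conservation, conservation = "score"),
      by = c("chrom", "pos")
    )
  } else {
    out$conservation <- NA_real_
  }
  out <- arrange(out, .data$pos, .data$alt)
  attr(out, "calls") <- calls
  class(out) <- c("editing_sites", class(out))
  out
}
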