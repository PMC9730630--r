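#' Editing level (variant allele frequency) from base counts
#'
#' The editing level at a site is alt/(ref+alt) over both strands; it is
#' undefined (NA) when fewer than `min_depth` informative (ref+alt) reads
#' cover the site.
#'
#' @param counts Base-count tibble.
#' @param alt Alternate base, recycled over rows.
#' @param min_depth Minimum informative depth for a defined level
#'   (default 8).
#' @return Numeric vector of levels in `[0, 1]`, NA where undefined.
#' @export
editing_level <- function(counts, alt, min_depth = 8) {
  n <- nrow(counts)
  alt <- rep_len(alt, n)
  ref_n <- count_at(counts, counts$ref, "fwd") + count_at(counts, counts$ref, "rev")
  alt_n <- count_at(counts, alt, "fwd") + count_at(counts, alt, "rev")
  informative <- ref_n + alt_n
  ifelse(informative >= min_depth, alt_n / informative, NA_real_)
}

#' Editing-level matrix across sites, patients and tissues
#'
#' Looks up RNA base counts at the given sites and returns the long-form
#' editing-level matrix used by the over-/under-editing and association
#' statistics. Entries with fewer than `min_depth` informative reads are
#' missing.
#'
#' @param counts Base-count tibble (RNA rows are used; a `material`
#'   column, if present, is filtered to `"RNA"`).
#' @param sites Tibble with `chrom, pos, alt` (e.g. an
#'   [assemble_editing_sites()] table or a truth table).
#' @param min_depth Minimum informative depth (default 8).
#' @return Tibble `chrom, pos, alt, sample, tissue, level, informative`.
#' @export
editing_level_matrix <- function(counts, sites, min_depth = 8) {
  if ("material" %in% names(counts)) {
    counts <- filter(counts, .data$material == "RNA")
  }
  sub <- counts |>
    inner_join(
      distinct(sites, .data$chrom, .data$pos, .data$alt),
      by = c("chrom", "pos")
    )
  ref_n <- count_at(sub, sub$ref, "fwd") + count_at(sub, sub$ref, "rev")
  alt_n <- count_at(sub, sub$alt, "fwd") + count_at(sub, sub$alt, "rev")
  informative <- ref_n + alt_n
  tibble(
    chrom = sub$chrom, pos = sub$pos, alt = sub$alt,
    sample = sub$sample, tissue = sub$tissue,
    level = ifelse(informative >= min_depth, alt_n / informative, NA_real_),
    informative = as.integer(informative)
  )
}
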