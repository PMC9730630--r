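#' Singleton / recurrent site summary
#'
#' Counts sites seen in exactly one versus two or more patients and
#' reports the singleton percentage in printed style (one decimal, half
#' away from zero). With the published cohort counts — 373 singletons of
#' 409 sites — this yields 91.2% and 36 recurrent sites.
#'
#' @param sites Editing-site tibble with a `recurrence` column.
#' @return One-row tibble `n_total, n_singleton, singleton_pct,
#'   n_recurrent`.
#' @export
recurrence_summary <- function(sites) {
  n_total <- nrow(sites)
  n_singleton <- sum(sites$recurrence == 1)
  tibble(
    n_total = n_total,
    n_singleton = n_singleton,
    singleton_pct = pct(n_singleton, n_total),
    n_recurrent = n_total - n_singleton
  )
}

#' Mismatch spectrum and annotation fractions
#'
#' Tabulates the 12 strand-collapsed mismatch types and the Alu /
#' known-catalogue membership fractions, over all sites and over the
#' recurrent (seen in >= 2 patients) subset. Percentages are printed-style
#' (one decimal, half away from zero) and reported next to their raw
#' numerators and denominators.
#'
#' @param sites Editing-site tibble with `mismatch_type`, `recurrence`,
#'   `is_alu`, `db_known` columns.
#' @return List with `spectrum` (tibble `scope, mismatch_type, n, pct`)
#'   and `flags` (tibble `scope, n, n_a_to_g, a_to_g_pct, n_alu, alu_pct,
#'   n_db, db_pct`).
#' @export
spectrum_fractions <- function(sites) {
  scopes <- list(all = sites, recurrent = filter(sites, .data$recurrence >= 2))
  spectrum <- imap_rows(scopes, function(df, scope) {
    counts <- table(factor(df$mismatch_type, levels = mismatch_types()))
    tibble(
      scope = scope,
      mismatch_type = names(counts),
      n = as.integer(counts),
      pct = pct(as.integer(counts), nrow(df))
    )
  })
  flags <- imap_rows(scopes, function(df, scope) {
    tibble(
      scope = scope,
      n = nrow(df),
      n_a_to_g = sum(df$mismatch_type == "A-to-G", na.rm = TRUE),
      a_to_g_pct = pct(sum(df$mismatch_type == "A-to-G", na.rm = TRUE), nrow(df)),
      n_alu = sum(df$is_alu),
      alu_pct = pct(sum(df$is_alu), nrow(df)),
      n_db = sum(df$db_known),
      db_pct = pct(sum(df$db_known), nrow(df))
    )
  })
  list(spectrum = spectrum, flags = flags)
}

imap_rows <- function(lst, f) {
  bind_rows(map2(lst, names(lst), f))
}

#' Per-patient over-/under-editing summary
#'
#' For each patient, compares paired tumor and normal editing levels site
#' by site: a site is over-edited when the tumor level exceeds the normal
#' level by strictly more than `delta` (default 10 percentage points) and
#' under-edited in the mirror case. Site-patient pairs missing a level in
#' either tissue are excluded for that patient; patients with no evaluable
#' site are excluded from the cohort denominator.
#'
#' @param levels Long editing-level tibble from [editing_level_matrix()]
#'   (`chrom, pos, alt, sample, tissue, level`).
#' @param site_subset Optional tibble `chrom, pos` (or `chrom, pos, alt`)
#'   restricting the computation, e.g. to a validated recurrent site set.
#' @param delta Strict difference threshold (default 0.10).
#' @return List of class `overediting_summary`: `patients` (tibble
#'   `sample, n_sites, n_over, n_under, over_fraction`) and `cohort`
#'   (one-row tibble `n_patients, n_over_dominant, over_dominant_pct`).
#' @export
patient_overediting <- function(levels, site_subset = NULL, delta = 0.10) {
  if (!is.null(site_subset)) {
    by <- intersect(c("chrom", "pos", "alt"), names(site_subset))
    levels <- semi_join(levels, site_subset, by = by)
  }
  wide <- levels |>
    select("chrom", "pos", "alt", "sample", "tissue", "level") |>
    pivot_wider(names_from = "tissue", values_from = "level") |>
    filter(!is.na(.data$tumor), !is.na(.data$normal))

  all_patients <- unique(levels$sample)
  patients <- wide |>
    group_by(.data$sample) |>
    summarise(
      n_sites = n(),
      n_over = sum(.data$tumor - .data$normal > delta),
      n_under = sum(.data$normal - .data$tumor > delta),
      .groups = "drop"
    ) |>
    mutate(
      over_fraction = ifelse(
        .data$n_over + .data$n_under > 0,
        .data$n_over / (.data$n_over + .data$n_under),
        NA_real_
      )
    )
  dropped <- setdiff(all_patients, patients$sample)
  if (length(dropped) > 0) {
    inform(sprintf(
      "%d patient(s) with no evaluable paired site excluded: %s",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  cohort <- tibble(
    n_patients = nrow(patients),
    n_over_dominant = sum(patients$n_over > patients$n_under),
    over_dominant_pct = pct(
      sum(patients$n_over > patients$n_under), nrow(patients)
    )
  )
  structure(
    list(patients = patients, cohort = cohort, delta = delta),
    class = "overediting_summary"
  )
}

#' @export
print.overediting_summary <- function(x, ...) {
  cat(sprintf(
    "<overediting_summary> delta = %g: %d/%d patients over-dominant (%s%%)\n",
    x$delta, x$cohort$n_over_dominant, x$cohort$n_patients,
    format(x$cohort$over_dominant_pct)
  ))
  print(x$patients)
  invisible(x)
}

#' @rdname patient_overediting
#' @param x An `overediting_summary`.
#' @param ... Unused.
#' @method tidy overediting_summary
#' @export
tidy.overediting_summary <- function(x, ...) x$patients

#' @rdname patient_overediting
#' @method glance overediting_summary
#' @export
glance.overediting_summary <- function(x, ...) x$cohort

#' Sequence-context (neighbor preference) profile of editing sites
#'
#' Computes per-position base frequencies in a +/- `window` nucleotide
#' neighborhood of each site on the transcribed strand (minus-strand
#' contexts are reverse-complemented before counting), the matrix behind a
#' neighbor-preference logo. Every row sums to 1 and the center row is
#' degenerate at A. Sites closer than `window` to a contig end are
#' dropped with a warning.
#'
#' @param sites Tibble with `chrom, pos, strand`.
#' @param reference Reference sequence (character scalar).
#' @param window Half-window in nucleotides (default 10).
#' @return Tibble of class `motif_matrix`: `position` (-window..window)
#'   and frequency columns `A, C, G, T`; attribute `n_sites`.
#' @export
motif_profile <- function(sites, reference, window = 10) {
  L <- nchar(reference)
  ok <- sites$pos > window & sites$pos + window <= L
  if (any(!ok)) {
    warn(sprintf("%d sites within %d nt of a contig end dropped",
                 sum(!ok), window))
    sites <- sites[ok, ]
  }
  if (nrow(sites) == 0) abort("no sites with a full context window")
  ctx <- substring(reference, sites$pos - window, sites$pos + window)
  minus <- sites$strand == "-"
  ctx[minus] <- revcomp(ctx[minus])
  mat <- matrix(
    unlist(strsplit(ctx, "", fixed = TRUE)),
    nrow = length(ctx), byrow = TRUE
  )
  freqs <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = BASES))
    as.numeric(tab) / length(col)
  })
  out <- as_tibble(t(freqs), .name_repair = ~BASES)
  out <- mutate(out, position = -window:window, .before = 1)
  attr(out, "n_sites") <- nrow(sites)
  class(out) <- c("motif_matrix", class(out))
  out
}
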