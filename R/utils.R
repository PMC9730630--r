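BASES <- c("A", "C", "G", "T")

COUNT_COLS <- c(
  "A_fwd", "C_fwd", "G_fwd", "T_fwd",
  "A_rev", "C_rev", "G_rev", "T_rev"
)

QUAL_COLS <- c("meanQ_A", "meanQ_C", "meanQ_G", "meanQ_T")

#' Complement and reverse-complement of short sequences
#'
#' Vectorised over character input. `complement_base()` complements each
#' base in place (no reversal); `revcomp()` reverse-complements whole
#' strings. Only upper-case A/C/G/T are handled; anything else passes
#' through `chartr()` unchanged.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' complement_base(c("A", "T"))
#' revcomp("ATGC")
complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' @rdname complement_base
#' @export
revcomp <- function(x) {
  vapply(
    strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}

#' Round half away from zero
#'
#' Percentages in cohort summaries are printed to one decimal with ties
#' rounded away from zero (so 91.15 -> 91.2), unlike base `round()`'s
#' round-half-even. Used everywhere a printed-style percentage is produced.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

pct <- function(num, den, digits = 1) {
  ifelse(den > 0, round_half_up(100 * num / den, digits), NA_real_)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# site-level key used throughout the cascade (1-based VCF-style position)
site_key <- function(chrom, pos, alt) paste(chrom, pos, alt, sep = ":")

# truncated-normal Phred qualities, N(35, 3) clipped to [2, 41]
draw_baseq <- function(n) pmin(pmax(rnorm(n, 35, 3), 2), 41)

# 1-based point inside a 0-based half-open interval table (start/end cols)
point_in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) {
    return(rep(FALSE, length(pos)))
  }
  q <- tibble(chrom = chrom, pos = pos, .row = seq_along(pos))
  hit <- q |>
    inner_join(intervals, by = "chrom", relationship = "many-to-many") |>
    filter(.data$pos > .data$start, .data$pos <= .data$end) |>
    distinct(.data$.row)
  out <- rep(FALSE, length(pos))
  out[hit$.row] <- TRUE
  out
}
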