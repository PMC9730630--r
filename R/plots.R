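#' Plot the mismatch-type spectrum of an editing-site table
#'
#' Bar chart of the 12 strand-collapsed mismatch types, over all sites
#' and over the recurrent subset.
#'
#' @param sites Editing-site tibble (from [assemble_editing_sites()]).
#' @return A ggplot object.
#' @export
plot_mismatch_spectrum <- function(sites) {
  spec <- spectrum_fractions(sites)$spectrum
  ggplot2::ggplot(
    spec,
    ggplot2::aes(
      x = factor(.data$mismatch_type, levels = mismatch_types()),
      y = .data$pct, fill = .data$scope
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "mismatch type (transcribed strand)", y = "% of sites",
      fill = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a neighbor-preference motif matrix
#'
#' Per-position base frequencies in the editing-site neighborhood, one
#' line per base.
#'
#' @param motif A `motif_matrix` from [motif_profile()].
#' @return A ggplot object.
#' @export
plot_motif <- function(motif) {
  long <- motif |>
    as_tibble() |>
    pivot_longer(all_of(BASES), names_to = "base", values_to = "freq")
  ggplot2::ggplot(
    long, ggplot2::aes(.data$position, .data$freq, colour = .data$base)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "position relative to edited A (nt)", y = "base frequency"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_motif
#' @param object,... `autoplot` arguments.
#' @method autoplot motif_matrix
#' @export
autoplot.motif_matrix <- function(object, ...) plot_motif(object)

#' Plot per-patient over-/under-editing counts
#'
#' Diverging bars: over-edited site counts up, under-edited down, one bar
#' pair per patient.
#'
#' @param summary An `overediting_summary` from [patient_overediting()].
#' @return A ggplot object.
#' @export
plot_overediting <- function(summary) {
  df <- summary$patients |>
    pivot_longer(c("n_over", "n_under"), names_to = "direction",
                 values_to = "n") |>
    mutate(n = ifelse(.data$direction == "n_under", -.data$n, .data$n))
  ggplot2::ggplot(
    df, ggplot2::aes(.data$sample, .data$n, fill = .data$direction)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(
      values = c(n_over = "#c0392b", n_under = "#2980b9"),
      labels = c(n_over = "over-edited", n_under = "under-edited")
    ) +
    ggplot2::labs(x = NULL, y = "sites (tumor vs normal)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname plot_overediting
#' @param object,... `autoplot` arguments.
#' @method autoplot overediting_summary
#' @export
autoplot.overediting_summary <- function(object, ...) plot_overediting(object)

#' @method autoplot edit_assoc
#' @export
autoplot.edit_assoc <- function(object, ...) {
  if (is.null(object$data)) abort("association object carries no data")
  if (object$statistic == "paired_t") {
    df <- object$data |>
      mutate(id = row_number()) |>
      pivot_longer(c("tumor", "normal"), names_to = "tissue",
                   values_to = "value")
    ggplot2::ggplot(
      df, ggplot2::aes(.data$tissue, .data$value, group = .data$id)
    ) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = NULL, y = "level",
        subtitle = sprintf("paired t, p = %.3g", object$p_value)
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$data, ggplot2::aes(.data$x, .data$y)) +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "burden / level", y = "expression",
        subtitle = sprintf("Spearman rho = %.2f, p = %.3g",
                           object$estimate, object$p_value)
      ) +
      ggplot2::theme_minimal()
  }
}
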