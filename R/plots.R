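#' Plot a standard curve
#'
#' Median corrected ratio against the amount of 14N material added, with the
#' ordinary least-squares line; the right-hand labels give r-protein
#' equivalents.
#'
#' @param object A `spike_curve` from [standard_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spike_curve
#' @export
autoplot.spike_curve <- function(object, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$amount_pmol,
                                    y = .data$median_corrected_ratio)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey60", linewidth = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(
        ~ . / (object$reference_amount / object$spike15_pmol),
        name = "r-protein equivalents"
      )
    ) +
    ggplot2::labs(x = "14N material added (pmol)",
                  y = "median corrected 14N/15N ratio") +
    ggplot2::theme_classic()
}

#' Plot a per-protein occupancy table
#'
#' @param object An `occupancy_table` from [protein_occupancy()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot occupancy_table
#' @export
autoplot.occupancy_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::arrange(.data$occupancy) |>
    dplyr::mutate(protein_id = factor(.data$protein_id,
                                      levels = .data$protein_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$occupancy,
                                   y = .data$protein_id,
                                   color = .data$below_loq)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        color = "grey70") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_color_manual(
      values = c(`FALSE` = "black", `TRUE` = "firebrick"),
      name = "below\nquantitation\nlimit"
    ) +
    ggplot2::labs(x = sprintf("occupancy (relative to %s)",
                              attr(object, "reference") %||% "reference"),
                  y = NULL) +
    ggplot2::theme_classic()
}

#' Plot theoretical 14N/15N envelope pairs of one peptide
#'
#' @param envelopes Table from [peptide_envelopes()].
#' @param peptide Peptide sequence to display.
#' @return A ggplot showing both channels at each charge.
#' @export
plot_peak_pair <- function(envelopes, peptide) {
  df <- dplyr::filter(envelopes, .data$peptide == !!peptide)
  if (nrow(df) == 0) stop("peptide not found in envelope table")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, ymax = .data$abundance,
                                   ymin = 0, color = .data$channel)) +
    ggplot2::geom_linerange() +
    ggplot2::facet_wrap(~charge, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_color_manual(values = c(N14 = "steelblue",
                                           N15 = "firebrick"),
                                name = "channel") +
    ggplot2::labs(x = "m/z", y = "relative abundance", title = peptide) +
    ggplot2::theme_classic()
}
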