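#' Plot per-section profile areas of a stack
#'
#' Bar chart of point-counted profile areas by section, faceted nowhere,
#' coloured by body — the virtual equivalent of scanning down a serial
#' ribbon.
#'
#' @param object A [section_stack].
#' @param pitch_nm Grid pitch for the area estimates.
#' @param seed Grid-offset seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot section_stack
#' @export
autoplot.section_stack <- function(object, pitch_nm = 4, seed = 1, ...) {
  prof <- profile_table(object, pitch_nm = pitch_nm, seed = seed)
  ggplot2::ggplot(prof,
                  ggplot2::aes(x = .data$section_index,
                               y = .data$area_nm2,
                               fill = .data$body_id)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "section", y = expression(area ~ (nm^2)),
                  fill = "body",
                  title = sprintf("%s profiles, t = %g nm",
                                  object$mode, object$spacing_nm)) +
    ggplot2::theme_minimal()
}

#' Partition of mitosomes across the two spindle pole bodies
#'
#' Per-cell paired counts on SPB1 and SPB2, cells ordered by total count;
#' uneven cells (difference above one) are flagged. The visual analogue of
#' tabulating evenness down a cohort.
#'
#' @param cohort A `meront_cohort`.
#' @return A ggplot object.
#' @export
plot_partition <- function(cohort) {
  part <- partition_table(cohort)
  long <- tidyr::pivot_longer(part, c("n_spb1", "n_spb2"),
                              names_to = "pole", values_to = "count")
  long$cell_id <- factor(long$cell_id,
                         levels = part$cell_id[order(part$n_spb1 +
                                                       part$n_spb2)])
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_id,
                                     y = .data$count,
                                     fill = .data$pole)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::geom_point(
      data = dplyr::mutate(part, uneven = !.data$even_or_near_even),
      ggplot2::aes(x = .data$cell_id, y = 0, alpha = .data$uneven),
      inherit.aes = FALSE, shape = 17, size = 2, colour = "red") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0),
                                guide = "none") +
    ggplot2::labs(x = "cell (ordered by total)", y = "mitosomes",
                  fill = "pole") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Overprojection factor as a function of section thickness
#'
#' Model-based curve `1 + t S / (4 V)` for one body over a thickness
#' range, with the thin-section limit 1 marked — useful for judging how
#' much a planned section thickness inflates Cavalieri volumes for
#' organelles of a given size.
#'
#' @param body A one-row body tibble.
#' @param t_max_nm Largest thickness to draw, nm.
#' @return A ggplot object.
#' @export
plot_factor_curve <- function(body, t_max_nm = 100) {
  t <- seq(0, t_max_nm, length.out = 200)
  df <- tibble::tibble(t_nm = t,
                       factor = vapply(t, model_based_factor,
                                       numeric(1), body = body))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_nm, y = .data$factor)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "section thickness t (nm)",
                  y = "predicted overprojection factor") +
    ggplot2::theme_minimal()
}

#' Scaling of mitosome complement with nucleus volume
#'
#' Scatter plots of per-cell total mitosome volume and count against
#' nucleus volume, with least-squares trends — the growth-pattern view of
#' a cohort.
#'
#' @param cohort A `meront_cohort`.
#' @return A ggplot object.
#' @export
plot_scaling <- function(cohort) {
  cells <- cohort$cells
  long <- tidyr::pivot_longer(
    dplyr::transmute(cells,
                     V_nuc_um3 = nm3_to_um3(.data$V_nuc_nm3),
                     `total mitosome volume (um^3)` =
                       nm3_to_um3(.data$V_mit_total_true_nm3),
                     `mitosome count` = as.numeric(.data$N_mit_true)),
    -"V_nuc_um3", names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$V_nuc_um3,
                                     y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = expression(nucleus ~ volume ~ (mu * m^3)),
                  y = NULL) +
    ggplot2::theme_minimal()
}
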