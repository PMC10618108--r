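#' Tidiers for cohorts and partition summaries
#'
#' broom-style accessors: `tidy()` returns the per-observation table and
#' `glance()` a one-row cohort summary.
#'
#' @param x A `meront_cohort` or `pooled_binomial` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy meront_cohort
#' @export
tidy.meront_cohort <- function(x, ...) {
  x$cells
}

#' @rdname tidy.meront_cohort
#' @method glance meront_cohort
#' @export
glance.meront_cohort <- function(x, ...) {
  m <- x$mitosomes
  tibble::tibble(
    n_cells = nrow(x$cells),
    species = x$config$species,
    perturbation = x$config$perturbation,
    mean_n_mit = mean(x$cells$N_mit_true),
    mean_v_mit_total_um3 = nm3_to_um3(mean(x$cells$V_mit_total_true_nm3)),
    mean_v_mit_um3 = nm3_to_um3(mean(x$cells$V_mit_total_true_nm3 /
                                       x$cells$N_mit_true)),
    tether_fraction = if (nrow(m) > 0) mean(m$tether != "free") else
      NA_real_,
    even_fraction = mean(classify_evenness(x$cells$n_spb1,
                                           x$cells$n_spb2))
  )
}

#' @rdname tidy.meront_cohort
#' @method tidy pooled_binomial
#' @export
tidy.pooled_binomial <- function(x, ...) {
  tibble::tibble(
    estimate = x$p_hat, conf_low = x$conf_low, conf_high = x$conf_high,
    highest_p = x$highest_p, highest_conf_low = x$highest_conf_low,
    highest_conf_high = x$highest_conf_high
  )
}

#' @rdname tidy.meront_cohort
#' @method glance pooled_binomial
#' @export
glance.pooled_binomial <- function(x, ...) {
  tibble::tibble(n_total = x$n_total, n_cells = x$n_cells,
                 conf_level = x$conf_level, method = x$method)
}
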