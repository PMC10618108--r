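#' Evenness of mitosome partitioning across the two spindle pole bodies
#'
#' A cell's partition is "even or near-even" when the two mSPB counts
#' differ by at most one — the most even split achievable for its total.
#' `classify_evenness()` is vectorised; `partition_table()` extracts the
#' per-cell partition records of a cohort (tethered mitosomes only — free
#' mitosomes belong to neither pole).
#'
#' @param n_spb1,n_spb2 Non-negative counts on the two poles.
#' @param cohort A `meront_cohort`.
#' @return A logical vector, or a tibble of partition records (`cell_id`,
#'   `n_spb1`, `n_spb2`, `even_or_near_even`).
#' @examples
#' classify_evenness(4, 3) # TRUE
#' classify_evenness(5, 2) # FALSE
#' @export
classify_evenness <- function(n_spb1, n_spb2) {
  if (any(n_spb1 < 0) || any(n_spb2 < 0)) abort("counts must be >= 0")
  abs(n_spb1 - n_spb2) <= 1
}

#' @rdname classify_evenness
#' @export
partition_table <- function(cohort) {
  stopifnot(inherits(cohort, "meront_cohort"))
  tibble::tibble(
    cell_id = cohort$cells$cell_id,
    n_spb1 = cohort$cells$n_spb1,
    n_spb2 = cohort$cells$n_spb2,
    even_or_near_even = classify_evenness(cohort$cells$n_spb1,
                                          cohort$cells$n_spb2)
  )
}

#' Pooled (count-weighted) binomial proportion across cells
#'
#' The weighted-average analysis of a per-cell split under a binomial
#' model: cells are pooled by their counts, `P = sum(n1) / sum(n1 + n2)`,
#' with a normal-approximation 95% interval
#' `P +/- 1.96 sqrt(P (1 - P) / n)` clipped to \[0, 1\] (Wilson interval
#' available as an option). Because pole labels are arbitrary, the
#' conventional summary is the larger of `P` and `1 - P`, reported as
#' `highest_p` with its interval.
#'
#' @param records A partition tibble with `n_spb1`, `n_spb2` (e.g. from
#'   [partition_table()] or [simulate_partition()]); at least one record
#'   with a positive total.
#' @param conf_level Confidence level for the interval.
#' @param method `"normal"` (default) or `"wilson"`.
#' @return An object of class `pooled_binomial` with fields `p_hat`,
#'   `conf_low`, `conf_high`, `highest_p`, `highest_conf_low`,
#'   `highest_conf_high`, `n_total`, `n_cells`, `method`; it has [tidy()]
#'   and [glance()] methods.
#' @examples
#' rec <- tibble::tibble(n_spb1 = c(1, 2, 3), n_spb2 = c(1, 2, 3))
#' pooled_binomial_proportion(rec)$p_hat # 0.5
#' @export
pooled_binomial_proportion <- function(records, conf_level = 0.95,
                                       method = c("normal", "wilson")) {
  method <- match.arg(method)
  if (!all(c("n_spb1", "n_spb2") %in% names(records))) {
    abort("records need n_spb1 and n_spb2 columns")
  }
  s1 <- sum(records$n_spb1)
  n <- sum(records$n_spb1 + records$n_spb2)
  if (n <= 0) abort("all-zero totals: pooled proportion undefined")
  p <- s1 / n
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- if (method == "normal") {
    half <- z * sqrt(p * (1 - p) / n)
    c(max(0, p - half), min(1, p + half))
  } else {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(max(0, centre - half), min(1, centre + half))
  }
  flip <- p < 0.5
  structure(list(
    p_hat = p, conf_low = ci[1], conf_high = ci[2],
    highest_p = max(p, 1 - p),
    highest_conf_low = if (flip) 1 - ci[2] else ci[1],
    highest_conf_high = if (flip) 1 - ci[1] else ci[2],
    n_total = n, n_cells = nrow(records),
    conf_level = conf_level, method = method
  ), class = "pooled_binomial")
}

#' @export
print.pooled_binomial <- function(x, ...) {
  cat(sprintf(
    "Pooled binomial proportion: P = %.4f [%.3f, %.3f] (n = %d)\n",
    x$p_hat, x$conf_low, x$conf_high, x$n_total))
  cat(sprintf("Highest P = %.4f [%.3f, %.3f], %s %g%% interval\n",
              x$highest_p, x$highest_conf_low, x$highest_conf_high,
              x$method, 100 * x$conf_level))
  invisible(x)
}

#' Probability of an even-or-near-even split under random assignment
#'
#' The null model for partition evenness: with `n` mitosomes assigned
#' independently to the two poles with probability 1/2,
#' `P(|n1 - n2| <= 1)` equals the central binomial term for even `n` and
#' twice the near-central term for odd `n`:
#' `choose(n, n/2) / 2^n` or `2 choose(n, (n-1)/2) / 2^n`.
#'
#' @param n Total count per cell, `>= 0`. Vectorised.
#' @return The probability of an even-or-near-even split.
#' @examples
#' even_split_null_probability(7) # 70/128 = 0.546875
#' @export
even_split_null_probability <- function(n) {
  if (any(n < 0) || any(n != floor(n))) {
    abort("n must be a non-negative integer")
  }
  vapply(n, function(k) {
    if (k <= 1) return(1)
    if (k %% 2 == 0) choose(k, k / 2) / 2^k
    else 2 * choose(k, (k - 1) / 2) / 2^k
  }, numeric(1))
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson's chi-square without continuity correction, with
#' `df = (rows - 1)(cols - 1)`; used for comparing binned
#' distance-to-envelope distributions between control and drug-treated
#' cells. All expected counts must be positive.
#'
#' @param table A matrix (or coercible) of non-negative counts.
#' @return A tibble: `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_contingency(rbind(c(20, 10), c(10, 20)))$statistic # 6.667
#' @export
chi_square_contingency <- function(table) {
  m <- as.matrix(table)
  if (any(!is.finite(m)) || any(m < 0)) {
    abort("the table must contain non-negative counts")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected <= 0)) {
    abort(paste0("zero expected count: merge sparse rows/columns or ",
                 "collect more observations before testing"))
  }
  res <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = unname(res$p.value))
}

#' Pairwise Pearson correlations over a cell-measurement table
#'
#' For each requested column pair, the Pearson correlation with its
#' two-sided p-value from the t transform and the number of complete
#' cases. Defaults reproduce the comparisons made between mitosome and
#' compartment quantities (total and mean mitosome volume, counts, nucleus
#' and cytoplasm volumes). P-values are reported raw — no multiplicity
#' adjustment.
#'
#' @param data A data frame of per-cell measurements.
#' @param pairs A list of character 2-vectors naming the columns to
#'   correlate; default: all pairs of numeric columns.
#' @return A tibble: `var_x`, `var_y`, `r`, `p_value`, `n`.
#' @export
correlation_table <- function(data, pairs = NULL) {
  if (is.null(pairs)) {
    num <- names(data)[vapply(data, is.numeric, logical(1))]
    pairs <- utils::combn(num, 2, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% names(data))) {
      abort(paste0("unknown columns in pair: ", paste(pr, collapse = ", ")))
    }
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) abort("each pair needs at least 3 complete cases")
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(var_x = pr[1], var_y = pr[2],
                   r = unname(ct$estimate), p_value = ct$p.value,
                   n = sum(ok))
  })
  dplyr::bind_rows(rows)
}

#' Maximum mitosome occupancy of a spindle pole body cap
#'
#' Models the mSPB as a half sphere of the given volume sitting on the
#' nuclear envelope, and asks how many mitosome "ends" of diameter `d` fit
#' on its cytoplasm-facing (curved) surface: radius
#' `r = (3 v / (2 pi))^(1/3)`, curved cap area `2 pi r^2`, end-on
#' footprint `pi (d/2)^2`, capacity the integer part of their ratio. All
#' intermediates are reported so alternative area conventions can be
#' explored.
#'
#' @param v_mspb_nm3 mSPB volume, nm^3, `> 0`.
#' @param mitosome_diameter_nm Mitosome cap diameter, nm, `> 0`.
#' @return A tibble: `r_nm`, `cap_area_nm2`, `footprint_nm2`, `capacity`.
#' @examples
#' mspb_occupancy_capacity(2 / 3 * pi * 30^3, 58)$capacity # 2
#' @export
mspb_occupancy_capacity <- function(v_mspb_nm3, mitosome_diameter_nm) {
  if (any(v_mspb_nm3 <= 0)) abort("mSPB volume must be > 0")
  if (any(mitosome_diameter_nm <= 0)) {
    abort("mitosome diameter must be > 0")
  }
  r <- (3 * v_mspb_nm3 / (2 * pi))^(1 / 3)
  cap <- 2 * pi * r^2
  foot <- pi * (mitosome_diameter_nm / 2)^2
  tibble::tibble(r_nm = r, cap_area_nm2 = cap, footprint_nm2 = foot,
                 capacity = floor(cap / foot))
}

#' Mitosome distance to the nuclear envelope
#'
#' Minimum surface-to-surface distance from each mitosome to the nucleus
#' sphere: the distance from the mitosome's axis segment to the nucleus
#' centre, minus both radii (clamped at zero). `bin_distances()` tabulates
#' the distances into categories ready for [chi_square_contingency()]
#' between conditions; the default four bins correspond to juxtanuclear,
#' near, intermediate and peripheral positions.
#'
#' @param cohort A `meront_cohort`.
#' @param distances_nm Numeric distances to bin.
#' @param breaks_nm Bin edges (left-closed), extended to `Inf`.
#' @return `distance_to_envelope()`: a tibble `cell_id`, `mito_id`,
#'   `tether`, `distance_nm`; `bin_distances()`: a tibble `bin`, `count`.
#' @export
distance_to_envelope <- function(cohort) {
  stopifnot(inherits(cohort, "meront_cohort"))
  m <- cohort$mitosomes
  if (nrow(m) == 0) {
    return(tibble::tibble(cell_id = character(0), mito_id = character(0),
                          tether = character(0), distance_nm = numeric(0)))
  }
  r_nuc <- cohort$cells$r_nuc_nm[match(m$cell_id, cohort$cells$cell_id)]
  h <- m$L_nm / 2 - m$r_nm
  e1 <- cbind(m$cx_nm - h * m$ax, m$cy_nm - h * m$ay, m$cz_nm - h * m$az)
  e2 <- cbind(m$cx_nm + h * m$ax, m$cy_nm + h * m$ay, m$cz_nm + h * m$az)
  seg_d <- vapply(seq_len(nrow(m)), function(i) {
    segment_point_distance(e1[i, ], e2[i, ], c(0, 0, 0))
  }, numeric(1))
  tibble::tibble(cell_id = m$cell_id, mito_id = m$body_id,
                 tether = m$tether,
                 distance_nm = pmax(0, seg_d - m$r_nm - r_nuc))
}

#' @rdname distance_to_envelope
#' @export
bin_distances <- function(distances_nm, breaks_nm = c(0, 50, 100, 200)) {
  if (length(distances_nm) == 0) {
    return(tibble::tibble(bin = character(0), count = integer(0)))
  }
  edges <- c(breaks_nm, Inf)
  cut_f <- cut(distances_nm, breaks = edges, right = FALSE,
               include.lowest = TRUE)
  tibble::tibble(bin = levels(cut_f),
                 count = as.integer(table(cut_f)))
}
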