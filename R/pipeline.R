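#' End-to-end simulation and estimation pipeline
#'
#' The four pipeline stages, each writing schema-checked CSV next to a
#' resolved configuration so identical configurations and seeds reproduce
#' identical bytes:
#'
#' 1. `pipeline_simulate()` — generate the cohort, write `cells.csv`,
#'    `mitosomes.csv`, `config.json`;
#' 2. `pipeline_section()` — cut every cell into serial sections and write
#'    `profiles.csv`;
#' 3. `pipeline_estimate()` — per-cell Cavalieri volumes (raw and
#'    overprojection-corrected) and appearance counts, written to
#'    `estimates.csv`;
#' 4. `pipeline_stats()` — cohort statistics: a correlation block over the
#'    cell-measurement table, the partition evenness summary with the
#'    pooled binomial proportion, written to `stats.csv` and a
#'    human-readable `report.txt`.
#'
#' `run_pipeline()` chains all four.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if needed).
#' @param t_nm Section thickness, nm.
#' @param every_k Cavalieri recording interval, sections.
#' @param pitch_nm Point-grid pitch for profile areas, nm.
#' @param correction_factor Overprojection factor applied to conventional
#'   volume estimates; `NULL` derives the model-based factor from the
#'   cohort's mean mitosome shape.
#' @param seed Sectioning/grid seed (the cohort has its own seed in
#'   `config`).
#' @return `run_pipeline()` returns the output paths invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  cohort <- generate_cohort(config)
  if (nrow(cohort$cells) == 0) {
    cohort$cells <- empty_cells_table(config)
    cohort$mitosomes <- empty_mitosomes_table()
  }
  write_cohort(cohort, out_dir)
  invisible(cohort)
}

empty_cells_table <- function(config) {
  tibble::tibble(cell_id = character(0), species = character(0),
                 stage = character(0), r_nuc_nm = numeric(0),
                 V_nuc_nm3 = numeric(0), r_cell_nm = numeric(0),
                 V_cyto_nm3 = numeric(0), spb_ux = numeric(0),
                 spb_uy = numeric(0), spb_uz = numeric(0),
                 r_spb1_nm = numeric(0), r_spb2_nm = numeric(0),
                 V_spb1_nm3 = numeric(0), V_spb2_nm3 = numeric(0),
                 S_spb1_nm2 = numeric(0), S_spb2_nm2 = numeric(0),
                 N_mit_true = integer(0),
                 V_mit_total_true_nm3 = numeric(0),
                 n_spb1 = integer(0), n_spb2 = integer(0),
                 n_free = integer(0))
}

empty_mitosomes_table <- function() {
  tibble::tibble(body_id = character(0), kind = character(0),
                 cx_nm = numeric(0), cy_nm = numeric(0),
                 cz_nm = numeric(0), ax = numeric(0), ay = numeric(0),
                 az = numeric(0), r_nm = numeric(0), L_nm = numeric(0),
                 tether = character(0), gap_nm = numeric(0),
                 cell_id = character(0))
}

#' @rdname pipeline_simulate
#' @param cohort A `meront_cohort` (e.g. from [pipeline_simulate()] or
#'   [read_cohort()]).
#' @export
pipeline_section <- function(cohort, out_dir, t_nm = 43, every_k = 1,
                             pitch_nm = 8, seed = 1) {
  stopifnot(inherits(cohort, "meront_cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  profs <- lapply(seq_len(nrow(cohort$cells)), function(i) {
    cid <- cohort$cells$cell_id[i]
    bodies <- cell_bodies(cohort, cid, include = "mitosomes")
    stack <- cut_serial(bodies, t_nm, seed = derive_seed(seed, i),
                        cell_id = cid)
    if (every_k > 1) {
      stack <- subsample_intermittent(stack, every_k,
                                      seed = derive_seed(seed, i))
    }
    profile_table(stack, pitch_nm = pitch_nm,
                  seed = derive_seed(seed, i + 31L))
  })
  profiles <- dplyr::bind_rows(profs)
  if (nrow(profiles) == 0) {
    profiles <- tibble::tibble(cell_id = character(0),
                               body_id = character(0),
                               section_index = integer(0),
                               z_lo_nm = numeric(0), t_nm = numeric(0),
                               mode = character(0),
                               point_hits = integer(0),
                               area_nm2 = numeric(0),
                               grid_pitch_nm = numeric(0),
                               format_version = character(0))
  }
  readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))
  invisible(profiles)
}

#' Count particles by appearance from an imported profile table
#'
#' Applies the appearance rule to a `profiles.csv`-style table: per body,
#' profiles on consecutive sections form runs, and each run ending before
#' the last section counts one particle. Profiles are linked by `body_id`
#' (simulation truth). Runs still alive at the final recorded section are
#' terminated only with `assume_empty_after = TRUE`, otherwise they are
#' reported as truncated.
#'
#' @param profiles A validated profiles table (one cell).
#' @param assume_empty_after Treat the section after the last as empty?
#' @return A one-row tibble as in [count_by_appearance()].
#' @export
count_profiles_by_appearance <- function(profiles,
                                         assume_empty_after = FALSE) {
  validate_profiles(profiles)
  if (nrow(profiles) == 0) {
    return(tibble::tibble(n_appearance = 0L, n_truncated = 0L,
                          n_sections_used = 0L))
  }
  last_sec <- max(profiles$section_index)
  ends <- 0L; truncated <- 0L
  for (bid in unique(profiles$body_id)) {
    secs <- sort(unique(profiles$section_index[profiles$body_id == bid]))
    runs <- split(secs, cumsum(c(1, diff(secs) != 1)))
    for (run in runs) {
      if (max(run) < last_sec || assume_empty_after) {
        ends <- ends + 1L
      } else {
        truncated <- truncated + 1L
      }
    }
  }
  if (truncated > 0) {
    warn(paste0(truncated, " profile run(s) reach the last recorded ",
                "section; counted without them (truncated stack)"))
  }
  tibble::tibble(n_appearance = ends, n_truncated = truncated,
                 n_sections_used = length(unique(profiles$section_index)))
}

#' @rdname pipeline_simulate
#' @param profiles Profile table from [pipeline_section()].
#' @export
pipeline_estimate <- function(profiles, cohort, out_dir,
                              correction_factor = NULL) {
  validate_profiles(profiles)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (nrow(profiles) == 0) {
    estimates <- tibble::tibble(cell_id = character(0),
                                quantity = character(0),
                                value = numeric(0), units = character(0),
                                ce = numeric(0),
                                correction_factor = numeric(0),
                                format_version = character(0))
    readr::write_csv(estimates, file.path(out_dir, "estimates.csv"))
    return(invisible(estimates))
  }
  if (is.null(correction_factor)) {
    correction_factor <- cohort_model_factor(cohort,
                                             t_nm = profiles$t_nm[1])
  }
  rows <- lapply(unique(profiles$cell_id), function(cid) {
    p <- profiles[profiles$cell_id == cid, ]
    spacing <- p$t_nm[1]
    v_raw <- cavalieri_volume(p$area_nm2, spacing,
                              point_hits = p$point_hits)$value_nm3
    n_cnt <- count_profiles_by_appearance(p, assume_empty_after = TRUE)
    tibble::tibble(
      cell_id = cid,
      quantity = c("V_mit_total_raw", "V_mit_total_corrected", "N_mit"),
      value = c(v_raw, v_raw / correction_factor,
                as.numeric(n_cnt$n_appearance)),
      units = c("nm3", "nm3", "count"),
      ce = NA_real_,
      correction_factor = c(NA_real_, correction_factor, NA_real_),
      format_version = ms_format_version()
    )
  })
  estimates <- dplyr::bind_rows(rows)
  if (nrow(estimates) > 0) {
    for (q in unique(estimates$quantity)) {
      sel <- estimates$quantity == q
      if (sum(sel) >= 2 && mean(estimates$value[sel]) > 0) {
        estimates$ce[sel] <- coefficient_of_error(estimates$value[sel])
      }
    }
  }
  readr::write_csv(estimates, file.path(out_dir, "estimates.csv"))
  invisible(estimates)
}

# model-based factor evaluated at the cohort's mean mitosome shape
cohort_model_factor <- function(cohort, t_nm) {
  m <- cohort$mitosomes
  if (nrow(m) == 0) return(1)
  body <- body_spherocylinder(mean(m$r_nm), mean(m$L_nm))
  model_based_factor(t_nm, body)
}

#' @rdname pipeline_simulate
#' @param estimates Estimates table from [pipeline_estimate()].
#' @export
pipeline_stats <- function(estimates, cohort, out_dir) {
  validate_estimates(estimates[setdiff(names(estimates),
                                       "format_version")])
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cells <- cohort$cells
  v_corr <- estimates[estimates$quantity == "V_mit_total_corrected", ]
  tab <- dplyr::left_join(
    cells,
    tibble::tibble(cell_id = v_corr$cell_id,
                   V_mit_est_nm3 = v_corr$value),
    by = "cell_id")
  pairs <- list(c("V_mit_est_nm3", "V_nuc_nm3"),
                c("V_mit_total_true_nm3", "V_nuc_nm3"),
                c("N_mit_true", "V_nuc_nm3"),
                c("V_mit_est_nm3", "V_cyto_nm3"))
  cors <- correlation_table(tab, pairs)
  part <- partition_table(cohort)
  pooled <- pooled_binomial_proportion(part)
  stats <- dplyr::bind_rows(
    dplyr::mutate(cors, block = "correlation"),
    tibble::tibble(var_x = "partition", var_y = "highest_p",
                   r = pooled$highest_p, p_value = NA_real_,
                   n = pooled$n_total, block = "partition"),
    tibble::tibble(var_x = "partition", var_y = "even_fraction",
                   r = mean(part$even_or_near_even), p_value = NA_real_,
                   n = nrow(part), block = "partition")
  )
  stats$format_version <- ms_format_version()
  readr::write_csv(stats, file.path(out_dir, "stats.csv"))
  report <- c(
    "Cohort report",
    "=============",
    sprintf("Cells: %d (%s)", nrow(cells), cohort$config$species),
    sprintf("Mean mitosomes per cell (truth): %.2f  CE_%d %.1f%%",
            mean(cells$N_mit_true), nrow(cells),
            100 * coefficient_of_error(cells$N_mit_true)),
    "",
    "Correlations (Pearson r, two-sided p, n):",
    sprintf("  %-28s vs %-14s r = %+.4f  p = %.4g  (n = %d)",
            cors$var_x, cors$var_y, cors$r, cors$p_value, cors$n),
    "",
    "Partition of mitosomes across the two mSPBs:",
    sprintf("  even or near-even: %d / %d cells",
            sum(part$even_or_near_even), nrow(part)),
    sprintf("  pooled binomial highest P = %.3f [%.3f, %.3f]",
            pooled$highest_p, pooled$highest_conf_low,
            pooled$highest_conf_high)
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(stats)
}

#' @rdname pipeline_simulate
#' @export
run_pipeline <- function(config, out_dir, t_nm = 43, every_k = 1,
                         pitch_nm = 8, correction_factor = NULL,
                         seed = 1) {
  cohort <- pipeline_simulate(config, out_dir)
  profiles <- pipeline_section(cohort, out_dir, t_nm = t_nm,
                               every_k = every_k, pitch_nm = pitch_nm,
                               seed = seed)
  estimates <- pipeline_estimate(profiles, cohort, out_dir,
                                 correction_factor = correction_factor)
  pipeline_stats(estimates, cohort, out_dir)
  # out_dir is implied by the file's location and would break
  # byte-reproducibility across directories, so it is not serialised
  run_cfg <- c(config_as_list(config),
               list(t_nm = t_nm, every_k = every_k, pitch_nm = pitch_nm))
  write_run_config(run_cfg, file.path(out_dir, "run_config.json"))
  invisible(file.path(out_dir, c("cells.csv", "mitosomes.csv",
                                 "profiles.csv", "estimates.csv",
                                 "stats.csv", "report.txt")))
}
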