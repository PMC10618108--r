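#' Read and write the pipeline's CSV tables
#'
#' All pipeline artefacts are flat CSV files with a header, explicit units
#' in column names (`*_nm`, `*_nm2`, `*_nm3`) and a `format_version`
#' column, so runs are diffable and language-agnostic:
#'
#' * `cells.csv` — one row per simulated cell with ground truth
#'   (`cell_id`, `species`, `stage`, `V_nuc_nm3`, `V_cyto_nm3`,
#'   `N_mit_true`, `V_mit_total_true_nm3`, `n_spb1`, `n_spb2`, ...);
#' * `mitosomes.csv` — one row per mitosome body
#'   (`cell_id`, `mito_id`, `r_nm`, `L_nm`, `tether`, centre and axis
#'   components);
#' * `profiles.csv` — one row per (section, body) profile
#'   (`cell_id`, `body_id`, `section_index`, `z_lo_nm`, `t_nm`, `mode`,
#'   `area_nm2`, `point_hits`);
#' * `estimates.csv` — one row per estimate
#'   (`cell_id`, `quantity`, `value`, `units`, `ce`,
#'   `correction_factor`).
#'
#' Schema validators reject files with missing columns, naming the columns
#' and offending rows.
#'
#' @param cohort A `meront_cohort`.
#' @param dir,path Output directory / file path.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meront_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cells <- cohort$cells
  cells$format_version <- ms_format_version()
  m <- cohort$mitosomes
  mitos <- tibble::tibble(
    cell_id = m$cell_id, mito_id = m$body_id, r_nm = m$r_nm,
    L_nm = m$L_nm, tether = m$tether,
    x_nm = m$cx_nm, y_nm = m$cy_nm, z_nm = m$cz_nm,
    axis_x = m$ax, axis_y = m$ay, axis_z = m$az,
    format_version = ms_format_version()
  )
  readr::write_csv(cells, file.path(dir, "cells.csv"))
  readr::write_csv(mitos, file.path(dir, "mitosomes.csv"))
  jsonlite::write_json(config_as_list(cohort$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$stage_schedule <- as.list(out$stage_schedule)
  out
}

#' @rdname pipeline_io
#' @export
read_cohort <- function(dir) {
  cells <- validate_cells(readr::read_csv(file.path(dir, "cells.csv"),
                                          show_col_types = FALSE))
  mit <- validate_mitosomes(readr::read_csv(
    file.path(dir, "mitosomes.csv"), show_col_types = FALSE))
  cfg_list <- jsonlite::read_json(file.path(dir, "config.json"),
                                  simplifyVector = TRUE)
  cfg_list$stage_schedule <- unlist(cfg_list$stage_schedule)
  cfg <- do.call(cohort_config, cfg_list[setdiff(names(cfg_list),
                                                 "format_version")])
  mitosomes <- tibble::tibble(
    body_id = mit$mito_id, kind = "spherocylinder",
    cx_nm = mit$x_nm, cy_nm = mit$y_nm, cz_nm = mit$z_nm,
    ax = mit$axis_x, ay = mit$axis_y, az = mit$axis_z,
    r_nm = mit$r_nm, L_nm = mit$L_nm,
    tether = mit$tether, gap_nm = NA_real_, cell_id = mit$cell_id
  )
  new_meront_cohort(cells[setdiff(names(cells), "format_version")],
                    mitosomes, cfg)
}

check_schema <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_rows <- function(df, ok, what, rule) {
  if (any(!ok)) {
    abort(paste0(what, ": ", rule, " violated at row(s) ",
                 paste(head(which(!ok), 5), collapse = ", ")))
  }
  invisible(df)
}

#' @rdname pipeline_io
#' @param cells,mitosomes,profiles,estimates Data frames to validate.
#' @export
validate_cells <- function(cells) {
  check_schema(cells, c("cell_id", "species", "stage", "V_nuc_nm3",
                        "V_cyto_nm3", "N_mit_true",
                        "V_mit_total_true_nm3", "n_spb1", "n_spb2"),
               "cells table")
  check_rows(cells, cells$V_cyto_nm3 > 0 & cells$V_nuc_nm3 > 0,
             "cells table", "positive compartment volumes")
  check_rows(cells, cells$N_mit_true >= 0, "cells table",
             "N_mit_true >= 0")
  cells
}

#' @rdname pipeline_io
#' @export
validate_mitosomes <- function(mitosomes) {
  check_schema(mitosomes, c("cell_id", "mito_id", "r_nm", "L_nm",
                            "tether", "x_nm", "y_nm", "z_nm",
                            "axis_x", "axis_y", "axis_z"),
               "mitosomes table")
  check_rows(mitosomes, mitosomes$r_nm > 0, "mitosomes table", "r_nm > 0")
  check_rows(mitosomes, mitosomes$L_nm >= 2 * mitosomes$r_nm - 1e-9,
             "mitosomes table", "L_nm >= 2 r_nm")
  mitosomes
}

#' @rdname pipeline_io
#' @export
validate_profiles <- function(profiles) {
  check_schema(profiles, c("cell_id", "body_id", "section_index",
                           "z_lo_nm", "t_nm", "mode", "area_nm2",
                           "point_hits"), "profiles table")
  check_rows(profiles, profiles$area_nm2 >= 0, "profiles table",
             "area_nm2 >= 0")
  check_rows(profiles, profiles$t_nm > 0, "profiles table", "t_nm > 0")
  profiles
}

#' @rdname pipeline_io
#' @export
validate_estimates <- function(estimates) {
  check_schema(estimates, c("cell_id", "quantity", "value", "units",
                            "ce", "correction_factor"),
               "estimates table")
  check_rows(estimates, is.finite(estimates$value) & estimates$value >= 0,
             "estimates table", "value >= 0")
  estimates
}

#' Run configuration files
#'
#' The resolved configuration of every pipeline run is serialised next to
#' its outputs as JSON (chosen over YAML/TOML because it round-trips
#' losslessly with no extra dependency). `read_run_config()` rejects
#' unknown keys by name.
#'
#' @param path JSON file path.
#' @param config A list of run parameters.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c(names(formals(cohort_config)), "t_nm", "dz_nm", "every_k",
             "pitch_nm", "superslice_k", "out_dir", "format_version")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
          class = "mitostereo_bad_config")
  }
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
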