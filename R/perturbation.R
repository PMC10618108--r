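#' Apply the dynamin-inhibition perturbation to a cohort
#'
#' Models the effect of dynamin inhibitors — fewer, larger mitosomes with
#' conserved aggregate volume — by pairwise merging within each cell.
#' Mitosomes are ordered (SPB1 group, then SPB2, then free) and consecutive
#' pairs merged: the merged body gets the pair's summed volume, the larger
#' of the two cap diameters, and its length is re-derived at that fixed
#' diameter via [spherocylinder_length_from_volume()]. An odd count leaves
#' the last mitosome unmerged, so per-cell totals are conserved exactly and
#' the new count is `ceiling(n / 2)` (minimum 1). Merged bodies inherit the
#' first partner's tether; tethered merges are re-anchored at their mSPB
#' with the contact gap preserved, free merges keep the first partner's
#' centre and axis (a long merged body may then locally protrude beyond the
#' idealised cell sphere; the sectioning module spans all bodies, so
#' nothing is lost).
#'
#' @param cohort An unperturbed `meront_cohort`.
#' @return A `meront_cohort` with perturbation `"dynamin_inhibition"`,
#'   updated `mitosomes` and refreshed ground-truth columns.
#' @examples
#' coh <- generate_cohort(cohort_config(n_cells = 2, seed = 7))
#' trt <- apply_dynamin_inhibition(coh)
#' trt$cells$N_mit_true # ceiling(n / 2)
#' @export
apply_dynamin_inhibition <- function(cohort) {
  stopifnot(inherits(cohort, "meront_cohort"))
  if (identical(attr(cohort, "perturbed"), TRUE)) {
    abort("cohort is already dynamin-inhibited")
  }
  new_mitos <- vector("list", nrow(cohort$cells))
  for (i in seq_len(nrow(cohort$cells))) {
    cell <- cohort$cells[i, ]
    m <- cohort$mitosomes[cohort$mitosomes$cell_id == cell$cell_id, ]
    if (nrow(m) == 0) abort("cannot perturb a cell with zero mitosomes")
    m <- m[order(match(m$tether, c("SPB1", "SPB2", "free"))), ]
    new_mitos[[i]] <- merge_pairs(m, cell)
  }
  mitosomes <- dplyr::bind_rows(new_mitos)
  cells <- cohort$cells
  counts <- table(factor(mitosomes$cell_id, levels = cells$cell_id))
  cells$N_mit_true <- as.integer(counts)
  vols <- tapply(body_volume(mitosomes), factor(mitosomes$cell_id,
                 levels = cells$cell_id), sum)
  cells$V_mit_total_true_nm3 <- as.numeric(vols)
  cells$n_spb1 <- as.integer(tapply(mitosomes$tether == "SPB1",
    factor(mitosomes$cell_id, levels = cells$cell_id), sum))
  cells$n_spb2 <- as.integer(tapply(mitosomes$tether == "SPB2",
    factor(mitosomes$cell_id, levels = cells$cell_id), sum))
  cells$n_free <- as.integer(tapply(mitosomes$tether == "free",
    factor(mitosomes$cell_id, levels = cells$cell_id), sum))
  cfg <- cohort$config
  cfg$perturbation <- "dynamin_inhibition"
  out <- new_meront_cohort(cells, mitosomes, cfg)
  attr(out, "perturbed") <- TRUE
  out
}

merge_pairs <- function(m, cell) {
  n <- nrow(m)
  n_pairs <- n %/% 2
  rows <- vector("list", n_pairs + n %% 2)
  vols <- body_volume(m[setdiff(names(m), c("cell_id", "tether", "gap_nm"))])
  for (p in seq_len(n_pairs)) {
    a <- m[2 * p - 1, ]; b <- m[2 * p, ]
    v <- vols[2 * p - 1] + vols[2 * p]
    d <- 2 * max(a$r_nm, b$r_nm)
    L <- spherocylinder_length_from_volume(v, d)
    r <- d / 2
    if (a$tether %in% c("SPB1", "SPB2")) {
      u <- c(cell$spb_ux, cell$spb_uy, cell$spb_uz) *
        if (a$tether == "SPB1") 1 else -1
      r_spb <- if (a$tether == "SPB1") cell$r_spb1_nm else cell$r_spb2_nm
      dir <- c(a$ax, a$ay, a$az)
      spb_center <- u * cell$r_nuc_nm
      center <- spb_center + dir * (r_spb + a$gap_nm + L / 2)
    } else {
      dir <- c(a$ax, a$ay, a$az)
      center <- c(a$cx_nm, a$cy_nm, a$cz_nm)
    }
    row <- body_spherocylinder(r, L, center = center, axis = dir,
                               body_id = paste0(a$body_id, "m"))
    row$tether <- a$tether
    row$gap_nm <- a$gap_nm
    row$cell_id <- a$cell_id
    rows[[p]] <- row
  }
  if (n %% 2 == 1) rows[[n_pairs + 1]] <- m[n, ]
  dplyr::bind_rows(rows)
}

#' Generate a *T. hominis* developmental stage series
#'
#' Simulates `config$n_cells` cells at every stage of the configured
#' schedule (default: early, three multinucleate stages, prespore). The
#' per-cell mitosome count is uniform on `config$count_range` (default
#' 14–18), and the tether fraction follows
#' `config$stage_schedule`, rising to 0.73 at the prespore stage —
#' progressive relocation of mitosomes to the spindle pole body as meronts
#' approach cellularisation.
#'
#' @param config A [cohort_config()] with `species = "thominis"`; a
#'   missing stage in the schedule is an error.
#' @param stages Stages to generate; default all names of the schedule.
#' @return A `meront_cohort` whose `cells$stage` spans the schedule.
#' @export
generate_thominis_stage_series <- function(config,
                                           stages = names(
                                             config$stage_schedule)) {
  validate_cohort_config(config)
  if (config$species != "thominis") {
    abort("stage series generation expects species = 'thominis'")
  }
  missing <- setdiff(stages, names(config$stage_schedule))
  if (length(missing) > 0) {
    abort(paste0("stage_schedule is missing stages: ",
                 paste(missing, collapse = ", ")))
  }
  cells <- list(); mitos <- list()
  for (s_idx in seq_along(stages)) {
    stage <- stages[[s_idx]]
    frac <- config$stage_schedule[[stage]]
    for (i in seq_len(config$n_cells)) {
      cell <- with_seed(derive_seed(config$seed, s_idx * 100000 + i), {
        generate_cell(config,
                      cell_id = sprintf("%s_cell_%03d", stage, i),
                      stage = stage, tether_fraction = frac)
      })
      cells[[length(cells) + 1]] <- cell$cell
      mitos[[length(mitos) + 1]] <- cell$mitosomes
    }
  }
  new_meront_cohort(dplyr::bind_rows(cells), dplyr::bind_rows(mitos),
                    config)
}

#' Simulate SPB partition records without cell geometry
#'
#' Fast null-model companion to the full generator: assigns `n_per_cell`
#' mitosomes per cell to the two spindle pole bodies either as evenly as
#' possible (`ordered_even`) or by independent fair coin flips
#' (`binomial_random`), and classifies each cell's evenness. Used to
#' compare observed partition patterns against the random-assignment null.
#'
#' @param n_cells Number of cells.
#' @param n_per_cell Mitosomes per cell (scalar or vector).
#' @param partition_mode `"ordered_even"` or `"binomial_random"`.
#' @param seed RNG seed.
#' @return A tibble of partition records: `cell_id`, `n_spb1`, `n_spb2`,
#'   `even_or_near_even`.
#' @examples
#' simulate_partition(5, 7, "binomial_random", seed = 1)
#' @export
simulate_partition <- function(n_cells, n_per_cell,
                               partition_mode = c("ordered_even",
                                                  "binomial_random"),
                               seed = 1) {
  partition_mode <- match.arg(partition_mode)
  n <- rep_len(as.integer(n_per_cell), n_cells)
  with_seed(seed, {
    n1 <- if (partition_mode == "binomial_random") {
      rbinom(n_cells, n, 0.5)
    } else {
      n %/% 2 + (n %% 2) * sample(0:1, n_cells, replace = TRUE)
    }
    tibble::tibble(
      cell_id = sprintf("cell_%05d", seq_len(n_cells)),
      n_spb1 = as.integer(n1), n_spb2 = n - as.integer(n1),
      even_or_near_even = abs(2L * as.integer(n1) - n) <= 1L
    )
  })
}
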