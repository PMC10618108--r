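#' Cohort-level volume estimation through the virtual microtome
#'
#' Convenience drivers that run the full measurement chain on simulated
#' cells: cut each cell's mitosomes into sections, point-count the profile
#' areas, and form the Cavalieri estimate per cell.
#'
#' `estimate_volume_thin()` uses thin tomographic slices (`thin_plane`
#' mode, spacing `dz_nm`) — the reference route, essentially free of
#' overprojection. `estimate_volume_serial()` uses conventional serial
#' sections (`overprojected` mode, thickness `t_nm`, optionally recording
#' only one section in `every_k`), the route that needs the overprojection
#' correction.
#'
#' @param cohort A `meront_cohort`.
#' @param cell_ids Cells to estimate (default: all).
#' @param dz_nm Thin-slice spacing, nm.
#' @param t_nm Conventional section thickness, nm.
#' @param every_k Record one section in every `every_k` (Cavalieri spacing
#'   becomes `every_k * t_nm`).
#' @param pitch_nm Point-grid spacing for area estimation, nm.
#' @param seed Root seed; each cell derives a substream.
#' @return A tibble with one row per cell: `cell_id`, `method`,
#'   `value_nm3` (estimated total mitosome volume), `n_sections`,
#'   `point_hits`, `spacing_nm`, and the ground truth
#'   `v_true_nm3` for convenience.
#' @export
estimate_volume_thin <- function(cohort, cell_ids = NULL, dz_nm = 2,
                                 pitch_nm = 4, seed = 1) {
  estimate_volume_cells(cohort, cell_ids, mode = "thin", dz_nm = dz_nm,
                        t_nm = NA, every_k = 1, pitch_nm = pitch_nm,
                        seed = seed)
}

#' @rdname estimate_volume_thin
#' @export
estimate_volume_serial <- function(cohort, cell_ids = NULL, t_nm = 43,
                                   every_k = 1, pitch_nm = 4, seed = 1) {
  estimate_volume_cells(cohort, cell_ids, mode = "serial", dz_nm = NA,
                        t_nm = t_nm, every_k = every_k,
                        pitch_nm = pitch_nm, seed = seed)
}

estimate_volume_cells <- function(cohort, cell_ids, mode, dz_nm, t_nm,
                                  every_k, pitch_nm, seed) {
  stopifnot(inherits(cohort, "meront_cohort"))
  cell_ids <- cell_ids %||% cohort$cells$cell_id
  rows <- lapply(seq_along(cell_ids), function(i) {
    cid <- cell_ids[[i]]
    bodies <- cell_bodies(cohort, cid, include = "mitosomes")
    s_cut <- derive_seed(seed, 2L * i)
    s_grid <- derive_seed(seed, 2L * i + 1L)
    if (mode == "thin") {
      stack <- cut_tomographic(bodies, dz_nm, seed = s_cut, cell_id = cid)
    } else {
      stack <- cut_serial(bodies, t_nm, seed = s_cut, cell_id = cid)
      if (every_k > 1) {
        stack <- subsample_intermittent(stack, every_k, seed = s_cut)
      }
    }
    prof <- profile_table(stack, pitch_nm = pitch_nm, seed = s_grid)
    est <- cavalieri_volume(prof$area_nm2, stack$spacing_nm,
                            point_hits = prof$point_hits)
    tibble::tibble(
      cell_id = cid,
      method = if (mode == "thin") "thin_cavalieri" else "serial_cavalieri",
      value_nm3 = est$value_nm3,
      n_sections = length(unique(prof$section_index)),
      point_hits = est$point_hits,
      spacing_nm = stack$spacing_nm,
      v_true_nm3 = cohort$cells$V_mit_total_true_nm3[
        cohort$cells$cell_id == cid]
    )
  })
  dplyr::bind_rows(rows)
}

#' Derive the cohort overprojection factor from paired estimates
#'
#' Mirrors the tomography-based calibration: a subset of cells is measured
#' twice — once with thin tomographic slices and once with conventional
#' thick sections — and the ratio of the summed thick to summed thin
#' Cavalieri estimates is the cohort correction factor. Conventional
#' estimates are then divided by this factor ("multiplied by 1/factor").
#'
#' @inheritParams estimate_volume_thin
#' @param cell_ids Calibration subset (default: all cells — use a few, as
#'   on real material).
#' @return A list with `factor`, and the two per-cell estimate tables
#'   `thin` and `thick`.
#' @export
derive_overprojection_factor <- function(cohort, cell_ids = NULL,
                                         t_nm = 43, dz_nm = 2,
                                         pitch_nm = 4, seed = 1) {
  cell_ids <- cell_ids %||% cohort$cells$cell_id
  thin <- estimate_volume_thin(cohort, cell_ids, dz_nm = dz_nm,
                               pitch_nm = pitch_nm, seed = seed)
  thick <- estimate_volume_serial(cohort, cell_ids, t_nm = t_nm,
                                  pitch_nm = pitch_nm,
                                  seed = derive_seed(seed, 999983L))
  list(factor = overprojection_factor(sum(thin$value_nm3),
                                      sum(thick$value_nm3)),
       thin = thin, thick = thick)
}

#' Apply an overprojection correction to volume estimates
#'
#' Adds `value_corrected_nm3 = value_nm3 / factor` and records the factor;
#' raw and corrected values are always both present in the result.
#'
#' @param estimates An estimate tibble with a `value_nm3` column.
#' @param factor Overprojection factor, `> 0`.
#' @return The tibble with `value_corrected_nm3` and
#'   `correction_applied` columns.
#' @export
apply_volume_correction <- function(estimates, factor) {
  if (!is.finite(factor) || factor <= 0) {
    abort("correction factor must be > 0")
  }
  dplyr::mutate(estimates,
                value_corrected_nm3 = .data$value_nm3 / factor,
                correction_applied = factor)
}

#' Appearance-count mitosome numbers on exhaustive serial stacks
#'
#' Cuts each cell (membrane, nucleus and mitosomes, so the stack spans the
#' whole cell) into serial sections and counts mitosomes by the
#' appearance rule. Because the stack spans every body, the space beyond
#' the last section is genuinely empty and runs reaching it are terminated
#' there (`assume_empty_after = TRUE`).
#'
#' @inheritParams estimate_volume_thin
#' @param t_nm Section thickness, nm.
#' @return A tibble: `cell_id`, `n_appearance`, `n_true`.
#' @export
estimate_number_serial <- function(cohort, cell_ids = NULL, t_nm = 43,
                                   seed = 1) {
  stopifnot(inherits(cohort, "meront_cohort"))
  cell_ids <- cell_ids %||% cohort$cells$cell_id
  rows <- lapply(seq_along(cell_ids), function(i) {
    cid <- cell_ids[[i]]
    bodies <- cell_bodies(cohort, cid,
                          include = c("mitosomes", "nucleus", "cell"))
    mito_ids <- setdiff(bodies$body_id, c("nucleus", "cell"))
    stack <- cut_serial(bodies, t_nm, seed = derive_seed(seed, i),
                        cell_id = cid)
    cnt <- count_by_appearance(stack, body_ids = mito_ids,
                               assume_empty_after = TRUE)
    tibble::tibble(cell_id = cid, n_appearance = cnt$n_appearance,
                   n_true = cohort$cells$N_mit_true[
                     cohort$cells$cell_id == cid])
  })
  dplyr::bind_rows(rows)
}

#' Number and volume densities from randomly placed ministacks
#'
#' The sampling design for cells too large to section exhaustively:
#' `n_stacks` short runs of `n_sections` consecutive sections are placed
#' uniformly at random within each cell's z-extent. Mitosomes are counted
#' by appearance (a lookahead section terminates runs at the stack end
#' without truncation bias), mitosome profile areas are point-counted on a
#' fine grid in overprojected mode, and the reference cytoplasm area is
#' point-counted on a coarser grid. Reference profiles are recorded as
#' mid-plane cross-sections: compartments hundreds of times larger than
#' the section thickness gain negligible overprojection, and this keeps
#' the reference volume unbiased.
#'
#' Per cell: `nv_per_nm3 = ends / sampled cytoplasm volume` and
#' `vv = (mitosome hits x fine-grid area) / (cytoplasm hits x
#' coarse-grid area)`.
#'
#' @inheritParams estimate_volume_thin
#' @param t_nm Section thickness, nm.
#' @param n_sections Sections per ministack.
#' @param n_stacks Ministacks per cell.
#' @param pitch_struct_nm Fine grid pitch for mitosome profiles, nm.
#' @param pitch_ref_nm Coarse grid pitch for the cytoplasm reference, nm.
#' @return A tibble per cell: appearance count, sampled reference volume,
#'   `nv_per_nm3`, `vv`, and ground truth `nv_true_per_nm3`, `vv_true`.
#' @export
estimate_nv_ministacks <- function(cohort, cell_ids = NULL, t_nm = 40,
                                   n_sections = 5, n_stacks = 6,
                                   pitch_struct_nm = 10,
                                   pitch_ref_nm = 40, seed = 1) {
  stopifnot(inherits(cohort, "meront_cohort"))
  cell_ids <- cell_ids %||% cohort$cells$cell_id
  rows <- lapply(seq_along(cell_ids), function(i) {
    cid <- cell_ids[[i]]
    cell <- cohort$cells[cohort$cells$cell_id == cid, ]
    bodies <- cell_bodies(cohort, cid,
                          include = c("mitosomes", "nucleus", "cell"))
    mitos <- bodies[!bodies$body_id %in% c("nucleus", "cell"), ]
    span <- range(c(body_z_extent(bodies)$z_min_nm,
                    body_z_extent(bodies)$z_max_nm))
    len <- n_sections * t_nm
    if (span[2] - span[1] <= len) {
      abort("ministack longer than the cell's z-extent; use cut_serial()")
    }
    starts <- with_seed(derive_seed(seed, i),
                        runif(n_stacks, span[1], span[2] - len))

    # appearance ends, batched: for convex bodies the appearance rule
    # (present in a section, absent in the next, lookahead-terminated)
    # counts exactly the mitosomes whose top z_max falls inside the
    # stack's z-range -- the form used here; the equivalence with
    # count_by_appearance() on explicit stacks is pinned by a test
    z_max <- body_z_extent(mitos)$z_max_nm
    ends <- sum(vapply(starts, function(s0) {
      sum(z_max >= s0 & z_max < s0 + len)
    }, numeric(1)))

    # all real sections of all stacks, one membership batch per body
    mid <- as.vector(vapply(starts, function(s0) {
      s0 + (seq_len(n_sections) - 0.5) * t_nm
    }, numeric(n_sections)))
    z_lo <- mid - t_nm / 2
    z_hi <- mid + t_nm / 2
    n_sec <- length(mid)
    offs <- with_seed(derive_seed(seed, i + 104729L),
                      matrix(runif(4 * n_sec, 0, 1), ncol = 4))

    # cytoplasm reference: coarse grid on mid-planes (cell minus nucleus)
    cell_body <- body_sphere(cell$r_cell_nm, body_id = "cell")
    nuc_body <- body_sphere(cell$r_nuc_nm, body_id = "nucleus")
    ref <- lapply(seq_len(n_sec), function(j) {
      gx <- lattice_coords(-cell$r_cell_nm, cell$r_cell_nm, pitch_ref_nm,
                           offs[j, 1] * pitch_ref_nm)
      gy <- lattice_coords(-cell$r_cell_nm, cell$r_cell_nm, pitch_ref_nm,
                           offs[j, 2] * pitch_ref_nm)
      list(x = rep(gx, times = length(gy)), y = rep(gy, each = length(gx)),
           z = rep(mid[j], length(gx) * length(gy)))
    })
    rx <- unlist(lapply(ref, `[[`, "x"))
    ry <- unlist(lapply(ref, `[[`, "y"))
    rz <- unlist(lapply(ref, `[[`, "z"))
    hits_cyto <- sum(in_cross_section(cell_body, rx, ry, rz) &
                       !in_cross_section(nuc_body, rx, ry, rz))

    # mitosome profile areas: fine grid on overprojected slab shadows
    hits_mit <- 0
    bb_all <- body_xy_bbox(mitos)
    zext <- body_z_extent(mitos)
    for (b in seq_len(nrow(mitos))) {
      body <- mitos[b, ]
      sec <- which(zext$z_min_nm[b] < z_hi & zext$z_max_nm[b] >= z_lo)
      if (length(sec) == 0) next
      pts <- lapply(sec, function(j) {
        gx <- lattice_coords(bb_all$x_min_nm[b], bb_all$x_max_nm[b],
                             pitch_struct_nm, offs[j, 3] * pitch_struct_nm)
        gy <- lattice_coords(bb_all$y_min_nm[b], bb_all$y_max_nm[b],
                             pitch_struct_nm, offs[j, 4] * pitch_struct_nm)
        n_pts <- length(gx) * length(gy)
        list(x = rep(gx, times = length(gy)),
             y = rep(gy, each = length(gx)),
             lo = rep(z_lo[j], n_pts), hi = rep(z_hi[j], n_pts))
      })
      hits_mit <- hits_mit +
        sum(in_shadow(body, unlist(lapply(pts, `[[`, "x")),
                      unlist(lapply(pts, `[[`, "y")),
                      unlist(lapply(pts, `[[`, "lo")),
                      unlist(lapply(pts, `[[`, "hi"))))
    }
    sampled_cyto_nm3 <- hits_cyto * pitch_ref_nm^2 * t_nm
    nv <- if (sampled_cyto_nm3 > 0) ends / sampled_cyto_nm3 else NA_real_
    vv <- if (hits_cyto > 0) {
      (hits_mit * pitch_struct_nm^2) / (hits_cyto * pitch_ref_nm^2)
    } else NA_real_
    tibble::tibble(
      cell_id = cid, n_appearance = as.integer(ends),
      sampled_cyto_nm3 = sampled_cyto_nm3,
      hits_mit = hits_mit, hits_cyto = hits_cyto,
      nv_per_nm3 = nv, vv = vv,
      nv_true_per_nm3 = cell$N_mit_true / cell$V_cyto_nm3,
      vv_true = cell$V_mit_total_true_nm3 / cell$V_cyto_nm3
    )
  })
  dplyr::bind_rows(rows)
}

# cytoplasm (cell minus nucleus) grid hits over the real sections of a
# ministack, mid-plane reference profiles
cytoplasm_hits <- function(stack, cell, pitch_nm, seed) {
  slabs <- stack$slabs[!stack$slabs$lookahead, ]
  cell_body <- body_sphere(cell$r_cell_nm, body_id = "cell")
  nuc_body <- body_sphere(cell$r_nuc_nm, body_id = "nucleus")
  offs <- with_seed(seed, matrix(runif(2 * nrow(slabs), 0, pitch_nm),
                                 ncol = 2))
  total <- 0L
  for (j in seq_len(nrow(slabs))) {
    mid <- (slabs$z_lo_nm[j] + slabs$z_hi_nm[j]) / 2
    gx <- lattice_coords(-cell$r_cell_nm, cell$r_cell_nm, pitch_nm,
                         offs[j, 1])
    gy <- lattice_coords(-cell$r_cell_nm, cell$r_cell_nm, pitch_nm,
                         offs[j, 2])
    if (length(gx) == 0 || length(gy) == 0) next
    px <- rep(gx, times = length(gy))
    py <- rep(gy, each = length(gx))
    in_cell <- in_cross_section(cell_body, px, py, mid)
    in_nuc <- in_cross_section(nuc_body, px, py, mid)
    total <- total + sum(in_cell & !in_nuc)
  }
  total
}

#' Cavalieri cytoplasm volume from an intermittent section stack
#'
#' Estimates a cell's cytoplasm volume the way large compartments are
#' measured: a serial stack through the whole cell, recording one section
#' in every `every_k`, point counting the cytoplasm (cell minus nucleus)
#' on each kept section, and applying Cavalieri with spacing
#' `every_k * t_nm`. Reference profiles are mid-plane cross-sections (see
#' [estimate_nv_ministacks()]).
#'
#' @inheritParams estimate_volume_thin
#' @param t_nm Section thickness, nm.
#' @param every_k Record one section in every `every_k`.
#' @return A tibble: `cell_id`, `v_cyto_nm3` (estimate), `v_true_nm3`.
#' @export
estimate_cyto_volume_intermittent <- function(cohort, cell_ids = NULL,
                                              t_nm = 40, every_k = 5,
                                              pitch_nm = 40, seed = 1) {
  stopifnot(inherits(cohort, "meront_cohort"))
  cell_ids <- cell_ids %||% cohort$cells$cell_id
  rows <- lapply(seq_along(cell_ids), function(i) {
    cid <- cell_ids[[i]]
    cell <- cohort$cells[cohort$cells$cell_id == cid, ]
    bodies <- cell_bodies(cohort, cid, include = c("nucleus", "cell"))
    stack <- cut_serial(bodies, t_nm, seed = derive_seed(seed, i),
                        cell_id = cid)
    stack <- subsample_intermittent(stack, every_k,
                                    seed = derive_seed(seed, i + 7L))
    hits <- cytoplasm_hits(stack, cell, pitch_nm,
                           seed = derive_seed(seed, i + 13L))
    tibble::tibble(cell_id = cid,
                   v_cyto_nm3 = hits * pitch_nm^2 * stack$spacing_nm,
                   v_true_nm3 = cell$V_cyto_nm3)
  })
  dplyr::bind_rows(rows)
}
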