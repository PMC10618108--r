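#' Generate a cohort of simulated meront cells
#'
#' Builds `config$n_cells` cells, each in its own coordinate frame with the
#' nucleus centred at the origin. A cell consists of a spherical nucleus, a
#' concentric spherical cell membrane (the shell between the two is the
#' cytoplasm), two half-sphere spindle pole bodies (mSPBs) sitting on
#' opposite poles of the nuclear envelope, and a list of spherocylinder
#' mitosomes. Tethered mitosomes grow outward from the mSPB cap along a
#' jittered radial axis with cap-to-cap distance at most the contact
#' criterion; free mitosomes are placed uniformly in the cytoplasm shell by
#' rejection. Ground-truth totals (`N_mit_true`,
#' `V_mit_total_true_nm3`) are recorded per cell and never modified by the
#' estimators.
#'
#' The generator is deterministic for a fixed seed: every cell derives an
#' independent RNG substream keyed by its index, and the caller's RNG state
#' is restored on exit.
#'
#' @param config A [cohort_config()].
#' @return An object of class `meront_cohort`: a list with tibbles `cells`
#'   (one row per cell, including ground truth and the SPB partition
#'   counts) and `mitosomes` (one body row per mitosome with its tether
#'   assignment), plus the generating `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_cells = 3, seed = 42))
#' coh$cells$N_mit_true
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cells <- vector("list", config$n_cells)
  mitos <- vector("list", config$n_cells)
  for (i in seq_len(config$n_cells)) {
    cell <- with_seed(derive_seed(config$seed, i), {
      generate_cell(config,
                    cell_id = sprintf("cell_%03d", i),
                    stage = if (config$species == "ecuniculi")
                      "interphase" else "prespore",
                    tether_fraction = config$tether_fraction)
    })
    cells[[i]] <- cell$cell
    mitos[[i]] <- cell$mitosomes
  }
  out <- new_meront_cohort(dplyr::bind_rows(cells),
                           dplyr::bind_rows(mitos), config)
  if (config$perturbation == "dynamin_inhibition") {
    out <- apply_dynamin_inhibition(out)
  }
  out
}

new_meront_cohort <- function(cells, mitosomes, config) {
  structure(list(cells = cells, mitosomes = mitosomes, config = config),
            class = "meront_cohort")
}

#' @export
print.meront_cohort <- function(x, ...) {
  cat(sprintf(
    "<meront_cohort> %d cells (%s, perturbation: %s)\n",
    nrow(x$cells), x$config$species, x$config$perturbation))
  cat(sprintf("  mitosomes: %d total, mean %.2f per cell\n",
              nrow(x$mitosomes),
              nrow(x$mitosomes) / max(1, nrow(x$cells))))
  invisible(x)
}

# --- single-cell construction (runs inside the cell's RNG substream) -----

generate_cell <- function(config, cell_id, stage, tether_fraction,
                          n_fixed = NULL) {
  r_nuc <- runif(1, config$nucleus_radius_range_nm[1],
                 config$nucleus_radius_range_nm[2])
  r_cell <- r_nuc + config$cytoplasm_offset_nm
  v_nuc <- 4 / 3 * pi * r_nuc^3
  v_cyto <- 4 / 3 * pi * (r_cell^3 - r_nuc^3)

  u <- as.numeric(isotropic_directions(1)[1, ])
  r_spb <- runif(2, config$mspb_radius_range_nm[1],
                 config$mspb_radius_range_nm[2])

  n_mit <- n_fixed %||% draw_mitosome_count(config, v_nuc)

  sizes <- draw_mitosome_sizes(config, n_mit)
  tethered <- runif(n_mit) < tether_fraction
  side <- integer(n_mit)
  side[tethered] <- assign_sides(sum(tethered), config$partition_mode)

  rows <- vector("list", n_mit)
  for (j in seq_len(n_mit)) {
    mito_id <- sprintf("%s_mito_%02d", cell_id, j)
    if (tethered[j]) {
      rows[[j]] <- place_tethered(config, mito_id, sizes$r[j], sizes$L[j],
                                  r_nuc, u * c(1, -1)[side[j]],
                                  r_spb[side[j]],
                                  c("SPB1", "SPB2")[side[j]])
    } else {
      rows[[j]] <- place_free(mito_id, sizes$r[j], sizes$L[j],
                              r_nuc, r_cell)
    }
    rows[[j]]$cell_id <- cell_id
  }
  mitosomes <- dplyr::bind_rows(rows)

  cell <- tibble::tibble(
    cell_id = cell_id, species = config$species, stage = stage,
    r_nuc_nm = r_nuc, V_nuc_nm3 = v_nuc,
    r_cell_nm = r_cell, V_cyto_nm3 = v_cyto,
    spb_ux = u[1], spb_uy = u[2], spb_uz = u[3],
    r_spb1_nm = r_spb[1], r_spb2_nm = r_spb[2],
    V_spb1_nm3 = 2 / 3 * pi * r_spb[1]^3,
    V_spb2_nm3 = 2 / 3 * pi * r_spb[2]^3,
    S_spb1_nm2 = 2 * pi * r_spb[1]^2,
    S_spb2_nm2 = 2 * pi * r_spb[2]^2,
    N_mit_true = n_mit,
    V_mit_total_true_nm3 = sum(body_volume(mitosomes)),
    n_spb1 = sum(mitosomes$tether == "SPB1"),
    n_spb2 = sum(mitosomes$tether == "SPB2"),
    n_free = sum(mitosomes$tether == "free")
  )
  list(cell = cell, mitosomes = mitosomes)
}

draw_mitosome_count <- function(config, v_nuc) {
  if (config$species == "ecuniculi") {
    m <- config$count_model
    max(1L, as.integer(round(m$intercept + m$slope_per_nm3 * v_nuc +
                               rnorm(1, 0, m$sd))))
  } else {
    sample(seq(config$count_range[1], config$count_range[2]), 1)
  }
}

# diameters uniform in the minor-axis range, lengths uniform in the
# major-axis range, conditioned on L >= 2r by rejection
draw_mitosome_sizes <- function(config, n) {
  r <- numeric(n); L <- numeric(n)
  for (j in seq_len(n)) {
    for (try in 1:1000) {
      d <- runif(1, config$minor_range_nm[1], config$minor_range_nm[2])
      len <- runif(1, config$major_range_nm[1], config$major_range_nm[2])
      if (len >= d) {
        r[j] <- d / 2; L[j] <- len
        break
      }
      if (try == 1000) abort("axis-range rejection sampling did not terminate")
    }
  }
  list(r = r, L = L)
}

# ordered_even: sides differ by at most one, the surplus side random;
# binomial_random: independent fair coin per mitosome
assign_sides <- function(k, partition_mode) {
  if (k == 0) return(integer(0))
  if (partition_mode == "ordered_even") {
    n1 <- k %/% 2 + (k %% 2) * sample(0:1, 1)
    sides <- rep(c(1L, 2L), c(n1, k - n1))
    sides[sample.int(k)] # length-safe shuffle (sample(x) mangles k = 1)
  } else {
    sample(c(1L, 2L), k, replace = TRUE)
  }
}

# min distance from the segment a--b to point p (3-vectors)
segment_point_distance <- function(a, b, p) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab^2), 1e-300)
  t <- min(max(t, 0), 1)
  sqrt(sum((a + t * ab - p)^2))
}

# a unit vector within `half_angle` (radians) of unit vector u
jittered_direction <- function(u, half_angle) {
  cosang <- 1 - runif(1) * (1 - cos(half_angle))
  sinang <- sqrt(max(0, 1 - cosang^2))
  phi <- runif(1, 0, 2 * pi)
  # orthonormal frame around u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  cosang * u + sinang * (cos(phi) * e1 + sin(phi) * e2)
}

# Tethered placement: the mitosome axis points outward from the mSPB cap
# (jittered within a cone), the nearer cap surface within the contact
# distance of the mSPB cap. Jitter draws that would push the body into the
# nucleus are rejected; the purely radial direction is always valid and is
# used as the fallback.
place_tethered <- function(config, mito_id, r, L, r_nuc, u_out, r_spb,
                           tether_label) {
  spb_center <- u_out * r_nuc
  gap <- runif(1, 0, config$contact_max_nm)
  half_angle <- config$tether_jitter_deg * pi / 180
  for (try in 1:200) {
    dir <- if (try < 200) jittered_direction(u_out, half_angle) else u_out
    center <- spb_center + dir * (r_spb + gap + L / 2)
    h <- L / 2 - r
    e1 <- center - dir * h
    e2 <- center + dir * h
    if (segment_point_distance(e1, e2, c(0, 0, 0)) >= r_nuc + r) break
  }
  out <- body_spherocylinder(r, L, center = center, axis = dir,
                             body_id = mito_id)
  out$tether <- tether_label
  out$gap_nm <- gap
  out
}

# Free placement: centre uniform in the cell ball, isotropic axis,
# accepted when the whole capsule lies inside the cytoplasm shell
# (outside the nucleus, inside the cell membrane). Bounded retries.
place_free <- function(mito_id, r, L, r_nuc, r_cell) {
  h <- L / 2 - r
  for (try in 1:1000) {
    g <- rnorm(3)
    g <- g / sqrt(sum(g^2))
    center <- g * r_cell * runif(1)^(1 / 3)
    dir <- as.numeric(isotropic_directions(1)[1, ])
    e1 <- center - dir * h
    e2 <- center + dir * h
    outside_nucleus <-
      segment_point_distance(e1, e2, c(0, 0, 0)) >= r_nuc + r
    inside_cell <-
      max(sqrt(sum(e1^2)), sqrt(sum(e2^2))) + r <= r_cell
    if (outside_nucleus && inside_cell) {
      out <- body_spherocylinder(r, L, center = center, axis = dir,
                                 body_id = mito_id)
      out$tether <- "free"
      out$gap_nm <- NA_real_
      return(out)
    }
  }
  abort("free-mitosome placement rejection did not terminate")
}

# --- cell geometry accessors --------------------------------------------

#' Assemble the body table of one simulated cell
#'
#' Collects the requested components of a cell into a single body tibble
#' ready for the virtual microtome: its mitosomes, the nucleus sphere
#' (`body_id = "nucleus"`), the whole-cell sphere (`"cell"`) and the two
#' mSPB half spheres (`"SPB1"`, `"SPB2"`).
#'
#' @param cohort A `meront_cohort`.
#' @param cell_id One cell identifier from `cohort$cells`.
#' @param include Character subset of
#'   `c("mitosomes", "nucleus", "cell", "mspb")`.
#' @return A body tibble (see [body_sphere()]).
#' @export
cell_bodies <- function(cohort, cell_id,
                        include = c("mitosomes", "nucleus", "cell")) {
  stopifnot(inherits(cohort, "meront_cohort"))
  cell <- cohort$cells[cohort$cells$cell_id == cell_id, ]
  if (nrow(cell) != 1) abort(paste0("unknown cell_id: ", cell_id))
  parts <- list()
  if ("mitosomes" %in% include) {
    m <- cohort$mitosomes[cohort$mitosomes$cell_id == cell_id, ]
    parts$mitosomes <- m[setdiff(names(m), c("cell_id", "tether", "gap_nm"))]
  }
  if ("nucleus" %in% include) {
    parts$nucleus <- body_sphere(cell$r_nuc_nm, body_id = "nucleus")
  }
  if ("cell" %in% include) {
    parts$cell <- body_sphere(cell$r_cell_nm, body_id = "cell")
  }
  if ("mspb" %in% include) {
    u <- c(cell$spb_ux, cell$spb_uy, cell$spb_uz)
    parts$spb1 <- body_half_sphere(cell$r_spb1_nm, center = u * cell$r_nuc_nm,
                                   axis = u, body_id = "SPB1")
    parts$spb2 <- body_half_sphere(cell$r_spb2_nm,
                                   center = -u * cell$r_nuc_nm,
                                   axis = -u, body_id = "SPB2")
  }
  dplyr::bind_rows(parts)
}
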