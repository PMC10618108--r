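#' Square lattice point grid
#'
#' The point-counting tool: a square lattice of spacing `spacing_nm` with a
#' random (or given) offset inside one grid cell, restricted to a
#' rectangular window. Each grid point carries an area `spacing_nm^2`, so a
#' profile's area is estimated as hits times that area.
#'
#' @param spacing_nm Grid spacing `s`, nm, `> 0`.
#' @param window Numeric length-4 `c(x_min, x_max, y_min, y_max)`, nm.
#' @param offset Numeric length-2 offset in `[0, s)^2`, or `NULL` to draw
#'   one uniformly (use `seed` for reproducibility).
#' @param seed Optional seed for the offset draw.
#' @return An object of class `point_grid` with fields `spacing_nm`,
#'   `offset`, `window`, and the lattice coordinates `x`, `y`.
#' @examples
#' g <- point_grid(5, window = c(-30, 30, -30, 30), seed = 1)
#' point_count(function(x, y) x^2 + y^2 <= 625, g)
#' @export
point_grid <- function(spacing_nm, window, offset = NULL, seed = NULL) {
  if (!is.finite(spacing_nm) || spacing_nm <= 0) {
    abort("grid spacing must be > 0")
  }
  if (length(window) != 4 || window[1] >= window[2] ||
      window[3] >= window[4]) {
    abort("window must be c(x_min, x_max, y_min, y_max) with min < max")
  }
  if (is.null(offset)) {
    offset <- if (is.null(seed)) runif(2, 0, spacing_nm) else
      with_seed(seed, runif(2, 0, spacing_nm))
  }
  if (any(offset < 0) || any(offset >= spacing_nm)) {
    abort("offset must lie in [0, spacing)^2")
  }
  structure(list(
    spacing_nm = spacing_nm, offset = offset, window = window,
    x = lattice_coords(window[1], window[2], spacing_nm,
                       window[1] + offset[1]),
    y = lattice_coords(window[3], window[4], spacing_nm,
                       window[3] + offset[2])
  ), class = "point_grid")
}

#' Count grid points hitting a profile
#'
#' Applies an exact membership query at every lattice point of the grid and
#' returns the hit count; `hits * spacing^2` is the unbiased area estimate.
#' The query is a function of two vectors `(x, y)` returning logicals —
#' build one from a stack with [profile_query()].
#'
#' @param query `function(x, y) -> logical`, the profile membership test.
#' @param grid A [point_grid()] whose window covers the profile's bounding
#'   box (the caller's responsibility; [profile_query()] checks it).
#' @return Integer hit count, with the estimated `area_nm2` as an
#'   attribute.
#' @export
point_count <- function(query, grid) {
  stopifnot(inherits(grid, "point_grid"))
  if (length(grid$x) == 0 || length(grid$y) == 0) {
    hits <- 0L
  } else {
    px <- rep(grid$x, times = length(grid$y))
    py <- rep(grid$y, each = length(grid$x))
    hits <- sum(query(px, py))
  }
  structure(as.integer(hits), area_nm2 = hits * grid$spacing_nm^2)
}

#' @rdname point_count
#' @param stack A [section_stack].
#' @param body_id Body whose profile is queried.
#' @param section_index Section of the stack.
#' @export
profile_query <- function(stack, body_id, section_index) {
  stopifnot(inherits(stack, "section_stack"))
  body <- stack$bodies[stack$bodies$body_id == body_id, ]
  if (nrow(body) != 1) abort(paste0("unknown body_id: ", body_id))
  force(section_index)
  function(x, y) profile_membership(stack, body, x, y, section_index)
}

check_window_covers <- function(grid, body) {
  bb <- body_xy_bbox(body)
  if (bb$x_min_nm < grid$window[1] || bb$x_max_nm > grid$window[2] ||
      bb$y_min_nm < grid$window[3] || bb$y_max_nm > grid$window[4]) {
    abort(paste0(
      "point-grid window does not cover the profile bounding box ",
      sprintf("[%.1f, %.1f] x [%.1f, %.1f]",
              bb$x_min_nm, bb$x_max_nm, bb$y_min_nm, bb$y_max_nm)))
  }
  invisible(grid)
}

#' Cavalieri volume estimate from section areas
#'
#' The Cavalieri principle: with profile areas recorded on equally spaced
#' sections a distance `spacing_nm` apart, the volume estimate is
#' `spacing * sum(areas)`. Areas usually come from point counting, in which
#' case `V = d * s^2 * sum(P)`.
#'
#' @param areas_nm2 Non-negative per-section areas, nm^2, from equally
#'   spaced sections (every kept section, zero areas included or omitted —
#'   they do not change the sum).
#' @param spacing_nm Distance between consecutive kept sections, nm.
#' @param point_hits Optional integer hit counts behind the areas,
#'   recorded in the estimate.
#' @param quantity Label for the estimated quantity.
#' @return A one-row estimate tibble: `quantity`, `value_nm3`,
#'   `n_sections`, `spacing_nm`, `point_hits`, `ce`,
#'   `correction_applied`.
#' @examples
#' cavalieri_volume(c(100, 100), spacing_nm = 43)$value_nm3 # 8600
#' @export
cavalieri_volume <- function(areas_nm2, spacing_nm, point_hits = NA_integer_,
                             quantity = "V") {
  if (!is.finite(spacing_nm) || spacing_nm <= 0) {
    abort("section spacing must be > 0")
  }
  if (any(!is.finite(areas_nm2)) || any(areas_nm2 < 0)) {
    abort("section areas must be finite and >= 0")
  }
  tibble::tibble(
    quantity = quantity,
    value_nm3 = spacing_nm * sum(areas_nm2),
    n_sections = length(areas_nm2),
    spacing_nm = spacing_nm,
    point_hits = as.integer(sum(point_hits)),
    ce = NA_real_,
    correction_applied = NA_real_
  )
}

#' Overprojection correction factor from paired volume estimates
#'
#' Conventional finite-thickness sections imaged as projections
#' overestimate profile areas (overprojection, the Holmes effect). The
#' empirical correction compares a Cavalieri estimate from thin tomographic
#' slices with one from thick (or superslice) sections of the same objects:
#' `factor = thick / thin`, and corrected conventional estimates are
#' `raw / factor`.
#'
#' @param thin_nm3 Thin-slice (reference) volume estimate, `> 0`.
#' @param thick_nm3 Thick-section volume estimate of the same objects.
#' @return The dimensionless factor.
#' @examples
#' overprojection_factor(100, 161) # 1.61
#' @export
overprojection_factor <- function(thin_nm3, thick_nm3) {
  if (!is.finite(thin_nm3) || thin_nm3 <= 0) {
    abort("thin-slice reference estimate must be > 0")
  }
  thick_nm3 / thin_nm3
}

#' Model-based overprojection factor for a convex body
#'
#' For an isotropically oriented convex body, the mean projected area is
#' `S / 4` (Cauchy's projection formula), so a full-shadow section of
#' thickness `t` inflates the expected Cavalieri volume to
#' `V + t * S / 4`; the predicted factor is `1 + t * S / (4 V)`. For a
#' sphere this reduces to `1 + 3 t / (4 r)`. This is the standard
#' formalisation of a "model-based" overprojection prediction for
#' cylinder-like particles and is labelled as such in pipeline output.
#'
#' @param t_nm Section thickness, nm, `>= 0` (`t = 0` gives 1).
#' @param body A one-row body tibble.
#' @return The predicted factor.
#' @examples
#' model_based_factor(43, body_sphere(25)) # 2.29
#' @export
model_based_factor <- function(t_nm, body) {
  if (!is.finite(t_nm) || t_nm < 0) abort("thickness must be >= 0")
  1 + t_nm * body_surface(body) / (4 * body_volume(body))
}

#' Appearance-based particle counting in serial sections
#'
#' Counts particles by the rule "a profile present in one section but not
#' in the next adjacent section is counted": every linked profile run that
#' ends inside the stack contributes one. For convex particles whose
#' z-extent is fully spanned by the stack this count is exact, not merely
#' unbiased, in both thin-plane and overprojected modes.
#'
#' Runs still present at the last section are terminated (and counted)
#' only when something follows the last section: a lookahead section (see
#' [sample_ministacks()]) or the explicit `assume_empty_after = TRUE` flag,
#' which appends a virtual empty section. Otherwise such runs are reported
#' as truncated with a warning.
#'
#' @param stack A [section_stack].
#' @param body_ids Bodies to count (default: all mitosome-like bodies, i.e.
#'   every body in the stack).
#' @param assume_empty_after Treat the section after the last one as empty?
#' @return A one-row tibble: `n_appearance`, `n_truncated`,
#'   `n_sections_used`.
#' @export
count_by_appearance <- function(stack, body_ids = NULL,
                                assume_empty_after = FALSE) {
  pres <- profile_presence(stack, body_ids)
  if (nrow(pres) == 0) {
    return(tibble::tibble(n_appearance = 0L, n_truncated = 0L,
                          n_sections_used = 0L))
  }
  has_lookahead <- any(pres$lookahead)
  bids <- unique(pres$body_id)
  ord <- order(match(pres$body_id, bids), pres$section_index)
  sec_u <- sort(unique(pres$section_index))
  n_sec <- length(sec_u)
  mat <- matrix(pres$present[ord], nrow = n_sec, ncol = length(bids))
  n_real <- sum(!pres$lookahead[match(sec_u, pres$section_index)])
  ends <- 0L
  truncated <- 0L
  for (b in seq_len(ncol(mat))) {
    col <- mat[, b]
    run_ends <- which(col[-n_sec] & !col[-1])
    # only ends at real sections count (lookahead rows sit at the bottom)
    ends <- ends + sum(run_ends <= n_real)
    if (col[n_real] && !has_lookahead) {
      if (assume_empty_after) ends <- ends + 1L else truncated <-
          truncated + 1L
    }
  }
  if (truncated > 0) {
    warn(paste0(truncated, " profile run(s) still present at the last ",
                "section; count reported without them (truncated stack)"))
  }
  tibble::tibble(n_appearance = as.integer(ends),
                 n_truncated = as.integer(truncated),
                 n_sections_used = as.integer(n_real))
}

#' Volume fraction, number density and totals
#'
#' `volume_fraction()` is the point-count ratio `Vv = P_struct / P_ref`;
#' `number_density()` divides an appearance count by the sampled reference
#' volume (`Nv`); `estimate_total_number()` scales `Nv` back up by an
#' independently estimated reference volume. Units are the caller's:
#' volumes in nm^3 give `Nv` per nm^3.
#'
#' @param points_structure,points_reference Grid hits over the structure
#'   and over the reference space, from the same grid and sections.
#' @param appearance_count Particles counted by appearance.
#' @param reference_volume Sampled reference volume.
#' @param nv Number density.
#' @param v_ref Total reference volume.
#' @return A numeric scalar.
#' @examples
#' volume_fraction(47, 10000) # 0.0047
#' number_density(10, 2) # 5 per unit volume
#' @export
volume_fraction <- function(points_structure, points_reference) {
  if (points_reference <= 0) abort("reference point count must be > 0")
  if (points_structure < 0) abort("structure point count must be >= 0")
  points_structure / points_reference
}

#' @rdname volume_fraction
#' @export
number_density <- function(appearance_count, reference_volume) {
  if (!is.finite(reference_volume) || reference_volume <= 0) {
    abort("reference volume must be > 0")
  }
  if (appearance_count == 0) {
    warn("zero particles counted; Nv = 0 (small-sample estimate)")
  }
  appearance_count / reference_volume
}

#' @rdname volume_fraction
#' @export
estimate_total_number <- function(nv, v_ref) nv * v_ref

#' Star volume from point-sampled intercepts
#'
#' `v* = (pi / 3) * mean(l^3)` over isotropic point-sampled intercept
#' lengths `l` through the structure. For a convex body (in particular a
#' sphere) the star volume equals the volume.
#'
#' @param chord_lengths_nm Intercept lengths, nm; must be non-empty.
#' @return Star volume, nm^3.
#' @examples
#' star_volume(1) # pi / 3
#' @export
star_volume <- function(chord_lengths_nm) {
  if (length(chord_lengths_nm) == 0) {
    abort("star volume needs at least one intercept length")
  }
  if (any(!is.finite(chord_lengths_nm)) || any(chord_lengths_nm < 0)) {
    abort("intercept lengths must be finite and >= 0")
  }
  pi / 3 * mean(chord_lengths_nm^3)
}

#' @rdname star_volume
#' @param body A one-row body tibble.
#' @param n Number of intercepts.
#' @param seed RNG seed.
#' @return `sample_star_intercepts()`: numeric vector of `n` point-sampled
#'   isotropic intercept lengths through the body, nm.
#' @export
sample_star_intercepts <- function(body, n, seed = 1) {
  with_seed(seed, {
    pts <- sample_interior_points(body, n)
    dirs <- isotropic_directions(n)
    intercept_lengths(body, pts, dirs)
  })
}

#' Constriction density per unit reference volume
#'
#' Division-site (constriction) loci counted by appearance, divided by the
#' reference cytoplasm volume; doubling the loci at fixed volume doubles
#' the rate.
#'
#' @param constriction_count Appearance count of constriction loci.
#' @param cytoplasm_volume Reference volume (caller's units).
#' @return Constrictions per unit volume.
#' @examples
#' constriction_density(4, 8) # 0.5
#' @export
constriction_density <- function(constriction_count, cytoplasm_volume) {
  number_density(constriction_count, cytoplasm_volume)
}

#' Coefficients of error
#'
#' `coefficient_of_error()` is the between-cell CE of a cohort mean:
#' `(SD / sqrt(n)) / mean` over `n` independent per-cell estimates — the
#' `CE_n` attached to cohort means in reports. The within-stack CE of one
#' systematic (Cavalieri) series, `ce_systematic()`, is the
#' Gundersen–Jensen form
#' `sqrt((3 A - 4 B + C) / 12) / sum(a)` with `A = sum(a_i^2)`,
#' `B = sum(a_i a_(i+1))`, `C = sum(a_i a_(i+2))`; it is provided as a
#' separate, clearly named output and never silently substituted for the
#' between-cell CE.
#'
#' @param values Per-cell estimates, `n >= 2`.
#' @param areas_nm2 Ordered per-section areas of one systematic series.
#' @return Dimensionless CE.
#' @examples
#' coefficient_of_error(c(1, 2, 3)) # 0.2887
#' @export
coefficient_of_error <- function(values) {
  if (length(values) < 2) abort("CE needs at least two per-cell estimates")
  m <- mean(values)
  if (m == 0) abort("CE undefined for zero mean")
  (sd(values) / sqrt(length(values))) / m
}

#' @rdname coefficient_of_error
#' @export
ce_systematic <- function(areas_nm2) {
  a <- areas_nm2
  if (length(a) < 3 || sum(a) == 0) return(NA_real_)
  A <- sum(a^2)
  B <- sum(head(a, -1) * tail(a, -1))
  C <- sum(head(a, -2) * tail(a, -2))
  sqrt(max(0, 3 * A - 4 * B + C) / 12) / sum(a)
}
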