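#' Section stacks: the virtual microtome output
#'
#' A `section_stack` is an ordered set of contiguous slabs of stated
#' thickness along the global z (cutting) axis, carrying the body table it
#' was cut from. Two profile modes exist:
#'
#' * `thin_plane` — each section's profile is the mid-plane cross-section
#'   (the tomographic-slice model);
#' * `overprojected` — each section's profile is the full slab shadow (a
#'   finite-thickness section imaged as a projection, the conventional-TEM
#'   model). Superslices assembled from thin stacks use the discrete
#'   shadow: the union of their member cross-sections.
#'
#' Profiles keep the identity of their generating body (simulation truth),
#' and exact membership queries are used by the estimators; rasterised
#' masks appear only where unions are needed.
#'
#' @name section_stack
NULL

new_section_stack <- function(slabs, mode, bodies, phase_nm,
                              spacing_nm, member_z = NULL,
                              cell_id = NA_character_) {
  structure(list(slabs = slabs, mode = mode, bodies = bodies,
                 phase_nm = phase_nm, spacing_nm = spacing_nm,
                 member_z = member_z, cell_id = cell_id),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("<section_stack> %d sections, mode %s, spacing %.3g nm\n",
              nrow(x$slabs), x$mode, x$spacing_nm))
  invisible(x)
}

bodies_z_span <- function(bodies) {
  if (nrow(bodies) == 0) return(NULL)
  ext <- body_z_extent(bodies)
  c(min(ext$z_min_nm), max(ext$z_max_nm))
}

make_slabs <- function(z0, z1, t, phase) {
  start <- z0 - phase
  n <- max(1L, as.integer(ceiling((z1 - start) / t - 1e-12)))
  idx <- seq_len(n)
  tibble::tibble(section_index = idx,
                 z_lo_nm = start + (idx - 1) * t,
                 z_hi_nm = start + idx * t,
                 t_nm = t,
                 lookahead = FALSE)
}

#' Cut a body table into serial sections or tomographic slices
#'
#' `cut_serial()` produces conventional serial sections of thickness `t_nm`
#' in `overprojected` mode; `cut_tomographic()` produces thin tomographic
#' slices of spacing `dz_nm` in `thin_plane` mode (profiles are mid-plane
#' cross-sections). In both, the stack spans the full z-extent of the
#' bodies and the first slab boundary sits at a random phase uniform on
#' `[0, t)` below the lowest body point, so section positions are
#' unbiased. Fix `phase_nm` (or `seed`) for reproducible cuts. An empty
#' body table yields an empty stack.
#'
#' @param bodies A body tibble (e.g. from [cell_bodies()]).
#' @param t_nm,dz_nm Section thickness / slice spacing, nm, `> 0`.
#' @param seed Optional seed for the phase draw.
#' @param phase_nm Optional explicit phase in `[0, t)`; overrides `seed`.
#' @param cell_id Optional label carried into profile tables.
#' @return A [section_stack].
#' @examples
#' st <- cut_serial(body_sphere(25), t_nm = 43, seed = 1)
#' nrow(st$slabs) # 2 or 3 depending on the phase
#' @export
cut_serial <- function(bodies, t_nm, seed = NULL, phase_nm = NULL,
                       cell_id = NA_character_) {
  cut_stack(bodies, t_nm, "overprojected", seed, phase_nm, cell_id)
}

#' @rdname cut_serial
#' @export
cut_tomographic <- function(bodies, dz_nm, seed = NULL, phase_nm = NULL,
                            cell_id = NA_character_) {
  cut_stack(bodies, dz_nm, "thin_plane", seed, phase_nm, cell_id)
}

cut_stack <- function(bodies, t, mode, seed, phase, cell_id) {
  if (!is.finite(t) || t <= 0) abort("section thickness must be > 0")
  validate_bodies(bodies)
  span <- bodies_z_span(bodies)
  if (is.null(span)) {
    return(new_section_stack(make_slabs(0, 0, t, 0)[0, ], mode, bodies,
                             NA_real_, t, cell_id = cell_id))
  }
  if (is.null(phase)) {
    phase <- if (is.null(seed)) runif(1, 0, t) else
      with_seed(seed, runif(1, 0, t))
  }
  if (phase < 0 || phase >= t) abort("phase_nm must lie in [0, t)")
  new_section_stack(make_slabs(span[1], span[2], t, phase), mode, bodies,
                    phase, t, cell_id = cell_id)
}

#' Assemble thin slices into overprojected superslices
#'
#' Merges consecutive groups of `k` thin slices into blocks whose profile
#' is the union of the member cross-sections — the discrete shadow that
#' emulates a conventional section of thickness `k * dz` built from
#' tomographic slices. `k = 1` returns the stack unchanged.
#'
#' @param thin A `thin_plane` [section_stack].
#' @param k Number of member slices per superslice, `>= 1`.
#' @return An `overprojected` [section_stack] whose slabs carry their
#'   member mid-plane positions.
#' @export
assemble_superslices <- function(thin, k) {
  stopifnot(inherits(thin, "section_stack"))
  if (thin$mode != "thin_plane") {
    abort("superslices are assembled from a thin_plane stack")
  }
  if (!is.finite(k) || k < 1) abort("k must be >= 1")
  k <- as.integer(k)
  if (k == 1L) return(thin)
  if (nrow(thin$slabs) == 0) return(thin)
  grp <- (thin$slabs$section_index - 1L) %/% k
  mids <- (thin$slabs$z_lo_nm + thin$slabs$z_hi_nm) / 2
  slabs <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(grp = grp,
                                   z_lo = thin$slabs$z_lo_nm,
                                   z_hi = thin$slabs$z_hi_nm), grp),
    z_lo_nm = min(.data$z_lo), z_hi_nm = max(.data$z_hi), .groups = "drop")
  slabs <- tibble::tibble(section_index = seq_len(nrow(slabs)),
                          z_lo_nm = slabs$z_lo_nm, z_hi_nm = slabs$z_hi_nm,
                          t_nm = slabs$z_hi_nm - slabs$z_lo_nm,
                          lookahead = FALSE)
  member_z <- split(mids, grp)
  names(member_z) <- NULL
  new_section_stack(slabs, "overprojected", thin$bodies, thin$phase_nm,
                    spacing_nm = k * thin$spacing_nm, member_z = member_z,
                    cell_id = thin$cell_id)
}

#' Keep one section in every k (intermittent sampling)
#'
#' Systematic subsampling of a serial stack: keeps sections whose index is
#' congruent to a random residue modulo `every_k`, and records the new
#' inter-section spacing `every_k * t` for Cavalieri estimation — the
#' "one in every five sections" recording scheme.
#'
#' @param stack A [section_stack].
#' @param every_k Keep one section in every `every_k`, `>= 1`.
#' @param seed Optional seed for the residue draw.
#' @param start Optional explicit residue in `1..every_k`.
#' @return A [section_stack] with the kept slabs and updated
#'   `spacing_nm`.
#' @export
subsample_intermittent <- function(stack, every_k, seed = NULL,
                                   start = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  if (!is.finite(every_k) || every_k < 1) abort("every_k must be >= 1")
  every_k <- as.integer(every_k)
  if (every_k == 1L) return(stack)
  if (is.null(start)) {
    start <- if (is.null(seed)) sample(seq_len(every_k), 1) else
      with_seed(seed, sample(seq_len(every_k), 1))
  }
  keep <- ((stack$slabs$section_index - start) %% every_k) == 0
  out <- stack
  out$slabs <- stack$slabs[keep, ]
  out$member_z <- if (!is.null(stack$member_z)) stack$member_z[keep]
  out$spacing_nm <- every_k * stack$spacing_nm
  out
}

#' Randomly placed ministacks of serial sections
#'
#' Samples `n_stacks` short runs of `n_sections` consecutive sections of
#' thickness `t_nm`, with start positions uniform over the bodies' z-extent
#' (stacks never extend beyond the bounding box). Used for number- and
#' volume-density estimation in cells too large for exhaustive serial
#' sectioning. With `lookahead = TRUE` (default) one extra flagged section
#' is appended to each stack so appearance counting can terminate runs at
#' the last real section without truncation bias; the lookahead section is
#' not part of the sampled volume.
#'
#' @param bodies A body tibble.
#' @param t_nm Section thickness, nm.
#' @param n_sections Sections per ministack, `>= 2`.
#' @param n_stacks Number of ministacks (0 gives an empty list).
#' @param seed Seed for start positions.
#' @param lookahead Append the extra run-terminating section?
#' @param cell_id Optional label carried into profile tables.
#' @return A list of `overprojected` [section_stack]s.
#' @export
sample_ministacks <- function(bodies, t_nm, n_sections, n_stacks, seed,
                              lookahead = TRUE,
                              cell_id = NA_character_) {
  if (n_sections < 2) abort("a ministack needs at least 2 sections")
  if (n_stacks == 0) return(list())
  validate_bodies(bodies)
  span <- bodies_z_span(bodies)
  if (is.null(span)) abort("cannot place ministacks in an empty body table")
  len <- n_sections * t_nm
  if (span[2] - span[1] <= len) {
    abort("ministack longer than the bodies' z-extent; use cut_serial()")
  }
  starts <- with_seed(seed, runif(n_stacks, span[1], span[2] - len))
  lapply(seq_len(n_stacks), function(s) {
    idx <- seq_len(n_sections + as.integer(lookahead))
    slabs <- tibble::tibble(
      section_index = idx,
      z_lo_nm = starts[s] + (idx - 1) * t_nm,
      z_hi_nm = starts[s] + idx * t_nm,
      t_nm = t_nm,
      lookahead = idx > n_sections
    )
    new_section_stack(slabs, "overprojected", bodies, NA_real_, t_nm,
                      cell_id = cell_id)
  })
}

# --- profile queries -----------------------------------------------------

# membership of points (x, y) in the profile of `body` at one slab,
# honouring the stack's profile mode
profile_membership <- function(stack, body, x, y, slab_index) {
  slab <- stack$slabs[stack$slabs$section_index == slab_index, ]
  if (nrow(slab) != 1) abort("unknown section_index")
  if (stack$mode == "thin_plane") {
    in_cross_section(body, x, y, (slab$z_lo_nm + slab$z_hi_nm) / 2)
  } else if (!is.null(stack$member_z)) {
    pos <- match(slab_index, stack$slabs$section_index)
    zs <- stack$member_z[[pos]]
    Reduce(`|`, lapply(zs, function(z) in_cross_section(body, x, y, z)))
  } else {
    in_shadow(body, x, y, slab$z_lo_nm, slab$z_hi_nm)
  }
}

#' Exact per-section presence of every body in a stack
#'
#' For each (section, body) pair, reports whether the body's profile is
#' non-empty in that section, using exact z-extent interval logic (not the
#' rasterised mask), so convex bodies always yield one contiguous run of
#' presence. This is the input of appearance-based counting.
#'
#' @param stack A [section_stack].
#' @param body_ids Bodies to include (default: all in the stack).
#' @return A tibble `section_index`, `body_id`, `present`, `lookahead`.
#' @export
profile_presence <- function(stack, body_ids = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  bodies <- stack$bodies
  if (!is.null(body_ids)) bodies <- bodies[bodies$body_id %in% body_ids, ]
  if (nrow(stack$slabs) == 0 || nrow(bodies) == 0) {
    return(tibble::tibble(section_index = integer(0),
                          body_id = character(0), present = logical(0),
                          lookahead = logical(0)))
  }
  ext <- body_z_extent(bodies)
  ns <- nrow(stack$slabs)
  nb <- nrow(bodies)
  # body-major layout: all sections of body 1, then body 2, ...
  si <- rep(stack$slabs$section_index, nb)
  z_lo <- rep(stack$slabs$z_lo_nm, nb)
  z_hi <- rep(stack$slabs$z_hi_nm, nb)
  look <- rep(stack$slabs$lookahead, nb)
  z_min <- rep(ext$z_min_nm, each = ns)
  z_max <- rep(ext$z_max_nm, each = ns)
  present <- if (stack$mode == "thin_plane") {
    mid <- (z_lo + z_hi) / 2
    mid >= z_min & mid <= z_max
  } else if (!is.null(stack$member_z)) {
    pos <- rep(seq_len(ns), nb)
    vapply(seq_along(si), function(i) {
      zs <- stack$member_z[[pos[i]]]
      any(zs >= z_min[i] & zs <= z_max[i])
    }, logical(1))
  } else {
    z_min < z_hi & z_max >= z_lo
  }
  tibble::tibble(section_index = si,
                 body_id = rep(bodies$body_id, each = ns),
                 present = present, lookahead = look)
}

#' Point-counted profile table of a stack
#'
#' Emulates the manual workflow: on every section, a square lattice grid of
#' pitch `pitch_nm` is positioned with a random offset, and each body's
#' profile area is estimated as (grid hits) x (area per point), using the
#' exact membership query of the stack's profile mode. One grid position is
#' drawn per section and shared by all bodies, as on a real micrograph.
#'
#' @param stack A [section_stack].
#' @param pitch_nm Grid spacing, nm.
#' @param seed Seed for grid offsets (one offset pair per section).
#' @param body_ids Bodies to tabulate (default: all).
#' @return A profile tibble: `cell_id`, `body_id`, `section_index`,
#'   `z_lo_nm`, `t_nm`, `mode`, `point_hits`, `area_nm2`, `grid_pitch_nm`,
#'   `format_version`.
#' @export
profile_table <- function(stack, pitch_nm = 4, seed = NULL,
                          body_ids = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  if (!is.finite(pitch_nm) || pitch_nm <= 0) abort("pitch_nm must be > 0")
  pres <- profile_presence(stack, body_ids)
  pres <- pres[pres$present & !pres$lookahead, ]
  slabs <- stack$slabs
  n_sec <- nrow(slabs)
  offsets <- if (is.null(seed)) {
    matrix(runif(2 * n_sec, 0, pitch_nm), ncol = 2)
  } else {
    with_seed(seed, matrix(runif(2 * n_sec, 0, pitch_nm), ncol = 2))
  }
  bodies <- stack$bodies
  bb_all <- body_xy_bbox(bodies)
  discrete <- !is.null(stack$member_z)
  out <- dplyr::bind_rows(lapply(unique(pres$body_id), function(bid) {
    body <- bodies[bodies$body_id == bid, ]
    bb <- bb_all[bb_all$body_id == bid, ]
    secs <- pres$section_index[pres$body_id == bid]
    pos <- match(secs, slabs$section_index)
    # one concatenated point set per body, then a single membership call
    per_sec <- lapply(seq_along(secs), function(j) {
      gx <- lattice_coords(bb$x_min_nm, bb$x_max_nm, pitch_nm,
                           offsets[pos[j], 1])
      gy <- lattice_coords(bb$y_min_nm, bb$y_max_nm, pitch_nm,
                           offsets[pos[j], 2])
      if (length(gx) == 0 || length(gy) == 0) return(NULL)
      n_pts <- length(gx) * length(gy)
      list(x = rep(gx, times = length(gy)), y = rep(gy, each = length(gx)),
           sec = rep(secs[j], n_pts), pos = rep(pos[j], n_pts))
    })
    per_sec <- per_sec[!vapply(per_sec, is.null, logical(1))]
    pts <- list(x = unlist(lapply(per_sec, `[[`, "x")),
                y = unlist(lapply(per_sec, `[[`, "y")),
                sec = unlist(lapply(per_sec, `[[`, "sec")),
                pos = unlist(lapply(per_sec, `[[`, "pos")))
    hits <- if (length(pts$x) == 0) {
      integer(0)
    } else if (stack$mode == "thin_plane") {
      mid <- (slabs$z_lo_nm[pts$pos] + slabs$z_hi_nm[pts$pos]) / 2
      in_cross_section(body, pts$x, pts$y, mid)
    } else if (discrete) {
      # discrete shadow: union over member mid-planes, per section
      res <- logical(length(pts$x))
      for (s in unique(pts$sec)) {
        ii <- which(pts$sec == s)
        res[ii] <- profile_membership(stack, body, pts$x[ii], pts$y[ii], s)
      }
      res
    } else {
      in_shadow(body, pts$x, pts$y, slabs$z_lo_nm[pts$pos],
                slabs$z_hi_nm[pts$pos])
    }
    n_hit <- if (length(hits) == 0) {
      setNames(integer(length(secs)), secs)
    } else {
      tab <- tapply(hits, factor(pts$sec, levels = secs), sum)
      tab[is.na(tab)] <- 0
      tab
    }
    tibble::tibble(
      cell_id = stack$cell_id, body_id = bid, section_index = secs,
      z_lo_nm = slabs$z_lo_nm[pos], t_nm = slabs$t_nm[pos],
      mode = stack$mode, point_hits = as.integer(n_hit),
      area_nm2 = as.numeric(n_hit) * pitch_nm^2, grid_pitch_nm = pitch_nm,
      format_version = ms_format_version()
    )
  }))
  if (nrow(out) == 0) {
    out <- tibble::tibble(cell_id = character(0), body_id = character(0),
                          section_index = integer(0), z_lo_nm = numeric(0),
                          t_nm = numeric(0), mode = character(0),
                          point_hits = integer(0), area_nm2 = numeric(0),
                          grid_pitch_nm = numeric(0),
                          format_version = character(0))
  }
  out
}

# lattice coordinates u + k * s covering [lo, hi]
lattice_coords <- function(lo, hi, s, offset) {
  k0 <- ceiling((lo - offset) / s)
  k1 <- floor((hi - offset) / s)
  if (k1 < k0) return(numeric(0))
  offset + (k0:k1) * s
}
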