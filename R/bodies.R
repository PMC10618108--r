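#' Parametric 3D solids for virtual stereology
#'
#' Bodies are stored as rows of a plain tibble so that whole cells (a
#' nucleus, two spindle pole bodies and a list of mitosomes) can be carried
#' around, filtered and joined with ordinary dplyr verbs. Three kinds are
#' supported:
#'
#' * `sphere` — radius `r_nm`, used for nuclei and whole cells;
#' * `spherocylinder` — a cylinder with hemispherical caps ("dumbbell"),
#'   radius `r_nm` and tip-to-tip length `L_nm >= 2 r_nm`; the degenerate
#'   case `L = 2r` is a sphere. This is the mitosome model;
#' * `half_sphere` — a hemisphere whose flat face sits on the nuclear
#'   envelope; the model for the microsporidian spindle pole body (mSPB).
#'
#' All coordinates are nanometres. `axis` must be a unit vector (tolerance
#' `1e-9`); it is ignored for spheres and stored as (0, 0, 1).
#'
#' @param r_nm Radius in nm, `> 0`.
#' @param L_nm Total tip-to-tip length in nm (spherocylinder only),
#'   `>= 2 * r_nm`.
#' @param center Numeric length-3 centre, nm. For a spherocylinder this is
#'   the midpoint of the axis; for a half sphere the centre of the flat
#'   face.
#' @param axis Numeric length-3 unit vector (spherocylinder and half
#'   sphere).
#' @param body_id Identifier stored with the row.
#' @return A one-row tibble with columns `body_id`, `kind`, `cx_nm`,
#'   `cy_nm`, `cz_nm`, `ax`, `ay`, `az`, `r_nm`, `L_nm`.
#' @examples
#' b <- body_spherocylinder(25, 150, axis = c(1, 0, 0))
#' body_volume(b)
#' @export
body_sphere <- function(r_nm, center = c(0, 0, 0), body_id = "body") {
  new_body(body_id, "sphere", center, c(0, 0, 1), r_nm, NA_real_)
}

#' @rdname body_sphere
#' @export
body_spherocylinder <- function(r_nm, L_nm, center = c(0, 0, 0),
                                axis = c(0, 0, 1), body_id = "body") {
  new_body(body_id, "spherocylinder", center, axis, r_nm, L_nm)
}

#' @rdname body_sphere
#' @export
body_half_sphere <- function(r_nm, center = c(0, 0, 0), axis = c(0, 0, 1),
                             body_id = "body") {
  new_body(body_id, "half_sphere", center, axis, r_nm, NA_real_)
}

new_body <- function(body_id, kind, center, axis, r_nm, L_nm) {
  stopifnot(length(center) == 3, length(axis) == 3)
  out <- tibble::tibble(
    body_id = as.character(body_id), kind = kind,
    cx_nm = center[[1]], cy_nm = center[[2]], cz_nm = center[[3]],
    ax = axis[[1]], ay = axis[[2]], az = axis[[3]],
    r_nm = as.numeric(r_nm), L_nm = as.numeric(L_nm)
  )
  validate_bodies(out)
}

#' Validate a body table
#'
#' Checks the geometric invariants: positive radii, `L >= 2r` for
#' spherocylinders, unit axes (within `1e-9`) for oriented kinds, and known
#' kinds. Returns its input invisibly-compatible for piping.
#'
#' @param bodies A body tibble (see [body_sphere()]).
#' @return The validated tibble.
#' @export
validate_bodies <- function(bodies) {
  req <- c("body_id", "kind", "cx_nm", "cy_nm", "cz_nm",
           "ax", "ay", "az", "r_nm", "L_nm")
  missing <- setdiff(req, names(bodies))
  if (length(missing) > 0) {
    abort(paste0("body table is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad_kind <- setdiff(unique(bodies$kind),
                      c("sphere", "spherocylinder", "half_sphere"))
  if (length(bad_kind) > 0) {
    abort(paste0("unknown body kind: ", paste(bad_kind, collapse = ", ")))
  }
  if (any(!is.finite(bodies$r_nm)) || any(bodies$r_nm <= 0)) {
    abort("body radius r_nm must be finite and > 0")
  }
  sc <- bodies$kind == "spherocylinder"
  if (any(sc)) {
    if (any(!is.finite(bodies$L_nm[sc]))) {
      abort("spherocylinder requires a finite total length L_nm")
    }
    if (any(bodies$L_nm[sc] < 2 * bodies$r_nm[sc] - 1e-9)) {
      abort("spherocylinder requires L_nm >= 2 * r_nm (tip-to-tip length)")
    }
  }
  oriented <- bodies$kind != "sphere"
  if (any(oriented)) {
    n2 <- bodies$ax[oriented]^2 + bodies$ay[oriented]^2 +
      bodies$az[oriented]^2
    if (any(abs(n2 - 1) > 1e-9)) {
      abort("body axis must be a unit vector (|axis| = 1 within 1e-9)")
    }
  }
  bodies
}

# one-row tibble -> plain list for scalar access in hot loops
as_body <- function(bodies) {
  stopifnot(nrow(bodies) == 1)
  as.list(bodies[1, ])
}

# half length of the spherocylinder axis segment (cap centres sit at +-h)
sc_half <- function(body) body$L_nm / 2 - body$r_nm

#' Exact volume and surface area of a body
#'
#' Closed forms: sphere `(4/3) pi r^3` and `4 pi r^2`; spherocylinder
#' `pi r^2 (L - 2r) + (4/3) pi r^3` and `2 pi r (L - 2r) + 4 pi r^2`;
#' half sphere `(2/3) pi r^3` and, by convention, the curved cap only,
#' `2 pi r^2` — the flat face sits on the nuclear envelope and is excluded
#' because the occupancy model counts mitosome footprints on the
#' cytoplasm-facing surface.
#'
#' @param bodies A body tibble; the functions are vectorised over rows.
#' @return Numeric vector, nm^3 (`body_volume`) or nm^2 (`body_surface`).
#' @examples
#' body_volume(body_sphere(25)) # 65449.8 nm^3
#' body_surface(body_half_sphere(25)) # 3927 nm^2, curved cap only
#' @export
body_volume <- function(bodies) {
  validate_bodies(bodies)
  r <- bodies$r_nm
  cyl <- ifelse(bodies$kind == "spherocylinder",
                pi * r^2 * (bodies$L_nm - 2 * r), 0)
  caps <- dplyr::case_match(bodies$kind,
    "sphere" ~ 4 / 3 * pi * r^3,
    "spherocylinder" ~ 4 / 3 * pi * r^3,
    "half_sphere" ~ 2 / 3 * pi * r^3
  )
  cyl + caps
}

#' @rdname body_volume
#' @export
body_surface <- function(bodies) {
  validate_bodies(bodies)
  r <- bodies$r_nm
  cyl <- ifelse(bodies$kind == "spherocylinder",
                2 * pi * r * (bodies$L_nm - 2 * r), 0)
  caps <- dplyr::case_match(bodies$kind,
    "sphere" ~ 4 * pi * r^2,
    "spherocylinder" ~ 4 * pi * r^2,
    "half_sphere" ~ 2 * pi * r^2
  )
  cyl + caps
}

#' Axis-aligned extents of bodies
#'
#' `body_z_extent()` returns the exact minimum and maximum z reached by
#' each solid (the cutting axis is the global z axis); `body_xy_bbox()` a
#' conservative bounding rectangle in the section plane. Both are used to
#' decide which sections a body can appear in and to size point-counting
#' windows.
#'
#' @param bodies A body tibble.
#' @return A tibble with one row per body: `z_min_nm`/`z_max_nm`, or
#'   `x_min_nm`/`x_max_nm`/`y_min_nm`/`y_max_nm`.
#' @export
body_z_extent <- function(bodies) {
  validate_bodies(bodies)
  r <- bodies$r_nm
  az <- bodies$az
  h <- ifelse(bodies$kind == "spherocylinder", bodies$L_nm / 2 - r, 0)
  # half_sphere: extreme z over unit vectors u with u . axis >= 0
  u_max <- ifelse(az >= 0, 1, sqrt(pmax(0, 1 - az^2)))
  u_min <- ifelse(az <= 0, -1, -sqrt(pmax(0, 1 - az^2)))
  lo <- dplyr::case_match(bodies$kind,
    "sphere" ~ -r,
    "spherocylinder" ~ -(h * abs(az) + r),
    "half_sphere" ~ r * u_min
  )
  hi <- dplyr::case_match(bodies$kind,
    "sphere" ~ r,
    "spherocylinder" ~ h * abs(az) + r,
    "half_sphere" ~ r * u_max
  )
  tibble::tibble(body_id = bodies$body_id,
                 z_min_nm = bodies$cz_nm + lo,
                 z_max_nm = bodies$cz_nm + hi)
}

#' @rdname body_z_extent
#' @export
body_xy_bbox <- function(bodies) {
  validate_bodies(bodies)
  r <- bodies$r_nm
  h <- ifelse(bodies$kind == "spherocylinder", bodies$L_nm / 2 - r, 0)
  dx <- h * abs(bodies$ax) + r
  dy <- h * abs(bodies$ay) + r
  tibble::tibble(body_id = bodies$body_id,
                 x_min_nm = bodies$cx_nm - dx, x_max_nm = bodies$cx_nm + dx,
                 y_min_nm = bodies$cy_nm - dy, y_max_nm = bodies$cy_nm + dy)
}

#' Exact membership queries: thin cross-sections and slab shadows
#'
#' `in_cross_section()` tests whether points `(x, y, z_plane)` lie inside
#' one solid — the thin-plane (tomographic slice) profile model. For a
#' spherocylinder a point is inside iff its distance to the axis segment is
#' at most `r`.
#'
#' `in_shadow()` tests whether a vertical line at `(x, y)` meets the solid
#' anywhere in the half-open slab `[z_lo, z_hi)` — the full-projection
#' shadow of a finite-thickness section imaged as a projection
#' (overprojection, also called the Holmes effect). Because every body kind
#' is convex, the set of z at which a vertical line is inside the body is
#' an interval; the query reduces to interval intersection (sphere, half
#' sphere) or to minimising the convex point-to-segment distance over z
#' (spherocylinder).
#'
#' Comparisons are strict `<=` on squared distances in exact arithmetic —
#' no epsilon inflation — so boundary behaviour is testable.
#'
#' @param body A one-row body tibble.
#' @param x,y Numeric vectors of section-plane coordinates, nm (recycled
#'   against each other).
#' @param z_plane Scalar or vector z of the cutting plane, nm.
#' @param z_lo,z_hi Slab bounds, nm; the slab is `[z_lo, z_hi)`. Scalars or
#'   vectors parallel to `x`.
#' @return Logical vector.
#' @examples
#' s <- body_sphere(25)
#' in_cross_section(s, 0, 0, z_plane = 25.1) # FALSE, beyond the pole
#' in_shadow(s, 0, 24, z_lo = 20, z_hi = 63) # FALSE, max in-slab radius 15
#' @export
in_cross_section <- function(body, x, y, z_plane) {
  b <- as_body(validate_bodies(body))
  n <- max(length(x), length(y), length(z_plane))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z_plane, n)
  wx <- x - b$cx_nm; wy <- y - b$cy_nm; wz <- z - b$cz_nm
  r2 <- b$r_nm^2
  switch(b$kind,
    sphere = wx^2 + wy^2 + wz^2 <= r2,
    half_sphere = {
      (wx^2 + wy^2 + wz^2 <= r2) &
        (wx * b$ax + wy * b$ay + wz * b$az >= 0)
    },
    spherocylinder = {
      h <- sc_half(b)
      tproj <- pmin(pmax(wx * b$ax + wy * b$ay + wz * b$az, -h), h)
      (wx - tproj * b$ax)^2 + (wy - tproj * b$ay)^2 +
        (wz - tproj * b$az)^2 <= r2
    }
  )
}

#' @rdname in_cross_section
#' @export
in_shadow <- function(body, x, y, z_lo, z_hi) {
  b <- as_body(validate_bodies(body))
  n <- max(length(x), length(y), length(z_lo), length(z_hi))
  x <- rep_len(x, n); y <- rep_len(y, n)
  z_lo <- rep_len(z_lo, n); z_hi <- rep_len(z_hi, n)
  if (any(z_hi <= z_lo)) abort("slab must have z_hi > z_lo")
  wx <- x - b$cx_nm; wy <- y - b$cy_nm
  r2 <- b$r_nm^2
  switch(b$kind,
    sphere = {
      rho2 <- wx^2 + wy^2
      s <- sqrt(pmax(0, r2 - rho2))
      # z-interval of the vertical line inside the ball vs [z_lo, z_hi)
      rho2 <= r2 & (b$cz_nm - s) < z_hi & (b$cz_nm + s) >= z_lo
    },
    half_sphere = {
      rho2 <- wx^2 + wy^2
      s <- sqrt(pmax(0, r2 - rho2))
      zA <- b$cz_nm - s
      zB <- b$cz_nm + s
      q <- wx * b$ax + wy * b$ay
      if (abs(b$az) < 1e-12) {
        ok <- q >= 0
        rho2 <= r2 & ok & zA < z_hi & zB >= z_lo
      } else {
        zcut <- b$cz_nm - q / b$az
        if (b$az > 0) zA <- pmax(zA, zcut) else zB <- pmin(zB, zcut)
        rho2 <= r2 & zA <= zB & zA < z_hi & zB >= z_lo
      }
    },
    spherocylinder = sc_shadow(b, wx, wy, z_lo - b$cz_nm, z_hi - b$cz_nm, r2)
  )
}

# Shadow test for a spherocylinder. The squared distance f(z) from the
# point (x, y, z) to the axis segment is convex and piecewise quadratic in
# z (three pieces: projection clamped at -h, free, clamped at +h). The
# minimum over the slab is therefore attained at one of the piece
# minimisers clamped into the slab, or at a slab boundary; evaluating the
# true f at all candidates and taking the smallest is exact. The z_hi
# boundary is open, so membership attained only exactly at z_hi (with
# equality) does not count.
sc_shadow <- function(b, wx, wy, lo, hi, r2) {
  h <- sc_half(b)
  q <- wx * b$ax + wy * b$ay       # axis component of the xy offset
  p2 <- wx^2 + wy^2
  az <- b$az
  az2 <- az^2
  f_at <- function(zeta) {
    tproj <- pmin(pmax(q + az * zeta, -h), h)
    p2 + zeta^2 - 2 * tproj * (q + az * zeta) + tproj^2
  }
  z_int <- if (az2 < 1) az * q / (1 - az2) else 0
  cand <- function(z) pmin(pmax(z, lo), hi)
  m_closed <- pmin(f_at(cand(z_int)), f_at(cand(h * az)),
                   f_at(cand(-h * az)), f_at(lo))
  m_closed <= r2 | f_at(hi) < r2
}

#' Random points and isotropic directions
#'
#' `sample_interior_points()` draws points uniformly inside a body by
#' rejection from its bounding box; `isotropic_directions()` draws unit
#' vectors uniformly on the sphere (z-component uniform on \[-1, 1\],
#' azimuth uniform on \[0, 2 pi)). Both consume the current RNG stream, so
#' wrap calls in `set.seed()` (or pass through the package generators,
#' which manage seeding).
#'
#' @param body A one-row body tibble.
#' @param n Number of draws.
#' @return A tibble with columns `x_nm`, `y_nm`, `z_nm` (points) or `ux`,
#'   `uy`, `uz` (directions).
#' @export
sample_interior_points <- function(body, n) {
  b <- as_body(validate_bodies(body))
  bb <- body_xy_bbox(body)
  zz <- body_z_extent(body)
  out_x <- numeric(0); out_y <- numeric(0); out_z <- numeric(0)
  guard <- 0
  while (length(out_x) < n && guard < 1000) {
    m <- max(2L * (n - length(out_x)), 100L)
    x <- runif(m, bb$x_min_nm, bb$x_max_nm)
    y <- runif(m, bb$y_min_nm, bb$y_max_nm)
    z <- runif(m, zz$z_min_nm, zz$z_max_nm)
    keep <- in_cross_section(body, x, y, z)
    out_x <- c(out_x, x[keep]); out_y <- c(out_y, y[keep])
    out_z <- c(out_z, z[keep])
    guard <- guard + 1
  }
  if (length(out_x) < n) abort("rejection sampling failed to fill the body")
  tibble::tibble(x_nm = out_x[1:n], y_nm = out_y[1:n], z_nm = out_z[1:n])
}

#' @rdname sample_interior_points
#' @export
isotropic_directions <- function(n) {
  uz <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - uz^2))
  tibble::tibble(ux = s * cos(phi), uy = s * sin(phi), uz = uz)
}

#' Full intercept (chord) lengths through interior points
#'
#' For each interior point and direction, returns the length of the full
#' linear intercept of the body along that direction — the quantity cubed
#' in the star-volume estimator. Bodies are convex, so membership along a
#' ray from an interior point is an interval and each boundary crossing is
#' located by bisection (60 iterations, sub-picometre accuracy).
#'
#' @param body A one-row body tibble.
#' @param points Tibble with `x_nm`, `y_nm`, `z_nm`, interior points.
#' @param dirs Tibble with `ux`, `uy`, `uz`, unit directions.
#' @return Numeric vector of chord lengths, nm.
#' @export
intercept_lengths <- function(body, points, dirs) {
  b <- as_body(validate_bodies(body))
  stopifnot(nrow(points) == nrow(dirs))
  px <- points$x_nm; py <- points$y_nm; pz <- points$z_nm
  if (!all(in_cross_section(body, px, py, pz))) {
    abort("all chord base points must lie inside the body")
  }
  # radius of a ball around the centre guaranteed to contain the body
  r_out <- switch(b$kind,
    sphere = b$r_nm,
    half_sphere = b$r_nm,
    spherocylinder = sc_half(b) + b$r_nm
  )
  d_cen <- sqrt((px - b$cx_nm)^2 + (py - b$cy_nm)^2 + (pz - b$cz_nm)^2)
  s_max <- d_cen + r_out + 1
  ray_root <- function(sx, sy, sz) {
    lo <- rep(0, length(px))      # inside
    hi <- s_max                   # outside by construction
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      ins <- in_cross_section(body, px + mid * sx, py + mid * sy,
                              pz + mid * sz)
      lo <- ifelse(ins, mid, lo)
      hi <- ifelse(ins, hi, mid)
    }
    (lo + hi) / 2
  }
  ray_root(dirs$ux, dirs$uy, dirs$uz) +
    ray_root(-dirs$ux, -dirs$uy, -dirs$uz)
}
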