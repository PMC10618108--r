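# shared fixtures, built lazily and cached for the whole test run

fixture_env <- new.env(parent = emptyenv())

# a small default E. cuniculi cohort reused by several files
small_cohort <- function() {
  if (is.null(fixture_env$small)) {
    fixture_env$small <- generate_cohort(cohort_config(n_cells = 12,
                                                       seed = 404))
  }
  fixture_env$small
}

# Monte-Carlo point-in-body volume (independent oracle for closed forms)
mc_volume <- function(body, n = 1e6, seed = 1) {
  bb <- body_xy_bbox(body)
  zz <- body_z_extent(body)
  withr::with_seed(seed, {
    x <- runif(n, bb$x_min_nm, bb$x_max_nm)
    y <- runif(n, bb$y_min_nm, bb$y_max_nm)
    z <- runif(n, zz$z_min_nm, zz$z_max_nm)
    p <- mean(in_cross_section(body, x, y, z))
    box <- (bb$x_max_nm - bb$x_min_nm) * (bb$y_max_nm - bb$y_min_nm) *
      (zz$z_max_nm - zz$z_min_nm)
    list(volume = p * box, se = sqrt(p * (1 - p) / n) * box)
  })
}

# uniformly random body of a random kind, for property loops
random_body <- function(kind = c("sphere", "spherocylinder",
                                 "half_sphere")) {
  kind <- match.arg(kind)
  r <- runif(1, 10, 60)
  centre <- runif(3, -50, 50)
  u <- rnorm(3)
  u <- u / sqrt(sum(u^2))
  switch(kind,
    sphere = body_sphere(r, centre),
    half_sphere = body_half_sphere(r, centre, axis = u),
    spherocylinder = body_spherocylinder(r, runif(1, 2 * r, 6 * r),
                                         centre, axis = u)
  )
}
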