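test_that("closed-form volumes and surfaces match their formulas and a
           Monte-Carlo oracle", {
  sphere25 <- body_sphere(25)
  sc_degen <- body_spherocylinder(25, 50)
  sc <- body_spherocylinder(25, 150, axis = c(1, 0, 0))
  half30 <- body_half_sphere(30)

  # degenerate spherocylinder (L = 2r) is a sphere
  expect_equal(body_volume(sc_degen), body_volume(sphere25))
  expect_equal(body_volume(sphere25), 4 / 3 * pi * 25^3)
  expect_equal(body_volume(sc), pi * 25^2 * 100 + 4 / 3 * pi * 25^3)
  expect_equal(body_volume(half30), 2 / 3 * pi * 30^3)

  expect_equal(body_surface(sphere25), 4 * pi * 25^2)
  expect_equal(body_surface(sc), 2 * pi * 25 * 100 + 4 * pi * 25^2)
  # half sphere: curved cap only, flat face excluded
  expect_equal(body_surface(body_half_sphere(25)), 2 * pi * 25^2)

  # Monte-Carlo point-in-body volume agrees within 3 SE for every kind
  for (body in list(sphere25, sc, half30,
                    body_spherocylinder(20, 90, c(10, -5, 3),
                                        axis = c(0.6, 0, 0.8)))) {
    mc <- mc_volume(body, n = 2e5, seed = 99)
    expect_lt(abs(mc$volume - body_volume(body)), 3 * mc$se)
  }
})

test_that("invalid bodies are rejected", {
  expect_error(body_sphere(-1), "r_nm")
  expect_error(body_spherocylinder(25, 40), "L_nm >= 2")
  expect_error(body_spherocylinder(25, 150, axis = c(1, 1, 0)),
               "unit vector")
  b <- body_sphere(25)
  b$kind <- "cube"
  expect_error(validate_bodies(b), "unknown body kind")
})

test_that("shape conversions reproduce reported dimensions", {
  # 0.0001 um^3 sphere-equivalent diameter prints as 58 nm
  expect_equal(sphere_diameter_from_volume(um3_to_nm3(0.0001)),
               (6e5 / pi)^(1 / 3))
  expect_equal(sphere_diameter_from_volume(um3_to_nm3(0.0001),
                                           round_nm = TRUE), 58)
  # inverse identity and exact round trip
  expect_equal(sphere_diameter_from_volume(pi / 6 * 1e6), 100)
  expect_equal(sphere_diameter_from_volume(body_volume(body_sphere(29))),
               58)
  expect_error(sphere_diameter_from_volume(0), "> 0")
})

test_that("capped-cylinder length from volume is the exact inverse of the
           volume formula", {
  # forward formula with L = 340, d = 50 gives v = 634,864 nm^3 (not the
  # 0.00025 um^3 sometimes paired with 340 nm, which maps to 144 nm)
  v340 <- body_volume(body_spherocylinder(25, 340))
  expect_equal(v340, 634864, tolerance = 1e-5)
  expect_equal(spherocylinder_length_from_volume(v340, 50), 340)
  expect_equal(spherocylinder_length_from_volume(um3_to_nm3(0.00025), 50),
               144.0, tolerance = 1e-3)
  # zero cylinder part and rejection below the cap sphere
  expect_equal(
    spherocylinder_length_from_volume(body_volume(body_sphere(25)), 50),
    50)
  expect_error(spherocylinder_length_from_volume(1e4, 50), "cap-sphere")

  # length-from-volume o volume is the identity on valid spherocylinders
  withr::with_seed(7, {
    for (i in 1:25) {
      r <- runif(1, 5, 60)
      L <- runif(1, 2 * r, 8 * r)
      v <- body_volume(body_spherocylinder(r, L))
      expect_equal(spherocylinder_length_from_volume(v, 2 * r), L,
                   tolerance = 1e-6)
    }
  })
})

test_that("cross-section membership is exact at poles, caps and axis
           offsets", {
  s <- body_sphere(25)
  expect_true(in_cross_section(s, 0, 0, 0))
  expect_false(in_cross_section(s, 0, 0, 25.1))
  expect_true(in_cross_section(s, 0, 0, 25)) # boundary, strict <=

  sc <- body_spherocylinder(25, 150, axis = c(1, 0, 0))
  # (70, 0, 0) is inside the cap region: cap centre at x = 50, tip at 75
  expect_true(in_cross_section(sc, 70, 0, 0))
  expect_false(in_cross_section(sc, 75.1, 0, 0))
  expect_true(in_cross_section(sc, 50, 25, 0))
  expect_false(in_cross_section(sc, 51, 25, 0))

  h <- body_half_sphere(25, axis = c(0, 0, 1))
  expect_true(in_cross_section(h, 0, 0, 10))
  expect_false(in_cross_section(h, 0, 0, -10)) # below the flat face
})

test_that("slab shadows contain every member cross-section and vanish off
           the body", {
  s <- body_sphere(25)
  expect_true(in_shadow(s, 0, 0, 20, 63))
  # max in-slab radius at z = 20 is sqrt(625 - 400) = 15 < 24
  expect_false(in_shadow(s, 0, 24, 20, 63))
  expect_true(in_shadow(s, 0, 14, 20, 63))
  # slab strictly outside the z-extent
  expect_false(in_shadow(s, 0, 0, 26, 60))
  expect_false(in_shadow(body_spherocylinder(10, 60, axis = c(1, 0, 0)),
                         0, 0, 11, 40))

  # property: shadow >= any cross-section inside the slab, random bodies
  withr::with_seed(11, {
    for (i in 1:40) {
      body <- random_body(sample(c("sphere", "spherocylinder",
                                   "half_sphere"), 1))
      z_lo <- runif(1, -80, 40)
      z_hi <- z_lo + runif(1, 5, 60)
      x <- runif(30, -120, 120)
      y <- runif(30, -120, 120)
      z <- runif(30, z_lo, z_hi)
      cs <- in_cross_section(body, x, y, z)
      sh <- in_shadow(body, x, y, z_lo, z_hi)
      expect_true(all(sh[cs]))
    }
  })
})

test_that("a slab covering the whole body casts its full projected
           shadow", {
  # sphere: projected area pi r^2, checked by 2D Monte-Carlo within 3 SE
  s <- body_sphere(25)
  withr::with_seed(3, {
    x <- runif(2e5, -26, 26)
    y <- runif(2e5, -26, 26)
    p <- mean(in_shadow(s, x, y, -30, 30))
    box <- 52^2
    expect_lt(abs(p * box - pi * 625), 3 * sqrt(p * (1 - p) / 2e5) * box)
    # tilted spherocylinder vs its own cross-section sampled over z:
    # full-extent shadow equals union of all cross-sections
    sc <- body_spherocylinder(20, 120, axis = c(0.6, 0, 0.8))
    xs <- runif(5e3, -90, 90)
    ys <- runif(5e3, -90, 90)
    sh <- in_shadow(sc, xs, ys, -90, 90)
    any_cs <- rep(FALSE, 5e3)
    for (z in seq(-88, 88, by = 2)) {
      any_cs <- any_cs | in_cross_section(sc, xs, ys, z)
    }
    expect_true(all(any_cs[!sh] == FALSE))
    expect_true(mean(sh) >= mean(any_cs))
  })
})

test_that("interior point sampling and intercepts respect convexity", {
  sc <- body_spherocylinder(20, 100, c(5, -10, 2), axis = c(0, 0.6, 0.8))
  withr::with_seed(21, {
    pts <- sample_interior_points(sc, 500)
    expect_true(all(in_cross_section(sc, pts$x_nm, pts$y_nm, pts$z_nm)))
    dirs <- isotropic_directions(500)
    expect_equal(dirs$ux^2 + dirs$uy^2 + dirs$uz^2, rep(1, 500))
    lens <- intercept_lengths(sc, pts, dirs)
    # chords are positive and bounded by the diameter of the body
    expect_true(all(lens > 0))
    expect_true(all(lens <= 100 + 1e-6))
    # chord through the centre of a sphere along any axis is 2r
    s <- body_sphere(25)
    cen <- tibble::tibble(x_nm = 0, y_nm = 0, z_nm = 0)
    d <- tibble::tibble(ux = 1, uy = 0, uz = 0)
    expect_equal(intercept_lengths(s, cen, d), 50, tolerance = 1e-6)
  })
})
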