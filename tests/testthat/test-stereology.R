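test_that("point counting is exact on aligned windows and unbiased over
           random offsets", {
  # full window of area A: hits * s^2 = A exactly when s divides the sides
  g <- point_grid(5, window = c(0, 50, 0, 40), offset = c(2.5, 2.5))
  hits <- point_count(function(x, y) rep(TRUE, length(x)), g)
  expect_equal(as.integer(hits) * 25, 50 * 40)
  # empty profile
  expect_equal(as.integer(point_count(function(x, y)
    rep(FALSE, length(x)), g)), 0L)

  # circle r = 25: mean(hits) * s^2 over random offsets ~ pi r^2
  withr::with_seed(14, {
    est <- vapply(1:400, function(i) {
      g <- point_grid(5, window = c(-30, 30, -30, 30))
      25 * point_count(function(x, y) x^2 + y^2 <= 625, g)
    }, numeric(1))
    expect_lt(abs(mean(est) - pi * 625),
              3 * sd(est) / sqrt(length(est)))
  })
  expect_error(point_grid(0, c(0, 1, 0, 1)), "> 0")
  expect_error(point_grid(5, c(1, 0, 0, 1)), "window")
})

test_that("Cavalieri volume is spacing times summed area", {
  expect_equal(cavalieri_volume(c(100, 100), 43)$value_nm3, 8600)
  expect_equal(cavalieri_volume(numeric(0), 43)$value_nm3, 0)
  expect_equal(cavalieri_volume(c(0, 0, 0), 10)$value_nm3, 0)
  expect_error(cavalieri_volume(c(-1, 2), 10), ">= 0")
  expect_error(cavalieri_volume(c(1, 2), 0), "> 0")

  # unbiasedness over random phases and offsets, sphere and spherocylinder
  withr::with_seed(15, {
    for (body in list(body_sphere(25),
                      body_spherocylinder(20, 100, axis = c(0, 0.6,
                                                            0.8)))) {
      v_true <- body_volume(body)
      est <- vapply(1:120, function(i) {
        st <- cut_tomographic(body, 5)
        pr <- profile_table(st, pitch_nm = 5)
        cavalieri_volume(pr$area_nm2, 5)$value_nm3
      }, numeric(1))
      expect_lt(abs(mean(est) - v_true), 3 * sd(est) / sqrt(length(est)))
    }
  })
})

test_that("overprojection factors behave like the Holmes model", {
  expect_equal(overprojection_factor(100, 161), 1.61)
  expect_equal(overprojection_factor(120, 120), 1)
  expect_error(overprojection_factor(0, 10), "> 0")

  s25 <- body_sphere(25)
  expect_equal(model_based_factor(0, s25), 1)
  # sphere: 1 + t S / (4V) = 1 + 3t/(4r)
  expect_equal(model_based_factor(43, s25), 1 + 3 * 43 / 100)
  expect_equal(model_based_factor(43, s25),
               1 + 43 * (4 * pi * 625) / (4 * body_volume(s25)))
  sc <- body_spherocylinder(25, 150)
  expect_equal(model_based_factor(43, sc),
               1 + 43 * body_surface(sc) / (4 * body_volume(sc)),
               tolerance = 1e-12)
  expect_equal(model_based_factor(43, sc), 1.9675)
  expect_error(model_based_factor(-1, s25), ">= 0")

  # factor > 1 for t > 0, non-decreasing in t, -> 1 as t -> 0
  ts <- seq(0.001, 100, length.out = 50)
  fs <- vapply(ts, model_based_factor, numeric(1), body = sc)
  expect_true(all(fs > 1))
  expect_true(all(diff(fs) >= 0))
  expect_equal(model_based_factor(1e-9, sc), 1, tolerance = 1e-6)
})

test_that("appearance counting is exact for convex bodies fully spanned by
           the stack", {
  bodies <- dplyr::bind_rows(
    body_sphere(20, c(0, 0, -60), body_id = "a"),
    body_spherocylinder(15, 80, c(10, 10, 10), axis = c(0, 0.6, 0.8),
                        body_id = "b"),
    body_sphere(10, c(-30, 0, 70), body_id = "c"),
    body_sphere(300, body_id = "frame") # spans everything
  )
  st <- cut_serial(bodies, 43, seed = 3)
  cnt <- count_by_appearance(st, body_ids = c("a", "b", "c"),
                             assume_empty_after = TRUE)
  expect_equal(cnt$n_appearance, 3L)

  # one body inside a single slab
  one <- cut_serial(body_sphere(10), 1000, phase_nm = 0)
  expect_equal(count_by_appearance(one,
                                   assume_empty_after = TRUE)$n_appearance,
               1L)
  # truncation: the body reaches the last section and no lookahead exists
  tr <- cut_serial(body_sphere(25), 43, phase_nm = 0)
  expect_warning(res <- count_by_appearance(tr), "truncated")
  expect_equal(res$n_truncated, 1L)
  expect_equal(res$n_appearance, 0L)

  # thin-plane mode counts the same particles
  th <- cut_tomographic(bodies, 10, seed = 4)
  expect_equal(count_by_appearance(th, body_ids = c("a", "b", "c"),
                                   assume_empty_after = TRUE)$n_appearance,
               3L)
})

test_that("batched ministack end-counting equals explicit appearance
           counting on the same stacks", {
  coh <- small_cohort()
  for (i in 1:2) {
    cid <- coh$cells$cell_id[i]
    bodies <- cell_bodies(coh, cid, include = c("mitosomes", "nucleus",
                                                "cell"))
    mito_ids <- setdiff(bodies$body_id, c("nucleus", "cell"))
    # the driver derives the stack starts from derive_seed(seed, i); feed
    # the same seed into sample_ministacks to reproduce its placements
    est <- estimate_nv_ministacks(coh, cell_ids = cid, t_nm = 43,
                                  n_sections = 5, n_stacks = 10,
                                  seed = 3100 + i)
    stacks <- sample_ministacks(bodies, 43, 5, 10,
                                seed = mitostereo:::derive_seed(3100 + i,
                                                                1),
                                lookahead = TRUE)
    ends <- sum(vapply(stacks, function(st) {
      count_by_appearance(st, body_ids = mito_ids)$n_appearance
    }, integer(1)))
    expect_identical(est$n_appearance, as.integer(ends))
  }
})

test_that("densities, fractions and totals are plain design ratios", {
  expect_equal(volume_fraction(47, 10000), 0.0047)
  expect_equal(volume_fraction(0, 10), 0)
  expect_error(volume_fraction(5, 0), "> 0")
  expect_equal(number_density(10, 2), 5)
  expect_warning(nv0 <- number_density(0, 2), "small-sample")
  expect_equal(nv0, 0)
  expect_equal(estimate_total_number(5, 2), 10)
  expect_equal(constriction_density(4, 8), 0.5)
  expect_equal(constriction_density(8, 8), 2 * constriction_density(4, 8))
})

test_that("planted constriction loci are recovered by appearance counting
           per volume", {
  # point-like loci in a cylinder of cytoplasm: k loci / V recovered
  withr::with_seed(33, {
    k <- 12
    box_r <- 400
    loci <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      body_sphere(4, c(runif(2, -box_r, box_r), runif(1, -300, 300)),
                  body_id = sprintf("locus_%02d", i))
    }))
    frame <- body_sphere(600, body_id = "frame")
    st <- cut_serial(dplyr::bind_rows(loci, frame), 43, seed = 2)
    cnt <- count_by_appearance(st, body_ids = loci$body_id,
                               assume_empty_after = TRUE)
    expect_equal(cnt$n_appearance, k)
    v_ref <- nm3_to_um3(4 / 3 * pi * 600^3)
    expect_equal(constriction_density(cnt$n_appearance, v_ref), k / v_ref)
  })
})

test_that("star volume follows its definition and scales cubically", {
  expect_equal(star_volume(1), pi / 3)
  expect_equal(star_volume(c(0, 0, 0)), 0)
  expect_error(star_volume(numeric(0)), "at least one")
  # scale invariance: rescaling chords by c scales v* by c^3
  withr::with_seed(40, {
    l <- runif(100, 10, 80)
    expect_equal(star_volume(3 * l), 27 * star_volume(l))
  })
  # sphere identity at modest n (the full 1e5-chord check runs in the
  # acceptance suite)
  s <- body_sphere(25)
  v <- star_volume(sample_star_intercepts(s, 2e4, seed = 8))
  expect_lt(abs(v - body_volume(s)) / body_volume(s), 0.04)
  # convex non-spherical body: v* positive and close to V as well
  sc <- body_spherocylinder(20, 100, axis = c(0, 0, 1))
  vs <- star_volume(sample_star_intercepts(sc, 2e4, seed = 9))
  expect_gt(vs, 0)
  expect_lt(abs(vs - body_volume(sc)) / body_volume(sc), 0.06)
})

test_that("coefficients of error match hand calculations", {
  expect_equal(coefficient_of_error(c(1, 2, 3)), (1 / sqrt(3)) / 2)
  expect_equal(coefficient_of_error(rep(4, 6)), 0)
  # scale invariance
  withr::with_seed(41, {
    x <- runif(20, 1, 5)
    expect_equal(coefficient_of_error(7 * x), coefficient_of_error(x))
  })
  expect_error(coefficient_of_error(1), "at least two")
  # Gundersen-Jensen systematic CE: small for smooth series, shrinking
  # with series length; NA for series too short to difference twice
  expect_lt(ce_systematic(rep(10, 8)), 0.06)
  expect_lt(ce_systematic(rep(10, 40)), ce_systematic(rep(10, 8)))
  expect_true(is.na(ce_systematic(c(1, 2))))
  a <- c(1, 4, 9, 4, 1)
  A <- sum(a^2); B <- sum(a[-5] * a[-1]); C <- sum(a[1:3] * a[3:5])
  expect_equal(ce_systematic(a), sqrt((3 * A - 4 * B + C) / 12) / sum(a))
})

test_that("the measured phase-averaged shadow factor matches the Cauchy
           prediction for a sphere", {
  # quick version of the oracle equivalence: 60 phases, exact areas
  s <- body_sphere(25)
  v_true <- body_volume(s)
  withr::with_seed(42, {
    est <- vapply(1:60, function(i) {
      st <- cut_serial(s, 43)
      pr <- profile_table(st, pitch_nm = 2)
      cavalieri_volume(pr$area_nm2, 43)$value_nm3
    }, numeric(1))
  })
  f <- mean(est) / v_true
  se <- sd(est) / sqrt(length(est)) / v_true
  expect_lt(abs(f - 2.29), 3 * se + 0.02)
})
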