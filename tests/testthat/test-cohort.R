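test_that("cohorts are deterministic for a fixed seed and reproducible
           independent of order", {
  a <- generate_cohort(cohort_config(n_cells = 5, seed = 77))
  b <- generate_cohort(cohort_config(n_cells = 5, seed = 77))
  expect_identical(a$cells, b$cells)
  expect_identical(a$mitosomes, b$mitosomes)
  # first cells of a longer cohort equal the shorter cohort (substreams
  # keyed by cell index, not by global draw order)
  c10 <- generate_cohort(cohort_config(n_cells = 10, seed = 77))
  expect_identical(c10$cells[1:5, ], a$cells)
})

test_that("generated mitosomes respect the configured axis ranges and
           geometry invariants", {
  coh <- small_cohort()
  m <- coh$mitosomes
  expect_true(all(2 * m$r_nm >= 47 & 2 * m$r_nm <= 119))
  expect_true(all(m$L_nm >= 78 & m$L_nm <= 267))
  expect_true(all(m$L_nm >= 2 * m$r_nm))

  # mitosomes lie outside the nucleus and inside the cell
  d <- distance_to_envelope(coh)
  expect_true(all(d$distance_nm >= 0))
  cells <- coh$cells
  for (i in seq_len(nrow(cells))) {
    mi <- m[m$cell_id == cells$cell_id[i], ]
    h <- mi$L_nm / 2 - mi$r_nm
    far <- pmax(
      sqrt((mi$cx_nm - h * mi$ax)^2 + (mi$cy_nm - h * mi$ay)^2 +
             (mi$cz_nm - h * mi$az)^2),
      sqrt((mi$cx_nm + h * mi$ax)^2 + (mi$cy_nm + h * mi$ay)^2 +
             (mi$cz_nm + h * mi$az)^2)) + mi$r_nm
    free <- mi$tether == "free"
    expect_true(all(far[free] <= cells$r_cell_nm[i] + 1e-9))
  }

  # ground truth is consistent with the body table
  expect_equal(cells$N_mit_true,
               as.integer(table(factor(m$cell_id,
                                       levels = cells$cell_id))))
  expect_equal(cells$V_mit_total_true_nm3,
               as.numeric(tapply(body_volume(
                 m[setdiff(names(m), c("cell_id", "tether", "gap_nm"))]),
                 factor(m$cell_id, levels = cells$cell_id), sum)))
})

test_that("tethered mitosomes satisfy the mSPB contact criterion", {
  coh <- small_cohort()
  cells <- coh$cells
  m <- coh$mitosomes[coh$mitosomes$tether != "free", ]
  cell <- cells[match(m$cell_id, cells$cell_id), ]
  sgn <- ifelse(m$tether == "SPB1", 1, -1)
  spb_x <- sgn * cell$spb_ux * cell$r_nuc_nm
  spb_y <- sgn * cell$spb_uy * cell$r_nuc_nm
  spb_z <- sgn * cell$spb_uz * cell$r_nuc_nm
  r_spb <- ifelse(m$tether == "SPB1", cell$r_spb1_nm, cell$r_spb2_nm)
  h <- m$L_nm / 2 - m$r_nm
  # nearer cap centre (the cap pointing back toward the mSPB)
  d1 <- sqrt((m$cx_nm - h * m$ax - spb_x)^2 +
               (m$cy_nm - h * m$ay - spb_y)^2 +
               (m$cz_nm - h * m$az - spb_z)^2)
  gap <- d1 - m$r_nm - r_spb
  expect_true(all(gap <= 10 + 1e-9))
  expect_true(all(gap >= -1e-9))
})

test_that("tether fraction, partition mode and count model behave as
           configured", {
  all_teth <- generate_cohort(cohort_config(n_cells = 8, seed = 2,
                                            tether_fraction = 1))
  expect_true(all(all_teth$mitosomes$tether != "free"))

  coh <- small_cohort()
  expect_true(all(abs(coh$cells$n_spb1 - coh$cells$n_spb2) <= 1))

  # empirical mean count within 3 SE of the calibrated mean 7.4
  big <- generate_cohort(cohort_config(n_cells = 200, seed = 9))
  n <- big$cells$N_mit_true
  expect_lt(abs(mean(n) - 7.4), 3 * sd(n) / sqrt(length(n)))
  # and the 92% tether default within 3 SE (binomial)
  teth <- big$mitosomes$tether != "free"
  expect_lt(abs(mean(teth) - 0.92),
            3 * sqrt(0.92 * 0.08 / length(teth)))
  # aggregate mitosome volume scales with nucleus volume
  ct <- correlation_table(big$cells,
                          list(c("V_mit_total_true_nm3", "V_nuc_nm3")))
  expect_gt(ct$r, 0)
  expect_lt(ct$p_value, 0.01)
})

test_that("infeasible configurations are rejected with informative
           errors", {
  expect_error(cohort_config(minor_range_nm = c(119, 47)), "minor_range")
  expect_error(cohort_config(minor_range_nm = c(100, 200),
                             major_range_nm = c(50, 80)), "infeasible")
  expect_error(cohort_config(tether_fraction = 1.2), "probabilities")
  expect_error(cohort_config(cytoplasm_offset_nm = -5), "cytoplasm")
})

test_that("dynamin inhibition halves counts by pairwise merging and
           conserves total volume", {
  coh <- generate_cohort(cohort_config(n_cells = 30, seed = 11))
  trt <- apply_dynamin_inhibition(coh)
  expect_equal(trt$cells$N_mit_true, ceiling(coh$cells$N_mit_true / 2))
  expect_equal(sum(trt$cells$V_mit_total_true_nm3),
               sum(coh$cells$V_mit_total_true_nm3))
  expect_equal(trt$cells$V_mit_total_true_nm3,
               coh$cells$V_mit_total_true_nm3)
  expect_true(all(trt$mitosomes$L_nm >= 2 * trt$mitosomes$r_nm - 1e-9))
  expect_error(apply_dynamin_inhibition(trt), "already")

  # even-count cell with equal volumes -> every merge doubles the volume
  even_cells <- coh$cells$cell_id[coh$cells$N_mit_true %% 2 == 0]
  v_before <- coh$cells$V_mit_total_true_nm3 / coh$cells$N_mit_true
  v_after <- trt$cells$V_mit_total_true_nm3 / trt$cells$N_mit_true
  sel <- coh$cells$cell_id %in% even_cells
  expect_equal(v_after[sel], 2 * v_before[sel])
})

test_that("treated-to-control mean individual volume ratio is about 2,
           diluted by odd remainders", {
  ctrl <- generate_cohort(cohort_config(n_cells = 100, seed = 55))
  trt <- apply_dynamin_inhibition(ctrl)
  ratio <- mean(trt$cells$V_mit_total_true_nm3 / trt$cells$N_mit_true) /
    mean(ctrl$cells$V_mit_total_true_nm3 / ctrl$cells$N_mit_true)
  expect_lt(abs(ratio - 2), 0.2)
})

test_that("the T. hominis stage series follows the association schedule
           and count range", {
  cfg <- cohort_config("thominis", n_cells = 25, seed = 12)
  ser <- generate_thominis_stage_series(cfg)
  expect_setequal(unique(ser$cells$stage), names(cfg$stage_schedule))
  expect_true(all(ser$cells$N_mit_true >= 14 & ser$cells$N_mit_true <= 18))

  m <- ser$mitosomes
  m$stage <- ser$cells$stage[match(m$cell_id, ser$cells$cell_id)]
  pre <- m[m$stage == "prespore", ]
  frac <- mean(pre$tether != "free")
  expect_lt(abs(frac - 0.73), 3 * sqrt(0.73 * 0.27 / nrow(pre)))

  # schedule of zeros -> nothing tethered; missing stage -> error
  cfg0 <- cohort_config("thominis", n_cells = 4, seed = 3,
                        stage_schedule = c(early = 0, prespore = 0))
  ser0 <- generate_thominis_stage_series(cfg0)
  expect_true(all(ser0$mitosomes$tether == "free"))
  expect_error(generate_thominis_stage_series(cfg0, stages = "sporont"),
               "missing stages")
})

test_that("tidy and glance summarise cohorts", {
  coh <- small_cohort()
  expect_identical(tidy(coh), coh$cells)
  g <- glance(coh)
  expect_equal(g$n_cells, nrow(coh$cells))
  expect_equal(g$mean_n_mit, mean(coh$cells$N_mit_true))
  expect_true(g$even_fraction == 1)
})
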