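test_that("evenness classification and partition records", {
  expect_true(classify_evenness(4, 3))
  expect_false(classify_evenness(5, 2))
  expect_true(classify_evenness(0, 0))
  expect_error(classify_evenness(-1, 2), ">= 0")

  part <- partition_table(small_cohort())
  expect_equal(part$even_or_near_even,
               abs(part$n_spb1 - part$n_spb2) <= 1)
  expect_true(all(part$even_or_near_even)) # ordered_even mode
})

test_that("pooled binomial proportion matches hand computation and label
           symmetry", {
  rec <- tibble::tibble(n_spb1 = c(1, 2, 3), n_spb2 = c(1, 2, 3))
  pb <- pooled_binomial_proportion(rec)
  expect_equal(pb$p_hat, 0.5)
  expect_equal(pb$conf_high - 0.5, 0.5 - pb$conf_low)

  # hand computation: 54 of 101, normal CI 0.5347 +/- 1.96 * 0.04963
  pb2 <- pooled_binomial_proportion(tibble::tibble(n_spb1 = 54,
                                                   n_spb2 = 47))
  expect_equal(pb2$p_hat, 54 / 101)
  half <- qnorm(0.975) * sqrt((54 / 101) * (47 / 101) / 101)
  expect_equal(pb2$conf_low, 54 / 101 - half)
  expect_equal(pb2$conf_high, 54 / 101 + half)
  expect_equal(round(c(pb2$conf_low, pb2$conf_high), 3), c(0.437, 0.632))

  # boundary: everything on one pole clips the interval at 1
  pb3 <- pooled_binomial_proportion(tibble::tibble(n_spb1 = 7,
                                                   n_spb2 = 0))
  expect_equal(pb3$p_hat, 1)
  expect_lte(pb3$conf_high, 1)

  # swapping all labels only flips P around 1/2; highest P is invariant
  swapped <- pooled_binomial_proportion(tibble::tibble(n_spb1 = 47,
                                                       n_spb2 = 54))
  expect_equal(swapped$highest_p, pb2$highest_p)
  expect_equal(swapped$highest_conf_low, pb2$highest_conf_low)
  expect_error(pooled_binomial_proportion(tibble::tibble(n_spb1 = 0,
                                                         n_spb2 = 0)),
               "all-zero")
  # tidy/glance
  td <- tidy(pb2)
  expect_equal(td$highest_p, pb2$highest_p)
  expect_equal(glance(pb2)$n_total, 101)
})

test_that("the even-split null probability equals exhaustive
           enumeration", {
  # brute-force oracle: enumerate all 2^n assignments
  enum <- function(n) {
    if (n == 0) return(1)
    mean(vapply(0:(2^n - 1), function(code) {
      bits <- as.integer(intToBits(code))[1:n]
      abs(sum(bits) - (n - sum(bits))) <= 1
    }, logical(1)))
  }
  for (n in 0:10) {
    expect_equal(even_split_null_probability(n), enum(n), info = n)
  }
  expect_equal(even_split_null_probability(1), 1)
  expect_equal(even_split_null_probability(2), 0.5)
  expect_equal(even_split_null_probability(7), 70 / 128)
  expect_error(even_split_null_probability(-1), "non-negative")
})

test_that("partition simulation matches its null model", {
  sim <- simulate_partition(4000, 7, "binomial_random", seed = 6)
  p0 <- even_split_null_probability(7)
  expect_lt(abs(mean(sim$even_or_near_even) - p0),
            3 * sqrt(p0 * (1 - p0) / 4000))
  ord <- simulate_partition(500, 7, "ordered_even", seed = 6)
  expect_true(all(ord$even_or_near_even))
  expect_true(all(ord$n_spb1 + ord$n_spb2 == 7))
})

test_that("chi-square contingency matches hand computation", {
  res0 <- chi_square_contingency(rbind(c(10, 10), c(10, 10)))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$df, 1)

  res <- chi_square_contingency(rbind(c(20, 10), c(10, 20)))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12) # 4 * 25/15
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))

  expect_equal(chi_square_contingency(matrix(5, 2, 4))$df, 3)
  # proportional rows give exactly 0
  expect_equal(chi_square_contingency(rbind(c(10, 20, 30),
                                            c(5, 10, 15)))$statistic, 0)
  expect_error(chi_square_contingency(rbind(c(0, 0), c(1, 2))),
               "expected")
  expect_error(chi_square_contingency(rbind(c(-1, 2), c(1, 2))),
               "non-negative")
})

test_that("correlation table reproduces the textbook formula to 1e-12", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1, 0.7)
  y <- c(0.9, 2.8, 2.5, 4.6, 4.4, 1.1)
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tab <- correlation_table(data.frame(x = x, y = y), list(c("x", "y")))
  expect_equal(tab$r, r_manual, tolerance = 1e-12)
  tstat <- r_manual * sqrt(4 / (1 - r_manual^2))
  expect_equal(tab$p_value, 2 * stats::pt(-abs(tstat), 4),
               tolerance = 1e-12)
  expect_equal(tab$n, 6)

  # exact linear relation
  expect_equal(correlation_table(data.frame(x = 1:5, y = 2 * (1:5)),
                                 list(c("x", "y")))$r, 1)
  # null calibration: independent variables give small r at n = 1000
  withr::with_seed(50, {
    d <- data.frame(a = rnorm(1000), b = rnorm(1000))
    expect_lt(abs(correlation_table(d, list(c("a", "b")))$r), 0.1)
  })
  expect_error(correlation_table(data.frame(x = 1:2, y = 1:2),
                                 list(c("x", "y"))), "3 complete")
  expect_error(correlation_table(data.frame(x = 1:5), list(c("x", "q"))),
               "unknown columns")
})

test_that("mSPB occupancy capacity reports its intermediates", {
  cap <- mspb_occupancy_capacity(body_volume(body_half_sphere(30)), 58)
  expect_equal(cap$r_nm, 30)
  expect_equal(cap$cap_area_nm2, 2 * pi * 900)
  expect_equal(cap$footprint_nm2, pi * 29^2)
  expect_equal(cap$capacity, 2)
  # capacity is non-decreasing in v at fixed d
  vs <- seq(5e4, 1e6, length.out = 40)
  caps <- mspb_occupancy_capacity(vs, 58)$capacity
  expect_true(all(diff(caps) >= 0))
  expect_error(mspb_occupancy_capacity(0, 58), "> 0")
  expect_error(mspb_occupancy_capacity(1e5, 0), "> 0")
})

test_that("distance to the nuclear envelope and binning", {
  # constructed case: mitosome centred at r_nuc + 100 + r along the x axis
  coh <- small_cohort()
  cell <- coh$cells[1, ]
  m <- coh$mitosomes[coh$mitosomes$cell_id == cell$cell_id, ][1, ]
  m$cx_nm <- cell$r_nuc_nm + 100 + m$r_nm
  m$cy_nm <- 0; m$cz_nm <- 0
  m$ax <- 0; m$ay <- 0; m$az <- 1
  fake <- coh
  fake$mitosomes <- m
  fake$cells <- cell
  d <- distance_to_envelope(fake)
  expect_equal(d$distance_nm, 100)

  # tethered mitosomes sit within contact distance + mSPB cap height
  dd <- distance_to_envelope(coh)
  teth <- dd$tether != "free"
  r_spb_max <- max(coh$cells$r_spb1_nm, coh$cells$r_spb2_nm)
  expect_true(all(dd$distance_nm[teth] <= r_spb_max + 10 + 1e-6))

  h <- bin_distances(c(10, 60, 150, 500, 40))
  expect_equal(sum(h$count), 5)
  expect_equal(h$count, c(2L, 1L, 1L, 1L))
  expect_equal(nrow(bin_distances(numeric(0))), 0)
})
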