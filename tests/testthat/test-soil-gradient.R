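test_that("element store converts concentration x density x thickness to t/ha", {
  expect_equal(element_store(0, 1.2, 0, 10), 0)
  # dimensional identity: 1 mg/g * 1 g/cm3 * 10 cm = 1 t/ha
  expect_equal(element_store(1, 1, 0, 10), 1)
  expect_error(element_store(1, 1, 10, 10), class = "invalid_horizon")
  # degree-1 homogeneity in each factor
  withr::with_seed(5, {
    for (i in 1:10) {
      cc <- runif(1, 0, 5); bd <- runif(1, 0.5, 1.5); th <- runif(1, 1, 40)
      k <- runif(1, 0.1, 4)
      base <- element_store(cc, bd, 0, th)
      expect_equal(element_store(k * cc, bd, 0, th), k * base)
      expect_equal(element_store(cc, k * bd, 0, th), k * base)
      expect_equal(element_store(cc, bd, 0, k * th), k * base)
    }
  })
  # stone correction reduces the fine-earth volume
  expect_equal(element_store(1, 1, 0, 10, stone_fraction = 0.25), 0.75)
})

test_that("profile store sums horizons and reports gaps", {
  h <- canonical_horizons()
  prof <- tibble::tibble(
    horizon_top_cm = h$top, horizon_bottom_cm = h$bottom,
    bulk_density_g_cm3 = 1, s_mg_g = 0, ca_exch_mg_g = 0)
  expect_equal(unname(profile_store(prof)), c(0, 0))
  # additivity: stores 0.3 (0-3 cm at 1 mg/g) and 0.5 via chosen concentrations
  prof$s_mg_g <- c(1, 5 / 7, 0, 0, 0)  # 0.3 + 0.5 t/ha
  expect_equal(unname(profile_store(prof, "s_mg_g")), 0.8)
  expect_error(profile_store(prof[-2, ], "s_mg_g"),
               class = "incomplete_profile")
  expect_error(profile_store(prof[-2, ], "s_mg_g"), "3-10")
  # refinement consistency: uniform profile equals one merged 0-50 horizon
  prof$s_mg_g <- 1.3
  merged <- element_store(1.3, 1, 0, 50)
  expect_equal(unname(profile_store(prof, "s_mg_g")), merged)
})

test_that("distance gradient sorts, separates uphill, and classifies", {
  d <- c(-55, 27, 55, 100, 150, 300)
  g <- distance_gradient(d, c(9, 1, 2, 3, 4, 5))
  expect_identical(g$verdict, "increasing")
  expect_equal(g$downhill$value, 1:5)
  expect_equal(g$uphill$value, 9)
  expect_identical(distance_gradient(d, c(1, 5, 4, 3, 2, 1))$verdict,
                   "decreasing")
  expect_identical(distance_gradient(d, rep(2, 6))$verdict,
                   "non-monotone: flat")
  expect_identical(distance_gradient(d, c(1, 1, 3, 2, 5, 4))$verdict,
                   "non-monotone")
  expect_error(distance_gradient(c(27, 27, 55), 1:3),
               class = "ambiguity_error")
  expect_error(distance_gradient(c(-55, 27, 55), 1:3),
               class = "invalid_input")
})

test_that("temporal delta aligns cells, is antisymmetric, flags mismatches", {
  cfg <- noiseless_config()
  sp <- generate_survey(cfg)
  # identity
  same <- list(early = sp$early, late = sp$early)
  expect_true(all(temporal_delta(same, "ph_h2o")$delta == 0))
  # single-cell arithmetic
  mk <- function(ph) tibble::tibble(site = "s", distance_cm = 27,
                                    horizon_top_cm = 0, horizon_bottom_cm = 3,
                                    ph_h2o = ph)
  expect_equal(temporal_delta(list(early = mk(3.5), late = mk(5.0)),
                              "ph_h2o")$delta, 1.5)
  # antisymmetry
  fwd <- temporal_delta(sp, "ph_h2o")
  bwd <- temporal_delta(list(early = sp$late, late = sp$early), "ph_h2o")
  expect_equal(fwd$delta, -bwd$delta)
  # unmatched cells are named
  broken <- list(early = sp$early[-1, ], late = sp$late)
  expect_error(temporal_delta(broken, "ph_h2o"), class = "alignment_error")
  expect_error(temporal_delta(sp, "no_such_var"), class = "alignment_error")
})

test_that("acidification front depth reads off the sign change", {
  h <- canonical_horizons()
  # all recovering: no front inside the profile
  expect_identical(
    acidification_front_depth(h$top, h$bottom, rep(0.2, 5))$flag, "no-front")
  # direct read-off at the 3-10 / 10-20 boundary
  f <- acidification_front_depth(h$top, h$bottom, c(0.5, 0.2, -0.3, -0.4, -0.6))
  expect_equal(f$depth_cm, 10)
  expect_identical(f$flag, "front")
  # acidifying throughout: front at the surface
  f0 <- acidification_front_depth(h$top, h$bottom, rep(-0.3, 5))
  expect_equal(f0$depth_cm, 0)
  expect_identical(f0$flag, "all-acidifying")
  # non-monotone sign pattern is flagged, not guessed
  fn <- acidification_front_depth(h$top, h$bottom, c(0.5, -0.2, 0.3, -0.4, -0.6))
  expect_true(is.na(fn$depth_cm))
  expect_identical(fn$flag, "non-monotone")
  expect_error(acidification_front_depth(c(10, 0, 20, 30, 40)[1:5], h$bottom,
                                         rep(-1, 5)),
               class = "ordering_error")
})

test_that("IDW interpolation honours exact hits, symmetry and value bounds", {
  s <- tibble::tibble(x_cm = c(0, 100), y_cm = c(0, 0), ph_h2o = c(4, 6))
  q <- tibble::tibble(x_cm = c(0, 50, 100), y_cm = 0)
  got <- idw_surface(s, q)
  expect_equal(got$ph_h2o, c(4, 5, 6))  # exact hits and midpoint symmetry
  for (p in c(0.5, 1, 2, 4)) {
    expect_equal(idw_surface(s, q[2, ], power = p)$ph_h2o, 5)
  }
  # a single sample gives a constant surface
  one <- idw_surface(s[1, ], tibble::tibble(x_cm = c(-30, 12, 250), y_cm = 1:3))
  expect_true(all(one$ph_h2o == 4))
  # no overshoot beyond the sample range
  withr::with_seed(9, {
    s2 <- tibble::tibble(x_cm = runif(15, -300, 300),
                         y_cm = runif(15, -300, 300),
                         ph_h2o = runif(15, 3, 7))
    q2 <- tibble::tibble(x_cm = runif(200, -300, 300),
                         y_cm = runif(200, -300, 300))
    z <- idw_surface(s2, q2)$ph_h2o
    expect_true(all(z >= min(s2$ph_h2o) - 1e-12))
    expect_true(all(z <= max(s2$ph_h2o) + 1e-12))
  })
  expect_error(idw_surface(s[0, ], q), class = "empty_input")
  expect_error(idw_surface(s, q, power = 0), class = "invalid_input")
})
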