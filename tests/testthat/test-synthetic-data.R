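test_that("noiseless survey hits its anchors and is seed-deterministic", {
  cfg <- noiseless_config()
  sp <- generate_survey(cfg)
  top83 <- sp$early[sp$early$horizon_top_cm == 0, ]
  expect_equal(top83$ph_h2o[top83$distance_cm == 27], 3.5)
  expect_equal(top83$ph_h2o[top83$distance_cm == 300], 6.5)
  # amplitude across distances is exactly the configured 3 pH units
  expect_equal(diff(range(top83$ph_h2o)), 3.0)
  sp2 <- generate_survey(cfg)
  expect_identical(sp$early, sp2$early)
  expect_identical(sp$late, sp2$late)
  # noisy surveys are deterministic too, and differ across seeds
  n1 <- generate_survey(synthetic_survey_config(seed = 4))
  n2 <- generate_survey(synthetic_survey_config(seed = 4))
  n3 <- generate_survey(synthetic_survey_config(seed = 5))
  expect_identical(n1$early, n2$early)
  expect_false(identical(n1$early, n3$early))
})

test_that("config invariants are enforced by name", {
  expect_error(synthetic_survey_config(ph_stem_1983 = 3, ph_far_1983 = 6.6),
               "ph_far_1983", class = "config_error")
  expect_error(synthetic_survey_config(s_profile_target = 1.2),
               "s_profile_target", class = "config_error")
  expect_error(synthetic_survey_config(noise_sd = c(ph = -1)),
               class = "config_error")
  expect_error(synthetic_survey_config(noise_sd = c(phh = 1)),
               class = "config_error")
  expect_error(synthetic_survey_config(replicates = 0), class = "config_error")
})

test_that("generated values respect the sample-type invariants even under heavy noise", {
  cfg <- synthetic_survey_config(seed = 2,
                                 noise_sd = c(ph = 2, conc_rel = 1, bd = 1))
  sp <- suppressMessages(generate_survey(cfg))
  for (df in list(sp$early, sp$late)) {
    expect_true(all(df$ph_h2o > 2 & df$ph_h2o < 9))
    expect_true(all(df$bulk_density_g_cm3 > 0.1 & df$bulk_density_g_cm3 < 2.5))
    for (el in c("ca_exch_mg_g", "mg_exch_mg_g", "c_mg_g", "n_mg_g", "s_mg_g")) {
      expect_true(all(df[[el]] >= 0))
    }
  }
})

test_that("noiseless S stores are distance-flat at the target; cations increase downhill", {
  cfg <- noiseless_config()
  sp <- generate_survey(cfg)
  st <- store_table(sp$early)
  s <- st$profile[st$profile$element == "s_mg_g", ]
  expect_lt(diff(range(s$store_t_ha)), 1e-9)
  expect_equal(s$store_t_ha, rep(cfg$s_profile_target, nrow(s)))
  ca <- st$profile[st$profile$element == "ca_exch_mg_g", ]
  g <- distance_gradient(ca$distance_cm, ca$store_t_ha)
  expect_identical(g$verdict, "increasing")
  # deep-soil depletion near the stem: the 27 cm deep horizon is the minimum
  deep <- st$by_horizon[st$by_horizon$element == "ca_exch_mg_g" &
                          st$by_horizon$horizon_top_cm == 30, ]
  expect_equal(deep$distance_cm[which.min(deep$store_t_ha)], 27)
})

test_that("grid generator is radially symmetric and follows the topsoil profile", {
  cfg <- noiseless_config()
  g <- generate_grid(cfg, year = 1983, grid_extent = 300, spacing = 50)
  r <- sqrt(g$x_cm^2 + g$y_cm^2)
  for (rad in unique(round(r, 6))) {
    expect_lt(diff(range(g$ph_h2o[round(r, 6) == rad])), 1e-12)
  }
  ph27 <- expected_topsoil_ph(cfg, 27, 1983)
  ph300 <- expected_topsoil_ph(cfg, 300, 1983)
  expect_gt(ph300 - ph27, 0)
  expect_identical(g, generate_grid(cfg, year = 1983, grid_extent = 300,
                                    spacing = 50))
  expect_error(generate_grid(cfg, spacing = 0), class = "config_error")
})

test_that("deposition history wraps the deterministic trajectories", {
  sc <- deposition_scenario(115, 10, 8, 12)
  noiseless <- generate_deposition_history(synthetic_deposition_config(1, 0), sc)
  tr <- suppressMessages(build_trajectory(sc))
  expect_equal(noiseless$input_s, tr$input_s)
  expect_equal(noiseless$output_s, tr$output_s)
  cfgn <- synthetic_deposition_config(7, 5)
  a <- suppressMessages(generate_deposition_history(cfgn, sc))
  b <- suppressMessages(generate_deposition_history(cfgn, sc))
  expect_identical(a, b)
  expect_true(all(a$input_s >= 0) && all(a$output_s >= 0))
  expect_error(synthetic_deposition_config(1, -1), class = "config_error")
})

test_that("noisy replicate histories put the mean recovery year near the noiseless one", {
  # steep post-plateau decline (~3 kg/ha/yr) against annual noise of sd 5
  sc <- deposition_scenario(115, 10, 0, 12)
  base <- recovery_year(suppressMessages(build_trajectory(sc)))$year
  years <- withr::with_seed(99, {
    vapply(1:1000, function(i) {
      cfg <- synthetic_deposition_config(seed = sample.int(2^30, 1), noise_sd = 5)
      tr <- suppressMessages(generate_deposition_history(cfg, sc))
      recovery_year(tr)$year
    }, integer(1))
  })
  expect_lte(abs(mean(years) - base), 2)
})

test_that("a line on log-distance recovers the configured pH amplitude", {
  cfg <- noiseless_config()
  sp <- generate_survey(cfg)
  top <- sp$early[sp$early$horizon_top_cm == 0, ]
  fit <- stats::lm(ph_h2o ~ log(abs(distance_cm)), data = top)
  amp <- unname(stats::coef(fit)[2]) * log(300 / 27)
  expect_equal(amp, 3, tolerance = 1e-9)
})
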