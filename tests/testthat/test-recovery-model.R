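test_that("input trajectory is the two-point line, then constant", {
  # no decline
  sc <- deposition_scenario(115, 115, 115, 12)
  expect_true(all(build_input_trajectory(sc) == 115))
  # linear midpoint
  sc <- deposition_scenario(100, 10, 10, 12)
  tr <- build_trajectory(sc)
  expect_equal(tr$input_s[tr$year == 1998], 55)
  # full agreement with the interpolation oracle
  sc <- deposition_scenario(15, 6, 6, 12)
  yrs <- 1983:2050
  expect_equal(build_input_trajectory(sc), oracle_input_series(sc, yrs),
               tolerance = 1e-12)
})

test_that("output trajectory holds the plateau, then declines through the anchor", {
  # degenerate no-delay case with shared endpoints collapses onto the input
  # (under a shared post-anchor rule)
  sc <- deposition_scenario(100, 10, 10, 0)
  expect_equal(build_output_trajectory(sc, post_anchor = "constant"),
               build_input_trajectory(sc, post_anchor = "constant"))
  expect_equal(suppressMessages(build_output_trajectory(sc)),
               suppressMessages(build_input_trajectory(sc,
                                                       post_anchor = "extrapolate")))
  # inside the plateau
  sc <- deposition_scenario(100, 10, 40, 12)
  tr <- suppressMessages(build_trajectory(sc))
  expect_equal(tr$output_s[tr$year == 1990], 100)
  # hand-checked two-point line: slope (40-100)/18 after 1995, value 70 at 2004
  expect_equal(tr$output_s[tr$year == 2004], 70)
  expect_error(deposition_scenario(100, 10, 40, 30), class = "invalid_delay")
})

test_that("trajectories agree with the interpolation oracle on random scenarios", {
  withr::with_seed(42, {
    for (i in 1:40) {
      sc <- random_scenario()
      yrs <- 1983:2050
      expect_equal(build_input_trajectory(sc), oracle_input_series(sc, yrs),
                   tolerance = 1e-9)
      expect_equal(suppressMessages(build_output_trajectory(sc)),
                   oracle_output_series(sc, yrs), tolerance = 1e-9)
    }
  })
})

test_that("trajectories are exactly linear between their breakpoints", {
  withr::with_seed(11, {
    for (i in 1:20) {
      sc <- random_scenario()
      tr <- suppressMessages(build_trajectory(sc))
      plateau_end <- sc$start_year + sc$delay
      floor_year <- if (any(tr$output_s == 0)) min(tr$year[tr$output_s == 0]) else Inf
      breaks_in <- c(sc$anchor_year)
      breaks_out <- c(plateau_end, sc$anchor_year, floor_year)
      seg <- function(vals, yrs, brk) {
        # second differences vanish within each segment
        pieces <- split(vals, findInterval(yrs, sort(unique(c(-Inf, brk)))))
        for (p in pieces) {
          if (length(p) >= 3) expect_lt(max(abs(diff(diff(p)))), 1e-9)
        }
      }
      seg(tr$input_s, tr$year, breaks_in)
      seg(tr$output_s, tr$year, breaks_out)
      expect_true(all(tr$input_s >= 0) && all(tr$output_s >= 0))
    }
  })
})

test_that("recovery year matches the exhaustive scan and handles edge cases", {
  # identity case
  sc <- deposition_scenario(100, 10, 10, 0)
  r <- recovery_year(build_trajectory(sc))
  expect_identical(r$year, 1983L)
  expect_identical(r$status, "always-balanced")
  # never recovers: output held constant above the input
  sc <- deposition_scenario(100, 10, 40, 12)
  tr <- build_trajectory(sc, output_post_anchor = "constant")
  r <- recovery_year(tr)
  expect_identical(r$year, NA_integer_)
  expect_identical(r$status, "not-recovered")
  # the derived example: scan oracle agrees
  sc <- deposition_scenario(100, 10, 40, 12)
  tr <- suppressMessages(build_trajectory(sc))
  r <- recovery_year(tr)
  o <- oracle_recovery_scan(sc, tr$input_s, tr$output_s, tr$year)
  expect_identical(r$year, as.integer(o$year))
  expect_identical(r$status, o$status)
  expect_error(recovery_year(tibble::tibble(year = integer(),
                                            input_s = numeric(),
                                            output_s = numeric()),
                             plateau_end = 1995),
               class = "invalid_input")
})

test_that("scenario sweep preserves order and validates loads", {
  tpl <- deposition_scenario(115, 10, 10, 12, distance = 300)
  # load equal to both endpoints: balanced from the start
  one <- scenario_sweep(10, deposition_scenario(10, 10, 10, 12))
  expect_identical(one$recovery_year, 1983L)
  expect_identical(one$status, "always-balanced")
  # ordering follows the input order
  tpl2 <- deposition_scenario(115, 10, 8, 12, distance = 300)
  fwd <- suppressMessages(scenario_sweep(c(115, 55, 15), tpl2))
  bwd <- suppressMessages(scenario_sweep(c(15, 55, 115), tpl2))
  expect_identical(fwd$recovery_year, rev(bwd$recovery_year))
  # higher historic load never recovers earlier (net-sink endpoints)
  expect_true(all(diff(bwd$recovery_year) >= 0))
  expect_error(scenario_sweep(5, tpl), class = "invalid_scenario")
  expect_error(scenario_sweep(numeric(), tpl), class = "invalid_scenario")
})

test_that("cumulative net sulfur matches trivial cases and the dense oracle", {
  sc <- deposition_scenario(100, 10, 10, 0)
  tr <- build_trajectory(sc, output_post_anchor = "constant")
  expect_equal(cumulative_net_s(tr, 1983, 2050), 0)
  expect_equal(cumulative_net_s(tr, 1990, 2000), 0)
  # constant excess of 2 over 10 years
  tr2 <- tibble::tibble(year = 2000:2010, input_s = 5, output_s = 7)
  expect_equal(cumulative_net_s(tr2, 2000, 2010), 20)
  expect_error(cumulative_net_s(tr2, 1990, 2005), class = "range_error")
  withr::with_seed(3, {
    for (i in 1:10) {
      sc <- random_scenario()
      tr <- suppressMessages(build_trajectory(sc))
      got <- cumulative_net_s(tr, 1983, 2050)
      want <- oracle_riemann_net(tr$year, tr$input_s, tr$output_s, 1983, 2050)
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("net source switches sign at the recovery crossing", {
  # once output stays below input, the cumulative balance must decline
  sc <- deposition_scenario(115, 10, 8, 12, distance = 27)
  tr <- suppressMessages(build_trajectory(sc))
  r <- recovery_year(tr)
  after <- vapply((r$year + 1):2049, function(y) {
    cumulative_net_s(tr, y, y + 1)
  }, numeric(1))
  expect_true(all(after <= 1e-9))
})
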