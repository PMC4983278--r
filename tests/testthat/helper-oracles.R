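# Independent oracles: two-point interpolation via stats::approx, an
# exhaustive annual recovery scan, and a dense midpoint Riemann sum. These
# deliberately do not share code with the trajectory construction in R/.

oracle_input_series <- function(sc, years) {
  vals <- numeric(length(years))
  pre <- years <= sc$anchor_year
  vals[pre] <- stats::approx(
    x = c(sc$start_year, sc$anchor_year),
    y = c(sc$load_1983, sc$input_2013), xout = years[pre])$y
  vals[!pre] <- sc$input_2013
  pmax(vals, 0)
}

oracle_output_series <- function(sc, years) {
  plateau_end <- sc$start_year + sc$delay
  slope <- (sc$output_2013 - sc$load_1983) / (sc$anchor_year - plateau_end)
  vals <- numeric(length(years))
  vals[years <= plateau_end] <- sc$load_1983
  mid <- years > plateau_end & years <= sc$anchor_year
  vals[mid] <- stats::approx(
    x = c(plateau_end, sc$anchor_year),
    y = c(sc$load_1983, sc$output_2013), xout = years[mid])$y
  post <- years > sc$anchor_year
  vals[post] <- sc$output_2013 + slope * (years[post] - sc$anchor_year)
  pmax(vals, 0)
}

# First year strictly after the plateau with output <= input, by brute scan.
oracle_recovery_scan <- function(sc, input_s, output_s, years) {
  if (all(output_s <= input_s)) {
    return(list(year = min(years), status = "always-balanced"))
  }
  for (i in seq_along(years)) {
    if (years[i] > sc$start_year + sc$delay && output_s[i] <= input_s[i]) {
      return(list(year = years[i], status = "recovered-within-horizon"))
    }
  }
  list(year = NA_integer_, status = "not-recovered")
}

# Dense midpoint Riemann sum of (output - input), step dt years, linear
# interpolation between annual nodes.
oracle_riemann_net <- function(years, input_s, output_s, from, to, dt = 0.001) {
  net <- output_s - input_s
  mids <- seq(from + dt / 2, to, by = dt)
  sum(stats::approx(years, net, xout = mids)$y) * dt
}

random_scenario <- function() {
  load <- stats::runif(1, 20, 150)
  deposition_scenario(
    load_1983 = load,
    input_2013 = stats::runif(1, 0, load),
    output_2013 = stats::runif(1, 0, load),
    delay = sample(0:12, 1),
    start_year = 1983L, anchor_year = 2013L, horizon_year = 2050L
  )
}

noiseless_config <- function(seed = 1L, ...) {
  synthetic_survey_config(seed = seed, noise_sd = 0, sites = "site_1", ...)
}
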