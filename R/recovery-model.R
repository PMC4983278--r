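# Piecewise-linear annual sulfur input/output trajectories for one soil
# column, and the recovery criterion (first year with output <= input).
#
# Construction: the 1983 input equals the historic load and declines
# linearly to the measured 2013 input; the output holds a plateau at the
# historic load (maximal output = maximal input, after a decade of roughly
# constant emissions) for `delay` years before declining linearly to the
# 2013 output. Post-2013 behaviour is not observable and is configurable.

#' Construct a deposition scenario
#'
#' All fluxes are areal sulfur fluxes in kg S ha^-1 yr^-1 on the column's
#' infiltration-area basis.
#'
#' @param load_1983 the column's input at `start_year` (the historic load).
#' @param input_2013 input at `anchor_year`.
#' @param output_2013 seepage output (50 cm depth) at `anchor_year`.
#' @param delay steady-state delay in whole years; the output plateau runs
#'   from `start_year` through `start_year + delay`. Must be shorter than
#'   the `start_year`-to-`anchor_year` span.
#' @param start_year,anchor_year,horizon_year calendar years (defaults
#'   1983, 2013, 2050).
#' @param distance optional column distance in cm, carried through to
#'   results.
#' @return a `deposition_scenario` list.
#' @export
deposition_scenario <- function(load_1983, input_2013, output_2013, delay,
                                start_year = 1983L, anchor_year = 2013L,
                                horizon_year = 2050L, distance = NA_real_) {
  for (v in c("load_1983", "input_2013", "output_2013")) {
    x <- get(v)
    if (!is_number(x) || x < 0) {
      abort2(sprintf("`%s` must be a non-negative flux", v), "invalid_scenario")
    }
  }
  if (!(start_year < anchor_year && anchor_year < horizon_year)) {
    abort2("need start_year < anchor_year < horizon_year", "invalid_scenario")
  }
  if (!is_number(delay) || delay < 0 || delay != round(delay)) {
    abort2("`delay` must be a non-negative whole number of years",
           "invalid_delay")
  }
  if (delay >= anchor_year - start_year) {
    abort2("`delay` must be shorter than the start-to-anchor span",
           "invalid_delay")
  }
  structure(
    list(load_1983 = load_1983, input_2013 = input_2013,
         output_2013 = output_2013, delay = as.integer(delay),
         start_year = as.integer(start_year),
         anchor_year = as.integer(anchor_year),
         horizon_year = as.integer(horizon_year), distance = distance),
    class = "deposition_scenario"
  )
}

scenario_years <- function(scenario) {
  seq.int(scenario$start_year, scenario$horizon_year)
}

#' Annual input trajectory
#'
#' Linear decline from `load_1983` at `start_year` to `input_2013` at
#' `anchor_year`; afterwards held constant (default) or extrapolated along
#' the same slope, floored at 0.
#'
#' @param scenario a [deposition_scenario()].
#' @param post_anchor `"constant"` (default) or `"extrapolate"`.
#' @return numeric vector of fluxes, one per year from `start_year` to
#'   `horizon_year`.
#' @export
build_input_trajectory <- function(scenario,
                                   post_anchor = c("constant", "extrapolate")) {
  post_anchor <- match.arg(post_anchor)
  yrs <- scenario_years(scenario)
  slope <- (scenario$input_2013 - scenario$load_1983) /
    (scenario$anchor_year - scenario$start_year)
  vals <- scenario$load_1983 + slope * (yrs - scenario$start_year)
  after <- yrs > scenario$anchor_year
  if (post_anchor == "constant") vals[after] <- scenario$input_2013
  clip_floor(vals)
}

#' Annual output trajectory
#'
#' Plateau at `load_1983` (the maximal input) from `start_year` through
#' `start_year + delay`; then linear so the value is `output_2013` at
#' `anchor_year`; afterwards continues with the same slope (default) or is
#' held constant. Floored at 0.
#'
#' @param scenario a [deposition_scenario()].
#' @param post_anchor `"extrapolate"` (default) or `"constant"`.
#' @return numeric vector of fluxes, one per year.
#' @export
build_output_trajectory <- function(scenario,
                                    post_anchor = c("extrapolate", "constant")) {
  post_anchor <- match.arg(post_anchor)
  yrs <- scenario_years(scenario)
  plateau_end <- scenario$start_year + scenario$delay
  slope <- (scenario$output_2013 - scenario$load_1983) /
    (scenario$anchor_year - plateau_end)
  vals <- ifelse(yrs <= plateau_end,
                 scenario$load_1983,
                 scenario$load_1983 + slope * (yrs - plateau_end))
  if (post_anchor == "constant") {
    vals[yrs > scenario$anchor_year] <- scenario$output_2013
  }
  clip_floor(vals)
}

clip_floor <- function(vals) {
  n_neg <- sum(vals < 0)
  if (n_neg > 0) {
    message(sprintf("clipped %d negative flux value(s) to 0", n_neg))
    vals[vals < 0] <- 0
  }
  vals
}

#' Build the paired annual trajectory table
#'
#' @inheritParams build_input_trajectory
#' @param input_post_anchor,output_post_anchor post-2013 rules, see
#'   [build_input_trajectory()] and [build_output_trajectory()].
#' @return tibble with columns `year`, `input_s`, `output_s`; the scenario
#'   is attached as attribute `"scenario"`.
#' @export
build_trajectory <- function(scenario,
                             input_post_anchor = "constant",
                             output_post_anchor = "extrapolate") {
  out <- tibble::tibble(
    year = scenario_years(scenario),
    input_s = build_input_trajectory(scenario, input_post_anchor),
    output_s = build_output_trajectory(scenario, output_post_anchor)
  )
  attr(out, "scenario") <- scenario
  out
}

#' First year of recovery (output <= input)
#'
#' Scans the annual trajectory strictly after the output plateau ends and
#' returns the first year with `output_s <= input_s`. When output never
#' exceeds input the column was always balanced and `start_year` is
#' returned; when no qualifying year exists up to the horizon the column
#' has not recovered.
#'
#' @param trajectory a table from [build_trajectory()], or any table with
#'   `year`, `input_s`, `output_s`; `plateau_end` then locates the last
#'   plateau year.
#' @param plateau_end last calendar year of the output plateau; defaults to
#'   `start_year + delay` of the attached scenario.
#' @return list with `year` (integer, `NA` if not recovered) and `status`
#'   (`"recovered-within-horizon"`, `"not-recovered"` or
#'   `"always-balanced"`).
#' @export
recovery_year <- function(trajectory, plateau_end = NULL) {
  if (!nrow(trajectory)) abort2("empty trajectory", "invalid_input")
  if (is.null(plateau_end)) {
    sc <- attr(trajectory, "scenario")
    if (is.null(sc)) {
      abort2("no attached scenario; supply `plateau_end`", "invalid_input")
    }
    plateau_end <- sc$start_year + sc$delay
  }
  yr <- trajectory$year
  bal <- trajectory$output_s <= trajectory$input_s
  if (all(bal)) {
    return(list(year = as.integer(min(yr)), status = "always-balanced"))
  }
  cand <- which(bal & yr > plateau_end)
  if (!length(cand)) {
    return(list(year = NA_integer_, status = "not-recovered"))
  }
  list(year = as.integer(yr[min(cand)]), status = "recovered-within-horizon")
}

#' Sweep historic deposition loads
#'
#' Rebuilds the scenario for each historic load (2013 endpoints, delay and
#' years held fixed) and reports the recovery year of each, in input order.
#'
#' @param loads historic 1983 loads, kg S ha^-1 yr^-1; each must be at
#'   least the template's `input_2013`.
#' @param template a [deposition_scenario()] providing all other fields.
#' @inheritParams build_trajectory
#' @return tibble with `column_distance`, `load_1983`, `recovery_year`,
#'   `status`, one row per load.
#' @export
scenario_sweep <- function(loads, template,
                           input_post_anchor = "constant",
                           output_post_anchor = "extrapolate") {
  if (!length(loads)) abort2("`loads` must be non-empty", "invalid_scenario")
  if (any(loads < template$input_2013)) {
    abort2("every load must be >= the template's input_2013 (no historic decline to model otherwise)",
           "invalid_scenario")
  }
  rows <- lapply(loads, function(ld) {
    sc <- deposition_scenario(
      load_1983 = ld, input_2013 = template$input_2013,
      output_2013 = template$output_2013, delay = template$delay,
      start_year = template$start_year, anchor_year = template$anchor_year,
      horizon_year = template$horizon_year, distance = template$distance
    )
    rec <- recovery_year(build_trajectory(sc, input_post_anchor,
                                          output_post_anchor))
    tibble::tibble(column_distance = sc$distance, load_1983 = ld,
                   recovery_year = rec$year, status = rec$status)
  })
  do.call(rbind, rows)
}

#' Cumulative net sulfur balance over an interval
#'
#' Trapezoidal integral of `output_s - input_s` over `[from_year, to_year]`,
#' in kg S ha^-1. Positive values mean the column was a net sulfur source
#' over the interval; the year the cumulative balance turns is where the
#' column switches from source to sink.
#'
#' @param trajectory trajectory table with `year`, `input_s`, `output_s`.
#' @param from_year,to_year integration bounds (calendar years inside the
#'   trajectory's range).
#' @return net mass in kg S ha^-1.
#' @export
cumulative_net_s <- function(trajectory, from_year, to_year) {
  if (from_year > to_year ||
      from_year < min(trajectory$year) || to_year > max(trajectory$year)) {
    abort2("integration bounds outside the trajectory's year range",
           "range_error")
  }
  keep <- trajectory$year >= from_year & trajectory$year <= to_year
  net <- trajectory$output_s[keep] - trajectory$input_s[keep]
  if (sum(keep) < 2) return(0)
  pracma::trapz(trajectory$year[keep], net)
}

#' Percentage decline between two emission totals
#'
#' `100 * (1 - to / from)`; e.g. national SO2 emissions of 385,000 t in 1980
#' falling to 17,000 t in 2013 is a 95.58 percent decline.
#'
#' @param from,to emission totals in the same unit, `from > 0`.
#' @return percentage decline.
#' @export
emission_decline_pct <- function(from, to) {
  if (!is_number(from) || from <= 0 || !is_number(to) || to < 0) {
    abort2("`from` must be > 0 and `to` >= 0", "invalid_input")
  }
  100 * (1 - to / from)
}
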