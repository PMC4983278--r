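# Default study configuration for the worked analysis: a single beech crown
# with the canonical column set, explicit steady-state delays, and synthetic
# stand-level flux fixtures. The 1983/2013 endpoint fluxes are NOT the
# original sites' measurements (those live in unpublished companion data);
# they are documented fixtures chosen to be of realistic magnitude, so the
# analysis demonstrates the method, not the sites.

#' Default beech stand
#'
#' Canonical distances -55, 27, 55, 100, 150, 300 cm; stemflow routing
#' fractions 0, 0.50, 0.25, 0.17, 0.10, 0 (the uphill and between-trees
#' columns receive no stemflow; the downhill fractions sum to 1.02 and are
#' kept as published, not renormalized); annulus infiltration areas within a
#' 50 m^2 crown projection; explicit steady-state delays 12, 4, 6, 7, 9, 12
#' years.
#'
#' @param strict reject routing-fraction sums above 1.05 (default `FALSE`).
#' @return a [stand_spec()].
#' @export
default_stand <- function(strict = FALSE) {
  distances <- canonical_distances()
  fractions <- c(0, 0.50, 0.25, 0.17, 0.10, 0)
  delays <- c(12L, 4L, 6L, 7L, 9L, 12L)
  areas <- default_infiltration_areas(distances, crown_projection_area = 50)
  cols <- lapply(seq_along(distances), function(i) {
    column_spec(distances[i], fractions[i], areas[i], delay = delays[i])
  })
  suppressWarnings(
    stand_spec(cols, crown_projection_area = 50, base_delay = 12L,
               strict = strict)
  )
}

#' Default stand-level flux fixtures
#'
#' Synthetic annual stand-area fluxes for the two anchor years: 1983 (peak
#' deposition) and 2013 (after the emission decline). S fluxes in
#' kg S ha^-1 yr^-1, water in mm yr^-1.
#'
#' @return tibble with rows for 1983 and 2013.
#' @export
default_flux_table <- function() {
  tibble::tibble(
    year = c(1983L, 2013L),
    tf_s = c(15, 10),
    sf_s = c(3, 0.6),
    tf_water = c(500, 500),
    sf_water = c(40, 40)
  )
}

#' Per-column deposition scenarios from stand fluxes
#'
#' Builds one [deposition_scenario()] per column of a stand from 1983 and
#' 2013 stand-level fluxes. Inputs are [column_input()] of each year's
#' fluxes. The 2013 output is `output_2013_far` for the outermost
#' (between-trees) column; the near-stem column's 2013 output is assumed
#' equal to its 2013 stemflow-derived input; every other column's output is
#' scaled from the far value in proportion to its 2013 input.
#'
#' @param stand a [stand_spec()].
#' @param flux_1983,flux_2013 one-row data frames with `tf_s`, `sf_s`.
#' @param output_2013_far seepage output at the outermost column in 2013,
#'   kg S ha^-1 yr^-1.
#' @param horizon_year simulation horizon (default 2050).
#' @return list of `deposition_scenario` objects, one per column, in stand
#'   order.
#' @export
column_scenarios <- function(stand, flux_1983, flux_2013, output_2013_far = 8,
                             horizon_year = 2050L) {
  cols <- stand$columns
  dist <- vapply(cols, `[[`, numeric(1), "distance")
  inner <- which(dist == min(dist[dist > 0]))
  outer <- which(dist == max(dist))
  in13 <- vapply(cols, function(cl) {
    column_input(flux_2013$tf_s, flux_2013$sf_s, cl, stand)
  }, numeric(1))
  lapply(seq_along(cols), function(i) {
    cl <- cols[[i]]
    out13 <- if (i == inner) {
      local_stemflow_flux(flux_2013$sf_s, cl, stand)
    } else if (i == outer) {
      output_2013_far
    } else {
      output_2013_far * in13[i] / in13[outer]
    }
    deposition_scenario(
      load_1983 = column_input(flux_1983$tf_s, flux_1983$sf_s, cl, stand),
      input_2013 = in13[i],
      output_2013 = out13,
      delay = cl$delay,
      start_year = 1983L, anchor_year = 2013L,
      horizon_year = horizon_year, distance = cl$distance
    )
  })
}
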