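# Stand-level routing of stemflow sulfur into per-column local inputs.
#
# The stand is a single beech crown; stemflow runs downhill from the trunk
# and infiltrates a sequence of soil columns at fixed distances. Each column
# receives a fixed fraction of the stand's stemflow flux, concentrated onto
# that column's infiltration area.

#' Construct a soil-column specification
#'
#' One downhill (or uphill) soil column at a fixed distance from the trunk.
#'
#' @param distance signed distance from the trunk in cm; negative = uphill.
#' @param routing_fraction fraction of the stand's stemflow routed through
#'   this column, in `[0, 1]`.
#' @param infiltration_area the column's infiltration area in m^2 (the area
#'   over which its share of stemflow spreads). Must be positive.
#' @param delay optional explicit steady-state delay in whole years; when
#'   supplied it takes precedence over the delay derived from the water time
#'   factor.
#' @return a `column_spec` list.
#' @export
column_spec <- function(distance, routing_fraction, infiltration_area,
                        delay = NULL) {
  if (!is_number(distance)) {
    abort2("`distance` must be a single finite number (cm)", "invalid_geometry")
  }
  if (!is_number(routing_fraction) || routing_fraction < 0 ||
      routing_fraction > 1) {
    abort2("`routing_fraction` must lie in [0, 1]", "invalid_fraction")
  }
  if (!is_number(infiltration_area) || infiltration_area <= 0) {
    abort2("`infiltration_area` must be > 0 m^2", "invalid_geometry")
  }
  if (!is.null(delay)) {
    if (!is_number(delay) || delay < 0 || delay != round(delay)) {
      abort2("`delay` must be a non-negative whole number of years",
             "invalid_delay")
    }
    delay <- as.integer(delay)
  }
  structure(
    list(distance = distance, routing_fraction = routing_fraction,
         infiltration_area = infiltration_area, delay = delay),
    class = "column_spec"
  )
}

#' Construct a stand specification
#'
#' A beech stand reduced to one representative crown with an ordered set of
#' soil columns downhill of the trunk. Routing fractions need not sum to 1:
#' the canonical set (0.50, 0.25, 0.17, 0.10, 0 at 27/55/100/150/300 cm)
#' sums to 1.02 and is accepted as-is with a warning; `strict = TRUE`
#' rejects sums above 1.05. Fractions are never renormalized.
#'
#' @param columns list of [column_spec()] objects, downhill distances
#'   strictly increasing.
#' @param crown_projection_area crown projection area in m^2 (default 50).
#' @param base_delay steady-state delay of the throughfall-only column, in
#'   whole years (default 12).
#' @param strict reject routing-fraction sums above 1.05 (default `FALSE`).
#' @return a `stand_spec` list.
#' @export
stand_spec <- function(columns, crown_projection_area = 50, base_delay = 12L,
                       strict = FALSE) {
  if (!is_number(crown_projection_area) || crown_projection_area <= 0) {
    abort2("`crown_projection_area` must be > 0 m^2", "invalid_geometry")
  }
  if (!is_number(base_delay) || base_delay < 0 || base_delay != round(base_delay)) {
    abort2("`base_delay` must be a non-negative whole number of years",
           "invalid_delay")
  }
  if (!length(columns) || !all(vapply(columns, inherits, TRUE, "column_spec"))) {
    abort2("`columns` must be a non-empty list of column_spec objects",
           "invalid_geometry")
  }
  dist <- vapply(columns, `[[`, numeric(1), "distance")
  down <- dist[dist > 0]
  if (any(diff(down) <= 0)) {
    abort2("downhill column distances must be strictly increasing",
           "invalid_geometry")
  }
  frac_sum <- sum(vapply(columns, `[[`, numeric(1), "routing_fraction"))
  if (frac_sum > 1 + 1e-12) {
    if (strict && frac_sum > 1.05) {
      abort2(sprintf("routing fractions sum to %.3f > 1.05 (strict mode)",
                     frac_sum), "invalid_fraction")
    }
    warning(sprintf("routing fractions sum to %.3f (> 1); kept as-is, not renormalized",
                    frac_sum), call. = FALSE)
  }
  for (i in seq_along(columns)) {
    d <- columns[[i]]$delay
    if (!is.null(d) && d > base_delay) {
      abort2("explicit column delay exceeds `base_delay`", "invalid_delay")
    }
  }
  structure(
    list(columns = columns, crown_projection_area = crown_projection_area,
         base_delay = as.integer(base_delay), routing_fraction_sum = frac_sum),
    class = "stand_spec"
  )
}

#' Annulus-based default infiltration areas
#'
#' The crown projection circle is split into concentric annuli: each downhill
#' column owns the ring between the midpoints to its neighbouring sampled
#' distances. The innermost ring starts at the stem surface (radius
#' `stem_radius`, default 25 cm), the outermost ends at the crown projection
#' radius `sqrt(area / pi)`. Uphill columns are assigned the annulus their
#' absolute distance would receive downhill.
#'
#' @param distances signed distances in cm.
#' @param crown_projection_area crown area in m^2.
#' @param stem_radius stem radius in cm (default 25).
#' @return infiltration areas in m^2, one per distance.
#' @export
default_infiltration_areas <- function(distances, crown_projection_area = 50,
                                       stem_radius = 25) {
  if (crown_projection_area <= 0 || stem_radius <= 0) {
    abort2("crown area and stem radius must be positive", "invalid_geometry")
  }
  crown_radius_cm <- sqrt(crown_projection_area / pi) * 100
  down <- sort(unique(abs(distances)))
  if (min(down) <= stem_radius) {
    abort2("column distances must exceed the stem radius", "invalid_geometry")
  }
  breaks <- c(stem_radius,
              if (length(down) > 1) (down[-length(down)] + down[-1]) / 2,
              max(crown_radius_cm, max(down)))
  ring <- pi * diff((breaks / 100)^2)  # m^2
  ring[match(abs(distances), down)]
}

#' Stemflow flux concentrated onto one column
#'
#' Routes the stand-area stemflow sulfur flux through a column: the column's
#' routing fraction of the stand total, re-expressed per unit of the column's
#' own infiltration area.
#'
#' @param sf_s stand-area stemflow S flux, kg S ha^-1 yr^-1.
#' @param column a [column_spec()].
#' @param stand the owning [stand_spec()].
#' @return local areal flux in kg S ha^-1 yr^-1 on the column's infiltration
#'   area: `routing_fraction * sf_s * crown_area / infiltration_area`.
#' @export
local_stemflow_flux <- function(sf_s, column, stand) {
  if (!is_number(sf_s) || sf_s < 0) {
    abort2("`sf_s` must be a non-negative flux", "invalid_flux")
  }
  if (column$infiltration_area <= 0) {
    abort2("non-positive infiltration area", "invalid_geometry")
  }
  column$routing_fraction * sf_s *
    stand$crown_projection_area / column$infiltration_area
}

#' Total sulfur input to one column
#'
#' Throughfall plus locally concentrated stemflow. For a column with routing
#' fraction 0 (between trees, or uphill) this is throughfall alone.
#'
#' @param tf_s stand-area throughfall S flux, kg S ha^-1 yr^-1.
#' @inheritParams local_stemflow_flux
#' @return areal input flux, kg S ha^-1 yr^-1.
#' @export
column_input <- function(tf_s, sf_s, column, stand) {
  if (!is_number(tf_s) || tf_s < 0) {
    abort2("`tf_s` must be a non-negative flux", "invalid_flux")
  }
  tf_s + local_stemflow_flux(sf_s, column, stand)
}

#' Water time factor of a column
#'
#' The false-chronosequence multiplier `(TF + SF) / TF` built from water
#' fluxes: a column receiving stemflow water on top of throughfall percolates
#' proportionally faster towards a new sulfate steady state.
#'
#' @param tf_water throughfall water flux, mm yr^-1 (must be positive).
#' @param local_sf_water stemflow water reaching this column, mm yr^-1 on
#'   the column's infiltration-area basis (routed like the S flux).
#' @return dimensionless factor `>= 1`.
#' @export
water_time_factor <- function(tf_water, local_sf_water) {
  if (!is_number(tf_water) || tf_water <= 0) {
    abort2("`tf_water` must be > 0", "invalid_flux")
  }
  if (!is.numeric(local_sf_water) || any(local_sf_water < 0)) {
    abort2("`local_sf_water` must be >= 0", "invalid_flux")
  }
  (tf_water + local_sf_water) / tf_water
}

#' Steady-state delay from a water time factor
#'
#' The throughfall-only column needs `base_delay` years to reach a sulfate
#' steady state after deposition stabilizes; a column flushed `factor` times
#' faster needs `base_delay / factor` years, rounded half-up to whole years.
#' Factors (3, 2, 12/7, 4/3, 1) with base 12 give delays (4, 6, 7, 9, 12).
#'
#' @param factor water time factor, `>= 1`.
#' @param base_delay delay of the throughfall-only column, whole years.
#' @return integer delay in years; equals `base_delay` at factor 1.
#' @export
delay_from_factor <- function(factor, base_delay) {
  if (!is.numeric(factor) || any(!is.finite(factor)) || any(factor < 1)) {
    abort2("`factor` must be >= 1", "invalid_factor")
  }
  if (!is_number(base_delay) || base_delay < 0) {
    abort2("`base_delay` must be >= 0", "invalid_delay")
  }
  as.integer(round_half_up(base_delay / factor))
}

#' Per-column routing summary for one flux record
#'
#' Applies the routing to every column of a stand for a single year's fluxes
#' and reports local stemflow S, total input, routed water, time factor and
#' delay (explicit delay takes precedence over the factor-derived one).
#' Also reports the total routed stemflow mass fraction, which is never
#' renormalized.
#'
#' @param stand a [stand_spec()].
#' @param tf_s,sf_s stand-area S fluxes, kg S ha^-1 yr^-1.
#' @param tf_water,sf_water stand-area water fluxes, mm yr^-1; when `NULL`,
#'   time factors are omitted and explicit delays are required.
#' @return tibble with one row per column.
#' @export
stand_local_inputs <- function(stand, tf_s, sf_s,
                               tf_water = NULL, sf_water = NULL) {
  cols <- stand$columns
  local_sf_s <- vapply(cols, function(cl) local_stemflow_flux(sf_s, cl, stand),
                       numeric(1))
  input_s <- tf_s + local_sf_s
  if (!is.null(tf_water) && !is.null(sf_water)) {
    local_sf_w <- vapply(cols, function(cl) {
      cl$routing_fraction * sf_water *
        stand$crown_projection_area / cl$infiltration_area
    }, numeric(1))
    factor <- water_time_factor(tf_water, local_sf_w)
  } else {
    local_sf_w <- rep(NA_real_, length(cols))
    factor <- rep(NA_real_, length(cols))
  }
  delay <- vapply(seq_along(cols), function(i) {
    if (!is.null(cols[[i]]$delay)) return(cols[[i]]$delay)
    if (is.na(factor[i])) {
      abort2(sprintf("column at %g cm: no explicit delay and no water fluxes",
                     cols[[i]]$distance), "invalid_delay")
    }
    delay_from_factor(factor[i], stand$base_delay)
  }, integer(1))
  tibble::tibble(
    distance_cm = vapply(cols, `[[`, numeric(1), "distance"),
    routing_fraction = vapply(cols, `[[`, numeric(1), "routing_fraction"),
    infiltration_area_m2 = vapply(cols, `[[`, numeric(1), "infiltration_area"),
    local_sf_s = local_sf_s,
    input_s = input_s,
    local_sf_water = local_sf_w,
    time_factor = factor,
    delay_yr = delay
  )
}
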