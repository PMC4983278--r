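# Micro-spatial soil-chemistry gradients around a beech stem: element
# stores per distance x horizon, distance gradients, survey-to-survey
# deltas, the depth of the acidification front, and IDW pH maps.

#' Canonical sampling design
#'
#' Six distances from the trunk (cm; negative = uphill) and five mineral
#' soil horizons (cm depth, half-open `[top, bottom)` intervals) down to
#' 50 cm.
#' @name canonical-design
NULL

#' @rdname canonical-design
#' @export
canonical_distances <- function() c(-55, 27, 55, 100, 150, 300)

#' @rdname canonical-design
#' @export
canonical_horizons <- function() {
  tibble::tibble(top = c(0, 3, 10, 20, 30), bottom = c(3, 10, 20, 30, 50))
}

#' Areal element store of one soil layer
#'
#' `concentration * bulk_density * thickness * 0.1` converts
#' mg g^-1 x g cm^-3 x cm into t ha^-1. An optional stone fraction reduces
#' the fine-earth volume as `(1 - stone_fraction)`.
#'
#' @param concentration element concentration, mg g^-1 (vectorized).
#' @param bulk_density fine-earth bulk density, g cm^-3.
#' @param top,bottom horizon depths in cm, `top < bottom`.
#' @param stone_fraction volumetric coarse-fragment fraction in `[0, 1)`,
#'   default 0.
#' @return areal stock in t ha^-1.
#' @export
element_store <- function(concentration, bulk_density, top, bottom,
                          stone_fraction = 0) {
  if (any(bottom - top <= 0)) {
    abort2("horizon thickness must be positive", "invalid_horizon")
  }
  if (any(concentration < 0) || any(bulk_density <= 0)) {
    abort2("concentration must be >= 0 and bulk density > 0", "invalid_input")
  }
  concentration * bulk_density * (bottom - top) * 0.1 * (1 - stone_fraction)
}

#' Whole-profile element stores at one distance
#'
#' Sums [element_store()] over a complete set of horizons for each element
#' column present. The profile must cover every requested horizon exactly
#' once; gaps are reported by name.
#'
#' @param samples data frame for one distance (and one survey year) with
#'   columns `horizon_top_cm`, `horizon_bottom_cm`, `bulk_density_g_cm3`,
#'   optionally `stone_fraction`, and one or more element-concentration
#'   columns (mg g^-1).
#' @param elements concentration columns to aggregate (default: all of
#'   `ca_exch_mg_g`, `mg_exch_mg_g`, `c_mg_g`, `n_mg_g`, `s_mg_g` that are
#'   present).
#' @param horizons required horizon table (default [canonical_horizons()]).
#' @return named numeric vector of profile stores, t ha^-1.
#' @export
profile_store <- function(samples, elements = NULL,
                          horizons = canonical_horizons()) {
  if (is.null(elements)) {
    elements <- intersect(
      c("ca_exch_mg_g", "mg_exch_mg_g", "c_mg_g", "n_mg_g", "s_mg_g"),
      names(samples))
  }
  key <- paste(samples$horizon_top_cm, samples$horizon_bottom_cm, sep = "-")
  want <- paste(horizons$top, horizons$bottom, sep = "-")
  missing <- setdiff(want, key)
  if (length(missing)) {
    abort2(paste0("incomplete profile; missing horizon(s): ",
                  paste(missing, "cm", collapse = ", ")), "incomplete_profile")
  }
  if (anyDuplicated(key)) {
    abort2("duplicated horizons in profile", "ambiguity_error")
  }
  sf <- if ("stone_fraction" %in% names(samples)) samples$stone_fraction else 0
  vapply(elements, function(el) {
    sum(element_store(samples[[el]], samples$bulk_density_g_cm3,
                      samples$horizon_top_cm, samples$horizon_bottom_cm, sf))
  }, numeric(1))
}

#' Distance gradient of a soil variable
#'
#' Orders per-distance values by downhill distance (the uphill sample is
#' reported separately) and classifies the downhill sequence as increasing,
#' decreasing, flat or non-monotone using non-strict comparisons with an
#' absolute tie tolerance.
#'
#' @param distance signed distances in cm.
#' @param value one value per distance.
#' @param tol tie tolerance in the variable's units (default 1e-9).
#' @return list with `downhill` (tibble sorted by distance), `uphill`
#'   (tibble, possibly empty) and `verdict` (one of `"increasing"`,
#'   `"decreasing"`, `"non-monotone: flat"`, `"non-monotone"`).
#' @export
distance_gradient <- function(distance, value, tol = 1e-9) {
  if (length(distance) != length(value)) {
    abort2("`distance` and `value` lengths differ", "invalid_input")
  }
  if (anyDuplicated(distance)) {
    abort2("duplicate distances; aggregate replicates first", "ambiguity_error")
  }
  down <- distance > 0
  if (sum(down) < 3) {
    abort2("need >= 3 downhill distances", "invalid_input")
  }
  ord <- order(distance[down])
  d_tab <- tibble::tibble(distance = distance[down][ord],
                          value = value[down][ord])
  u_tab <- tibble::tibble(distance = distance[!down], value = value[!down])
  dv <- diff(d_tab$value)
  verdict <-
    if (all(abs(dv) <= tol)) "non-monotone: flat"
    else if (all(dv >= -tol)) "increasing"
    else if (all(dv <= tol)) "decreasing"
    else "non-monotone"
  list(downhill = d_tab, uphill = u_tab, verdict = verdict)
}

#' Per-cell change between two surveys
#'
#' Aligns the two surveys of a survey pair on (site, distance, horizon)
#' cells — averaging replicates within a cell — and returns the late-minus-
#' early difference of one variable per cell. Cells present in only one
#' survey raise an alignment error naming the offenders.
#'
#' @param pair a survey pair: list with data frames `early` and `late` in
#'   the soil-table dialect (see [read_soil_table()]).
#' @param variable name of the numeric column to difference (e.g.
#'   `"ph_h2o"`).
#' @return tibble with `site`, `distance_cm`, `horizon_top_cm`,
#'   `horizon_bottom_cm`, `early`, `late`, `delta`.
#' @export
temporal_delta <- function(pair, variable) {
  cellify <- function(df) {
    if (!variable %in% names(df)) {
      abort2(sprintf("variable `%s` not present in both surveys", variable),
             "alignment_error")
    }
    ok <- !is.na(df[[variable]])
    n_drop <- sum(!ok)
    if (n_drop > 0) {
      message(sprintf("temporal_delta: excluded %d cell(s) with missing `%s`",
                      n_drop, variable))
    }
    df <- df[ok, , drop = FALSE]
    agg <- stats::aggregate(
      df[[variable]],
      by = list(site = df$site, distance_cm = df$distance_cm,
                horizon_top_cm = df$horizon_top_cm,
                horizon_bottom_cm = df$horizon_bottom_cm),
      FUN = mean)
    names(agg)[names(agg) == "x"] <- "value"
    agg
  }
  e <- cellify(pair$early)
  l <- cellify(pair$late)
  key <- function(df) paste(df$site, df$distance_cm, df$horizon_top_cm,
                            df$horizon_bottom_cm, sep = "|")
  ke <- key(e); kl <- key(l)
  off <- c(setdiff(ke, kl), setdiff(kl, ke))
  if (length(off)) {
    abort2(paste0("unmatched survey cells (site|distance|top|bottom): ",
                  paste(off, collapse = "; ")), "alignment_error")
  }
  m <- match(ke, kl)
  out <- tibble::as_tibble(e[c("site", "distance_cm", "horizon_top_cm",
                               "horizon_bottom_cm")])
  out$early <- e$value
  out$late <- l$value[m]
  out$delta <- out$late - out$early
  out[order(out$site, out$distance_cm, out$horizon_top_cm), ]
}

#' Depth of the acidification front at one distance
#'
#' Given late-minus-early pH deltas ordered by depth, the front is the
#' boundary between the recovered upper profile (deltas `>= 0`) and the
#' still-acidifying lower profile (deltas `< 0`). A profile that is negative
#' throughout has its front at the surface (0 cm: no recovered layer); a
#' profile positive throughout has no front (`NA`). A sign pattern that is
#' not "non-negative prefix then negative suffix" is non-monotone and also
#' returns `NA`, flagged.
#'
#' @param top,bottom horizon depths, cm, ordered by `top`.
#' @param delta pH change (late minus early) per horizon.
#' @return list with `depth_cm` (numeric or `NA`) and `flag` (`"front"`,
#'   `"no-front"`, `"all-acidifying"` or `"non-monotone"`).
#' @export
acidification_front_depth <- function(top, bottom, delta) {
  if (is.unsorted(top, strictly = TRUE)) {
    abort2("horizons must be ordered by increasing top depth", "ordering_error")
  }
  neg <- delta < 0
  if (!any(neg)) return(list(depth_cm = NA_real_, flag = "no-front"))
  first_neg <- which(neg)[1]
  if (!all(neg[first_neg:length(neg)])) {
    return(list(depth_cm = NA_real_, flag = "non-monotone"))
  }
  if (first_neg == 1) return(list(depth_cm = top[1], flag = "all-acidifying"))
  list(depth_cm = top[first_neg], flag = "front")
}

#' Inverse-distance-weighted interpolation of grid pH
#'
#' Plain IDW with exponent `power`, all samples used (no search radius). A
#' query within 1e-9 cm of a sample returns that sample's value exactly; by
#' construction the surface never overshoots the sample value range.
#'
#' @param samples data frame with `x_cm`, `y_cm`, `ph_h2o`.
#' @param query data frame with `x_cm`, `y_cm`.
#' @param power IDW exponent, `> 0` (default 2).
#' @return `query` with an added `ph_h2o` column.
#' @export
idw_surface <- function(samples, query, power = 2) {
  if (!nrow(samples)) abort2("no samples to interpolate from", "empty_input")
  if (!is_number(power) || power <= 0) {
    abort2("`power` must be > 0", "invalid_input")
  }
  d2 <- outer(query$x_cm, samples$x_cm, `-`)^2 +
    outer(query$y_cm, samples$y_cm, `-`)^2
  d <- sqrt(d2)
  vals <- vapply(seq_len(nrow(query)), function(i) {
    di <- d[i, ]
    hit <- which(di < 1e-9)
    if (length(hit)) return(samples$ph_h2o[hit[1]])
    w <- di^(-power)
    sum(w * samples$ph_h2o) / sum(w)
  }, numeric(1))
  out <- tibble::as_tibble(query[c("x_cm", "y_cm")])
  out$ph_h2o <- vals
  out
}

#' Store table per distance, horizon and survey year
#'
#' Convenience wrapper: computes [element_store()] row-wise for a whole soil
#' table (replicates averaged within cells) and, per distance, the profile
#' totals.
#'
#' @param soil data frame in the soil-table dialect.
#' @param elements concentration columns to convert (default as in
#'   [profile_store()]).
#' @return list with `by_horizon` (store per site x year x distance x
#'   horizon x element) and `profile` (store summed over horizons).
#' @export
store_table <- function(soil, elements = NULL) {
  if (is.null(elements)) {
    elements <- intersect(
      c("ca_exch_mg_g", "mg_exch_mg_g", "c_mg_g", "n_mg_g", "s_mg_g"),
      names(soil))
  }
  sf <- if ("stone_fraction" %in% names(soil)) soil$stone_fraction else 0
  long <- do.call(rbind, lapply(elements, function(el) {
    tibble::tibble(
      site = soil$site, survey_year = soil$survey_year,
      distance_cm = soil$distance_cm, horizon_top_cm = soil$horizon_top_cm,
      horizon_bottom_cm = soil$horizon_bottom_cm, element = el,
      store_t_ha = element_store(soil[[el]], soil$bulk_density_g_cm3,
                                 soil$horizon_top_cm, soil$horizon_bottom_cm,
                                 sf))
  }))
  by_h <- stats::aggregate(
    store_t_ha ~ site + survey_year + distance_cm + horizon_top_cm +
      horizon_bottom_cm + element, data = long, FUN = mean)
  prof <- stats::aggregate(
    store_t_ha ~ site + survey_year + distance_cm + element,
    data = by_h, FUN = sum)
  list(by_horizon = tibble::as_tibble(by_h), profile = tibble::as_tibble(prof))
}
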