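# Seeded synthetic soil surveys, pH grids and deposition histories with the
# gradient structure the downstream analyses assume:
#   * 1983 topsoil pH up to three units lower at the stem than at 3 m,
#   * a flattened / inverted 2010 topsoil gradient (recovery near the stem),
#   * 2010 deep-horizon pH below 1983 values (the acidification front moved
#     down, deeper near the stem),
#   * exchangeable Ca/Mg stores increasing downhill, depletion concentrated
#     in the deep soil near the stem,
#   * total-S profile stores flat across distances, 0.7-1.0 t/ha.
# All values are fixtures for testing the method, not site reconstructions.

#' Configuration of the synthetic soil survey generator
#'
#' Defaults encode the qualitative micro-spatial pattern a stemflow-affected
#' beech stand shows after three decades of declining sulfur deposition.
#' Distances/horizons default to the canonical design. pH expectations vary
#' with distance along a saturating (log-distance) profile between the stem
#' anchor (at the innermost downhill distance) and the far anchor (at the
#' outermost distance); uphill samples follow their absolute distance.
#'
#' @param seed integer RNG seed; identical seed and config give
#'   byte-identical surveys.
#' @param distances signed sampling distances, cm.
#' @param horizons data frame with `top`, `bottom` (cm).
#' @param sites site identifiers (default three synthetic sites).
#' @param ph_stem_1983,ph_far_1983 1983 topsoil pH anchors (defaults 3.5 and
#'   6.5: a 3-unit gradient).
#' @param ph_stem_2010_top,ph_far_2010_top 2010 topsoil anchors (defaults
#'   5.5 and 5.0: gradient flattened and inverted).
#' @param deep_acidification_shift pH change applied to 2010 horizons below
#'   the local acidification front (default -0.4).
#' @param ca_far_store,mg_far_store whole-profile exchangeable-cation stores
#'   at the far distance, t ha^-1 (defaults 8 and 1.5; fixtures).
#' @param ca_stem_depletion fraction of the far store lost at the stem
#'   (default 0.6), applied with increasing weight towards the deep soil.
#' @param s_profile_target whole-profile total-S store at every distance,
#'   t ha^-1, must lie in `[0.7, 1.0]` (default 0.85).
#' @param c_profile_store,n_profile_store whole-profile C and N stores,
#'   t ha^-1 (defaults 90 and 7; distance-flat).
#' @param noise_sd named numeric vector `c(ph = , conc_rel = , bd = )`:
#'   additive pH sd (pH units), relative concentration sd (fraction,
#'   multiplicative) and additive bulk-density sd (g cm^-3). A single 0
#'   disables all noise. Defaults `c(0.1, 0.05, 0.03)`.
#' @param replicates soil cores per site x distance x horizon (default 1).
#' @param profile_shape `"log"` (default, steep change near the stem) or
#'   `"linear"` distance response.
#' @return a `synthetic_survey_config` list.
#' @export
synthetic_survey_config <- function(seed = 1L,
                                    distances = canonical_distances(),
                                    horizons = canonical_horizons(),
                                    sites = c("site_1", "site_2", "site_3"),
                                    ph_stem_1983 = 3.5, ph_far_1983 = 6.5,
                                    ph_stem_2010_top = 5.5,
                                    ph_far_2010_top = 5.0,
                                    deep_acidification_shift = -0.4,
                                    ca_far_store = 8, mg_far_store = 1.5,
                                    ca_stem_depletion = 0.6,
                                    s_profile_target = 0.85,
                                    c_profile_store = 90, n_profile_store = 7,
                                    noise_sd = c(ph = 0.1, conc_rel = 0.05,
                                                 bd = 0.03),
                                    replicates = 1L,
                                    profile_shape = c("log", "linear")) {
  profile_shape <- match.arg(profile_shape)
  if (ph_far_1983 - ph_stem_1983 > 3 + 1e-12) {
    abort2("`ph_far_1983 - ph_stem_1983` must not exceed 3 pH units",
           "config_error")
  }
  if (s_profile_target < 0.7 || s_profile_target > 1.0) {
    abort2("`s_profile_target` must lie in [0.7, 1.0] t/ha", "config_error")
  }
  if (ca_stem_depletion < 0 || ca_stem_depletion >= 1) {
    abort2("`ca_stem_depletion` must lie in [0, 1)", "config_error")
  }
  noise_sd <- expand_noise_sd(noise_sd)
  if (any(noise_sd < 0)) abort2("`noise_sd` must be >= 0", "config_error")
  if (!is_number(replicates) || replicates < 1) {
    abort2("`replicates` must be >= 1", "config_error")
  }
  if (sum(distances > 0) < 2) {
    abort2("need at least two downhill `distances`", "config_error")
  }
  structure(
    list(seed = as.integer(seed), distances = distances, horizons = horizons,
         sites = sites, ph_stem_1983 = ph_stem_1983,
         ph_far_1983 = ph_far_1983, ph_stem_2010_top = ph_stem_2010_top,
         ph_far_2010_top = ph_far_2010_top,
         deep_acidification_shift = deep_acidification_shift,
         ca_far_store = ca_far_store, mg_far_store = mg_far_store,
         ca_stem_depletion = ca_stem_depletion,
         s_profile_target = s_profile_target,
         c_profile_store = c_profile_store,
         n_profile_store = n_profile_store,
         noise_sd = noise_sd, replicates = as.integer(replicates),
         profile_shape = profile_shape),
    class = "synthetic_survey_config"
  )
}

expand_noise_sd <- function(noise_sd) {
  full <- c(ph = 0, conc_rel = 0, bd = 0)
  if (length(noise_sd) == 1L && is.null(names(noise_sd))) {
    full[] <- noise_sd
  } else {
    bad <- setdiff(names(noise_sd), names(full))
    if (length(bad)) {
      abort2(paste0("unknown noise_sd component(s): ",
                    paste(bad, collapse = ", ")), "config_error")
    }
    full[names(noise_sd)] <- noise_sd
  }
  full
}

# 0 at the innermost downhill distance, 1 at the outermost; |d| clamped.
distance_weight <- function(config, distance) {
  down <- sort(config$distances[config$distances > 0])
  dmin <- down[1]; dmax <- down[length(down)]
  d <- pmin(pmax(abs(distance), dmin), dmax)
  if (config$profile_shape == "log") {
    log(d / dmin) / log(dmax / dmin)
  } else {
    (d - dmin) / (dmax - dmin)
  }
}

#' Noiseless topsoil pH expectation
#'
#' The deterministic topsoil (shallowest horizon) pH profile the generator
#' is built around, for either survey year.
#'
#' @param config a [synthetic_survey_config()].
#' @param distance signed distance(s), cm (or radial distance for grids).
#' @param year 1983 or 2010.
#' @return pH value(s).
#' @export
expected_topsoil_ph <- function(config, distance, year) {
  w <- distance_weight(config, distance)
  if (year == 1983) {
    config$ph_stem_1983 + (config$ph_far_1983 - config$ph_stem_1983) * w
  } else {
    config$ph_stem_2010_top +
      (config$ph_far_2010_top - config$ph_stem_2010_top) * w
  }
}

# Acidification-front bottom depth (cm) at one distance: scales with the
# local topsoil recovery (2010 minus 1983) relative to the stem's, so the
# front sits deepest at the stem and at the surface where the topsoil still
# acidifies. Returns 0 when the topsoil delta is <= 0.
front_depth <- function(config, distance) {
  delta <- expected_topsoil_ph(config, distance, 2010) -
    expected_topsoil_ph(config, distance, 1983)
  down <- sort(config$distances[config$distances > 0])
  max_delta <- expected_topsoil_ph(config, down[1], 2010) -
    expected_topsoil_ph(config, down[1], 1983)
  nh <- nrow(config$horizons)
  vapply(seq_along(delta), function(i) {
    if (delta[i] <= 0 || max_delta <= 0) return(0)
    k <- min(nh - 1L, max(1L, ceiling((nh - 1L) * delta[i] / max_delta)))
    config$horizons$bottom[k]
  }, numeric(1))
}

# Noiseless pH for every horizon at one distance and year.
expected_profile_ph <- function(config, distance, year) {
  h <- config$horizons
  ph83 <- expected_topsoil_ph(config, distance, 1983)
  if (year == 1983) return(rep(ph83, nrow(h)))
  mid <- (h$top + h$bottom) / 2
  f <- front_depth(config, distance)
  delta_top <- expected_topsoil_ph(config, distance, 2010) - ph83
  ph <- ph83 + config$deep_acidification_shift  # below-front default
  ph <- rep(ph, nrow(h))
  above <- h$bottom <= f & f > 0
  ph[above] <- ph83 + delta_top * (1 - mid[above] / f)
  ph[1] <- expected_topsoil_ph(config, distance, 2010)
  ph
}

# Horizon allocation share of a whole-profile store: thickness-weighted,
# tapering with depth (topsoil-enriched).
horizon_shares <- function(horizons) {
  mid <- (horizons$top + horizons$bottom) / 2
  w <- (horizons$bottom - horizons$top) / (1 + mid / 20)
  w / sum(w)
}

# Depletion weight: depletion acts hardest on the deepest horizon.
depletion_weights <- function(horizons) {
  mid <- (horizons$top + horizons$bottom) / 2
  0.4 + 0.6 * mid / max(mid)
}

default_bulk_density <- function(horizons) {
  mid <- (horizons$top + horizons$bottom) / 2
  pmin(1.5, 0.8 + 0.016 * mid)
}

# Noiseless concentrations (mg/g) for all elements at one distance.
expected_concentrations <- function(config, distance) {
  h <- config$horizons
  thick <- h$bottom - h$top
  bd <- default_bulk_density(h)
  share <- horizon_shares(h)
  dw <- depletion_weights(h)
  w <- distance_weight(config, distance)
  cation_mult <- 1 - config$ca_stem_depletion * dw * (1 - w)
  to_conc <- function(store_h) store_h / (bd * thick * 0.1)
  list(
    ca_exch_mg_g = to_conc(share * config$ca_far_store * cation_mult),
    mg_exch_mg_g = to_conc(share * config$mg_far_store * cation_mult),
    c_mg_g = to_conc(share * config$c_profile_store),
    n_mg_g = to_conc(share * config$n_profile_store),
    s_mg_g = to_conc(share * config$s_profile_target),
    bulk_density_g_cm3 = bd
  )
}

#' Generate an aligned pair of synthetic soil surveys
#'
#' Produces 1983-type and 2010-type surveys over all sites x distances x
#' horizons x replicates, with the configured noiseless expectations plus
#' independent Gaussian noise (no spatial autocorrelation). Values are
#' clipped into the physical ranges pH (2, 9), bulk density (0.1, 2.5) and
#' concentration >= 0, with a message when clipping occurs.
#'
#' @param config a [synthetic_survey_config()].
#' @return a `survey_pair`: list with tibbles `early` (1983) and `late`
#'   (2010) in the soil-table dialect, plus `config`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_survey_config"))
  one_year <- function(year) {
    grid <- expand.grid(
      replicate = seq_len(config$replicates),
      horizon = seq_len(nrow(config$horizons)),
      distance_cm = config$distances,
      site = config$sites,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    h <- config$horizons[grid$horizon, ]
    per_dist_ph <- lapply(config$distances, expected_profile_ph,
                          config = config, year = year)
    names(per_dist_ph) <- as.character(config$distances)
    per_dist_cc <- lapply(config$distances, expected_concentrations,
                          config = config)
    names(per_dist_cc) <- as.character(config$distances)
    dchr <- as.character(grid$distance_cm)
    pick <- function(field) {
      vapply(seq_len(nrow(grid)), function(i) {
        per_dist_cc[[dchr[i]]][[field]][grid$horizon[i]]
      }, numeric(1))
    }
    tibble::tibble(
      site = grid$site,
      survey_year = year,
      distance_cm = grid$distance_cm,
      replicate = grid$replicate,
      horizon_top_cm = h$top,
      horizon_bottom_cm = h$bottom,
      ph_h2o = vapply(seq_len(nrow(grid)), function(i) {
        per_dist_ph[[dchr[i]]][grid$horizon[i]]
      }, numeric(1)),
      ca_exch_mg_g = pick("ca_exch_mg_g"),
      mg_exch_mg_g = pick("mg_exch_mg_g"),
      c_mg_g = pick("c_mg_g"),
      n_mg_g = pick("n_mg_g"),
      s_mg_g = pick("s_mg_g"),
      bulk_density_g_cm3 = pick("bulk_density_g_cm3")
    )
  }
  add_noise <- function(df) {
    sd <- config$noise_sd
    n <- nrow(df)
    if (sd["ph"] > 0) df$ph_h2o <- df$ph_h2o + stats::rnorm(n, 0, sd["ph"])
    if (sd["conc_rel"] > 0) {
      for (el in c("ca_exch_mg_g", "mg_exch_mg_g", "c_mg_g", "n_mg_g",
                   "s_mg_g")) {
        df[[el]] <- df[[el]] * stats::rnorm(n, 1, sd["conc_rel"])
      }
    }
    if (sd["bd"] > 0) {
      df$bulk_density_g_cm3 <- df$bulk_density_g_cm3 + stats::rnorm(n, 0, sd["bd"])
    }
    clip_range <- function(x, lo, hi, what) {
      bad <- x < lo | x > hi
      if (any(bad)) {
        message(sprintf("generate_survey: clipped %d %s value(s)",
                        sum(bad), what))
        x <- pmin(pmax(x, lo), hi)
      }
      x
    }
    df$ph_h2o <- clip_range(df$ph_h2o, 2 + 1e-6, 9 - 1e-6, "pH")
    df$bulk_density_g_cm3 <- clip_range(df$bulk_density_g_cm3,
                                        0.1 + 1e-6, 2.5 - 1e-6, "bulk density")
    for (el in c("ca_exch_mg_g", "mg_exch_mg_g", "c_mg_g", "n_mg_g", "s_mg_g")) {
      df[[el]] <- clip_range(df[[el]], 0, Inf, el)
    }
    df
  }
  pair <- withr::with_seed(config$seed, {
    list(early = add_noise(one_year(1983L)), late = add_noise(one_year(2010L)))
  })
  structure(list(early = pair$early, late = pair$late, config = config),
            class = "survey_pair")
}

#' Generate a synthetic topsoil pH grid around the stem
#'
#' A square sampling grid centred on the stem at (0, 0); the noiseless
#' expectation is radially symmetric and follows the survey's topsoil pH
#' profile for the requested year.
#'
#' @param config a [synthetic_survey_config()].
#' @param year 1983 or 2010.
#' @param grid_extent half-width of the grid, cm (default 300).
#' @param spacing grid spacing, cm (must be positive and at most
#'   `grid_extent`).
#' @return tibble with `x_cm`, `y_cm`, `ph_h2o`.
#' @export
generate_grid <- function(config, year = 2010, grid_extent = 300,
                          spacing = 50) {
  if (!is_number(spacing) || spacing <= 0 || grid_extent < spacing) {
    abort2("need spacing > 0 and grid_extent >= spacing", "config_error")
  }
  ax <- seq(-grid_extent, grid_extent, by = spacing)
  g <- expand.grid(x_cm = ax, y_cm = ax, KEEP.OUT.ATTRS = FALSE)
  r <- sqrt(g$x_cm^2 + g$y_cm^2)
  ph <- expected_topsoil_ph(config, r, year)
  withr::with_seed(config$seed, {
    if (config$noise_sd["ph"] > 0) {
      ph <- ph + stats::rnorm(length(ph), 0, config$noise_sd["ph"])
    }
  })
  ph <- pmin(pmax(ph, 2 + 1e-6), 9 - 1e-6)
  tibble::tibble(x_cm = g$x_cm, y_cm = g$y_cm, ph_h2o = ph)
}

#' Configuration for synthetic deposition histories
#'
#' @param seed integer RNG seed.
#' @param noise_sd standard deviation of independent annual Gaussian
#'   perturbations of both flux series, kg S ha^-1 yr^-1 (0 = exact
#'   trajectories).
#' @return a `synthetic_deposition_config` list.
#' @export
synthetic_deposition_config <- function(seed = 1L, noise_sd = 0) {
  if (!is_number(noise_sd) || noise_sd < 0) {
    abort2("`noise_sd` must be >= 0", "config_error")
  }
  structure(list(seed = as.integer(seed), noise_sd = noise_sd),
            class = "synthetic_deposition_config")
}

#' Generate a (possibly noisy) annual deposition/seepage history
#'
#' Noiseless mode returns exactly the deterministic trajectories of
#' [build_trajectory()]; noisy mode perturbs each annual value with
#' independent Gaussian noise, floored at 0.
#'
#' @param config a [synthetic_deposition_config()].
#' @param scenario a [deposition_scenario()].
#' @return trajectory tibble (`year`, `input_s`, `output_s`) with the
#'   scenario attached, as from [build_trajectory()].
#' @export
generate_deposition_history <- function(config, scenario) {
  stopifnot(inherits(config, "synthetic_deposition_config"))
  traj <- build_trajectory(scenario)
  if (config$noise_sd > 0) {
    traj <- withr::with_seed(config$seed, {
      n <- nrow(traj)
      traj$input_s <- pmax(0, traj$input_s + stats::rnorm(n, 0, config$noise_sd))
      traj$output_s <- pmax(0, traj$output_s + stats::rnorm(n, 0, config$noise_sd))
      traj
    })
    attr(traj, "scenario") <- scenario
  }
  traj
}
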