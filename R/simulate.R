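#' Generate a synthetic small-area geography
#'
#' Builds a Voronoi tessellation of the unit square from seed points whose
#' density is highest at the map centre, so peripheral polygons come out
#' systematically larger than central ones -- the urban/rural size gradient
#' of real census data zones. Zone diabetic populations are drawn from a
#' lognormal with the configured mean and coefficient of variation.
#'
#' Deterministic for a fixed `config$seed`: two calls with the same config
#' return bit-identical coordinates and populations.
#'
#' @param config a [sim_config()].
#' @return A `zone_set` (quintiles unassigned).
#' @export
generate_geography <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_zones
  with_seed(config$seed, {
    pts <- sample_center_weighted(n)
    tess <- deldir::deldir(pts[, 1], pts[, 2], rw = c(0, 1, 0, 1))
    tiles <- deldir::tile.list(tess)
    if (length(tiles) != n) {
      stop("tessellation lost ", n - length(tiles), " duplicate seed points")
    }
    geometry <- lapply(tiles, function(tl) {
      ring <- cbind(tl$x, tl$y)
      if (ring_signed_area(ring) < 0) ring <- ring[rev(seq_len(nrow(ring))), ]
      list(ring)
    })
    cv <- config$population_cv
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(config$mean_population) - sdlog^2 / 2
    pop <- pmax(1L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
    zone_set(sprintf("DZ%04d", seq_len(n)), geometry, population = pop)
  })
}

# rejection-sample n points in the unit square with density ~4x higher at
# the centre than at the corners (Gaussian bump over a uniform floor)
sample_center_weighted <- function(n, sigma = 0.2, floor_p = 0.25) {
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 32L)
    cand <- cbind(stats::runif(m), stats::runif(m))
    d2 <- (cand[, 1] - 0.5)^2 + (cand[, 2] - 0.5)^2
    keep <- stats::runif(m) < floor_p + (1 - floor_p) * exp(-d2 / (2 * sigma^2))
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Assign a spatially autocorrelated deprivation surface
#'
#' Draws an i.i.d. Gaussian score at each zone centroid and smooths it with a
#' Gaussian kernel of range `smoothness` (in map-width units), giving a cheap
#' approximation to a Gaussian random field with tunable spatial correlation.
#' Scores are ranked highest-to-lowest and cut into five rank quintiles of
#' equal size (within one zone), quintile 1 = most deprived = highest score.
#'
#' @param zones a `zone_set`.
#' @param smoothness non-negative kernel range; 0 means no smoothing (labels
#'   spatially independent).
#' @param seed integer seed.
#' @return The `zone_set` with `quintile` filled in.
#' @export
assign_deprivation <- function(zones, smoothness, seed) {
  stopifnot(inherits(zones, "zone_set"))
  if (!is.numeric(smoothness) || smoothness < 0) {
    stop("invalid config: smoothness must be >= 0")
  }
  n <- n_zones(zones)
  score <- with_seed(seed, {
    eps <- stats::rnorm(n)
    if (smoothness == 0) {
      eps
    } else {
      cen <- zone_centroids(zones)
      d2 <- as.matrix(stats::dist(cen))^2
      k <- exp(-d2 / (2 * smoothness^2))
      as.vector(k %*% eps) / rowSums(k)
    }
  })
  ord <- order(score, decreasing = TRUE)          # rank 1 = most deprived
  sizes <- rep(n %/% 5L, 5L)
  extra <- n %% 5L
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  q <- integer(n)
  q[ord] <- rep(1:5, times = sizes)
  zones$quintile <- q
  zones
}

#' Build the per-zone outcome risk surface
#'
#' Per-zone event probability for each outcome = baseline rate x the zone's
#' deprivation-quintile relative risk x the product of any planted-cluster
#' multipliers covering the zone, capped at 0.99. A planted cluster covers
#' its centre zone and every zone within `radius` queen-contiguity hops of
#' it; this planted truth is what cluster-recovery tests are scored against.
#'
#' @param zones a `zone_set` with quintiles assigned.
#' @param config a [sim_config()] (quintile risks, planted clusters, bases).
#' @return An object of class `risk_surface`: per-zone probabilities for
#'   `dfu`, `lea` and `death` (death conditional on DFU/LEA history), plus
#'   the planted-cluster membership used.
#' @export
build_risk_surface <- function(zones, config) {
  stopifnot(inherits(zones, "zone_set"), inherits(config, "sim_config"))
  if (anyNA(zones$quintile)) stop("quintiles must be assigned before building a risk surface")
  n <- n_zones(zones)
  mult <- config$quintile_relative_risks[zones$quintile]
  planted <- c(config$planted_hot, config$planted_cold)
  covered <- list()
  if (length(planted) > 0) {
    qw <- queen_contiguity(zones)
    for (p in planted) {
      ci <- resolve_zone(p$center, zones)
      members <- hop_neighborhood(qw, ci, p$radius)
      mult[members] <- mult[members] * p$rr
      covered[[length(covered) + 1L]] <-
        list(center = ci, radius = p$radius, rr = p$rr, members = members)
    }
  }
  rates <- lapply(config$base_rates[c("dfu", "lea", "death")],
                  function(b) pmin(b * mult, 0.99))
  structure(
    list(zone_id = zones$zone_id, dfu = rates$dfu, lea = rates$lea,
         death = rates$death, planted = covered),
    class = "risk_surface")
}

# map a cluster centre given as index or zone id to a row index
resolve_zone <- function(center, zones) {
  if (is.character(center)) {
    i <- match(center, zones$zone_id)
  } else {
    i <- as.integer(center)
    if (!is.na(i) && (i < 1 || i > n_zones(zones))) i <- NA_integer_
  }
  if (is.na(i)) stop("unknown cluster center zone: ", center)
  i
}

# zones within `hops` steps of `start` in a weights graph (BFS; includes start)
hop_neighborhood <- function(w, start, hops) {
  seen <- start
  frontier <- start
  h <- 0L
  while (h < hops && length(frontier) > 0) {
    frontier <- setdiff(unique(unlist(w$nb[frontier])), seen)
    seen <- c(seen, frontier)
    h <- h + 1L
  }
  sort(seen)
}

#' Simulate an individual-level diabetes cohort
#'
#' Draws `population`-many people per zone. Foot-ulcer (DFU) and amputation
#' (LEA) events are Bernoulli with the zone's risk-surface probabilities and
#' dated uniformly inside the analysis window; among amputation cases a
#' fraction `dfu_before_lea` (default 0.8) have a DFU on record on or before
#' the amputation date, replacing the independent DFU draw for those people.
#' Death is only generated for people with a DFU or LEA history (the study's
#' mortality outcome is death preceded by one of them) and is dated after
#' their last event. Event dates run from 1 January of the window's start
#' year to 7 November of its end year, mirroring a November registry
#' extraction.
#'
#' @param zones a `zone_set`.
#' @param surface a `risk_surface` defined on the same zones.
#' @param config a [sim_config()]; `config$seed` makes the draw deterministic.
#' @return A data frame of person records: `person_id`, `zone_id`,
#'   `entry_date`, `dfu_date`, `lea_date`, `lea_level`, `death_date`
#'   (`Date` columns, `NA` = no event).
#' @export
simulate_cohort <- function(zones, surface, config) {
  stopifnot(inherits(zones, "zone_set"), inherits(surface, "risk_surface"),
            inherits(config, "sim_config"))
  if (!identical(surface$zone_id, zones$zone_id)) {
    stop("risk surface is not defined on these zones")
  }
  start <- as.Date(sprintf("%d-01-01", config$window[1]))
  end <- as.Date(sprintf("%d-11-07", config$window[2]))
  zi <- rep(seq_len(n_zones(zones)), times = zones$population)
  np <- length(zi)
  with_seed(config$seed + 2L, {
    u_entry <- stats::runif(np)
    lea <- stats::runif(np) < surface$lea[zi]
    prior <- stats::runif(np) < config$dfu_before_lea
    dfu_raw <- stats::runif(np) < surface$dfu[zi]
    u_lea <- stats::runif(np)
    u_dfu <- stats::runif(np)
    major <- stats::runif(np) < 0.3
    died <- stats::runif(np) < surface$death[zi]
    u_death <- stats::runif(np)

    span <- as.integer(end - start)
    entry <- start + as.integer(floor(u_entry * (span + 1)))
    dfu <- ifelse(lea, prior, dfu_raw)

    lea_date <- rep(as.Date(NA), np)
    lea_date[lea] <- entry[lea] +
      as.integer(floor(u_lea[lea] * (as.integer(end - entry[lea]) + 1)))
    dfu_date <- rep(as.Date(NA), np)
    coupled <- lea & prior
    dfu_date[coupled] <- entry[coupled] +
      as.integer(floor(u_dfu[coupled] * (as.integer(lea_date[coupled] - entry[coupled]) + 1)))
    free <- dfu & !lea
    dfu_date[free] <- entry[free] +
      as.integer(floor(u_dfu[free] * (as.integer(end - entry[free]) + 1)))

    lea_level <- rep(NA_character_, np)
    lea_level[lea] <- ifelse(major[lea], "major", "minor")

    hist <- dfu | lea
    died <- died & hist
    last_ev <- pmax(dfu_date, lea_date, na.rm = TRUE)
    death_date <- rep(as.Date(NA), np)
    death_date[died] <- last_ev[died] +
      as.integer(floor(u_death[died] * (as.integer(end - last_ev[died]) + 1)))

    data.frame(
      person_id = sprintf("P%07d", seq_len(np)),
      zone_id = zones$zone_id[zi],
      entry_date = entry,
      dfu_date = dfu_date,
      lea_date = lea_date,
      lea_level = lea_level,
      death_date = death_date,
      stringsAsFactors = FALSE)
  })
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper: geography, deprivation quintiles, risk surface and
#' cohort in one call, all driven by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `zones`, `surface` and `cohort`.
#' @export
simulate_study <- function(config) {
  zones <- generate_geography(config)
  zones <- assign_deprivation(zones, config$deprivation_smoothness,
                              seed = config$seed + 1L)
  surface <- build_risk_surface(zones, config)
  cohort <- simulate_cohort(zones, surface, config)
  list(zones = zones, surface = surface, cohort = cohort)
}
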