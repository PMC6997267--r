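#' Simulation configuration for the synthetic geography and cohort
#'
#' Bundles every knob of the synthetic stand-in for a linked diabetes
#' register on a small-area geography: the number of data zones and their
#' mean diabetic population, the spatial range of the deprivation surface,
#' per-quintile relative risks, planted excess-risk clusters, and baseline
#' outcome rates. Defaults reproduce the study conditions the pipeline is
#' validated under: 200 zones (a scaled-down health board; the real one has
#' 1,460), mean population 760, a roughly four-fold risk gradient from the
#' most to the least deprived quintile, and baseline rates of 4.6% for foot
#' ulceration (DFU), 1.3% for lower-extremity amputation (LEA) and 25%
#' mortality conditional on a DFU/LEA history.
#'
#' @param n_zones number of data zones (>= 10).
#' @param mean_population mean diabetic population per zone (> 0).
#' @param seed integer seed; every stochastic step is deterministic given it.
#' @param deprivation_smoothness spatial correlation range of the latent
#'   deprivation score, as a fraction of the unit-square map width; 0 gives a
#'   spatially independent surface.
#' @param quintile_relative_risks five positive risk multipliers, quintile 1
#'   (most deprived) first.
#' @param planted_hot,planted_cold lists of planted clusters, each
#'   `list(center = <zone index>, radius = <neighbour hops>, rr = <multiplier>)`;
#'   coverage is by queen-contiguity hops from the centre zone.
#' @param base_rates named list of baseline probabilities: `dfu`, `lea`, and
#'   `death` (conditional on a prior DFU or LEA).
#' @param window analysis window as `c(start_year, end_year)`; event dates are
#'   drawn inside it.
#' @param population_cv coefficient of variation of the lognormal zone
#'   population distribution.
#' @param dfu_before_lea probability that an amputation case has an earlier or
#'   same-day foot ulcer on record (around 80% in routine data).
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_zones = 200,
                       mean_population = 760,
                       seed = 1L,
                       deprivation_smoothness = 0.15,
                       quintile_relative_risks = c(2.5, 1.5, 1.0, 0.8, 0.6),
                       planted_hot = list(),
                       planted_cold = list(),
                       base_rates = list(dfu = 0.046, lea = 0.013, death = 0.25),
                       window = c(2002L, 2016L),
                       population_cv = 0.3,
                       dfu_before_lea = 0.8) {
  if (!is.numeric(n_zones) || length(n_zones) != 1 || n_zones < 10) {
    stop("invalid config: n_zones must be a single number >= 10")
  }
  if (!is.numeric(mean_population) || mean_population <= 0) {
    stop("invalid config: mean_population must be > 0")
  }
  if (!is.numeric(deprivation_smoothness) || deprivation_smoothness < 0) {
    stop("invalid config: deprivation_smoothness must be >= 0")
  }
  if (length(quintile_relative_risks) != 5 || any(quintile_relative_risks <= 0)) {
    stop("invalid config: quintile_relative_risks must be 5 positive multipliers")
  }
  for (nm in c("dfu", "lea", "death")) {
    if (is.null(base_rates[[nm]]) || base_rates[[nm]] < 0 || base_rates[[nm]] >= 1) {
      stop("invalid config: base_rates$", nm, " must be a probability in [0, 1)")
    }
  }
  check_planted <- function(pl, what) {
    for (p in pl) {
      if (is.null(p$center) || is.null(p$radius) || is.null(p$rr) ||
          p$radius < 0 || p$rr <= 0) {
        stop("invalid config: each ", what,
             " cluster needs center, radius >= 0 and rr > 0")
      }
    }
  }
  check_planted(planted_hot, "planted_hot")
  check_planted(planted_cold, "planted_cold")
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("invalid config: window must be c(start_year, end_year), start < end")
  }
  if (population_cv <= 0) stop("invalid config: population_cv must be > 0")
  if (dfu_before_lea < 0 || dfu_before_lea > 1) {
    stop("invalid config: dfu_before_lea must be a probability")
  }
  structure(
    list(n_zones = as.integer(n_zones), mean_population = mean_population,
         seed = as.integer(seed),
         deprivation_smoothness = deprivation_smoothness,
         quintile_relative_risks = as.numeric(quintile_relative_risks),
         planted_hot = planted_hot, planted_cold = planted_cold,
         base_rates = base_rates, window = as.integer(window),
         population_cv = population_cv, dfu_before_lea = dfu_before_lea),
    class = "sim_config")
}

# run `expr` under a fixed seed, restoring the caller's RNG state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
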