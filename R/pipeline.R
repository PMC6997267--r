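#' Run the full small-area hot-spot workflow on a synthetic study
#'
#' Chains every stage of the analysis: simulate geography + deprivation +
#' cohort, build the spatial weights, then for each outcome aggregate
#' per-zone counts, compute rates, run the Gi* hot-spot classification, and
#' test hot- and cold-spot concentration across deprivation quintiles with
#' one-sample chi-square tests. Optionally writes every artefact (GeoJSON,
#' cohort CSV, rate/spot CSVs, association JSON, SVG maps) to a directory.
#'
#' @param config a [sim_config()].
#' @param outcomes outcomes to analyse (default: DFU, LEA and the two
#'   mortality outcomes, as in the published analysis).
#' @param scheme weights scheme (`"hybrid"` default).
#' @param expected expected-proportion model for the chi-square tests
#'   (`"zones"` or `"uniform"`).
#' @param out_dir if non-`NULL`, artefacts are written here.
#' @param render also write SVG maps (only with `out_dir`).
#' @return list with `zones`, `surface`, `cohort`, `weights`, and per
#'   outcome: `table`, `rates`, `spots`, `summary`, `chi2_hot`, `chi2_cold`
#'   (`NULL` where a direction has no spots).
#' @export
run_hotspot_pipeline <- function(config = sim_config(),
                                 outcomes = c("dfu", "lea", "death_after_dfu",
                                              "death_after_lea"),
                                 scheme = "hybrid",
                                 expected = "zones",
                                 out_dir = NULL, render = FALSE) {
  study <- simulate_study(config)
  zones <- study$zones
  weights <- zone_weights_for(zones, scheme)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_zones(zones, file.path(out_dir, "zones.geojson"))
    write_cohort(study$cohort, file.path(out_dir, "cohort.csv"))
    write_weights(weights, file.path(out_dir, "weights.csv"),
                  file.path(out_dir, "weights_summary.json"))
  }
  res <- list(zones = zones, surface = study$surface, cohort = study$cohort,
              weights = weights, outcomes = list())
  for (oc in outcomes) {
    tab <- aggregate_outcome(study$cohort, zones, oc)
    rates <- zone_rates(tab)
    spots <- hotspot_analysis(rates, weights)
    summ <- spot_summary(spots)
    chi_for <- function(which) {
      qc <- quintile_counts(spots, zones, which, expected = expected)
      if (sum(qc$counts) == 0) NULL else chi_square_one_sample(qc)
    }
    entry <- list(table = tab, rates = rates, spots = spots, summary = summ,
                  chi2_hot = chi_for("hot"), chi2_cold = chi_for("cold"))
    if (!is.null(out_dir)) {
      write_rates(rates, file.path(out_dir, paste0("rates_", oc, ".csv")))
      write_spots(spots, file.path(out_dir, paste0("spots_", oc, ".csv")),
                  rates = rates)
      assoc <- Filter(Negate(is.null),
                      list(hot = entry$chi2_hot, cold = entry$chi2_cold))
      if (length(assoc)) {
        write_association(assoc, file.path(out_dir, paste0("assoc_", oc, ".json")))
      }
      if (render) {
        render_map(zones, spots, file.path(out_dir, paste0("map_", oc, ".svg")))
      }
    }
    res$outcomes[[oc]] <- entry
  }
  res
}
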