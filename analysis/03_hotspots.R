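#!/usr/bin/env Rscript
# Stage 3 -- spatial weights and Gi* hot/cold-spot classification. The
# spatial model is the hybrid scheme: an auto-thresholded fixed distance
# band on zone centroids (counterbalancing unequal polygon sizes) corrected
# by queen contiguity so every pair of touching zones is a neighbour pair.
# Zones are binned at two-tailed 90/95/99% confidence.
#
# Writes spots_<outcome>.csv, map_<outcome>.svg, weights.csv + summary.

library(geofoot)

zones <- read_zones("results/zones.geojson")
cohort <- read_cohort("results/cohort.csv")

w <- zone_weights_for(zones, "hybrid")
print(w)
write_weights(w, "results/weights.csv", "results/weights_summary.json")
cat(sprintf("auto distance-band threshold: %.4f map units\n", w$threshold))

for (oc in c("dfu", "lea", "death_after_dfu", "death_after_lea")) {
  rt <- zone_rates(aggregate_outcome(cohort, zones, oc))
  cl <- hotspot_analysis(rt, w)
  s <- spot_summary(cl)
  write_spots(cl, file.path("results", paste0("spots_", oc, ".csv")), rates = rt)
  render_map(zones, cl, file.path("results", paste0("map_", oc, ".svg")))
  cat(sprintf("%-22s hot %3d (%4.1f%%)  cold %3d (%4.1f%%)  of %d zones\n",
              oc, s$hot[["count"]], s$hot[["percent"]],
              s$cold[["count"]], s$cold[["percent"]], s$n))
}
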