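#!/usr/bin/env Rscript
# Stage 2 -- aggregate the cohort into per-zone numerators/denominators and
# compute crude rates for each outcome: DFU prevalence (2012-2016 screening
# window), LEA prevalence (2002-2016), and incidence of mortality preceded
# by DFU or LEA (per 10,000 per year over 14 years).
#
# Reads results/zones.geojson + results/cohort.csv; writes rates_<outcome>.csv.

library(geofoot)

zones <- read_zones("results/zones.geojson")
cohort <- read_cohort("results/cohort.csv")

for (oc in c("dfu", "lea", "death_after_dfu", "death_after_lea")) {
  tab <- aggregate_outcome(cohort, zones, oc)
  rt <- zone_rates(tab)
  write_rates(rt, file.path("results", paste0("rates_", oc, ".csv")))
  unit <- if (attr(rt, "kind") == "prevalence_percent") "%" else " per 10,000/yr"
  cat(sprintf("%-22s overall %5.1f%s | zone range %.1f-%.1f | %d low-confidence zones\n",
              oc, attr(rt, "overall"), unit,
              min(rt$rate, na.rm = TRUE), max(rt$rate, na.rm = TRUE),
              sum(rt$flag == "low_confidence")))
}
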