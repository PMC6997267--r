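#' Crude prevalence rate
#'
#' Unstandardised percentage of the at-risk population with the outcome:
#' `100 * numerator / denominator`. Published outputs round to one decimal
#' place; all internal statistics use the unrounded value.
#'
#' @param numerator,denominator non-negative counts (vectorised).
#' @return percentage(s) in \[0, 100\]; `NA` with a warning where the
#'   denominator is zero.
#' @export
prevalence_rate <- function(numerator, denominator) {
  if (any(numerator < 0 | denominator < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  if (any(numerator > denominator, na.rm = TRUE)) {
    stop("numerator exceeds denominator")
  }
  out <- 100 * numerator / denominator
  zero <- !is.na(denominator) & denominator == 0
  if (any(zero)) {
    warning(sum(zero), " zone(s) with zero denominator set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Incidence rate per 10,000 per year
#'
#' Closed-cohort person-time approximation: `10000 * events /
#' (population * years)`. The cohort is treated as fully observed over the
#' window, so person-time is population x window length.
#'
#' @param events non-negative event count(s).
#' @param population cohort size(s) at risk.
#' @param years positive window length in years.
#' @return rate(s) per 10,000 person-years; `NA` with a warning for zero
#'   population.
#' @export
incidence_rate <- function(events, population, years) {
  if (any(years <= 0)) stop("invalid config: years must be > 0")
  if (any(events < 0 | population < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  out <- 10000 * events / (population * years)
  zero <- !is.na(population) & population == 0
  if (any(zero)) {
    warning(sum(zero), " zone(s) with zero population set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Per-zone rates from an outcome table
#'
#' Applies the rate appropriate to the outcome zone-wise: prevalence percent
#' for `dfu` and `lea`, incidence per 10,000 per year (over the table's
#' window length) for the mortality outcomes. Zones with a zero denominator
#' are flagged `missing`; zones below `min_denominator` are flagged
#' `low_confidence` but still computed. The overall rate pools counts first
#' (`rate(sum num, sum den)`), which is not the mean of zone rates when zone
#' sizes differ.
#'
#' @param table an `outcome_table` from [aggregate_outcome()].
#' @param min_denominator zones below this denominator are flagged (default 5).
#' @return An object of class `rate_table`: data frame `zone_id`,
#'   `numerator`, `denominator`, `rate`, `flag` with attributes `kind`
#'   (`"prevalence_percent"` or `"incidence_per_10k_per_year"`),
#'   `window_years` and `overall`.
#' @export
zone_rates <- function(table, min_denominator = 5) {
  stopifnot(inherits(table, "outcome_table"))
  outcome <- attr(table, "outcome")
  window <- attr(table, "window")
  kind <- if (outcome %in% c("dfu", "lea")) "prevalence_percent"
          else "incidence_per_10k_per_year"
  num <- table$numerator; den <- table$denominator
  rate <- withCallingHandlers(
    if (kind == "prevalence_percent") prevalence_rate(num, den)
    else incidence_rate(num, den, window$years),
    warning = function(w) invokeRestart("muffleWarning"))
  overall <- if (kind == "prevalence_percent") {
    prevalence_rate(sum(num), sum(den))
  } else {
    incidence_rate(sum(num), sum(den), window$years)
  }
  flag <- ifelse(den == 0, "missing",
                 ifelse(den < min_denominator, "low_confidence", "ok"))
  out <- data.frame(zone_id = table$zone_id, numerator = num,
                    denominator = den, rate = rate, flag = flag,
                    stringsAsFactors = FALSE)
  structure(out, class = c("rate_table", "data.frame"),
            outcome = outcome, kind = kind,
            window_years = window$years, overall = overall)
}

#' @export
print.rate_table <- function(x, ...) {
  cat("<rate_table> ", attr(x, "outcome"), " (", attr(x, "kind"), "), ",
      nrow(x), " zones; overall ", round(attr(x, "overall"), 1),
      if (attr(x, "kind") == "prevalence_percent") "%" else " per 10,000/yr",
      "\n", sep = "")
  cat("  flags: ", sum(x$flag == "missing"), " missing, ",
      sum(x$flag == "low_confidence"), " low-confidence\n", sep = "")
  invisible(x)
}

#' Write a rate table as CSV
#' @param rates a `rate_table`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "rate_table"))
  df <- as.data.frame(rates)
  df$rate <- round(df$rate, 1)            # published precision
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
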