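#' Analysis windows
#'
#' The two windows the study design uses: `"full"` (1 January 2002 to
#' 7 November 2016; amputation and mortality outcomes, whose hospital and
#' death-register sources are complete over the whole period) and
#' `"dfu_subset"` (1 January 2012 to 7 November 2016; foot-ulcer prevalence,
#' restricted because foot screening only reached complete geographic
#' coverage towards the end of 2011). `window_years` for the full window is
#' 14 by convention (the single published incidence rate is computed over 14
#' years); custom windows use exact elapsed years.
#'
#' @param label `"full"`, `"dfu_subset"`, or `"custom"`.
#' @param start,end window bounds (`Date` or ISO-8601 strings) for
#'   `label = "custom"`.
#' @return An object of class `analysis_window` with fields `label`, `start`,
#'   `end`, `years`.
#' @export
analysis_window <- function(label = c("full", "dfu_subset", "custom"),
                            start = NULL, end = NULL) {
  label <- match.arg(label)
  w <- switch(label,
    full = list(start = as.Date("2002-01-01"), end = as.Date("2016-11-07"),
                years = 14),
    dfu_subset = list(start = as.Date("2012-01-01"), end = as.Date("2016-11-07"),
                      years = as.numeric(as.Date("2016-11-07") - as.Date("2012-01-01")) / 365.25),
    custom = {
      start <- as.Date(start); end <- as.Date(end)
      list(start = start, end = end, years = as.numeric(end - start) / 365.25)
    })
  if (w$start >= w$end) stop("window start must precede end")
  structure(c(list(label = label), w), class = "analysis_window")
}

outcome_names <- c("dfu", "lea", "death_after_dfu", "death_after_lea",
                   "death_after_dfu_or_lea")

#' Validate individual-level person records
#'
#' Checks the record invariants before aggregation: every `zone_id` must
#' exist in the zone set, and a recorded death date must not precede any
#' other event date (registry extracts satisfy this by construction; a
#' violation signals corrupted input).
#'
#' @param records person-record data frame (see [simulate_cohort()] for the
#'   column layout).
#' @param zones a `zone_set`.
#' @return invisibly, the records; errors describe every offending id.
#' @export
validate_records <- function(records, zones) {
  stopifnot(is.data.frame(records), inherits(zones, "zone_set"))
  needed <- c("person_id", "zone_id", "entry_date")
  miss <- setdiff(needed, names(records))
  if (length(miss)) stop("records are missing columns: ", paste(miss, collapse = ", "))
  unknown <- setdiff(unique(records$zone_id), zones$zone_id)
  if (length(unknown)) {
    stop("records reference unknown zone ids: ",
         paste(utils::head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) sprintf(" (and %d more)", length(unknown) - 10))
  }
  dd <- records$death_date
  if (!is.null(dd)) {
    bad <- rep(FALSE, nrow(records))
    for (col in intersect(c("dfu_date", "lea_date", "entry_date"), names(records))) {
      ev <- records[[col]]
      bad <- bad | (!is.na(dd) & !is.na(ev) & ev > dd)
    }
    if (any(bad)) {
      stop("death precedes another recorded event for: ",
           paste(utils::head(records$person_id[bad], 10), collapse = ", "))
    }
  }
  invisible(records)
}

#' Aggregate person records into per-zone outcome counts
#'
#' Produces the numerator/denominator table one outcome needs for rate
#' mapping. The denominator is everyone registered by the window end
#' (`entry_date <= end`). Numerator rules follow the study's outcome
#' definitions:
#'
#' * `dfu` -- any foot ulcer recorded on or before the window end, including
#'   pre-window ulcers ("previous or active ulcer" risk stratification is
#'   history-based); only meaningful against the `dfu_subset` window, and
#'   other windows are rejected.
#' * `lea` -- any amputation on or before the window end.
#' * `death_after_dfu` / `death_after_lea` / `death_after_dfu_or_lea` --
#'   death dated inside the window and preceded (same day counts) by the
#'   qualifying event.
#'
#' Each person contributes at most once per outcome.
#'
#' @param records validated person records.
#' @param zones a `zone_set`.
#' @param outcome one of `"dfu"`, `"lea"`, `"death_after_dfu"`,
#'   `"death_after_lea"`, `"death_after_dfu_or_lea"`.
#' @param window an [analysis_window()] (defaults: `dfu_subset` for the DFU
#'   outcome, `full` otherwise).
#' @return An object of class `outcome_table`: data frame with `zone_id`,
#'   `numerator`, `denominator` (all zones, zero-filled), with the outcome,
#'   window and column totals as attributes.
#' @export
aggregate_outcome <- function(records, zones, outcome, window = NULL) {
  outcome <- match.arg(outcome, outcome_names)
  if (is.null(window)) {
    window <- analysis_window(if (outcome == "dfu") "dfu_subset" else "full")
  }
  stopifnot(inherits(window, "analysis_window"))
  if (outcome == "dfu" && window$label != "dfu_subset") {
    stop("the dfu outcome must use the dfu_subset window: ",
         "foot-screening coverage is incomplete before 2012")
  }
  validate_records(records, zones)

  in_denom <- records$entry_date <= window$end
  dfu_d <- records$dfu_date
  lea_d <- records$lea_date
  death_d <- records$death_date
  death_in <- !is.na(death_d) & death_d >= window$start & death_d <= window$end
  hit <- switch(outcome,
    dfu = !is.na(dfu_d) & dfu_d <= window$end,
    lea = !is.na(lea_d) & lea_d <= window$end,
    death_after_dfu = death_in & !is.na(dfu_d) & dfu_d <= death_d,
    death_after_lea = death_in & !is.na(lea_d) & lea_d <= death_d,
    death_after_dfu_or_lea = death_in &
      ((!is.na(dfu_d) & dfu_d <= death_d) | (!is.na(lea_d) & lea_d <= death_d)))
  hit <- hit & in_denom

  zi <- factor(records$zone_id, levels = zones$zone_id)
  num <- as.integer(tapply(hit, zi, sum, default = 0L))
  den <- as.integer(tapply(in_denom, zi, sum, default = 0L))
  out <- data.frame(zone_id = zones$zone_id, numerator = num,
                    denominator = den, stringsAsFactors = FALSE)
  structure(out,
            class = c("outcome_table", "data.frame"),
            outcome = outcome, window = window,
            totals = c(numerator = sum(num), denominator = sum(den)))
}

#' Read / write cohort CSV files
#'
#' The interchange dialect for person records: columns `person_id`,
#' `zone_id`, `entry_date`, `dfu_date`, `lea_date`, `lea_level`,
#' `death_date`; ISO-8601 dates; empty field = no event.
#'
#' @param records person-record data frame.
#' @param path file path.
#' @return `read_cohort` returns the data frame with `Date` columns.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character",
                                       zone_id = "character"))
  for (col in intersect(c("entry_date", "dfu_date", "lea_date", "death_date"),
                        names(df))) {
    v <- df[[col]]
    v[v == ""] <- NA
    df[[col]] <- as.Date(v)
  }
  if ("lea_level" %in% names(df)) df$lea_level[df$lea_level == ""] <- NA
  df
}
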