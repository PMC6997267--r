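#' Count hot or cold spots by deprivation quintile
#'
#' Pools all significance tiers in the requested direction (the published
#' association analysis treats hot vs cold as a single dichotomy) and counts
#' zones per quintile, alongside the expected proportions the one-sample
#' chi-square test will use.
#'
#' @param classification a `spot_classification`.
#' @param zones a `zone_set` with quintiles assigned (quintile 1 = most
#'   deprived).
#' @param which `"hot"` or `"cold"`.
#' @param expected `"zones"` (each quintile's share of all data zones; the
#'   default, since spots are zone-level events and quintile zone counts
#'   need not be equal within one health board), `"uniform"` (1/5 each), or
#'   a numeric vector of 5 proportions.
#' @return An object of class `quintile_counts`: list with `counts` (length
#'   5), `expected_prop`, `unit` label and `expected_model`.
#' @export
quintile_counts <- function(classification, zones, which = c("hot", "cold"),
                            expected = c("zones", "uniform")) {
  stopifnot(inherits(classification, "spot_classification"),
            inherits(zones, "zone_set"))
  which <- match.arg(which)
  idx <- match(classification$zone_id, zones$zone_id)
  if (anyNA(idx)) stop("classified zones missing from the zone set")
  q <- zones$quintile[idx]
  if (anyNA(q)) {
    stop("zones without a quintile: ",
         paste(utils::head(classification$zone_id[is.na(q)], 5), collapse = ", "))
  }
  sel <- if (which == "hot") is_hot(classification$bin) else is_cold(classification$bin)
  counts <- tabulate(q[sel], nbins = 5)
  if (is.numeric(expected)) {
    if (length(expected) != 5 || any(expected <= 0)) {
      stop("expected proportions must be 5 positive values")
    }
    prop <- expected / sum(expected)
    model <- "custom"
  } else {
    model <- match.arg(expected)
    prop <- switch(model,
      uniform = rep(0.2, 5),
      zones = {
        zq <- tabulate(zones$quintile, nbins = 5)
        zq / sum(zq)
      })
  }
  structure(list(counts = counts, expected_prop = prop,
                 unit = paste0(which, "_spot_zones"), expected_model = model),
            class = "quintile_counts")
}

#' One-sample chi-square goodness-of-fit test over quintiles
#'
#' Tests whether observed category counts depart from stated expected
#' proportions: \eqn{\chi^2 = \sum_q (O_q - E_q)^2 / E_q} with
#' \eqn{E_q = N \cdot p_q}, referred to the chi-square distribution with
#' `df = categories - 1` (4 for quintiles).
#'
#' @param counts a `quintile_counts`, or a plain numeric vector of observed
#'   counts (then `expected_prop` supplies the proportions).
#' @param expected_prop expected proportions (ignored when `counts` is a
#'   `quintile_counts`; default uniform).
#' @return An object of class `chi_square_result`: list with `statistic`,
#'   `df`, `p`, `observed`, `expected` and `expected_model`.
#' @export
chi_square_one_sample <- function(counts, expected_prop = NULL) {
  if (inherits(counts, "quintile_counts")) {
    obs <- counts$counts
    prop <- counts$expected_prop
    model <- counts$expected_model
    unit <- counts$unit
  } else {
    obs <- as.numeric(counts)
    prop <- if (is.null(expected_prop)) rep(1 / length(obs), length(obs))
            else expected_prop / sum(expected_prop)
    model <- if (is.null(expected_prop)) "uniform" else "custom"
    unit <- "counts"
  }
  if (length(obs) < 2) stop("need at least two categories")
  if (length(prop) != length(obs)) stop("expected proportions mismatch")
  if (any(obs < 0)) stop("counts must be non-negative")
  total <- sum(obs)
  if (total == 0) stop("zero total count: chi-square test undefined")
  exp_cnt <- total * prop
  if (any(exp_cnt <= 0)) stop("zero expected count: chi-square test undefined")
  stat <- sum((obs - exp_cnt)^2 / exp_cnt)
  df <- length(obs) - 1L
  structure(
    list(statistic = stat, df = df,
         p = stats::pchisq(stat, df, lower.tail = FALSE),
         observed = obs, expected = exp_cnt,
         expected_model = model, unit = unit),
    class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("one-sample chi-square (%s, expected: %s): X2[%d] = %.1f, p %s\n",
              x$unit, x$expected_model, x$df, x$statistic,
              if (x$p < 0.001) "< 0.001" else sprintf("= %.3f", x$p)))
  invisible(x)
}

#' Write a chi-square association report as JSON
#'
#' @param result a `chi_square_result` or a named list of them.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_association <- function(result, path) {
  as_rep <- function(r) list(unit = r$unit, observed = r$observed,
                             expected = r$expected, chi2 = r$statistic,
                             df = r$df, p = r$p,
                             expected_model = r$expected_model)
  rep <- if (inherits(result, "chi_square_result")) as_rep(result)
         else lapply(result, as_rep)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
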