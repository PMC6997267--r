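#' Getis-Ord Gi* local hot-spot statistic
#'
#' For each zone i the statistic compares the weighted sum of the value over
#' i's neighbourhood (the focal zone included: w_ii = 1, the "star"
#' convention) against what a random draw from the global distribution of
#' the value would give:
#'
#' \deqn{G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
#'   {S \sqrt{\frac{n \sum_j w_{ij}^2 - W_i^2}{n - 1}}}}
#'
#' with \eqn{W_i = \sum_j w_{ij}}, \eqn{\bar{X} = \sum_j x_j / n} and
#' \eqn{S = \sqrt{\sum_j x_j^2 / n - \bar{X}^2}} (the population SD). The
#' result is a z-score, treated as standard normal: large positive values
#' mean a cluster of high rates (hot spot), large negative a cluster of low
#' rates (cold spot). For binary weights \eqn{\sum_j w_{ij}^2 = W_i}.
#'
#' A constant value field has S = 0 and carries no spatial information; by
#' convention all z are returned as 0 with a warning.
#'
#' @param x numeric vector of zone values (e.g. rates), aligned with the
#'   weights' zone order; no missing values (exclude such zones, and their
#'   weights rows, with [subset_weights()] beforehand -- see
#'   [hotspot_analysis()]).
#' @param weights a `zone_weights` on the same zones.
#' @return numeric vector of z-scores, one per zone.
#' @export
gi_star <- function(x, weights) {
  stopifnot(inherits(weights, "zone_weights"))
  n <- length(weights$ids)
  if (length(x) != n) stop("values and weights cover different zone universes")
  if (anyNA(x) || any(!is.finite(x))) {
    stop("x contains missing or non-finite values; exclude those zones first")
  }
  if (n < 3) stop("Gi* needs at least 3 zones")
  w <- weights_sparse(weights)
  wi <- Matrix::rowSums(w)
  sw2 <- Matrix::rowSums(w^2)             # = wi for binary weights
  lag <- as.vector(w %*% x)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  if (s == 0 || !is.finite(s)) {
    warning("constant value field: all Gi* z-scores set to 0")
    return(rep(0, n))
  }
  denom_sq <- (n * sw2 - wi^2) / (n - 1)
  if (any(denom_sq <= 0)) {
    stop("degenerate weights row (a zone neighbours every zone); Gi* undefined")
  }
  (lag - xbar * wi) / (s * sqrt(denom_sq))
}

# two-tailed z thresholds for the 90/95/99% confidence tiers
gi_thresholds <- c(`90` = 1.645, `95` = 1.960, `99` = 2.576)

spot_bins <- c("cold_99", "cold_95", "cold_90", "not_significant",
               "hot_90", "hot_95", "hot_99")

#' Classify zones into hot/cold-spot confidence tiers
#'
#' Two-tailed binning of Gi* z-scores at the 90% (|z| >= 1.645), 95%
#' (|z| >= 1.960) and 99% (|z| >= 2.576) confidence levels; the sign gives
#' the direction (hot = high-value cluster, cold = low). A score exactly on
#' a threshold takes the higher-confidence bin.
#'
#' @param z numeric vector of Gi* z-scores (finite).
#' @param zone_id optional zone identifiers.
#' @return An object of class `spot_classification`: data frame with
#'   `zone_id`, `z`, `p` (two-tailed normal) and ordered factor `bin`.
#' @export
classify_spots <- function(z, zone_id = NULL) {
  if (anyNA(z) || any(!is.finite(z))) stop("non-finite z-scores cannot be classified")
  if (is.null(zone_id)) zone_id <- as.character(seq_along(z))
  tier <- findInterval(abs(z), gi_thresholds)   # 0..3
  bin <- rep("not_significant", length(z))
  sig <- tier > 0
  bin[sig] <- paste0(ifelse(z[sig] > 0, "hot_", "cold_"),
                     names(gi_thresholds)[tier[sig]])
  out <- data.frame(
    zone_id = as.character(zone_id),
    z = z,
    p = 2 * stats::pnorm(-abs(z)),
    bin = factor(bin, levels = spot_bins),
    stringsAsFactors = FALSE)
  structure(out, class = c("spot_classification", "data.frame"))
}

is_hot <- function(bin) bin %in% c("hot_90", "hot_95", "hot_99")
is_cold <- function(bin) bin %in% c("cold_90", "cold_95", "cold_99")

#' Summarise hot and cold spot counts
#'
#' Counts zones classified hot or cold at any confidence tier and their
#' share of all zones, as a percentage rounded to one decimal place.
#'
#' @param classification a `spot_classification`.
#' @return list with `n`, `hot = c(count, percent)`, `cold = c(count,
#'   percent)` and the per-tier count table.
#' @export
spot_summary <- function(classification) {
  stopifnot(inherits(classification, "spot_classification"))
  n <- nrow(classification)
  nh <- sum(is_hot(classification$bin))
  nc <- sum(is_cold(classification$bin))
  list(n = n,
       hot = c(count = nh, percent = round(100 * nh / n, 1)),
       cold = c(count = nc, percent = round(100 * nc / n, 1)),
       tiers = table(classification$bin))
}

#' Run the hot-spot analysis on a rate table
#'
#' The full local-cluster step: zones flagged `missing` in the rate table
#' are excluded (with their weights rows) and reported, Gi* is computed on
#' the remaining rates, and zones are classified into confidence tiers.
#'
#' @param rates a `rate_table`.
#' @param weights a `zone_weights` on the same zone universe.
#' @return a `spot_classification` covering the non-missing zones, with the
#'   excluded zone ids in attribute `excluded`.
#' @export
hotspot_analysis <- function(rates, weights) {
  stopifnot(inherits(rates, "rate_table"), inherits(weights, "zone_weights"))
  if (!identical(rates$zone_id, weights$ids)) {
    stop("rate table and weights cover different zone universes")
  }
  keep <- !is.na(rates$rate)
  w <- if (all(keep)) weights else subset_weights(weights, keep)
  z <- gi_star(rates$rate[keep], w)
  out <- classify_spots(z, zone_id = rates$zone_id[keep])
  attr(out, "excluded") <- rates$zone_id[!keep]
  out
}

#' Write a spot classification as CSV
#'
#' Columns: zone_id, rate (if supplied), z, p, bin.
#'
#' @param classification a `spot_classification`.
#' @param path output path.
#' @param rates optional `rate_table` to join the underlying rate in.
#' @return invisibly, the path.
#' @export
write_spots <- function(classification, path, rates = NULL) {
  df <- as.data.frame(classification)
  if (!is.null(rates)) {
    df$rate <- rates$rate[match(df$zone_id, rates$zone_id)]
    df <- df[, c("zone_id", "rate", "z", "p", "bin")]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
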