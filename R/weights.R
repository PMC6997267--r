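#' Spatial weights matrices for local cluster statistics
#'
#' Binary, symmetric neighbour structures over a zone set, stored sparsely as
#' per-zone neighbour index sets. Three schemes are provided, mirroring the
#' spatial model used for hot-spot analysis of data zones of very unequal
#' physical size: a fixed distance band on centroids (so small urban and
#' large rural zones get comparable neighbourhoods), queen contiguity
#' (shared edge or corner), and their union ("hybrid"), which applies the
#' band and then corrects it so that every pair of touching polygons is a
#' neighbour pair.
#'
#' The Gi* statistic includes the focal zone itself (w_ii = 1); that
#' convention is carried on the object as `include_self` rather than stored
#' in the neighbour sets, so plain-Gi analysis stays available.
#'
#' @name zone_weights
NULL

new_zone_weights <- function(ids, nb, scheme, threshold = NA_real_,
                             include_self = TRUE) {
  nb <- lapply(nb, function(v) sort(unique(as.integer(v))))
  structure(
    list(ids = as.character(ids), nb = nb, scheme = scheme,
         threshold = threshold, include_self = include_self),
    class = "zone_weights")
}

#' @export
print.zone_weights <- function(x, ...) {
  deg <- lengths(x$nb)
  cat("<zone_weights> ", length(x$ids), " zones, scheme = ", x$scheme,
      if (!is.na(x$threshold)) sprintf(" (threshold %.4g)", x$threshold),
      "\n  degree: min ", min(deg), ", median ", stats::median(deg),
      ", max ", max(deg),
      "; self-inclusion ", if (x$include_self) "on" else "off", "\n", sep = "")
  invisible(x)
}

#' Fixed distance band neighbours
#'
#' Two zones are neighbours when their area-weighted centroids lie within
#' `threshold` of each other. `threshold = "auto"` picks the smallest band
#' under which no zone is isolated: the maximum over zones of the
#' nearest-neighbour centroid distance.
#'
#' @param zones a `zone_set`.
#' @param threshold positive distance in map units, or `"auto"`.
#' @return a `zone_weights` with scheme `"distance_band"`.
#' @export
fixed_distance_band <- function(zones, threshold = "auto") {
  stopifnot(inherits(zones, "zone_set"))
  cen <- zone_centroids(zones)
  n <- nrow(cen)
  d <- as.matrix(stats::dist(cen))
  if (identical(threshold, "auto")) {
    diag(d) <- Inf
    threshold <- max(apply(d, 1, min))
    diag(d) <- 0
  } else {
    if (!is.numeric(threshold) || threshold <= 0) {
      stop("invalid config: threshold must be > 0 or \"auto\"")
    }
  }
  tol <- threshold * (1 + 1e-9)          # keep pairs sitting exactly on the band
  nb <- lapply(seq_len(n), function(i) {
    j <- which(d[i, ] <= tol)
    j[j != i]
  })
  new_zone_weights(zones$zone_id, nb, "distance_band", threshold = threshold)
}

#' Queen contiguity neighbours
#'
#' Two zones are neighbours when their boundaries share at least one point:
#' a common edge or a common corner. Detection is by shared polygon
#' vertices after snapping coordinates to a grid of `snap_tolerance`
#' (default 1e-8 of the map width); tessellation and grid geometries always
#' express edge contact through shared vertices, so this captures both edge
#' and corner adjacency.
#'
#' @param zones a `zone_set`.
#' @param snap_tolerance vertex snapping distance, or `NULL` for the default.
#' @return a `zone_weights` with scheme `"queen"`.
#' @export
queen_contiguity <- function(zones, snap_tolerance = NULL) {
  stopifnot(inherits(zones, "zone_set"))
  n <- n_zones(zones)
  bb <- zone_bbox(zones)
  width <- max(bb[3] - bb[1], bb[4] - bb[2])
  if (is.null(snap_tolerance)) snap_tolerance <- 1e-8 * width
  if (snap_tolerance <= 0) stop("invalid config: snap_tolerance must be > 0")
  keys <- vector("list", n)
  for (i in seq_len(n)) {
    v <- do.call(rbind, zones$geometry[[i]])
    if (any(!is.finite(v))) stop("invalid geometry in zone '", zones$zone_id[i], "'")
    keys[[i]] <- unique(paste(round(v[, 1] / snap_tolerance),
                              round(v[, 2] / snap_tolerance)))
  }
  zone_of <- rep.int(seq_len(n), lengths(keys))
  key <- unlist(keys, use.names = FALSE)
  groups <- split(zone_of, key)
  pairs <- unique(do.call(rbind, lapply(groups[lengths(groups) > 1], function(g) {
    g <- sort(unique(g))
    if (length(g) < 2) return(NULL)
    t(utils::combn(g, 2))
  })))
  nb <- rep(list(integer(0)), n)
  if (!is.null(pairs) && nrow(pairs) > 0) {
    half <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
    idx <- as.integer(names(half))
    nb[idx] <- half
  }
  new_zone_weights(zones$zone_id, nb, "queen")
}

#' Hybrid (union) weights: distance band corrected by contiguity
#'
#' Union of the two neighbour relations: w_ij = 1 if either the band or the
#' contiguity scheme links i and j. This is the spatial model the hot-spot
#' analysis uses by default -- the band handles unequal polygon sizes, the
#' contiguity correction guarantees every pair of touching zones counts as
#' neighbours.
#'
#' @param band,queen `zone_weights` on the same zone universe.
#' @return a `zone_weights` with scheme `"hybrid"`.
#' @export
hybrid_weights <- function(band, queen) {
  stopifnot(inherits(band, "zone_weights"), inherits(queen, "zone_weights"))
  if (!identical(band$ids, queen$ids)) {
    stop("weights are defined on different zone universes")
  }
  nb <- mapply(function(a, b) sort(unique(c(a, b))),
               band$nb, queen$nb, SIMPLIFY = FALSE)
  new_zone_weights(band$ids, nb, "hybrid", threshold = band$threshold)
}

#' Build the default spatial weights for a zone set
#'
#' Convenience constructor for the hybrid scheme: auto-banded fixed distance
#' plus queen contiguity.
#'
#' @param zones a `zone_set`.
#' @param scheme one of `"hybrid"`, `"distance_band"`, `"queen"`.
#' @param threshold band threshold, or `"auto"`.
#' @return a `zone_weights`.
#' @export
zone_weights_for <- function(zones, scheme = c("hybrid", "distance_band", "queen"),
                             threshold = "auto") {
  scheme <- match.arg(scheme)
  switch(scheme,
    distance_band = fixed_distance_band(zones, threshold),
    queen = queen_contiguity(zones),
    hybrid = hybrid_weights(fixed_distance_band(zones, threshold),
                            queen_contiguity(zones)))
}

# sparse 0/1 adjacency (dgCMatrix); diagonal set by the include_self flag
weights_sparse <- function(w) {
  n <- length(w$ids)
  i <- rep.int(seq_len(n), lengths(w$nb))
  j <- unlist(w$nb, use.names = FALSE)
  if (w$include_self) {
    i <- c(i, seq_len(n)); j <- c(j, seq_len(n))
  }
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
}

#' Restrict a weights object to a subset of zones
#'
#' Drops the excluded zones and every reference to them in the remaining
#' neighbour sets, preserving symmetry. Used to remove zones flagged missing
#' (zero denominator) before computing Gi*.
#'
#' @param w a `zone_weights`.
#' @param keep logical or integer index of zones to retain.
#' @return a `zone_weights` on the retained zones.
#' @export
subset_weights <- function(w, keep) {
  idx <- seq_along(w$ids)[keep]
  remap <- match(seq_along(w$ids), idx)
  nb <- lapply(w$nb[idx], function(v) remap[v][!is.na(remap[v])])
  new_zone_weights(w$ids[idx], nb, w$scheme, threshold = w$threshold,
                   include_self = w$include_self)
}

#' Write a weights object as a sparse adjacency table plus summary
#'
#' Writes the i < j neighbour pairs as CSV (`from`, `to` zone ids) and a JSON
#' summary (n, scheme, threshold, degree histogram).
#'
#' @param w a `zone_weights`.
#' @param csv_path,json_path output file paths (`NULL` to skip either).
#' @return invisibly, the pair data frame.
#' @export
write_weights <- function(w, csv_path, json_path = NULL) {
  stopifnot(inherits(w, "zone_weights"))
  i <- rep.int(seq_along(w$ids), lengths(w$nb))
  j <- unlist(w$nb, use.names = FALSE)
  keep <- i < j
  df <- data.frame(from = w$ids[i[keep]], to = w$ids[j[keep]],
                   stringsAsFactors = FALSE)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    deg <- lengths(w$nb)
    jsonlite::write_json(
      list(n = length(w$ids), scheme = w$scheme, threshold = w$threshold,
           degree_histogram = as.list(table(deg))),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(df)
}
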