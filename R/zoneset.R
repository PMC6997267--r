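#' Zone sets: the small-area geography
#'
#' A `zone_set` holds an ordered collection of data zones: polygon geometry,
#' diabetic population and (once assigned) a multiple-deprivation quintile.
#' It is the geographic unit of every downstream computation, playing the
#' role of the census data-zone layer (mean population about 760 people per
#' zone) that small-area disease mapping in Scotland is built on.
#'
#' Geometry is stored per zone as a list of rings; each ring is an unclosed
#' two-column matrix of planar (projected) coordinates. Exterior rings are
#' counter-clockwise, holes clockwise, so signed ring areas combine directly.
#'
#' @param zone_id character vector of unique zone identifiers.
#' @param geometry list (one element per zone) of lists of ring matrices.
#' @param population integer vector of diabetic population per zone.
#' @param quintile integer vector in 1..5 (1 = most deprived) or `NA` if
#'   deprivation has not been assigned yet.
#' @param extra optional data frame of additional per-zone properties carried
#'   through file round-trips untouched.
#' @return An object of class `zone_set`.
#' @export
zone_set <- function(zone_id, geometry, population = NA_integer_,
                     quintile = NA_integer_, extra = NULL) {
  zone_id <- as.character(zone_id)
  n <- length(zone_id)
  if (anyDuplicated(zone_id)) {
    stop("zone ids must be unique; duplicated: ",
         paste(unique(zone_id[duplicated(zone_id)]), collapse = ", "))
  }
  if (length(geometry) != n) stop("geometry must have one entry per zone")
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) g <- list(g)
    lapply(g, function(r) {
      r <- as.matrix(r)
      if (ncol(r) != 2 || nrow(r) < 3) stop("each ring needs >= 3 points in 2 columns")
      storage.mode(r) <- "double"
      dimnames(r) <- NULL
      r
    })
  })
  population <- rep_len(as.integer(population), n)
  quintile <- rep_len(as.integer(quintile), n)
  if (any(!is.na(quintile) & !(quintile %in% 1:5))) {
    stop("quintile must be in 1..5 (1 = most deprived)")
  }
  if (!is.null(extra)) {
    extra <- as.data.frame(extra, stringsAsFactors = FALSE)
    if (nrow(extra) != n) stop("extra must have one row per zone")
  }
  structure(
    list(zone_id = zone_id, geometry = geometry,
         population = population, quintile = quintile, extra = extra),
    class = "zone_set")
}

#' Number of zones in a zone set
#' @param zones a `zone_set`.
#' @return integer count.
#' @export
n_zones <- function(zones) {
  stopifnot(inherits(zones, "zone_set"))
  length(zones$zone_id)
}

#' @export
print.zone_set <- function(x, ...) {
  cat("<zone_set> ", n_zones(x), " zones\n", sep = "")
  cat("  population: ",
      if (all(is.na(x$population))) "unset" else
        paste0("mean ", round(mean(x$population, na.rm = TRUE), 1)), "\n", sep = "")
  cat("  quintiles:  ",
      if (all(is.na(x$quintile))) "unassigned" else
        paste(tabulate(x$quintile, 5), collapse = "/"), "\n", sep = "")
  invisible(x)
}

# ---- planar polygon primitives ------------------------------------------

# signed area of one unclosed ring (positive = counter-clockwise)
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# area-weighted centroid of one ring, via the shoelace moment formula;
# consistent in sign with ring_signed_area
ring_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

zone_signed_area <- function(rings) sum(vapply(rings, ring_signed_area, 0))

#' Polygon areas of each zone
#' @param zones a `zone_set`.
#' @return numeric vector of areas (holes subtracted).
#' @export
zone_areas <- function(zones) {
  stopifnot(inherits(zones, "zone_set"))
  vapply(zones$geometry, zone_signed_area, 0)
}

#' Area-weighted centroids of each zone
#'
#' Representative points used by the fixed-distance-band neighbour scheme.
#' Holes (clockwise rings) carry negative weight, so the centroid of an
#' annulus or an L-shape is the true area centroid, not a vertex average.
#'
#' @param zones a `zone_set`.
#' @return an `n x 2` matrix of (x, y) centroids, rownames = zone ids.
#' @export
zone_centroids <- function(zones) {
  stopifnot(inherits(zones, "zone_set"))
  out <- t(vapply(seq_along(zones$geometry), function(i) {
    rings <- zones$geometry[[i]]
    a <- vapply(rings, ring_signed_area, 0)
    if (abs(sum(a)) < .Machine$double.eps * 100) {
      stop("zone '", zones$zone_id[i], "' has a degenerate (zero-area) polygon")
    }
    cents <- t(vapply(rings, ring_centroid, c(0, 0)))
    colSums(cents * a) / sum(a)
  }, c(0, 0)))
  rownames(out) <- zones$zone_id
  out
}

# bounding box of all geometry: c(xmin, ymin, xmax, ymax)
zone_bbox <- function(zones) {
  xs <- unlist(lapply(zones$geometry, function(g) lapply(g, function(r) r[, 1])))
  ys <- unlist(lapply(zones$geometry, function(g) lapply(g, function(r) r[, 2])))
  c(min(xs), min(ys), max(xs), max(ys))
}
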