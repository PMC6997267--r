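#' Write a zone set as GeoJSON
#'
#' RFC 7946-style FeatureCollection on planar (projected) coordinates:
#' exterior rings counter-clockwise, holes clockwise, rings closed.
#' Properties per feature: `zone_id`, `population`, `quintile`, any `extra`
#' columns, and optionally extra per-zone analysis columns joined by zone id
#' (rates, spot bins). Key order is fixed, output deterministic.
#'
#' @param zones a `zone_set`.
#' @param path output path.
#' @param extra_properties optional data frame with a `zone_id` column whose
#'   remaining columns are added to each feature's properties.
#' @return invisibly, the path.
#' @export
write_zones <- function(zones, path, extra_properties = NULL) {
  stopifnot(inherits(zones, "zone_set"))
  n <- n_zones(zones)
  if (!is.null(extra_properties)) {
    stopifnot(is.data.frame(extra_properties), "zone_id" %in% names(extra_properties))
    m <- match(zones$zone_id, extra_properties$zone_id)
  }
  features <- lapply(seq_len(n), function(i) {
    props <- list(zone_id = zones$zone_id[i],
                  population = na_null(zones$population[i]),
                  quintile = na_null(zones$quintile[i]))
    if (!is.null(zones$extra)) {
      for (nm in names(zones$extra)) props[[nm]] <- na_null(zones$extra[[nm]][i])
    }
    if (!is.null(extra_properties) && !is.na(m[i])) {
      for (nm in setdiff(names(extra_properties), "zone_id")) {
        props[[nm]] <- na_null(to_scalar(extra_properties[[nm]][m[i]]))
      }
    }
    rings <- lapply(zones$geometry[[i]], function(r) rbind(r, r[1, ]))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

na_null <- function(x) if (length(x) == 1 && is.na(x)) NULL else x
to_scalar <- function(x) if (is.factor(x)) as.character(x) else x

#' Read a zone set from GeoJSON or an ESRI shapefile
#'
#' Validates the zone-set invariants on the way in: unique ids, quintiles in
#' 1..5 (null allowed), simple non-empty polygons. Ring orientation is
#' normalised to exterior counter-clockwise / holes clockwise, with a
#' warning when repair was needed. Geographic (longitude/latitude)
#' coordinate systems are refused with an instructive error: the distance
#' band and centroid computations assume planar projected coordinates, and
#' the file must be reprojected first. Detection uses declared CRS metadata
#' (a GeoJSON `crs` member naming CRS84/EPSG:4326, or a `.prj` starting with
#' `GEOGCS`).
#'
#' @param path path to a `.geojson`/`.json` file or a `.shp` file (the
#'   sibling `.dbf` supplies attributes; `.shx` is not required).
#' @param format `"auto"` (by extension), `"geojson"` or `"shapefile"`.
#' @param property_map names of the id/population/quintile properties in the
#'   file, for files using different field names.
#' @return a `zone_set`; unrecognised properties are carried in `extra`.
#' @export
read_zones <- function(path, format = c("auto", "geojson", "shapefile"),
                       property_map = list(zone_id = "zone_id",
                                           population = "population",
                                           quintile = "quintile")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.shp$", path, ignore.case = TRUE)) "shapefile" else "geojson"
  }
  pm <- utils::modifyList(list(zone_id = "zone_id", population = "population",
                               quintile = "quintile"), property_map)
  if (format == "geojson") read_zones_geojson(path, pm) else read_zones_shapefile(path, pm)
}

read_zones_geojson <- function(path, pm) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  crs_name <- tryCatch(obj$crs$properties$name, error = function(e) NULL)
  if (!is.null(crs_name) && grepl("CRS84|4326", crs_name)) {
    stop("geographic (longitude/latitude) coordinates are not supported: ",
         "reproject the data to a planar projected CRS before reading")
  }
  feats <- obj$features
  if (length(feats) == 0) {
    return(zone_set(character(0), list(), integer(0), integer(0)))
  }
  prop_names <- names(feats[[1]]$properties)
  get_prop <- function(f, key) {
    v <- f$properties[[key]]
    if (is.null(v)) NA else v
  }
  if (!(pm$zone_id %in% prop_names)) {
    stop("missing required property '", pm$zone_id, "'; available: ",
         paste(prop_names, collapse = ", "))
  }
  for (key in c(pm$population, pm$quintile)) {
    if (!(key %in% prop_names)) {
      stop("missing required property '", key, "'; available: ",
           paste(prop_names, collapse = ", "))
    }
  }
  repaired <- FALSE
  geometry <- lapply(feats, function(f) {
    g <- f$geometry
    parts <- switch(g$type,
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      stop("unsupported geometry type: ", g$type))
    rings <- list()
    for (part in parts) {
      for (k in seq_along(part)) {
        ring <- do.call(rbind, lapply(part[[k]], function(pt) c(pt[[1]], pt[[2]])))
        if (nrow(ring) >= 2 &&
            isTRUE(all.equal(ring[1, ], ring[nrow(ring), ]))) {
          ring <- ring[-nrow(ring), , drop = FALSE]
        }
        want_ccw <- (k == 1)
        if ((ring_signed_area(ring) > 0) != want_ccw) {
          ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
          repaired <<- TRUE
        }
        rings[[length(rings) + 1L]] <- ring
      }
    }
    rings
  })
  if (repaired) warning("ring orientation repaired to exterior-CCW convention")
  ids <- vapply(feats, function(f) as.character(get_prop(f, pm$zone_id)), "")
  pop <- vapply(feats, function(f) as_int_na(get_prop(f, pm$population)), 0L)
  quin <- vapply(feats, function(f) as_int_na(get_prop(f, pm$quintile)), 0L)
  known <- unlist(pm, use.names = FALSE)
  extra_keys <- setdiff(prop_names, known)
  extra <- NULL
  if (length(extra_keys) > 0) {
    extra <- as.data.frame(
      lapply(stats::setNames(extra_keys, extra_keys), function(k) {
        vals <- lapply(feats, get_prop, key = k)
        numeric_ok <- all(vapply(vals, function(v) {
          length(v) == 1 && (is.numeric(v) || is.na(v))
        }, TRUE))
        if (numeric_ok) {
          vapply(vals, function(v) if (is.na(v[1])) NA_real_ else as.numeric(v), 0)
        } else {
          vapply(vals, function(v) if (is.na(v[1])) NA_character_ else as.character(v), "")
        }
      }), stringsAsFactors = FALSE, optional = TRUE)
  }
  zone_set(ids, geometry, population = pop, quintile = quin, extra = extra)
}

as_int_na <- function(v) if (is.null(v) || is.na(v[1])) NA_integer_ else as.integer(v)

# ---- minimal ESRI shapefile (polygon) reader ----------------------------
# Reads .shp shape type 5 records directly (no .shx needed) and joins the
# sibling .dbf attribute table. Ring order follows the ESRI convention
# (exterior clockwise, holes counter-clockwise); vertex order is reversed on
# read to the exterior-CCW convention used internally.

read_zones_shapefile <- function(path, pm) {
  prj <- sub("\\.shp$", ".prj", path, ignore.case = TRUE)
  if (file.exists(prj)) {
    wkt <- paste(readLines(prj, warn = FALSE), collapse = "")
    if (grepl("^\\s*GEOGCS", wkt)) {
      stop("geographic (longitude/latitude) coordinates are not supported: ",
           "reproject the shapefile to a planar projected CRS before reading")
    }
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 9994L)) stop("not an ESRI shapefile: ", path)
  seek(con, 24)
  file_len_words <- readBin(con, "integer", 1, size = 4, endian = "big")
  seek(con, 32)
  shp_type <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (shp_type != 5L) stop("only polygon shapefiles (type 5) are supported, got type ", shp_type)
  seek(con, 100)
  geoms <- list()
  bytes_read <- 100L
  while (bytes_read < 2L * file_len_words) {
    readBin(con, "integer", 1, size = 4, endian = "big")          # record number
    content_words <- readBin(con, "integer", 1, size = 4, endian = "big")
    rec_type <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (rec_type == 0L) {                                          # null shape
      geoms[[length(geoms) + 1L]] <- list()
    } else {
      if (rec_type != 5L) stop("unexpected record shape type ", rec_type)
      readBin(con, "double", 4, endian = "little")                 # record bbox
      n_parts <- readBin(con, "integer", 1, size = 4, endian = "little")
      n_points <- readBin(con, "integer", 1, size = 4, endian = "little")
      parts <- readBin(con, "integer", n_parts, size = 4, endian = "little")
      xy <- matrix(readBin(con, "double", 2 * n_points, endian = "little"),
                   ncol = 2, byrow = TRUE)
      bounds <- c(parts, n_points)
      rings <- lapply(seq_len(n_parts), function(k) {
        ring <- xy[(bounds[k] + 1):bounds[k + 1], , drop = FALSE]
        if (nrow(ring) >= 2 &&
            isTRUE(all.equal(ring[1, ], ring[nrow(ring), ]))) {
          ring <- ring[-nrow(ring), , drop = FALSE]
        }
        ring[rev(seq_len(nrow(ring))), , drop = FALSE]             # ESRI CW -> CCW
      })
      geoms[[length(geoms) + 1L]] <- rings
    }
    bytes_read <- bytes_read + 8L + 2L * content_words
  }
  dbf <- sub("\\.shp$", ".dbf", path, ignore.case = TRUE)
  if (!file.exists(dbf)) stop("attribute table not found: ", dbf)
  attrs <- foreign::read.dbf(dbf, as.is = TRUE)
  if (nrow(attrs) != length(geoms)) {
    stop("shapefile geometry and attribute counts differ")
  }
  for (key in c(pm$zone_id, pm$population, pm$quintile)) {
    if (!(key %in% names(attrs))) {
      stop("missing required property '", key, "'; available: ",
           paste(names(attrs), collapse = ", "))
    }
  }
  extra_keys <- setdiff(names(attrs), unlist(pm, use.names = FALSE))
  zone_set(as.character(attrs[[pm$zone_id]]), geoms,
           population = as.integer(attrs[[pm$population]]),
           quintile = as.integer(attrs[[pm$quintile]]),
           extra = if (length(extra_keys)) attrs[extra_keys] else NULL)
}
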