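make_zones <- function() {
  z <- grid_zone_set(2, 2, population = c(100L, 200L, 300L, 400L),
                     quintile = c(1L, 2L, 3L, 4L))
  z$extra <- data.frame(name = c("Øst", "west", "north", "south"),
                        stringsAsFactors = FALSE)
  z
}

test_that("GeoJSON write/read round-trips ids, attributes and coordinates", {
  z <- make_zones()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_zones(z, path)
  back <- read_zones(path)
  expect_identical(back$zone_id, z$zone_id)
  expect_identical(back$quintile, z$quintile)
  expect_identical(back$population, z$population)
  expect_equal(back$extra$name, z$extra$name)   # non-ASCII preserved
  for (i in 1:4) {
    expect_equal(back$geometry[[i]][[1]], z$geometry[[i]][[1]],
                 tolerance = 1e-12)
  }
  # deterministic serialisation
  path2 <- withr::local_tempfile(fileext = ".geojson")
  write_zones(z, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("GeoJSON output is a structurally valid FeatureCollection", {
  z <- generate_geography(sim_config(n_zones = 60, seed = 2))
  z <- assign_deprivation(z, 0.2, seed = 2)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_zones(z, path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(obj$type, "FeatureCollection")
  expect_length(obj$features, 60)
  f <- obj$features[[7]]
  expect_equal(f$type, "Feature")
  expect_equal(f$geometry$type, "Polygon")
  ring <- f$geometry$coordinates[[1]]
  expect_identical(ring[[1]], ring[[length(ring)]])   # rings closed
  # exterior rings counter-clockwise (RFC 7946)
  m <- do.call(rbind, lapply(ring[-length(ring)], unlist))
  expect_gt(geofoot:::ring_signed_area(m), 0)
  # empty collection is still valid
  empty <- zone_set(character(0), list(), integer(0), integer(0))
  p2 <- withr::local_tempfile(fileext = ".geojson")
  write_zones(empty, p2)
  obj2 <- jsonlite::fromJSON(p2, simplifyVector = FALSE)
  expect_equal(obj2$type, "FeatureCollection")
  expect_length(obj2$features, 0)
})

test_that("missing required properties and geographic CRS are refused", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = list(zone_id = "a", population = 10),   # quintile absent
      geometry = list(type = "Polygon", coordinates = list(list(
        c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))))))),
    auto_unbox = TRUE), path)
  expect_error(read_zones(path), "quintile")
  expect_error(read_zones(path, property_map = list(zone_id = "nope")),
               "nope.*available", perl = TRUE)
  crs_path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(jsonlite::toJSON(list(
    type = "FeatureCollection",
    crs = list(type = "name",
               properties = list(name = "urn:ogc:def:crs:OGC:1.3:CRS84")),
    features = list()), auto_unbox = TRUE), crs_path)
  expect_error(read_zones(crs_path), "planar projected CRS")
})

test_that("ring orientation is repaired on read with a warning", {
  z <- make_zones()
  path <- withr::local_tempfile(fileext = ".geojson")
  write_zones(z, path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ring <- obj$features[[1]]$geometry$coordinates[[1]]
  obj$features[[1]]$geometry$coordinates[[1]] <- rev(ring)   # make it clockwise
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  expect_warning(back <- read_zones(path), "orientation")
  expect_gt(geofoot:::ring_signed_area(back$geometry[[1]][[1]]), 0)
})

test_that("shapefile and GeoJSON encodings of one fixture load identically", {
  z <- make_zones()
  z$extra <- NULL                      # dbf carries only the core attributes
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_zones(z, gj)
  base <- file.path(withr::local_tempdir(), "zones")
  write_polygon_shapefile(z, base)
  from_gj <- read_zones(gj)
  from_shp <- read_zones(paste0(base, ".shp"))
  expect_identical(from_shp$zone_id, from_gj$zone_id)
  expect_identical(from_shp$quintile, from_gj$quintile)
  expect_identical(from_shp$population, from_gj$population)
  for (i in 1:4) {
    a <- from_shp$geometry[[i]][[1]]; b <- from_gj$geometry[[i]][[1]]
    # same ring up to starting vertex; normalise to minimal rotation
    rot <- function(m) { k <- which.min(m[, 1] * 1e6 + m[, 2]); if (k > 1) rbind(m[k:nrow(m), ], m[seq_len(k - 1), ]) else m }
    expect_equal(rot(a), rot(b), tolerance = 1e-12)
  }
  # geographic .prj refused
  base2 <- file.path(withr::local_tempdir(), "geo")
  write_polygon_shapefile(z, base2,
    prj = 'GEOGCS["GCS_WGS_1984",DATUM["D_WGS_1984",SPHEROID["WGS_1984",6378137,298.257223563]]]')
  expect_error(read_zones(paste0(base2, ".shp")), "planar projected CRS")
})

test_that("rate and bin properties can be appended to the GeoJSON", {
  z <- make_zones()
  extra <- data.frame(zone_id = z$zone_id, rate = c(4.6, 1.3, 10.5, 0),
                      bin = c("hot_95", "not_significant", "cold_90", "hot_99"),
                      stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_zones(z, path, extra_properties = extra)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(obj$features[[1]]$properties$rate, 4.6)
  expect_equal(obj$features[[3]]$properties$bin, "cold_90")
})

test_that("choropleth SVG colours polygons by tier and is byte-deterministic", {
  skip_if_not_installed("xml2")
  z <- make_zones()
  # one hot_99 zone, rest not significant
  cl <- classify_spots(c(3.1, 0, 0, 0), zone_id = z$zone_id)
  path <- withr::local_tempfile(fileext = ".svg")
  render_map(z, cl, path)
  doc <- xml2::read_xml(path)
  fills <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[local-name() = 'path']"), "fill")
  expect_equal(sum(fills == "#a50f15"), 1)
  expect_equal(sum(fills == "#cccccc"), 3)
  # all-null classification renders monochrome grey
  cl0 <- classify_spots(rep(0, 4), zone_id = z$zone_id)
  p0 <- withr::local_tempfile(fileext = ".svg")
  render_map(z, cl0, p0)
  d0 <- xml2::read_xml(p0)
  f0 <- xml2::xml_attr(xml2::xml_find_all(d0, "//*[local-name() = 'path']"), "fill")
  expect_true(all(f0 == "#cccccc"))
  # byte-identical on repeat render
  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  render_map(z, cl, p1); render_map(z, cl, p2)
  expect_identical(readLines(p1), readLines(p2))
  # rate maps render with a sequential ramp; missing zones white
  recs <- rbind(person("p1", "g1_1", dfu = "2013-01-01"),
                do.call(rbind, lapply(2:20, function(k) person(paste0("p", k), "g1_2"))))
  rt <- zone_rates(aggregate_outcome(recs, z, "dfu"))
  p3 <- withr::local_tempfile(fileext = ".svg")
  render_map(z, rt, p3)
  f3 <- xml2::xml_attr(xml2::xml_find_all(xml2::read_xml(p3),
                                          "//*[local-name() = 'path']"), "fill")
  expect_equal(sum(f3 == "#ffffff"), 2)   # the two unpopulated zones
})
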