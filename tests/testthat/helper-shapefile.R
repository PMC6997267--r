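# test-only ESRI shapefile writer, used to build cross-format fixtures at
# test time (binary files are never stored in the repository). Writes .shp,
# .shx and .dbf for polygon (type 5) geometry; rings are written closed and
# in the ESRI orientation (exterior clockwise, holes counter-clockwise).

write_polygon_shapefile <- function(zones, base, prj = NULL) {
  shp <- paste0(base, ".shp"); shx <- paste0(base, ".shx")
  n <- n_zones(zones)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    rings <- lapply(zones$geometry[[i]], function(r) {
      r <- r[rev(seq_len(nrow(r))), , drop = FALSE]     # internal CCW -> ESRI CW
      rbind(r, r[1, ])
    })
    pts <- do.call(rbind, rings)
    parts <- cumsum(c(0L, vapply(rings, nrow, 0L)))[seq_along(rings)]
    rec[[i]] <- list(rings = rings, pts = pts, parts = parts,
                     box = c(min(pts[, 1]), min(pts[, 2]),
                             max(pts[, 1]), max(pts[, 2])))
  }
  content_words <- vapply(rec, function(r) {
    (4L + 32L + 4L + 4L + 4L * length(r$parts) + 16L * nrow(r$pts)) %/% 2L
  }, 0L)
  file_words <- 50L + sum(8L %/% 2L + content_words)
  allpts <- do.call(rbind, lapply(rec, `[[`, "pts"))
  header <- function(con, words) {
    writeBin(9994L, con, size = 4, endian = "big")
    writeBin(integer(5), con, size = 4, endian = "big")
    writeBin(as.integer(words), con, size = 4, endian = "big")
    writeBin(1000L, con, size = 4, endian = "little")
    writeBin(5L, con, size = 4, endian = "little")
    writeBin(c(min(allpts[, 1]), min(allpts[, 2]),
               max(allpts[, 1]), max(allpts[, 2]),
               0, 0, 0, 0), con, endian = "little")
  }
  con <- file(shp, "wb")
  header(con, file_words)
  for (i in seq_len(n)) {
    r <- rec[[i]]
    writeBin(i, con, size = 4, endian = "big")
    writeBin(content_words[i], con, size = 4, endian = "big")
    writeBin(5L, con, size = 4, endian = "little")
    writeBin(r$box, con, endian = "little")
    writeBin(length(r$parts), con, size = 4, endian = "little")
    writeBin(nrow(r$pts), con, size = 4, endian = "little")
    writeBin(as.integer(r$parts), con, size = 4, endian = "little")
    writeBin(as.vector(t(r$pts)), con, endian = "little")
  }
  close(con)
  con <- file(shx, "wb")
  header(con, 50L + 4L * n)
  offset <- 50L
  for (i in seq_len(n)) {
    writeBin(offset, con, size = 4, endian = "big")
    writeBin(content_words[i], con, size = 4, endian = "big")
    offset <- offset + 4L + content_words[i]
  }
  close(con)
  foreign::write.dbf(
    data.frame(zone_id = zones$zone_id, population = zones$population,
               quintile = zones$quintile, stringsAsFactors = FALSE),
    paste0(base, ".dbf"))
  if (!is.null(prj)) writeLines(prj, paste0(base, ".prj"))
  invisible(base)
}
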