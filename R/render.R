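#' Render a choropleth map as SVG
#'
#' Draws the zone polygons filled by either the hot/cold-spot confidence
#' tier (diverging reds for hot spots, blues for cold spots, darker = higher
#' confidence, neutral grey for non-significant zones -- the usual hot-spot
#' map convention) or by a continuous rate (sequential red ramp). Zones
#' without a value (excluded from analysis) are drawn white. Output is plain
#' SVG text written deterministically: the same input yields byte-identical
#' files.
#'
#' @param zones a `zone_set`.
#' @param values a `spot_classification` (fills by `bin`) or a `rate_table`
#'   (fills by `rate`), joined to zones by `zone_id`.
#' @param path output `.svg` path.
#' @param width canvas width in pixels (height follows the map aspect ratio,
#'   plus a legend strip).
#' @return invisibly, the path.
#' @export
render_map <- function(zones, values, path, width = 600) {
  stopifnot(inherits(zones, "zone_set"))
  if (inherits(values, "spot_classification")) {
    bin <- as.character(values$bin[match(zones$zone_id, values$zone_id)])
    fill <- ifelse(is.na(bin), "#ffffff", spot_palette[bin])
    legend <- spot_palette
  } else if (inherits(values, "rate_table")) {
    r <- values$rate[match(zones$zone_id, values$zone_id)]
    if (all(is.na(r))) stop("no rates to render")
    fill <- ramp_fill(r)
    rng <- range(r, na.rm = TRUE)
    legend <- stats::setNames(ramp_fill(seq(rng[1], rng[2], length.out = 5)),
                              formatC(seq(rng[1], rng[2], length.out = 5),
                                      format = "f", digits = 1))
  } else {
    stop("values must be a spot_classification or a rate_table")
  }
  bb <- zone_bbox(zones)
  span_x <- bb[3] - bb[1]; span_y <- bb[4] - bb[2]
  h <- width * span_y / span_x
  legend_h <- 22 * length(legend) + 10
  tx <- function(x) (x - bb[1]) / span_x * width
  ty <- function(y) (bb[4] - y) / span_y * h          # SVG y grows downward
  paths <- vapply(seq_len(n_zones(zones)), function(i) {
    d <- paste(vapply(zones$geometry[[i]], function(ring) {
      pts <- sprintf("%.6f,%.6f", tx(ring[, 1]), ty(ring[, 2]))
      paste0("M", paste(pts, collapse = " L"), " Z")
    }, ""), collapse = " ")
    sprintf('<path d="%s" fill="%s" fill-rule="evenodd" stroke="#555555" stroke-width="0.4"><title>%s</title></path>',
            d, fill[i], xml_escape(zones$zone_id[i]))
  }, "")
  leg <- vapply(seq_along(legend), function(k) {
    y <- h + 10 + (k - 1) * 22
    sprintf(paste0('<rect x="10" y="%.1f" width="16" height="16" fill="%s" stroke="#555555"/>',
                   '<text x="32" y="%.1f" font-family="sans-serif" font-size="12">%s</text>'),
            y, legend[k], y + 13, xml_escape(names(legend)[k]))
  }, "")
  svg <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%.1f" viewBox="0 0 %d %.1f">',
            as.integer(width), h + legend_h, as.integer(width), h + legend_h),
    '<rect width="100%" height="100%" fill="#ffffff"/>',
    paths, leg, "</svg>")
  writeLines(svg, path)
  invisible(path)
}

spot_palette <- c(
  hot_99 = "#a50f15", hot_95 = "#de2d26", hot_90 = "#fb6a4a",
  not_significant = "#cccccc",
  cold_90 = "#6baed6", cold_95 = "#3182bd", cold_99 = "#08519c")

ramp_fill <- function(r) {
  rng <- range(r, na.rm = TRUE)
  f <- if (diff(rng) == 0) rep(0, length(r)) else (r - rng[1]) / diff(rng)
  cols <- grDevices::colorRamp(c("#fee5d9", "#a50f15"))(ifelse(is.na(f), 0, f))
  ifelse(is.na(r), "#ffffff",
         grDevices::rgb(cols[, 1], cols[, 2], cols[, 3], maxColorValue = 255))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
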