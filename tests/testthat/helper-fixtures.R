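# shared fixture builders and independent oracles

# nr x nc grid of unit squares, row-major ids; quintile cycling 1..5
grid_zone_set <- function(nr, nc, cell = 1, population = 100L,
                          quintile = NULL) {
  geoms <- list(); ids <- character(0)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      x0 <- (c - 1) * cell; y0 <- (r - 1) * cell
      geoms[[length(geoms) + 1L]] <- list(rbind(
        c(x0, y0), c(x0 + cell, y0), c(x0 + cell, y0 + cell), c(x0, y0 + cell)))
      ids <- c(ids, sprintf("g%d_%d", r, c))
    }
  }
  if (is.null(quintile)) quintile <- rep_len(1:5, nr * nc)
  zone_set(ids, geoms, population = population, quintile = quintile)
}

# person-record rows with defaults; dates as strings for readability
person <- function(person_id, zone_id, entry = "2002-06-01", dfu = NA,
                   lea = NA, lea_level = NA, death = NA) {
  data.frame(person_id = person_id, zone_id = zone_id,
             entry_date = as.Date(entry), dfu_date = as.Date(dfu),
             lea_date = as.Date(lea), lea_level = as.character(lea_level),
             death_date = as.Date(death), stringsAsFactors = FALSE)
}

# independent brute-force Gi*: dense weights, explicit loops, no shared code
# with the package implementation
gi_star_dense <- function(x, nb, include_self = TRUE) {
  n <- length(x)
  z <- numeric(n)
  xbar <- sum(x) / n
  s <- sqrt(sum(x^2) / n - xbar^2)
  for (i in seq_len(n)) {
    w <- numeric(n)
    w[nb[[i]]] <- 1
    if (include_self) w[i] <- 1
    wi <- sum(w)
    num <- sum(w * x) - xbar * wi
    den <- s * sqrt((n * sum(w^2) - wi^2) / (n - 1))
    z[i] <- num / den
  }
  z
}

# random symmetric neighbour structure (no self links, not complete)
random_nb <- function(n, p = 0.3) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      adj[i, j] <- adj[j, i] <- stats::runif(1) < p
    }
  }
  lapply(seq_len(n), function(i) which(adj[i, ]))
}

make_weights <- function(nb, ids = NULL, include_self = TRUE) {
  if (is.null(ids)) ids <- as.character(seq_along(nb))
  geofoot:::new_zone_weights(ids, nb, scheme = "manual",
                             include_self = include_self)
}

# classification with a prescribed number of hot/cold zones (for summary
# arithmetic): hot zones get z = 3, cold z = -3, the rest 0
synthetic_classification <- function(n_hot, n_cold, n_total) {
  z <- c(rep(3, n_hot), rep(-3, n_cold), rep(0, n_total - n_hot - n_cold))
  classify_spots(z)
}
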