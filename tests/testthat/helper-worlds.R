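# Shared fixtures, all built in code at test time.

# small seeded world reused across tests (moderate noise, monsoonal)
test_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_climate(32, 32, seed = 42)
    cache
  }
})

# a constant-climate grid: every cell, every month identical
constant_grid <- function(tavg = 20, half_range = 5, prcp = 100,
                          nrow = 6, ncol = 6) {
  arr <- function(v) array(v, c(nrow, ncol, 12))
  climate_grid(arr(tavg), arr(tavg - half_range), arr(tavg + half_range),
               arr(prcp), matrix(TRUE, nrow, ncol))
}

# grid where cell climates are set directly from per-cell monthly vectors
grid_from_cells <- function(tavg_list, prcp_list, nrow, ncol) {
  tavg <- array(0, c(nrow, ncol, 12))
  prcp <- array(0, c(nrow, ncol, 12))
  i <- 1
  for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
    tavg[r, c, ] <- tavg_list[[i]]
    prcp[r, c, ] <- prcp_list[[i]]
    i <- i + 1
  }
  climate_grid(tavg, tavg - 5, tavg + 5, prcp, matrix(TRUE, nrow, ncol))
}

# localities at the centres of given cells
localities_at <- function(grid, rows, cols, species = "sp") {
  ll <- lonlat_from_cell(grid, rows, cols)
  tibble::tibble(id = sprintf("L%03d", seq_along(rows)),
                 lon = ll$lon, lat = ll$lat,
                 species = species, source = "native")
}

# independent O(n^3)-flavoured hull oracle: a point is a hull vertex iff it
# is not strictly inside the hull of the others; edges walked gift-wrap
# style. Slow and simple on purpose.
giftwrap_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3) return(pts)
  start <- which.min(pts[, 2] + pts[, 1] * 1e-9)  # lowest, then leftmost
  hull_idx <- start
  current <- start
  repeat {
    candidate <- if (current == 1) 2 else 1
    for (k in seq_len(n)) {
      if (k == current || k == candidate) next
      cr <- (pts[candidate, 1] - pts[current, 1]) * (pts[k, 2] - pts[current, 2]) -
        (pts[candidate, 2] - pts[current, 2]) * (pts[k, 1] - pts[current, 1])
      d_cand <- sum((pts[candidate, ] - pts[current, ])^2)
      d_k <- sum((pts[k, ] - pts[current, ])^2)
      if (cr > 1e-12 || (abs(cr) <= 1e-12 && d_k > d_cand)) candidate <- k
    }
    if (candidate == start) break
    hull_idx <- c(hull_idx, candidate)
    current <- candidate
    if (length(hull_idx) > n) stop("gift wrap failed")
  }
  pts[hull_idx, , drop = FALSE]
}

# canonical form of a polygon for comparison: vertices sorted, names dropped
canon_poly <- function(poly) {
  poly <- round(unname(`dimnames<-`(poly, NULL)), 9)
  poly[order(poly[, 1], poly[, 2]), , drop = FALSE]
}

# brute-force per-variable MESS similarity, written independently of the
# package implementation (loop + percentile count)
brute_mess <- function(v, ref) {
  rmin <- min(ref); rmax <- max(ref)
  f <- 100 * sum(ref < v) / length(ref)
  if (f == 0) 100 * (v - rmin) / (rmax - rmin)
  else if (f <= 50) 2 * f
  else if (f < 100) 2 * (100 - f)
  else 100 * (rmax - v) / (rmax - rmin)
}
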