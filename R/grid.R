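#' Monthly climate grid
#'
#' The central raster container of the package: a regular lon/lat lattice
#' carrying twelve months each of mean (`tavg`), minimum (`tmin`) and maximum
#' (`tmax`) temperature in degrees Celsius and precipitation (`prcp`) in
#' mm/month, plus a logical land mask. All bands share one lattice. Rows are
#' stored north to south (row 1 is the northernmost), columns west to east,
#' matching the on-disk layout of an ESRI ASCII grid.
#'
#' Units are enforced, never converted: temperatures must be plausible
#' degrees Celsius and precipitation non-negative mm/month. Cells violating
#' `tmin <= tavg <= tmax` are dropped from the land mask at construction.
#'
#' @param tavg,tmin,tmax Numeric arrays `c(nrow, ncol, 12)`, degrees Celsius.
#' @param prcp Numeric array `c(nrow, ncol, 12)`, mm/month, non-negative.
#' @param land Logical matrix `c(nrow, ncol)`; `TRUE` for land cells.
#' @param xmin,ymin Geographic coordinates (degrees) of the lower-left corner
#'   of the lattice.
#' @param cellsize Cell edge length in degrees.
#'
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(tavg, tmin, tmax, prcp, land,
                         xmin = 0, ymin = 0, cellsize = 1) {
  dims <- dim(tavg)
  if (length(dims) != 3L || dims[3] != 12L) {
    stop("climate bands must be <nrow x ncol x 12> arrays", call. = FALSE)
  }
  for (band in list(tmin, tmax, prcp)) {
    if (!identical(dim(band), dims)) {
      stop("all bands must share one lattice", call. = FALSE)
    }
  }
  if (!is.matrix(land) || !identical(dim(land), dims[1:2])) {
    stop("land mask must be a logical matrix on the same lattice", call. = FALSE)
  }
  if (any(prcp < 0, na.rm = TRUE)) {
    stop("precipitation must be non-negative mm/month", call. = FALSE)
  }
  # temperature ordering is an invariant, not a warning: offending cells are
  # removed from the land mask so no downstream op ever sees them
  bad <- matrix(FALSE, dims[1], dims[2])
  for (m in seq_len(12L)) {
    viol <- (tmin[, , m] > tavg[, , m]) | (tavg[, , m] > tmax[, , m])
    viol[is.na(viol)] <- TRUE
    bad <- bad | viol
  }
  structure(
    list(
      nrow = dims[1], ncol = dims[2],
      xmin = xmin, ymin = ymin, cellsize = cellsize,
      tavg = tavg, tmin = tmin, tmax = tmax, prcp = prcp,
      land = land & !bad,
      n_invalid = sum(land & bad)
    ),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(sprintf(
    "<climate_grid> %d x %d cells, cellsize %g deg, %d land cells\n",
    x$nrow, x$ncol, x$cellsize, sum(x$land)
  ))
  if (x$n_invalid > 0) {
    cat(sprintf("  %d cells dropped for tmin<=tavg<=tmax violations\n", x$n_invalid))
  }
  invisible(x)
}

#' @export
dim.climate_grid <- function(x) c(x$nrow, x$ncol)

grid_ymax <- function(grid) grid$ymin + grid$nrow * grid$cellsize

#' Map geographic coordinates to lattice cells
#'
#' Points are assigned under half-open cell intervals: a cell covers
#' `[x, x + cellsize)` in longitude and `(y - cellsize, y]` downward from its
#' top edge, so every in-bounds point belongs to exactly one cell and cell
#' centres map back to their own cell.
#'
#' @param grid A [climate_grid()] (or anything with the same lattice fields).
#' @param lon,lat Numeric vectors of coordinates in degrees.
#' @return A tibble with columns `row`, `col` (1-based; `NA` if out of
#'   bounds).
#' @export
cell_from_lonlat <- function(grid, lon, lat) {
  col <- floor((lon - grid$xmin) / grid$cellsize) + 1
  row <- floor((grid_ymax(grid) - lat) / grid$cellsize) + 1
  # the top edge of row 1 belongs to row 1 (closed northern boundary)
  row[lat == grid_ymax(grid)] <- 1
  oob <- row < 1 | row > grid$nrow | col < 1 | col > grid$ncol
  row[oob] <- NA_integer_
  col[oob] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Cell centres in geographic coordinates
#'
#' Inverse companion of [cell_from_lonlat()]: returns the centre of each
#' requested cell.
#'
#' @inheritParams cell_from_lonlat
#' @param row,col Integer vectors of 1-based cell indices.
#' @return A tibble with columns `lon`, `lat`.
#' @export
lonlat_from_cell <- function(grid, row, col) {
  tibble::tibble(
    lon = grid$xmin + (col - 0.5) * grid$cellsize,
    lat = grid_ymax(grid) - (row - 0.5) * grid$cellsize
  )
}

#' Region masks
#'
#' A region mask is a logical matrix on the lattice of a [climate_grid()];
#' used for native ranges, biotic suitability, background regions and
#' implausible-region screens.
#'
#' @param grid A [climate_grid()].
#' @param value Logical scalar or matrix used to fill the mask.
#' @return A logical `nrow x ncol` matrix.
#' @export
region_mask <- function(grid, value = FALSE) {
  if (is.matrix(value)) {
    stopifnot(identical(dim(value), c(grid$nrow, grid$ncol)))
    return(value & TRUE)
  }
  matrix(isTRUE(value), grid$nrow, grid$ncol)
}

assert_same_lattice <- function(grid, mask, what = "mask") {
  if (!identical(dim(mask), c(grid$nrow, grid$ncol))) {
    stop(sprintf("%s is not on the grid's lattice", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Distance to coast in cell units
#'
#' Breadth-first search from every land cell that touches a sea cell
#' (4-neighbourhood). Sea cells get `NA`; coastal land cells get 1.
#'
#' @param grid A [climate_grid()].
#' @return An integer matrix of cell-count distances.
#' @export
coast_distance <- function(grid) {
  land <- grid$land
  nr <- nrow(land); nc <- ncol(land)
  dist <- matrix(NA_integer_, nr, nc)
  # seed queue: land cells adjacent to sea (or to the lattice edge, which we
  # treat as sea so distance is always defined)
  is_coastal <- function(r, c) {
    (r == 1 || !land[r - 1, c]) || (r == nr || !land[r + 1, c]) ||
      (c == 1 || !land[r, c - 1]) || (c == nc || !land[r, c + 1])
  }
  queue_r <- integer(0); queue_c <- integer(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (land[r, c] && is_coastal(r, c)) {
      dist[r, c] <- 1L
      queue_r <- c(queue_r, r); queue_c <- c(queue_c, c)
    }
  }
  head <- 1L
  while (head <= length(queue_r)) {
    r <- queue_r[head]; c <- queue_c[head]; head <- head + 1L
    d <- dist[r, c]
    for (step in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + step[1]; cc <- c + step[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          land[rr, cc] && is.na(dist[rr, cc])) {
        dist[rr, cc] <- d + 1L
        queue_r <- c(queue_r, rr); queue_c <- c(queue_c, cc)
      }
    }
  }
  dist
}

#' Connected component of a mask reachable from a seed cell
#'
#' Flood fill under 4-connectivity, used to model dispersal access.
#'
#' @param mask Logical matrix of traversable cells.
#' @param seed_row,seed_col Seed cell (1-based).
#' @return Logical matrix: the component of `mask` containing the seed, or an
#'   all-`FALSE` mask (with a warning) if the seed is not traversable.
#' @export
flood_fill <- function(mask, seed_row, seed_col) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!isTRUE(mask[seed_row, seed_col])) {
    warning("seed cell is not in the mask; returning empty component")
    return(out)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  queue_r <- seed_row; queue_c <- seed_col
  out[seed_row, seed_col] <- TRUE
  head <- 1L
  while (head <= length(queue_r)) {
    r <- queue_r[head]; c <- queue_c[head]; head <- head + 1L
    for (step in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + step[1]; cc <- c + step[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
          mask[rr, cc] && !out[rr, cc]) {
        out[rr, cc] <- TRUE
        queue_r <- c(queue_r, rr); queue_c <- c(queue_c, cc)
      }
    }
  }
  out
}
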