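#' Read and write single-band ESRI ASCII grids
#'
#' Plain-text raster interchange: a six-line header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' cell values, northernmost row first. Values are written at full double
#' precision so write/read round-trips are exact.
#'
#' @param path File path.
#' @return For `read_esri_ascii`, a list with `data` (numeric matrix, row 1 =
#'   north), `xmin`, `ymin`, `cellsize`, `nodata`.
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop(sprintf("malformed ESRI ASCII header in %s", path), call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]]
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop(sprintf("expected %d cells, found %d in %s",
                 hdr$ncols * hdr$nrows, length(vals), path), call. = FALSE)
  }
  data <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(nodata)) data[data == nodata] <- NA_real_
  list(data = data, xmin = hdr$xllcorner, ymin = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

#' @rdname read_esri_ascii
#' @param data Numeric matrix, row 1 = northernmost row.
#' @param xmin,ymin Lower-left corner in degrees.
#' @param cellsize Cell size in degrees.
#' @param nodata Value written for `NA` cells.
#' @export
write_esri_ascii <- function(data, path, xmin = 0, ymin = 0, cellsize = 1,
                             nodata = -9999) {
  stopifnot(is.matrix(data))
  out <- data
  out[is.na(out)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(data)),
    sprintf("nrows %d", nrow(data)),
    sprintf("xllcorner %.10g", xmin),
    sprintf("yllcorner %.10g", ymin),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(out, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

monthly_band_path <- function(prefix, var, month) {
  sprintf("%s_%s_%02d.asc", prefix, var, month)
}

#' Read a monthly climate stack from ESRI ASCII bands
#'
#' Expects 49 files sharing a path prefix: `<prefix>_<var>_<mm>.asc` for
#' `var` in `tavg`, `tmin`, `tmax`, `prcp` and `mm` in `01..12`, plus
#' `<prefix>_land.asc` holding the 0/1 land mask. Units are checked, never
#' rescaled: temperatures outside [-90, 60] degrees C (e.g. tenths of a
#' degree as some archives ship) raise an explicit unit error, as does
#' negative precipitation.
#'
#' @param prefix Path prefix shared by all band files.
#' @return A [climate_grid()]. Cells whose bands violate
#'   `tmin <= tavg <= tmax` are excluded from the land mask.
#' @export
read_monthly_raster <- function(prefix) {
  land_band <- read_esri_ascii(paste0(prefix, "_land.asc"))
  nr <- nrow(land_band$data); nc <- ncol(land_band$data)
  read_var <- function(var) {
    arr <- array(NA_real_, c(nr, nc, 12))
    for (m in 1:12) {
      p <- monthly_band_path(prefix, var, m)
      if (!file.exists(p)) {
        stop(sprintf("missing band: %s (12 monthly bands per variable required)", p),
             call. = FALSE)
      }
      band <- read_esri_ascii(p)
      if (nrow(band$data) != nr || ncol(band$data) != nc) {
        stop(sprintf("band %s is not on the shared lattice", p), call. = FALSE)
      }
      arr[, , m] <- band$data
    }
    arr
  }
  tavg <- read_var("tavg"); tmin <- read_var("tmin")
  tmax <- read_var("tmax"); prcp <- read_var("prcp")
  land <- !is.na(land_band$data) & land_band$data != 0
  for (nm in c("tavg", "tmin", "tmax")) {
    vals <- get(nm)[rep(land, 12)]
    vals <- vals[!is.na(vals)]
    if (length(vals) && (max(vals) > 60 || min(vals) < -90)) {
      stop(sprintf(
        "%s values outside [-90, 60]: temperatures must be degrees C, not tenths; no auto-rescale",
        nm), call. = FALSE)
    }
  }
  if (any(prcp[rep(land, 12)] < 0, na.rm = TRUE)) {
    stop("negative precipitation: units must be mm/month", call. = FALSE)
  }
  climate_grid(tavg, tmin, tmax, prcp, land,
               xmin = land_band$xmin, ymin = land_band$ymin,
               cellsize = land_band$cellsize)
}

#' Write a monthly climate stack as ESRI ASCII bands
#'
#' Companion of [read_monthly_raster()]; writes the 48 monthly bands and the
#' land mask under one path prefix.
#'
#' @param grid A [climate_grid()].
#' @param prefix Path prefix for the band files.
#' @export
write_monthly_raster <- function(grid, prefix) {
  for (var in c("tavg", "tmin", "tmax", "prcp")) {
    for (m in 1:12) {
      band <- grid[[var]][, , m]
      band[!grid$land] <- NA_real_
      write_esri_ascii(band, monthly_band_path(prefix, var, m),
                       xmin = grid$xmin, ymin = grid$ymin,
                       cellsize = grid$cellsize)
    }
  }
  write_esri_ascii(grid$land + 0, paste0(prefix, "_land.asc"),
                   xmin = grid$xmin, ymin = grid$ymin,
                   cellsize = grid$cellsize, nodata = -9999)
  invisible(prefix)
}

#' Read a locality table
#'
#' Localities are presence records: `id`, `lon`, `lat`, `species` and an
#' optional `source` tag. With `collapse = TRUE` and a reference grid,
#' duplicate records falling in one raster cell are collapsed to the
#' first-read record, the usual thinning applied to museum records so that
#' each ~pixel contributes one point.
#'
#' @param path CSV file with header `id,lon,lat,species[,source]`.
#' @param collapse Collapse multiple localities per grid cell to the first?
#' @param grid A [climate_grid()]; required when `collapse = TRUE`.
#' @return A tibble with columns `id`, `lon`, `lat`, `species`, `source`.
#' @export
read_localities <- function(path, collapse = FALSE, grid = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("id", "lon", "lat", "species")
  if (!all(need %in% names(df))) {
    stop("locality CSV must have header id,lon,lat,species[,source]", call. = FALSE)
  }
  if (!"source" %in% names(df)) df$source <- "unknown"
  df <- tibble::as_tibble(df[c("id", "lon", "lat", "species", "source")])
  df$id <- as.character(df$id)
  bad <- which(df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90 |
                 is.na(df$lon) | is.na(df$lat))
  if (length(bad)) {
    stop(sprintf("out-of-range coordinates at data row(s) %s (file line %s)",
                 paste(bad, collapse = ", "),
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("locality ids must be unique within a table", call. = FALSE)
  }
  if (collapse) {
    if (is.null(grid)) stop("collapse = TRUE requires a reference grid", call. = FALSE)
    cells <- cell_from_lonlat(grid, df$lon, df$lat)
    key <- paste(cells$row, cells$col)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df
}

#' @rdname read_localities
#' @param localities A locality tibble.
#' @export
write_localities <- function(localities, path) {
  readr::write_csv(localities, path)
  invisible(path)
}

#' Suitability maps
#'
#' A suitability map is a classification of every cell of a lattice into
#' unsuitable (0), suitable (1) and — kept deliberately distinct — novel
#' climate (2), i.e. conditions outside the range used to build the model.
#' Novelty is information about extrapolation, not a suitability verdict, so
#' the two are never conflated in the encoding.
#'
#' @param grid A [climate_grid()] supplying the lattice.
#' @param suitable Logical matrix of suitable cells.
#' @param novel Optional logical matrix of novel-climate cells.
#' @return An object of class `suitability_map` (a list with the lattice
#'   fields and an integer `values` matrix; sea cells are `NA`).
#' @export
suitability_map <- function(grid, suitable, novel = NULL) {
  assert_same_lattice(grid, suitable, "suitability matrix")
  values <- matrix(0L, grid$nrow, grid$ncol)
  values[suitable] <- 1L
  if (!is.null(novel)) {
    assert_same_lattice(grid, novel, "novel mask")
    values[novel] <- 2L
  }
  values[!grid$land] <- NA_integer_
  structure(
    list(values = values, nrow = grid$nrow, ncol = grid$ncol,
         xmin = grid$xmin, ymin = grid$ymin, cellsize = grid$cellsize),
    class = "suitability_map"
  )
}

#' @export
print.suitability_map <- function(x, ...) {
  tab <- table(factor(x$values, levels = 0:2,
                      labels = c("unsuitable", "suitable", "novel")))
  cat("<suitability_map>", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname suitability_map
#' @param map A `suitability_map`.
#' @param path Output .asc path.
#' @param template Optional [climate_grid()]; if supplied, the map's lattice
#'   must match it.
#' @export
write_suitability <- function(map, path, template = NULL) {
  if (!is.null(template)) {
    if (map$nrow != template$nrow || map$ncol != template$ncol ||
        map$cellsize != template$cellsize) {
      stop("suitability map lattice does not match the template grid", call. = FALSE)
    }
  }
  write_esri_ascii(map$values, path, xmin = map$xmin, ymin = map$ymin,
                   cellsize = map$cellsize, nodata = -9999)
  invisible(path)
}

#' @rdname suitability_map
#' @export
read_suitability <- function(path) {
  band <- read_esri_ascii(path)
  structure(
    list(values = matrix(as.integer(band$data), nrow(band$data), ncol(band$data)),
         nrow = nrow(band$data), ncol = ncol(band$data),
         xmin = band$xmin, ymin = band$ymin, cellsize = band$cellsize),
    class = "suitability_map"
  )
}

#' Tidy a suitability map into a cell table
#'
#' @param x A `suitability_map`.
#' @param ... Unused.
#' @return A tibble with `row`, `col`, `lon`, `lat`, `status` (factor:
#'   unsuitable/suitable/novel), land cells only.
#' @export
tidy.suitability_map <- function(x, ...) {
  idx <- which(!is.na(x$values), arr.ind = TRUE)
  ll <- lonlat_from_cell(x, idx[, 1], idx[, 2])
  tibble::tibble(
    row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
    lon = ll$lon, lat = ll$lat,
    status = factor(x$values[idx], levels = 0:2,
                    labels = c("unsuitable", "suitable", "novel"))
  )
}
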