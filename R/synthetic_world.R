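#' Seeded synthetic climate world
#'
#' Generates a monthly climate grid with the statistical structure the
#' downstream methods assume: a latitudinal temperature gradient with
#' seasonality growing poleward, a monsoonal precipitation regime whose
#' seasonal concentration grows with `monsoon_strength`, spatially smooth
#' noise fields, and a land/sea split with a lobed vertical coastline so that
#' distance-to-coast is defined everywhere.
#'
#' The domain spans latitudes `lat_range[1]` (southern edge) to
#' `lat_range[2]`; monthly mean temperature at a cell is
#' `base(lat) + amp(lat) * cos(2*pi*(m - 7)/12) + noise`, i.e. July-peaking
#' seasonality, with `base` decreasing linearly poleward and `amp`
#' proportional to latitude. `tmin`/`tmax` are `tavg` minus/plus a diurnal
#' half-range that grows inland (continentality). Precipitation follows an
#' August-peaking monsoon: monthly shares proportional to
#' `exp(monsoon_strength * cos(2*pi*(m - 8)/12))`, scaled by an annual total
#' that decays poleward, floored at zero after noise.
#'
#' @param width,height Lattice size in cells.
#' @param seasonal_amplitude Peak-to-mean seasonal temperature swing (deg C)
#'   at the poleward edge; 0 gives 12 identical months.
#' @param monsoon_strength Concentration of rainfall in the wet season
#'   (0 = uniform through the year).
#' @param noise_sd Standard deviation (after smoothing) of the spatial noise
#'   added to each climate field.
#' @param seed Integer RNG seed; same seed, same world.
#' @param lat_range Latitudes (degrees) of the south and north domain edges.
#' @param land_fraction Approximate fraction of columns that are land
#'   (land lies to the west, sea to the east, with seeded coastal lobes).
#' @return A [climate_grid()].
#' @export
generate_climate <- function(width, height,
                             seasonal_amplitude = 8,
                             monsoon_strength = 2,
                             noise_sd = 0.5,
                             seed = 1,
                             lat_range = c(5, 45),
                             land_fraction = 0.65) {
  stopifnot(width >= 4, height >= 4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  cellsize <- (lat_range[2] - lat_range[1]) / height
  lat <- lat_range[2] - (seq_len(height) - 0.5) * cellsize  # row 1 = north
  lat_frac <- (lat - lat_range[1]) / (lat_range[2] - lat_range[1])

  # lobed vertical coastline: land in columns <= coast(r)
  base_coast <- land_fraction * width
  lobe <- 0.12 * width * sin(2 * pi * seq_len(height) / height * stats::runif(1, 1, 3) +
                               stats::runif(1, 0, 2 * pi))
  coast_col <- pmin(width - 1, pmax(2, round(base_coast + lobe)))
  land <- matrix(FALSE, height, width)
  for (r in seq_len(height)) land[r, seq_len(coast_col[r])] <- TRUE

  noise_field <- function(sd) {
    if (sd <= 0) return(matrix(0, height, width))
    smooth_field(matrix(stats::rnorm(height * width), height, width), passes = 3) * sd
  }

  months <- 1:12
  t_base <- 28 - 18 * lat_frac              # warm equatorward edge, cool poleward
  t_amp <- seasonal_amplitude * lat_frac    # seasonality grows poleward
  # one smooth anomaly field per month: monthly climates vary around the
  # seasonal cycle independently, as real monthly normals do
  t_noise_m <- lapply(months, function(m) noise_field(noise_sd))
  dcoast <- {
    g0 <- list(land = land)
    d <- coast_distance(structure(g0, class = "climate_grid"))
    d[is.na(d)] <- 0L
    d
  }
  continentality <- dcoast / max(1, max(dcoast))
  half_range <- 4 + 4 * continentality      # diurnal half-range, deg C

  tavg <- array(0, c(height, width, 12))
  tmin <- tmax <- tavg
  for (m in months) {
    season <- cos(2 * pi * (m - 7) / 12)
    field <- matrix(t_base, height, width) +
      matrix(t_amp, height, width) * season + t_noise_m[[m]]
    tavg[, , m] <- field
    tmin[, , m] <- field - half_range
    tmax[, , m] <- field + half_range
  }

  annual_p <- 1800 - 1200 * lat_frac        # mm/yr, wetter equatorward
  share <- exp(monsoon_strength * cos(2 * pi * (months - 8) / 12))
  share <- share / sum(share)
  prcp <- array(0, c(height, width, 12))
  for (m in months) {
    p_noise <- noise_field(noise_sd * 8)
    prcp[, , m] <- pmax(0, matrix(annual_p, height, width) * share[m] + p_noise)
  }

  climate_grid(tavg, tmin, tmax, prcp, land,
               xmin = 0, ymin = lat_range[1], cellsize = cellsize)
}

# separable box-smoothing of a matrix (reflecting edges); repeated passes
# approximate a Gaussian kernel. Rescaled to unit SD so callers control
# amplitude directly.
smooth_field <- function(x, passes = 3, radius = 2) {
  k <- rep(1, 2 * radius + 1)
  sm1 <- function(v) {
    padded <- c(rev(v[seq_len(radius)]), v, rev(v[length(v) - seq_len(radius) + 1]))
    stats::filter(padded, k / length(k), sides = 2)[(radius + 1):(radius + length(v))]
  }
  for (i in seq_len(passes)) {
    x <- t(apply(x, 1, sm1))
    x <- apply(x, 2, sm1)
  }
  s <- stats::sd(as.vector(x))
  if (s > 0) x <- x / s
  x
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Define a virtual species
#'
#' A virtual species is specified directly in climate space: a convex
#' fundamental polygon in (mean monthly temperature deg C, log10
#' precipitation mm/month), true hibernation and aestivation tolerances in
#' months, an access seed cell from which the species can disperse, and a
#' biotic-suitability mask. Its realized range is then a derived quantity,
#' never an input.
#'
#' @param fundamental_polygon Two-column matrix (t, p_log) of polygon
#'   vertices; its convex hull is used. Must have positive area.
#' @param h_true,a_true True tolerated months of hibernation (coldest) and
#'   aestivation (hottest); `h_true + a_true <= 11`.
#' @param access_seed Length-2 integer vector `c(row, col)`.
#' @param biotic_mask Logical matrix; `NULL` means biotically suitable
#'   everywhere.
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(fundamental_polygon, h_true = 3, a_true = 0,
                            access_seed, biotic_mask = NULL) {
  stopifnot(is.matrix(fundamental_polygon), ncol(fundamental_polygon) == 2)
  hull <- convex_hull(fundamental_polygon)
  if (nrow(hull) < 3) stop("fundamental polygon is degenerate", call. = FALSE)
  if (h_true < 0 || a_true < 0 || h_true + a_true > 11) {
    stop("need 0 <= h_true + a_true <= 11", call. = FALSE)
  }
  structure(
    list(fundamental_polygon = hull, h_true = h_true, a_true = a_true,
         access_seed = as.integer(access_seed), biotic_mask = biotic_mask),
    class = "virtual_species"
  )
}

#' Default virtual species for a generated world
#'
#' Builds the fundamental polygon from climate quantiles of the world's land
#' cells so the species occupies a substantial but bounded part of climate
#' space, places the access seed at the most suitable coastal cell, and
#' (optionally) withholds a northern band biotically.
#'
#' @param grid A [climate_grid()].
#' @param h_true,a_true Tolerances passed to [virtual_species()].
#' @param biotic Either `NULL` (favourable everywhere) or a logical matrix.
#' @return A `virtual_species`.
#' @export
default_species <- function(grid, h_true = 3, a_true = 0, biotic = NULL) {
  pts <- land_climate_points(grid)
  tq <- stats::quantile(pts$t, c(0.25, 0.95))
  pq <- stats::quantile(pts$p_log, c(0.15, 0.95))
  poly <- cbind(
    t = c(tq[1], tq[2], tq[2], tq[1]),
    p_log = c(pq[1], pq[1], pq[2], pq[2])
  )
  sp <- virtual_species(poly, h_true, a_true, access_seed = c(1L, 1L),
                        biotic_mask = biotic)
  suit <- climatic_suitability(sp$fundamental_polygon, grid, h_true, a_true)
  if (!is.null(biotic)) suit <- suit & biotic
  if (!any(suit)) stop("species polygon matches no land cell", call. = FALSE)
  # seed dispersal from the largest contiguous suitable region: a species'
  # occupied range is its main landmass block, not a peripheral outlier cell
  remaining <- suit
  best <- NULL
  while (any(remaining)) {
    cell <- which(remaining, arr.ind = TRUE)[1, ]
    comp <- flood_fill(remaining, cell[1], cell[2])
    if (is.null(best) || sum(comp) > sum(best)) best <- comp
    remaining <- remaining & !comp
  }
  sp$access_seed <- as.integer(which(best, arr.ind = TRUE)[1, ])
  sp
}

# all land cell-month points in (t, log10 prcp) space
land_climate_points <- function(grid) {
  cells <- which(grid$land, arr.ind = TRUE)
  t <- as.vector(vapply(1:12, function(m) grid$tavg[, , m][cells], numeric(nrow(cells))))
  p <- as.vector(vapply(1:12, function(m) grid$prcp[, , m][cells], numeric(nrow(cells))))
  tibble::tibble(t = t, p_log = log10(pmax(p, 0.1)))
}

# cells whose every active month (after h/a exclusion) lies in the polygon
climatic_suitability <- function(polygon, grid, h, a) {
  cells <- which(grid$land, arr.ind = TRUE)
  suit <- matrix(FALSE, grid$nrow, grid$ncol)
  if (nrow(cells) == 0) return(suit)
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, 1]; c <- cells[i, 2]
    tv <- grid$tavg[r, c, ]
    pv <- log10(pmax(grid$prcp[r, c, ], 0.1))
    act <- active_months(tv, h, a)
    suit[r, c] <- all(points_in_hull(cbind(tv[act], pv[act]), polygon))
  }
  suit
}

#' Fundamental climate envelope of a virtual species
#'
#' Wraps the species' known fundamental polygon as a climate envelope under
#' its true tolerances, so it can be projected and compared with envelopes
#' estimated from sampled localities.
#'
#' @param species A [virtual_species()].
#' @return A `climate_envelope`.
#' @export
fundamental_envelope <- function(species) {
  hull <- species$fundamental_polygon
  colnames(hull) <- c("t", "p_log")
  structure(
    list(hull = hull, h = species$h_true, a = species$a_true,
         source_count = 0L, prcp_floor = 0.1),
    class = "climate_envelope"
  )
}

#' Realized range of a virtual species
#'
#' The realized range is the intersection of climatic suitability under the
#' species' (or an overridden) hibernation/aestivation hypothesis, the
#' biotic mask, and the set of cells reachable from the access seed through
#' suitable-and-biotic cells (4-connectivity) — fundamental climate space
#' cut down by biotic and access constraints.
#'
#' @param species A [virtual_species()].
#' @param grid A [climate_grid()].
#' @param h,a Hypothesis override; defaults to the species' true tolerances.
#' @return A logical region mask.
#' @export
realized_range <- function(species, grid, h = species$h_true, a = species$a_true) {
  suit <- climatic_suitability(species$fundamental_polygon, grid, h, a)
  biotic <- species$biotic_mask
  if (is.null(biotic)) biotic <- matrix(TRUE, grid$nrow, grid$ncol)
  assert_same_lattice(grid, biotic, "biotic mask")
  traversable <- suit & biotic
  if (!traversable[species$access_seed[1], species$access_seed[2]]) {
    warning("access seed cell is not suitable; realized range is empty")
    return(matrix(FALSE, grid$nrow, grid$ncol))
  }
  flood_fill(traversable, species$access_seed[1], species$access_seed[2])
}

#' Contaminant region: a ring around the realized range
#'
#' Default stand-in for a sister species' adjacent range: land cells within
#' `width` cells (Chebyshev dilation) of the realized range but outside it.
#' By adjacency its climate largely overlaps the focal species' envelope,
#' which is exactly what makes such mislabeled records hard to spot.
#'
#' @param grid A [climate_grid()].
#' @param realized Logical realized-range mask.
#' @param width Ring width in cells.
#' @return A logical mask.
#' @export
contaminant_region <- function(grid, realized, width = 2) {
  dil <- realized
  for (i in seq_len(width)) {
    grown <- dil
    nr <- nrow(dil); nc <- ncol(dil)
    grown[-1, ] <- grown[-1, ] | dil[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | dil[-1, ]
    grown[, -1] <- grown[, -1] | dil[, -nc]
    grown[, -nc] <- grown[, -nc] | dil[, -1]
    dil <- grown
  }
  dil & !realized & grid$land
}

#' Draw collection localities with coastal bias and contamination
#'
#' Emulates museum collection records: cells of the realized range are drawn
#' with probability proportional to `exp(-d_coast / coastal_bias_scale)`
#' (records cluster near coasts and ports), and a fraction
#' `floor(error_rate * n)` of records is drawn from a sister-species region
#' and mislabeled with the focal species name. Ground truth is preserved in
#' the `source` column (`"native"` vs `"contaminant"`), which a real analyst
#' would not have.
#'
#' @param species A [virtual_species()].
#' @param grid A [climate_grid()].
#' @param n Number of localities.
#' @param coastal_bias_scale Decay length (cells) of collection probability
#'   with distance from coast; `Inf` gives uniform sampling.
#' @param error_rate Fraction of records drawn from the contaminant region.
#' @param seed RNG seed.
#' @param contaminant_mask Mask of the sister-species region; defaults to
#'   [contaminant_region()] of the realized range.
#' @param species_name Label written into the `species` column.
#' @return A locality tibble (`id`, `lon`, `lat`, `species`, `source`).
#' @export
sample_localities <- function(species, grid, n,
                              coastal_bias_scale = 6,
                              error_rate = 0,
                              seed = 1,
                              contaminant_mask = NULL,
                              species_name = "virtualis") {
  stopifnot(n >= 1, error_rate >= 0, error_rate < 1)
  realized <- realized_range(species, grid)
  if (!any(realized)) stop("realized range is empty", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  dcoast <- coast_distance(grid)
  n_err <- floor(error_rate * n)
  n_native <- n - n_err

  draw_from <- function(mask, k) {
    cells <- which(mask, arr.ind = TRUE)
    w <- if (is.infinite(coastal_bias_scale)) {
      rep(1, nrow(cells))
    } else {
      exp(-dcoast[cells] / coastal_bias_scale)
    }
    idx <- sample.int(nrow(cells), k, replace = TRUE, prob = w)
    cells[idx, , drop = FALSE]
  }

  native_cells <- draw_from(realized, n_native)
  rows <- native_cells[, 1]; cols <- native_cells[, 2]
  src <- rep("native", n_native)
  if (n_err > 0) {
    cmask <- contaminant_mask
    if (is.null(cmask)) cmask <- contaminant_region(grid, realized)
    if (!any(cmask)) stop("contaminant region is empty", call. = FALSE)
    err_cells <- draw_from(cmask, n_err)
    rows <- c(rows, err_cells[, 1]); cols <- c(cols, err_cells[, 2])
    src <- c(src, rep("contaminant", n_err))
  }
  # jitter within the cell so coordinates are point-like, not lattice-like
  u <- stats::runif(length(rows), 0.05, 0.95)
  v <- stats::runif(length(rows), 0.05, 0.95)
  lon <- grid$xmin + (cols - 1 + u) * grid$cellsize
  lat <- grid_ymax(grid) - (rows - 1 + v) * grid$cellsize
  tibble::tibble(
    id = sprintf("loc%04d", seq_along(rows)),
    lon = lon, lat = lat,
    species = species_name,
    source = src
  )
}
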