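#' Convex hull of climate points
#'
#' Returns the minimum convex polygon of a 2-column point matrix as its
#' vertices in counter-clockwise order, duplicates and collinear interior
#' vertices removed.
#'
#' @param points Two-column numeric matrix.
#' @return A two-column matrix of hull vertices (CCW), possibly with fewer
#'   than 3 rows when the input is degenerate.
#' @export
convex_hull <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2)
  pts <- unique(points[stats::complete.cases(points), , drop = FALSE])
  if (nrow(pts) < 3) return(pts)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[idx, , drop = FALSE]
  # chull returns clockwise order; flip to CCW if needed
  if (signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  drop_collinear(hull)
}

signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

drop_collinear <- function(hull, tol = 1e-12) {
  n <- nrow(hull)
  if (n < 3) return(hull)
  scale <- max(abs(hull), 1)
  keep <- vapply(seq_len(n), function(i) {
    a <- hull[if (i == 1) n else i - 1, ]
    b <- hull[i, ]
    c <- hull[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    abs(cross) > tol * scale^2
  }, logical(1))
  hull[keep, , drop = FALSE]
}

#' Test points against a convex polygon (boundary inclusive)
#'
#' @param points Two-column matrix of query points.
#' @param hull Two-column matrix of convex polygon vertices in CCW order.
#' @return Logical vector; `TRUE` when inside or on the boundary.
#' @export
points_in_hull <- function(points, hull) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  n <- nrow(hull)
  if (n < 3) {
    # degenerate hull: containment only for coincident points / on-segment
    if (n == 0) return(rep(FALSE, nrow(points)))
    if (n == 1) {
      return(abs(points[, 1] - hull[1, 1]) < 1e-12 &
               abs(points[, 2] - hull[1, 2]) < 1e-12)
    }
    return(on_segment(points, hull[1, ], hull[2, ]))
  }
  eps <- 1e-9 * max(abs(hull), 1)^2
  inside <- rep(TRUE, nrow(points))
  for (i in seq_len(n)) {
    a <- hull[i, ]
    b <- hull[if (i == n) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (points[, 2] - a[2]) -
      (b[2] - a[2]) * (points[, 1] - a[1])
    inside <- inside & (cross >= -eps)
  }
  inside
}

on_segment <- function(points, a, b) {
  cross <- (b[1] - a[1]) * (points[, 2] - a[2]) - (b[2] - a[2]) * (points[, 1] - a[1])
  dot <- (points[, 1] - a[1]) * (b[1] - a[1]) + (points[, 2] - a[2]) * (b[2] - a[2])
  len2 <- sum((b - a)^2)
  abs(cross) < 1e-9 * max(len2, 1) & dot >= 0 & dot <= len2
}

#' Monthly climate-space points for localities
#'
#' Maps each locality to its grid cell and returns the twelve (temperature,
#' log10 precipitation) points, one per month. Precipitation is floored at
#' `prcp_floor` mm/month before the log so dry months stay finite;
#' the default 0.1 matches the resolution of the climate-space area grid.
#'
#' @param localities Locality tibble (`id`, `lon`, `lat`, ...).
#' @param grid A [climate_grid()].
#' @param prcp_floor Precipitation floor in mm/month.
#' @return A tibble with columns `id`, `month`, `t`, `p_log`.
#' @export
locality_monthly_points <- function(localities, grid, prcp_floor = 0.1) {
  cells <- cell_from_lonlat(grid, localities$lon, localities$lat)
  off <- is.na(cells$row) | !grid$land[cbind(cells$row, cells$col)]
  if (any(off)) {
    stop(sprintf("locality on sea/no-data cell: %s",
                 paste(localities$id[off], collapse = ", ")), call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(localities)), function(i) {
    r <- cells$row[i]; c <- cells$col[i]
    tibble::tibble(
      id = localities$id[i],
      month = 1:12,
      t = grid$tavg[r, c, ],
      p_log = log10(pmax(grid$prcp[r, c, ], prcp_floor))
    )
  })
}

#' Activity-season months under a hibernation/aestivation hypothesis
#'
#' Removes the consecutive (circular) block of `h` months with the lowest
#' mean temperature (hibernation) and then, from the remaining arc, the
#' consecutive block of `a` months with the highest mean temperature
#' (aestivation). Ties are broken by the earliest starting month. The two
#' blocks may abut, merging into one long inactive season.
#'
#' @param t Numeric vector of 12 monthly temperatures.
#' @param h,a Months of hibernation and aestivation; `h + a <= 11`.
#' @return Sorted integer vector of the `12 - h - a` active months.
#' @export
active_months <- function(t, h, a) {
  stopifnot(length(t) == 12, h >= 0, a >= 0, h + a <= 11)
  months <- 1:12
  hib <- integer(0)
  if (h > 0) {
    hib <- best_window(t, h, which.fn = min)
  }
  aest <- integer(0)
  if (a > 0) {
    remaining <- setdiff(months, hib)
    aest <- best_window(t, a, which.fn = max, allowed = remaining)
  }
  sort(setdiff(months, c(hib, aest)))
}

# circular k-month window optimizing mean t; earliest start wins ties.
# `allowed`: window must lie entirely within these months.
best_window <- function(t, k, which.fn, allowed = 1:12) {
  best_start <- NA_integer_
  best_val <- NA_real_
  for (s in 1:12) {
    win <- ((s - 1 + 0:(k - 1)) %% 12) + 1
    if (!all(win %in% allowed)) next
    v <- mean(t[win])
    better <- if (is.na(best_val)) TRUE else {
      if (identical(which.fn, min)) v < best_val - 1e-12 else v > best_val + 1e-12
    }
    if (better) {
      best_val <- v
      best_start <- s
    }
  }
  if (is.na(best_start)) stop("no admissible window", call. = FALSE)
  ((best_start - 1 + 0:(k - 1)) %% 12) + 1
}

#' Build a climate envelope from localities
#'
#' The rule-based climate-matching model: each locality contributes its
#' active-season monthly points (its own hibernation/aestivation months
#' excluded, the same rule later used in projection), and the envelope is
#' the minimum convex polygon of the pooled points. Duplicate localities add
#' duplicate points and therefore never change the hull — the method has no
#' central-tendency weighting, so only *divergent* climates enlarge it.
#'
#' @param localities Locality tibble.
#' @param grid A [climate_grid()].
#' @param h,a Hypothesized months of hibernation/aestivation.
#' @param prcp_floor Precipitation floor (mm/month) before log10.
#' @return An object of class `climate_envelope` with fields `hull` (CCW
#'   vertex matrix), `h`, `a`, `source_count`, `prcp_floor`.
#' @export
build_envelope <- function(localities, grid, h = 0, a = 0, prcp_floor = 0.1) {
  pts <- locality_monthly_points(localities, grid, prcp_floor)
  active <- pts |>
    dplyr::group_by(.data$id) |>
    dplyr::filter(.data$month %in% active_months(.data$t, h, a)) |>
    dplyr::ungroup()
  hull <- convex_hull(cbind(active$t, active$p_log))
  if (nrow(hull) < 3) {
    stop("degenerate envelope: all active-month climate points are collinear",
         call. = FALSE)
  }
  colnames(hull) <- c("t", "p_log")
  structure(
    list(hull = hull, h = h, a = a,
         source_count = nrow(localities), prcp_floor = prcp_floor),
    class = "climate_envelope"
  )
}

#' @export
print.climate_envelope <- function(x, ...) {
  cat(sprintf(
    "<climate_envelope> %d vertices, h = %d, a = %d, %d localities, area %d cells\n",
    nrow(x$hull), x$h, x$a, x$source_count, envelope_area(x)
  ))
  invisible(x)
}

#' Tidy a climate envelope into its vertex table
#'
#' @param x A `climate_envelope`.
#' @param ... Unused.
#' @return A tibble `vertex`, `t`, `p_log` in CCW order.
#' @export
tidy.climate_envelope <- function(x, ...) {
  tibble::tibble(vertex = seq_len(nrow(x$hull)),
                 t = x$hull[, "t"], p_log = x$hull[, "p_log"])
}

#' Plot a climate envelope in climate space
#'
#' The minimum convex polygon in (temperature, log10 precipitation) space,
#' optionally over the monthly climate points it was built from.
#'
#' @param object A `climate_envelope`.
#' @param points Optional tibble of climate points (columns `t`, `p_log`)
#'   drawn underneath, e.g. from [locality_monthly_points()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.climate_envelope <- function(object, points = NULL, ...) {
  hull_df <- tidy(object)
  p <- ggplot2::ggplot(hull_df, ggplot2::aes(x = .data$t, y = .data$p_log))
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points, alpha = 0.3, size = 0.6)
  }
  p +
    ggplot2::geom_polygon(fill = NA, colour = "black") +
    ggplot2::labs(x = "Mean monthly temperature (°C)",
                  y = "log10 precipitation (mm/month)")
}

#' Climate-space area of an envelope in standard grid cells
#'
#' Counts lattice cells of size `cell_t` degrees C by `cell_p` log10 units
#' (anchored at integer degrees and multiples of `cell_p`) whose centres lie
#' inside or on the hull. The count is a deterministic integer, so envelope
#' areas from different samples are directly comparable.
#'
#' @param env A `climate_envelope`.
#' @param cell_t Cell width in degrees C (default 1).
#' @param cell_p Cell height in log10 precipitation units (default 0.1).
#' @return Integer number of cells.
#' @export
envelope_area <- function(env, cell_t = 1, cell_p = 0.1) {
  hull <- env$hull
  if (is.null(hull) || nrow(hull) < 3) {
    warning("degenerate hull: area 0")
    return(0L)
  }
  t_lo <- floor(min(hull[, 1]) / cell_t) - 1
  t_hi <- ceiling(max(hull[, 1]) / cell_t) + 1
  p_lo <- floor(min(hull[, 2]) / cell_p) - 1
  p_hi <- ceiling(max(hull[, 2]) / cell_p) + 1
  centers_t <- (seq(t_lo, t_hi) + 0.5) * cell_t
  centers_p <- (seq(p_lo, p_hi) + 0.5) * cell_p
  gridpts <- cbind(rep(centers_t, times = length(centers_p)),
                   rep(centers_p, each = length(centers_t)))
  sum(points_in_hull(gridpts, hull))
}

#' Does the envelope contain a climate point?
#'
#' Implements the interaction rule: a temperature occupied somewhere and a
#' rainfall occupied somewhere do not make their *combination* suitable —
#' only combinations inside the minimum convex polygon are. Boundary points
#' count as inside.
#'
#' @param env A `climate_envelope`.
#' @param t,p_log Coordinates of the query point(s).
#' @return Logical vector.
#' @export
env_contains <- function(env, t, p_log) {
  points_in_hull(cbind(t, p_log), env$hull)
}

#' Project an envelope onto a climate grid
#'
#' A land cell is suitable iff the climate point of every one of its active
#' months (under the `h`/`a` hypothesis) lies inside the hull.
#'
#' @param env A `climate_envelope`.
#' @param grid A [climate_grid()].
#' @param h,a Hypothesis; defaults to the envelope's own.
#' @param novel Optional logical mask of novel-climate cells to carry into
#'   the map (kept distinct from unsuitable).
#' @return A [suitability_map()].
#' @export
project_envelope <- function(env, grid, h = env$h, a = env$a, novel = NULL) {
  suit <- climatic_suitability(env$hull, grid, h, a)
  suitability_map(grid, suit, novel)
}
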