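#' Locality-subsampling capture curve
#'
#' Quantifies how much of the full-sample climate-space area smaller
#' locality samples capture. For each decile d of the sample size, `draws`
#' random subsets of size round-half-up(d * N) are drawn without
#' replacement, an envelope is built from each, and its area is expressed as
#' a percentage of the full-sample envelope area. The 100% decile is the
#' full set itself (one draw, 100% by construction). Subsets whose
#' active-month points are collinear yield a degenerate hull; those draws
#' are retained as area 0 and flagged, keeping the estimator unbiased and
#' the curve reproducible.
#'
#' @param localities Locality tibble (>= 10 rows).
#' @param grid A [climate_grid()].
#' @param h,a Hibernation/aestivation hypothesis.
#' @param draws Random draws per decile (default 10).
#' @param seed RNG seed.
#' @return A `capture_curve`: a tibble with columns `decile` (10..100, %),
#'   `mean_pct`, `se_pct`, `n_draws`, `n_degenerate`, plus attributes
#'   `full_area` and `n_localities`.
#' @export
capture_curve <- function(localities, grid, h = 0, a = 0, draws = 10, seed = 1) {
  n <- nrow(localities)
  stopifnot(n >= 10)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  full_env <- build_envelope(localities, grid, h, a)
  full_area <- envelope_area(full_env)
  if (full_area == 0) stop("full-sample envelope has zero area", call. = FALSE)

  subset_area <- function(idx) {
    tryCatch(
      envelope_area(build_envelope(localities[idx, , drop = FALSE], grid, h, a)),
      error = function(e) 0L
    )
  }
  round_half_up <- function(x) floor(x + 0.5)

  rows <- purrr::map_dfr(1:10, function(d) {
    if (d == 10L) {
      return(tibble::tibble(decile = 100, mean_pct = 100, se_pct = 0,
                            n_draws = 1L, n_degenerate = 0L))
    }
    k <- max(1L, round_half_up(d / 10 * n))
    areas <- vapply(seq_len(draws), function(i) {
      subset_area(sample.int(n, k))
    }, numeric(1))
    pct <- 100 * areas / full_area
    tibble::tibble(
      decile = d * 10,
      mean_pct = mean(pct),
      se_pct = stats::sd(pct) / sqrt(draws),
      n_draws = as.integer(draws),
      n_degenerate = sum(areas == 0L)
    )
  })
  structure(rows, class = c("capture_curve", class(rows)),
            full_area = full_area, n_localities = n)
}

#' Plot a capture curve
#'
#' Mean percentage of full-sample climate space captured at each sample-size
#' decile, with +/- 1 SE error bars.
#'
#' @param object A [capture_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.capture_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$decile, y = .data$mean_pct)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_pct - .data$se_pct,
                   ymax = .data$mean_pct + .data$se_pct),
      width = 2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Sample size (% of localities)",
      y = "Climate space captured (% of full sample)"
    ) +
    ggplot2::ylim(0, NA)
}
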