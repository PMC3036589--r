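#' Per-variable environmental similarity
#'
#' The MESS building block: the similarity of a value `v` to a reference
#' sample of one variable, on a percentile scale with maximum 100 at the
#' reference median and negative values marking conditions outside the
#' reference range. With `f` the percentage of reference values strictly
#' below `v` (ties count as not-below):
#' \itemize{
#'   \item `f = 0`:   `100 * (v - min) / (max - min)` (negative below the minimum)
#'   \item `0 < f <= 50`: `2 f`
#'   \item `50 < f < 100`: `2 (100 - f)`
#'   \item `f = 100`: `100 * (max - v) / (max - min)`
#' }
#'
#' @param v Numeric vector of query values.
#' @param reference Non-empty numeric vector of reference values.
#' @return Numeric vector of similarities (<= 100).
#' @export
mess_similarity <- function(v, reference) {
  if (!length(reference)) stop("empty reference", call. = FALSE)
  rmin <- min(reference); rmax <- max(reference)
  if (rmax == rmin) {
    # zero-span reference: equality is a perfect match, anything else is
    # novel with an arbitrary (infinite) magnitude; flag rather than hide
    warning("reference variable has zero span")
    return(ifelse(v == rmin, 100, -Inf))
  }
  n <- length(reference)
  f <- 100 * vapply(v, function(x) sum(reference < x), numeric(1)) / n
  out <- numeric(length(v))
  b1 <- f == 0
  b2 <- f > 0 & f <= 50
  b3 <- f > 50 & f < 100
  b4 <- f == 100
  out[b1] <- 100 * (v[b1] - rmin) / (rmax - rmin)
  out[b2] <- 2 * f[b2]
  out[b3] <- 2 * (100 - f[b3])
  out[b4] <- 100 * (rmax - v[b4]) / (rmax - rmin)
  out
}

#' Multivariate environmental similarity surface
#'
#' For each query row (cell), the minimum across variables of
#' [mess_similarity()], plus the identity of the most dissimilar variable.
#' A cell is novel iff its similarity is negative, i.e. at least one
#' variable falls outside the range covered by the reference (presence plus
#' background) table. Novelty flags extrapolation and is reported separately
#' from any suitability verdict.
#'
#' @param cells A data frame of environmental values, one row per cell.
#' @param reference A data frame with the same variable columns, holding the
#'   presence + background values the model was built from.
#' @param vars Variables to use; default: all shared numeric columns of
#'   `reference` also present in `cells` (excluding `row`/`col` indices).
#' @return A `mess_result` tibble: any `row`/`col` columns of `cells`, then
#'   `similarity`, `most_dissimilar` (variable name), `novel`.
#' @export
mess_surface <- function(cells, reference, vars = NULL) {
  if (is.null(vars)) {
    vars <- setdiff(intersect(names(reference), names(cells)), c("row", "col"))
    vars <- vars[vapply(reference[vars], is.numeric, logical(1))]
  }
  if (!length(vars)) stop("no shared variables between cells and reference", call. = FALSE)
  missing <- setdiff(vars, names(cells))
  if (length(missing)) {
    stop(sprintf("variables absent from cells: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  sim <- vapply(vars, function(vn) {
    mess_similarity(cells[[vn]], reference[[vn]])
  }, numeric(nrow(cells)))
  sim <- matrix(sim, nrow = nrow(cells),
                dimnames = list(NULL, vars))
  min_idx <- apply(sim, 1, which.min)
  out <- tibble::tibble(
    similarity = sim[cbind(seq_len(nrow(sim)), min_idx)],
    most_dissimilar = vars[min_idx],
    novel = sim[cbind(seq_len(nrow(sim)), min_idx)] < 0
  )
  keep <- intersect(c("row", "col"), names(cells))
  out <- dplyr::bind_cols(cells[keep], out)
  class(out) <- c("mess_result", class(out))
  out
}

#' Plot a MESS surface
#'
#' Tile map of similarity with novel cells outlined; requires `row`/`col`
#' columns in the result.
#'
#' @param object A [mess_surface()] result with `row` and `col` columns.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mess_result <- function(object, ...) {
  stopifnot(all(c("row", "col") %in% names(object)))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$similarity)) +
    ggplot2::geom_point(data = object[object$novel, ], shape = 4, size = 0.8) +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", midpoint = 0) +
    ggplot2::labs(x = "column", y = "row", fill = "MESS")
}
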