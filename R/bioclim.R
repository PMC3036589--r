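#' Derive the 19 bioclimatic variables
#'
#' Standard bioclim summaries computed from monthly means. Quarters are all
#' twelve circular 3-month windows (Dec-Jan-Feb allowed); the wettest and
#' driest quarters maximize/minimize summed precipitation and the warmest
#' and coldest mean temperature, ties broken by earliest starting month.
#' Seasonality follows the WorldClim dialect: BIO4 = 100 * SD of monthly
#' mean temperature, BIO15 = 100 * SD of monthly precipitation divided by
#' (1 + BIO12/12) — stated here because a CV-percent dialect also exists.
#'
#' @param grid A [climate_grid()].
#' @param cells Two-column matrix or data frame of (row, col) cell indices;
#'   defaults to every land cell.
#' @return A tibble with columns `row`, `col`, `bio1`..`bio19`. BIO3 is `NA`
#'   (flagged) where BIO7 = 0.
#' @export
derive_bioclim <- function(grid, cells = NULL) {
  if (is.null(cells)) {
    cells <- which(grid$land, arr.ind = TRUE)
  }
  cells <- as.matrix(cells)[, 1:2, drop = FALSE]
  n <- nrow(cells)
  lin <- (cells[, 2] - 1) * grid$nrow + cells[, 1]  # robust for 1-cell grids
  band12 <- function(arr) {
    t(matrix(vapply(1:12, function(m) {
      arr[lin + (m - 1) * grid$nrow * grid$ncol]
    }, numeric(n)), nrow = n))
  }
  tavg <- band12(grid$tavg)
  tmin <- band12(grid$tmin)
  tmax <- band12(grid$tmax)
  prcp <- band12(grid$prcp)
  # 12 x n matrices; quarter windows are rows of a 12 x 3 index table
  qwin <- t(vapply(1:12, function(s) as.integer((s - 1 + 0:2) %% 12) + 1L, integer(3)))
  qsum <- function(mat) {
    t(matrix(vapply(1:12, function(s) colSums(mat[qwin[s, ], , drop = FALSE]),
                    numeric(n)), nrow = n))
  }
  qmean <- function(mat) qsum(mat) / 3
  qt <- qmean(tavg)   # 12 starts x n cells: quarter mean temperature
  qp <- qsum(prcp)    # quarter total precipitation
  # earliest-start tie-breaks: which.max/min on a vector pick the first index
  pick <- function(score, fn) apply(score, 2, fn)
  warmest_q <- pick(qt, which.max); coldest_q <- pick(qt, which.min)
  wettest_q <- pick(qp, which.max); driest_q  <- pick(qp, which.min)
  at <- function(mat, idx) mat[cbind(idx, seq_len(n))]

  sd12 <- function(mat) apply(mat, 2, stats::sd)
  bio1 <- colMeans(tavg)
  bio2 <- colMeans(tmax - tmin)
  bio5 <- apply(tmax, 2, max)
  bio6 <- apply(tmin, 2, min)
  bio7 <- bio5 - bio6
  bio3 <- ifelse(bio7 > 0, bio2 / bio7 * 100, NA_real_)
  bio4 <- 100 * sd12(tavg)
  bio12 <- colSums(prcp)
  bio13 <- apply(prcp, 2, max)
  bio14 <- apply(prcp, 2, min)
  bio15 <- 100 * sd12(prcp) / (1 + bio12 / 12)

  tibble::tibble(
    row = as.integer(cells[, 1]), col = as.integer(cells[, 2]),
    bio1 = bio1, bio2 = bio2, bio3 = bio3, bio4 = bio4,
    bio5 = bio5, bio6 = bio6, bio7 = bio7,
    bio8 = at(qt, wettest_q), bio9 = at(qt, driest_q),
    bio10 = at(qt, warmest_q), bio11 = at(qt, coldest_q),
    bio12 = bio12, bio13 = bio13, bio14 = bio14, bio15 = bio15,
    bio16 = at(qp, wettest_q), bio17 = at(qp, driest_q),
    bio18 = at(qp, warmest_q), bio19 = at(qp, coldest_q)
  )
}

bioclim_cols <- function() paste0("bio", 1:19)

#' Sample background cells from a region mask
#'
#' Uniform, seeded sampling without replacement of cells from a mask, the
#' standard way to characterize available environment for collinearity
#' audits and presence-background models.
#'
#' @param mask Logical region mask.
#' @param n Number of cells (default 5000).
#' @param seed RNG seed.
#' @return A tibble with columns `row`, `col`. If the mask holds fewer than
#'   `n` cells, all cells are returned with a warning.
#' @export
sample_background <- function(mask, n = 5000, seed = 1) {
  cells <- which(mask, arr.ind = TRUE)
  if (nrow(cells) == 0) stop("empty mask", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (n == 0) {
    return(tibble::tibble(row = integer(0), col = integer(0)))
  }
  if (nrow(cells) < n) {
    warning(sprintf("mask has only %d cells (< %d); returning all", nrow(cells), n))
    n <- nrow(cells)
  }
  idx <- sample.int(nrow(cells), n)
  tibble::tibble(row = as.integer(cells[idx, 1]), col = as.integer(cells[idx, 2]))
}

#' Pairwise collinearity audit of a bioclim table
#'
#' Pearson correlations between all unordered pairs of the 19 bioclim
#' columns, summarized the way multi-collinearity is usually reported: a
#' decile histogram of signed r, the modal decile, and counts of pairs above
#' thresholds. Because whether a threshold refers to r or |r| is often left
#' ambiguous, both counts are reported and neither is preferred.
#'
#' @param table A tibble containing `bio1`..`bio19` columns (other columns
#'   ignored); >= 3 rows.
#' @param thresholds Thresholds for the exceedance counts.
#' @return A `collinearity_summary` list: `r` (19 x 19 matrix, `NA` rows for
#'   dropped columns), `pair_count` (raw, 171), `effective_pair_count`
#'   (pairs with both columns non-constant), `histogram` (tibble of signed-r
#'   deciles), `modal_decile`, `counts` (tibble with `threshold`,
#'   `n_signed`, `n_absolute`), `dropped` (zero-variance columns).
#' @export
collinearity_summary <- function(table, thresholds = c(0.5, 0.8)) {
  cols <- intersect(bioclim_cols(), names(table))
  if (length(cols) < 2) stop("need at least two bioclim columns", call. = FALSE)
  mat <- as.matrix(table[cols])
  if (nrow(mat) < 3) stop("need >= 3 rows", call. = FALSE)
  variances <- apply(mat, 2, stats::var, na.rm = TRUE)
  dropped <- cols[!is.finite(variances) | variances == 0]
  keep <- setdiff(cols, dropped)
  r <- matrix(NA_real_, length(cols), length(cols), dimnames = list(cols, cols))
  r[keep, keep] <- stats::cor(mat[, keep, drop = FALSE],
                              use = "pairwise.complete.obs")
  diag(r) <- 1
  pair_count <- length(cols) * (length(cols) - 1) / 2
  rvals <- r[upper.tri(r)]
  rvals <- rvals[!is.na(rvals)]
  breaks <- seq(-1, 1, by = 0.1)
  bins <- cut(rvals, breaks = breaks, include.lowest = TRUE, right = FALSE)
  # r = 1 (identical columns) belongs in the top decile
  bins[rvals >= 1 - 1e-12] <- levels(bins)[length(levels(bins))]
  hist_tbl <- tibble::tibble(
    decile = levels(bins),
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    count = as.integer(table(bins))
  )
  modal <- hist_tbl$decile[which.max(hist_tbl$count)]
  counts <- purrr::map_dfr(thresholds, function(th) {
    tibble::tibble(threshold = th,
                   n_signed = sum(rvals > th),
                   n_absolute = sum(abs(rvals) > th))
  })
  structure(
    list(r = r, pair_count = pair_count,
         effective_pair_count = length(rvals),
         histogram = hist_tbl, modal_decile = modal,
         counts = counts, dropped = dropped),
    class = "collinearity_summary"
  )
}

#' @export
print.collinearity_summary <- function(x, ...) {
  cat(sprintf("<collinearity_summary> %d pairs (%d effective), modal decile %s\n",
              x$pair_count, x$effective_pair_count, x$modal_decile))
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  r > %.1f: %d pairs; |r| > %.1f: %d pairs\n",
                x$counts$threshold[i], x$counts$n_signed[i],
                x$counts$threshold[i], x$counts$n_absolute[i]))
  }
  if (length(x$dropped)) cat("  dropped zero-variance columns:",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Glance at a collinearity summary
#'
#' @param x A `collinearity_summary`.
#' @param ... Unused.
#' @return A one-row tibble with `pair_count`, `effective_pair_count`,
#'   `modal_decile`, and one column per threshold count.
#' @export
glance.collinearity_summary <- function(x, ...) {
  out <- tibble::tibble(
    pair_count = x$pair_count,
    effective_pair_count = x$effective_pair_count,
    modal_decile = x$modal_decile
  )
  for (i in seq_len(nrow(x$counts))) {
    out[[sprintf("n_r_gt_%g", x$counts$threshold[i])]] <- x$counts$n_signed[i]
    out[[sprintf("n_abs_r_gt_%g", x$counts$threshold[i])]] <- x$counts$n_absolute[i]
  }
  out
}

#' Plot the signed-r decile histogram of a collinearity summary
#'
#' @param object A `collinearity_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.collinearity_summary <- function(object, ...) {
  h <- object$histogram
  h$mid <- (h$lower + h$upper) / 2
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = 0.095) +
    ggplot2::labs(x = "Pairwise Pearson r (decile bins)", y = "Pairs")
}
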