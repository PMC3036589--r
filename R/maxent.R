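#' Build a feature set for a presence-background model
#'
#' Features are derived from environmental variables and scaled to [0, 1]
#' using background minima and maxima only (the background defines what is
#' available; presences must never influence the scaling). Supported
#' classes: `linear` (min-max scaled variable), `quadratic` (square of the
#' scaled variable), `product` (pairwise products of scaled variables), and
#' `hinge` (forward hinges `max(0, (x - k)/(max - k))` with knots `k` at
#' background quantiles). This is a deliberately simple, fully specified
#' feature dialect: it reproduces the qualitative behaviour of
#' maximum-entropy niche models while remaining auditable; it is not a clone
#' of any particular MaxEnt release.
#'
#' @param background Data frame of background environmental values.
#' @param vars Variables to use; default: all numeric columns except
#'   `row`/`col`.
#' @param classes Feature classes to build.
#' @param hinge_count Hinge knots per variable (at quantiles
#'   `j / (hinge_count + 1)`).
#' @return A `feature_set`: a tibble of feature descriptors (`name`, `kind`,
#'   `var`, `var2`, `knot`, `min`, `max`) with class attributes.
#' @export
build_features <- function(background,
                           vars = NULL,
                           classes = c("linear", "quadratic", "hinge"),
                           hinge_count = 4) {
  if (nrow(background) < 2) stop("need >= 2 background rows", call. = FALSE)
  classes <- match.arg(classes, c("linear", "quadratic", "product", "hinge"),
                       several.ok = TRUE)
  if (is.null(vars)) {
    vars <- setdiff(names(background), c("row", "col"))
    vars <- vars[vapply(background[vars], is.numeric, logical(1))]
  }
  rng <- lapply(vars, function(v) range(background[[v]], na.rm = TRUE))
  names(rng) <- vars
  constant <- vars[vapply(rng, function(r) r[1] == r[2], logical(1))]
  if (length(constant)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(constant, collapse = ", ")))
    vars <- setdiff(vars, constant)
  }
  if (!length(vars)) stop("no usable variables", call. = FALSE)

  feats <- list()
  add <- function(name, kind, var, var2 = NA_character_, knot = NA_real_) {
    feats[[length(feats) + 1]] <<- tibble::tibble(
      name = name, kind = kind, var = var, var2 = var2, knot = knot,
      min = rng[[var]][1], max = rng[[var]][2]
    )
  }
  for (v in vars) {
    if ("linear" %in% classes) add(paste0("lin:", v), "linear", v)
    if ("quadratic" %in% classes) add(paste0("quad:", v), "quadratic", v)
    if ("hinge" %in% classes && hinge_count > 0) {
      probs <- seq_len(hinge_count) / (hinge_count + 1)
      knots <- stats::quantile(background[[v]], probs, names = FALSE, na.rm = TRUE)
      for (k in knots) {
        if (k < rng[[v]][2]) add(sprintf("hinge:%s@%.6g", v, k), "hinge", v, knot = k)
      }
    }
  }
  if ("product" %in% classes && length(vars) > 1) {
    combs <- utils::combn(vars, 2)
    for (j in seq_len(ncol(combs))) {
      add(paste0("prod:", combs[1, j], "*", combs[2, j]),
          "product", combs[1, j], var2 = combs[2, j])
    }
  }
  fs <- dplyr::bind_rows(feats)
  # product features need the second variable's range too
  fs$min2 <- ifelse(is.na(fs$var2), NA_real_,
                    vapply(fs$var2, function(v) if (is.na(v)) NA_real_ else rng[[v]][1], numeric(1)))
  fs$max2 <- ifelse(is.na(fs$var2), NA_real_,
                    vapply(fs$var2, function(v) if (is.na(v)) NA_real_ else rng[[v]][2], numeric(1)))
  structure(fs, class = c("feature_set", class(fs)), vars = vars)
}

#' Evaluate a feature set on environmental rows
#'
#' Raw variables are min-max scaled with the *background* scaling stored in
#' the feature set and clamped to [0, 1] (projection never extrapolates a
#' feature beyond its training range).
#'
#' @param features A [build_features()] result.
#' @param data Data frame with the feature set's variables.
#' @return Numeric matrix, one column per feature.
#' @export
feature_matrix <- function(features, data) {
  scale01 <- function(x, lo, hi) pmin(1, pmax(0, (x - lo) / (hi - lo)))
  n <- nrow(data)
  out <- matrix(0, n, nrow(features))
  colnames(out) <- features$name
  for (j in seq_len(nrow(features))) {
    f <- features[j, ]
    x <- data[[f$var]]
    out[, j] <- switch(
      f$kind,
      linear = scale01(x, f$min, f$max),
      quadratic = scale01(x, f$min, f$max)^2,
      product = scale01(x, f$min, f$max) * scale01(data[[f$var2]], f$min2, f$max2),
      hinge = pmin(1, pmax(0, (x - f$knot) / (f$max - f$knot)))
    )
  }
  out
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a penalized maximum-entropy presence-background model
#'
#' Fits a Gibbs distribution over the background,
#' `P(x) = exp(lambda . f(x)) / Z`, by maximizing the L1-penalized presence
#' log-likelihood
#' `sum_presence lambda . f(x) - n log Z - n sum_j beta_j |lambda_j|`,
#' with per-feature penalties `beta_j = beta_multiplier * s_j` where `s_j`
#' is the feature's presence-sample standard deviation divided by `sqrt(n)`
#' (a lasso-style rule, floored at `0.05 / sqrt(n)` so every feature always
#' carries a positive penalty). The penalty acts on the per-presence likelihood
#' scale (hence the factor `n`): the amount of shrinkage a given
#' `beta_multiplier` applies is then comparable across sample sizes, a very
#' large multiplier shrinks every coefficient to exactly zero, and a small
#' one recovers an unpenalized fit. Optimization is cyclic coordinate descent: each
#' coordinate takes a Newton step followed by exact soft-thresholding (so
#' shrunk coefficients are exactly zero) and a halving line search that
#' guarantees the objective never decreases. Convergence is declared when a
#' full sweep improves the objective by less than `tol`.
#'
#' The background characterizes the available environment and is assumed to
#' include the presence conditions (the usual presence-background
#' convention: pass `bind_rows(presences, background_sample)`). A background
#' that excludes them can make presences linearly separable from every
#' background row, in which case the penalized likelihood has no maximum and
#' the fit stops with a non-convergence error.
#'
#' @param presences,background Data frames of environmental values.
#' @param features A [build_features()] result.
#' @param beta_multiplier Regularization multiplier; larger is sparser.
#' @param tol Convergence tolerance on the objective (default 1e-7).
#' @param max_sweeps Sweep budget; exceeding it is an error carrying the
#'   objective trace.
#' @return A `maxent_model`: `lambda` (named vector), `features`,
#'   `beta_multiplier`, `beta_j`, `log_z`, `entropy`, `K` (nonzero
#'   coefficients), `n`, `n_background`, `objective`, `trace`.
#' @export
maxent_fit <- function(presences, background, features,
                       beta_multiplier = 1, tol = 1e-7, max_sweeps = 2000) {
  n <- nrow(presences)
  if (n < 5) stop("need >= 5 presences", call. = FALSE)
  Fp <- feature_matrix(features, presences)
  Fb <- feature_matrix(features, background)
  p <- ncol(Fp)
  s_j <- apply(Fp, 2, stats::sd) / sqrt(n)
  s_j <- pmax(s_j, 0.05 / sqrt(n))   # constant features still carry a penalty
  beta_j <- beta_multiplier * s_j
  pen_j <- n * beta_j          # penalty on the total-likelihood scale

  lambda <- numeric(p)
  eta_b <- rep(0, nrow(Fb))
  sum_fp <- colSums(Fp)        # sufficient statistics of the presences
  pres_lin <- 0                # lambda . sum_fp, tracked incrementally

  objective <- function(pres_lin, eta_b, lambda) {
    pres_lin - n * log_sum_exp(eta_b) - sum(pen_j * abs(lambda))
  }
  obj <- objective(pres_lin, eta_b, lambda)
  trace <- obj

  # second-order correction over the currently active (nonzero) features:
  # cyclic descent alone zigzags on collinear feature sets, so after each
  # sweep a Newton step on the active set (orthant-projected, so signs can
  # only be kept or clamped to zero) is tried with a halving line search.
  newton_step <- function(lambda, eta_b, pres_lin, obj) {
    act <- which(lambda != 0)
    if (length(act) < 2) return(list(lambda = lambda, eta_b = eta_b,
                                     pres_lin = pres_lin, obj = obj))
    w <- exp(eta_b - max(eta_b)); w <- w / sum(w)
    Fa <- Fb[, act, drop = FALSE]
    ebg <- drop(crossprod(Fa, w))
    H <- n * (crossprod(Fa * sqrt(w)) - tcrossprod(ebg))
    diag(H) <- diag(H) + 1e-8 * (1 + mean(diag(H)))
    grad <- -(sum_fp[act] - n * ebg) + pen_j[act] * sign(lambda[act])
    dir <- tryCatch(-solve(H, grad), error = function(e) NULL)
    if (is.null(dir)) return(list(lambda = lambda, eta_b = eta_b,
                                  pres_lin = pres_lin, obj = obj))
    step <- 1
    while (step > 1e-6) {
      la <- lambda[act] + step * dir
      la[sign(la) * sign(lambda[act]) < 0] <- 0   # stay in the orthant
      lam_new <- lambda
      lam_new[act] <- la
      d <- lam_new - lambda
      nz <- which(d != 0)
      if (!length(nz)) break
      eta_new <- eta_b + drop(Fb[, nz, drop = FALSE] %*% d[nz])
      pres_new <- pres_lin + sum(d[nz] * sum_fp[nz])
      obj_new <- objective(pres_new, eta_new, lam_new)
      if (obj_new > obj + 1e-12) {
        return(list(lambda = lam_new, eta_b = eta_new,
                    pres_lin = pres_new, obj = obj_new))
      }
      step <- step / 2
    }
    list(lambda = lambda, eta_b = eta_b, pres_lin = pres_lin, obj = obj)
  }

  for (sweep in seq_len(max_sweeps)) {
    obj_start <- obj
    for (j in seq_len(p)) {
      w <- exp(eta_b - max(eta_b))
      w <- w / sum(w)
      ebg <- sum(w * Fb[, j])
      g <- sum_fp[j] - n * ebg                      # unpenalized gradient
      h <- n * max(sum(w * Fb[, j]^2) - ebg^2, 1e-10)
      z <- lambda[j] * h + g
      cand <- sign(z) * max(0, abs(z) - pen_j[j]) / h
      if (cand == lambda[j]) next
      delta <- cand - lambda[j]
      step <- 1
      repeat {
        new_lambda_j <- lambda[j] + step * delta
        # keep the exact zero from the soft threshold at full step
        if (step < 1 && cand == 0 && abs(new_lambda_j) < 1e-14) new_lambda_j <- 0
        d <- new_lambda_j - lambda[j]
        eta_new <- eta_b + d * Fb[, j]
        pres_new <- pres_lin + d * sum_fp[j]
        lam_new <- lambda
        lam_new[j] <- new_lambda_j
        obj_new <- objective(pres_new, eta_new, lam_new)
        if (obj_new >= obj - 1e-12) {
          lambda[j] <- new_lambda_j
          eta_b <- eta_new
          pres_lin <- pres_new
          obj <- obj_new
          break
        }
        step <- step / 2
        if (step < 1e-10) break
      }
    }
    for (it in 1:25) {
      ns <- newton_step(lambda, eta_b, pres_lin, obj)
      gained <- ns$obj - obj
      lambda <- ns$lambda; eta_b <- ns$eta_b
      pres_lin <- ns$pres_lin; obj <- ns$obj
      if (gained < tol / 10) break
    }
    trace <- c(trace, obj)
    if (obj - obj_start < tol) {
      log_z <- log_sum_exp(eta_b)
      raw <- exp(eta_b - log_z)
      entropy <- -sum(raw * log(pmax(raw, 1e-300)))
      out <- structure(
        list(lambda = stats::setNames(lambda, features$name),
             features = features,
             beta_multiplier = beta_multiplier,
             beta_j = stats::setNames(beta_j, features$name),
             log_z = log_z,
             entropy = entropy,
             K = sum(lambda != 0),
             n = n,
             n_background = nrow(Fb),
             objective = obj,
             trace = trace),
        class = "maxent_model"
      )
      return(out)
    }
  }
  cond <- simpleError(sprintf(
    "coordinate descent did not converge in %d sweeps (last objective %.8g)",
    max_sweeps, obj))
  cond$trace <- trace
  stop(cond)
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf(
    "<maxent_model> %d features, K = %d nonzero, beta = %g, n = %d presences\n",
    length(x$lambda), x$K, x$beta_multiplier, x$n))
  invisible(x)
}

#' Tidy a fitted maxent model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return A tibble with one row per feature: `feature`, `kind`, `variable`,
#'   `estimate` (lambda), `penalty`.
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble::tibble(
    feature = names(x$lambda),
    kind = x$features$kind,
    variable = x$features$var,
    estimate = unname(x$lambda),
    penalty = unname(x$beta_j)
  )
}

#' Glance at a fitted maxent model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return One-row tibble: `K`, `beta_multiplier`, `n`, `n_background`,
#'   `entropy`, `objective`.
#' @export
glance.maxent_model <- function(x, ...) {
  tibble::tibble(
    K = x$K, beta_multiplier = x$beta_multiplier, n = x$n,
    n_background = x$n_background, entropy = x$entropy,
    objective = x$objective
  )
}

#' Raw (Gibbs) scores of cells under a fitted model
#'
#' `exp(lambda . f(x)) / Z` with `Z` frozen from the fitting background, so
#' raw scores sum to 1 over that background.
#'
#' @param model A `maxent_model`.
#' @param cells Data frame of environmental values.
#' @return Numeric vector.
#' @export
raw_scores <- function(model, cells) {
  Fm <- feature_matrix(model$features, cells)
  exp(drop(Fm %*% model$lambda) - model$log_z)
}

#' Logistic suitability scores in (0, 1)
#'
#' The standard monotone transform of raw scores,
#' `c r / (1 + c r)` with `c = exp(H)` (H the entropy of the fitted
#' distribution over the background), chosen so a typical background cell
#' scores near 0.5. Rankings under raw and logistic scores are identical.
#'
#' @inheritParams raw_scores
#' @return Numeric vector in (0, 1).
#' @export
suitability <- function(model, cells) {
  r <- raw_scores(model, cells)
  cr <- exp(model$entropy) * r
  cr / (1 + cr)
}

#' Minimum training presence threshold
#'
#' The lowest suitability among training presences; the conventional
#' zero-omission threshold for converting a continuous suitability surface
#' into a binary one.
#'
#' @param model A `maxent_model`.
#' @param presences The training presence rows.
#' @return A single suitability value.
#' @export
min_training_presence <- function(model, presences) {
  min(suitability(model, presences))
}

#' Rank-based AUC of presence vs background scores
#'
#' The probability a random presence outranks a random background point,
#' with ties given half credit (Mann-Whitney form).
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in [0, 1].
#' @export
auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("both score sets must be non-empty", call. = FALSE)
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Count model parameters
#'
#' The number of features with exactly nonzero coefficients — exact zeros
#' arise from the soft-threshold step, so this is a clean count, not a
#' tolerance judgement.
#'
#' @param model A `maxent_model`.
#' @return Integer K.
#' @export
count_parameters <- function(model) {
  sum(model$lambda != 0)
}

#' Small-sample corrected AIC of a fitted model
#'
#' `AICc = 2K - 2 lnL + 2K(K+1)/(n - K - 1)`, with the log-likelihood taken
#' over raw scores normalized on the fitting background (the model's
#' landscape) and `K` the nonzero-coefficient count. Inadmissible when
#' `n - K - 1 <= 0`.
#'
#' @param model A `maxent_model`.
#' @param presences The presence rows to score.
#' @return A list: `aicc`, `lnl`, `k`, `n`.
#' @export
aicc <- function(model, presences) {
  k <- count_parameters(model)
  n <- nrow(presences)
  if (n - k - 1 <= 0) {
    stop(sprintf("AICc undefined: n - K - 1 = %d <= 0 (model inadmissible)",
                 n - k - 1), call. = FALSE)
  }
  lnl <- sum(log(raw_scores(model, presences)))
  list(aicc = 2 * k - 2 * lnl + 2 * k * (k + 1) / (n - k - 1),
       lnl = lnl, k = k, n = n)
}

#' Sweep the regularization multiplier and select by AICc
#'
#' Fits the model at each beta, records K, lnL and AICc, and selects the
#' AICc-minimizing beta; ties go to the larger (more parsimonious) beta.
#' Betas whose models are inadmissible (`n - K - 1 <= 0`) are kept in the
#' table with `NA` AICc and excluded from selection.
#'
#' @inheritParams maxent_fit
#' @param betas Numeric vector of multipliers (>= 2 values, or 1 to fit a
#'   single model).
#' @return A `beta_sweep`: list with `table` (tibble `beta`, `K`, `lnl`,
#'   `aicc`, `admissible`), `best_beta`, `best_model`.
#' @export
beta_sweep <- function(presences, background, features, betas) {
  stopifnot(length(betas) >= 1)
  betas <- sort(unique(betas))
  fits <- lapply(betas, function(b) {
    maxent_fit(presences, background, features, beta_multiplier = b)
  })
  rows <- purrr::map2_dfr(fits, betas, function(m, b) {
    adm <- m$n - m$K - 1 > 0
    if (adm) {
      a <- aicc(m, presences)
      tibble::tibble(beta = b, K = m$K, lnl = a$lnl, aicc = a$aicc, admissible = TRUE)
    } else {
      tibble::tibble(beta = b, K = m$K,
                     lnl = sum(log(raw_scores(m, presences))),
                     aicc = NA_real_, admissible = FALSE)
    }
  })
  ok <- which(rows$admissible)
  if (!length(ok)) stop("all betas inadmissible (n - K - 1 <= 0 everywhere)", call. = FALSE)
  best_aicc <- min(rows$aicc[ok])
  cand <- ok[rows$aicc[ok] <= best_aicc + 1e-9]
  best <- cand[which.max(rows$beta[cand])]   # ties -> larger beta
  structure(
    list(table = rows, best_beta = rows$beta[best], best_model = fits[[best]]),
    class = "beta_sweep"
  )
}

#' @export
print.beta_sweep <- function(x, ...) {
  cat(sprintf("<beta_sweep> %d betas, AICc-selected beta = %g (K = %d)\n",
              nrow(x$table), x$best_beta, x$best_model$K))
  print(x$table)
  invisible(x)
}

#' @export
tidy.beta_sweep <- function(x, ...) x$table

#' Plot AICc and parameter count against the regularization multiplier
#'
#' @param object A [beta_sweep()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beta_sweep <- function(object, ...) {
  tab <- tidyr::pivot_longer(object$table, c("K", "aicc"),
                             names_to = "metric", values_to = "value")
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$beta, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_beta, linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Regularization multiplier", y = NULL)
}

#' Replicated-holdout cross-validation of a maxent model
#'
#' Refits the model `replicates` times, each time withholding a different
#' random fraction of the presences as a test set (holdout size =
#' `ceiling(holdout * n)`), and reports mean and standard error of the
#' parameter count, minimum training presence, and training/test AUC.
#'
#' @inheritParams maxent_fit
#' @param replicates Number of refits (default 25).
#' @param holdout Fraction of presences withheld each time (default 0.10).
#' @param seed RNG seed for the partitions.
#' @return A `maxent_cv`: list with `replicates` (tibble per replicate:
#'   `replicate`, `K`, `mtp`, `auc_train`, `auc_test`) and `summary`
#'   (tibble `metric`, `mean`, `se`).
#' @export
cross_validate <- function(presences, background, features, beta_multiplier = 1,
                           replicates = 25, holdout = 0.10, seed = 1) {
  n <- nrow(presences)
  n_test <- ceiling(holdout * n)
  stopifnot(n_test >= 1, n - n_test >= 5)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  rows <- purrr::map_dfr(seq_len(replicates), function(rep) {
    test_idx <- sample.int(n, n_test)
    train <- presences[-test_idx, , drop = FALSE]
    test <- presences[test_idx, , drop = FALSE]
    m <- maxent_fit(train, background, features, beta_multiplier)
    bg_scores <- suitability(m, background)
    tibble::tibble(
      replicate = rep,
      K = m$K,
      mtp = min_training_presence(m, train),
      auc_train = auc(suitability(m, train), bg_scores),
      auc_test = auc(suitability(m, test), bg_scores)
    )
  })
  summary <- rows |>
    tidyr::pivot_longer(-"replicate", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  structure(list(replicates = rows, summary = summary,
                 beta_multiplier = beta_multiplier),
            class = "maxent_cv")
}

#' @export
print.maxent_cv <- function(x, ...) {
  cat(sprintf("<maxent_cv> %d replicates at beta = %g\n",
              nrow(x$replicates), x$beta_multiplier))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.maxent_cv <- function(x, ...) x$replicates

#' @export
glance.maxent_cv <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "se"))
  dplyr::bind_cols(tibble::tibble(beta_multiplier = x$beta_multiplier), wide)
}

#' Permutation importance of environmental variables
#'
#' For each variable, its values are permuted jointly across the pooled
#' presence + background rows, the model is re-scored (not refit), and the
#' drop in training AUC is recorded; drops are floored at zero and
#' normalized to sum to 100. Variables whose features all carry zero
#' coefficients get importance 0 by construction.
#'
#' @param model A `maxent_model`.
#' @param presences,background The data the model was trained on.
#' @param seed RNG seed for the permutations.
#' @param n_perm Permutations per variable (drops are averaged).
#' @return A tibble `variable`, `auc_drop`, `importance` (percent).
#' @export
permutation_importance <- function(model, presences, background,
                                   seed = 1, n_perm = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  vars <- attr(model$features, "vars")
  np <- nrow(presences)
  pooled <- dplyr::bind_rows(presences[intersect(vars, names(presences))],
                             background[intersect(vars, names(background))])
  bg_scores <- suitability(model, background)
  auc0 <- auc(suitability(model, presences), bg_scores)
  drops <- vapply(vars, function(v) {
    # zero-coefficient variables cannot change any score
    uses <- model$features$var == v |
      (!is.na(model$features$var2) & model$features$var2 == v)
    if (all(model$lambda[uses] == 0)) return(0)
    mean(vapply(seq_len(n_perm), function(i) {
      perm <- pooled
      perm[[v]] <- sample(perm[[v]])
      sp <- suitability(model, perm[seq_len(np), , drop = FALSE])
      sb <- suitability(model, perm[-seq_len(np), , drop = FALSE])
      max(0, auc0 - auc(sp, sb))
    }, numeric(1)))
  }, numeric(1))
  total <- sum(drops)
  tibble::tibble(
    variable = vars,
    auc_drop = unname(drops),
    importance = if (total > 0) 100 * unname(drops) / total else rep(0, length(vars))
  )
}
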