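# shared fixture: a 2-variable background and presences drawn from a known
# Gibbs density over it
gibbs_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    set.seed(101)
    bg <- tibble::tibble(x = stats::runif(600, 0, 10),
                         y = stats::runif(600, 0, 5))
    fs <- build_features(bg, classes = "linear", hinge_count = 0)
    Fb <- feature_matrix(fs, bg)
    lambda_true <- c(2.0, -1.2)
    w <- exp(drop(Fb %*% lambda_true))
    idx <- sample.int(nrow(bg), 2000, replace = TRUE, prob = w)
    cache <<- list(bg = bg, fs = fs, pres = bg[idx, ], lambda_true = lambda_true)
    cache
  }
})

test_that("feature building scales on background, drops constants, places quantile knots", {
  bg <- tibble::tibble(a = c(0, 5, 10, 2, 7), b = 3)
  expect_warning(fs <- build_features(bg, classes = c("linear", "hinge"),
                                      hinge_count = 2), "constant")
  expect_true(all(fs$var == "a"))
  Fm <- feature_matrix(fs, bg)
  lin <- Fm[, "lin:a"]
  expect_equal(lin, (bg$a - 0) / 10)                 # min-max scaling
  knots <- stats::quantile(bg$a, (1:2) / 3, names = FALSE)
  expect_equal(sort(fs$knot[fs$kind == "hinge"]), sort(knots))
  # hinge_count = 0 -> no hinges
  fs0 <- build_features(tibble::tibble(a = 1:5), classes = c("linear", "hinge"),
                        hinge_count = 0)
  expect_false(any(fs0$kind == "hinge"))
  # quadratic and product behave as squares/products of scaled variables
  bg2 <- tibble::tibble(a = 1:6, b = c(2, 4, 8, 1, 9, 5))
  fs2 <- build_features(bg2, classes = c("linear", "quadratic", "product"))
  F2 <- feature_matrix(fs2, bg2)
  expect_equal(F2[, "quad:a"], F2[, "lin:a"]^2)
  expect_equal(F2[, "prod:a*b"], F2[, "lin:a"] * F2[, "lin:b"])
  # projection clamps outside the background range
  F3 <- feature_matrix(fs2, tibble::tibble(a = 100, b = -100))
  expect_equal(unname(F3[, "lin:a"]), 1)
  expect_equal(unname(F3[, "lin:b"]), 0)
})

test_that("the fit recovers a known Gibbs density and shrinks to uniform", {
  fx <- gibbs_fixture()
  m <- maxent_fit(fx$pres, fx$bg, fx$fs, beta_multiplier = 0.01)
  expect_lt(max(abs(m$lambda - fx$lambda_true) / abs(fx$lambda_true)), 0.10)

  # objective is monotone over sweeps
  expect_true(all(diff(m$trace) >= -1e-9))

  # raw scores sum to 1 over the background
  expect_equal(sum(raw_scores(m, fx$bg)), 1)

  # huge beta: full shrinkage, uniform raw scores
  m0 <- maxent_fit(fx$pres, fx$bg, fx$fs, beta_multiplier = 1e3)
  expect_equal(unname(m0$lambda), c(0, 0))
  expect_equal(count_parameters(m0), 0)
  expect_equal(raw_scores(m0, fx$bg), rep(1 / nrow(fx$bg), nrow(fx$bg)))

  # duplicated background rows leave the model unchanged
  m2 <- maxent_fit(fx$pres, dplyr::bind_rows(fx$bg, fx$bg), fx$fs,
                   beta_multiplier = 0.01)
  expect_equal(m2$lambda, m$lambda, tolerance = 1e-5)
})

test_that("scores, MTP, and AUC behave as rank statistics", {
  fx <- gibbs_fixture()
  m <- maxent_fit(fx$pres, fx$bg, fx$fs, beta_multiplier = 1)
  s_bg <- suitability(m, fx$bg)
  expect_true(all(s_bg > 0 & s_bg < 1))
  # identical ranking under raw and logistic
  r_bg <- raw_scores(m, fx$bg)
  expect_equal(order(r_bg), order(s_bg))
  # all-zero lambda -> constant logistic output
  m0 <- maxent_fit(fx$pres, fx$bg, fx$fs, beta_multiplier = 1e3)
  expect_equal(length(unique(suitability(m0, fx$bg))), 1)

  # MTP equals the brute-force minimum; single presence is its own score
  expect_equal(min_training_presence(m, fx$pres), min(suitability(m, fx$pres)))
  expect_equal(min_training_presence(m, fx$pres[5, ]),
               suitability(m, fx$pres[5, ]))

  # AUC: separation, identity, brute-force all-pairs agreement
  expect_equal(auc(c(5, 6, 7), c(1, 2, 3)), 1)
  set.seed(3)
  a <- stats::rnorm(150); b <- stats::rnorm(150)
  expect_lt(abs(auc(a, b) - 0.5), 0.12)
  brute_auc <- function(p, q) {
    mean(outer(p, q, function(i, j) (i > j) + 0.5 * (i == j)))
  }
  p <- sample(1:20, 80, replace = TRUE); q <- sample(5:25, 60, replace = TRUE)
  expect_equal(auc(p, q), brute_auc(p, q))
})

test_that("AICc matches a hand-computed toy landscape and penalizes K", {
  # 5-cell landscape, one linear feature with known values
  bg <- tibble::tibble(x = c(0, 1, 2, 3, 4))
  fs <- build_features(bg, classes = "linear", hinge_count = 0)
  pres <- tibble::tibble(x = c(4, 3, 4, 2, 4, 4))
  m <- maxent_fit(pres, bg, fs, beta_multiplier = 0.5)
  # calculator oracle: lnL = sum log(exp(lambda*f_i)/Z), K = #nonzero
  f <- c(0, 0.25, 0.5, 0.75, 1)
  lam <- unname(m$lambda)
  z <- sum(exp(lam * f))
  lnl_oracle <- sum(lam * f[c(5, 4, 5, 3, 5, 5)] - log(z))
  k <- sum(lam != 0); n <- 6
  aicc_oracle <- 2 * k - 2 * lnl_oracle + 2 * k * (k + 1) / (n - k - 1)
  out <- aicc(m, pres)
  expect_equal(out$lnl, lnl_oracle, tolerance = 1e-9)
  expect_equal(out$aicc, aicc_oracle, tolerance = 1e-9)

  # K = 0 model: AICc = -2 lnL
  m0 <- maxent_fit(pres, bg, fs, beta_multiplier = 1e4)
  out0 <- aicc(m0, pres)
  expect_equal(out0$k, 0)
  expect_equal(out0$aicc, -2 * out0$lnl)

  # penalty is monotone in K at fixed lnL (closed form)
  pen <- function(k, n) 2 * k + 2 * k * (k + 1) / (n - k - 1)
  expect_true(all(diff(pen(0:10, 20)) > 0))

  # inadmissible when n - K - 1 <= 0
  pres_tiny <- tibble::tibble(x = c(4, 4, 4, 2, 3))
  m_t <- maxent_fit(pres_tiny, bg, fs, beta_multiplier = 0.01)
  fake <- m_t; fake$lambda <- stats::setNames(rep(1, 1), names(m_t$lambda))
  expect_error(aicc(fake, pres_tiny[1:2, ]), "inadmissible")
})

test_that("beta sweeps select by AICc with parsimony ties and monotone K", {
  fx <- gibbs_fixture()
  pres <- fx$pres[1:120, ]
  bg <- dplyr::bind_rows(pres, fx$bg)
  fs <- build_features(bg, classes = c("linear", "quadratic", "hinge"),
                       hinge_count = 4)
  sw <- beta_sweep(pres, bg, fs, c(0.25, 0.5, 1, 2, 4, 8))
  expect_equal(nrow(sw$table), 6)
  # K non-increasing in beta (allowing ties)
  expect_true(all(diff(sw$table$K) <= 0))
  expect_equal(sw$table$aicc[sw$table$beta == sw$best_beta],
               min(sw$table$aicc, na.rm = TRUE))
  # single beta -> itself
  sw1 <- beta_sweep(pres, bg, fs, 1)
  expect_equal(sw1$best_beta, 1)
  # selected K never exceeds K at the default multiplier
  k_default <- sw$table$K[sw$table$beta == 1]
  expect_lte(sw$best_model$K, k_default)
})

test_that("cross-validation is seeded and train AUC exceeds test AUC on average", {
  fx <- gibbs_fixture()
  pres <- fx$pres[1:60, ]
  bg <- dplyr::bind_rows(pres, fx$bg)
  fs <- build_features(bg, classes = c("linear", "quadratic", "hinge"),
                       hinge_count = 3)
  cv1 <- cross_validate(pres, bg, fs, beta_multiplier = 0.5,
                        replicates = 8, seed = 7)
  cv2 <- cross_validate(pres, bg, fs, beta_multiplier = 0.5,
                        replicates = 8, seed = 7)
  expect_identical(cv1$replicates, cv2$replicates)
  expect_equal(nrow(cv1$replicates), 8)
  # holdout size: ceil(0.10 * 60) = 6 withheld each time
  expect_true(all(c("K", "mtp", "auc_train", "auc_test") %in% cv1$summary$metric))
  m_train <- cv1$summary$mean[cv1$summary$metric == "auc_train"]
  m_test <- cv1$summary$mean[cv1$summary$metric == "auc_test"]
  expect_gte(m_train, m_test - 0.02)
})

test_that("permutation importance isolates informative variables", {
  set.seed(202)
  bg <- tibble::tibble(x = stats::runif(400, 0, 10),
                       noise = stats::runif(400, 0, 1))
  fs <- build_features(bg, classes = "linear", hinge_count = 0)
  Fb <- feature_matrix(fs, bg)
  w <- exp(3 * Fb[, "lin:x"])
  pres <- bg[sample.int(400, 300, replace = TRUE, prob = w), ]
  m <- maxent_fit(pres, bg, fs, beta_multiplier = 0.05)
  imp <- permutation_importance(m, pres, bg, seed = 1)
  expect_equal(sum(imp$importance), 100)
  # the sole informative variable takes all importance
  expect_gt(imp$importance[imp$variable == "x"], 99)
  # a variable with all-zero coefficients has importance exactly 0
  if (any(m$lambda[fs$var == "noise"] == 0) && all(m$lambda[fs$var == "noise"] == 0)) {
    expect_equal(imp$importance[imp$variable == "noise"], 0)
  }
  # stability across permutation seeds
  imp2 <- permutation_importance(m, pres, bg, seed = 99, n_perm = 2)
  expect_lt(abs(imp2$importance[imp2$variable == "x"] -
                  imp$importance[imp$variable == "x"]), 5)
})

test_that("removing contaminant localities changes the fitted model", {
  g <- test_world()
  sp <- default_species(g, h_true = 3)
  loc <- sample_localities(sp, g, n = 80, error_rate = 0.05, seed = 31)
  cells <- cell_from_lonlat(g, loc$lon, loc$lat)
  bio_all <- derive_bioclim(g, as.matrix(cells))
  bg <- derive_bioclim(g, sample_background(g$land, 300, seed = 32))
  clean <- bio_all[loc$source == "native", ]
  fit_bg_all <- dplyr::bind_rows(bio_all, bg)
  fit_bg_clean <- dplyr::bind_rows(clean, bg)
  fs_all <- build_features(fit_bg_all, hinge_count = 2)
  fs_clean <- build_features(fit_bg_clean, hinge_count = 2)
  m_all <- maxent_fit(bio_all, fit_bg_all, fs_all, beta_multiplier = 1)
  m_clean <- maxent_fit(clean, fit_bg_clean, fs_clean, beta_multiplier = 1)
  # asserted only as "the models differ", not which drivers move
  expect_false(isTRUE(all.equal(m_all$lambda, m_clean$lambda, tolerance = 1e-3)))
})
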