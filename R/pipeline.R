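#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers where possible, otherwise kept as strings; comma-separated
#' values become vectors. Defaults cover every stage of [run_pipeline()], so
#' an empty config is a complete demo configuration.
#'
#' @param path Optional config file; omit for defaults only.
#' @param overrides Named list applied after the file.
#' @return A named list of parameters.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1, width = 48, height = 48,
    seasonal_amplitude = 8, monsoon_strength = 2, noise_sd = 0.5,
    h = 3, a = 0,
    n_localities = 90, coastal_bias_scale = 6, error_rate = 0.045,
    betas = c(0.5, 1, 2, 4, 8, 16),
    n_background = 1000, hinge_count = 4,
    cv_replicates = 5, cv_holdout = 0.10,
    min_coverage = 0.95, mtp_cutoff = 0.1, overfit_factor = 2
  )
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop(sprintf("malformed config line: %s", ln), call. = FALSE)
      key <- trimws(kv[1])
      vals <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
      num <- suppressWarnings(as.numeric(vals))
      cfg[[key]] <- if (!anyNA(num)) num else vals
    }
  }
  utils::modifyList(cfg, overrides)
}

#' Run the full synthetic-world analysis pipeline
#'
#' Simulate a world and a virtual species, sample biased and contaminated
#' localities, fit the rule-based envelope and the maxent model with an
#' AICc beta sweep and cross-validation, derive bioclim variables and their
#' collinearity summary, compute the MESS novelty mask, and screen the
#' candidate models. All products (rasters, CSV reports, and a log of every
#' seed and parameter) are written under `out_dir`; the run is fully
#' deterministic given the config.
#'
#' @param config A [run_config()] list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory results (`grid`, `species`,
#'   `localities`, `envelope`, `capture`, `collinearity`, `sweep`, `cv`,
#'   `mess`, `report`).
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(...)), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cat(sprintf("run started with seed %d\n", config$seed), file = log_path)

  grid <- stage("simulate", generate_climate(
    config$width, config$height,
    seasonal_amplitude = config$seasonal_amplitude,
    monsoon_strength = config$monsoon_strength,
    noise_sd = config$noise_sd, seed = config$seed))
  logf("simulate", "world %dx%d seed=%d", config$width, config$height, config$seed)
  write_monthly_raster(grid, file.path(out_dir, "climate"))

  species <- stage("species", default_species(grid, h_true = config$h, a_true = config$a))
  realized <- stage("species", realized_range(species, grid))
  logf("species", "h_true=%d a_true=%d realized=%d cells",
       species$h_true, species$a_true, sum(realized))

  localities <- stage("sample", sample_localities(
    species, grid, n = config$n_localities,
    coastal_bias_scale = config$coastal_bias_scale,
    error_rate = config$error_rate, seed = config$seed + 1))
  write_localities(localities, file.path(out_dir, "localities.csv"))
  logf("sample", "n=%d error_rate=%g seed=%d",
       config$n_localities, config$error_rate, config$seed + 1)

  env <- stage("envelope", build_envelope(localities, grid, h = config$h, a = config$a))
  env_map <- stage("envelope", project_envelope(env, grid))
  write_suitability(env_map, file.path(out_dir, "envelope_suitability.asc"))
  readr::write_csv(tidy(env), file.path(out_dir, "envelope_hull.csv"))
  logf("envelope", "vertices=%d area=%d cells", nrow(env$hull), envelope_area(env))

  capture <- stage("sensitivity", capture_curve(
    localities, grid, h = config$h, a = config$a, seed = config$seed + 2))
  readr::write_csv(tibble::as_tibble(capture), file.path(out_dir, "capture_curve.csv"))
  logf("sensitivity", "draws=%d seed=%d", capture$n_draws[1], config$seed + 2)

  bg_cells <- stage("bioclim", sample_background(
    grid$land, n = min(config$n_background, sum(grid$land)), seed = config$seed + 3))
  bio_bg <- stage("bioclim", derive_bioclim(grid, bg_cells))
  collin <- stage("bioclim", collinearity_summary(bio_bg))
  readr::write_csv(bio_bg, file.path(out_dir, "bioclim_background.csv"))
  readr::write_csv(glance(collin), file.path(out_dir, "collinearity.csv"))
  logf("bioclim", "background=%d cells seed=%d", nrow(bg_cells), config$seed + 3)

  loc_cells <- cell_from_lonlat(grid, localities$lon, localities$lat)
  bio_pres <- stage("maxent", derive_bioclim(grid, as.matrix(loc_cells)))
  # background is assumed to include the presences (presence-background
  # convention); the sampled cells alone could be separable from them
  bio_fit_bg <- dplyr::bind_rows(bio_pres, bio_bg)
  features <- stage("maxent", build_features(bio_fit_bg, hinge_count = config$hinge_count))
  sweep <- stage("maxent", beta_sweep(bio_pres, bio_fit_bg, features, config$betas))
  readr::write_csv(sweep$table, file.path(out_dir, "beta_sweep.csv"))
  logf("maxent", "best beta=%g K=%d", sweep$best_beta, sweep$best_model$K)

  cv <- stage("maxent", cross_validate(
    bio_pres, bio_fit_bg, features, beta_multiplier = sweep$best_beta,
    replicates = config$cv_replicates, holdout = config$cv_holdout,
    seed = config$seed + 4))
  readr::write_csv(cv$summary, file.path(out_dir, "cv_summary.csv"))
  logf("maxent", "cv replicates=%d holdout=%g seed=%d",
       config$cv_replicates, config$cv_holdout, config$seed + 4)

  reference <- dplyr::bind_rows(bio_pres, bio_bg)
  bio_all <- stage("mess", derive_bioclim(grid))
  mess <- stage("mess", mess_surface(bio_all, reference))
  logf("mess", "novel=%d of %d cells", sum(mess$novel), nrow(mess))

  default_model <- stage("screen", maxent_fit(bio_pres, bio_fit_bg, features,
                                              beta_multiplier = 1))
  native_cov <- function(model) {
    s <- suitability(model, bio_all)
    thr <- min_training_presence(model, bio_pres)
    suitable <- matrix(FALSE, grid$nrow, grid$ncol)
    suitable[cbind(bio_all$row, bio_all$col)] <- s >= thr
    sum(suitable & realized) / max(1, sum(realized))
  }
  metrics <- tibble::tibble(
    name = c("default-beta", sprintf("aicc-beta-%g", sweep$best_beta)),
    native_coverage = c(native_cov(default_model), native_cov(sweep$best_model)),
    mtp = c(min_training_presence(default_model, bio_pres),
            min_training_presence(sweep$best_model, bio_pres)),
    K = c(default_model$K, sweep$best_model$K),
    K_opt = sweep$best_model$K,
    implausible_overlap = NA_real_
  )
  report <- screening_report(metrics,
                             min_coverage = config$min_coverage,
                             mtp_cutoff = config$mtp_cutoff,
                             overfit_factor = config$overfit_factor)
  readr::write_csv(report$table, file.path(out_dir, "screening_report.csv"))
  logf("screen", "retained: %s", paste(report$retained, collapse = ", "))

  cfg_lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(config[[k]], collapse = ","))
  }, character(1))
  writeLines(cfg_lines, file.path(out_dir, "config_used.txt"))

  invisible(list(grid = grid, species = species, localities = localities,
                 envelope = env, capture = capture, collinearity = collin,
                 sweep = sweep, cv = cv, mess = mess, report = report))
}
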