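#' Four-screen evaluation of climate-match models
#'
#' Candidate models are screened, not ranked: each screen can only disqualify.
#' The four screens are (1) native-range inclusion — a model predicting low
#' suitability over a major portion of the occupied native range has failed
#' to capture even the realized climate space (omissions are penalized,
#' commissions never are, because the fundamental climate space is expected
#' to exceed the realized one); (2) minimum training presence — a very low
#' MTP means nearly the whole suitability range is called suitable, i.e. the
#' model barely discriminates; (3) overfitting — parameter counts in excess
#' of a factor of the AICc-optimal count; (4) eco-plausibility — overlap
#' with an expert-supplied mask of regions the species' biology rules out.
#'
#' @name screening
NULL

screen_verdict <- function(pass) ifelse(pass, "pass", "fail")

#' @describeIn screening Native-range inclusion screen. `coverage` is the
#'   fraction of native-range cells predicted suitable; fails when coverage
#'   < `min_coverage`. The 0.95 default operationalizes "any major portion";
#'   it is a package choice, configurable and always reported.
#' @param suit A [suitability_map()] (novel cells count as not-suitable for
#'   coverage, since novelty withholds judgement).
#' @param native Logical native-range mask on the same lattice.
#' @param min_coverage Minimum acceptable coverage.
#' @return `screen_native_range`: list `verdict`, `coverage`, `threshold`.
#' @export
screen_native_range <- function(suit, native, min_coverage = 0.95) {
  if (!identical(dim(native), dim(suit$values))) {
    stop("native mask is not on the map's lattice", call. = FALSE)
  }
  n_native <- sum(native, na.rm = TRUE)
  if (n_native == 0) stop("empty native mask", call. = FALSE)
  suitable <- !is.na(suit$values) & suit$values == 1L
  coverage <- sum(suitable & native) / n_native
  list(verdict = screen_verdict(coverage >= min_coverage),
       coverage = coverage, threshold = min_coverage)
}

#' @describeIn screening Minimum-training-presence screen: fails when
#'   `mtp < cutoff` (default 0.1, i.e. more than 90% of the suitability
#'   range judged suitable).
#' @param mtp Minimum training presence in [0, 1].
#' @param cutoff Failing threshold.
#' @export
screen_mtp <- function(mtp, cutoff = 0.1) {
  stopifnot(mtp >= 0, mtp <= 1)
  list(verdict = screen_verdict(mtp >= cutoff), mtp = mtp, threshold = cutoff)
}

#' @describeIn screening Overfitting screen: fails when the parameter count
#'   strictly exceeds `factor` times the AICc-optimal count.
#' @param K Parameter count of the model under evaluation.
#' @param K_opt AICc-optimal parameter count (>= 1).
#' @param factor Allowed inflation factor (default 2).
#' @export
screen_overfitting <- function(K, K_opt, factor = 2) {
  stopifnot(K_opt >= 1)
  list(verdict = screen_verdict(K <= factor * K_opt),
       K = K, K_opt = K_opt, factor = factor)
}

#' @describeIn screening Eco-plausibility screen: fails when the fraction of
#'   the expert-supplied implausible region predicted suitable exceeds
#'   `max_overlap` (default 0: any overlap fails). An empty mask yields the
#'   verdict `"not evaluated"` — expert input is an input, never inferred.
#' @param implausible Logical mask of ecologically implausible regions.
#' @param max_overlap Tolerated overlap fraction.
#' @export
screen_ecoplausibility <- function(suit, implausible, max_overlap = 0) {
  if (!identical(dim(implausible), dim(suit$values))) {
    stop("implausible mask is not on the map's lattice", call. = FALSE)
  }
  n_imp <- sum(implausible, na.rm = TRUE)
  if (n_imp == 0) {
    return(list(verdict = "not evaluated", overlap = NA_real_,
                threshold = max_overlap))
  }
  suitable <- !is.na(suit$values) & suit$values == 1L
  overlap <- sum(suitable & implausible) / n_imp
  list(verdict = screen_verdict(overlap <= max_overlap),
       overlap = overlap, threshold = max_overlap)
}

#' Aggregate screening report over candidate models
#'
#' Applies the four screens to a table of per-model metrics and lists the
#' retained models: those passing every screen that could be evaluated.
#' Metrics that are `NA` mark a screen as `"not evaluated"` for that model
#' (it then cannot disqualify).
#'
#' @param models A data frame with columns `name`, and any of
#'   `native_coverage`, `mtp`, `K`, `K_opt`, `implausible_overlap`.
#' @param min_coverage,mtp_cutoff,overfit_factor,max_overlap Screen
#'   thresholds (see the individual screens).
#' @return A `screening_report`: list with `table` (tibble: metrics plus the
#'   four verdict columns and `retained`), `retained` (character vector of
#'   model names), and `thresholds`.
#' @export
screening_report <- function(models,
                             min_coverage = 0.95,
                             mtp_cutoff = 0.1,
                             overfit_factor = 2,
                             max_overlap = 0) {
  models <- tibble::as_tibble(models)
  if (nrow(models) == 0) {
    return(structure(list(table = models, retained = character(0),
                          thresholds = list()), class = "screening_report"))
  }
  get_col <- function(nm) if (nm %in% names(models)) models[[nm]] else rep(NA_real_, nrow(models))
  coverage <- get_col("native_coverage")
  mtp <- get_col("mtp")
  K <- get_col("K"); K_opt <- get_col("K_opt")
  overlap <- get_col("implausible_overlap")

  verdict_or_na <- function(metric, pass) {
    ifelse(is.na(metric), "not evaluated", screen_verdict(pass))
  }
  tab <- models
  tab$native_range <- verdict_or_na(coverage, coverage >= min_coverage)
  tab$min_training_presence <- verdict_or_na(mtp, mtp >= mtp_cutoff)
  tab$overfitting <- verdict_or_na(K + K_opt, K <= overfit_factor * K_opt)
  tab$eco_plausibility <- verdict_or_na(overlap, overlap <= max_overlap)
  verdicts <- tab[c("native_range", "min_training_presence",
                    "overfitting", "eco_plausibility")]
  tab$retained <- apply(verdicts, 1, function(v) !any(v == "fail"))
  structure(
    list(table = tab,
         retained = tab$name[tab$retained],
         thresholds = list(min_coverage = min_coverage,
                           mtp_cutoff = mtp_cutoff,
                           overfit_factor = overfit_factor,
                           max_overlap = max_overlap)),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d models, %d retained\n",
              nrow(x$table), length(x$retained)))
  if (nrow(x$table)) {
    print(x$table[c("name", "native_range", "min_training_presence",
                    "overfitting", "eco_plausibility", "retained")])
  }
  invisible(x)
}

#' @export
tidy.screening_report <- function(x, ...) x$table
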