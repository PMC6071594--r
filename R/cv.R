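#' Build the NA10-NA100 year-structured masking schemes
#'
#' For each masking fraction `f` and repeat, a uniform random sample without
#' replacement of `round(f * cohort size)` target-year lines (round half
#' up) becomes the test set; the training set is everything else (all other
#' cohorts plus the unmasked target-year lines). Fraction 1 (NA100, the
#' forward-prediction scenario) yields one deterministic scheme with no
#' repeats. With the study cohort sizes (280, 280, 270, 270) and target
#' 2012 this reproduces the published train/test sizes 1072/28 (NA10),
#' 1044/56 (NA20), 960/140 (NA50) and 820/280 (NA100).
#'
#' @param cohorts named integer vector: year per line.
#' @param target_year cohort year whose lines are masked.
#' @param fractions masking fractions in (0, 1].
#' @param n_repeats random repeats per fraction (default 10).
#' @param seed base seed; repeat `r` uses `seed + r`.
#' @return list of schemes, each a list with `scenario` (e.g. "NA50"),
#'   `target_year`, `repeat_index`, `train_ids`, `test_ids`, `seed`.
#' @export
buildNaSchemes <- function(cohorts, target_year,
                           fractions = seq(0.1, 1.0, by = 0.1),
                           n_repeats = 10, seed = 1) {
  stopifnot(!is.null(names(cohorts)), all(fractions > 0), all(fractions <= 1))
  pool <- names(cohorts)[cohorts == target_year]
  if (!length(pool)) stop("target year absent from cohorts")
  others <- names(cohorts)[cohorts != target_year]
  schemes <- list()
  for (f in fractions) {
    n_test <- roundHalfUp(f * length(pool))
    if (n_test < 1) stop("fraction ", f, " yields an empty test set")
    if (f < 1 && n_test >= length(pool))
      stop("fraction ", f, " leaves no target-year training remainder")
    scen <- paste0("NA", roundHalfUp(100 * f))
    reps <- if (f == 1) 1L else n_repeats
    for (r in seq_len(reps)) {
      if (f == 1) {
        test <- pool
      } else {
        set.seed(as.integer(seed) + r)
        test <- sample(pool, n_test)
      }
      schemes[[length(schemes) + 1L]] <-
        list(scenario = scen, target_year = target_year, repeat_index = r,
             train_ids = c(others, setdiff(pool, test)), test_ids = test,
             seed = as.integer(seed) + r)
    }
  }
  schemes
}

#' Build a skip-year forward-prediction scheme
#'
#' Training set is every cohort except the target year and the skipped year
#' (the year whose advanced trial would coincide with the prediction);
#' the test set is the full target-year cohort.
#'
#' @inheritParams buildNaSchemes
#' @param skip_year cohort year excluded from training (not the target).
#' @return A single scheme list (scenario `"skip<year>"`).
#' @export
buildSkipYearSchemes <- function(cohorts, target_year, skip_year) {
  if (skip_year == target_year) stop("skip_year must differ from target_year")
  years <- unique(cohorts)
  if (!target_year %in% years) stop("target year absent from cohorts")
  if (!skip_year %in% years) stop("skip year absent from cohorts")
  train <- names(cohorts)[!cohorts %in% c(target_year, skip_year)]
  if (!length(train)) stop("no cohort left in the training set")
  list(scenario = paste0("skip", skip_year), target_year = target_year,
       repeat_index = 1L, train_ids = train,
       test_ids = names(cohorts)[cohorts == target_year], seed = NA_integer_)
}

#' Run cross-validation schemes through the GBLUP engine
#'
#' For each scheme the test lines' phenotypes are masked, the GBLUP model
#' fitted on the rest, and the predictive ability (Pearson correlation of
#' test-set GEBVs with test-set yearly BLUPs) computed. Per-repeat values
#' are returned; summarize per scenario with [summarizePa()] (averaging
#' run-level correlations, never pooling pairs across runs).
#'
#' @param yearly_blups named numeric vector: one BLUP per line.
#' @param grm a [Grm-class] covering all scheme lines.
#' @param schemes list of schemes from [buildNaSchemes()] /
#'   [buildSkipYearSchemes()].
#' @param method `"reml"` (deterministic) or `"gibbs"`.
#' @param n_iter,n_burnin,seed Gibbs settings (ignored for REML; each
#'   scheme's own seed is combined with `seed`).
#' @return data.frame with `scenario`, `target_year`, `repeat_index`, `pa`,
#'   `n_test` (PA is `NA` with a warning when the test BLUPs are
#'   degenerate).
#' @export
runCv <- function(yearly_blups, grm, schemes, method = c("reml", "gibbs"),
                  n_iter = 12000, n_burnin = 2000, seed = 1) {
  method <- match.arg(method)
  stopifnot(!is.null(names(yearly_blups)))
  rows <- lapply(schemes, function(sc) {
    ids <- c(sc$train_ids, sc$test_ids)
    if (!all(ids %in% names(yearly_blups)))
      stop("scheme lines missing a yearly BLUP")
    if (!all(ids %in% lineIds(grm)))
      stop("scheme lines missing from the GRM")
    y <- yearly_blups
    y[sc$test_ids] <- NA_real_
    fit <- if (method == "reml") fitGblupReml(y, grm)
           else fitGblupGibbs(y, grm, n_iter, n_burnin,
                              seed = as.integer(seed) +
                                (sc$repeat_index %||% 1L))
    pred <- predictMasked(fit, sc$test_ids)
    obs <- yearly_blups[sc$test_ids]
    pa <- safeCor(pred, obs)
    if (is.na(pa))
      warning("degenerate test-set BLUP variance in ", sc$scenario,
              " repeat ", sc$repeat_index, "; PA recorded as NA")
    data.frame(scenario = sc$scenario, target_year = sc$target_year,
               repeat_index = sc$repeat_index, pa = pa,
               n_test = length(sc$test_ids), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average predictive ability per scenario
#'
#' @param pa_results output of [runCv()].
#' @return data.frame with `scenario`, `target_year`, `mean_pa`,
#'   `n_repeats`.
#' @export
summarizePa <- function(pa_results) {
  agg <- stats::aggregate(pa ~ scenario + target_year, data = pa_results,
                          FUN = function(v) mean(v, na.rm = TRUE))
  n <- stats::aggregate(pa ~ scenario + target_year, data = pa_results,
                        FUN = length)
  names(agg)[3] <- "mean_pa"
  agg$n_repeats <- n$pa
  agg[order(agg$target_year, agg$scenario), , drop = FALSE]
}
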