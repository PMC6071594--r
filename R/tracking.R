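#' Genomic vs phenotypic selection ability for advanced lines
#'
#' Over the advanced lines only, computes `r_gs` = Pearson correlation of
#' the preliminary-trial GEBVs with the advanced-trial BLUPs (genomic
#' selection ability) and `r_ps` = correlation of preliminary-trial BLUPs
#' with advanced-trial BLUPs (phenotypic selection ability).
#'
#' @param pyt_gebv,pyt_blup,ayt_blup named numeric vectors covering
#'   `advanced_ids`.
#' @param advanced_ids ids of the advanced lines (>= 3).
#' @return list with `r_gs`, `r_ps`, `n`.
#' @export
gsVsPs <- function(pyt_gebv, pyt_blup, ayt_blup, advanced_ids) {
  if (length(advanced_ids) < 3) stop("need at least 3 advanced lines")
  for (v in list(pyt_gebv, pyt_blup, ayt_blup))
    if (!all(advanced_ids %in% names(v)))
      stop("advanced line missing a value")
  g <- pyt_gebv[advanced_ids]; b <- pyt_blup[advanced_ids]
  a <- ayt_blup[advanced_ids]
  if (stats::sd(g) == 0 || stats::sd(b) == 0 || stats::sd(a) == 0)
    stop("zero-variance input")
  list(r_gs = stats::cor(g, a), r_ps = stats::cor(b, a),
       n = length(advanced_ids))
}

# classify lines into the four BLUP/GEBV quadrants against thresholds
.quadrants <- function(blup, gebv, thr_blup, thr_gebv) {
  both <- blup >= thr_blup & gebv >= thr_gebv
  blup_only <- blup >= thr_blup & gebv < thr_gebv
  gebv_only <- blup < thr_blup & gebv >= thr_gebv
  c(both_above = sum(both), blup_only = sum(blup_only),
    gebv_only = sum(gebv_only), neither = sum(!both & !blup_only & !gebv_only))
}

#' Quadrant tracking of advanced lines by years retained
#'
#' Classifies each advanced line of a cohort into the four quadrants formed
#' by the cohort-mean BLUP (vertical) and cohort-mean or 75th-percentile
#' GEBV (horizontal) thresholds, tabulated by the number of years the line
#' was retained. "Above" is the non-strict `>=`. The mean BLUP of the
#' advanced subset is reported as the secondary vertical threshold.
#'
#' @param yearly_blups named numeric vector of cohort BLUPs.
#' @param gebv named numeric vector of cohort GEBVs.
#' @param records data.frame with `line_id` and `years_retained` (e.g. from
#'   [simulateAdvancement()], one cohort at a time).
#' @param threshold `"mean"` (default) or `"p75"` for the GEBV axis.
#' @return list of class `"QuadrantCounts"`: `counts` (matrix, one row per
#'   years-retained class, columns both_above/blup_only/gebv_only/neither),
#'   `frac_both_above` per class, `thresholds` (named: blup mean, gebv
#'   threshold, advanced-subset blup mean).
#' @export
quadrantTracking <- function(yearly_blups, gebv, records,
                             threshold = c("mean", "p75")) {
  threshold <- match.arg(threshold)
  tracked <- records$line_id
  if (!all(tracked %in% names(yearly_blups)) ||
      !all(tracked %in% names(gebv)))
    stop("every tracked line needs a BLUP and a GEBV")
  thr_blup <- mean(yearly_blups)
  thr_gebv <- if (threshold == "mean") mean(gebv)
              else stats::quantile(gebv, 0.75, names = FALSE, type = 7)
  adv <- records[records$years_retained >= 2, , drop = FALSE]
  classes <- sort(unique(adv$years_retained))
  counts <- t(vapply(classes, function(k) {
    ids <- adv$line_id[adv$years_retained == k]
    .quadrants(yearly_blups[ids], gebv[ids], thr_blup, thr_gebv)
  }, numeric(4)))
  rownames(counts) <- paste0("retained_", classes)
  frac <- counts[, "both_above"] / pmax(rowSums(counts), 1)
  structure(list(counts = counts, frac_both_above = frac,
                 thresholds = c(blup_mean = thr_blup, gebv_thr = thr_gebv,
                                advanced_blup_mean =
                                  mean(yearly_blups[adv$line_id]))),
            class = "QuadrantCounts")
}

#' @export
print.QuadrantCounts <- function(x, ...) {
  print(x$counts)
  cat("fraction both-above:",
      paste(sprintf("%.2f", x$frac_both_above), collapse = ", "), "\n")
  invisible(x)
}

#' Quadrant tracking with NA50-style GEBVs
#'
#' Recomputes each cohort's GEBVs under the half-masking scenario: the
#' cohort is split into two random halves; each half in turn is masked and
#' predicted from the other half plus all other cohorts, and every line's
#' GEBV is taken from the single fit in which it was masked (so predictions
#' never condition on a line's own phenotype). Quadrant tabulation then
#' proceeds as in [quadrantTracking()].
#'
#' @param yearly_blups named numeric vector over all lines (all cohorts).
#' @param grm a [Grm-class] over all lines.
#' @param cohorts named integer vector, year per line.
#' @param records advancement records for the tracked cohort (`line_id`,
#'   `years_retained`); all from one `origin_year`.
#' @param target_year cohort year to track (defaults to
#'   `records$origin_year[1]`).
#' @param threshold `"mean"` or `"p75"` as in [quadrantTracking()].
#' @param method GBLUP engine, `"reml"` or `"gibbs"`.
#' @param seed integer seed for the half-split.
#' @param ... further arguments to [runCv()]'s engine (Gibbs settings).
#' @return A `"QuadrantCounts"` with an extra `gebv` element (the
#'   masked-half GEBVs of the cohort).
#' @export
na50TrackingVariant <- function(yearly_blups, grm, cohorts, records,
                                target_year = NULL,
                                threshold = c("mean", "p75"),
                                method = c("reml", "gibbs"), seed = 1, ...) {
  threshold <- match.arg(threshold)
  method <- match.arg(method)
  if (is.null(target_year)) target_year <- records$origin_year[1]
  pool <- names(cohorts)[cohorts == target_year]
  if (length(pool) < 2) stop("cohort too small to split")
  set.seed(substreamSeed(as.integer(seed), "cv"))
  half1 <- sample(pool, roundHalfUp(length(pool) / 2))
  halves <- list(half1, setdiff(pool, half1))
  gebv_cohort <- stats::setNames(rep(NA_real_, length(pool)), pool)
  for (h in halves) {
    y <- yearly_blups
    y[h] <- NA_real_
    fit <- if (method == "reml") fitGblupReml(y, grm)
           else fitGblupGibbs(y, grm, seed = seed, ...)
    gebv_cohort[h] <- predictMasked(fit, h)
  }
  blups_cohort <- yearly_blups[pool]
  out <- quadrantTracking(blups_cohort, gebv_cohort, records, threshold)
  out$gebv <- gebv_cohort
  out
}
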