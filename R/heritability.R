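#' Broad-sense heritability within a location
#'
#' Plug-in estimate `H = sigma_G^2 / (sigma_G^2 + sigma_R^2 / r)` from a
#' fitted location model, where `r` is the number of replicates within the
#' location. For unreplicated augmented trials `r = 1` (genetic and residual
#' variances are separated through the replicated checks).
#'
#' @param fit a `"LocationFit"` (or any list with a `varcomps` element
#'   carrying `sigma_G2` and `sigma_R2`).
#' @param r number of replicates within the location (>= 1).
#' @return list of class `"Heritability"`: `H`, `sigma_G2`, `sigma_R2`,
#'   `divisor`, `scope`.
#' @examples
#' f <- list(varcomps = c(sigma_G2 = 1, sigma_R2 = 1), converged = TRUE)
#' h2WithinLocation(f, r = 1)$H  # 0.5
#' h2WithinLocation(f, r = 2)$H  # 2/3
#' @export
h2WithinLocation <- function(fit, r = 1) {
  stopifnot(r >= 1)
  if (!is.null(fit$converged) && !fit$converged)
    stop("fit did not converge")
  sg <- max(unname(fit$varcomps["sigma_G2"]), 0)
  se <- max(unname(fit$varcomps["sigma_R2"]), 0)
  denom <- sg + se / r
  if (denom == 0) stop("zero total variance; heritability undefined")
  structure(list(H = sg / denom, sigma_G2 = sg, sigma_R2 = se,
                 divisor = as.integer(r), scope = "within_location"),
            class = "Heritability")
}

# long-format helper: accepts a line x location matrix or a long data.frame
.blupLong <- function(location_blups) {
  if (is.matrix(location_blups)) {
    df <- data.frame(line_id = rep(rownames(location_blups),
                                   ncol(location_blups)),
                     location = rep(colnames(location_blups),
                                    each = nrow(location_blups)),
                     blup = as.vector(location_blups),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(location_blups)
    stopifnot(all(c("line_id", "location", "blup") %in% names(df)))
  }
  df[!is.na(df$blup), , drop = FALSE]
}

#' Broad-sense heritability across locations within a year
#'
#' Fits `blup = mu + location (fixed) + line (random) + e` by REML on the
#' per-location BLUP table (locations are fixed because they are
#' preselected) and returns
#' `H = sigma_G^2 / (sigma_G^2 + sigma_R^2 / L)` with `L` the number of
#' locations. Negative component estimates are clipped at zero (flagged via
#' the `boundary` element).
#'
#' @param location_blups a line x location numeric matrix (NAs allowed) or a
#'   long data.frame with columns `line_id`, `location`, `blup`.
#' @return list of class `"Heritability"` with `H`, `sigma_G2`, `sigma_R2`,
#'   `divisor` (= L), `scope`, `boundary`.
#' @export
h2AcrossLocations <- function(location_blups) {
  df <- .blupLong(location_blups)
  L <- length(unique(df$location))
  if (L < 2) stop("at least 2 locations required")
  if (stats::sd(df$blup) == 0) stop("all-constant input")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(blup ~ factor(location) + (1 | line_id), data = df,
               REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sg <- max(vc$vcov[vc$grp == "line_id"], 0)
  se <- max(vc$vcov[vc$grp == "Residual"], 0)
  denom <- sg + se / L
  if (denom == 0) stop("zero total variance; heritability undefined")
  structure(list(H = sg / denom, sigma_G2 = sg, sigma_R2 = se,
                 divisor = as.integer(L), scope = "across_locations",
                 boundary = (sg == 0 || se == 0)),
            class = "Heritability")
}

#' Heritability accumulation over sequentially added locations
#'
#' Recomputes the across-location heritability on the first `k` locations of
#' `ordering` for `k = 2, ..., L`, mirroring the sequential-addition curves
#' used to show how testing more locations raises `H`.
#'
#' @param location_blups as in [h2AcrossLocations()].
#' @param ordering character vector, a permutation of the available
#'   locations (default: their natural order).
#' @return data.frame with `k`, `location_added`, `H`.
#' @export
h2Accumulation <- function(location_blups, ordering = NULL) {
  df <- .blupLong(location_blups)
  locs <- unique(df$location)
  if (is.null(ordering)) ordering <- locs
  if (!setequal(ordering, locs))
    stop("ordering must be a permutation of the available locations")
  out <- lapply(2:length(ordering), function(k) {
    sub <- df[df$location %in% ordering[seq_len(k)], , drop = FALSE]
    data.frame(k = k, location_added = ordering[k],
               H = h2AcrossLocations(sub)$H, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.Heritability <- function(x, ...) {
  cat(sprintf("H = %.3f (%s, divisor %d); sigma_G2 = %.4g, sigma_R2 = %.4g\n",
              x$H, x$scope, x$divisor, x$sigma_G2, x$sigma_R2))
  invisible(x)
}
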