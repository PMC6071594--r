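#' Filter markers by missingness
#'
#' Removes markers whose fraction of missing calls exceeds `max_missing`
#' (strictly greater than: a marker missing in exactly 80% of lines is
#' retained at the default threshold).
#'
#' @param panel a [GenotypePanel-class].
#' @param max_missing maximum tolerated missing fraction, in (0, 1].
#' @return The filtered [GenotypePanel-class]; the number of removed markers
#'   is logged.
#' @export
filterMissingness <- function(panel, max_missing = 0.80) {
  stopifnot(is(panel, "GenotypePanel"), max_missing > 0, max_missing <= 1)
  frac <- colMeans(is.na(calls(panel)))
  keep <- frac <= max_missing
  if (!any(keep)) stop("all markers removed by the missingness filter")
  bgsLog("filterMissingness: removed ", sum(!keep), " of ", length(keep),
         " markers (> ", 100 * max_missing, "% missing)")
  subsetMarkers(panel, keep)
}

#' Filter markers by minor allele frequency and imputation quality
#'
#' Removes markers with MAF strictly below `maf_min` (heterozygotes counted
#' as half an allele, missing calls excluded) or allelic R-squared strictly
#' below `r2_min`. The quality filter is skipped with a warning when the
#' panel carries no allelic R-squared scores.
#'
#' @param panel a [GenotypePanel-class].
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param r2_min minimum allelic R-squared (default 0.5); set `NULL` to skip.
#' @return The filtered [GenotypePanel-class].
#' @export
filterMafQuality <- function(panel, maf_min = 0.05, r2_min = 0.5) {
  stopifnot(is(panel, "GenotypePanel"))
  keep <- maf(panel) >= maf_min
  n_maf <- sum(!keep)
  if (!is.null(r2_min)) {
    r2 <- allelicR2(panel)
    if (!length(r2)) {
      warning("no allelic R2 scores available; quality filter skipped")
    } else {
      r2v <- rep(NA_real_, ncol(calls(panel)))
      names(r2v) <- markerIds(panel)
      r2v[names(r2)] <- r2
      keep <- keep & !is.na(r2v) & r2v >= r2_min
    }
  }
  if (!any(keep)) stop("all markers removed by the MAF/quality filter")
  bgsLog("filterMafQuality: removed ", sum(!keep), " markers (",
         n_maf, " by MAF)")
  subsetMarkers(panel, keep)
}

# subset a panel's markers, keeping map and quality scores aligned
subsetMarkers <- function(panel, keep) {
  m <- calls(panel)[, keep, drop = FALSE]
  ids <- colnames(m)
  map <- markerMap(panel)
  if (nrow(map)) map <- map[map$marker_id %in% ids, , drop = FALSE]
  r2 <- allelicR2(panel)
  if (length(r2)) r2 <- r2[names(r2) %in% ids]
  GenotypePanel(m, map = map, allelicR2 = r2)
}

#' Encode half-dosage calls as 2/0/1 dosages
#'
#' Multiplies the half-dosage calls by two: 1 -> 2 (homozygous major),
#' 0 -> 0 (homozygous minor), 0.5 -> 1 (heterozygous). Missing calls are
#' either an error (default) or naively filled with the column mean dosage
#' when `fill = TRUE` (flagged in a log message).
#'
#' @param panel a [GenotypePanel-class].
#' @param fill fill missing calls with the column mean dosage?
#' @return A [NumericGenotypes-class] when the matrix is fully observed, or
#'   (with `fill = TRUE` and actual fills) a plain numeric matrix carrying
#'   non-integer filled dosages suitable for [computeGrm()].
#' @export
encodeNumeric <- function(panel, fill = FALSE) {
  stopifnot(is(panel, "GenotypePanel"))
  X <- calls(panel) * 2
  if (anyNA(X)) {
    if (!fill)
      stop("missing calls present; filter or enable fill before encoding")
    n_fill <- sum(is.na(X))
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
    bgsLog("encodeNumeric: filled ", n_fill,
           " missing calls with column-mean dosages")
    return(X)
  }
  new("NumericGenotypes", X = X)
}

#' Compute the genomic relationship matrix
#'
#' Centers each marker column by its mean and scales by its standard
#' deviation (n-1 denominator), then returns `G = X X' / p` with `p` the
#' number of retained markers. Zero-variance columns are dropped with a
#' warning. Under this scaling `mean(diag(G)) = (n - 1) / n` exactly.
#'
#' @param num a [NumericGenotypes-class] or a numeric line x marker matrix
#'   (e.g. the filled output of [encodeNumeric()]).
#' @return A [Grm-class].
#' @examples
#' X <- matrix(sample(0:2, 24, TRUE), 4, 6,
#'             dimnames = list(paste0("L", 1:4), paste0("M", 1:6)))
#' g <- computeGrm(new("NumericGenotypes", X = X))
#' mean(diag(grmMatrix(g)))  # (4 - 1) / 4
#' @export
computeGrm <- function(num) {
  X <- if (is(num, "NumericGenotypes")) dosages(num) else num
  if (nrow(X) < 2) stop("at least 2 lines required")
  if (anyNA(X)) stop("missing dosages; fill or filter first")
  s <- apply(X, 2, stats::sd)
  keep <- s > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance marker(s) dropped from the GRM")
    X <- X[, keep, drop = FALSE]
  }
  p <- ncol(X)
  if (p == 0) stop("no polymorphic markers left")
  Xs <- scale(X, center = TRUE, scale = TRUE)
  G <- tcrossprod(Xs) / p
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(X), rownames(X))
  new("Grm", G = G, nMarkersUsed = as.integer(p))
}
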