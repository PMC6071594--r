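#' @import methods
NULL

HALF_DOSAGE_ALPHABET <- c(0, 0.5, 1)

#' GenotypePanel: line-by-marker genotype calls
#'
#' Container for a line x marker matrix of genotype calls in the
#' "half-dosage" coding used by the deposited panel dialect: 1 = homozygous
#' major, 0 = homozygous minor, 0.5 = heterozygous, `NA` = missing. An
#' optional marker map (chromosome, position) and optional per-marker
#' imputation-quality scores (allelic R-squared in `[0, 1]`) travel with the
#' calls so downstream filters can consume them.
#'
#' @slot calls numeric matrix, rows = lines, columns = markers, entries in
#'   \{1, 0, 0.5, NA\}; dimnames carry line and marker ids.
#' @slot map data.frame with columns `marker_id`, `chrom`, `pos` (possibly
#'   zero rows when no map is available).
#' @slot allelicR2 named numeric vector of per-marker imputation quality
#'   scores (length zero when absent).
#'
#' @seealso [readGenotypeMatrix()], [vcfToCalls()], [filterMissingness()],
#'   [encodeNumeric()]
#' @export
setClass("GenotypePanel",
  representation(calls = "matrix", map = "data.frame", allelicR2 = "numeric"))

setValidity("GenotypePanel", function(object) {
  msg <- character()
  cl <- object@calls
  if (is.null(rownames(cl)) || is.null(colnames(cl)))
    msg <- c(msg, "calls must have line ids as rownames and marker ids as colnames")
  if (anyDuplicated(rownames(cl)))
    msg <- c(msg, "duplicated line ids")
  if (anyDuplicated(colnames(cl)))
    msg <- c(msg, "duplicated marker ids")
  vals <- cl[!is.na(cl)]
  if (length(vals) && !all(vals %in% HALF_DOSAGE_ALPHABET))
    msg <- c(msg, "calls outside the {1, 0, 0.5, NA} alphabet")
  if (nrow(object@map) > 0) {
    if (!all(c("marker_id", "chrom", "pos") %in% names(object@map)))
      msg <- c(msg, "map must have columns marker_id, chrom, pos")
    else {
      if (anyDuplicated(object@map$marker_id))
        msg <- c(msg, "map entries must be unique per marker_id")
      if (!all(object@map$marker_id %in% colnames(cl)))
        msg <- c(msg, "map contains markers absent from the calls matrix")
    }
  }
  if (length(object@allelicR2)) {
    if (is.null(names(object@allelicR2)) ||
        !all(names(object@allelicR2) %in% colnames(cl)))
      msg <- c(msg, "allelicR2 must be named by marker ids present in calls")
    r2 <- object@allelicR2[!is.na(object@allelicR2)]
    if (length(r2) && (any(r2 < 0) || any(r2 > 1)))
      msg <- c(msg, "allelicR2 values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' @param calls numeric matrix of calls in \{1, 0, 0.5, NA\} with line ids as
#'   rownames and marker ids as colnames.
#' @param map optional data.frame (`marker_id`, `chrom`, `pos`).
#' @param allelicR2 optional named numeric vector of per-marker imputation
#'   quality scores.
#' @return A [GenotypePanel-class] object.
#' @examples
#' m <- matrix(c(1, 0, 0.5, 1), 2, 2,
#'             dimnames = list(c("L1", "L2"), c("M1", "M2")))
#' GenotypePanel(m)
#' @export
GenotypePanel <- function(calls, map = NULL, allelicR2 = NULL) {
  if (is.null(map))
    map <- data.frame(marker_id = character(), chrom = character(),
                      pos = integer(), stringsAsFactors = FALSE)
  if (is.null(allelicR2)) allelicR2 <- numeric()
  storage.mode(calls) <- "double"
  new("GenotypePanel", calls = calls, map = map, allelicR2 = allelicR2)
}

#' NumericGenotypes: centered-ready dosage matrix
#'
#' Line x marker matrix of minor-allele-reference dosages on the 2/0/1 scale
#' (2 = homozygous major, 0 = homozygous minor, 1 = heterozygous), i.e. the
#' half-dosage calls multiplied by 2. No missing values are allowed: filling
#' or filtering must precede encoding.
#'
#' @slot X numeric matrix of dosages in \{0, 1, 2\} with line/marker dimnames.
#' @seealso [encodeNumeric()], [computeGrm()], [genotypePca()]
#' @export
setClass("NumericGenotypes", representation(X = "matrix"))

setValidity("NumericGenotypes", function(object) {
  msg <- character()
  X <- object@X
  if (is.null(rownames(X)) || is.null(colnames(X)))
    msg <- c(msg, "X must carry line and marker ids as dimnames")
  if (anyNA(X))
    msg <- c(msg, "X may not contain missing values")
  else if (length(X) && !all(X %in% c(0, 1, 2)))
    msg <- c(msg, "dosages outside the {0, 1, 2} alphabet")
  if (length(msg)) msg else TRUE
})

#' Grm: genomic relationship matrix
#'
#' Realized genomic relationship matrix `G = X X' / p` computed from the
#' column-centered, column-scaled dosage matrix of `p` markers. Under this
#' scaling the mean diagonal element is exactly `(n - 1) / n`.
#'
#' @slot G symmetric numeric line x line matrix.
#' @slot nMarkersUsed integer, number of markers entering the cross-product.
#' @seealso [computeGrm()], [mrkc()], [fitGblupReml()]
#' @export
setClass("Grm", representation(G = "matrix", nMarkersUsed = "integer"))

setValidity("Grm", function(object) {
  msg <- character()
  G <- object@G
  if (nrow(G) != ncol(G)) msg <- c(msg, "G must be square")
  if (is.null(rownames(G)) || !identical(rownames(G), colnames(G)))
    msg <- c(msg, "G must have identical line ids on rows and columns")
  if (nrow(G) && max(abs(G - t(G))) > 1e-10)
    msg <- c(msg, "G must be symmetric to 1e-10")
  if (length(msg)) msg else TRUE
})

#' GblupFit: fitted GBLUP model
#'
#' Result of fitting `y = mu + g + e` with `g ~ N(0, G sigma_g^2)` either by
#' Gibbs sampling (posterior means) or by eigendecomposition REML (exact
#' BLUPs at the variance estimates). GEBVs are defined for every line in G,
#' including lines whose phenotype was missing or masked.
#'
#' @slot mu numeric intercept estimate.
#' @slot gebv named numeric vector of genomic estimated breeding values.
#' @slot sigmaG2 numeric genomic variance estimate (>= 0).
#' @slot sigmaE2 numeric residual variance estimate (>= 0).
#' @slot method character, `"gibbs"` or `"reml"`.
#' @slot nIter,nBurnin integer Gibbs settings (0 for REML).
#' @slot seed integer seed used for the sampler (NA for REML).
#' @slot observedIds character vector of lines whose phenotype entered the fit.
#' @export
setClass("GblupFit",
  representation(mu = "numeric", gebv = "numeric", sigmaG2 = "numeric",
                 sigmaE2 = "numeric", method = "character", nIter = "integer",
                 nBurnin = "integer", seed = "integer",
                 observedIds = "character"))

setValidity("GblupFit", function(object) {
  msg <- character()
  if (is.null(names(object@gebv)))
    msg <- c(msg, "gebv must be named by line ids")
  if (!object@method %in% c("gibbs", "reml"))
    msg <- c(msg, "method must be 'gibbs' or 'reml'")
  if (!is.na(object@sigmaG2) && object@sigmaG2 < 0)
    msg <- c(msg, "sigmaG2 must be >= 0")
  if (!is.na(object@sigmaE2) && object@sigmaE2 < 0)
    msg <- c(msg, "sigmaE2 must be >= 0")
  if (!all(object@observedIds %in% names(object@gebv)))
    msg <- c(msg, "observedIds must be a subset of the gebv names")
  if (length(msg)) msg else TRUE
})
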