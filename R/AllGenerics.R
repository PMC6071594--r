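#' Accessors for genotype containers
#'
#' `calls()` returns the raw half-dosage call matrix, `dosages()` the 0/1/2
#' numeric matrix, `lineIds()` / `markerIds()` the identifier vectors,
#' `markerMap()` the per-marker map, `allelicR2()` the imputation quality
#' scores, `maf()` the per-marker minor allele frequency (heterozygotes
#' counted as half an allele, missing calls excluded), `grmMatrix()` the
#' dense relationship matrix, `nMarkersUsed()` the number of markers behind
#' a GRM, `gebv()` the genomic estimated breeding values and `varComps()`
#' the variance components of a fit.
#'
#' @param object a [GenotypePanel-class], [NumericGenotypes-class],
#'   [Grm-class] or [GblupFit-class] object as appropriate.
#' @return The slot contents described above; `maf()` returns a named
#'   numeric vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("calls", function(object) standardGeneric("calls"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("lineIds", function(object) standardGeneric("lineIds"))
#' @rdname accessors
#' @export
setGeneric("markerIds", function(object) standardGeneric("markerIds"))
#' @rdname accessors
#' @export
setGeneric("markerMap", function(object) standardGeneric("markerMap"))
#' @rdname accessors
#' @export
setGeneric("allelicR2", function(object) standardGeneric("allelicR2"))
#' @rdname accessors
#' @export
setGeneric("maf", function(object) standardGeneric("maf"))
#' @rdname accessors
#' @export
setGeneric("grmMatrix", function(object) standardGeneric("grmMatrix"))
#' @rdname accessors
#' @export
setGeneric("nMarkersUsed", function(object) standardGeneric("nMarkersUsed"))
#' @rdname accessors
#' @export
setGeneric("gebv", function(object) standardGeneric("gebv"))
#' @rdname accessors
#' @export
setGeneric("varComps", function(object) standardGeneric("varComps"))

#' @rdname accessors
setMethod("calls", "GenotypePanel", function(object) object@calls)
#' @rdname accessors
setMethod("lineIds", "GenotypePanel", function(object) rownames(object@calls))
#' @rdname accessors
setMethod("markerIds", "GenotypePanel", function(object) colnames(object@calls))
#' @rdname accessors
setMethod("markerMap", "GenotypePanel", function(object) object@map)
#' @rdname accessors
setMethod("allelicR2", "GenotypePanel", function(object) object@allelicR2)

#' @rdname accessors
setMethod("maf", "GenotypePanel", function(object) {
  # count minor alleles (hom-minor = 2, het = 1) over the observed calls so
  # frequencies at filter boundaries are exact ratios of integers
  cl <- object@calls
  minor <- 2 * colSums(cl == 0, na.rm = TRUE) + colSums(cl == 0.5, na.rm = TRUE)
  total <- 2 * colSums(!is.na(cl))
  p <- minor / total
  pmin(p, 1 - p)
})

#' @rdname accessors
setMethod("dosages", "NumericGenotypes", function(object) object@X)
#' @rdname accessors
setMethod("lineIds", "NumericGenotypes", function(object) rownames(object@X))
#' @rdname accessors
setMethod("markerIds", "NumericGenotypes", function(object) colnames(object@X))

#' @rdname accessors
setMethod("grmMatrix", "Grm", function(object) object@G)
#' @rdname accessors
setMethod("lineIds", "Grm", function(object) rownames(object@G))
#' @rdname accessors
setMethod("nMarkersUsed", "Grm", function(object) object@nMarkersUsed)

#' @rdname accessors
setMethod("gebv", "GblupFit", function(object) object@gebv)
#' @rdname accessors
setMethod("varComps", "GblupFit", function(object)
  c(sigmaG2 = object@sigmaG2, sigmaE2 = object@sigmaE2))

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel:", nrow(object@calls), "lines x",
      ncol(object@calls), "markers\n")
  miss <- mean(is.na(object@calls))
  cat(sprintf("  missing calls: %.2f%%; map: %s; allelic R2: %s\n",
              100 * miss,
              if (nrow(object@map)) "yes" else "no",
              if (length(object@allelicR2)) "yes" else "no"))
})

setMethod("show", "Grm", function(object) {
  cat("Grm:", nrow(object@G), "lines,", object@nMarkersUsed,
      "markers used\n")
  if (nrow(object@G))
    cat(sprintf("  mean diagonal: %.4f\n", mean(diag(object@G))))
})

setMethod("show", "GblupFit", function(object) {
  cat(sprintf("GblupFit (%s): %d lines (%d observed)\n", object@method,
              length(object@gebv), length(object@observedIds)))
  cat(sprintf("  mu = %.4g, sigma_g^2 = %.4g, sigma_e^2 = %.4g\n",
              object@mu, object@sigmaG2, object@sigmaE2))
})
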