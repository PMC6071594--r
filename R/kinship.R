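#' Maximum realized kinship coefficient between test and training sets
#'
#' For each test line `i`, `mrkc_i = max_j G[i, j]` over the training lines
#' `j`, a diagnostic of how related the test set is to the lines the model
#' learns from; the arithmetic mean over test lines summarizes the set.
#'
#' @param grm a [Grm-class].
#' @param test_ids,train_ids disjoint, non-empty sets of line ids in G.
#' @return list of class `"KinshipSummary"`: `mrkc` (named per-test-line),
#'   `mean_mrkc`, `test_ids`, `train_ids`.
#' @export
mrkc <- function(grm, test_ids, train_ids) {
  stopifnot(length(test_ids) > 0, length(train_ids) > 0)
  if (length(intersect(test_ids, train_ids)))
    stop("test and training sets overlap")
  G <- grmMatrix(grm)
  unknown <- setdiff(c(test_ids, train_ids), rownames(G))
  if (length(unknown))
    stop("ids not in G: ", paste(utils::head(unknown, 5), collapse = ", "))
  vals <- apply(G[test_ids, train_ids, drop = FALSE], 1, max)
  structure(list(mrkc = vals, mean_mrkc = mean(vals),
                 test_ids = test_ids, train_ids = train_ids),
            class = "KinshipSummary")
}

#' @export
print.KinshipSummary <- function(x, ...) {
  cat(sprintf("MRKC over %d test vs %d training lines: mean %.3f (range %.3f-%.3f)\n",
              length(x$test_ids), length(x$train_ids), x$mean_mrkc,
              min(x$mrkc), max(x$mrkc)))
  invisible(x)
}

#' Principal component analysis of the genotype matrix
#'
#' Eigen-analysis (via SVD) of the same column-centered, column-scaled
#' dosage matrix that underlies the GRM, so PCA scores and GRM share
#' eigenvectors. Variance explained is `100 * lambda_k / sum(lambda)` over
#' all components and sums to 100.
#'
#' @param num a [NumericGenotypes-class] or numeric line x marker matrix.
#' @param n_components number of components to return (default all).
#' @return list of class `"PcaResult"`: `scores` (line x component),
#'   `varexp` (percent per returned component), `varexp_all` (all
#'   components), `n_components`.
#' @export
genotypePca <- function(num, n_components = NULL) {
  X <- if (is(num, "NumericGenotypes")) dosages(num) else num
  if (nrow(X) < 2) stop("at least 2 lines required")
  s <- apply(X, 2, stats::sd)
  Xs <- scale(X[, s > 0, drop = FALSE], center = TRUE, scale = TRUE)
  sv <- svd(Xs)
  lambda <- sv$d^2
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank)
    stop("n_components exceeds the matrix rank (", rank, ")")
  scores <- sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  varexp_all <- 100 * lambda / sum(lambda)
  structure(list(scores = scores,
                 varexp = varexp_all[seq_len(n_components)],
                 varexp_all = varexp_all,
                 n_components = as.integer(n_components)),
            class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "lines,", x$n_components, "components\n")
  cat("  varexp (%):", paste(sprintf("%.1f", utils::head(x$varexp, 5)),
                             collapse = ", "),
      if (x$n_components > 5) "..." else "", "\n")
  invisible(x)
}
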