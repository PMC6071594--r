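# Shared fixtures, built once per test run.
options(BreedGS.verbose = FALSE)

# small two-cohort population used across modules
tiny_cfg <- simConfig(n_founders = 40, n_markers = 300, n_years = 2,
                      lines_per_year = c(60, 60), n_qtl = 40,
                      n_locations = 3, field_dims = c(10, 8),
                      h2_line_mean = 0.5, seed = 42)
tiny_sim <- simulateCohorts(tiny_cfg)
tiny_grm <- suppressWarnings(computeGrm(encodeNumeric(tiny_sim$panel)))

# a deterministic small trial table with two replicated checks
makeToyTrial <- function(n_lines = 16, n_checks = 2, seed = 5, sd_y = 3) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  checks <- paste0("C", seq_len(n_checks))
  ids <- c(lines, rep(checks, 2))
  n <- length(ids)
  nc <- 5
  data.frame(line_id = ids, year = 2012L, location = "X",
             row = ((seq_len(n) - 1) %/% nc) + 1L,
             col = ((seq_len(n) - 1) %% nc) + 1L,
             block = rep(1:2, each = ceiling(n / 2))[seq_len(n)],
             rep = 1L,
             is_check = ids %in% checks,
             yield = stats::rnorm(n, 50, sd_y),
             stringsAsFactors = FALSE)
}

# hand-rolled GRM oracle: explicit double loop over centered/scaled columns
grmOracle <- function(X) {
  n <- nrow(X); p <- ncol(X)
  Xs <- matrix(0, n, p)
  for (j in seq_len(p)) Xs[, j] <- (X[, j] - mean(X[, j])) / stats::sd(X[, j])
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n))
    G[i, k] <- sum(Xs[i, ] * Xs[k, ]) / p
  dimnames(G) <- list(rownames(X), rownames(X))
  G
}

# dense mixed-model-equation BLUP oracle for y = 1 mu + g + e,
# g ~ N(0, G sg2): g_hat = sg2 G (sg2 G + se2 I)^{-1} (y - mu_gls)
mmeGblupOracle <- function(y, G, sg2, se2) {
  V <- sg2 * G + se2 * diag(length(y))
  Vi <- solve(V)
  one <- rep(1, length(y))
  mu <- drop(crossprod(one, Vi %*% y) / crossprod(one, Vi %*% one))
  list(mu = mu, g = drop(sg2 * G %*% Vi %*% (y - mu)))
}
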