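# shared preparation: align phenotypes with the GRM, eigendecompose the
# observed block with a PSD guard (eigenvalues floored at 1e-8 * max)
.gblupPrep <- function(y, grm) {
  G <- grmMatrix(grm)
  ids <- rownames(G)
  if (is.null(names(y))) {
    if (length(y) != length(ids)) stop("unnamed y must match G's dimension")
    names(y) <- ids
  }
  if (!all(names(y) %in% ids)) stop("phenotyped lines missing from G")
  yv <- stats::setNames(rep(NA_real_, length(ids)), ids)
  yv[names(y)] <- y
  obs <- ids[!is.na(yv)]
  if (length(obs) < 2) stop("at least 2 observed phenotypes required")
  Go <- G[obs, obs, drop = FALSE]
  eg <- eigen(Go, symmetric = TRUE)
  dmax <- max(eg$values)
  if (min(eg$values) < -1e-8 * max(dmax, 1))
    stop("G is not positive semidefinite beyond tolerance; ",
         "add a small diagonal jitter (e.g. G + 1e-6 * I)")
  d <- pmax(eg$values, 1e-8 * max(dmax, 1e-12))
  list(G = G, ids = ids, obs = obs, unobs = setdiff(ids, obs),
       y = yv[obs], U = eg$vectors, d = d)
}

.constantFit <- function(prep, method, n_iter = 0L, n_burnin = 0L,
                         seed = NA_integer_) {
  gebv <- stats::setNames(rep(0, length(prep$ids)), prep$ids)
  new("GblupFit", mu = unname(prep$y[1]), gebv = gebv, sigmaG2 = 0,
      sigmaE2 = 0, method = method, nIter = as.integer(n_iter),
      nBurnin = as.integer(n_burnin), seed = as.integer(seed),
      observedIds = prep$obs)
}

#' Fit GBLUP by eigendecomposition REML
#'
#' Deterministic solver for `y = mu + g + e`, `g ~ N(0, G sigma_g^2)`,
#' `e ~ N(0, I sigma_e^2)`: the observed block of G is eigendecomposed once
#' and the REML criterion maximized over the single variance ratio
#' `lambda = sigma_g^2 / sigma_e^2`. BLUPs at the estimates are
#' `g_hat = lambda G[, obs] (I + lambda G_obs)^{-1} (y - mu)`, which extends
#' the prediction to unobserved lines through the genomic covariances.
#'
#' @param y named numeric vector of line phenotypes (yearly BLUPs); `NA`
#'   marks masked/unobserved lines. Lines absent from `y` are treated as
#'   unobserved.
#' @param grm a [Grm-class] covering all lines.
#' @return A [GblupFit-class] with `method = "reml"` and GEBVs for every
#'   line in G.
#' @export
fitGblupReml <- function(y, grm) {
  prep <- .gblupPrep(y, grm)
  if (stats::sd(prep$y) == 0) return(.constantFit(prep, "reml"))
  n <- length(prep$y)
  yt <- drop(crossprod(prep$U, prep$y))
  xt <- drop(crossprod(prep$U, rep(1, n)))
  d <- prep$d

  profile <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (1 + lam * d)
    xwx <- sum(w * xt^2)
    mu <- sum(w * xt * yt) / xwx
    rss <- sum(w * (yt - mu * xt)^2)
    s2e <- rss / (n - 1)
    ll <- -0.5 * ((n - 1) * (log(s2e) + 1) + sum(log(1 + lam * d)) +
                    log(xwx))
    list(loglik = ll, mu = mu, s2e = s2e, lam = lam, w = w)
  }
  opt <- stats::optimize(function(p) -profile(p)$loglik,
                         interval = c(-25, 25), tol = 1e-10)
  sol <- profile(opt$minimum)
  lam <- sol$lam; s2e <- sol$s2e; mu <- sol$mu
  r <- prep$y - mu
  # (I + lam G_obs)^{-1} r in the eigenbasis
  t_vec <- drop(prep$U %*% (sol$w * drop(crossprod(prep$U, r))))
  gebv <- lam * drop(prep$G[, prep$obs, drop = FALSE] %*% t_vec)
  names(gebv) <- prep$ids
  new("GblupFit", mu = mu, gebv = gebv, sigmaG2 = lam * s2e, sigmaE2 = s2e,
      method = "reml", nIter = 0L, nBurnin = 0L, seed = NA_integer_,
      observedIds = prep$obs)
}

#' Fit GBLUP by Gibbs sampling
#'
#' Bayesian fit of the same Gaussian model sampled in the eigenbasis of the
#' observed G block (one rotation up front, O(n) per sweep). Variance
#' components get scaled-inverse-chi-squared priors with `df0 = 5` and
#' scales set so each prior mode equals half the sample phenotypic
#' variance. GEBVs are posterior means over the post-burn-in samples;
#' unobserved lines are predicted through the genomic covariances (their
#' conditional mean given the sampled observed-line effects), which for a
#' Gaussian model equals keeping them inside the joint prior. No thinning
#' is applied.
#'
#' @inheritParams fitGblupReml
#' @param n_iter total Gibbs iterations (default 12000).
#' @param n_burnin burn-in iterations discarded (default 2000).
#' @param seed integer seed for the sampler.
#' @return A [GblupFit-class] with `method = "gibbs"`, posterior-mean
#'   `mu`, GEBVs and variance components.
#' @export
fitGblupGibbs <- function(y, grm, n_iter = 12000, n_burnin = 2000, seed = 1) {
  stopifnot(n_iter > n_burnin)
  prep <- .gblupPrep(y, grm)
  if (stats::sd(prep$y) == 0)
    return(.constantFit(prep, "gibbs", n_iter, n_burnin, seed))
  set.seed(substreamSeed(as.integer(seed), "gibbs"))
  n <- length(prep$y)
  yt <- drop(crossprod(prep$U, prep$y))
  xt <- drop(crossprod(prep$U, rep(1, n)))
  d <- prep$d

  vy <- stats::var(prep$y)
  df0 <- 5
  S0 <- 0.5 * vy * (df0 + 2)   # prior mode = half the phenotypic variance

  mu <- mean(prep$y)
  s2g <- vy / 2; s2e <- vy / 2
  alpha <- rep(0, n)
  keep <- n_iter - n_burnin
  sum_alpha <- rep(0, n)
  sum_mu <- 0; sum_s2g <- 0; sum_s2e <- 0

  for (it in seq_len(n_iter)) {
    prec <- 1 / s2e + 1 / (s2g * d)
    cond_mean <- ((yt - mu * xt) / s2e) / prec
    alpha <- cond_mean + stats::rnorm(n, 0, sqrt(1 / prec))
    # intercept given the line effects
    resid0 <- yt - alpha
    mu <- stats::rnorm(1, sum(xt * resid0) / n, sqrt(s2e / n))
    s2g <- (S0 + sum(alpha^2 / d)) / stats::rchisq(1, df0 + n)
    s2e <- (S0 + sum((yt - mu * xt - alpha)^2)) /
      stats::rchisq(1, df0 + n)
    if (it > n_burnin) {
      sum_alpha <- sum_alpha + alpha
      sum_mu <- sum_mu + mu
      sum_s2g <- sum_s2g + s2g
      sum_s2e <- sum_s2e + s2e
    }
  }
  alpha_bar <- sum_alpha / keep
  g_obs <- drop(prep$U %*% alpha_bar)
  gebv <- stats::setNames(rep(NA_real_, length(prep$ids)), prep$ids)
  gebv[prep$obs] <- g_obs
  if (length(prep$unobs)) {
    # conditional mean G_uo G_oo^{-1} g_o, via the eigenbasis
    proj <- prep$G[prep$unobs, prep$obs, drop = FALSE] %*%
      (prep$U %*% (drop(crossprod(prep$U, g_obs)) / d))
    gebv[prep$unobs] <- drop(proj)
  }
  new("GblupFit", mu = sum_mu / keep, gebv = gebv,
      sigmaG2 = sum_s2g / keep, sigmaE2 = sum_s2e / keep,
      method = "gibbs", nIter = as.integer(n_iter),
      nBurnin = as.integer(n_burnin), seed = as.integer(seed),
      observedIds = prep$obs)
}

#' Extract GEBVs of masked lines
#'
#' Returns the fitted GEBVs of the requested lines. Because masked
#' phenotypes are `NA` at fit time, these predictions never condition on
#' the masked lines' own phenotypes, whether masking happened before or at
#' the fit call.
#'
#' @param fit a [GblupFit-class].
#' @param masked_ids character vector of line ids present in the fit.
#' @return Named numeric vector of GEBVs.
#' @export
predictMasked <- function(fit, masked_ids) {
  stopifnot(is(fit, "GblupFit"))
  missing_ids <- setdiff(masked_ids, names(gebv(fit)))
  if (length(missing_ids))
    stop("ids not in the fitted G: ", paste(missing_ids, collapse = ", "))
  gebv(fit)[masked_ids]
}
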