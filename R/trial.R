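#' Specify a per-location mixed model
#'
#' A catalogue member for [fitLocationModel()]: which design terms enter as
#' random effects and whether the residual is iid or a separable first-order
#' autoregressive (AR1xAR1) field over rows and columns. The fixed part is
#' always intercept + check-cultivar indicators; experimental lines are
#' always random. When the trial has more than one replicate, a random
#' replicate term and block-within-replicate nesting are added automatically.
#'
#' @param name display name.
#' @param random subset of `c("block", "row", "col")` fitted as iid random
#'   effects.
#' @param residual `"iid"` or `"ar1xar1"`.
#' @return A list of class `"ModelSpec"`.
#' @export
modelSpec <- function(name, random = character(), residual = c("iid", "ar1xar1")) {
  residual <- match.arg(residual)
  stopifnot(all(random %in% c("block", "row", "col")))
  structure(list(name = name, random = random, residual = residual),
            class = "ModelSpec")
}

#' Default model catalogue
#'
#' The five candidate models compared per location: design-only (incomplete
#' blocks), row+column, pure spatial AR1xAR1, and AR1xAR1 combined with the
#' design features.
#'
#' @return list of [modelSpec()] objects.
#' @export
defaultCatalogue <- function() {
  list(modelSpec("iid_block", "block", "iid"),
       modelSpec("iid_rowcol", c("row", "col"), "iid"),
       modelSpec("ar1xar1", character(), "ar1xar1"),
       modelSpec("ar1xar1_block", "block", "ar1xar1"),
       modelSpec("ar1xar1_rowcol", c("row", "col"), "ar1xar1"))
}

# design matrices for one location-year trial
.trialDesign <- function(df, spec) {
  n <- nrow(df)
  check_ids <- sort(unique(df$line_id[df$is_check]))
  if (length(check_ids)) {
    cf <- factor(ifelse(df$is_check, df$line_id, ".line"),
                 levels = c(".line", check_ids))
    X <- stats::model.matrix(~cf)
    colnames(X) <- c("(Intercept)", check_ids)
  } else {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }

  Zs <- list()
  lines <- sort(unique(df$line_id[!df$is_check]))
  Zg <- matrix(0, n, length(lines), dimnames = list(NULL, lines))
  ok <- !df$is_check
  Zg[cbind(which(ok), match(df$line_id[ok], lines))] <- 1
  Zs$line <- Zg

  multi_rep <- length(unique(df$rep)) > 1
  if (multi_rep) {
    fr <- factor(df$rep)
    Zs$rep <- stats::model.matrix(~ fr - 1)
  }
  for (term in spec$random) {
    f <- switch(term,
                block = if (multi_rep) interaction(df$rep, df$block)
                        else factor(df$block),
                row = factor(df$row),
                col = factor(df$col))
    Zs[[term]] <- stats::model.matrix(~ factor(f) - 1)
  }
  list(X = X, Zs = Zs, lines = lines, check_ids = check_ids)
}

# profiled REML log-likelihood pieces at H = I + sum gamma_k K_k, where the
# K_k are component covariance matrices (Z Z' for design terms, the AR1xAR1
# correlation for the spatial trend) and the iid nugget carries the
# profiled scale
.remlEval <- function(y, X, Ks, gammas) {
  n <- length(y); p <- ncol(X)
  H <- diag(n)
  for (k in seq_along(Ks)) H <- H + gammas[k] * Ks[[k]]
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) return(list(loglik = -1e10))
  logdetH <- 2 * sum(log(diag(ch)))
  Hi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Hi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtHiX <- crossprod(X, Hi_X)
  chx <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(chx)) return(list(loglik = -1e10))
  logdetX <- 2 * sum(log(diag(chx)))
  beta <- backsolve(chx, forwardsolve(t(chx), crossprod(X, Hi_y)))
  r <- y - X %*% beta
  Hi_r <- backsolve(ch, forwardsolve(t(ch), r))
  quad <- drop(crossprod(r, Hi_r))
  s2 <- quad / (n - p)
  loglik <- -0.5 * ((n - p) * (log(s2) + 1 + log(2 * pi)) +
                      logdetH + logdetX)
  list(loglik = loglik, s2 = s2, beta = drop(beta), Hi_r = drop(Hi_r),
       chol = ch)
}

#' Fit a per-location mixed model by REML
#'
#' Fits yield = checks (fixed) + line (random) + optional design random
#' terms by profiled REML (Nelder-Mead over log variance ratios and
#' transformed AR1 correlations, after a coarse correlation grid for the
#' spatial models). For `residual = "ar1xar1"` the spatial trend is a
#' random field with separable AR1xAR1 correlation over rows and columns
#' plus an iid nugget residual (the "units" formulation), so `sigma_R2`
#' always denotes the iid residual variance and `sigma_spatial2` the
#' spatial-trend variance. Line BLUPs are the empirical best linear
#' unbiased predictors at the variance estimates. Missing-yield plots are
#' dropped from the likelihood.
#'
#' @param trial trial table for a single location-year (see
#'   [readTrialTable()]).
#' @param spec a [modelSpec()].
#' @param tol convergence tolerance on the REML log-likelihood.
#' @param maxIter iteration cap for the optimizer.
#' @param varcomps optional named list fixing the variance parameters
#'   (`sigma_G2`, `sigma_R2`, optionally `sigma_block2`, `sigma_row2`,
#'   `sigma_col2`, `sigma_rep2`, `sigma_spatial2`, `rho_row`, `rho_col`);
#'   no optimization is performed when supplied.
#' @param strict error on non-convergence (default) instead of returning a
#'   fit flagged `converged = FALSE`.
#' @return A list of class `"LocationFit"`: `model`, `varcomps`,
#'   `loglik_reml`, `aic`, `n_varparams`, `line_blups`, `fixef`,
#'   `residuals`, `converged`, `boundary`.
#' @export
fitLocationModel <- function(trial, spec, tol = 1e-6, maxIter = 200,
                             varcomps = NULL, strict = TRUE) {
  stopifnot(inherits(spec, "ModelSpec"))
  df <- validateTrialTable(trial)
  if (length(unique(paste(df$location, df$year))) != 1)
    stop("fitLocationModel expects a single location-year")
  df <- df[!is.na(df$yield), , drop = FALSE]
  if (nrow(df) < 2) stop("fewer than 2 observed plots")
  y <- df$yield
  n <- length(y)

  if (stats::sd(y) == 0) {
    # degenerate trial: no variance to partition
    des <- .trialDesign(df, spec)
    blups <- stats::setNames(rep(0, length(des$lines)), des$lines)
    vc <- c(sigma_G2 = 0, sigma_R2 = 0)
    return(structure(list(model = spec, varcomps = vc, loglik_reml = NA_real_,
                          aic = NA_real_, n_varparams = 2L,
                          line_blups = blups,
                          fixef = c(`(Intercept)` = y[1]),
                          residuals = rep(0, n), converged = TRUE,
                          boundary = TRUE), class = "LocationFit"))
  }

  des <- .trialDesign(df, spec)
  Zs <- des$Zs
  nZ <- length(Zs)
  ar1 <- spec$residual == "ar1xar1"
  if (ar1 && (anyNA(df$row) || anyNA(df$col)))
    stop("ar1xar1 residual requires complete plot grid coordinates")

  ZZt <- lapply(Zs, tcrossprod)
  if (ar1) {
    Dr <- abs(outer(df$row, df$row, "-"))
    Dc <- abs(outer(df$col, df$col, "-"))
  }
  makeKs <- function(rho) {
    if (!ar1) ZZt
    else c(ZZt, list(spatial = rho[1]^Dr * rho[2]^Dc))
  }
  nK <- nZ + as.integer(ar1)

  if (!is.null(varcomps)) {
    s2 <- varcomps$sigma_R2
    if (is.null(s2) || s2 <= 0) stop("varcomps must give sigma_R2 > 0")
    gmap <- c(line = "sigma_G2", rep = "sigma_rep2", block = "sigma_block2",
              row = "sigma_row2", col = "sigma_col2",
              spatial = "sigma_spatial2")
    comp_names <- c(names(Zs), if (ar1) "spatial")
    gammas <- vapply(comp_names, function(nm) {
      v <- varcomps[[gmap[[nm]]]]
      if (is.null(v)) stop("varcomps missing ", gmap[[nm]])
      v / s2
    }, numeric(1))
    rho <- c(varcomps$rho_row %||% 0, varcomps$rho_col %||% 0)
    ev <- .remlEval(y, des$X, makeKs(rho), gammas)
    ev$s2 <- s2
    conv <- TRUE
  } else {
    obj <- function(par) {
      gammas <- pmin(exp(par[seq_len(nK)]), 1e8)
      rho <- if (ar1) tanh(par[nK + 1:2]) else c(0, 0)
      -.remlEval(y, des$X, makeKs(rho), gammas)$loglik
    }
    start <- rep(0, nK)
    if (ar1) {
      # coarse grid over the AR1 correlations, short inner optimizations
      grid <- expand.grid(r = c(0.2, 0.5, 0.8), c = c(0.2, 0.5, 0.8))
      best <- NULL; bestval <- Inf
      for (i in seq_len(nrow(grid))) {
        p0 <- c(start, atanh(grid$r[i]), atanh(grid$c[i]))
        o <- stats::optim(p0, obj, method = "Nelder-Mead",
                          control = list(maxit = 40))
        if (o$value < bestval) { bestval <- o$value; best <- o$par }
      }
      start <- best
    }
    o <- if (length(start) == 1)
      stats::optim(start, obj, method = "Brent", lower = -20, upper = 20,
                   control = list(maxit = max(maxIter, 200)))
    else
      stats::optim(start, obj, method = "Nelder-Mead",
                   control = list(maxit = max(maxIter * 5, 500),
                                  reltol = tol))
    conv <- o$convergence == 0
    comp_names <- c(names(Zs), if (ar1) "spatial")
    gammas <- stats::setNames(pmin(exp(o$par[seq_len(nK)]), 1e8),
                              comp_names)
    rho <- if (ar1) tanh(o$par[nK + 1:2]) else c(0, 0)
    ev <- .remlEval(y, des$X, makeKs(rho), gammas)
    s2 <- ev$s2
    if (!conv && strict) {
      cond <- simpleError("REML did not converge within the iteration cap")
      cond$fit <- list(par = o$par, loglik = -o$value)
      stop(cond)
    }
  }

  # BLUPs: u_k = gamma_k Z_k' H^{-1} (y - X beta)
  blup_list <- lapply(seq_along(Zs), function(k)
    gammas[k] * drop(crossprod(Zs[[k]], ev$Hi_r)))
  names(blup_list) <- names(Zs)
  line_blups <- stats::setNames(blup_list$line, des$lines)

  fitted_re <- Reduce(`+`, lapply(seq_along(Zs), function(k)
    drop(Zs[[k]] %*% blup_list[[k]])))
  if (ar1) {
    Ksp <- rho[1]^Dr * rho[2]^Dc
    fitted_re <- fitted_re + gammas["spatial"] * drop(Ksp %*% ev$Hi_r)
  }
  resid <- y - drop(des$X %*% ev$beta) - fitted_re

  boundary <- any(gammas < 1e-6)
  vc <- c(sigma_G2 = unname(gammas["line"] * s2), sigma_R2 = s2)
  extra <- setdiff(names(Zs), "line")
  for (nm in extra) vc[paste0("sigma_", nm, "2")] <- gammas[nm] * s2
  if (ar1) {
    vc["sigma_spatial2"] <- gammas["spatial"] * s2
    vc["rho_row"] <- rho[1]
    vc["rho_col"] <- rho[2]
  }
  k_var <- 1L + length(gammas) + if (ar1) 2L else 0L
  loglik <- ev$loglik
  structure(list(model = spec, varcomps = vc, loglik_reml = loglik,
                 aic = -2 * loglik + 2 * k_var, n_varparams = k_var,
                 line_blups = line_blups,
                 fixef = stats::setNames(ev$beta, colnames(des$X)),
                 residuals = resid, converged = conv, boundary = boundary),
            class = "LocationFit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.LocationFit <- function(x, ...) {
  cat("LocationFit [", x$model$name, "] ",
      if (x$converged) "converged" else "NOT converged",
      if (x$boundary) " (boundary)" else "", "\n", sep = "")
  print(round(x$varcomps, 4))
  cat("REML loglik:", format(x$loglik_reml), " AIC:", format(x$aic), "\n")
  invisible(x)
}

#' Select the best per-location model by AIC
#'
#' Fits every catalogue member, keeps the converged fits, and returns the
#' one with minimal AIC (ties broken toward fewer variance parameters).
#' REML AICs are comparable because all members share the identical fixed
#' part (intercept + checks); `k` counts variance/correlation parameters
#' only. A diagnostics summary (residual skewness and the t-statistic of a
#' linear residual trend over field columns) is attached per model.
#'
#' @param trial single location-year trial table.
#' @param catalogue list of [modelSpec()]s (default [defaultCatalogue()]).
#' @param ... passed to [fitLocationModel()].
#' @return list with `best` (the chosen `"LocationFit"`) and `table`
#'   (data.frame: model, aic, converged, n_varparams, resid_skewness,
#'   col_trend_t).
#' @export
selectModel <- function(trial, catalogue = defaultCatalogue(), ...) {
  stopifnot(length(catalogue) >= 1)
  fits <- lapply(catalogue, function(sp)
    tryCatch(fitLocationModel(trial, sp, strict = FALSE, ...),
             error = function(e) NULL))
  rows <- lapply(seq_along(catalogue), function(i) {
    f <- fits[[i]]
    if (is.null(f))
      return(data.frame(model = catalogue[[i]]$name, aic = NA_real_,
                        converged = FALSE, n_varparams = NA_integer_,
                        resid_skewness = NA_real_, col_trend_t = NA_real_))
    r <- f$residuals
    sk <- if (stats::sd(r) > 0) mean((r - mean(r))^3) / stats::sd(r)^3 else 0
    df <- trial[!is.na(trial$yield), , drop = FALSE]
    ct <- if (stats::sd(r) > 0 && length(unique(df$col)) > 1)
      summary(stats::lm(r ~ df$col))$coefficients[2, 3] else 0
    data.frame(model = catalogue[[i]]$name, aic = f$aic,
               converged = f$converged, n_varparams = f$n_varparams,
               resid_skewness = sk, col_trend_t = ct)
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$converged & !is.na(tab$aic))
  if (!length(ok)) stop("no model converged")
  ord <- ok[order(tab$aic[ok], tab$n_varparams[ok])]
  list(best = fits[[ord[1]]], table = tab)
}

#' Average per-location BLUPs into yearly line values
#'
#' Takes the unweighted mean of the available per-location BLUPs for each
#' line; lines absent from every fit are excluded.
#'
#' @param fits list of `"LocationFit"` objects sharing a line namespace.
#' @return data.frame with `line_id`, `blup` (mean across locations), and
#'   `n_locations_used`.
#' @export
combineLocations <- function(fits) {
  if (!length(fits)) stop("empty input")
  all_ids <- sort(unique(unlist(lapply(fits, function(f) names(f$line_blups)))))
  M <- sapply(fits, function(f) f$line_blups[all_ids])
  M <- matrix(M, nrow = length(all_ids))
  means <- rowMeans(M, na.rm = TRUE)
  nl <- rowSums(!is.na(M))
  keep <- nl > 0
  data.frame(line_id = all_ids[keep], blup = means[keep],
             n_locations_used = as.integer(nl[keep]),
             stringsAsFactors = FALSE)
}
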