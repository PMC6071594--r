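test_that("fixed-varcomp BLUPs match the dense mixed-model-equation solve", {
  tt <- makeToyTrial(n_lines = 16, n_checks = 2, seed = 5)
  vc <- list(sigma_G2 = 2, sigma_R2 = 1.5, sigma_block2 = 0.8)
  f <- fitLocationModel(tt, modelSpec("toy", "block", "iid"), varcomps = vc)

  # independent dense Henderson-MME oracle
  df <- tt; y <- df$yield
  lines <- sort(unique(df$line_id[!df$is_check]))
  cf <- factor(ifelse(df$is_check, df$line_id, ".line"),
               levels = c(".line", "C1", "C2"))
  X <- model.matrix(~cf)
  Zg <- matrix(0, nrow(df), length(lines), dimnames = list(NULL, lines))
  ok <- !df$is_check
  Zg[cbind(which(ok), match(df$line_id[ok], lines))] <- 1
  Zb <- model.matrix(~ factor(df$block) - 1)
  Z <- cbind(Zg, Zb)
  Ginv <- diag(c(rep(1 / vc$sigma_G2, length(lines)),
                 rep(1 / vc$sigma_block2, 2)))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + vc$sigma_R2 * Ginv))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  u_mme <- sol[ncol(X) + seq_along(lines)]
  expect_lt(max(abs(f$line_blups[lines] - u_mme)), 1e-8)
})

test_that("free REML agrees with lme4 on a replicated iid trial", {
  set.seed(9)
  lines <- paste0("L", 1:12)
  tt <- data.frame(line_id = rep(lines, 2), year = 2012L, location = "X",
                   row = rep(1:4, each = 6), col = rep(1:6, 4),
                   block = rep(1:2, each = 12), rep = rep(1:2, each = 12),
                   is_check = FALSE,
                   yield = rep(rnorm(12, 50, 2), 2) + rnorm(24, 0, 1))
  f <- fitLocationModel(tt, modelSpec("iid", character(), "iid"))
  lm4 <- suppressMessages(lme4::lmer(yield ~ (1 | line_id) + (1 | rep),
                                     data = tt, REML = TRUE))
  vc4 <- as.data.frame(lme4::VarCorr(lm4))
  expect_equal(unname(f$varcomps["sigma_G2"]),
               vc4$vcov[vc4$grp == "line_id"], tolerance = 0.02)
  expect_equal(unname(f$varcomps["sigma_R2"]),
               vc4$vcov[vc4$grp == "Residual"], tolerance = 0.02)
  expect_equal(f$loglik_reml, as.numeric(logLik(lm4)), tolerance = 1e-3)
  b <- lme4::ranef(lm4)$line_id[, 1]
  names(b) <- rownames(lme4::ranef(lm4)$line_id)
  expect_equal(unname(f$line_blups[names(b)]), unname(b), tolerance = 0.01)
})

test_that("single-rep no-block fit obeys the scalar shrinkage identity", {
  set.seed(10)
  n <- 40
  tt <- data.frame(line_id = paste0("L", 1:n), year = 2012L, location = "X",
                   row = rep(1:5, each = 8), col = rep(1:8, 5),
                   block = 1L, rep = 1L, is_check = FALSE,
                   yield = rnorm(n, 50, 2))
  f <- fitLocationModel(tt, modelSpec("iid0", character(), "iid"))
  sg <- f$varcomps["sigma_G2"]; se <- f$varcomps["sigma_R2"]
  mu <- f$fixef["(Intercept)"]
  shrink <- unname((tt$yield - mu) * sg / (sg + se))
  expect_equal(unname(f$line_blups[tt$line_id]), shrink, tolerance = 1e-5)
})

test_that("line BLUPs sum to zero and degenerate trials are flagged", {
  tt <- simulateTrial(tiny_sim, tiny_cfg, 2012, 1)
  for (sp in defaultCatalogue()[c(1, 3)]) {
    f <- fitLocationModel(tt, sp, strict = FALSE)
    expect_lt(abs(sum(f$line_blups)), 1e-6 * nrow(tt) * sd(tt$yield))
  }
  flat <- tt; flat$yield <- 7
  f0 <- fitLocationModel(flat, defaultCatalogue()[[1]])
  expect_true(f0$boundary)
  expect_equal(unname(f0$varcomps["sigma_G2"]), 0)
  expect_true(all(f0$line_blups == 0))
})

test_that("checks are reproduced by fixed effects as residual variance vanishes", {
  # near-noiseless trial: check plots all equal their cultivar mean
  cfg <- simConfig(n_founders = 20, n_markers = 100, n_years = 1,
                   lines_per_year = 28, n_qtl = 10, h2_line_mean = 1,
                   var_gxe_ratio = 0, spatial_var_ratio = 0,
                   n_blocks = 2, field_dims = c(4, 10), seed = 21)
  sim <- simulateCohorts(cfg)
  tt <- simulateTrial(sim, cfg, 2012, 1)
  f <- fitLocationModel(tt, modelSpec("iid0", character(), "iid"),
                        strict = FALSE)
  pred_checks <- f$fixef["(Intercept)"] + f$fixef[cfg$check_ids]
  true_checks <- cfg$mu + sim$truth$check_effects[cfg$check_ids]
  expect_equal(unname(pred_checks), unname(true_checks), tolerance = 1e-4)
})

test_that("model selection prefers spatial models on strongly trended fields", {
  cfg <- simConfig(n_founders = 30, n_markers = 200, n_years = 1,
                   lines_per_year = 280, n_qtl = 40, n_locations = 1,
                   field_dims = c(30, 10), rho_row = 0.6, rho_col = 0.6,
                   spatial_var_ratio = 1, var_gxe_ratio = 0,
                   h2_line_mean = 0.45, seed = 11)
  hits <- 0
  for (s in 1:5) {
    cfg$seed <- 300 + s
    sim <- simulateCohorts(cfg)
    tt <- simulateTrial(sim, cfg, 2012, 1)
    sel <- selectModel(tt)
    if (grepl("ar1", sel$best$model$name)) hits <- hits + 1
    expect_true(all(c("aic", "converged", "resid_skewness") %in%
                      names(sel$table)))
  }
  expect_gte(hits, 4)
})

test_that("without spatial trend the iid models sit near the AIC minimum", {
  cfg <- simConfig(n_founders = 30, n_markers = 200, n_years = 1,
                   lines_per_year = 90, n_qtl = 40, n_locations = 1,
                   field_dims = c(10, 11), spatial_var_ratio = 0,
                   var_gxe_ratio = 0, h2_line_mean = 0.5, n_blocks = 5,
                   seed = 13)
  hits <- 0
  for (s in 1:5) {
    cfg$seed <- 400 + s
    sim <- simulateCohorts(cfg)
    tt <- simulateTrial(sim, cfg, 2012, 1)
    sel <- selectModel(tt)
    iid_aic <- min(sel$table$aic[grepl("^iid", sel$table$model)], na.rm = TRUE)
    if (iid_aic <= min(sel$table$aic, na.rm = TRUE) + 2) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("a one-model catalogue returns that model", {
  tt <- makeToyTrial()
  sel <- selectModel(tt, list(modelSpec("only", "block", "iid")))
  expect_equal(sel$best$model$name, "only")
  expect_equal(nrow(sel$table), 1)
})

test_that("combining locations averages the available BLUPs per line", {
  mk <- function(vals) list(line_blups = vals)
  f1 <- mk(c(A = 1, B = 2, C = 3))
  f2 <- mk(c(A = 2, B = 4))
  f3 <- mk(c(A = 3, B = 6, C = 5))
  out <- combineLocations(list(f1, f2, f3))
  expect_equal(out$blup[out$line_id == "A"], 2)
  expect_equal(out$blup[out$line_id == "C"], 4)
  expect_equal(out$n_locations_used[out$line_id == "C"], 2L)
  # identical BLUPs at 3 locations -> that value
  same <- combineLocations(list(f1, f1, f1))
  expect_equal(same$blup, unname(f1$line_blups))
  expect_error(combineLocations(list()), "empty")
  # definitional check on simulator output over 3 locations
  fits <- lapply(1:3, function(l)
    fitLocationModel(simulateTrial(tiny_sim, tiny_cfg, 2012, l),
                     modelSpec("iid_block", "block", "iid"), strict = FALSE))
  comb <- combineLocations(fits)
  manual <- rowMeans(sapply(fits, function(f) f$line_blups[comb$line_id]))
  expect_equal(comb$blup, unname(manual))
})

test_that("stronger genetic signal raises BLUP-truth correlation", {
  cors <- sapply(c(0.2, 0.8), function(h2) {
    cfg <- simConfig(n_founders = 30, n_markers = 200, n_years = 1,
                     lines_per_year = 100, n_qtl = 40, n_locations = 1,
                     field_dims = c(10, 12), h2_line_mean = h2,
                     var_gxe_ratio = 0.1, spatial_var_ratio = 0.1,
                     n_blocks = 5, seed = 77)
    sim <- simulateCohorts(cfg)
    tt <- simulateTrial(sim, cfg, 2012, 1)
    f <- fitLocationModel(tt, modelSpec("iid_block", "block", "iid"),
                          strict = FALSE)
    cor(f$line_blups, sim$truth$true_bv[names(f$line_blups)])
  })
  expect_gt(cors[2], cors[1])
})
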