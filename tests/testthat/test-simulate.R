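test_that("cohorts are disjoint with the requested sizes and inbreeding", {
  expect_equal(length(tiny_sim$cohorts), 120)
  expect_equal(as.integer(table(tiny_sim$cohorts)), c(60L, 60L))
  expect_false(anyDuplicated(names(tiny_sim$cohorts)) > 0)
  # residual heterozygosity shrinks with selfing; at 20 generations ~ gone
  cfg20 <- simConfig(n_founders = 30, n_markers = 400, n_years = 1,
                     lines_per_year = 200, selfing_generations = 20,
                     n_qtl = 20, seed = 7)
  sim20 <- simulateCohorts(cfg20)
  expect_lt(mean(calls(sim20$panel) == 0.5), 1e-4)
  # at 5 generations het sites persist at roughly 0.5^5 of F1 het sites
  expect_gt(mean(calls(tiny_sim$panel) == 0.5), 0)
  expect_lt(mean(calls(tiny_sim$panel) == 0.5), 0.5^5)
})

test_that("founder allele frequencies respect maf_range up to sampling error", {
  cfg <- simConfig(n_founders = 200, n_markers = 400, n_years = 1,
                   lines_per_year = 400, n_qtl = 10,
                   maf_range = c(0.2, 0.4), seed = 3)
  sim <- simulateCohorts(cfg)
  # cohort MAFs estimate the founder frequencies; allow binomial sampling
  # error at both generations (founder draw + transmission)
  m <- maf(sim$panel)
  slack <- 4 * sqrt(0.4 * 0.6 / (2 * 200)) + 0.03
  expect_gt(mean(m > 0.2 - slack & m < 0.4 + slack), 0.95)
})

test_that("true breeding values are QTL sums and vary", {
  expect_gt(var(tiny_sim$truth$true_bv), 0)
  X <- dosages(encodeNumeric(tiny_sim$panel))
  # minor-allele dosage = 2 - major dosage
  D <- 2 - X[, tiny_sim$truth$qtl_ids, drop = FALSE]
  expect_equal(unname(drop(D %*% tiny_sim$truth$qtl_effects)),
               unname(tiny_sim$truth$true_bv))
  expect_error(simConfig(n_qtl = 2000, n_markers = 100), "n_qtl")
})

test_that("noise-free trial reproduces mu + bv exactly", {
  cfg <- simConfig(n_founders = 20, n_markers = 100, n_years = 1,
                   lines_per_year = 28, n_qtl = 10, h2_line_mean = 1,
                   var_gxe_ratio = 0, spatial_var_ratio = 0,
                   n_blocks = 2, field_dims = c(4, 10), seed = 9)
  sim <- simulateCohorts(cfg)
  tt <- simulateTrial(sim, cfg, 2012, 1)
  non_check <- !tt$is_check
  expect_equal(tt$yield[non_check],
               unname(cfg$mu + sim$truth$true_bv[tt$line_id[non_check]]))
})

test_that("augmented layout places every check once per incomplete block", {
  cfg <- tiny_cfg
  tt <- simulateTrial(tiny_sim, cfg, 2012, 2)
  expect_equal(nrow(tt), 60 + 2 * 10)
  for (chk in cfg$check_ids) {
    expect_equal(sum(tt$line_id == chk), 10)
    expect_equal(sort(unique(tt$block[tt$line_id == chk])), 1:10)
  }
  expect_silent(validateTrialTable(tt))
  expect_error(simulateTrial(tiny_sim, simConfig(field_dims = c(2, 2),
                                                 n_years = 2,
                                                 lines_per_year = c(60, 60),
                                                 seed = 42),
                             2012, 1), "too small")
})

test_that("alpha lattice places every entry once per replicate", {
  cfg <- simConfig(n_founders = 20, n_markers = 100, n_years = 1,
                   lines_per_year = 57, n_qtl = 10,
                   check_ids = c("C1", "C2", "C3"),
                   design = "alpha_lattice", n_reps = 2,
                   field_dims = c(12, 10), seed = 4)
  sim <- simulateCohorts(cfg)
  tt <- simulateTrial(sim, cfg, 2012, 1)
  expect_equal(nrow(tt), 2 * 60)
  counts <- table(tt$line_id, tt$rep)
  expect_true(all(counts == 1))
})

test_that("generated spatial field has the requested lag-1 autocorrelation", {
  set.seed(31)
  acs <- replicate(5, {
    f <- BreedGS:::.ar1Field(50, 50, 0.6, 0.3)
    c(row = cor(as.vector(f[-1, ]), as.vector(f[-50, ])),
      col = cor(as.vector(f[, -1]), as.vector(f[, -50])),
      sd = sd(as.vector(f)))
  })
  expect_lt(abs(mean(acs["row", ]) - 0.6), 0.05)
  expect_lt(abs(mean(acs["col", ]) - 0.3), 0.05)
  expect_lt(abs(mean(acs["sd", ]) - 1), 0.1)
})

test_that("plot yields regress on true bv with slope 1 and R2 ~ h2", {
  cfg <- simConfig(n_founders = 50, n_markers = 300, n_years = 1,
                   lines_per_year = 280, n_qtl = 50, h2_line_mean = 0.6,
                   var_gxe_ratio = 0.3, spatial_var_ratio = 0.2,
                   n_locations = 8, field_dims = c(15, 20), seed = 12)
  sim <- simulateCohorts(cfg)
  plots <- do.call(rbind, lapply(1:8, function(l)
    simulateTrial(sim, cfg, 2012, l)))
  plots <- plots[!plots$is_check, ]
  fit <- lm(plots$yield ~ sim$truth$true_bv[plots$line_id])
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(summary(fit)$r.squared, 0.6, tolerance = 0.05)
})

test_that("advancement truncation keeps exactly the top lines", {
  blups <- tiny_sim$truth$true_bv[tiny_sim$cohorts == 2012]
  rec <- simulateAdvancement(list(`2012` = blups), n_keep = 12,
                             n_years_tracked = 4,
                             truth = tiny_sim$truth, seed = 8)
  adv <- rec$line_id[rec$years_retained >= 2]
  expect_setequal(adv, names(sort(blups, decreasing = TRUE))[1:12])
  expect_equal(sum(rec$years_retained >= 2) / length(blups), 0.2)
  # n_keep = cohort size -> everyone retained at least 2 years
  rec_all <- simulateAdvancement(list(`2012` = blups),
                                 n_keep = length(blups),
                                 n_years_tracked = 3, seed = 8)
  expect_true(all(rec_all$years_retained >= 2))
  # flags consistent with years_retained
  fl <- attr(rec, "flags")[["2012"]]
  expect_equal(unname(1L + rowSums(fl)[rec$line_id]), rec$years_retained)
  expect_error(simulateAdvancement(list(`2012` = blups), n_keep = 100),
               "cohort size")
})

test_that("randomness substreams make stages independently reproducible", {
  s1 <- simulateCohorts(tiny_cfg)
  expect_identical(calls(s1$panel), calls(tiny_sim$panel))
  expect_identical(s1$truth$true_bv, tiny_sim$truth$true_bv)
  t1 <- simulateTrial(s1, tiny_cfg, 2013, 1)
  t2 <- simulateTrial(tiny_sim, tiny_cfg, 2013, 1)
  expect_identical(t1, t2)
})
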