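test_that("missingness filter uses strict > threshold semantics", {
  set.seed(2)
  m <- matrix(sample(c(1, 0, 0.5), 100 * 10, TRUE), 100, 10,
              dimnames = list(paste0("L", 1:100), paste0("M", 1:10)))
  m[1:81, 1] <- NA   # 81% missing -> removed
  m[1:80, 2] <- NA   # 80% exactly -> retained
  panel <- GenotypePanel(m)
  out <- filterMissingness(panel, 0.80)
  expect_false("M1" %in% markerIds(out))
  expect_true("M2" %in% markerIds(out))
  # fully observed panel passes through unchanged
  expect_equal(calls(filterMissingness(tiny_sim$panel)),
               calls(tiny_sim$panel))
})

test_that("missingness survivors match a brute-force per-column recount", {
  set.seed(3)
  m <- matrix(sample(c(1, 0, 0.5, NA), 10 * 20, TRUE,
                     prob = c(0.3, 0.3, 0.1, 0.3)), 10, 20,
              dimnames = list(paste0("L", 1:10), paste0("M", 1:20)))
  panel <- GenotypePanel(m)
  thr <- 0.3
  survivors <- markerIds(filterMissingness(panel, thr))
  brute <- colnames(m)[vapply(seq_len(ncol(m)), function(j)
    sum(is.na(m[, j])) / nrow(m) <= thr, logical(1))]
  expect_identical(survivors, brute)
})

test_that("MAF and allelic-R2 filters use strict < threshold semantics", {
  # 50 lines (100 alleles); heterozygotes contribute half an allele
  m <- matrix(1, 50, 3, dimnames = list(paste0("L", 1:50),
                                        c("M_004", "M_005", "M_ok")))
  m[1:2, "M_004"] <- 0                   # 4 minor alleles / 100 = 0.04
  m[1:2, "M_005"] <- 0; m[3, "M_005"] <- 0.5  # 5 / 100 = 0.05 exactly
  m[1:10, "M_ok"] <- 0                   # 20 / 100 = 0.20
  panel <- GenotypePanel(m)
  expect_equal(unname(maf(panel)[c("M_004", "M_005", "M_ok")]),
               c(0.04, 0.05, 0.20))
  kept <- markerIds(filterMafQuality(panel, maf_min = 0.05, r2_min = NULL))
  expect_identical(kept, c("M_005", "M_ok"))

  r2 <- c(M_005 = 0.49, M_ok = 0.50, M_004 = 0.9)
  panel2 <- GenotypePanel(m, allelicR2 = r2)
  kept2 <- markerIds(filterMafQuality(panel2, maf_min = 0.05, r2_min = 0.5))
  expect_identical(kept2, "M_ok")
  expect_warning(
    filterMafQuality(GenotypePanel(m), maf_min = 0.05, r2_min = 0.5),
    "skipped")
})

test_that("MAF filter survivors match a brute-force recount", {
  set.seed(4)
  m <- matrix(sample(c(1, 0, 0.5), 10 * 30, TRUE, prob = c(0.7, 0.2, 0.1)),
              10, 30, dimnames = list(paste0("L", 1:10), paste0("M", 1:30)))
  panel <- GenotypePanel(m)
  kept <- markerIds(filterMafQuality(panel, maf_min = 0.2, r2_min = NULL))
  brute <- colnames(m)[vapply(seq_len(ncol(m)), function(j) {
    cnt_minor <- sum(m[, j] == 0) * 2 + sum(m[, j] == 0.5)
    p <- cnt_minor / (2 * nrow(m))
    min(p, 1 - p) >= 0.2
  }, logical(1))]
  expect_identical(kept, brute)
})

test_that("numeric encoding doubles the calls and fills column means", {
  m <- matrix(c(1, 0.5, 0), 3, 1, dimnames = list(paste0("L", 1:3), "M1"))
  expect_equal(unname(dosages(encodeNumeric(GenotypePanel(m)))[, 1]),
               c(2, 1, 0))
  m2 <- matrix(c(2, 0, NA, 2, 0, 2) / 2, 3, 2,
               dimnames = list(paste0("L", 1:3), c("M1", "M2")))
  expect_error(encodeNumeric(GenotypePanel(m2)), "missing")
  filled <- encodeNumeric(GenotypePanel(m2), fill = TRUE)
  expect_equal(unname(filled[3, "M1"]), 1.0)  # mean of {2, 0}
})

test_that("GRM matches the double-loop oracle and its diagonal identity", {
  set.seed(6)
  X <- matrix(sample(0:2, 4 * 6, TRUE), 4, 6,
              dimnames = list(paste0("L", 1:4), paste0("M", 1:6)))
  while (any(apply(X, 2, sd) == 0))
    X <- matrix(sample(0:2, 4 * 6, TRUE), 4, 6,
                dimnames = dimnames(X))
  g <- computeGrm(new("NumericGenotypes", X = X))
  expect_lt(max(abs(grmMatrix(g) - grmOracle(X))), 1e-12)
  expect_equal(mean(diag(grmMatrix(g))), 3 / 4, tolerance = 1e-12)
  expect_equal(mean(diag(grmMatrix(tiny_grm))), 119 / 120, tolerance = 1e-12)
  # centered columns sum to zero
  Xs <- scale(X)
  expect_lt(max(abs(colSums(Xs))), 1e-9)
})

test_that("duplicated lines share diagonal and off-diagonal entries", {
  set.seed(7)
  X <- matrix(sample(0:2, 5 * 20, TRUE), 5, 20,
              dimnames = list(paste0("L", 1:5), paste0("M", 1:20)))
  X[2, ] <- X[1, ]
  g <- grmMatrix(suppressWarnings(computeGrm(new("NumericGenotypes", X = X))))
  expect_equal(g[1, 2], g[1, 1])
  expect_equal(g[2, 2], g[1, 1])
})

test_that("GRM is invariant to line and marker permutations", {
  X <- dosages(encodeNumeric(tiny_sim$panel))[1:20, 1:50]
  g1 <- grmMatrix(suppressWarnings(computeGrm(new("NumericGenotypes", X = X))))
  set.seed(8)
  pl <- sample(nrow(X)); pm <- sample(ncol(X))
  g2 <- grmMatrix(suppressWarnings(
    computeGrm(new("NumericGenotypes", X = X[pl, pm]))))
  expect_equal(g2, g1[pl, pl])
})

test_that("full sibs are more related than lines from unrelated founder pairs", {
  G <- grmMatrix(tiny_grm)
  pp <- tiny_sim$truth$parent_pairs
  ids <- rownames(pp)
  n <- length(ids)
  sib <- c(); unrel <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(pp[i, ], pp[j, ]))
    if (shared == 2) sib <- c(sib, G[ids[i], ids[j]])
    else if (shared == 0) unrel <- c(unrel, G[ids[i], ids[j]])
  }
  expect_gt(length(sib), 0)
  expect_gt(mean(sib), mean(unrel))
})
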