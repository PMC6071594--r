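#' Configuration for the synthetic breeding-program generator
#'
#' Bundles every knob of the simulator: founder panel, marker panel, cohort
#' structure, genetic architecture, heritability, genotype-by-environment
#' variation, and field-trial geometry. Defaults emulate the study system:
#' four yearly cohorts of 280/280/270/270 near-inbred (five selfing
#' generations) lines, augmented trials of 10 incomplete blocks with
#' replicated checks at eight locations, and a separable AR1xAR1 spatial
#' trend.
#'
#' @param n_founders number of inbred founder lines.
#' @param n_markers number of biallelic markers.
#' @param maf_range range of per-marker founder minor-allele frequencies,
#'   within (0, 0.5].
#' @param n_years number of yearly cohorts (first cohort year is 2012).
#' @param lines_per_year integer scalar or vector of length `n_years`.
#' @param selfing_generations selfing generations after the cross (5
#'   emulates F\eqn{_{3:6}} inbreds; residual heterozygosity per marker is
#'   about `0.5^selfing_generations`).
#' @param n_qtl number of markers carrying additive effects.
#' @param h2_line_mean plot-level heritability in (0, 1]: the fraction of
#'   plot variance (genetic + GxE + spatial + iid noise) due to true
#'   breeding values.
#' @param var_gxe_ratio ratio of line-by-location variance to genetic
#'   variance (>= 0).
#' @param n_locations locations per year.
#' @param field_dims `(rows, cols)` of the field grid.
#' @param rho_row,rho_col AR1 correlations of the spatial trend, in (-1, 1).
#' @param spatial_var_ratio ratio of spatial-trend variance to genetic
#'   variance (>= 0).
#' @param check_ids ids of the replicated check cultivars.
#' @param design `"augmented"` (unreplicated lines, checks once per
#'   incomplete block) or `"alpha_lattice"` (all entries once per replicate).
#' @param n_blocks incomplete blocks per trial (per replicate for the
#'   lattice).
#' @param n_reps replicates for the alpha-lattice design.
#' @param mu overall yield mean (arbitrary units).
#' @param seed run seed; all stages draw from named substreams of it.
#' @return A list of class `"SimConfig"`.
#' @export
simConfig <- function(n_founders = 200, n_markers = 1000,
                      maf_range = c(0.05, 0.5), n_years = 4,
                      lines_per_year = c(280, 280, 270, 270),
                      selfing_generations = 5, n_qtl = 100,
                      h2_line_mean = 0.5, var_gxe_ratio = 0.5,
                      n_locations = 8, field_dims = c(15, 20),
                      rho_row = 0.4, rho_col = 0.4,
                      spatial_var_ratio = 0.3,
                      check_ids = c("Camelot", "Goodstreak"),
                      design = c("augmented", "alpha_lattice"),
                      n_blocks = 10, n_reps = 2, mu = 50, seed = 1) {
  design <- match.arg(design)
  if (length(lines_per_year) == 1)
    lines_per_year <- rep(lines_per_year, n_years)
  stopifnot(length(lines_per_year) == n_years,
            all(c(n_founders, n_markers, n_years, lines_per_year,
                  n_qtl, n_locations, field_dims, n_blocks) > 0),
            h2_line_mean > 0, h2_line_mean <= 1,
            abs(rho_row) < 1, abs(rho_col) < 1,
            var_gxe_ratio >= 0, spatial_var_ratio >= 0,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  if (n_qtl > n_markers) stop("n_qtl may not exceed n_markers")
  cfg <- list(n_founders = n_founders, n_markers = n_markers,
              maf_range = maf_range, n_years = n_years,
              lines_per_year = lines_per_year,
              selfing_generations = selfing_generations, n_qtl = n_qtl,
              h2_line_mean = h2_line_mean, var_gxe_ratio = var_gxe_ratio,
              n_locations = n_locations, field_dims = field_dims,
              rho_row = rho_row, rho_col = rho_col,
              spatial_var_ratio = spatial_var_ratio, check_ids = check_ids,
              design = design, n_blocks = n_blocks, n_reps = n_reps,
              mu = mu, seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

# one gamete from an individual given its two haplotypes (0/1 minor allele)
.gamete <- function(h1, h2) {
  het <- h1 != h2
  g <- h1
  if (any(het)) g[het] <- stats::rbinom(sum(het), 1, 0.5)
  g
}

#' Simulate multi-year cohorts of near-inbred lines
#'
#' Draws an inbred founder panel with per-marker allele frequencies uniform
#' in `maf_range`, then builds each yearly cohort by crossing two randomly
#' chosen parents (founders, and from the second year on each parent is an
#' earlier-cohort line with probability 0.5) followed by
#' `selfing_generations` generations of single-seed-descent selfing, so
#' residual per-marker heterozygosity is about `0.5^selfing_generations`.
#' True breeding values are sums of minor-allele QTL dosages times normal
#' effects; line-by-location deviations are iid normal with variance
#' `var_gxe_ratio` times the genetic variance.
#'
#' @param config a [simConfig()] object.
#' @return A list of class `"CohortSim"` with elements `panel`
#'   ([GenotypePanel-class] of all lines), `cohorts` (named integer vector,
#'   year per line, starting 2012), and `truth` (list: `true_bv`,
#'   `qtl_ids`, `qtl_effects`, `env_deviations` line x location matrix,
#'   `parent_pairs`, `check_effects`).
#' @export
simulateCohorts <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  m <- config$n_markers
  set.seed(substreamSeed(config$seed, "founders"))
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  founders <- matrix(stats::rbinom(config$n_founders * m, 1, rep(p, each = config$n_founders)),
                     nrow = config$n_founders, ncol = m)

  n_total <- sum(config$lines_per_year)
  years <- 2011L + rep(seq_len(config$n_years), config$lines_per_year)
  ids <- sprintf("NE%d%04d", years, unlist(lapply(config$lines_per_year, seq_len)))
  H1 <- matrix(0L, n_total, m)
  H2 <- matrix(0L, n_total, m)
  parent_pairs <- matrix(NA_character_, n_total, 2,
                         dimnames = list(ids, c("parent1", "parent2")))
  keep_p <- 0.5^config$selfing_generations

  set.seed(substreamSeed(config$seed, "cohorts"))
  idx <- 0L
  for (y in seq_len(config$n_years)) {
    prior <- which(years < 2011L + y)
    for (k in seq_len(config$lines_per_year[y])) {
      idx <- idx + 1L
      par_h <- vector("list", 2)
      par_id <- character(2)
      for (s in 1:2) {
        use_line <- y > 1 && length(prior) > 0 && stats::runif(1) < 0.5
        if (use_line) {
          j <- sample(prior, 1)
          par_h[[s]] <- list(H1[j, ], H2[j, ])
          par_id[s] <- ids[j]
        } else {
          j <- sample.int(config$n_founders, 1)
          par_h[[s]] <- list(founders[j, ], founders[j, ])
          par_id[s] <- paste0("F", j)
        }
      }
      c1 <- .gamete(par_h[[1]][[1]], par_h[[1]][[2]])
      c2 <- .gamete(par_h[[2]][[1]], par_h[[2]][[2]])
      het <- which(c1 != c2)
      if (length(het)) {
        stay <- stats::rbinom(length(het), 1, keep_p) == 1
        fix <- het[!stay]
        if (length(fix)) {
          pick1 <- stats::rbinom(length(fix), 1, 0.5) == 1
          c2[fix[pick1]] <- c1[fix[pick1]]
          c1[fix[!pick1]] <- c2[fix[!pick1]]
        }
      }
      H1[idx, ] <- c1
      H2[idx, ] <- c2
      parent_pairs[idx, ] <- par_id
    }
  }

  dosage <- H1 + H2                      # minor-allele count 0/1/2
  calls_m <- 1 - dosage / 2              # half-dosage major coding
  dimnames(calls_m) <- list(ids, sprintf("S%05d", seq_len(m)))

  set.seed(substreamSeed(config$seed, "qtl"))
  qtl <- sort(sample.int(m, config$n_qtl))
  eff <- stats::rnorm(config$n_qtl)
  bv <- drop(dosage[, qtl, drop = FALSE] %*% eff)
  names(bv) <- ids
  sd_bv <- stats::sd(bv)
  check_effects <- stats::rnorm(length(config$check_ids), 0, sd_bv)
  names(check_effects) <- config$check_ids

  set.seed(substreamSeed(config$seed, "gxe"))
  locs <- paste0("LOC", seq_len(config$n_locations))
  env <- matrix(stats::rnorm(n_total * config$n_locations, 0,
                             sqrt(config$var_gxe_ratio) * sd_bv),
                n_total, config$n_locations, dimnames = list(ids, locs))

  names(years) <- ids
  structure(list(
    panel = GenotypePanel(calls_m,
                          map = data.frame(marker_id = colnames(calls_m),
                                           chrom = paste0("C", 1 + (seq_len(m) - 1) %% 7),
                                           pos = seq_len(m) * 1000L,
                                           stringsAsFactors = FALSE)),
    cohorts = years,
    truth = list(true_bv = bv, qtl_ids = colnames(calls_m)[qtl],
                 qtl_effects = eff, env_deviations = env,
                 parent_pairs = parent_pairs,
                 check_effects = check_effects)),
    class = "CohortSim")
}

# exact AR1 x AR1 Gaussian surface with unit marginal variance, via the
# Cholesky factors of the two correlation matrices
.ar1Field <- function(nr, nc, rho_r, rho_c) {
  Rr <- rho_r^abs(outer(seq_len(nr), seq_len(nr), "-"))
  Rc <- rho_c^abs(outer(seq_len(nc), seq_len(nc), "-"))
  Z <- matrix(stats::rnorm(nr * nc), nr, nc)
  t(chol(Rr)) %*% Z %*% chol(Rc)
}

# residual plot variance solving the plot-level heritability calibration
.residVar <- function(var_g, config) {
  var_e <- var_g * (1 - config$h2_line_mean) / config$h2_line_mean -
    (config$var_gxe_ratio + config$spatial_var_ratio) * var_g
  if (var_e < -1e-9)
    stop("h2_line_mean too high for the requested GxE and spatial ratios")
  max(var_e, 0)
}

#' Simulate one location-year field trial
#'
#' Lays out the target-year cohort on a `field_dims` grid (row-major),
#' assigns incomplete blocks, and generates plot yields as overall mean +
#' true breeding value (or check effect) + line-by-location deviation +
#' AR1xAR1 spatial trend + iid noise. The iid-noise variance solves
#' `var_g * (1 - h2) / h2 = var_gxe + var_spatial + var_e` so the
#' plot-level heritability equals `h2_line_mean`. In the augmented design
#' every check appears once per incomplete block; in the alpha lattice all
#' entries appear once per replicate.
#'
#' @param sim a `"CohortSim"` from [simulateCohorts()].
#' @param config the [simConfig()] used to build `sim`.
#' @param year cohort year (e.g. 2012).
#' @param location location index in `1:n_locations`.
#' @return A trial table data.frame (see [readTrialTable()]).
#' @export
simulateTrial <- function(sim, config, year, location) {
  stopifnot(inherits(sim, "CohortSim"), inherits(config, "SimConfig"))
  cohort <- names(sim$cohorts)[sim$cohorts == year]
  if (!length(cohort)) stop("no cohort for year ", year)
  stopifnot(location >= 1, location <= config$n_locations)

  set.seed(substreamSeed(config$seed, "fields") +
             (year - 2012L) * 101L + location)

  n_l <- length(cohort)
  checks <- config$check_ids
  n_b <- config$n_blocks
  if (config$design == "augmented") {
    perm <- sample(cohort)
    # near-equal block sizes: split the permuted cohort into n_b chunks
    blk_of <- sort(rep(seq_len(n_b), length.out = n_l))
    entries <- character(0); blocks <- integer(0)
    for (b in seq_len(n_b)) {
      in_b <- sample(c(perm[blk_of == b], checks))
      entries <- c(entries, in_b)
      blocks <- c(blocks, rep(b, length(in_b)))
    }
    reps <- rep(1L, length(entries))
  } else {
    entries <- character(0); blocks <- integer(0); reps <- integer(0)
    for (r in seq_len(config$n_reps)) {
      perm <- sample(c(cohort, checks))
      blk_of <- sort(rep(seq_len(n_b), length.out = length(perm)))
      entries <- c(entries, perm)
      blocks <- c(blocks, blk_of)
      reps <- c(reps, rep(r, length(perm)))
    }
  }
  n_plots <- length(entries)
  nr <- config$field_dims[1]; nc <- config$field_dims[2]
  if (config$design == "alpha_lattice") {
    # replicated trials need a field large enough for all replicates
    need <- ceiling(n_plots / nc)
    if (need > nr) nr <- need
  }
  if (nr * nc < n_plots)
    stop("field of ", nr, "x", nc, " too small for ", n_plots, " plots")
  pos <- seq_len(n_plots)
  prow <- ((pos - 1) %/% nc) + 1L
  pcol <- ((pos - 1) %% nc) + 1L

  bv_all <- sim$truth$true_bv
  var_g <- stats::var(bv_all[cohort])
  sd_s <- sqrt(config$spatial_var_ratio * var_g)
  sd_e <- sqrt(.residVar(var_g, config))
  field <- if (sd_s > 0) sd_s * .ar1Field(nr, nc, config$rho_row, config$rho_col)
           else matrix(0, nr, nc)

  is_check <- entries %in% checks
  gen <- ifelse(is_check, sim$truth$check_effects[entries],
                bv_all[entries])
  env <- numeric(n_plots)
  env[!is_check] <- sim$truth$env_deviations[entries[!is_check], location]
  y <- config$mu + gen + env + field[cbind(prow, pcol)] +
    stats::rnorm(n_plots, 0, sd_e)

  data.frame(line_id = entries, year = as.integer(year),
             location = paste0("LOC", location), row = prow, col = pcol,
             block = blocks, rep = reps, is_check = is_check, yield = y,
             stringsAsFactors = FALSE)
}

#' Simulate one phenotype per line (line-mean scale)
#'
#' Convenience generator of line-level phenotypes `mu + bv + e` with
#' `var(e) = var(bv) * (1 - h2) / h2`, i.e. a single unreplicated
#' observation at line-mean heritability `h2`. Used for desk-scale GBLUP
#' benchmarks where the field layer is not under study.
#'
#' @param sim a `"CohortSim"`.
#' @param h2 heritability of the line means, in (0, 1].
#' @param seed integer seed.
#' @return Named numeric vector of phenotypes for all lines.
#' @export
simulateLineMeans <- function(sim, h2, seed = 1) {
  stopifnot(h2 > 0, h2 <= 1)
  bv <- sim$truth$true_bv
  set.seed(substreamSeed(as.integer(seed), "noise"))
  sd_e <- sqrt(stats::var(bv) * (1 - h2) / h2)
  bv + stats::rnorm(length(bv), 0, sd_e) + 50
}

#' Simulate multi-year line advancement by truncation selection
#'
#' Emulates stage advancement: the top `n_keep` lines of each origin-year
#' cohort by BLUP enter the next stage (retained a second year); in each
#' subsequent tracked year the survivors are re-phenotyped as true breeding
#' value plus fresh noise at heritability `h2` and the top `keep_fraction`
#' are retained again.
#'
#' @param blups_by_year named list: year -> named numeric vector of line
#'   BLUPs for that cohort.
#' @param n_keep number of lines advanced from each cohort (<= cohort size).
#' @param n_years_tracked total years a line can be retained (>= 2).
#' @param truth optional truth list from [simulateCohorts()]; required for
#'   the noisy re-phenotyping (defaults to reusing the BLUPs with fresh
#'   noise scaled to their variance when absent).
#' @param h2 heritability of the regenerated phenotypes.
#' @param keep_fraction fraction retained at each subsequent truncation.
#' @param seed integer seed.
#' @return data.frame with `line_id`, `origin_year`, `years_retained`;
#'   attribute `"flags"` holds the per-subsequent-year logical advancement
#'   matrix.
#' @export
simulateAdvancement <- function(blups_by_year, n_keep, n_years_tracked = 5,
                                truth = NULL, h2 = 0.5, keep_fraction = 0.5,
                                seed = 1) {
  stopifnot(n_years_tracked >= 2, keep_fraction > 0, keep_fraction <= 1)
  set.seed(substreamSeed(as.integer(seed), "advancement"))
  out <- list()
  for (yr in names(blups_by_year)) {
    blups <- blups_by_year[[yr]]
    if (n_keep > length(blups)) stop("n_keep exceeds cohort size in ", yr)
    retained <- rep(1L, length(blups))
    names(retained) <- names(blups)
    flags <- matrix(FALSE, length(blups), n_years_tracked - 1,
                    dimnames = list(names(blups),
                                    paste0("year", 2:n_years_tracked)))
    keep <- names(sort(blups, decreasing = TRUE))[seq_len(n_keep)]
    retained[keep] <- 2L
    flags[keep, 1] <- TRUE
    if (n_years_tracked > 2) {
      for (t in 3:n_years_tracked) {
        if (length(keep) < 1) break
        base <- if (!is.null(truth)) truth$true_bv[keep] else blups[keep]
        sd_e <- sqrt(max(stats::var(blups), 1e-12) * (1 - h2) / h2)
        pheno <- base + stats::rnorm(length(keep), 0, sd_e)
        n_next <- max(1L, roundHalfUp(keep_fraction * length(keep)))
        keep <- names(sort(pheno, decreasing = TRUE))[seq_len(n_next)]
        retained[keep] <- t
        flags[keep, t - 1] <- TRUE
      }
    }
    out[[yr]] <- list(df = data.frame(line_id = names(retained),
                                      origin_year = as.integer(yr),
                                      years_retained = unname(retained),
                                      stringsAsFactors = FALSE),
                      flags = flags)
  }
  df <- do.call(rbind, lapply(out, `[[`, "df"))
  rownames(df) <- NULL
  attr(df, "flags") <- lapply(out, `[[`, "flags")
  df
}
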