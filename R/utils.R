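# Internal helpers shared across modules.

# round-half-up (R's round() is banker's); reproduces the 28/56/140 test-set
# sizes from a 280-line cohort.
roundHalfUp <- function(x) floor(x + 0.5)

# Named randomness substreams: every simulation stage reseeds from the run
# seed plus a fixed stream offset so stages are independently reproducible.
SUBSTREAMS <- c(founders = 1L, cohorts = 2L, qtl = 3L, gxe = 4L,
                fields = 5L, noise = 6L, advancement = 7L, cv = 8L,
                gibbs = 9L)

substreamSeed <- function(seed, stream) {
  stopifnot(stream %in% names(SUBSTREAMS))
  (as.integer(seed) %% 1000000L) * 1000L + SUBSTREAMS[[stream]]
}

bgsLog <- function(...) {
  if (isTRUE(getOption("BreedGS.verbose", TRUE))) message(...)
}

# Pearson correlation that returns NA (with a warning upstream) on
# degenerate input instead of erroring.
safeCor <- function(x, y) {
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
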