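# internal helpers shared across modules

# population-variance standardization of a numeric vector
.stdVec <- function(v) {
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s == 0) stop("cannot standardize a constant vector")
  (v - m) / s
}

# Pearson correlation via population moments on already-centered data;
# plain cor() is used where inputs are raw
.pcor <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(x * y) / (sx * sy)
}

# two-sided p for a Pearson correlation via the exact t transform
.corPvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single number")
}

# deterministic per-stage seed derivation from a single pipeline seed
.stageSeed <- function(seed, stage) {
  offsets <- c(synth = 1L, trn = 2L, phenotype = 3L, triplets = 4L,
               screen = 5L, regions = 6L, crnet = 7L, stats = 8L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 21474836L) * 100L + offsets[[stage]]
}
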