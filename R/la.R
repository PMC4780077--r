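#' Split samples by the level of a modulator gene
#'
#' Orders samples by the modulator's expression and takes the top
#' \eqn{\lceil fraction \cdot n \rceil} as the high stratum.  At
#' \code{fraction = 0.5} the remaining \eqn{\lfloor n/2 \rfloor} samples form
#' the low stratum, so the split partitions all samples at the median; for
#' smaller fractions the low stratum is the bottom
#' \eqn{\lceil fraction \cdot n \rceil} and mid-range samples are left out.
#' Ties are broken by sample order, so the split is deterministic, disjoint
#' and (at 0.5) exhaustive.
#'
#' @param z numeric modulator series.
#' @param fraction fraction of samples per stratum, in (0, 0.5].
#' @return list with integer index vectors \code{high} and \code{low}.
#' @export
splitByModulator <- function(z, fraction = 0.5) {
  n <- length(z)
  if (fraction <= 0 || fraction > 0.5) stop("fraction must be in (0, 0.5]")
  nh <- ceiling(fraction * n)
  nl <- if (fraction == 0.5) n - nh else nh
  if (min(nh, nl) < 5) stop("too few samples per stratum (need >= 5)")
  if (max(z) == min(z)) stop("modulator has no dynamic range")
  o <- order(z, seq_len(n))
  list(high = sort(o[(n - nh + 1):n]), low = sort(o[seq_len(nl)]))
}

#' Fast approximate liquid association
#'
#' Measures how the co-expression of a pair (X, Y) changes with the level of
#' a modulator Z: samples are stratified by Z (high vs low), the Pearson
#' correlation of X and Y is computed in each stratum, and
#' \deqn{LA(X,Y|Z) = (\rho_{high} - \rho_{low}) / 2.}
#' Significance comes from the Fisher-transformation Z-test for two
#' correlations,
#' \deqn{z = \frac{\mathrm{atanh}\,\rho_1 - \mathrm{atanh}\,\rho_2}
#'   {\sqrt{1/(n_1-3) + 1/(n_2-3)}},}
#' with a two-sided normal tail.  A stratum correlation at exactly
#' \eqn{|\rho| = 1} is clamped to \eqn{1 - 10^{-7}} before the transform and
#' the result is flagged (\code{clamped = TRUE}).
#'
#' @param x,y standardized series (the TF and target gene).
#' @param z modulator series (the chromatin regulator).
#' @param fraction per-stratum fraction passed to [splitByModulator()].
#' @return list with \code{la}, \code{rho_high}, \code{rho_low}, \code{n1},
#'   \code{n2}, \code{z_stat}, \code{p} and \code{clamped}.
#' @seealso [permutationLAPvalue()] for the permutation oracle.
#' @export
fastLA <- function(x, y, z, fraction = 0.5) {
  n <- length(z)
  if (length(x) != n || length(y) != n) stop("x, y, z must have equal length")
  s <- splitByModulator(z, fraction)
  for (nm in c("high", "low")) {
    idx <- s[[nm]]
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0)
      stop("zero variance in the ", nm, "-Z stratum")
  }
  r1 <- .pcor(x[s$high], y[s$high])
  r2 <- .pcor(x[s$low], y[s$low])
  n1 <- length(s$high); n2 <- length(s$low)
  clamped <- abs(r1) >= 1 - 1e-12 || abs(r2) >= 1 - 1e-12
  cl <- function(r) max(min(r, 1 - 1e-7), -1 + 1e-7)
  zstat <- (atanh(cl(r1)) - atanh(cl(r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(la = (r1 - r2) / 2, rho_high = r1, rho_low = r2,
       n1 = n1, n2 = n2, z_stat = zstat,
       p = 2 * stats::pnorm(-abs(zstat)), clamped = clamped)
}

#' Permutation p-value for liquid association
#'
#' The non-parametric reference: permutes the modulator profile Z and
#' recomputes \eqn{|LA|} each time; the two-sided p-value uses the add-one
#' estimator \eqn{(1 + \#\{|LA'| \ge |LA|\}) / (n_{perm} + 1)}, so it is
#' never zero.  Reproducible from \code{seed}.
#'
#' @inheritParams fastLA
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @return scalar p-value \eqn{\ge 1/(n_{perm}+1)}.
#' @export
permutationLAPvalue <- function(x, y, z, fraction = 0.5, nPerm = 1e5, seed = 1) {
  n <- length(z)
  if (length(x) != n || length(y) != n) stop("x, y, z must have equal length")
  s <- splitByModulator(z, fraction)
  obs <- abs(.pcor(x[s$high], y[s$high]) - .pcor(x[s$low], y[s$low])) / 2
  nh <- length(s$high); nl <- length(s$low)
  set.seed(as.integer(seed))

  # permuting z only permutes stratum membership; compute stratum
  # correlations from subset sums in chunks of permutations
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  M <- cbind(x, y, x^2, y^2, x * y)
  chunk <- 2000L
  exceed <- 0L
  done <- 0L
  while (done < nPerm) {
    k <- min(chunk, nPerm - done)
    H <- matrix(0, k, n)
    for (j in seq_len(k)) {
      o <- sample.int(n)
      H[j, o[(n - nh + 1):n]] <- 1      # high stratum of this permutation
      if (fraction < 0.5) {
        # mark low stratum with -1 so both subsets come from one matrix
        H[j, o[seq_len(nl)]] <- -1
      }
    }
    hi <- pmax(H, 0) %*% M
    lo <- if (fraction < 0.5) (-pmin(H, 0)) %*% M else
      matrix(c(sx, sy, sxx, syy, sxy), k, 5, byrow = TRUE) - hi
    rr <- function(S, m) {
      num <- S[, 5] - S[, 1] * S[, 2] / m
      den <- sqrt(pmax(S[, 3] - S[, 1]^2 / m, 0) *
                  pmax(S[, 4] - S[, 2]^2 / m, 0))
      ifelse(den > 0, num / den, NA_real_)
    }
    la <- abs(rr(hi, nh) - rr(lo, nl)) / 2
    exceed <- exceed + sum(la >= obs - 1e-15, na.rm = TRUE)
    done <- done + k
  }
  (1 + exceed) / (nPerm + 1)
}
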