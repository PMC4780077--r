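#' Group target genes into genomic regions
#'
#' Places the TGs of the surviving triplets into regions, either by midpoint
#' overlap with user-supplied region intervals, or -- when none are given --
#' by single-linkage clustering of TG midpoints per chromosome with a
#' maximum gap of \code{window} (default 1 Mb).  Each region's TF parents
#' are the TFs regulating its member TGs in the triplets; its CR parents are
#' the union of modulators of any triplet whose TG lies in the region.
#' Regions with fewer than two TGs are dropped (a single-TG region cannot
#' identify a latent activity) with a message, as are TGs missing from the
#' annotation.
#'
#' @param annotation named \code{GRanges} of gene loci.
#' @param triplets (screened) triplet table.
#' @param regionBed optional \code{GRanges} of predefined regions.
#' @param window single-linkage gap in bp.
#' @return named list of region specs, each a list with \code{region}
#'   (\code{GRanges}), \code{tgs}, \code{tfParents} (named list) and
#'   \code{crParents}; the input of [fitRegion()].
#' @export
assignRegions <- function(annotation, triplets, regionBed = NULL,
                          window = 1e6) {
  tgs <- unique(triplets$tg)
  missing <- setdiff(tgs, names(annotation))
  if (length(missing)) {
    message(length(missing), " TG(s) missing from annotation dropped: ",
            paste(utils::head(missing, 5), collapse = ", "))
    tgs <- setdiff(tgs, missing)
  }
  if (!length(tgs)) stop("no annotated TGs to assign")
  loci <- annotation[tgs]
  mid <- (start(loci) + end(loci)) / 2

  if (!is.null(regionBed)) {
    midGR <- GRanges(seqnames(loci), IRanges(mid, mid))
    ov <- GenomicRanges::findOverlaps(midGR, regionBed, select = "first")
    groups <- split(tgs, ov)
    groups <- groups[!is.na(names(groups))]
    bounds <- lapply(names(groups), function(i) regionBed[as.integer(i)])
    names(bounds) <- names(groups)
  } else {
    df <- data.frame(tg = tgs, chrom = as.character(seqnames(loci)), mid = mid)
    groups <- list(); bounds <- list(); k <- 0
    for (chr in unique(df$chrom)) {
      d <- df[df$chrom == chr, ]
      d <- d[order(d$mid), ]
      brk <- cumsum(c(0, diff(d$mid) > window))
      for (g in split(d$tg, brk)) {
        k <- k + 1
        groups[[k]] <- g
        gl <- loci[g]
        bounds[[k]] <- GRanges(chr, IRanges(min(start(gl)), max(end(gl))))
      }
    }
  }

  small <- lengths(groups) < 2
  if (any(small))
    message(sum(small), " candidate region(s) with < 2 TGs dropped")
  groups <- groups[!small]; bounds <- bounds[!small]
  if (!length(groups)) stop("no region with >= 2 TGs")

  out <- list()
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    tr <- triplets[triplets$tg %in% g, , drop = FALSE]
    tfParents <- lapply(stats::setNames(g, g), function(tg)
      sort(unique(tr$tf[tr$tg == tg])))
    b <- bounds[[i]]
    nm <- sprintf("%s:%d-%d", as.character(seqnames(b)), start(b), end(b))
    out[[nm]] <- list(region = b, tgs = g, tfParents = tfParents,
                      crParents = sort(unique(tr$cr)))
  }
  out[order(names(out))]
}

#' Fit the latent chromatin-activity model of one region
#'
#' Linear-Gaussian Bayesian network with a hidden chromatin-activity (CA)
#' series: \eqn{CA_t \sim N(\beta_0 + \sum_l \beta_l R_{lt},\,
#' \sigma_{CA}^2)} over the region's CR parents, and each member TG
#' \eqn{T_{nt} \sim N(\alpha_n + \alpha_{n0} CA_t + \sum_k \alpha_{nk}
#' F_{kt},\, \sigma_n^2)} over CA and its TF parents.  Fitted by
#' hard-assignment EM: the E-step sets each \eqn{CA_t} to its exact Gaussian
#' conditional posterior mean (equal to the mode) -- a precision-weighted
#' combination of the CR prediction and each TG's back-projection -- and the
#' M-step is ordinary least squares for every TG regression and for the CA
#' regression, plus residual-variance updates.  The complete-data
#' log-likelihood is nondecreasing across iterations; the best of
#' \code{nRestarts} runs (CA initialized at the first principal component of
#' the TG rows, restarts perturbed with seeded Gaussian noise) is returned.
#' After convergence CA is re-standardized and its sign fixed so the
#' largest-magnitude CR coefficient is positive, with the TG loadings
#' rescaled compensatingly.
#'
#' @param x a standardized [CRExperiment-class], or a numeric matrix (rows =
#'   genes) containing all TG, TF and CR series.
#' @param spec region spec as produced by [assignRegions()] (or any list
#'   with \code{region}, \code{tgs}, \code{tfParents}, \code{crParents}).
#' @param maxIter,tol EM iteration cap and relative-objective tolerance.
#' @param nRestarts number of EM starts.
#' @param seed integer seed for the restart perturbations.
#' @return A [RegionModel-class].
#' @export
fitRegion <- function(x, spec, maxIter = 500, tol = 1e-9, nRestarts = 5,
                      seed = 1) {
  m <- if (is(x, "CRExperiment")) assay(x, "exprs") else as.matrix(x)
  tgs <- spec$tgs
  if (length(tgs) < 2)
    stop("region has fewer than 2 TGs: the latent activity is unidentifiable")
  crs <- intersect(spec$crParents, rownames(m))
  tfParents <- lapply(spec$tfParents[tgs], function(v) intersect(v, rownames(m)))
  n <- ncol(m)
  maxPar <- max(2 + lengths(tfParents), 1 + length(crs))
  if (n <= maxPar)
    stop("more parameters per regression (", maxPar, ") than samples (", n, ")")

  Tm <- m[tgs, , drop = FALSE]
  R <- if (length(crs)) t(m[crs, , drop = FALSE]) else matrix(0, n, 0)
  Flist <- lapply(tfParents, function(tf)
    if (length(tf)) t(m[tf, , drop = FALSE]) else matrix(0, n, 0))

  # PC1 of the TG rows: the no-TF special case of the model
  pc1 <- stats::prcomp(t(Tm), center = TRUE, scale. = FALSE)$x[, 1]
  pc1 <- .stdVec(pc1)

  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    ca0 <- if (r == 1) pc1 else .stdVec(pc1 + stats::rnorm(n, sd = 0.2))
    fit <- .emRegion(Tm, R, Flist, ca0, maxIter, tol)
    if (is.null(best) ||
        fit$loglik[length(fit$loglik)] > best$loglik[length(best$loglik)])
      best <- fit
  }
  fit <- best

  # identifiability conventions: standardized CA, largest-|beta| positive
  mu <- mean(fit$ca); sdev <- sqrt(mean((fit$ca - mu)^2))
  sgn <- 1
  if (length(crs)) {
    b <- fit$beta
    if (b[which.max(abs(b))] < 0) sgn <- -1
  } else if (fit$a0[1] < 0) sgn <- -1
  ca <- sgn * (fit$ca - mu) / sdev
  alpha <- list()
  for (i in seq_along(tgs)) {
    alpha[[tgs[i]]] <- list(
      intercept = fit$aint[i] + fit$a0[i] * mu,
      ca = sgn * fit$a0[i] * sdev,
      tf = stats::setNames(fit$atf[[i]], tfParents[[tgs[i]]]))
  }
  beta <- stats::setNames(sgn * fit$beta / sdev, crs)
  beta0 <- sgn * (fit$beta0 - mu) / sdev
  region <- if (!is.null(spec$region)) spec$region else GRanges("chrNA", IRanges(1, 2))

  new("RegionModel", region = region, tgs = tgs, tfParents = tfParents,
      crParents = crs, alpha = alpha, beta = beta, betaIntercept = beta0,
      sigmaTG = stats::setNames(fit$sigT, tgs), sigmaCA = fit$sigCA / sdev,
      activity = ca, loglikPath = fit$loglik, converged = fit$converged)
}

# hard EM core; Tm: TGs x n, R: n x L CR design, Flist: per-TG n x K design
.emRegion <- function(Tm, R, Flist, ca, maxIter, tol) {
  nTG <- nrow(Tm); n <- ncol(Tm); L <- ncol(R)
  sigT <- rep(1, nTG); sigCA <- 1
  aint <- numeric(nTG); a0 <- rep(1, nTG)
  atf <- lapply(Flist, function(f) rep(0, ncol(f)))
  beta <- rep(0, L); beta0 <- 0
  ll <- numeric(0); converged <- FALSE

  mstep <- function(ca) {
    for (i in seq_len(nTG)) {
      X <- cbind(1, ca, Flist[[i]])
      cf <- .lsfit(X, Tm[i, ])
      aint[i] <<- cf[1]; a0[i] <<- cf[2]
      atf[[i]] <<- if (ncol(Flist[[i]])) cf[-(1:2)] else numeric(0)
      res <- Tm[i, ] - X %*% cf
      # floor at 0.1% of the standardized scale: an exactly-fitted gene
      # must not acquire unbounded precision and pin the latent series
      sigT[i] <<- sqrt(max(mean(res^2), 1e-6))
    }
    Xc <- cbind(1, R)
    cf <- .lsfit(Xc, ca)
    beta0 <<- cf[1]; beta <<- if (L) cf[-1] else numeric(0)
    res <- ca - Xc %*% cf
    sigCA <<- sqrt(max(mean(res^2), 1e-6))
  }
  loglik <- function(ca) {
    v <- sum(stats::dnorm(ca, beta0 + if (L) as.vector(R %*% beta) else 0,
                          sigCA, log = TRUE))
    for (i in seq_len(nTG)) {
      mu <- aint[i] + a0[i] * ca +
        (if (ncol(Flist[[i]])) as.vector(Flist[[i]] %*% atf[[i]]) else 0)
      v <- v + sum(stats::dnorm(Tm[i, ], mu, sigT[i], log = TRUE))
    }
    v
  }

  mstep(ca)
  ll <- loglik(ca)
  for (it in seq_len(maxIter)) {
    caPrev <- ca
    # E-step: exact conditional posterior mean of CA_t given data and theta
    prior <- beta0 + if (L) as.vector(R %*% beta) else rep(0, n)
    prec <- 1 / sigCA^2 + sum(a0^2 / sigT^2)
    num <- prior / sigCA^2
    for (i in seq_len(nTG)) {
      resid <- Tm[i, ] - aint[i] -
        (if (ncol(Flist[[i]])) as.vector(Flist[[i]] %*% atf[[i]]) else 0)
      num <- num + a0[i] * resid / sigT[i]^2
    }
    ca <- num / prec
    mstep(ca)
    ll <- c(ll, loglik(ca))
    k <- length(ll)
    # stop on objective stability, or on stability of the gauge-invariant
    # latent direction (the complete-data likelihood of a hard-EM latent
    # linear-Gaussian model is unbounded along the latent-scale direction,
    # so the objective can keep creeping while every identifiable quantity
    # has converged; see the methods vignette)
    dirChange <- if (stats::sd(ca) > 0 && stats::sd(caPrev) > 0)
      1 - abs(stats::cor(ca, caPrev)) else 1
    if (abs(ll[k] - ll[k - 1]) < tol * (abs(ll[k - 1]) + 1e-12) ||
        (it >= 3 && dirChange < 1e-10)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("EM did not converge in ", maxIter, " iterations; returning best iterate")
  list(ca = as.vector(ca), aint = aint, a0 = a0, atf = atf, beta = beta,
       beta0 = beta0, sigT = sigT, sigCA = sigCA, loglik = ll,
       converged = converged)
}

# least squares with ridge fallback for collinear designs
.lsfit <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("collinear parents; using ridge fallback (lambda = 1e-6)")
    A <- crossprod(X) + diag(1e-6, ncol(X))
    return(as.vector(solve(A, crossprod(X, y))))
  }
  as.vector(qr.coef(qrX, y))
}

#' Rank a region's CR parents by effect on chromatin activity
#'
#' Orders the fitted CR coefficients by decreasing magnitude (inputs are
#' standardized, so the \eqn{\beta_l} are comparable); the sign separates
#' activators from repressors of the region.
#'
#' @param model a fitted [RegionModel-class].
#' @return data.frame with columns \code{cr}, \code{beta},
#'   \code{abs_beta}, \code{sign}, ordered by decreasing \code{abs_beta}.
#' @export
rankRegionCRs <- function(model) {
  stopifnot(is(model, "RegionModel"))
  b <- model@beta
  out <- data.frame(cr = names(b), beta = unname(b), abs_beta = abs(unname(b)),
                    sign = sign(unname(b)))
  out <- out[order(-out$abs_beta, out$cr), ]
  rownames(out) <- NULL
  out
}
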