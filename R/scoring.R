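#' Fisher's combined probability test
#'
#' Combines k independent p-values into the chi-square modulation score
#' \eqn{\chi^2 = -2\sum_i \ln p_i} with \eqn{2k} degrees of freedom; the
#' combined p-value is the upper chi-square tail.
#'
#' @param p numeric vector of p-values in (0, 1]; the modulation score uses
#'   exactly four (MI, liquid association, CR-phenotype, TF-phenotype), but
#'   any k is supported.
#' @return list with \code{chi2} and \code{p_combined}.
#' @examples
#' combineFisher(rep(0.01, 4))$chi2   # -8 * log(0.01) = 36.8414
#' @export
combineFisher <- function(p) {
  if (!length(p)) stop("need at least one p-value")
  if (any(p <= 0))
    stop("p-values must be > 0 (floor at the pipeline level first)")
  if (any(p > 1)) stop("p-values must be <= 1")
  chi2 <- -2 * sum(log(p))
  list(chi2 = chi2,
       p_combined = stats::pchisq(chi2, df = 2 * length(p), lower.tail = FALSE))
}

#' Score all CR-TF-TG triplets
#'
#' For every (modulator, regulation edge) pair with the modulator distinct
#' from both TF and TG, combines four lines of evidence into the modulation
#' score: the edge's MI p-value, the liquid-association p-value of the edge
#' given the modulator, and the phenotype-consistency p-values of modulator
#' and TF.  Component p-values are floored at 1e-300 before the log (rows
#' where flooring occurred are flagged in the \code{floored} column).
#'
#' @param x a standardized [CRExperiment-class].
#' @param roles a [GeneRoles-class].
#' @param edges edge table from [inferTRN()].
#' @param fraction stratum fraction for the liquid-association split.
#' @param modulators candidate modulator genes; default the CR list.  Pass
#'   \code{"all"} to screen every gene as a candidate modulator (used for
#'   the CR vs non-CR modulation-degree comparison).
#' @param index phenotype series; computed from the marker panel when
#'   omitted.
#' @return data.frame, one row per triplet, sorted by decreasing
#'   \code{chi2} (ties broken lexicographically by cr, tf, tg), with columns
#'   \code{cr}, \code{tf}, \code{tg}, \code{p_mi}, \code{p_la},
#'   \code{p_cr_pheno}, \code{p_tf_pheno}, \code{chi2}, \code{p_combined},
#'   \code{q} (Bonferroni over this table) and \code{floored}.
#' @export
scoreTriplets <- function(x, roles, edges, fraction = 0.5, modulators = NULL,
                          index = NULL) {
  stopifnot(is(x, "CRExperiment"), is(roles, "GeneRoles"))
  if (!isStandardized(x)) stop("expression must be standardized first")
  m <- assay(x, "exprs")
  if (is.null(modulators)) modulators <- crGenes(roles)
  else if (identical(modulators, "all")) modulators <- rownames(m)
  modulators <- intersect(modulators, rownames(m))
  if (!length(modulators)) stop("no candidate modulators in the matrix")
  if (!nrow(edges)) {
    return(data.frame(cr = character(), tf = character(), tg = character(),
                      p_mi = numeric(), p_la = numeric(),
                      p_cr_pheno = numeric(), p_tf_pheno = numeric(),
                      chi2 = numeric(), p_combined = numeric(), q = numeric(),
                      floored = logical()))
  }
  if (is.null(index)) index <- pluripotencyIndex(x)$values

  phenoP <- vapply(unique(c(edges$tf, modulators)), function(g)
    phenotypeCorrelation(m[g, ], index)$p, 0)

  # per-modulator stratum split computed once
  splits <- lapply(modulators, function(cr) splitByModulator(m[cr, ], fraction))
  names(splits) <- modulators

  rows <- vector("list", length(modulators))
  for (ci in seq_along(modulators)) {
    cr <- modulators[ci]
    s <- splits[[cr]]
    keep <- edges$tf != cr & edges$tg != cr
    e <- edges[keep, , drop = FALSE]
    if (!nrow(e)) next
    n1 <- length(s$high); n2 <- length(s$low)
    Xh <- m[e$tf, s$high, drop = FALSE]; Yh <- m[e$tg, s$high, drop = FALSE]
    Xl <- m[e$tf, s$low, drop = FALSE];  Yl <- m[e$tg, s$low, drop = FALSE]
    rsub <- function(A, B) {
      A <- A - rowMeans(A); B <- B - rowMeans(B)
      num <- rowSums(A * B)
      den <- sqrt(rowSums(A^2) * rowSums(B^2))
      ifelse(den > 0, num / den, NA_real_)
    }
    r1 <- rsub(Xh, Yh); r2 <- rsub(Xl, Yl)
    cl <- function(r) pmax(pmin(r, 1 - 1e-7), -1 + 1e-7)
    zs <- (atanh(cl(r1)) - atanh(cl(r2))) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    pla <- 2 * stats::pnorm(-abs(zs))
    rows[[ci]] <- data.frame(cr = cr, tf = e$tf, tg = e$tg,
                             p_mi = e$p, p_la = pla,
                             p_cr_pheno = phenoP[[cr]],
                             p_tf_pheno = unname(phenoP[e$tf]),
                             stringsAsFactors = FALSE)
  }
  tr <- do.call(rbind, rows)
  if (is.null(tr)) stop("no triplets could be formed")
  pm <- as.matrix(tr[, c("p_mi", "p_la", "p_cr_pheno", "p_tf_pheno")])
  tr$floored <- apply(pm < 1e-300, 1, any)
  pm <- pmax(pm, 1e-300)
  tr$chi2 <- -2 * rowSums(log(pm))
  tr$p_combined <- stats::pchisq(tr$chi2, df = 8, lower.tail = FALSE)
  tr$q <- pmin(1, tr$p_combined * nrow(tr))
  tr <- tr[order(-tr$chi2, tr$cr, tr$tf, tr$tg), ]
  rownames(tr) <- NULL
  tr[, c("cr", "tf", "tg", "p_mi", "p_la", "p_cr_pheno", "p_tf_pheno",
         "chi2", "p_combined", "q", "floored")]
}

#' Two-layer false-positive screen
#'
#' Layer 1 adjusts the combined p-values over the whole triplet table
#' (Bonferroni as named by the procedure, \eqn{q = \min(1, p N)}; or
#' Benjamini-Hochberg via \code{method = "BH"}) and keeps triplets with
#' \eqn{q \le q_{max}}.  Layer 2 removes triplets whose modulator has low
#' degree in the resulting modulation network: a modulator must modulate
#' more than \code{minCRDegree} distinct TFs among the layer-1 survivors.
#' The screen is order-independent.
#'
#' @param triplets full scored table from [scoreTriplets()].
#' @param qMax adjusted-p cutoff (default 0.001).
#' @param minCRDegree minimum distinct-TF degree (default 50; set 0 to
#'   disable; at synthetic scale the TF pool is far smaller than in a
#'   genome-wide screen, so tests typically disable it).
#' @param method multiplicity adjustment, \code{"bonferroni"} or
#'   \code{"BH"}.
#' @return the surviving rows, with \code{q} recomputed per \code{method}.
#' @export
screenTriplets <- function(triplets, qMax = 0.001, minCRDegree = 50,
                           method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  if (!nrow(triplets)) return(triplets)
  q <- if (method == "bonferroni") pmin(1, triplets$p_combined * nrow(triplets))
       else stats::p.adjust(triplets$p_combined, method = "BH")
  out <- triplets
  out$q <- q
  out <- out[q <= qMax, , drop = FALSE]
  if (nrow(out) && minCRDegree > 0) {
    deg <- vapply(split(out$tf, out$cr), function(v) length(unique(v)), 0L)
    out <- out[deg[out$cr] > minCRDegree, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Chromatin regulation scores
#'
#' Per-modulator sum of the chi-square modulation scores over its surviving
#' triplets, with triplet, distinct-TF and distinct-TG counts.
#'
#' @param triplets (screened) triplet table.
#' @return data.frame sorted by decreasing \code{score} with columns
#'   \code{cr}, \code{score}, \code{n_triplets}, \code{n_tfs_modulated},
#'   \code{n_tgs}.
#' @export
crScores <- function(triplets) {
  if (!nrow(triplets))
    return(data.frame(cr = character(), score = numeric(),
                      n_triplets = integer(), n_tfs_modulated = integer(),
                      n_tgs = integer()))
  sp <- split(triplets, triplets$cr)
  out <- data.frame(
    cr = names(sp),
    score = vapply(sp, function(d) sum(d$chi2), 0),
    n_triplets = vapply(sp, nrow, 0L),
    n_tfs_modulated = vapply(sp, function(d) length(unique(d$tf)), 0L),
    n_tgs = vapply(sp, function(d) length(unique(d$tg)), 0L))
  out <- out[order(-out$score, out$cr), ]
  rownames(out) <- NULL
  out
}

#' Modulation subnetwork of one chromatin regulator
#'
#' Extracts, from the triplet table, the TF-to-TG regulation edges and
#' CR-to-TF modulation edges touching the named modulator.
#'
#' @param triplets (screened) triplet table.
#' @param cr modulator gene id.
#' @return data.frame with columns \code{from}, \code{to}, \code{type}
#'   (\code{"regulation"} or \code{"modulation"}) and \code{n_triplets}.
#' @export
crSubnetwork <- function(triplets, cr) {
  if (!cr %in% triplets$cr) stop("unknown CR id: ", cr)
  d <- triplets[triplets$cr == cr, , drop = FALSE]
  reg <- stats::aggregate(list(n_triplets = d$tg), by = list(from = d$tf, to = d$tg),
                          FUN = length)
  reg$type <- "regulation"
  mod <- stats::aggregate(list(n_triplets = d$tf), by = list(to = d$tf),
                          FUN = length)
  mod$from <- cr
  mod$type <- "modulation"
  out <- rbind(reg[, c("from", "to", "type", "n_triplets")],
               mod[, c("from", "to", "type", "n_triplets")])
  out <- out[order(out$type, out$from, out$to), ]
  rownames(out) <- NULL
  out
}
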