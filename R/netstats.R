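#' Pile triplets into the modulation network
#'
#' Collapses the triplet table into the two-layer modulation network:
#' regulation edges (TF to TG) and modulation edges (CR to TF), each with a
#' multiplicity count.
#'
#' @param triplets (screened) triplet table.
#' @return list with data.frames \code{regulation} (\code{tf}, \code{tg},
#'   \code{count}) and \code{modulation} (\code{cr}, \code{tf},
#'   \code{count}).
#' @export
modulationNetwork <- function(triplets) {
  reg <- stats::aggregate(list(count = triplets$cr),
                          by = list(tf = triplets$tf, tg = triplets$tg),
                          FUN = length)
  mod <- stats::aggregate(list(count = triplets$tg),
                          by = list(cr = triplets$cr, tf = triplets$tf),
                          FUN = length)
  reg <- reg[order(reg$tf, reg$tg), ]; rownames(reg) <- NULL
  mod <- mod[order(mod$cr, mod$tf), ]; rownames(mod) <- NULL
  list(regulation = reg, modulation = mod)
}

# distinct-TF modulation degree per modulator gene
.modulationDegree <- function(triplets, genes) {
  deg <- vapply(split(triplets$tf, triplets$cr),
                function(v) length(unique(v)), 0L)
  out <- stats::setNames(rep(0L, length(genes)), genes)
  common <- intersect(genes, names(deg))
  out[common] <- deg[common]
  out
}

#' Compare modulation degrees between two gene groups
#'
#' Per-gene count of distinct TFs modulated (from a triplet table scored
#' with every gene as candidate modulator), compared between two disjoint
#' groups by Welch's t-test.  Also reports the fraction of "modulators"
#' (genes modulating more than \code{threshold} TFs) per group with a
#' chi-square test, and -- when roles are supplied -- the per-CR-category
#' breakdown against the non-CR group.
#'
#' @param triplets triplet table (modulators need not be CRs).
#' @param groupA,groupB disjoint character vectors of gene ids.
#' @param threshold modulator cutoff on distinct-TF degree (default 50).
#' @param roles optional [GeneRoles-class] for the category breakdown.
#' @return list with \code{mean_a}, \code{mean_b}, \code{t_stat}, \code{p},
#'   \code{modulator_fraction} (2x2 counts + chi-square p) and, if roles
#'   given, \code{by_category}.
#' @export
modulationDegreeComparison <- function(triplets, groupA, groupB,
                                       threshold = 50, roles = NULL) {
  if (!length(groupA) || !length(groupB)) stop("empty gene group")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  dA <- .modulationDegree(triplets, groupA)
  dB <- .modulationDegree(triplets, groupB)
  tt <- if (stats::sd(dA) == 0 && stats::sd(dB) == 0 && mean(dA) == mean(dB))
    list(statistic = 0, p.value = 1)
  else stats::t.test(dA, dB)
  cnt <- matrix(c(sum(dA > threshold), sum(dA <= threshold),
                  sum(dB > threshold), sum(dB <= threshold)), 2, 2,
                dimnames = list(c("modulator", "non_modulator"), c("A", "B")))
  chi <- if (all(rowSums(cnt) > 0) && all(colSums(cnt) > 0))
    suppressWarnings(stats::chisq.test(cnt, correct = FALSE)$p.value) else NA_real_
  out <- list(mean_a = mean(dA), mean_b = mean(dB),
              t_stat = unname(tt$statistic), p = tt$p.value,
              modulator_fraction = list(counts = cnt, chisq_p = chi))
  if (!is.null(roles)) {
    cats <- crCategories(roles)
    out$by_category <- lapply(sort(unique(cats)), function(cc) {
      gA <- intersect(groupA, names(cats)[cats == cc])
      if (!length(gA)) return(NULL)
      ttc <- stats::t.test(.modulationDegree(triplets, gA), dB)
      list(category = cc, mean = mean(.modulationDegree(triplets, gA)),
           p = ttc$p.value)
    })
    names(out$by_category) <- sort(unique(cats))
  }
  out
}

#' Compare modulation in-degrees between two TF groups
#'
#' Modulation in-degree of a TF = number of distinct CRs modulating it in
#' the triplet table.  Groups (e.g. pioneer vs non-pioneer TFs) are compared
#' by the Wilcoxon rank-sum test.
#'
#' @param triplets (screened) triplet table.
#' @param tfGroupA,tfGroupB character vectors of TF ids.
#' @return list with \code{mean_a}, \code{mean_b}, \code{stat}, \code{p}
#'   and the per-TF degree vectors.
#' @export
indegreeComparison <- function(triplets, tfGroupA, tfGroupB) {
  if (!length(tfGroupA) || !length(tfGroupB)) stop("empty TF group")
  deg <- vapply(split(triplets$cr, triplets$tf),
                function(v) length(unique(v)), 0L)
  get <- function(g) {
    out <- stats::setNames(rep(0L, length(g)), g)
    common <- intersect(g, names(deg))
    out[common] <- deg[common]
    out
  }
  dA <- get(tfGroupA); dB <- get(tfGroupB)
  wt <- if (identical(sort(unname(dA)), sort(unname(dB))))
    list(statistic = NA_real_, p.value = 1)
  else suppressWarnings(stats::wilcox.test(dA, dB))
  list(mean_a = mean(dA), mean_b = mean(dB),
       stat = unname(wt$statistic), p = wt$p.value,
       degrees_a = dA, degrees_b = dB)
}

#' Hub tables of the modulation network
#'
#' Top-k chromatin regulators by chromatin regulation score, TFs by
#' modulation in-degree and regulation out-degree, and TGs by regulation
#' in-degree.  Deterministic ordering; ties broken lexicographically.
#'
#' @param triplets (screened) triplet table.
#' @param k table size (capped at the number of nodes).
#' @return list of data.frames \code{crs}, \code{tfs}, \code{tgs}.
#' @export
hubTables <- function(triplets, k = 10) {
  cs <- crScores(triplets)
  net <- modulationNetwork(triplets)
  tfIn <- vapply(split(net$modulation$cr, net$modulation$tf),
                 function(v) length(unique(v)), 0L)
  tfOut <- vapply(split(net$regulation$tg, net$regulation$tf),
                  function(v) length(unique(v)), 0L)
  tfs <- sort(unique(c(names(tfIn), names(tfOut))))
  tfTab <- data.frame(
    tf = tfs,
    in_degree = ifelse(tfs %in% names(tfIn), tfIn[tfs], 0L),
    out_degree = ifelse(tfs %in% names(tfOut), tfOut[tfs], 0L))
  tfTab <- tfTab[order(-tfTab$in_degree, -tfTab$out_degree, tfTab$tf), ]
  tgIn <- vapply(split(net$regulation$tf, net$regulation$tg),
                 function(v) length(unique(v)), 0L)
  tgTab <- data.frame(tg = names(tgIn), in_degree = unname(tgIn))
  tgTab <- tgTab[order(-tgTab$in_degree, tgTab$tg), ]
  rownames(tfTab) <- rownames(tgTab) <- NULL
  list(crs = utils::head(cs, k), tfs = utils::head(tfTab, k),
       tgs = utils::head(tgTab, k))
}
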