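#' The 16 core pluripotency marker genes
#'
#' Default marker panel whose mean standardized expression defines the
#' pluripotency index.
#'
#' @return character vector of 16 gene symbols.
#' @export
pluripotencyMarkers <- function() {
  c("Pou5f1", "Sox2", "Nanog", "Klf4", "Myc", "Tcf3", "Esrrb", "Zfp42",
    "Nr0b1", "Stat3", "Sall4", "Phc1", "Klf2", "Rest", "Zfp281", "Tbx3")
}

#' Pluripotency index (phenotype series)
#'
#' Per-sample mean of the available marker gene rows.  Computed on
#' standardized expression so each marker contributes equally.  Missing
#' markers are tolerated down to half the panel and reported.
#'
#' @param x a [CRExperiment-class] (standardized for the pipeline; any
#'   expression scale is accepted for direct use).
#' @param markers marker gene ids; default the 16-gene panel.
#' @return list with \code{values} (numeric per sample), \code{markers_used}
#'   and \code{missing_markers}.
#' @export
pluripotencyIndex <- function(x, markers = pluripotencyMarkers()) {
  stopifnot(is(x, "CRExperiment"))
  m <- assay(x, "exprs")
  used <- intersect(markers, rownames(m))
  missing <- setdiff(markers, rownames(m))
  if (length(used) < length(markers) / 2)
    stop("fewer than half the phenotype markers are present (",
         length(used), "/", length(markers), ")")
  if (length(missing))
    message(length(missing), " marker(s) missing from the matrix: ",
            paste(missing, collapse = ", "))
  list(values = colMeans(m[used, , drop = FALSE]),
       markers_used = used, missing_markers = missing)
}

#' Phenotype consistency of a gene
#'
#' Pearson correlation between a gene's expression series and the phenotype
#' index, with the exact two-sided t-test p-value
#' (\eqn{t = r\sqrt{(n-2)/(1-r^2)}}, \eqn{df = n-2}).
#'
#' @param gene numeric expression series.
#' @param index numeric phenotype series of equal length (\eqn{n \ge 4}).
#' @return list with \code{r} and \code{p}.
#' @export
phenotypeCorrelation <- function(gene, index) {
  n <- length(gene)
  if (length(index) != n) stop("series lengths differ")
  if (n < 4) stop("need at least 4 samples")
  if (stats::sd(gene) == 0 || stats::sd(index) == 0)
    stop("constant input series")
  r <- .pcor(gene, index)
  list(r = r, p = .corPvalue(r, n))
}
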