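#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#' @importFrom IRanges IRanges
NULL

#' Expression container for modulation analysis
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a genes x
#' samples expression matrix (assay \code{"exprs"}) together with the sample
#' metadata the method needs: dataset of origin, ordinal timepoint and
#' replicate index.  A logical flag in \code{metadata()} records whether every
#' gene row has been standardized to mean 0 and (population) variance 1, the
#' scale on which all downstream statistics operate.
#'
#' @slot standardized scalar logical; \code{TRUE} once every row has mean
#'   0 (+- 1e-9) and population variance 1 (+- 1e-6).
#'
#' @seealso [CRExperiment()] for the constructor, [standardizeExpression()].
#' @export
setClass("CRExperiment",
  contains = "SummarizedExperiment",
  representation(standardized = "logical"),
  prototype(standardized = FALSE)
)

setValidity("CRExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  need <- c("dataset", "timepoint", "replicate")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (length(msg) == 0 && anyNA(assay(object, "exprs")))
    msg <- c(msg, "expression values must not contain NA")
  if (length(msg) == 0 && isTRUE(object@standardized)) {
    x <- assay(object, "exprs")
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    if (any(abs(mu) > 1e-9) || any(abs(v - 1) > 1e-6))
      msg <- c(msg, "standardized flag set but rows are not mean 0 / variance 1")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CRExperiment
#'
#' @param exprs numeric matrix, genes x samples, with unique rownames (gene
#'   ids) and colnames (sample ids).
#' @param sampleMeta data.frame with one row per sample and columns
#'   \code{dataset}, \code{timepoint} (ordinal) and \code{replicate}
#'   (integer).  Row order (or rownames) must match \code{colnames(exprs)}.
#' @param standardized logical; set only if rows are already standardized.
#'
#' @return A [CRExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(dataset = "D1", timepoint = rep(1:2, each = 2),
#'                    replicate = rep(1:2, 2))
#' ce <- CRExperiment(m, meta)
#' @export
CRExperiment <- function(exprs, sampleMeta, standardized = FALSE) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  sampleMeta <- as.data.frame(sampleMeta)
  if (!is.null(rownames(sampleMeta)) &&
      !all(rownames(sampleMeta) == as.character(seq_len(nrow(sampleMeta))))) {
    if (!setequal(rownames(sampleMeta), colnames(exprs)))
      stop("sample ids in metadata do not match expression columns: ",
           paste(union(setdiff(rownames(sampleMeta), colnames(exprs)),
                       setdiff(colnames(exprs), rownames(sampleMeta))),
                 collapse = ", "))
    sampleMeta <- sampleMeta[colnames(exprs), , drop = FALSE]
  } else if (nrow(sampleMeta) != ncol(exprs)) {
    stop("sampleMeta must have one row per sample")
  }
  se <- SummarizedExperiment(assays = list(exprs = exprs),
                             colData = DataFrame(sampleMeta,
                                                 row.names = colnames(exprs)))
  new("CRExperiment", se, standardized = standardized)
}

#' @describeIn CRExperiment Is the expression row-standardized?
#' @param x a \code{CRExperiment}
#' @export
isStandardized <- function(x) {
  stopifnot(is(x, "CRExperiment"))
  isTRUE(x@standardized)
}

setMethod("show", "CRExperiment", function(object) {
  callNextMethod()
  cat("standardized:", isTRUE(object@standardized), "\n")
})

#' Gene role assignments
#'
#' Records which genes act as transcription factors (TFs), which as chromatin
#' regulators (CRs) -- with their category (\code{Epi} epigenetic factor,
#' \code{CME} chromatin-modifying enzyme, \code{CRP} chromatin-remodeling
#' protein) and family -- and the ordered pluripotency marker list used for
#' the phenotype index.  A gene may be both TF and CR.
#'
#' @slot tfs character vector of TF gene ids.
#' @slot crs \code{DataFrame} with columns \code{gene}, \code{category},
#'   \code{family}.
#' @slot markers ordered character vector of phenotype marker gene ids.
#' @export
setClass("GeneRoles",
  representation(tfs = "character", crs = "DataFrame", markers = "character"))

setValidity("GeneRoles", function(object) {
  msg <- character()
  if (anyDuplicated(object@tfs)) msg <- c(msg, "duplicate TF ids")
  need <- c("gene", "category", "family")
  if (!all(need %in% colnames(object@crs)))
    msg <- c(msg, "crs must have columns gene, category, family")
  else {
    if (anyDuplicated(object@crs$gene)) msg <- c(msg, "duplicate CR ids")
    bad <- setdiff(unique(object@crs$category), c("Epi", "CME", "CRP"))
    if (length(bad))
      msg <- c(msg, paste0("unknown CR category: ", paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneRoles object
#'
#' @param tfs character vector of TF gene ids.
#' @param crs data.frame with columns \code{gene}, \code{category}
#'   (one of \code{"Epi"}, \code{"CME"}, \code{"CRP"}) and \code{family}.
#' @param markers character vector of phenotype marker genes; defaults to the
#'   16 core pluripotency genes (see [pluripotencyMarkers()]).
#' @return A [GeneRoles-class] object.
#' @export
GeneRoles <- function(tfs, crs, markers = pluripotencyMarkers()) {
  crs <- DataFrame(as.data.frame(crs))
  new("GeneRoles", tfs = as.character(tfs), crs = crs,
      markers = as.character(markers))
}

#' @describeIn GeneRoles TF gene ids
#' @param x a \code{GeneRoles}
#' @export
tfGenes <- function(x) { stopifnot(is(x, "GeneRoles")); x@tfs }

#' @describeIn GeneRoles CR gene ids
#' @export
crGenes <- function(x) { stopifnot(is(x, "GeneRoles")); as.character(x@crs$gene) }

#' @describeIn GeneRoles named vector gene -> category
#' @export
crCategories <- function(x) {
  stopifnot(is(x, "GeneRoles"))
  stats::setNames(as.character(x@crs$category), as.character(x@crs$gene))
}

#' @describeIn GeneRoles named vector gene -> family
#' @export
crFamilies <- function(x) {
  stopifnot(is(x, "GeneRoles"))
  stats::setNames(as.character(x@crs$family), as.character(x@crs$gene))
}

#' @describeIn GeneRoles phenotype marker gene ids
#' @export
markerGenes <- function(x) { stopifnot(is(x, "GeneRoles")); x@markers }

setMethod("show", "GeneRoles", function(object) {
  cat("GeneRoles:", length(object@tfs), "TFs,", nrow(object@crs), "CRs (",
      paste(names(table(object@crs$category)), table(object@crs$category),
            collapse = ", "), "),",
      length(object@markers), "phenotype markers\n")
})

#' Fitted region model with latent chromatin activity
#'
#' One genomic region whose member target genes (TGs) are modeled as linear
#' Gaussian in a shared latent chromatin activity (CA) series and their TF
#' parents, while CA itself is linear Gaussian in the region's CR parents.
#' Fitted by hard-assignment EM; CA is standardized post hoc and its sign
#' fixed so the largest-magnitude CR coefficient is positive.
#'
#' @slot region \code{GRanges} of length 1.
#' @slot tgs character, member target genes.
#' @slot tfParents named list: per-TG character vector of TF parents.
#' @slot crParents character, CR parents of the region.
#' @slot alpha named list per TG: \code{intercept}, \code{ca} (CA
#'   coefficient), \code{tf} (named TF coefficients).
#' @slot beta named numeric CR coefficients; attribute-free, see
#'   \code{betaIntercept}.
#' @slot betaIntercept scalar intercept of the CA regression.
#' @slot sigmaTG named numeric per-TG residual SD.
#' @slot sigmaCA scalar residual SD of CA.
#' @slot activity numeric latent CA series (one value per sample).
#' @slot loglikPath numeric per-iteration objective (complete-data
#'   log-likelihood after each M-step).
#' @slot converged logical.
#' @export
setClass("RegionModel",
  representation(region = "GRanges", tgs = "character", tfParents = "list",
                 crParents = "character", alpha = "list", beta = "numeric",
                 betaIntercept = "numeric", sigmaTG = "numeric",
                 sigmaCA = "numeric", activity = "numeric",
                 loglikPath = "numeric", converged = "logical"))

setValidity("RegionModel", function(object) {
  msg <- character()
  if (length(object@region) != 1) msg <- c(msg, "region must be a single range")
  if (length(object@activity)) {
    mu <- mean(object@activity)
    v <- mean((object@activity - mu)^2)
    if (abs(mu) > 1e-9 || abs(v - 1) > 1e-6)
      msg <- c(msg, "activity series must be standardized")
  }
  if (length(object@beta)) {
    bmax <- object@beta[which.max(abs(object@beta))]
    if (bmax < 0) msg <- c(msg, "sign convention: largest |beta| must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn RegionModel latent chromatin-activity series
#' @param x a \code{RegionModel}
#' @export
regionActivity <- function(x) { stopifnot(is(x, "RegionModel")); x@activity }

#' @describeIn RegionModel named CR coefficients of the CA regression
#' @export
regionBeta <- function(x) { stopifnot(is(x, "RegionModel")); x@beta }

#' @describeIn RegionModel member target genes
#' @export
regionTGs <- function(x) { stopifnot(is(x, "RegionModel")); x@tgs }

setMethod("show", "RegionModel", function(object) {
  cat(sprintf("RegionModel %s:%d-%d | %d TGs, %d CR parents | %s (%d iter)\n",
              as.character(seqnames(object@region)), start(object@region),
              end(object@region), length(object@tgs), length(object@crParents),
              if (object@converged) "converged" else "NOT converged",
              length(object@loglikPath)))
})

#' CR-CR combinational-modulation network
#'
#' Undirected simple graph over chromatin regulators; an edge joins two CRs
#' whose sets of modulated genomic regions overlap more than expected by the
#' one-sided Fisher exact test at the build threshold.  Holds the module
#' partition and, when computed, the CR-class proximity table.
#'
#' @slot graph the underlying \code{igraph} object.
#' @slot edges data.frame: \code{crA}, \code{crB}, \code{shared},
#'   \code{fisher_p}.
#' @slot alpha build significance threshold.
#' @slot modules named integer module membership (empty until
#'   [detectModules()] is run).
#' @slot proximity data.frame of class-pair mean shortest paths and
#'   permutation p-values (empty until [classProximity()] is run).
#' @export
setClass("CRNetwork",
  representation(graph = "ANY", edges = "data.frame", alpha = "numeric",
                 modules = "integer", proximity = "data.frame"))

setValidity("CRNetwork", function(object) {
  msg <- character()
  g <- object@graph
  if (!igraph::is_igraph(g)) msg <- c(msg, "graph must be an igraph object")
  else {
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops not allowed")
  }
  if (nrow(object@edges) && any(object@edges$fisher_p >= object@alpha))
    msg <- c(msg, "every edge must have fisher_p < alpha")
  if (length(msg)) msg else TRUE
})

#' @describeIn CRNetwork the underlying igraph object
#' @param x a \code{CRNetwork}
#' @export
crGraph <- function(x) { stopifnot(is(x, "CRNetwork")); x@graph }

#' @describeIn CRNetwork edge table with shared-region counts and p-values
#' @export
crEdges <- function(x) { stopifnot(is(x, "CRNetwork")); x@edges }

#' @describeIn CRNetwork module membership (named integer)
#' @export
crModules <- function(x) { stopifnot(is(x, "CRNetwork")); x@modules }

setMethod("show", "CRNetwork", function(object) {
  cat(sprintf("CRNetwork: %d CRs, %d edges (Fisher p < %g)%s\n",
              igraph::vcount(object@graph), nrow(object@edges), object@alpha,
              if (length(object@modules))
                sprintf(", %d modules", length(unique(object@modules))) else ""))
})
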