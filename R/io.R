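#' Read an expression matrix with sample metadata
#'
#' Reads a tab-separated genes x samples matrix (header row of sample ids,
#' first column gene ids) plus a metadata TSV mapping each sample id to its
#' dataset, timepoint and replicate.  Gene rows containing any missing value
#' are dropped with a warning; duplicate gene ids are collapsed to their
#' elementwise mean; constant-valued genes are flagged in
#' \code{metadata()$constant_genes} since they cannot be standardized.
#'
#' @param path path to the expression TSV.
#' @param metaPath path to the sample metadata TSV with columns
#'   \code{sample_id}, \code{dataset}, \code{timepoint}, \code{replicate}.
#' @return A [CRExperiment-class] with assay \code{"exprs"} (not yet
#'   standardized).
#' @seealso [standardizeExpression()]
#' @export
readExpression <- function(path, metaPath) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])[1]
    stop("ragged expression file: line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes

  drop <- apply(m, 1, anyNA)
  if (any(drop)) {
    warning(sum(drop), " gene row(s) with missing values dropped: ",
            paste(utils::head(genes[drop], 5), collapse = ", "))
    m <- m[!drop, , drop = FALSE]
    genes <- genes[!drop]
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    message(length(dups), " duplicate gene id(s) collapsed by mean: ",
            paste(utils::head(dups, 5), collapse = ", "))
    m <- rowsum(m, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- rownames(m)
  }

  meta <- utils::read.delim(metaPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "dataset", "timepoint", "replicate")
  miss <- setdiff(need, colnames(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  offenders <- union(setdiff(meta$sample_id, colnames(m)),
                     setdiff(colnames(m), meta$sample_id))
  if (length(offenders))
    stop("sample ids disagree between matrix and metadata: ",
         paste(offenders, collapse = ", "))
  rownames(meta) <- meta$sample_id
  meta <- meta[colnames(m), c("dataset", "timepoint", "replicate")]

  ce <- CRExperiment(m, meta)
  constant <- apply(m, 1, function(r) max(r) == min(r))
  metadata(ce)$constant_genes <- rownames(m)[constant]
  if (any(constant))
    message(sum(constant), " constant gene row(s) flagged (cannot be standardized)")
  ce
}

#' Standardize every gene row to mean 0 and variance 1
#'
#' Uses the population variance (divisor \eqn{n}); the standardization the
#' modulation statistics assume.  Idempotent, and invariant to per-row affine
#' rescaling up to the sign of the scale factor.
#'
#' @param x a [CRExperiment-class].
#' @return The same object with standardized rows and the
#'   \code{standardized} flag set.
#' @examples
#' m <- matrix(c(1, 2, 3, 5, 1, 0), 2, 3, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
#' meta <- data.frame(dataset = "D1", timepoint = 1:3, replicate = 1L)
#' st <- standardizeExpression(CRExperiment(m, meta))
#' rowMeans(assay(st))   # ~0
#' @export
standardizeExpression <- function(x) {
  stopifnot(is(x, "CRExperiment"))
  m <- assay(x, "exprs")
  mu <- rowMeans(m)
  v <- rowMeans((m - mu)^2)
  if (any(v == 0))
    stop("constant gene row(s) cannot be standardized: ",
         paste(utils::head(rownames(m)[v == 0], 5), collapse = ", "),
         " (drop them first)")
  m <- (m - mu) / sqrt(v)
  SummarizedExperiment::assay(x, "exprs") <- m
  x@standardized <- TRUE
  validObject(x)
  x
}

#' Read gene loci from a BED file
#'
#' Parses a BED4+ file (chrom, start, end, name) into a \code{GRanges} named
#' by gene id.  BED's 0-based half-open coordinates are converted to the
#' 1-based inclusive convention of \code{GenomicRanges}.  Duplicate gene ids
#' are resolved to the longest span, with a message.
#'
#' @param path path to the BED file.
#' @return A named \code{GRanges}, one range per gene.
#' @export
readGeneBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 4)) stop("BED file needs >= 4 columns (line ",
                           which(ncols < 4)[1], ")")
  chrom <- vapply(parts, `[`, "", 1L)
  s <- vapply(parts, `[`, "", 2L)
  e <- vapply(parts, `[`, "", 3L)
  name <- vapply(parts, `[`, "", 4L)
  strand <- if (all(ncols >= 6)) vapply(parts, `[`, "", 6L) else rep("*", length(parts))
  strand[!strand %in% c("+", "-", "*")] <- "*"
  if (any(grepl("[^0-9]", s)) || any(grepl("[^0-9]", e)))
    stop("non-integer coordinates in BED file")
  s <- as.numeric(s); e <- as.numeric(e)
  if (any(s >= e)) stop("BED intervals must satisfy start < end")
  gr <- GRanges(chrom, IRanges(s + 1, e), strand = strand)
  names(gr) <- name
  if (anyDuplicated(name)) {
    dups <- unique(name[duplicated(name)])
    message(length(dups), " duplicate gene id(s) resolved to longest span: ",
            paste(utils::head(dups, 5), collapse = ", "))
    keep <- unlist(lapply(split(seq_along(gr), name), function(i)
      i[which.max(width(gr)[i])]), use.names = FALSE)
    gr <- gr[sort(keep)]
  }
  gr
}

#' Write / read a TF-to-target edge table
#'
#' Plain TSV with header \code{tf, tg, mi, p}; round-trips exactly (values
#' written at full precision).
#'
#' @param path file path.
#' @param edges data.frame with columns \code{tf}, \code{tg}, \code{mi},
#'   \code{p}.
#' @return \code{readEdges} returns the edge data.frame.
#' @export
writeEdges <- function(path, edges) {
  stopifnot(all(c("tf", "tg", "mi", "p") %in% colnames(edges)))
  utils::write.table(format(edges, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEdges
#' @export
readEdges <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  e$mi <- as.numeric(e$mi); e$p <- as.numeric(e$p)
  e
}

#' Write / read a scored triplet table
#'
#' One row per CR-TF-TG triplet carrying the four component p-values, the
#' chi-square modulation score, the combined p and the adjusted q-value.
#'
#' @param path file path.
#' @param triplets data.frame as returned by [scoreTriplets()].
#' @return \code{readTriplets} returns the triplet data.frame.
#' @export
writeTriplets <- function(path, triplets) {
  need <- c("cr", "tf", "tg", "p_mi", "p_la", "p_cr_pheno", "p_tf_pheno",
            "chi2", "p_combined", "q")
  stopifnot(all(need %in% colnames(triplets)))
  utils::write.table(format(triplets, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTriplets
#' @export
readTriplets <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cl in setdiff(colnames(tr), c("cr", "tf", "tg")))
    tr[[cl]] <- as.numeric(tr[[cl]])
  tr
}

#' Read gene roles from a TSV
#'
#' Expects columns \code{gene}, \code{role} (\code{TF} or \code{CR}) and, for
#' CRs, \code{category} (\code{Epi}/\code{CME}/\code{CRP}) and \code{family}.
#' A gene may appear once as TF and once as CR.
#'
#' @param path path to the roles TSV.
#' @param markers marker gene ids (default: the 16 core pluripotency genes).
#' @return A [GeneRoles-class] object.
#' @export
readGeneRoles <- function(path, markers = pluripotencyMarkers()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "role") %in% colnames(tab)))
  tfs <- tab$gene[tab$role == "TF"]
  crtab <- tab[tab$role == "CR", , drop = FALSE]
  if (nrow(crtab) && !all(c("category", "family") %in% colnames(tab)))
    stop("CR rows need category and family columns")
  GeneRoles(tfs = tfs,
            crs = data.frame(gene = crtab$gene, category = crtab$category,
                             family = crtab$family),
            markers = markers)
}

#' Write gene roles to a TSV (inverse of [readGeneRoles()])
#' @param path file path.
#' @param roles a [GeneRoles-class] object.
#' @export
writeGeneRoles <- function(path, roles) {
  stopifnot(is(roles, "GeneRoles"))
  tf <- data.frame(gene = tfGenes(roles), role = "TF",
                   category = "", family = "")
  cr <- data.frame(gene = crGenes(roles), role = "CR",
                   category = unname(crCategories(roles)),
                   family = unname(crFamilies(roles)))
  utils::write.table(rbind(tf, cr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a named GRanges as BED4
#' @param path file path.
#' @param gr named \code{GRanges}.
#' @export
writeGeneBed <- function(path, gr) {
  stopifnot(is(gr, "GRanges"), !is.null(names(gr)))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = format(start(gr) - 1, scientific = FALSE, trim = TRUE),
                   end = format(end(gr), scientific = FALSE, trim = TRUE),
                   name = names(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an expression matrix + metadata as TSV (inverse of
#' [readExpression()])
#' @param path expression TSV path.
#' @param metaPath metadata TSV path.
#' @param x a [CRExperiment-class].
#' @export
writeExpression <- function(path, metaPath, x) {
  stopifnot(is(x, "CRExperiment"))
  m <- assay(x, "exprs")
  tab <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(format(tab, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(colData(x))
  meta <- data.frame(sample_id = rownames(cd), cd)
  utils::write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
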