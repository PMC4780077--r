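#' Pipeline configuration
#'
#' Collects all thresholds, flags and the master seed of an end-to-end run.
#' The master seed is expanded into per-stage seeds by a fixed derivation
#' (\code{seed * 100 + stage index}, modulo 2^31), so stages are individually
#' reproducible.
#'
#' @param miAlpha TRN edge significance cutoff.
#' @param qMax triplet screen adjusted-p cutoff.
#' @param minCRDegree triplet screen degree cutoff (distinct TFs).
#' @param laFraction stratum fraction of the liquid-association split.
#' @param crnetAlpha CR-CR network edge cutoff.
#' @param window region single-linkage gap in bp.
#' @param seed master seed.
#' @param bhInsteadOfBonferroni use Benjamini-Hochberg in the screen.
#' @param allGenesAsModulators score every gene as candidate modulator.
#' @param crnetPerms permutations for the class-proximity null.
#' @return named list of class \code{mochaConfig}.
#' @export
mochaConfig <- function(miAlpha = 0.005, qMax = 0.001, minCRDegree = 50,
                        laFraction = 0.5, crnetAlpha = 0.005, window = 1e6,
                        seed = 1, bhInsteadOfBonferroni = FALSE,
                        allGenesAsModulators = FALSE, crnetPerms = 1000) {
  stopifnot(miAlpha >= 0, miAlpha <= 1, qMax >= 0, qMax <= 1,
            minCRDegree >= 0, laFraction > 0, laFraction <= 0.5,
            crnetAlpha >= 0, crnetAlpha <= 1, window > 0, crnetPerms >= 1)
  structure(list(miAlpha = miAlpha, qMax = qMax, minCRDegree = minCRDegree,
                 laFraction = laFraction, crnetAlpha = crnetAlpha,
                 window = window, seed = as.integer(seed),
                 bhInsteadOfBonferroni = isTRUE(bhInsteadOfBonferroni),
                 allGenesAsModulators = isTRUE(allGenesAsModulators),
                 crnetPerms = crnetPerms),
            class = "mochaConfig")
}

#' Write / read a pipeline configuration as flat key=value text
#' @param config a [mochaConfig()] list.
#' @param path file path.
#' @return \code{readConfig} returns the \code{mochaConfig}; round-trips
#'   unchanged.
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "mochaConfig"))
  lines <- vapply(names(config), function(k)
    paste0(k, "=", format(config[[k]], digits = 17, scientific = FALSE)), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    if (v %in% c("TRUE", "FALSE")) as.logical(v) else as.numeric(v)
  })
  names(vals) <- vapply(kv, `[`, "", 1L)
  do.call(mochaConfig, vals)
}

.provenance <- function(config) {
  sprintf("# mocha %s | config %s | seed %d",
          as.character(utils::packageVersion("mocha")),
          substr(tools::md5sum(tempConfig <- {
            f <- tempfile(); writeConfig(config, f); f
          })[[1]], 1, 8),
          config$seed)
}

.writeStage <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Run the full modulation pipeline
#'
#' Executes the stages in order -- TRN inference, phenotype index, triplet
#' scoring, false-positive screen, region assignment + chromatin-activity
#' fitting, CR-CR network, topology statistics -- writing each stage's
#' output into \code{outDir} with a provenance header (package version,
#' config hash, seed).  Rerunning with the same config and inputs is
#' bit-identical for the deterministic stages and seed-identical for the
#' stochastic ones.  A stage failure aborts with the stage name; outputs of
#' completed stages are preserved.
#'
#' @param x a (raw or standardized) [CRExperiment-class]; standardized
#'   internally if needed.
#' @param roles a [GeneRoles-class].
#' @param annotation named \code{GRanges} of gene loci.
#' @param config a [mochaConfig()].
#' @param outDir run directory (created; existing stage outputs are not
#'   overwritten by later stages -- the directory is append-only).
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
runMocha <- function(x, roles, annotation, config = mochaConfig(),
                     outDir = tempfile("mocha_run_")) {
  stopifnot(is(x, "CRExperiment"), is(roles, "GeneRoles"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance(config)
  res <- list(config = config)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!isStandardized(x)) {
    const <- apply(assay(x, "exprs"), 1, function(r) max(r) == min(r))
    if (any(const)) x <- x[!const, ]
    x <- standardizeExpression(x)
  }

  res$edges <- stage("trn", function()
    inferTRN(x, roles, alpha = config$miAlpha))
  .writeStage(res$edges, file.path(outDir, "edges.tsv"), hdr)

  res$phenotype <- stage("phenotype", function() pluripotencyIndex(x))
  .writeStage(data.frame(sample_id = colnames(x),
                         index = res$phenotype$values),
              file.path(outDir, "phenotype.tsv"), hdr)

  res$triplets <- stage("triplets", function()
    scoreTriplets(x, roles, res$edges, fraction = config$laFraction,
                  modulators = if (config$allGenesAsModulators) "all" else NULL,
                  index = res$phenotype$values))
  .writeStage(res$triplets, file.path(outDir, "triplets.tsv"), hdr)

  res$screened <- stage("screen", function()
    screenTriplets(res$triplets, qMax = config$qMax,
                   minCRDegree = config$minCRDegree,
                   method = if (config$bhInsteadOfBonferroni) "BH" else "bonferroni"))
  .writeStage(res$screened, file.path(outDir, "triplets_screened.tsv"), hdr)

  res$regions <- stage("regions", function() {
    if (!nrow(res$screened)) return(list())
    specs <- tryCatch(
      assignRegions(annotation, res$screened, window = config$window),
      error = function(e) {
        message("regions: ", conditionMessage(e), " (continuing without)")
        list()
      })
    lapply(specs, function(sp)
      fitRegion(x, sp, seed = .stageSeed(config$seed, "regions")))
  })
  if (length(res$regions)) {
    ca <- do.call(rbind, lapply(names(res$regions), function(nm)
      data.frame(region = nm, sample_id = colnames(x),
                 activity = regionActivity(res$regions[[nm]]))))
    .writeStage(ca, file.path(outDir, "chromatin_activity.tsv"), hdr)
    pars <- lapply(res$regions, function(mdl) list(
      tgs = regionTGs(mdl), beta = as.list(regionBeta(mdl)),
      sigma_ca = mdl@sigmaCA, converged = mdl@converged))
    jsonlite::write_json(pars, file.path(outDir, "region_models.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  res$crnet <- stage("crnet", function() {
    if (length(res$regions) < 1) return(NULL)
    regionCRMap <- lapply(res$regions, function(mdl) mdl@crParents)
    if (length(unique(unlist(regionCRMap))) < 2) return(NULL)
    net <- buildCRNetwork(regionCRMap, alpha = config$crnetAlpha)
    net <- detectModules(net, seed = .stageSeed(config$seed, "crnet"))
    cats <- crCategories(roles)
    have <- intersect(igraph::V(net@graph)$name, names(cats))
    if (length(unique(cats[have])) >= 2 && igraph::ecount(net@graph) > 0)
      net <- classProximity(net, cats[have], nPerm = config$crnetPerms,
                            seed = .stageSeed(config$seed, "crnet"))
    net
  })
  if (!is.null(res$crnet))
    .writeStage(crEdges(res$crnet), file.path(outDir, "crnet_edges.tsv"), hdr)

  res$stats <- stage("stats", function() {
    if (!nrow(res$screened)) return(NULL)
    hubTables(res$screened, k = 20)
  })
  if (!is.null(res$stats))
    .writeStage(res$stats$crs, file.path(outDir, "cr_scores.tsv"), hdr)

  writeConfig(config, file.path(outDir, "config.txt"))
  invisible(res)
}
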