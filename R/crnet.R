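#' @importFrom igraph graph_from_data_frame vcount ecount V E degree
#'   cluster_fast_greedy membership distances rewire keeping_degseq
#'   make_empty_graph add_vertices is_igraph is_directed which_loop
NULL

#' Shared-region enrichment between two chromatin regulators
#'
#' One-sided (enrichment) Fisher exact test on the 2x2 table (shared,
#' A-only, B-only, neither) of two CRs' modulated-region sets within the
#' region universe.
#'
#' @param regionsA,regionsB character vectors (or any vectors) of region
#'   identifiers; both must lie inside the universe.
#' @param universeSize total number of regions in the universe.
#' @return list with \code{overlap} and one-sided \code{p}.
#' @export
sharedRegionTest <- function(regionsA, regionsB, universeSize) {
  regionsA <- unique(regionsA); regionsB <- unique(regionsB)
  if (universeSize < 1) stop("empty region universe")
  nu <- length(union(regionsA, regionsB))
  if (universeSize < nu)
    stop("universe smaller than |A union B| (", nu, ")")
  k <- length(intersect(regionsA, regionsB))
  a <- length(regionsA); b <- length(regionsB)
  # one-sided enrichment p = P(X >= k), X hypergeometric
  p <- stats::phyper(k - 1, a, universeSize - a, b, lower.tail = FALSE)
  list(overlap = k, p = min(p, 1))
}

#' Build the CR-CR combinational-modulation network
#'
#' Nodes are all CRs modulating at least one region; an edge joins two CRs
#' whose shared-region count is significant by [sharedRegionTest()] at
#' \code{alpha}.  Isolated CRs are retained as nodes.  Node and edge order
#' are deterministic (lexicographic), so the build is invariant to the input
#' order of the map.
#'
#' @param regionCRMap named list: region id -> character vector of CR ids
#'   modulating that region (the universe is its length).
#' @param alpha edge significance threshold (default 0.005).
#' @return A [CRNetwork-class].
#' @export
buildCRNetwork <- function(regionCRMap, alpha = 0.005) {
  if (length(regionCRMap) < 1) stop("empty region map")
  crSets <- list()
  for (rg in names(regionCRMap))
    for (cr in regionCRMap[[rg]])
      crSets[[cr]] <- c(crSets[[cr]], rg)
  crs <- sort(names(crSets))
  if (length(crs) < 2) stop("need at least 2 CRs with >= 1 region")
  U <- length(regionCRMap)
  rows <- list()
  for (i in seq_along(crs)[-length(crs)]) {
    for (j in (i + 1):length(crs)) {
      ft <- sharedRegionTest(crSets[[crs[i]]], crSets[[crs[j]]], U)
      if (ft$p < alpha)
        rows[[length(rows) + 1]] <- data.frame(
          crA = crs[i], crB = crs[j], shared = ft$overlap, fisher_p = ft$p,
          stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(crA = character(), crB = character(), shared = integer(),
               fisher_p = numeric())
  g <- make_empty_graph(0, directed = FALSE)
  g <- add_vertices(g, length(crs), name = crs)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$crA, edges$crB))
  new("CRNetwork", graph = g, edges = edges, alpha = alpha,
      modules = integer(0), proximity = data.frame())
}

#' Partition the CR network into densely connected modules
#'
#' Greedy modularity maximization (Newman's fast algorithm).  An edgeless
#' network yields one singleton module per node, with a warning.
#'
#' @param network a [CRNetwork-class].
#' @param seed integer seed (the greedy algorithm is deterministic; the seed
#'   fixes any library-internal tie handling).
#' @return the network with its \code{modules} slot filled (named integer).
#' @export
detectModules <- function(network, seed = 1) {
  stopifnot(is(network, "CRNetwork"))
  g <- network@graph
  if (ecount(g) == 0) {
    warning("edgeless network: every node is its own module")
    mem <- stats::setNames(seq_len(vcount(g)), V(g)$name)
  } else {
    set.seed(as.integer(seed))
    cl <- cluster_fast_greedy(g)
    mem <- stats::setNames(as.integer(membership(cl)), V(g)$name)
    # greedy merging can stop below the trivial partition's modularity on
    # degenerate graphs (e.g. a single clique); never return worse than it
    if (igraph::modularity(g, mem) <
        igraph::modularity(g, rep(1L, vcount(g))))
      mem <- stats::setNames(rep(1L, vcount(g)), V(g)$name)
  }
  network@modules <- mem
  network
}

#' CR-class proximity with a degree-preserving null
#'
#' For every pair of CR classes, the observed mean shortest-path length
#' between members of the two classes (unreachable pairs are excluded and
#' counted), compared against graphs rewired by random double-edge swaps
#' (10 x |E| attempts per permutation) that preserve every node's degree
#' exactly.  \eqn{p = (1 + \#\{mean_{perm} \le mean_{obs}\}) / (n_{perm}+1)}
#' (one-sided: closer than expected).
#'
#' @param network a [CRNetwork-class].
#' @param classMap named character vector: node -> class.
#' @param nPerm number of rewired graphs.
#' @param seed integer seed.
#' @return the network with its \code{proximity} slot filled: columns
#'   \code{classA}, \code{classB}, \code{mean_path}, \code{n_pairs},
#'   \code{n_unreachable}, \code{p}.
#' @export
classProximity <- function(network, classMap, nPerm = 1000, seed = 1) {
  stopifnot(is(network, "CRNetwork"))
  g <- network@graph
  classMap <- classMap[intersect(names(classMap), V(g)$name)]
  classes <- sort(unique(classMap))
  if (length(classes) < 2) stop("need at least 2 CR classes")
  big <- names(which(table(classMap) >= 2))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  pairs <- c(pairs, lapply(classes, function(cc) c(cc, cc)))

  meanPath <- function(gr) {
    D <- distances(gr)
    vapply(pairs, function(pr) {
      a <- names(classMap)[classMap == pr[1]]
      b <- names(classMap)[classMap == pr[2]]
      d <- D[a, b, drop = FALSE]
      if (pr[1] == pr[2]) d <- d[upper.tri(d)]
      d <- d[is.finite(d) & d > 0]
      if (length(d)) mean(d) else NA_real_
    }, 0)
  }
  countPairs <- function() {
    vapply(pairs, function(pr) {
      a <- sum(classMap == pr[1]); b <- sum(classMap == pr[2])
      if (pr[1] == pr[2]) a * (a - 1) / 2 else a * b
    }, 0)
  }

  obs <- meanPath(g)
  set.seed(as.integer(seed))
  hits <- rep(0, length(pairs)); used <- rep(0, length(pairs))
  deg0 <- degree(g)
  for (k in seq_len(nPerm)) {
    gp <- rewire(g, keeping_degseq(niter = 10 * max(ecount(g), 1)))
    if (!identical(degree(gp), deg0))
      stop("internal error: rewiring changed the degree sequence")
    mp <- meanPath(gp)
    ok <- !is.na(mp) & !is.na(obs)
    hits[ok] <- hits[ok] + (mp[ok] <= obs[ok])
    used[ok] <- used[ok] + 1
  }
  D <- distances(g)
  unreach <- vapply(pairs, function(pr) {
    a <- names(classMap)[classMap == pr[1]]
    b <- names(classMap)[classMap == pr[2]]
    d <- D[a, b, drop = FALSE]
    if (pr[1] == pr[2]) d <- d[upper.tri(d)]
    sum(!is.finite(d))
  }, 0)

  tab <- data.frame(
    classA = vapply(pairs, `[`, "", 1L),
    classB = vapply(pairs, `[`, "", 2L),
    mean_path = obs, n_pairs = countPairs(), n_unreachable = unreach,
    p = ifelse(used > 0, (1 + hits) / (used + 1), NA_real_))
  skip <- !(tab$classA %in% big & tab$classB %in% big)
  if (any(skip)) {
    message(sum(skip), " class pair(s) skipped (a class has < 2 members)")
    tab <- tab[!skip, , drop = FALSE]
  }
  rownames(tab) <- NULL
  network@proximity <- tab
  network
}

#' Class-in-module enrichment
#'
#' Hypergeometric enrichment of each CR class in each module against the
#' network's node universe, Benjamini-Hochberg adjusted across the whole
#' table.
#'
#' @param network a [CRNetwork-class] with modules detected.
#' @param classMap named character vector: node -> class.
#' @return data.frame with columns \code{module}, \code{class},
#'   \code{in_module}, \code{module_size}, \code{class_size}, \code{p},
#'   \code{p_adj}.
#' @export
classInModuleEnrichment <- function(network, classMap) {
  stopifnot(is(network, "CRNetwork"))
  if (!length(network@modules)) stop("run detectModules() first")
  mem <- network@modules
  classMap <- classMap[names(mem)]
  N <- length(mem)
  rows <- list()
  for (mod in sort(unique(mem))) {
    inMod <- names(mem)[mem == mod]
    for (cl in sort(unique(classMap))) {
      K <- sum(classMap == cl, na.rm = TRUE)
      k <- sum(classMap[inMod] == cl, na.rm = TRUE)
      p <- stats::phyper(k - 1, K, N - K, length(inMod), lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module = mod, class = cl, in_module = k,
        module_size = length(inMod), class_size = K, p = p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
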