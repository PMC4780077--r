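test_that("shared-region test handles saturated and disjoint sets", {
  u <- paste0("r", 1:20)
  res <- sharedRegionTest(u, u, 20)
  expect_identical(res$overlap, 20L)
  expect_equal(res$p, 1)

  res2 <- sharedRegionTest(paste0("r", 1:5), paste0("q", 1:5), 1000)
  expect_identical(res2$overlap, 0L)
  expect_gte(res2$p, 0.97)   # depletion is not enrichment, one-sided

  expect_error(sharedRegionTest(u, u, 0), "empty")
  expect_error(sharedRegionTest(u, u, 10), "universe smaller")
})

test_that("shared-region test equals combinatorial enumeration on small tables", {
  for (U in c(4, 7, 8)) {
    for (a in 1:U) for (b in 1:U) {
      for (k in max(0, a + b - U):min(a, b)) {
        A <- paste0("r", seq_len(a))
        B <- paste0("r", c(seq_len(k), if (b > k) U - seq_len(b - k) + 1))
        res <- sharedRegionTest(A, B, U)
        expect_identical(res$overlap, as.integer(k))
        expect_equal(res$p, hyperTailOracle(k, a, b, U), tolerance = 1e-10)
      }
    }
  }
})

test_that("shared-region test is symmetric", {
  set.seed(1)
  A <- sample(paste0("r", 1:50), 20)
  B <- sample(paste0("r", 1:50), 15)
  expect_equal(sharedRegionTest(A, B, 50)$p, sharedRegionTest(B, A, 50)$p,
               tolerance = 1e-14)
})

test_that("network build keeps significant pairs and isolated nodes", {
  regions <- paste0("r", 1:1000)
  map <- setNames(vector("list", 1000), regions)
  for (r in regions[1:20]) map[[r]] <- c("crA", "crB")
  map[["r21"]] <- "crC"
  for (r in regions[22:1000]) map[[r]] <- character()
  net <- buildCRNetwork(map, alpha = 0.005)
  expect_identical(nrow(crEdges(net)), 1L)
  expect_setequal(c(crEdges(net)$crA, crEdges(net)$crB), c("crA", "crB"))
  # oracle confirms the edge is far below threshold
  expect_lt(hyperTailOracle(20, 20, 20, 1000), 1e-10)
  # isolated CR retained as a node
  expect_true("crC" %in% igraph::V(crGraph(net))$name)

  net0 <- buildCRNetwork(map, alpha = 0)
  expect_identical(nrow(crEdges(net0)), 0L)
})

test_that("network build is invariant to region-map input order", {
  set.seed(2)
  regions <- paste0("r", 1:80)
  crs <- paste0("CR", 1:6)
  map <- lapply(regions, function(r) sample(crs, rbinom(1, 4, 0.4)))
  names(map) <- regions
  net1 <- buildCRNetwork(map, alpha = 0.05)
  net2 <- buildCRNetwork(map[sample(length(map))], alpha = 0.05)
  expect_identical(crEdges(net1), crEdges(net2))
})

test_that("permuted region labels produce few edges", {
  set.seed(3)
  regions <- paste0("r", 1:200)
  crs <- paste0("CR", 1:8)
  edgeCounts <- replicate(50, {
    map <- lapply(regions, function(r) sample(crs, 3))
    names(map) <- regions
    nrow(crEdges(buildCRNetwork(map, alpha = 0.005)))
  })
  nPairs <- choose(8, 2)
  expect_lte(mean(edgeCounts), 3 * 0.005 * nPairs)
})

test_that("two bridged 6-cliques split into exactly their cliques", {
  g <- igraph::make_full_graph(6) + igraph::make_full_graph(6)
  g <- igraph::add_edges(g, c(1, 7))
  igraph::V(g)$name <- paste0("CR", 1:12)
  net <- new("CRNetwork", graph = g, edges = data.frame(), alpha = 1,
             modules = integer(0), proximity = data.frame())
  net <- detectModules(net, seed = 1)
  mem <- crModules(net)
  expect_identical(length(unique(mem)), 2L)
  expect_identical(length(unique(mem[1:6])), 1L)
  expect_identical(length(unique(mem[7:12])), 1L)

  # exhaustive bipartition oracle: the returned partition attains the
  # maximum hand-computed modularity over all 2-block partitions
  best <- -Inf
  for (code in 0:(2^11 - 1)) {
    part <- c(1L, as.integer(intToBits(code)[1:11]) + 1L)
    best <- max(best, modularityOracle(g, part))
  }
  expect_gte(modularityOracle(g, mem) + 1e-12, best)
  expect_gte(modularityOracle(g, mem),
             modularityOracle(g, rep(1L, 12)))  # beats the trivial partition
})

test_that("a single clique is one module; edgeless graphs warn", {
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("CR", 1:5)
  net <- new("CRNetwork", graph = g, edges = data.frame(), alpha = 1,
             modules = integer(0), proximity = data.frame())
  expect_identical(length(unique(crModules(detectModules(net, 1)))), 1L)

  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g0)$name <- paste0("CR", 1:3)
  net0 <- new("CRNetwork", graph = g0, edges = data.frame(), alpha = 1,
              modules = integer(0), proximity = data.frame())
  expect_warning(net0 <- detectModules(net0, 1), "edgeless")
  expect_identical(length(unique(crModules(net0))), 3L)
})

proximityFixture <- function() {
  # two classes forming one clique, a third attached by a long path
  g <- igraph::make_full_graph(8)
  g <- igraph::add_vertices(g, 4)
  g <- igraph::add_edges(g, c(8, 9, 9, 10, 10, 11, 11, 12))
  igraph::V(g)$name <- paste0("CR", 1:12)
  classMap <- setNames(c(rep("A", 4), rep("B", 4), rep("C", 4)),
                       paste0("CR", 1:12))
  net <- new("CRNetwork", graph = g, edges = data.frame(), alpha = 1,
             modules = integer(0), proximity = data.frame())
  list(net = net, classMap = classMap)
}

test_that("class proximity separates close from distant classes", {
  f <- proximityFixture()
  net <- classProximity(f$net, f$classMap, nPerm = 200, seed = 1)
  tab <- net@proximity
  ab <- tab[tab$classA == "A" & tab$classB == "B", ]
  ac <- tab[tab$classA == "A" & tab$classB == "C", ]
  expect_lt(ab$mean_path, ac$mean_path)
  expect_lt(ab$p, ac$p)
})

test_that("every rewiring preserves the degree sequence", {
  # the implementation asserts degree preservation per permutation and
  # aborts otherwise; a clean run over many permutations is the evidence
  f <- proximityFixture()
  expect_no_error(classProximity(f$net, f$classMap, nPerm = 300, seed = 2))
  # independent spot check of the same null model
  g <- f$net@graph
  d0 <- igraph::degree(g)
  set.seed(3)
  for (i in 1:20) {
    gp <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
    expect_identical(igraph::degree(gp), d0)
  }
})

test_that("small classes are skipped with a note", {
  f <- proximityFixture()
  cm <- f$classMap
  cm["CR12"] <- "D"   # a singleton class
  expect_message(net <- classProximity(f$net, cm, nPerm = 50, seed = 1),
                 "skipped")
  expect_false("D" %in% c(net@proximity$classA, net@proximity$classB))
})

test_that("class-in-module enrichment finds a pure module", {
  set.seed(4)
  nNodes <- 60
  g <- igraph::sample_gnp(nNodes, 0.15)
  igraph::V(g)$name <- paste0("CR", seq_len(nNodes))
  net <- new("CRNetwork", graph = g, edges = data.frame(), alpha = 1,
             modules = integer(0), proximity = data.frame())
  # hand a partition with one pure 10-node module
  mem <- setNames(c(rep(1L, 10), rep(2L, nNodes - 10)), igraph::V(g)$name)
  net@modules <- mem
  classMap <- setNames(c(rep("X", 10), sample(c("Y", "Z"), nNodes - 10,
                                              replace = TRUE)),
                       igraph::V(g)$name)
  tab <- classInModuleEnrichment(net, classMap)
  top <- tab[which.min(tab$p), ]
  expect_identical(top$module, 1L)
  expect_identical(top$class, "X")
  expect_equal(top$p, hyperTailOracle(10, 10, 10, nNodes), tolerance = 1e-10)
  # the partition covers every node
  expect_equal(sum(tab$in_module[tab$module == 1]) +
               sum(tab$in_module[tab$module == 2]), nNodes)
})
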