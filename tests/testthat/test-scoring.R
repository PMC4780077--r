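test_that("Fisher's combination matches hand values and the quadrature oracle", {
  res <- combineFisher(c(1, 1, 1, 1))
  expect_identical(res$chi2, 0)
  expect_equal(res$p_combined, 1)

  res <- combineFisher(rep(0.01, 4))
  expect_equal(res$chi2, -8 * log(0.01), tolerance = 1e-10)
  expect_equal(res$chi2, 36.8414, tolerance = 1e-3)

  # independent oracle: numerical quadrature of the analytic chi-square(8)
  # density x^3 exp(-x/2) / 96
  dens <- function(x) x^3 * exp(-x / 2) / 96
  tail8 <- function(q) integrate(dens, q, Inf, rel.tol = 1e-13)$value
  set.seed(1)
  for (i in 1:25) {
    p <- runif(4, 1e-6, 1)
    res <- combineFisher(p)
    expect_equal(res$p_combined, tail8(res$chi2), tolerance = 1e-10)
  }

  expect_error(combineFisher(c(0.5, 0)), "> 0")
  expect_error(combineFisher(c(0.5, 1.2)), "<= 1")
})

test_that("chi2 strictly increases when any component p decreases", {
  p <- c(0.2, 0.4, 0.6, 0.8)
  base <- combineFisher(p)$chi2
  for (j in 1:4) {
    p2 <- p; p2[j] <- p[j] / 2
    expect_gt(combineFisher(p2)$chi2, base)
  }
})

scoredFixture <- function(seed = 1) {
  sim <- simulateMochaData(nReps = 10, seed = seed)
  x <- standardizeExpression(sim$expr)
  edges <- inferTRN(x, sim$roles)
  list(sim = sim, x = x, edges = edges,
       triplets = scoreTriplets(x, sim$roles, edges))
}

test_that("triplet scoring excludes self-modulators and orders deterministically", {
  f <- scoredFixture()
  expect_false(any(f$triplets$cr == f$triplets$tf |
                   f$triplets$cr == f$triplets$tg))
  expect_true(all(diff(f$triplets$chi2) <= 1e-12))
  # invariant: chi2 reconstructed from the four components
  pm <- pmax(as.matrix(f$triplets[, c("p_mi", "p_la", "p_cr_pheno",
                                      "p_tf_pheno")]), 1e-300)
  expect_equal(f$triplets$chi2, -2 * rowSums(log(pm)), tolerance = 1e-9)
  # p_combined consistent with combineFisher
  i <- 5
  expect_equal(f$triplets$p_combined[i],
               combineFisher(pm[i, ])$p_combined, tolerance = 1e-12)
})

test_that("screening layers behave by contract", {
  f <- scoredFixture()
  tr <- f$triplets

  idf <- screenTriplets(tr, qMax = 1, minCRDegree = 0)
  expect_identical(nrow(idf), nrow(tr))

  sc <- screenTriplets(tr, qMax = 0.001, minCRDegree = 0)
  # brute-force Bonferroni oracle over the full table
  qOracle <- pmin(1, tr$p_combined * nrow(tr))
  expect_setequal(paste(sc$cr, sc$tf, sc$tg),
                  paste(tr$cr, tr$tf, tr$tg)[qOracle <= 0.001])
  expect_equal(sc$q, pmin(1, sc$p_combined * nrow(tr)), tolerance = 1e-12)

  # order independence
  set.seed(2)
  shuf <- tr[sample(nrow(tr)), ]
  sc2 <- screenTriplets(shuf, qMax = 0.001, minCRDegree = 0)
  expect_setequal(paste(sc2$cr, sc2$tf, sc2$tg), paste(sc$cr, sc$tf, sc$tg))

  # BH alternative is at least as permissive as Bonferroni
  bh <- screenTriplets(tr, qMax = 0.001, minCRDegree = 0, method = "BH")
  expect_gte(nrow(bh), nrow(sc))
})

test_that("the degree filter drops low-degree modulators", {
  # CR "big" modulates 51 distinct TFs, CR "small" only 2
  tab <- data.frame(
    cr = c(rep("big", 51), rep("small", 2)),
    tf = c(sprintf("TF%02d", 1:51), "TF01", "TF02"),
    tg = "tg1",
    p_mi = 1e-10, p_la = 1e-10, p_cr_pheno = 1e-10, p_tf_pheno = 1e-10,
    chi2 = 184.2, p_combined = 1e-30, q = 1e-28)
  out <- screenTriplets(tab, qMax = 0.001, minCRDegree = 50)
  expect_setequal(unique(out$cr), "big")
  out0 <- screenTriplets(tab, qMax = 0.001, minCRDegree = 2)
  expect_setequal(unique(out0$cr), "big")  # small has exactly 2, needs > 2
})

test_that("chromatin regulation scores sum the surviving chi2", {
  tab <- data.frame(cr = c("A", "A", "B"), tf = c("t1", "t2", "t1"),
                    tg = c("g1", "g2", "g1"),
                    p_mi = 0.1, p_la = 0.1, p_cr_pheno = 0.1, p_tf_pheno = 0.1,
                    chi2 = c(10, 20, 7), p_combined = 0.5, q = 1)
  cs <- crScores(tab)
  expect_equal(cs$score[cs$cr == "A"], 30)
  expect_equal(cs$n_tfs_modulated[cs$cr == "A"], 2L)
  expect_identical(sum(cs$n_triplets), nrow(tab))
})

test_that("the modulation subnetwork contains only the named CR's edges", {
  tab <- data.frame(cr = c("A", "A", "B"), tf = c("t1", "t2", "t1"),
                    tg = c("g1", "g2", "g1"),
                    p_mi = 0.1, p_la = 0.1, p_cr_pheno = 0.1, p_tf_pheno = 0.1,
                    chi2 = c(10, 20, 7), p_combined = 0.5, q = 1)
  sub <- crSubnetwork(tab, "A")
  expect_setequal(sub$from[sub$type == "modulation"], "A")
  expect_setequal(sub$to[sub$type == "modulation"], c("t1", "t2"))
  expect_setequal(paste(sub$from[sub$type == "regulation"],
                        sub$to[sub$type == "regulation"]),
                  c("t1 g1", "t2 g2"))
  expect_error(crSubnetwork(tab, "nope"), "unknown CR")
})

test_that("planted modulations outrank unplanted triplets", {
  f <- scoredFixture(seed = 3)
  pt <- paste(f$sim$truth$planted_triplets$cr,
              f$sim$truth$planted_triplets$tf,
              f$sim$truth$planted_triplets$tg)
  lab <- paste(f$triplets$cr, f$triplets$tf, f$triplets$tg) %in% pt
  expect_gt(sum(lab), 3)
  rk <- rank(f$triplets$chi2)
  auc <- (mean(rk[lab]) - (sum(lab) + 1) / 2) / sum(!lab)
  expect_gte(auc, 0.8)
})
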