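mkTriplets <- function(counts, prefix = "G") {
  # build a triplet table where gene i modulates counts[i] distinct TFs
  rows <- list()
  for (i in seq_along(counts)) {
    if (counts[i] == 0) next
    rows[[i]] <- data.frame(cr = paste0(prefix, i),
                            tf = sprintf("TF%03d", seq_len(counts[i])),
                            tg = "tg1", p_mi = 0.1, p_la = 0.1,
                            p_cr_pheno = 0.1, p_tf_pheno = 0.1,
                            chi2 = 18.4, p_combined = 0.02, q = 1)
  }
  do.call(rbind, rows)
}

test_that("identical degree profiles give a null comparison", {
  tr <- mkTriplets(c(5, 5, 5, 5))
  res <- modulationDegreeComparison(tr, c("G1", "G2"), c("G3", "G4"))
  expect_equal(res$t_stat, 0)
  expect_equal(res$p, 1)
})

test_that("a planted degree excess is detected with the right direction", {
  set.seed(1)
  hits <- 0
  for (s in 1:10) {
    counts <- c(rpois(10, 20), rpois(30, 2))
    tr <- mkTriplets(counts)
    crGroup <- paste0("G", 1:10)
    nonCR <- paste0("G", 11:40)
    res <- modulationDegreeComparison(tr, crGroup, nonCR)
    hits <- hits + (res$p < 0.01 && res$mean_a > res$mean_b)
  }
  expect_gte(hits, 9)
})

test_that("the modulator-fraction chi-square matches the hand formula", {
  # 30/100 vs 5/100 genes above threshold
  counts <- c(rep(60, 30), rep(1, 70), rep(60, 5), rep(1, 95))
  tr <- mkTriplets(counts)
  res <- modulationDegreeComparison(tr, paste0("G", 1:100),
                                    paste0("G", 101:200), threshold = 50)
  expect_identical(unname(res$modulator_fraction$counts[1, ]), c(30L, 5L))
  # independent oracle: Pearson chi-square statistic by hand, df = 1
  O <- matrix(c(30, 70, 5, 95), 2, 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  pOracle <- pchisq(sum((O - E)^2 / E), df = 1, lower.tail = FALSE)
  expect_equal(res$modulator_fraction$chisq_p, pOracle, tolerance = 1e-10)
})

test_that("group contracts are enforced", {
  tr <- mkTriplets(c(3, 3))
  expect_error(modulationDegreeComparison(tr, character(), "G2"), "empty")
  expect_error(modulationDegreeComparison(tr, "G1", "G1"), "disjoint")
  expect_error(indegreeComparison(tr, character(), "TF001"), "empty")
})

test_that("modulation in-degree equals the distinct-CR count by brute force", {
  set.seed(2)
  tr <- data.frame(cr = sample(paste0("CR", 1:6), 60, TRUE),
                   tf = sample(paste0("TF", 1:8), 60, TRUE),
                   tg = sample(paste0("TG", 1:10), 60, TRUE),
                   p_mi = 0.1, p_la = 0.1, p_cr_pheno = 0.1, p_tf_pheno = 0.1,
                   chi2 = 18.4, p_combined = 0.02, q = 1)
  res <- indegreeComparison(tr, paste0("TF", 1:4), paste0("TF", 5:8))
  for (tf in paste0("TF", 1:4)) {
    brute <- length(unique(tr$cr[tr$tf == tf]))
    expect_identical(unname(res$degrees_a[tf]), brute)
  }
  # identical groups compare as null
  same <- indegreeComparison(tr, paste0("TF", 1:4), paste0("TF", 1:4))
  expect_equal(same$p, 1)
})

test_that("a heavily modulated TF group is detected", {
  set.seed(3)
  rows <- list()
  for (tf in paste0("A", 1:6))
    rows[[tf]] <- data.frame(cr = paste0("CR", 1:12), tf = tf, tg = "t")
  for (tf in paste0("B", 1:6))
    rows[[tf]] <- data.frame(cr = paste0("CR", 1:2), tf = tf, tg = "t")
  tr <- do.call(rbind, rows)
  tr[c("p_mi", "p_la", "p_cr_pheno", "p_tf_pheno")] <- 0.1
  tr$chi2 <- 18.4; tr$p_combined <- 0.02; tr$q <- 1
  res <- indegreeComparison(tr, paste0("A", 1:6), paste0("B", 1:6))
  expect_gt(res$mean_a, res$mean_b)
  expect_lt(res$p, 0.05)
})

test_that("the piled modulation network counts multiplicities correctly", {
  tr <- data.frame(cr = c("C1", "C1", "C2"), tf = c("T1", "T1", "T1"),
                   tg = c("g1", "g2", "g1"))
  net <- modulationNetwork(tr)
  expect_identical(net$modulation$count[net$modulation$cr == "C1"], 2L)
  # invariant: sum of TF in-degrees equals distinct (CR, TF) pairs
  inDeg <- vapply(split(net$modulation$cr, net$modulation$tf),
                  function(v) length(unique(v)), 0L)
  expect_identical(sum(inDeg), length(unique(paste(tr$cr, tr$tf))))
})

test_that("hub tables are deterministic, complete and brute-force consistent", {
  set.seed(4)
  tr <- data.frame(cr = sample(paste0("CR", 1:5), 50, TRUE),
                   tf = sample(paste0("TF", 1:6), 50, TRUE),
                   tg = sample(paste0("TG", 1:7), 50, TRUE),
                   p_mi = 0.1, p_la = 0.1, p_cr_pheno = 0.1, p_tf_pheno = 0.1,
                   chi2 = runif(50, 10, 40), p_combined = 0.02, q = 1)
  hub <- hubTables(tr, k = 100)
  expect_identical(nrow(hub$crs), length(unique(tr$cr)))
  for (i in seq_len(nrow(hub$tgs))) {
    brute <- length(unique(tr$tf[tr$tg == hub$tgs$tg[i]]))
    expect_identical(hub$tgs$in_degree[i], brute)
  }
  hub2 <- hubTables(tr[sample(nrow(tr)), ], k = 100)
  expect_identical(hub, hub2)
})
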