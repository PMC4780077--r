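chr7Annotation <- function() {
  # six genes inside the 1.39 Mb imprinted region on chromosome 7
  genes <- c("Sct", "Eps8l2", "Tollip", "Ctsd", "H19", "Igf2")
  starts <- c(141278331, 141450000, 141700000, 141980000, 142400000, 142600000)
  gr <- GenomicRanges::GRanges("chr7",
    IRanges::IRanges(starts, width = c(5000, 20000, 30000, 10000, 3000, 15000)))
  names(gr) <- genes
  gr
}

tripletsFor <- function(tgs, cr = "CR1", tf = "TF1") {
  data.frame(cr = cr, tf = tf, tg = tgs, p_mi = 1e-6, p_la = 1e-6,
             p_cr_pheno = 1e-3, p_tf_pheno = 1e-3, chi2 = 70,
             p_combined = 1e-12, q = 1e-8)
}

test_that("co-located genes cluster into one region (chromosome 7 example)", {
  ann <- chr7Annotation()
  specs <- assignRegions(ann, tripletsFor(names(ann)), window = 1.5e6)
  expect_length(specs, 1)
  sp <- specs[[1]]
  expect_setequal(sp$tgs, names(ann))
  expect_identical(as.character(GenomicRanges::seqnames(sp$region)), "chr7")
  expect_identical(GenomicRanges::start(sp$region), 141278331L)
  expect_setequal(sp$crParents, "CR1")
  expect_setequal(unlist(sp$tfParents), "TF1")
})

test_that("distant genes form singleton candidates that are dropped", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1e6, 6e6), width = 1e4))
  names(gr) <- c("a", "b")
  expect_error(
    suppressMessages(assignRegions(gr, tripletsFor(c("a", "b")), window = 1e6)),
    "no region")
})

test_that("predefined region intervals assign by midpoint lookup", {
  ann <- chr7Annotation()
  regionBed <- GenomicRanges::GRanges("chr7",
    IRanges::IRanges(c(141e6, 142.3e6), width = c(1.2e6, 1e6)))
  specs <- assignRegions(ann, tripletsFor(names(ann)), regionBed = regionBed)
  expect_length(specs, 2)
  got <- lapply(specs, `[[`, "tgs")
  mids <- (GenomicRanges::start(ann) + GenomicRanges::end(ann)) / 2
  inFirst <- names(ann)[mids >= 141e6 & mids < 142.2e6]
  expect_true(any(vapply(got, function(g) setequal(g, inFirst), TRUE)))
})

test_that("TGs missing from the annotation are dropped with a message", {
  ann <- chr7Annotation()
  tr <- tripletsFor(c(names(ann), "ghost"))
  expect_message(specs <- assignRegions(ann, tr, window = 1.5e6), "ghost")
  expect_setequal(specs[[1]]$tgs, names(ann))
})

test_that("unidentifiable regions are refused", {
  sim <- simulateRegion(nTGs = 2, nCRs = 0, n = 50, seed = 1)
  spec <- sim$spec
  spec$tgs <- spec$tgs[1]
  expect_error(fitRegion(sim$exprs, spec), "unidentifiable")

  sim2 <- simulateRegion(nTGs = 3, nCRs = 8, n = 8, seed = 1)
  expect_error(fitRegion(stdMatrix(sim2$exprs), sim2$spec), "samples")
})

test_that("the EM objective is nondecreasing on random fixtures", {
  for (s in 1:10) {
    set.seed(s)
    sim <- simulateRegion(nTGs = 2 + s %% 4, nCRs = 1 + s %% 3,
                          n = 60 + 10 * (s %% 5), sigmaTG = 0.5,
                          sigmaCA = 0.5, seed = s)
    mdl <- fitRegion(stdMatrix(sim$exprs), sim$spec, seed = s, nRestarts = 1)
    ll <- mdl@loglikPath
    expect_true(all(diff(ll) >= -1e-9 * (abs(ll[-length(ll)]) + 1e-12)))
  }
})

test_that("EM recovers the latent activity and CR effects", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulateRegion(n = 300, sigmaTG = 0.3, sigmaCA = 0.3, seed = s)
    mdl <- fitRegion(stdMatrix(sim$exprs), sim$spec, seed = s)
    cc <- cor(regionActivity(mdl), sim$ca)
    bcor <- cor(sign(cc) * regionBeta(mdl)[names(sim$params$beta)],
                sim$params$beta)
    hits <- hits + (abs(cc) >= 0.9 && bcor >= 0.9)
  }
  expect_gte(hits, 4)
})

test_that("noise-free data are recovered up to an affine map", {
  # near-noiseless data converge slowly along the latent scale/rotation
  # ridge; give the EM a larger iteration budget
  sim <- simulateRegion(n = 200, sigmaTG = 1e-8, sigmaCA = 1e-8, seed = 42)
  mdl <- fitRegion(stdMatrix(sim$exprs), sim$spec, seed = 1,
                   maxIter = 5000, nRestarts = 2)
  expect_gte(abs(cor(regionActivity(mdl), sim$ca)), 0.999)

  # restart stability: two seeds agree up to sign
  mdl2 <- fitRegion(stdMatrix(sim$exprs), sim$spec, seed = 99,
                    maxIter = 5000, nRestarts = 2)
  expect_gte(abs(cor(regionActivity(mdl), regionActivity(mdl2))), 0.99)
})

test_that("identifiability conventions hold on the fitted model", {
  sim <- simulateRegion(n = 150, seed = 7)
  mdl <- fitRegion(stdMatrix(sim$exprs), sim$spec, seed = 1)
  ca <- regionActivity(mdl)
  expect_lt(abs(mean(ca)), 1e-9)
  expect_lt(abs(mean((ca - mean(ca))^2) - 1), 1e-6)
  b <- regionBeta(mdl)
  expect_gt(b[which.max(abs(b))], 0)
})

test_that("CR ranking finds the dominant planted regulator with its sign", {
  hits <- signs <- 0
  for (s in 1:6) {
    sim <- simulateRegion(nCRs = 4, beta = c(1, 0.1, 0.1, -0.1),
                          n = 300, seed = s)
    mdl <- fitRegion(stdMatrix(sim$exprs), sim$spec, seed = s)
    rk <- rankRegionCRs(mdl)
    hits <- hits + (rk$cr[1] == names(sim$params$beta)[1])
    signs <- signs + (rk$sign[1] > 0)  # convention makes the top CR positive
  }
  expect_gte(hits, 5)
  expect_gte(signs, 5)
})

test_that("an all-null CR block yields only small fitted effects", {
  sim <- simulateRegion(nCRs = 3, beta = c(0, 0, 0), sigmaCA = 1,
                        n = 300, seed = 3)
  mdl <- fitRegion(stdMatrix(sim$exprs), sim$spec, seed = 1)
  expect_lt(max(abs(regionBeta(mdl))), 0.2)
})

test_that("collinear CR parents trigger the ridge fallback", {
  sim <- simulateRegion(nCRs = 2, n = 100, seed = 5)
  m <- sim$exprs
  m <- rbind(m, CRdup = m["CR01", ])
  spec <- sim$spec
  spec$crParents <- c(spec$crParents, "CRdup")
  expect_warning(fitRegion(stdMatrix(m), spec, seed = 1, nRestarts = 1),
                 "ridge")
})

test_that("fitted parameters reproduce the TG covariance", {
  sim <- simulateRegion(nTGs = 4, nCRs = 3, n = 4000, sigmaTG = 0.4, seed = 9)
  m <- stdMatrix(sim$exprs)
  mdl <- fitRegion(m, sim$spec, seed = 1)
  tgs <- regionTGs(mdl)
  k <- length(tgs)
  pred <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ai <- mdl@alpha[[tgs[i]]]; aj <- mdl@alpha[[tgs[j]]]
    v <- ai$ca * aj$ca   # Var(CA) = 1 by convention
    shared <- intersect(names(ai$tf), names(aj$tf))
    # TF rows are standardized: unit variance
    if (length(shared)) v <- v + sum(ai$tf[shared] * aj$tf[shared])
    if (i == j) v <- v + mdl@sigmaTG[tgs[i]]^2
    pred[i, j] <- v
  }
  emp <- tcrossprod(m[tgs, ]) / ncol(m)
  expect_lt(norm(emp - pred, "F") / norm(emp, "F"), 0.1)
})
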