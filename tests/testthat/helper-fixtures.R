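# shared fixture builders; everything is generated in code

std01 <- function(v) (v - mean(v)) / sqrt(mean((v - mean(v))^2))

tinyExperiment <- function(m = NULL, nGenes = 3, nSamples = 4, seed = 1) {
  if (is.null(m)) {
    set.seed(seed)
    m <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples)
  }
  rownames(m) <- rownames(m) %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  meta <- data.frame(dataset = "D1",
                     timepoint = rep(seq_len(ceiling(ncol(m) / 2)),
                                     length.out = ncol(m)),
                     replicate = 1L)
  CRExperiment(m, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeExprFixture <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "expr.tsv")
  writeLines(lines, path)
  meta <- file.path(dir, "meta.tsv")
  header <- strsplit(lines[1], "\t")[[1]][-1]
  writeLines(c("sample_id\tdataset\ttimepoint\treplicate",
               sprintf("%s\tD1\t%d\t1", header, seq_along(header))), meta)
  list(expr = path, meta = meta)
}

# independent hypergeometric tail by explicit combinatorial enumeration
hyperTailOracle <- function(k, a, b, U) {
  js <- max(0, a + b - U):min(a, b)
  pm <- vapply(js, function(j) choose(a, j) * choose(U - a, b - j), 0) /
    choose(U, b)
  sum(pm[js >= k])
}

# modularity by the hand formula Q = sum_c [ e_c/m - (d_c/(2m))^2 ]
modularityOracle <- function(g, membership) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  deg <- igraph::degree(g)
  q <- 0
  for (cc in unique(membership)) {
    idx <- which(membership == cc)
    ein <- sum(membership[el[, 1]] == cc & membership[el[, 2]] == cc)
    q <- q + ein / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# standardize a plain matrix row-wise (population variance)
stdMatrix <- function(m) {
  mu <- rowMeans(m)
  v <- rowMeans((m - mu)^2)
  (m - mu) / sqrt(v)
}
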