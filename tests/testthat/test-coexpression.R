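# Signed adjacency, scale-free fit, TOM, module detection and module
# intersection.

# expression rows with an exact Pearson correlation r
exactCorPair <- function(r, n = 20) {
  x <- scale(seq_len(n))[, 1]
  z <- stats::resid(stats::lm(rnorm(n) ~ x))
  z <- z / sqrt(sum(z^2) / (n - 1))
  rbind(a = x, b = r * x + sqrt(1 - r^2) * z)
}

test_that("signed adjacency follows ((1+cor)/2)^beta exactly", {
  set.seed(2)
  m1 <- rbind(a = 1:10, b = 2 * (1:10) + 3) # cor = 1
  expect_equal(signedAdjacency(m1, beta = 7)["a", "b"], 1)

  m2 <- rbind(a = 1:10, b = -(1:10)) # cor = -1
  expect_equal(signedAdjacency(m2, beta = 3)["a", "b"], 0)

  m3 <- exactCorPair(0.6)
  expect_equal(signedAdjacency(m3, beta = 2)["a", "b"], 0.64,
    tolerance = 1e-12
  )

  # constant gene: correlation treated as 0
  m4 <- rbind(a = 1:10, b = rep(2, 10))
  a4 <- signedAdjacency(m4, beta = 2)
  expect_equal(a4["a", "b"], 0.25)
  expect_equal(unname(diag(a4)), c(0, 0))

  expect_error(signedAdjacency(m1[, 1:3], 2), "4 samples")
  expect_error(signedAdjacency(m1, 0.5), "beta")
})

test_that("raising beta never increases off-diagonal adjacency", {
  set.seed(12)
  m <- matrix(rnorm(30 * 12), nrow = 30)
  rownames(m) <- paste0("g", 1:30)
  a6 <- signedAdjacency(m, 6)
  a12 <- signedAdjacency(m, 12)
  expect_true(all(a12 <= a6 + 1e-12))
})

test_that("scale-free fit is exact on a constructed power-law and bounded", {
  # disjoint weighted pairs: 32 nodes with k = 0.25, 8 with k = 1,
  # 2 with k = 4 -> counts fall as k^-1, exactly log-log linear
  sizes <- c(32, 8, 2)
  ks <- c(0.25, 1, 4)
  n <- sum(sizes)
  a <- matrix(0, n, n)
  idx <- 0
  for (j in seq_along(sizes)) {
    for (p in seq_len(sizes[j] / 2)) {
      a[idx + 1, idx + 2] <- a[idx + 2, idx + 1] <- ks[j]
      idx <- idx + 2
    }
  }
  rownames(a) <- colnames(a) <- paste0("n", 1:n)
  expect_equal(scaleFreeFit(a, nBins = 10), 1, tolerance = 1e-10)

  set.seed(4)
  m <- matrix(rnorm(40 * 10), nrow = 40)
  rownames(m) <- paste0("g", 1:40)
  r2 <- scaleFreeFit(signedAdjacency(m, 6))
  expect_gte(r2, 0)
  expect_lte(r2, 1)
})

test_that("soft thresholding drives simulated module data toward scale-freeness", {
  s <- refSim(1)
  v <- vstCounts(SummarizedExperiment::assay(s$cohort$se))
  vv <- apply(v, 1, var)
  expr <- v[names(sort(vv, decreasing = TRUE))[1:200], ]
  r2_1 <- scaleFreeFit(signedAdjacency(expr, 1))
  r2_12 <- scaleFreeFit(signedAdjacency(expr, 12))
  expect_gte(r2_12, r2_1)
})

test_that("TOM matches hand-computed values and its contracts", {
  a <- matrix(0, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  a["x", "y"] <- a["y", "x"] <- 0.8
  a["x", "z"] <- a["z", "x"] <- 0.5
  a["y", "z"] <- a["z", "y"] <- 0.2
  tom <- topologicalOverlap(a)
  expect_equal(tom["x", "y"], 0.75, tolerance = 1e-12) # (0.1+0.8)/(1.0+1-0.8)
  expect_equal(unname(diag(tom)), rep(1, 3))

  iso <- matrix(0, 4, 4)
  iso[1, 2] <- iso[2, 1] <- 1
  rownames(iso) <- colnames(iso) <- paste0("g", 1:4)
  expect_equal(topologicalOverlap(iso)[1, 2], 1)

  set.seed(6)
  r <- matrix(runif(100), 10, 10)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  rownames(r) <- colnames(r) <- paste0("g", 1:10)
  tr <- topologicalOverlap(r)
  expect_true(all(tr >= 0 & tr <= 1))
  expect_equal(tr, t(tr))
  # lower-bound sanity: TOM_ij >= a_ij / (max k + 1)
  kmax <- max(rowSums(r))
  off <- row(r) != col(r)
  expect_true(all(tr[off] >= r[off] / (kmax + 1) - 1e-12))

  bad <- r
  diag(bad) <- 1
  expect_error(topologicalOverlap(bad), "diagonal")
})

# two latent-factor blocks with strong within-block correlation
blockExpr <- function(nPerBlock = 25, nSamples = 30, noise = 0.4, seed = 13) {
  set.seed(seed)
  f1 <- rnorm(nSamples)
  f2 <- rnorm(nSamples)
  m <- rbind(
    t(sapply(seq_len(nPerBlock), function(i) f1 + rnorm(nSamples, 0, noise))),
    t(sapply(seq_len(nPerBlock), function(i) f2 + rnorm(nSamples, 0, noise)))
  )
  rownames(m) <- c(
    paste0("a", seq_len(nPerBlock)), paste0("b", seq_len(nPerBlock))
  )
  m
}

test_that("module detection recovers planted blocks", {
  m <- blockExpr()
  net <- buildCoexpressionNetwork(m, beta = 12, minModuleSize = 10)
  lab <- moduleLabels(net)
  truth <- rep(1:2, each = 25)
  expect_equal(length(setdiff(unique(lab), 0L)), 2)
  expect_gte(mclust::adjustedRandIndex(lab, truth), 0.8)

  # permuting gene order permutes labels consistently
  set.seed(21)
  perm <- sample(nrow(m))
  lab2 <- moduleLabels(
    buildCoexpressionNetwork(m[perm, ], beta = 12, minModuleSize = 10)
  )
  expect_gte(mclust::adjustedRandIndex(lab2[rownames(m)], lab), 0.999)

  # min size above n leaves everything unassigned
  tom <- tomMatrix(net)
  expect_true(all(detectModules(tom, minModuleSize = 1000) == 0L))
})

test_that("moduleOf returns members or an explicit no-module result", {
  lab <- setNames(c(1L, 1L, 1L, 1L, 1L, 0L, 2L), paste0("g", 1:7))
  res <- moduleOf(lab, "g2")
  expect_true(res$assigned)
  expect_setequal(res$genes, paste0("g", 1:5))
  none <- moduleOf(lab, "g6")
  expect_false(none$assigned)
  expect_length(none$genes, 0)
  expect_error(moduleOf(lab, "g99"), "not in network")
})

test_that("module intersection partitions by biotype", {
  ann <- toyAnnotation()
  mi <- intersectModules(
    c("pcgB", "pcgC", "lncA"), c("pcgC", "lncA", "lncD"), ann
  )
  expect_setequal(commonGenes(mi), c("pcgC", "lncA"))
  expect_equal(commonPCG(mi), "pcgC")
  expect_equal(commonNcRNA(mi), "lncA")
  expect_equal(
    length(commonPCG(mi)) + length(commonNcRNA(mi)), length(commonGenes(mi))
  )

  none <- intersectModules(c("pcgB"), c("lncD"), ann)
  expect_length(commonGenes(none), 0)
  expect_error(
    intersectModules(c("pcgB", "mystery"), c("mystery"), ann),
    "missing from annotation"
  )
})

test_that("target nomination flags cohort up-regulation and is PCG-only", {
  ann <- toyAnnotation()
  mi <- intersectModules(
    c("pcgB", "pcgC", "lncA"), c("pcgB", "pcgC", "lncA"), ann
  )
  de <- list(
    grpA = data.frame(
      gene_id = c("pcgB", "pcgC"), log2fc = c(1.2, 0.1),
      p = c(0.01, 0.8), stringsAsFactors = FALSE
    ),
    grpB = data.frame(
      gene_id = c("pcgB", "pcgC"), log2fc = c(0.2, -1),
      p = c(0.5, 0.01), stringsAsFactors = FALSE
    )
  )
  tg <- nominateTargets(mi, de)
  expect_setequal(tg$gene_id, c("pcgB", "pcgC"))
  expect_true(all(tg$gene_id %in% ann$gene_id[ann$biotype == "protein_coding"]))
  expect_equal(tg$up_in_any[tg$gene_id == "pcgB"], TRUE)
  expect_equal(tg$up_in_any[tg$gene_id == "pcgC"], FALSE)

  empty <- intersectModules("pcgB", "lncD", ann)
  expect_equal(nrow(nominateTargets(empty, de)), 0)
})
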