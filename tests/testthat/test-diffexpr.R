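# Normalization, transforms, lncRNA classification and the NB tests.

test_that("lncRNA classification applies the biotype and length rules", {
  ann <- toyAnnotation()
  expect_setequal(classifyLncRNA(ann), "lncA") # lincRNA, 500 bp
  # antisense at 150 bp and protein_coding/pseudogene at any length fail
  expect_false("lncD" %in% classifyLncRNA(ann))
  expect_false(any(c("pcgB", "pcgC", "pseudoE") %in% classifyLncRNA(ann)))

  ann$biotype[1] <- NA
  expect_warning(out <- classifyLncRNA(ann), "missing biotype")
  expect_length(out, 0)
})

test_that("median-of-ratios size factors match hand-computed values", {
  m <- cbind(s1 = c(2, 2), s2 = c(8, 8))
  expect_equal(unname(sizeFactorsMedianRatio(m)), c(0.5, 2.0))

  m2 <- matrix(c(5, 9, 13, 5, 9, 13), ncol = 2)
  expect_equal(unname(sizeFactorsMedianRatio(m2)), c(1, 1))

  # factors are defined up to overall scale: tripling one sample's
  # counts triples its factor relative to the others
  set.seed(1)
  m3 <- matrix(rpois(60, 50), ncol = 3)
  f1 <- sizeFactorsMedianRatio(m3)
  m3b <- m3
  m3b[, 2] <- m3[, 2] * 3
  f2 <- sizeFactorsMedianRatio(m3b)
  expect_equal((f2[2] / f2[1]) / (f1[2] / f1[1]), 3, tolerance = 1e-12)

  # no all-nonzero gene: total-count fallback with warning
  m4 <- rbind(c(0, 4), c(4, 0))
  expect_warning(f4 <- sizeFactorsMedianRatio(m4), "total-count")
  expect_equal(unname(f4), c(1, 1))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(42)
  m <- matrix(rnbinom(500 * 6, mu = 100, size = 5), ncol = 6)
  m <- sweep(m, 2, c(0.5, 0.8, 1, 1.2, 1.5, 2), "*")
  expect_equal(
    unname(sizeFactorsMedianRatio(m)),
    unname(DESeq2::estimateSizeFactorsForMatrix(m)),
    tolerance = 1e-6
  )
})

test_that("FPKM follows its defining proportionalities", {
  ann2 <- GenomicRanges::GRanges(
    rep("chr1", 3), IRanges::IRanges(c(1, 2001, 5001), width = 1000),
    gene_id = c("a", "b", "filler"), biotype = "protein_coding",
    transcript_length = c(1000, 2000, 1000)
  )
  # column sums to 1e6 via a filler gene
  m <- rbind(a = 10, b = 0)
  m <- rbind(m, filler = 1e6 - colSums(m))
  f <- fpkmMatrix(m, ann2)
  expect_equal(unname(f["a", 1]), 10) # 10 / (1 kb x 1 M)
  expect_equal(unname(f["b", 1]), 0)
  ann2$transcript_length[1] <- 2000
  expect_equal(unname(fpkmMatrix(m, ann2)["a", 1]), 5) # doubling length halves it
})

test_that("the log2 transform is exact on knowns and monotone", {
  m <- rbind(g1 = c(0, 7), g2 = c(7, 0), g3 = c(3, 100))
  v <- vstCounts(m, sizeFactors = c(1, 1))
  expect_equal(unname(v["g1", 1]), 0)
  expect_equal(unname(v["g1", 2]), 3) # log2(8)
  expect_equal(order(m[, 1]), order(v[, 1]))
})

test_that("method-of-moments dispersion is consistent and floored", {
  # Poisson data: estimates concentrate near zero
  sim <- nbCountMatrix(300, c(10, 10), mu = 100, alpha = 0, seed = 11)
  a <- estimateDispersionMoM(sim$counts, sim$groups)
  expect_lte(median(a), 0.05)

  # variance below the mean and constant genes hit the floor
  m <- rbind(under = rep(c(9, 10, 11, 10), 2), const = rep(5, 8))
  a2 <- estimateDispersionMoM(m, rep("g1", 8), sizeFactors = rep(1, 8))
  expect_equal(unname(a2), c(1e-8, 1e-8))

  # recovers a substantial true dispersion on average
  sim3 <- nbCountMatrix(400, c(10, 10), mu = 200, alpha = 0.2, seed = 12)
  a3 <- estimateDispersionMoM(sim3$counts, sim3$groups)
  expect_equal(median(a3), 0.2, tolerance = 0.35)
})

test_that("the Wald test is antisymmetric and null on identical groups", {
  sim <- nbCountMatrix(50, c(5, 5), mu = 100, alpha = 0.1, seed = 21)
  d1 <- nbWaldTest(sim$counts, sim$groups, contrast = c("grp1", "grp2"))
  d2 <- nbWaldTest(sim$counts, sim$groups, contrast = c("grp2", "grp1"))
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p, d2$p)
  expect_true(all(d1$padj >= d1$p - 1e-12))

  m <- matrix(rep(c(5, 9, 13), 4), ncol = 4)
  rownames(m) <- paste0("g", 1:3)
  dd <- nbWaldTest(m, c("A", "A", "B", "B"),
    contrast = c("A", "B"),
    sizeFactors = rep(1, 4)
  )
  expect_equal(dd$log2fc, rep(0, 3))

  z <- matrix(0L, 3, 4, dimnames = list(paste0("g", 1:3), NULL))
  dz <- nbWaldTest(z, c("A", "A", "B", "B"),
    contrast = c("A", "B"),
    sizeFactors = rep(1, 4), dispersions = rep(0.1, 3)
  )
  expect_equal(dz$p, rep(1, 3))
  expect_equal(dz$log2fc, rep(0, 3))
})

test_that("at vanishing dispersion the Wald p matches a Poisson LRT oracle", {
  set.seed(31)
  n <- 100
  mu <- runif(n, 500, 2000)
  sim <- nbCountMatrix(n, c(6, 6), mu = mu, alpha = 0, seed = 31)
  de <- nbWaldTest(sim$counts, sim$groups,
    contrast = c("grp1", "grp2"),
    sizeFactors = rep(1, 12), dispersions = rep(1e-8, n)
  )
  g <- factor(sim$groups)
  oracle <- vapply(seq_len(n), function(i) {
    k <- sim$counts[i, ]
    full <- glm(k ~ g, family = poisson())
    red <- glm(k ~ 1, family = poisson())
    stat <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
    pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
  dlp <- abs(log10(pmax(de$p, 1e-300)) - log10(pmax(oracle, 1e-300)))
  expect_lt(max(dlp), 0.3)
})

test_that("the LRT is non-negative, nested-identical and direction-aware", {
  sim <- nbCountMatrix(40, c(4, 4, 4), mu = 80, alpha = 0.1, seed = 41)
  full <- factor(sim$groups)
  de <- nbLRT(sim$counts, full)
  expect_true(all(de$stat >= 0))
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_true(all(de$padj >= de$p - 1e-12))

  same <- nbLRT(sim$counts, full, reduced = full)
  expect_equal(same$stat, rep(0, 40))
  expect_equal(same$p, rep(1, 40))

  expect_error(
    nbLRT(sim$counts, factor(rep(c("a", "b"), 6)),
      reduced = factor(rep(c("x", "y", "z"), each = 4))
    ),
    "nested"
  )

  # a strong planted up-effect is reported with a positive log2fc
  up <- nbCountMatrix(10, c(5, 5), mu = 100, alpha = 0.05, seed = 42, lfc = 2)
  deu <- nbLRT(up$counts, factor(up$groups), sizeFactors = rep(1, 10))
  expect_true(all(deu$log2fc > 1))
})

test_that("Wald and LRT agree in gene ranking", {
  sim <- nbCountMatrix(150, c(6, 6),
    mu = 150, alpha = 0.1, seed = 51,
    lfc = rnorm(150, 0, 0.8)
  )
  w <- nbWaldTest(sim$counts, sim$groups, contrast = c("grp1", "grp2"))
  l <- nbLRT(sim$counts, factor(sim$groups))
  expect_gte(cor(w$p, l$p, method = "spearman"), 0.9)
})

test_that("results are invariant to relabeling samples within groups", {
  sim <- nbCountMatrix(30, c(5, 5), mu = 120, alpha = 0.1, seed = 61)
  perm <- c(sample(1:5), sample(6:10))
  w1 <- nbWaldTest(sim$counts, sim$groups, contrast = c("grp1", "grp2"))
  w2 <- nbWaldTest(
    sim$counts[, perm], sim$groups[perm],
    contrast = c("grp1", "grp2")
  )
  expect_equal(w1$log2fc, w2$log2fc)
  expect_equal(w1$p, w2$p)
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.73), 0.73)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_true(is.nan(bhAdjust(c(0.5, NaN))[2]))
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})
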