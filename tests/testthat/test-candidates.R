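# Spearman correlation, the cis window, candidate selection, cohort
# replication and the IFN score.

test_that("Spearman handles monotone, antitone and the 5-point example", {
  x <- 1:8
  expect_equal(spearmanCor(x, 2 * x + 1)$rho, 1)
  expect_equal(spearmanCor(x, -x^3)$rho, -1)
  expect_equal(spearmanCor(x, 2 * x + 1)$p, 0)

  r <- spearmanCor(1:5, c(1, 2, 3, 5, 4))
  expect_equal(r$rho, 0.9, tolerance = 1e-12)
  # t-approximation: t = 0.9 sqrt(3 / 0.19), df = 3, two-sided
  expect_equal(r$p, 2 * pt(-0.9 * sqrt(3 / 0.19), df = 3), tolerance = 1e-12)

  expect_warning(rc <- spearmanCor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(rc$rho))
  expect_error(spearmanCor(1:3, 1:3), "at least 4")
})

test_that("all-pairs correlation retains duplicates and calibrates under the null", {
  set.seed(3)
  pcg <- matrix(rnorm(5 * 30), nrow = 5,
    dimnames = list(paste0("p", 1:5), paste0("s", 1:30))
  )
  lnc <- rbind(l1 = pcg["p3", ], l2 = rnorm(30))
  colnames(lnc) <- colnames(pcg)
  out <- correlateLncPcg(lnc, pcg, corrPMax = 0.05)
  hit <- out[out$lnc_id == "l1" & out$pcg_id == "p3", ]
  expect_equal(hit$rho, 1)

  # null calibration: independent lncRNAs are retained for about the
  # nominal fraction of PCGs
  frac <- vapply(1:3, function(s) {
    set.seed(100 + s)
    A <- matrix(rnorm(20 * 30), nrow = 20,
      dimnames = list(paste0("l", 1:20), paste0("s", 1:30))
    )
    B <- matrix(rnorm(40 * 30), nrow = 40,
      dimnames = list(paste0("p", 1:40), paste0("s", 1:30))
    )
    nrow(correlateLncPcg(A, B, corrPMax = 0.05)) / (20 * 40)
  }, numeric(1))
  expect_lt(mean(frac), 0.10)
  expect_gt(mean(frac), 0.02)

  empty <- correlateLncPcg(
    lnc, pcg[integer(), , drop = FALSE], corrPMax = 0.05
  )
  expect_equal(nrow(empty), 0)
})

test_that("cis pairing is inclusive at the window, symmetric and monotone", {
  ann <- toyAnnotation()
  # lncA [100000,101000] vs pcgB [251000,260000]: gap 149,999
  cp <- cisPairs(ann["lncA"], ann["pcgB"], window = 150000)
  expect_equal(cp$gap, 149999)
  expect_equal(nrow(cisPairs(ann["lncA"], ann["pcgB"], window = 149998)), 0)

  # overlap gives gap 0; different chromosomes never pair
  ov <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100500, 100900),
    gene_id = "pcgX", biotype = "protein_coding", transcript_length = 400
  )
  names(ov) <- "pcgX"
  expect_equal(cisPairs(ann["lncA"], ov, window = 0)$gap, 0)
  expect_equal(nrow(cisPairs(ann["lncD"], ann["pcgB"], window = 1e9)), 0)

  # symmetry in the two arguments
  a <- cisPairs(ann[c("lncA", "lncD")], ann[c("pcgB", "pcgC")], 150000)
  b <- cisPairs(ann[c("pcgB", "pcgC")], ann[c("lncA", "lncD")], 150000)
  expect_setequal(
    paste(a$lnc_id, a$pcg_id, a$gap),
    paste(b$pcg_id, b$lnc_id, b$gap)
  )

  # widening the window never removes pairs
  w1 <- cisPairs(ann[c("lncA", "lncD")], ann[c("pcgB", "pcgC")], 150000)
  w2 <- cisPairs(ann[c("lncA", "lncD")], ann[c("pcgB", "pcgC")], 500000)
  expect_true(all(
    paste(w1$lnc_id, w1$pcg_id) %in% paste(w2$lnc_id, w2$pcg_id)
  ))
})

test_that("candidate selection needs correlation AND cis support", {
  corr <- data.frame(
    lnc_id = c("l1", "l2"), pcg_id = c("p1", "p2"),
    rho = c(0.9, 0.8), p = c(0.001, 0.01), stringsAsFactors = FALSE
  )
  cis <- data.frame(
    lnc_id = c("l1", "l3"), pcg_id = c("p1", "p3"),
    gap = c(50, 10), stringsAsFactors = FALSE
  )
  out <- selectIFNViralLncRNAs(corr, cis)
  expect_equal(out$lnc_id, "l1") # l2 correlated-only, l3 cis-only
  expect_equal(out$support_pcgs, "p1")
  expect_equal(out$best_rho, 0.9)
})

test_that("planted cis-paired lncRNAs are recovered from correlation + cis", {
  hits <- tot <- 0L
  for (s in 1:3) {
    sim <- refSim(s)
    truth <- sim$tc$truth
    v <- vstCounts(SummarizedExperiment::assay(sim$tc$se))
    mg <- modulatedGenes(truth)
    lnc <- mg$gene_id[grepl("^LNC", mg$gene_id)]
    pcgMod <- setdiff(mg$gene_id, lnc)
    corr <- correlateLncPcg(
      v[lnc, , drop = FALSE], v[pcgMod, , drop = FALSE], 0.05
    )
    cis <- cisPairs(sim$ann[lnc], sim$ann[pcgMod], 150000)
    cand <- selectIFNViralLncRNAs(corr, cis)
    planted <- plantedCisPairs(truth)$lnc_id
    hits <- hits + length(intersect(cand$lnc_id, planted))
    tot <- tot + length(planted)
  }
  expect_gte(hits / tot, 0.8)
})

test_that("the replication filter applies inclusive up-only thresholds", {
  mk <- function(lfc, p) {
    data.frame(gene_id = "g", log2fc = lfc, p = p, stringsAsFactors = FALSE)
  }
  # boundary values in exactly 2 of 3 groups pass
  de <- list(a = mk(0.58, 0.05), b = mk(0.58, 0.05), c = mk(0.1, 0.5))
  expect_equal(cohortReplicationFilter(de), "g")
  # one group only fails
  de1 <- list(a = mk(2, 0.001), b = mk(0, 0.9), c = mk(0, 0.9))
  expect_length(cohortReplicationFilter(de1), 0)
  # strong downregulation everywhere fails the sign rule
  deDown <- list(a = mk(-0.9, 0.001), b = mk(-0.9, 0.001), c = mk(-0.9, 0.001))
  expect_length(cohortReplicationFilter(deDown), 0)
  expect_error(cohortReplicationFilter(de[1]), "at least 2")
})

test_that("the IFN score is an HC-referenced z average", {
  genes <- c("IFI27", "IFI44L", "IFIT1", "IFIT2", "IFIT3", "SERPING1")
  set.seed(8)
  hc <- matrix(rnorm(6 * 10, mean = 5), nrow = 6,
    dimnames = list(genes, paste0("HC", 1:10))
  )
  mu <- rowMeans(hc)
  sdv <- apply(hc, 1, sd)
  extra <- cbind(atMean = mu, twoUp = mu + 2 * sdv)
  expr <- cbind(hc, extra)
  sc <- ifnScore(expr, genes, hcSamples = colnames(hc))
  expect_equal(sc$score[sc$sample_id == "atMean"], 0, tolerance = 1e-12)
  expect_equal(sc$score[sc$sample_id == "twoUp"], 2, tolerance = 1e-12)
  expect_equal(mean(sc$score[sc$sample_id %in% colnames(hc)]), 0,
    tolerance = 1e-12
  )

  expect_warning(
    ifnScore(expr[1:5, ], genes, hcSamples = colnames(hc)), "missing"
  )
  exprC <- expr
  exprC["IFI27", colnames(hc)] <- 1
  expect_warning(
    scC <- ifnScore(exprC, genes, hcSamples = colnames(hc)),
    "zero HC standard deviation"
  )
  expect_equal(scC$score[scC$sample_id == "atMean"], 0, tolerance = 1e-12)
})

test_that("score correlation is exact for a score-tracking lncRNA", {
  genes <- paste0("sig", 1:4)
  set.seed(9)
  expr <- matrix(rnorm(4 * 20, 5), nrow = 4,
    dimnames = list(genes, paste0("s", 1:20))
  )
  sc <- ifnScore(expr, genes, hcSamples = paste0("s", 1:8))
  lnc <- setNames(sc$score, sc$sample_id) # perfectly tracking
  r <- scoreCorrelation(lnc, sc)
  expect_equal(r$rho, 1)
})

test_that("DE-set intersection returns the full lattice", {
  out <- intersectDESets(list(
    lps = c("A", "B", "C"), ssc = c("B", "C"), sle = "C"
  ))
  expect_equal(out$full, "C")
  expect_equal(out$fullSize, 1L)
  expect_equal(out$pairwise["lps", "ssc"], 2L)
  expect_equal(unname(out$sizes), c(3L, 2L, 1L))

  expect_equal(intersectDESets(list(a = "x", b = "y"))$fullSize, 0L)
  same <- intersectDESets(list(a = c("p", "q"), b = c("q", "p")))
  expect_setequal(same$full, c("p", "q"))
  expect_error(intersectDESets(list(c("a"))), "at least 2")
})
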