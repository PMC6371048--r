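# Normalization, abundance transforms, lncRNA classification and
# simplified negative-binomial differential-expression tests.
#
# The NB model is mean mu with Var = mu + alpha * mu^2. Dispersion is a
# per-gene method-of-moments estimate (no shrinkage, no outlier
# filtering); calibration of the resulting tests is enforced by the test
# suite rather than by model refinements.

countsOf <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(x, "counts")
  } else {
    m <- as.matrix(x)
  }
  if (any(m < 0)) stop("counts must be non-negative")
  m
}

#' Classify lncRNAs from a gene annotation
#'
#' A gene is treated as a long non-coding RNA when its biotype is neither
#' \code{protein_coding} nor \code{pseudogene} and its transcript length
#' is at least 200 bp. Genes with a missing biotype are rejected with a
#' warning.
#'
#' @param annotation a [GenomicRanges::GRanges] with \code{biotype} and
#'   \code{transcript_length} metadata columns.
#' @return Character vector of lncRNA gene ids.
#' @examples
#' ann <- generateAnnotation(simulationConfig(nPCG = 30, nLnc = 20, seed = 2))
#' length(classifyLncRNA(ann))
#' @export
classifyLncRNA <- function(annotation) {
  bt <- annotation$biotype
  len <- annotation$transcript_length
  miss <- is.na(bt)
  if (any(miss)) {
    warning(sum(miss), " gene(s) with missing biotype rejected")
  }
  keep <- !miss & !(bt %in% c("protein_coding", "pseudogene")) & len >= 200
  annotation$gene_id[keep]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (nonzero in
#' every sample) of the ratio of the sample's count to the gene's
#' geometric mean. When no gene is nonzero in all samples, total-count
#' ratios are used with a warning.
#'
#' @param counts a count matrix (genes x samples) or a
#'   \code{SummarizedExperiment} with a \code{counts} assay.
#' @return Positive numeric vector, one factor per sample.
#' @examples
#' m <- cbind(s1 = c(2, 2), s2 = c(8, 8))
#' sizeFactorsMedianRatio(m) # 0.5, 2
#' @export
sizeFactorsMedianRatio <- function(counts) {
  m <- countsOf(counts)
  ok <- rowSums(m == 0) == 0L
  if (!any(ok)) {
    warning("no gene is nonzero in all samples; using total-count ratios")
    sf <- colSums(m) / mean(colSums(m))
  } else {
    lg <- log(m[ok, , drop = FALSE])
    geo <- rowMeans(lg)
    sf <- apply(exp(lg - geo), 2, median)
  }
  if (any(sf <= 0)) stop("non-positive size factor")
  setNames(sf, colnames(m))
}

#' FPKM matrix
#'
#' \code{FPKM = count / (transcript length in kb x mapped reads in
#' millions)}, with mapped reads taken as the column sum.
#'
#' @inheritParams sizeFactorsMedianRatio
#' @param annotation annotation providing \code{transcript_length} for all
#'   genes in \code{counts}.
#' @return Numeric matrix of FPKM values.
#' @export
fpkmMatrix <- function(counts, annotation) {
  m <- countsOf(counts)
  len <- setNames(annotation$transcript_length, annotation$gene_id)
  if (!all(rownames(m) %in% names(len))) {
    stop("annotation lacks transcript lengths for some genes")
  }
  tot <- colSums(m)
  if (any(tot == 0)) stop("zero column sum: cannot compute FPKM")
  sweep(m / (len[rownames(m)] / 1e3), 2, tot / 1e6, "/")
}

#' Variance-flattening log transform of normalized counts
#'
#' \code{log2(count / size factor + 1)}; strictly monotone in the counts
#' of each sample. Used wherever the pipeline needs approximately
#' homoskedastic expression values (z-scored kinetics, correlation,
#' networks, the IFN score).
#'
#' @inheritParams sizeFactorsMedianRatio
#' @param sizeFactors optional precomputed factors; defaults to
#'   [sizeFactorsMedianRatio()].
#' @return Numeric matrix, same dimensions as the counts.
#' @export
vstCounts <- function(counts, sizeFactors = NULL) {
  m <- countsOf(counts)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
  log2(sweep(m, 2, sizeFactors, "/") + 1)
}

#' Method-of-moments NB dispersion
#'
#' On normalized counts, \code{alpha = max(0, (pooled within-group
#' variance - mean) / mean^2)}, floored at 1e-8. Groups with fewer than
#' two samples are excluded from pooling.
#'
#' @inheritParams vstCounts
#' @param groups factor of sample group labels.
#' @return Per-gene dispersion vector.
#' @export
estimateDispersionMoM <- function(counts, groups, sizeFactors = NULL) {
  m <- countsOf(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(m)) stop("groups must label every sample")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
  q <- sweep(m, 2, sizeFactors, "/")
  keep_groups <- names(which(table(groups) >= 2L))
  if (!length(keep_groups)) stop("need at least one group with >= 2 samples")
  use <- groups %in% keep_groups
  qq <- q[, use, drop = FALSE]
  g <- droplevels(groups[use])
  sse <- rowSums(vapply(levels(g), function(l) {
    x <- qq[, g == l, drop = FALSE]
    rowSums((x - rowMeans(x))^2)
  }, numeric(nrow(qq))))
  df <- ncol(qq) - nlevels(g)
  v <- sse / df
  mu <- rowMeans(qq)
  alpha <- (v - mu) / mu^2
  alpha[!is.finite(alpha)] <- 0
  setNames(pmax(alpha, 1e-8), rownames(m))
}

FC_PSEUDOCOUNT <- 0.5

# With few replicates the per-gene moment estimator often collapses to the
# 1e-8 floor even when counts are overdispersed, which makes the Wald and
# LRT tests anticonservative. Flooring each gene at the experiment-wide
# median dispersion (computed over reasonably expressed genes) restores
# near-nominal type-I error without per-gene shrinkage machinery.
moderateDispersions <- function(alpha, baseMean) {
  informative <- alpha[baseMean > 1]
  if (!length(informative)) informative <- alpha
  pmax(alpha, median(informative))
}

groupMeansVar <- function(q, sf, alpha, idx) {
  mu <- rowMeans(q[, idx, drop = FALSE])
  n <- length(idx)
  # Var(mean of count/sf) under NB: (1/n^2) sum_s (mu/sf_s + alpha mu^2)
  vmu <- (mu * sum(1 / sf[idx]) + alpha * mu^2 * n) / n^2
  list(mu = mu, vmu = vmu)
}

#' NB Wald test for a two-group contrast
#'
#' Group means are fitted on size-factor-normalized counts; the log2
#' fold-change uses a pseudocount of 0.5 in both groups, its standard
#' error comes from the delta method under the NB variance function, and
#' the two-sided p-value from the standard normal. Adjusted p-values are
#' Benjamini-Hochberg.
#'
#' @inheritParams estimateDispersionMoM
#' @param contrast length-2 character vector \code{c(reference, test)};
#'   the reported fold-change is test over reference.
#' @param dispersions optional per-gene dispersions; by default
#'   [estimateDispersionMoM()] on the two groups, floored at the
#'   experiment-wide median dispersion as a small-sample guard.
#' @return data.frame with columns gene_id, base_mean, log2fc, stat, p,
#'   padj, test, contrast.
#' @export
nbWaldTest <- function(counts, groups, contrast, sizeFactors = NULL,
                       dispersions = NULL) {
  m <- countsOf(counts)
  groups <- as.character(groups)
  if (!all(contrast %in% groups)) stop("contrast levels absent from groups")
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
  sel <- groups %in% contrast
  q <- sweep(m, 2, sizeFactors, "/")
  if (is.null(dispersions)) {
    raw <- estimateDispersionMoM(
      m[, sel, drop = FALSE], factor(groups[sel]), sizeFactors[sel]
    )
    dispersions <- moderateDispersions(
      raw, rowMeans(q[, sel, drop = FALSE])
    )
  }
  a <- groupMeansVar(q, sizeFactors, dispersions, which(groups == contrast[1]))
  b <- groupMeansVar(q, sizeFactors, dispersions, which(groups == contrast[2]))
  eps <- FC_PSEUDOCOUNT
  lfc <- log2((b$mu + eps) / (a$mu + eps))
  se <- sqrt(a$vmu / (a$mu + eps)^2 + b$vmu / (b$mu + eps)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * pnorm(-abs(stat)), 1)
  allzero <- a$mu == 0 & b$mu == 0
  lfc[allzero] <- 0
  stat[allzero] <- 0
  p[allzero] <- 1
  data.frame(
    gene_id = rownames(m),
    base_mean = rowMeans(q[, sel, drop = FALSE]),
    log2fc = lfc, stat = stat, p = p, padj = bhAdjust(p),
    test = "wald",
    contrast = paste0(contrast[2], "_vs_", contrast[1]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

nbLogLik <- function(k, f, fml, alpha) {
  theta <- 1 / max(alpha, 1e-8)
  fit <- suppressWarnings(glm(fml,
    family = MASS::negative.binomial(theta = theta),
    data = data.frame(k = k, f = f)
  ))
  as.numeric(logLik(fit))
}

#' NB likelihood-ratio test for nested factors
#'
#' Per gene, the fixed-dispersion NB log-likelihood is maximized under
#' the full factor (one mean per level, size factors as offsets) and the
#' nested reduced factor; the statistic \code{2 * delta logL} is referred
#' to a chi-square with (levels(full) - levels(reduced)) degrees of
#' freedom. The reported log2 fold-change is the level-vs-reference
#' fold-change of largest magnitude (reference = first level of
#' \code{full}).
#'
#' @inheritParams nbWaldTest
#' @param full,reduced factors over samples; \code{reduced} must be
#'   nested in \code{full}.
#' @return data.frame as [nbWaldTest()] with \code{test = "lrt"}.
#' @export
nbLRT <- function(counts, full, reduced = NULL, sizeFactors = NULL,
                  dispersions = NULL) {
  m <- countsOf(counts)
  full <- droplevels(as.factor(full))
  if (is.null(reduced)) reduced <- factor(rep("all", ncol(m)))
  reduced <- droplevels(as.factor(reduced))
  nest <- tapply(as.character(reduced), full, function(x) length(unique(x)))
  if (any(nest != 1L)) stop("reduced factor is not nested in full")
  df <- nlevels(full) - nlevels(reduced)
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(m)
  q <- sweep(m, 2, sizeFactors, "/")
  if (is.null(dispersions)) {
    dispersions <- moderateDispersions(
      estimateDispersionMoM(m, full, sizeFactors), rowMeans(q)
    )
  }
  ref <- levels(full)[1]
  lvl_means <- vapply(levels(full), function(l) {
    rowMeans(q[, full == l, drop = FALSE])
  }, numeric(nrow(m)))

  stat <- numeric(nrow(m))
  p <- rep(1, nrow(m))
  off <- log(sizeFactors)
  for (i in seq_len(if (df > 0L) nrow(m) else 0L)) {
    k <- m[i, ]
    if (all(k == 0)) {
      stat[i] <- 0
      p[i] <- 1
      next
    }
    llf <- nbLogLik(k, off, k ~ 0 + full + offset(f), dispersions[i])
    llr <- if (nlevels(reduced) == 1L) {
      nbLogLik(k, off, k ~ 1 + offset(f), dispersions[i])
    } else {
      nbLogLik(k, off, k ~ 0 + reduced + offset(f), dispersions[i])
    }
    stat[i] <- max(0, 2 * (llf - llr))
    p[i] <- pchisq(stat[i], df = df, lower.tail = FALSE)
  }

  eps <- FC_PSEUDOCOUNT
  lfc_all <- log2((lvl_means[, -1, drop = FALSE] + eps) /
    (lvl_means[, 1] + eps))
  pick <- max.col(abs(lfc_all), ties.method = "first")
  lfc <- lfc_all[cbind(seq_len(nrow(m)), pick)]
  lfc[rowSums(m) == 0] <- 0
  data.frame(
    gene_id = rownames(m), base_mean = rowMeans(q),
    log2fc = lfc, stat = stat, p = p, padj = bhAdjust(p),
    test = "lrt",
    contrast = paste0("full_vs_", ref),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving with the input; NaN/NA
#' p-values propagate.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- p.adjust(p, method = "BH")
  out[is.nan(p)] <- NaN
  out
}

#' Summarize differential-expression direction
#'
#' Counts significantly up- and down-regulated genes at an adjusted
#' p-value cutoff and reports their percentages — the headline
#' "modulated transcripts" arithmetic of a discovery run.
#'
#' @param de a DE result data.frame (from [nbWaldTest()] or [nbLRT()]).
#' @param padjMax adjusted-p threshold (strict, \code{padj < padjMax}).
#' @return List with \code{up}, \code{down}, \code{total}, \code{upPct},
#'   \code{downPct}.
#' @export
deDirectionSummary <- function(de, padjMax = 0.05) {
  sig <- !is.na(de$padj) & de$padj < padjMax
  up <- sum(sig & de$log2fc > 0)
  down <- sum(sig & de$log2fc < 0)
  total <- up + down
  list(
    up = up, down = down, total = total,
    upPct = if (total > 0) 100 * up / total else NA_real_,
    downPct = if (total > 0) 100 * down / total else NA_real_
  )
}
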