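# Candidate integration: Spearman lncRNA-PCG correlation, the cis
# genomic-window filter, cohort replication and the IFN signature score.

#' Spearman correlation with t-approximation p-value
#'
#' Ranks use average ties; the two-sided p-value comes from
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} with n - 2 degrees of
#' freedom (p = 0 when |rho| = 1). Constant input is flagged with an NA
#' coefficient.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return List with \code{rho} and \code{p}.
#' @examples
#' spearmanCor(1:5, c(1, 2, 3, 5, 4)) # rho = 0.9
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  if (sdPop(x) == 0 || sdPop(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- cor(x, y, method = "spearman")
  p <- spearmanP(rho, n)
  list(rho = rho, p = p)
}

spearmanP <- function(rho, n) {
  r <- pmin(pmax(rho, -1), 1)
  p <- ifelse(abs(r) >= 1, 0, {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    2 * pt(-abs(tt), df = n - 2)
  })
  p
}

#' All-pairs lncRNA x PCG Spearman correlation
#'
#' Computes Spearman rho for every lncRNA-PCG pair over matched samples
#' and keeps pairs with p at most \code{corrPMax} (both correlation
#' signs). Constant rows are dropped with a warning.
#'
#' @param lncExpr,pcgExpr expression matrices (genes x samples) with
#'   identical sample columns.
#' @param corrPMax p-value threshold (inclusive).
#' @return data.frame with lnc_id, pcg_id, rho, p.
#' @export
correlateLncPcg <- function(lncExpr, pcgExpr, corrPMax = 0.05) {
  if (ncol(lncExpr) != ncol(pcgExpr) ||
    !identical(colnames(lncExpr), colnames(pcgExpr))) {
    stop("sample columns of the two matrices do not match")
  }
  if (nrow(lncExpr) == 0L || nrow(pcgExpr) == 0L) {
    return(data.frame(
      lnc_id = character(), pcg_id = character(),
      rho = numeric(), p = numeric(), stringsAsFactors = FALSE
    ))
  }
  n <- ncol(lncExpr)
  dropConst <- function(m, what) {
    keep <- apply(m, 1, sdPop) > 0
    if (!all(keep)) {
      warning(sum(!keep), " constant ", what, " row(s) dropped")
    }
    m[keep, , drop = FALSE]
  }
  lncExpr <- dropConst(lncExpr, "lncRNA")
  pcgExpr <- dropConst(pcgExpr, "PCG")
  rho <- cor(t(lncExpr), t(pcgExpr), method = "spearman")
  p <- spearmanP(rho, n)
  keep <- which(p <= corrPMax, arr.ind = TRUE)
  out <- data.frame(
    lnc_id = rownames(rho)[keep[, 1]],
    pcg_id = colnames(rho)[keep[, 2]],
    rho = rho[keep], p = p[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$lnc_id, out$p), , drop = FALSE]
}

#' Cis lncRNA-PCG pairs within a genomic window
#'
#' Same-chromosome pairs whose gene-body gap is at most \code{window} bp
#' (inclusive; 0 when the bodies overlap). The gap is
#' \code{max(0, max(start_a, start_b) - min(end_a, end_b) - 1)} and
#' strand is ignored.
#'
#' @param lnc,pcg [GenomicRanges::GRanges] subsets of the annotation,
#'   named by gene id.
#' @param window window size in bp (default 150,000).
#' @return data.frame with lnc_id, pcg_id, gap.
#' @export
cisPairs <- function(lnc, pcg, window = 150000) {
  if (length(lnc) == 0L || length(pcg) == 0L) {
    return(data.frame(
      lnc_id = character(), pcg_id = character(),
      gap = numeric(), stringsAsFactors = FALSE
    ))
  }
  hits <- GenomicRanges::findOverlaps(lnc, pcg,
    maxgap = window,
    ignore.strand = TRUE
  )
  gap <- GenomicRanges::distance(
    lnc[S4Vectors::queryHits(hits)], pcg[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE
  )
  keep <- !is.na(gap) & gap <= window
  out <- data.frame(
    lnc_id = names(lnc)[S4Vectors::queryHits(hits)][keep],
    pcg_id = names(pcg)[S4Vectors::subjectHits(hits)][keep],
    gap = gap[keep], stringsAsFactors = FALSE
  )
  out <- out[out$lnc_id != out$pcg_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select candidate "IFN/viral" lncRNAs
#'
#' A lncRNA becomes a candidate when at least one protein-coding gene is
#' both significantly correlated with it and located in cis; the
#' supporting PCGs are attached.
#'
#' @param corr data.frame from [correlateLncPcg()].
#' @param cis data.frame from [cisPairs()].
#' @return data.frame with one row per candidate lncRNA: lnc_id,
#'   n_support, support_pcgs (comma-separated), best_rho, best_p,
#'   min_gap.
#' @export
selectIFNViralLncRNAs <- function(corr, cis) {
  sup <- merge(corr, cis, by = c("lnc_id", "pcg_id"))
  if (nrow(sup) == 0L) {
    return(data.frame(
      lnc_id = character(), n_support = integer(),
      support_pcgs = character(), best_rho = numeric(),
      best_p = numeric(), min_gap = numeric(), stringsAsFactors = FALSE
    ))
  }
  parts <- split(sup, sup$lnc_id)
  out <- do.call(rbind, lapply(parts, function(d) {
    b <- which.min(d$p)
    data.frame(
      lnc_id = d$lnc_id[1], n_support = nrow(d),
      support_pcgs = paste(d$pcg_id, collapse = ","),
      best_rho = d$rho[b], best_p = d$p[b], min_gap = min(d$gap),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Cohort replication filter
#'
#' A gene replicates when it is significantly up-regulated
#' (\code{log2fc >= log2fcMin} and \code{p <= pMax}, inclusive) in at
#' least \code{minGroups} case-vs-control contrasts. Down-regulation
#' never counts.
#'
#' @param deList named list of DE data.frames, one per case group
#'   (case vs control contrast).
#' @param log2fcMin,pMax thresholds (defaults 0.58 and 0.05).
#' @param minGroups minimal number of supporting contrasts (default 2).
#' @return Character vector of replicating gene ids.
#' @export
cohortReplicationFilter <- function(deList, log2fcMin = 0.58, pMax = 0.05,
                                    minGroups = 2L) {
  if (length(deList) < minGroups) {
    stop(
      "need at least ", minGroups, " case contrasts, got ",
      length(deList)
    )
  }
  hits <- lapply(deList, function(de) {
    de$gene_id[!is.na(de$p) & de$log2fc >= log2fcMin & de$p <= pMax]
  })
  tab <- table(unlist(hits, use.names = FALSE))
  sort(names(tab)[tab >= minGroups])
}

#' Per-sample interferon signature score
#'
#' For each signature gene, expression is standardized against the
#' healthy-control samples (\code{(x - HC mean) / HC sd}); the score is
#' the mean of these z-values over the signature genes. Missing genes
#' and genes with zero HC standard deviation are dropped with a warning.
#'
#' @param expr expression matrix (genes x samples), typically
#'   [vstCounts()] output.
#' @param ifnGenes signature gene ids (default: the six-gene panel
#'   IFI27, IFI44L, IFIT1, IFIT2, IFIT3, SERPING1).
#' @param hcSamples healthy-control sample ids (>= 2 required).
#' @return data.frame with sample_id and score.
#' @export
ifnScore <- function(expr,
                     ifnGenes = c(
                       "IFI27", "IFI44L", "IFIT1", "IFIT2",
                       "IFIT3", "SERPING1"
                     ),
                     hcSamples) {
  hcSamples <- intersect(hcSamples, colnames(expr))
  if (length(hcSamples) < 2L) stop("need at least 2 HC samples")
  present <- intersect(ifnGenes, rownames(expr))
  if (length(present) < length(ifnGenes)) {
    warning(
      "signature gene(s) missing from expression matrix: ",
      paste(setdiff(ifnGenes, present), collapse = ", ")
    )
  }
  if (!length(present)) stop("no signature genes present")
  x <- expr[present, , drop = FALSE]
  mu <- rowMeans(x[, hcSamples, drop = FALSE])
  s <- apply(x[, hcSamples, drop = FALSE], 1, sd)
  bad <- s == 0
  if (any(bad)) {
    warning(
      "zero HC standard deviation, gene(s) dropped: ",
      paste(present[bad], collapse = ", ")
    )
    x <- x[!bad, , drop = FALSE]
    mu <- mu[!bad]
    s <- s[!bad]
    if (!nrow(x)) stop("no usable signature genes")
  }
  z <- (x - mu) / s
  data.frame(
    sample_id = colnames(expr), score = colMeans(z),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Correlation of a lncRNA with the IFN score
#'
#' @param lncExpr named numeric vector of the candidate lncRNA's
#'   expression per sample.
#' @param scores data.frame from [ifnScore()].
#' @return List with \code{rho} and \code{p} (Spearman, t-approximation).
#' @export
scoreCorrelation <- function(lncExpr, scores) {
  common <- intersect(names(lncExpr), scores$sample_id)
  if (length(common) < length(scores$sample_id)) {
    stop("samples of lncExpr and scores do not match")
  }
  spearmanCor(
    lncExpr[common],
    scores$score[match(common, scores$sample_id)]
  )
}

#' Intersection lattice of DE gene sets
#'
#' For two or more gene sets (e.g. the modulated sets of independent
#' datasets) returns every set size, all pairwise intersection sizes and
#' the full intersection.
#'
#' @param sets named list of character vectors (>= 2).
#' @return List with \code{sizes} (named), \code{pairwise} (matrix of
#'   intersection sizes), \code{full} (gene ids common to all sets) and
#'   \code{fullSize}.
#' @export
intersectDESets <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  pw <- matrix(0L, length(sets), length(sets), dimnames = list(nm, nm))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    }
  }
  full <- Reduce(intersect, sets)
  list(
    sizes = lengths(sets), pairwise = pw,
    full = sort(full), fullSize = length(full)
  )
}
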