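# Signed weighted co-expression networks: soft-threshold adjacency,
# topological overlap, static-cut module detection, and cross-dataset
# module intersection for target nomination.

#' Signed weighted adjacency
#'
#' \code{a_ij = ((1 + cor(x_i, x_j)) / 2)^beta} with Pearson
#' correlation; anticorrelated genes get near-zero adjacency. The
#' diagonal is set to 0 so row sums are network connectivities.
#' Correlations involving constant genes are treated as 0.
#'
#' @param expr expression matrix (genes x samples, >= 4 samples).
#' @param beta soft-threshold power (>= 1).
#' @return Symmetric adjacency matrix in [0, 1] with zero diagonal.
#' @export
signedAdjacency <- function(expr, beta) {
  if (ncol(expr) < 4L) stop("need at least 4 samples")
  if (beta < 1) stop("beta must be >= 1")
  cc <- suppressWarnings(cor(t(expr)))
  cc[!is.finite(cc)] <- 0
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit
#'
#' Connectivities \code{k_i = sum_j a_ij} are binned; the R-squared of
#' the linear regression of log10 frequency on log10 mean connectivity
#' over the occupied bins measures how closely the degree distribution
#' follows a power law.
#'
#' @param adjacency adjacency matrix from [signedAdjacency()].
#' @param nBins number of connectivity bins.
#' @return R-squared in [0, 1].
#' @export
scaleFreeFit <- function(adjacency, nBins = 10L) {
  k <- rowSums(adjacency)
  br <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  freq <- as.numeric(table(bin)) / length(k)
  kmean <- tapply(k, bin, mean)
  ok <- freq > 0 & !is.na(kmean) & kmean > 0
  if (sum(ok) < 3L) stop("fewer than 3 occupied connectivity bins")
  x <- log10(kmean[ok])
  y <- log10(freq[ok])
  fit <- stats::lm(y ~ x)
  # summary.lm warns on an (intended) exactly collinear fit
  suppressWarnings(summary(fit)$r.squared)
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)} for
#' \code{i != j}, where \code{l_ij = sum_u a_iu a_uj} counts shared
#' neighbourhood strength; \code{TOM_ii = 1}.
#'
#' @param adjacency symmetric adjacency with zero diagonal, entries in
#'   [0, 1].
#' @return Symmetric TOM in [0, 1] with unit diagonal.
#' @export
topologicalOverlap <- function(adjacency) {
  if (max(abs(adjacency - t(adjacency))) > 1e-10) {
    stop("adjacency must be symmetric")
  }
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  k <- rowSums(adjacency)
  l <- adjacency %*% adjacency
  denom <- outer(k, k, pmin) + 1 - adjacency
  stopifnot(all(denom > 0))
  tom <- (l + adjacency) / denom
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2
  pmin(pmax(tom, 0), 1)
}

#' Detect modules by average-linkage clustering of 1 - TOM
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity,
#' cut statically at \code{cutHeight}; clusters smaller than
#' \code{minModuleSize} are unassigned (label 0). Labels are ordered by
#' decreasing module size (1 = largest).
#'
#' @param tom TOM matrix from [topologicalOverlap()].
#' @param minModuleSize minimum module size.
#' @param cutHeight static cut height on the dissimilarity.
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
detectModules <- function(tom, minModuleSize = 10L, cutHeight = 0.995) {
  d <- 1 - tom
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  cl <- cutree(hc, h = cutHeight)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= minModuleSize]
  ord <- big[order(-sizes[big], as.integer(big))]
  lab <- integer(length(cl))
  for (i in seq_along(ord)) lab[cl == as.integer(ord[i])] <- i
  setNames(lab, rownames(tom))
}

#' Build a co-expression network
#'
#' Convenience constructor running [signedAdjacency()],
#' [topologicalOverlap()] and [detectModules()].
#'
#' @inheritParams signedAdjacency
#' @inheritParams detectModules
#' @return A [CoexpressionNetwork-class].
#' @export
buildCoexpressionNetwork <- function(expr, beta, minModuleSize = 10L,
                                     cutHeight = 0.995) {
  a <- signedAdjacency(expr, beta)
  tom <- topologicalOverlap(a)
  labels <- detectModules(tom, minModuleSize, cutHeight)
  new("CoexpressionNetwork",
    geneIds = rownames(expr), beta = as.numeric(beta),
    adjacency = a, tom = tom, moduleLabels = unname(labels)
  )
}

#' Module of a query gene
#'
#' @param labels named module labels (as from [moduleLabels()] or
#'   [detectModules()]).
#' @param query gene id present in the network.
#' @return List with \code{assigned} (logical), \code{label} and
#'   \code{genes} (character vector of module members; empty when the
#'   query is unassigned — an explicit no-module result, not an error).
#' @export
moduleOf <- function(labels, query) {
  if (!query %in% names(labels)) stop("query gene not in network: ", query)
  lab <- labels[[query]]
  if (lab == 0L) {
    return(list(assigned = FALSE, label = 0L, genes = character()))
  }
  list(
    assigned = TRUE, label = lab,
    genes = names(labels)[labels == lab]
  )
}

#' Intersect two modules and split by biotype
#'
#' @param moduleA,moduleB character vectors of gene ids.
#' @param annotation annotation covering both sets (provides biotype).
#' @return A [ModuleIntersection-class]; the protein-coding part is the
#'   putative target set.
#' @export
intersectModules <- function(moduleA, moduleB, annotation) {
  common <- intersect(moduleA, moduleB)
  missing <- setdiff(common, annotation$gene_id)
  if (length(missing)) {
    stop(
      "gene(s) missing from annotation: ",
      paste(head(missing, 5), collapse = ", ")
    )
  }
  bt <- setNames(annotation$biotype, annotation$gene_id)
  pcg <- common[bt[common] == "protein_coding"]
  new("ModuleIntersection",
    moduleA = unique(moduleA), moduleB = unique(moduleB),
    common = common, commonPCG = pcg,
    commonNcRNA = setdiff(common, pcg)
  )
}

#' Nominate putative target genes
#'
#' The protein-coding genes common to both modules are reported with
#' their differential-expression status in each cohort contrast,
#' supporting the check that targets are up-regulated in at least one
#' case group.
#'
#' @param intersection a [ModuleIntersection-class].
#' @param deList named list of cohort DE data.frames (may be empty).
#' @param log2fcMin,pMax thresholds used for the per-contrast "up" flag.
#' @return data.frame with gene_id, one logical \code{up_<group>} column
#'   per contrast, and \code{up_in_any}.
#' @export
nominateTargets <- function(intersection, deList = list(),
                            log2fcMin = 0.58, pMax = 0.05) {
  genes <- commonPCG(intersection)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  if (!nrow(out)) {
    out$up_in_any <- logical()
    return(out)
  }
  flags <- matrix(FALSE, nrow(out), length(deList))
  for (j in seq_along(deList)) {
    de <- deList[[j]]
    i <- match(genes, de$gene_id)
    flags[, j] <- !is.na(i) & !is.na(de$p[i]) &
      de$log2fc[i] >= log2fcMin & de$p[i] <= pMax
    out[[paste0("up_", names(deList)[j])]] <- flags[, j]
  }
  out$up_in_any <- if (length(deList)) rowSums(flags) > 0 else NA
  out
}
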