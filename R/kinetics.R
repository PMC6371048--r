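# Kinetic classification of time-course profiles: z-score the
# per-timepoint mean profiles, K-means them, and label each cluster
# centroid early / early_transient / late by a rule on its changes from
# baseline.

#' Z-score per-timepoint expression profiles
#'
#' For each gene, the per-timepoint means of the expression values are
#' standardized to mean 0 and (population) standard deviation 1.
#' Zero-variance genes give an all-zero row and are flagged in the
#' \code{"constant"} attribute.
#'
#' @param expr expression matrix (genes x samples), typically
#'   [vstCounts()] output.
#' @param timepoints per-sample timepoint labels (length = ncol(expr)).
#' @return Matrix genes x timepoints (columns in order of first
#'   appearance), with a logical \code{"constant"} attribute.
#' @examples
#' zscoreProfiles(rbind(g = c(1, 2, 3)), timepoints = c("a", "b", "c"))
#' @export
zscoreProfiles <- function(expr, timepoints) {
  if (length(timepoints) != ncol(expr)) {
    stop("timepoints must label every sample")
  }
  tp <- factor(timepoints, levels = unique(timepoints))
  means <- vapply(levels(tp), function(l) {
    rowMeans(expr[, tp == l, drop = FALSE])
  }, numeric(nrow(expr)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1)
  dimnames(means) <- list(rownames(expr), levels(tp))
  ctr <- means - rowMeans(means)
  s <- sqrt(rowMeans(ctr^2))
  const <- s == 0
  z <- ctr / ifelse(const, 1, s)
  z[const, ] <- 0
  attr(z, "constant") <- setNames(const, rownames(expr))
  z
}

#' Seeded K-means clustering of z-scored profiles
#'
#' Lloyd's algorithm, best of \code{restarts} seeded initializations by
#' total within-cluster sum of squares; deterministic given the seed. An
#' initialization that produces an empty cluster is re-drawn.
#'
#' @param z z-scored profile matrix from [zscoreProfiles()].
#' @param k number of clusters (>= 2, <= nrow(z)).
#' @param seed integer seed.
#' @param restarts number of random initializations.
#' @return data.frame with gene_id and cluster; the cluster centroids
#'   matrix is attached as attribute \code{"centroids"}.
#' @export
kmeansProfiles <- function(z, k = 3L, seed = 1L, restarts = 10L) {
  if (k < 2L) stop("k must be at least 2")
  if (nrow(z) < k) stop("need at least k rows")
  best <- NULL
  attempt <- 0L
  done <- 0L
  while (done < restarts && attempt < restarts * 20L) {
    attempt <- attempt + 1L
    fit <- withSeed(seed + attempt, {
      centers <- z[sample(nrow(z), k), , drop = FALSE]
      tryCatch(
        suppressWarnings( # Lloyd convergence chatter; objective decides
          kmeans(z, centers = centers, iter.max = 100L, algorithm = "Lloyd")
        ),
        error = function(e) NULL # empty cluster: re-seed this restart
      )
    })
    if (is.null(fit)) next
    done <- done + 1L
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed to produce k non-empty clusters")
  out <- data.frame(
    gene_id = rownames(z), cluster = unname(best$cluster),
    stringsAsFactors = FALSE
  )
  attr(out, "centroids") <- best$centers
  out
}

#' Kinetic class of a centroid
#'
#' With baseline change \code{d1 = c(t1.5) - c(t0)} and \code{d2 =
#' c(t4) - c(t0)}: \emph{early} when the 1.5 h change is at least
#' \code{delta} and persists at 4 h (|d2| >= 0.75 |d1|, same sign);
#' \emph{early_transient} when the 1.5 h change has decayed by 4 h
#' (|d2| < 0.5 |d1|); \emph{late} when only the 4 h change reaches
#' \code{delta}; otherwise \emph{unclassified}.
#'
#' @param centroid numeric length-3 z-score vector over (t0, t1.5, t4).
#' @param delta minimal z-score change (default 0.5).
#' @return One of "early", "early_transient", "late", "unclassified".
#' @examples
#' assignKineticClass(c(-1, 0.5, 0.5)) # early
#' assignKineticClass(c(-0.5, 1.2, -0.7)) # early_transient
#' assignKineticClass(c(-0.6, -0.6, 1.2)) # late
#' @export
assignKineticClass <- function(centroid, delta = 0.5) {
  stopifnot(length(centroid) == 3L)
  d1 <- centroid[2] - centroid[1]
  d2 <- centroid[3] - centroid[1]
  if (abs(d1) >= delta) {
    if (abs(d2) >= 0.75 * abs(d1) && sign(d2) == sign(d1)) {
      return("early")
    }
    if (abs(d2) < 0.5 * abs(d1)) {
      return("early_transient")
    }
    return("unclassified")
  }
  if (abs(d2) >= delta) {
    return("late")
  }
  "unclassified"
}

#' Cluster time-course profiles and assign kinetic classes
#'
#' Convenience wrapper: z-scored profiles are K-means clustered and each
#' gene inherits the class of its cluster centroid via
#' [assignKineticClass()]. The direction (up/down) is reported
#' separately from the class, using the sign of the dominant change.
#'
#' @inheritParams kmeansProfiles
#' @param delta class-rule threshold, see [assignKineticClass()].
#' @return data.frame with gene_id, cluster, klass, direction and the
#'   three centroid coordinates.
#' @export
classifyKinetics <- function(z, k = 3L, seed = 1L, restarts = 10L,
                             delta = 0.5) {
  cl <- kmeansProfiles(z, k = k, seed = seed, restarts = restarts)
  cen <- attr(cl, "centroids")
  klass <- apply(cen, 1, assignKineticClass, delta = delta)
  dirn <- apply(cen, 1, function(ce) {
    d1 <- ce[2] - ce[1]
    d2 <- ce[3] - ce[1]
    if (abs(d1) >= delta) sign(d1) else sign(d2)
  })
  data.frame(
    gene_id = cl$gene_id, cluster = cl$cluster,
    klass = klass[cl$cluster], direction = dirn[cl$cluster],
    z_t0 = cen[cl$cluster, 1], z_t1 = cen[cl$cluster, 2],
    z_t2 = cen[cl$cluster, 3],
    row.names = NULL, stringsAsFactors = FALSE
  )
}
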