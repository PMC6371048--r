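# Synthetic-data generator.
#
# The generator lays out a small genome, plants stimulus effects with
# early / early-transient / late kinetics on a subset of lncRNAs and
# protein-coding genes, places a share of modulated lncRNAs in cis of a
# dedicated protein-coding partner, and defines an IFN-signature module
# tracked by one NRIR-like lncRNA. Counts are negative-binomial with
# mean mu and Var = mu + alpha * mu^2. All randomness flows from
# cfg@seed; fixed sub-seeds keep annotation, time course, cohort and
# term map independently reproducible.

KINETIC_CLASSES <- c("early", "early_transient", "late")

# fraction of planted effects that are up-regulated (mirrors the observed
# up/down balance of stimulus-modulated lncRNAs)
UP_FRACTION <- 0.7

# k(t): fraction of the planted log2FC active at time t (hours)
kineticTemplate <- function(class, t) {
  if (!class %in% KINETIC_CLASSES) {
    stop("invalid kinetic class template: ", class)
  }
  switch(class,
    early = as.numeric(t > 0),
    early_transient = as.numeric(t > 0 & t < 4),
    late = as.numeric(t >= 4)
  )
}

# Deterministic planted design shared by all generators.
plantDesign <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  withSeed(cfg@seed, {
    pcg_ids <- sprintf("PCG%04d", seq_len(cfg@nPCG))
    canonical <- c("IFI27", "IFI44L", "IFIT1", "IFIT2", "IFIT3", "SERPING1")
    nsig <- min(cfg@nSignatureGenes, cfg@nPCG)
    sig_ids <- if (nsig == 6L) canonical else sprintf("SIG%02d", seq_len(nsig))
    pcg_ids[seq_len(nsig)] <- sig_ids
    lnc_ids <- sprintf("LNC%04d", seq_len(cfg@nLnc))

    # noncoding decoys: pseudogenes and sub-200 bp transcripts must be
    # rejected by the lncRNA filter
    n_pseudo <- floor(0.10 * cfg@nLnc)
    n_short <- floor(0.05 * cfg@nLnc)
    nc_biotype <- sample(
      c("lincRNA", "antisense", "processed_transcript"),
      cfg@nLnc,
      replace = TRUE
    )
    decoy_idx <- sample(cfg@nLnc, n_pseudo + n_short)
    pseudo_idx <- head(decoy_idx, n_pseudo)
    short_idx <- setdiff(decoy_idx, pseudo_idx)
    nc_biotype[pseudo_idx] <- "pseudogene"

    lnc_len <- round(runif(cfg@nLnc, 300, 3000))
    lnc_len[short_idx] <- 150L
    pcg_len <- round(runif(cfg@nPCG, 1000, 8000))

    eligible <- lnc_ids[nc_biotype != "pseudogene" & lnc_len >= 200]
    n_mod <- round(cfg@fracLncModulated * length(eligible))
    mod_lnc <- sample(eligible, n_mod)
    lnc_sign <- ifelse(runif(n_mod) < UP_FRACTION, 1, -1)
    lnc_class <- sample(KINETIC_CLASSES, n_mod,
      replace = TRUE,
      prob = cfg@kineticClassProbs
    )
    names(lnc_sign) <- names(lnc_class) <- mod_lnc

    # cis pairs are planted on up-modulated lncRNAs: the discovery funnel
    # retains only up-regulated partner PCGs
    up_lnc <- mod_lnc[lnc_sign[mod_lnc] > 0]
    n_cis <- min(round(cfg@fracCisPaired * n_mod), length(up_lnc))
    cis_lnc <- if (n_cis > 0) sample(up_lnc, n_cis) else character()

    nrir <- if (length(cis_lnc)) {
      cis_lnc[1L]
    } else if (length(mod_lnc)) {
      mod_lnc[1L]
    } else if (length(eligible)) eligible[1L] else lnc_ids[1L]
    if (nrir %in% names(lnc_class)) {
      # the tracked lncRNA is a slow, IFN-dependent transcript
      lnc_class[nrir] <- "late"
      lnc_sign[nrir] <- 1
    }

    free_pcg <- setdiff(pcg_ids, sig_ids)
    partners <- if (n_cis > 0) sample(free_pcg, n_cis) else character()
    names(partners) <- cis_lnc
    cis_gap <- if (n_cis > 0) {
      round(runif(n_cis, cfg@cisGapRange[1], cfg@cisGapRange[2]))
    } else {
      numeric()
    }

    nrir_partner <- if (nrir %in% cis_lnc) partners[[nrir]] else character()
    pool <- setdiff(free_pcg, partners)
    # ISGs cluster genomically; the tracked lncRNA sits in such a cluster,
    # so it gets a second, upstream module gene in cis
    nrir_flank <- if (length(nrir_partner) && length(pool)) {
      sample(pool, 1)
    } else {
      character()
    }
    pool <- setdiff(pool, nrir_flank)
    if (length(nrir_flank)) {
      cis_lnc <- c(cis_lnc, nrir)
      partners <- c(partners, setNames(nrir_flank, nrir))
      cis_gap <- c(
        cis_gap, round(runif(1, cfg@cisGapRange[1], cfg@cisGapRange[2]))
      )
    }
    n_extra <- max(0L, cfg@plantedModuleSize - length(sig_ids) -
      length(nrir_partner) - length(nrir_flank))
    module <- c(
      sig_ids, nrir_partner, nrir_flank,
      sample(pool, min(n_extra, length(pool)))
    )

    # planted module shares the NRIR-like gene's kinetics in the time course
    pcg_class <- setNames(rep("late", length(module)), module)
    pcg_sign <- setNames(rep(1, length(module)), module)
    other_partners <- setdiff(partners, module)
    if (length(other_partners)) {
      pcg_class[other_partners] <- lnc_class[names(partners)[match(
        other_partners, partners
      )]]
      pcg_sign[other_partners] <- 1
    }
    rest <- setdiff(pcg_ids, c(module, partners))
    n_mod_pcg <- round(cfg@fracPCGModulated * cfg@nPCG)
    n_mod_pcg <- min(n_mod_pcg, length(rest))
    extra_pcg <- if (n_mod_pcg > 0) sample(rest, n_mod_pcg) else character()
    if (length(extra_pcg)) {
      pcg_class[extra_pcg] <- sample(KINETIC_CLASSES, length(extra_pcg),
        replace = TRUE, prob = cfg@kineticClassProbs
      )
      pcg_sign[extra_pcg] <- ifelse(runif(length(extra_pcg)) < UP_FRACTION, 1, -1)
    }

    low_pool <- setdiff(rest, extra_pcg)
    n_low <- min(round(cfg@lowExprFrac * cfg@nPCG), length(low_pool))
    low_pcg <- if (n_low > 0) sample(low_pool, n_low) else character()

    # relative expression weights; planted genes are kept well-expressed
    rel <- setNames(exp(rnorm(cfg@nPCG + cfg@nLnc, 0, 1.2)), c(pcg_ids, lnc_ids))
    hot <- c(module, partners, mod_lnc)
    rel[hot] <- exp(rnorm(length(hot), 1.2, 0.4))
    rel[low_pcg] <- rel[low_pcg] * 1e-4

    gene_id <- c(pcg_ids, lnc_ids)
    biotype <- c(rep("protein_coding", cfg@nPCG), nc_biotype)
    length_bp <- c(pcg_len, lnc_len)
    eff <- cfg@effectLog2FC
    lfc <- setNames(rep(0, length(gene_id)), gene_id)
    klass <- setNames(rep(NA_character_, length(gene_id)), gene_id)
    lfc[names(lnc_sign)] <- eff * lnc_sign
    klass[names(lnc_class)] <- lnc_class
    lfc[names(pcg_sign)] <- eff * pcg_sign
    klass[names(pcg_class)] <- pcg_class

    design <- data.frame(
      gene_id = gene_id, biotype = biotype, length = length_bp,
      rel_expr = rel[gene_id], log2fc = lfc[gene_id],
      class = klass[gene_id], stringsAsFactors = FALSE
    )
    rownames(design) <- gene_id

    list(
      design = design,
      cis = data.frame(
        lnc_id = cis_lnc, pcg_id = unname(partners),
        gap = cis_gap, stringsAsFactors = FALSE
      ),
      signature = sig_ids, nrir = nrir, module = module
    )
  })
}

placeGenes <- function(dsg, cfg) {
  withSeed(cfg@seed + 1000L, {
    design <- dsg$design
    # a placement unit is a chain of genes with fixed gene-body gaps:
    # (pcg, lnc) for a planted pair, (pcg2, lnc, pcg1) when the lncRNA
    # has partners on both sides, or a single gene
    units <- list()
    for (l in unique(dsg$cis$lnc_id)) {
      rows <- dsg$cis[dsg$cis$lnc_id == l, , drop = FALSE]
      if (nrow(rows) == 1L) {
        units[[length(units) + 1L]] <- list(
          genes = c(l, rows$pcg_id), gaps = rows$gap
        )
      } else {
        units[[length(units) + 1L]] <- list(
          genes = c(rows$pcg_id[2], l, rows$pcg_id[1]),
          gaps = c(rows$gap[2], rows$gap[1])
        )
      }
    }
    singles <- setdiff(design$gene_id, c(dsg$cis$lnc_id, dsg$cis$pcg_id))
    units <- c(units, lapply(singles, function(g) {
      list(genes = g, gaps = numeric())
    }))
    units <- units[sample(length(units))]
    chrom_of <- rep_len(seq_len(cfg@nChrom), length(units))

    out <- vector("list", length(units))
    cursor <- rep(0, cfg@nChrom)
    for (i in seq_along(units)) {
      u <- units[[i]]
      ch <- chrom_of[i]
      start <- cursor[ch] + round(runif(1, 2e4, 6e4))
      rows <- list()
      for (j in seq_along(u$genes)) {
        g <- u$genes[j]
        len <- design[g, "length"]
        end <- start + len - 1
        rows[[g]] <- data.frame(
          gene_id = g, chrom = paste0("chr", ch),
          start = start, end = end, stringsAsFactors = FALSE
        )
        if (j < length(u$genes)) start <- end + u$gaps[j] + 1
      }
      cursor[ch] <- max(vapply(rows, function(r) r$end, numeric(1)))
      if (cursor[ch] > cfg@chromLength) {
        stop(
          "capacity error: genes cannot be placed on ", cfg@nChrom,
          " chromosomes of length ", cfg@chromLength
        )
      }
      out[[i]] <- do.call(rbind, rows)
    }
    coords <- do.call(rbind, out)
    rownames(coords) <- coords$gene_id
    coords[design$gene_id, ]
  })
}

#' Generate a synthetic gene annotation
#'
#' Places protein-coding genes and noncoding genes (lincRNA, antisense,
#' processed_transcript, plus pseudogene and short-transcript decoys) on a
#' small genome. A configured share of up-modulated lncRNAs is planted
#' within \code{cisGapRange} bp of a dedicated protein-coding partner.
#' Coordinates are 1-based inclusive.
#'
#' @param cfg a [SimulationConfig-class].
#' @return A [GenomicRanges::GRanges] with metadata columns \code{gene_id},
#'   \code{biotype} and \code{transcript_length}, named by gene id.
#' @examples
#' ann <- generateAnnotation(simulationConfig(nPCG = 50, nLnc = 20, seed = 1))
#' table(ann$biotype)
#' @export
generateAnnotation <- function(cfg) {
  dsg <- plantDesign(cfg)
  coords <- placeGenes(dsg, cfg)
  strand <- withSeed(cfg@seed + 2000L, {
    sample(c("+", "-"), nrow(coords), replace = TRUE)
  })
  gr <- GenomicRanges::GRanges(
    seqnames = coords$chrom,
    ranges = IRanges::IRanges(start = coords$start, end = coords$end),
    strand = strand,
    gene_id = coords$gene_id,
    biotype = dsg$design$biotype,
    transcript_length = dsg$design$length
  )
  names(gr) <- coords$gene_id
  gr
}

groundTruthFromDesign <- function(dsg) {
  mg <- dsg$design[!is.na(dsg$design$class) & dsg$design$log2fc != 0,
    c("gene_id", "biotype", "log2fc", "class"),
    drop = FALSE
  ]
  rownames(mg) <- NULL
  new("GroundTruth",
    modulatedGenes = mg, cisPairs = dsg$cis,
    signatureGenes = dsg$signature, nrirLikeId = dsg$nrir,
    plantedModule = dsg$module
  )
}

checkAnnotationMatchesConfig <- function(annotation, dsg) {
  if (!setequal(names(annotation), dsg$design$gene_id)) {
    stop("annotation does not match the configuration's planted design")
  }
}

nbDraw <- function(mu, alpha) {
  n <- length(mu)
  if (alpha <= 0) stop("non-positive dispersion")
  matrix(rnbinom(n, mu = mu, size = 1 / alpha), nrow = nrow(mu),
    dimnames = dimnames(mu)
  )
}

#' Simulate a stimulation time course
#'
#' Draws negative-binomial counts for samples at t0, t1.5 and t4 (hours),
#' \code{repsPerTimepoint} replicates each. Planted genes have their mean
#' multiplied by \code{2^(log2FC * k(t) * eta_s)} where the kinetic
#' template k(t) is (0,1,1) for early, (0,1,0) for early-transient and
#' (0,0,1) for late genes, and \code{eta_s ~ Normal(1, responseSD^2)} is a
#' per-sample stimulation strength shared by every planted gene — the
#' pool-to-pool response variability that makes co-regulated genes
#' co-fluctuate across samples. Unmodulated genes are constant in
#' expectation. Library sizes are drawn log-uniformly over
#' \code{libSizeRange}.
#'
#' @param annotation annotation from [generateAnnotation()] (same config).
#' @param cfg the [SimulationConfig-class] used for the annotation.
#' @return A list with \code{se}, a
#'   [SummarizedExperiment::SummarizedExperiment] (assay \code{"counts"},
#'   colData columns \code{condition}, \code{timepoint}, \code{group}), and
#'   \code{truth}, the [GroundTruth-class].
#' @examples
#' cfg <- simulationConfig(nPCG = 40, nLnc = 20, seed = 7)
#' sim <- simulateTimecourse(generateAnnotation(cfg), cfg)
#' dim(SummarizedExperiment::assay(sim$se))
#' @export
simulateTimecourse <- function(annotation, cfg) {
  dsg <- plantDesign(cfg)
  checkAnnotationMatchesConfig(annotation, dsg)
  design <- dsg$design
  tps <- c(0, 1.5, 4)
  reps <- cfg@repsPerTimepoint
  sample_tp <- rep(tps, each = reps)
  sample_id <- sprintf("t%g_r%d", sample_tp, rep(seq_len(reps), times = 3))

  w <- design$rel_expr / sum(design$rel_expr)
  kmat <- vapply(tps, function(t) {
    k <- rep(0, nrow(design))
    has <- !is.na(design$class)
    k[has] <- vapply(design$class[has], kineticTemplate, numeric(1), t = t)
    k
  }, numeric(nrow(design)))

  withSeed(cfg@seed + 1L, {
    lib <- exp(runif(
      length(sample_id),
      log(cfg@libSizeRange[1]), log(cfg@libSizeRange[2])
    ))
    # shared per-sample stimulation strength: co-regulated planted genes
    # co-fluctuate through it
    eta <- rnorm(length(sample_id), mean = 1, sd = cfg@responseSD)
    kgs <- kmat[, match(sample_tp, tps)] # genes x samples
    expo <- sweep(design$log2fc * kgs, 2, eta, "*")
    mu <- (w * 2^expo) %*% diag(lib)
    dimnames(mu) <- list(design$gene_id, sample_id)
    counts <- nbDraw(mu, cfg@nbDispersion)
  })

  cd <- S4Vectors::DataFrame(
    sample = sample_id,
    condition = sprintf("t%g", sample_tp),
    timepoint = sample_tp,
    group = NA_character_,
    row.names = sample_id
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = cd
  )
  list(se = se, truth = groundTruthFromDesign(dsg))
}

#' Simulate a case/control cohort
#'
#' Each sample carries a latent IFN activity a ~ Normal(shift, 1): shift 0
#' in the control group \code{HC} and \code{caseShift} in case groups. The
#' signature genes, the planted module and the NRIR-like lncRNA have their
#' mean multiplied by \code{2^(signatureB * a)}, which builds in both the
#' lncRNA-score correlation and the co-expression structure the network
#' stage is meant to recover. All other genes are unaffected by group.
#'
#' @inheritParams simulateTimecourse
#' @return As [simulateTimecourse()]; colData column \code{group} holds the
#'   cohort group labels.
#' @export
simulateCohort <- function(annotation, cfg) {
  dsg <- plantDesign(cfg)
  checkAnnotationMatchesConfig(annotation, dsg)
  if (!"HC" %in% names(cfg@groups)) {
    stop("cfg@groups must contain a control group labelled 'HC'")
  }
  design <- dsg$design
  grp <- rep(names(cfg@groups), times = cfg@groups)
  sample_id <- unlist(lapply(names(cfg@groups), function(g) {
    sprintf("%s_%02d", g, seq_len(cfg@groups[[g]]))
  }), use.names = FALSE)

  b <- setNames(rep(0, nrow(design)), design$gene_id)
  linked <- unique(c(dsg$signature, dsg$module, dsg$nrir))
  b[linked] <- cfg@signatureB
  w <- design$rel_expr / sum(design$rel_expr)

  withSeed(cfg@seed + 2L, {
    lib <- exp(runif(
      length(sample_id),
      log(cfg@libSizeRange[1]), log(cfg@libSizeRange[2])
    ))
    a <- rnorm(length(sample_id), mean = ifelse(grp == "HC", 0, cfg@caseShift))
    mu <- outer(w, lib) * 2^(outer(b, a))
    dimnames(mu) <- list(design$gene_id, sample_id)
    counts <- nbDraw(mu, cfg@nbDispersion)
  })

  cd <- S4Vectors::DataFrame(
    sample = sample_id, condition = grp,
    timepoint = NA_real_, group = grp, row.names = sample_id
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd
  )
  list(se = se, truth = groundTruthFromDesign(dsg))
}

#' Generate a synthetic gene-set collection
#'
#' Emits one interferon-response term containing the planted signature and
#' module protein-coding genes, one antiviral term containing the cis
#' partner genes, and background terms of randomly drawn protein-coding
#' genes. The collection is GMT-serializable via [writeGMT()].
#'
#' @inheritParams simulateTimecourse
#' @param nBackground number of background terms (total terms >= 10).
#' @return A [TermMap-class].
#' @export
generateTermMap <- function(annotation, cfg, nBackground = 10L) {
  dsg <- plantDesign(cfg)
  checkAnnotationMatchesConfig(annotation, dsg)
  pcg <- dsg$design$gene_id[dsg$design$biotype == "protein_coding"]
  ifn <- unique(c(dsg$signature, intersect(dsg$module, pcg)))
  viral <- unique(c(dsg$cis$pcg_id, head(dsg$module, 5)))
  if (length(viral) < 2) viral <- unique(c(viral, head(ifn, 2)))
  bg_names <- c(
    "cell cycle", "ribosome biogenesis", "lipid metabolic process",
    "chromatin organization", "vesicle transport", "DNA repair",
    "translation", "apoptotic process", "cytoskeleton organization",
    "oxidative phosphorylation", "protein folding", "RNA splicing"
  )
  withSeed(cfg@seed + 3L, {
    gsets <- c(
      list(ifn, viral),
      lapply(seq_len(nBackground), function(i) {
        sample(pcg, min(sample(5:40, 1), length(pcg)))
      })
    )
    termMap(
      ids = sprintf("GO:SIM%04d", seq_along(gsets)),
      termNames = c(
        "response to type I interferon", "defense response to virus",
        rep_len(bg_names, nBackground)
      ),
      genes = gsets
    )
  })
}
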