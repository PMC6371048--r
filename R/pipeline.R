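# End-to-end orchestration: discovery on the stimulation time course,
# replication + IFN scoring on a cohort, and network-based target
# nomination. Each runner optionally writes its tables and a JSON run
# manifest so outputs are traceable to a config + seed.

cfgToList <- function(cfg) {
  sn <- slotNames(class(cfg))
  out <- lapply(sn, function(s) {
    v <- slot(cfg, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  names(out) <- sn
  out
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()]; missing keys take
#' the defaults. \code{betas} and \code{minModuleSize} may be given as
#' named mappings.
#'
#' @param path YAML file path.
#' @return A [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  do.call(pipelineConfig, y)
}

writeManifest <- function(outdir, cfg, stage, outputs, extra = list()) {
  man <- c(
    list(
      stage = stage,
      tool = "lncDiscover",
      version = as.character(utils::packageVersion("lncDiscover")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = cfg@seed,
      config = cfgToList(cfg),
      outputs = outputs,
      output_md5 = as.list(tools::md5sum(unlist(outputs)))
    ),
    extra
  )
  path <- file.path(outdir, paste0(stage, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

timeOrder <- function(se) {
  tp <- SummarizedExperiment::colData(se)$timepoint
  cond <- SummarizedExperiment::colData(se)$condition
  if (is.null(cond)) stop("colData must provide a 'condition' column")
  lev <- unique(cond[order(tp)])
  factor(cond, levels = lev)
}

#' Run the lncRNA discovery pipeline on a stimulation time course
#'
#' Executes the full funnel: lncRNA filter, likelihood-ratio test across
#' timepoints (padj < \code{padjMax}), kinetic classification of the
#' modulated lncRNAs, selection of expressed up-regulated protein-coding
#' genes (mean FPKM > \code{fpkmMin} in at least one condition),
#' hypergeometric enrichment and keyword selection of IFN/antiviral
#' terms, all-pairs Spearman correlation, the cis window filter, and the
#' final candidate selection. Gene counts surviving each stage are
#' logged and returned as the \code{funnel}.
#'
#' @param se time-course \code{SummarizedExperiment} (counts assay;
#'   colData columns \code{condition} and \code{timepoint} covering
#'   t0 / t1.5 / t4).
#' @param annotation gene annotation \code{GRanges}.
#' @param terms a [TermMap-class].
#' @param cfg a [PipelineConfig-class].
#' @param outdir optional directory for TSV outputs plus a run manifest.
#' @return List with \code{candidates}, \code{de}, \code{summary} (up /
#'   down counts of modulated lncRNAs), \code{kinetics},
#'   \code{enrichment}, \code{selectedTerms}, \code{ifnPCG},
#'   \code{corr}, \code{cis}, \code{funnel}, \code{vst} and
#'   \code{modulatedLnc}. An empty candidate set is a valid outcome.
#' @export
runDiscovery <- function(se, annotation, terms, cfg = pipelineConfig(),
                         outdir = NULL) {
  cond <- timeOrder(se)
  if (nlevels(cond) < 3L) {
    stop("time course must contain the three timepoints t0, t1.5 and t4")
  }
  m <- countsOf(se)
  sf <- sizeFactorsMedianRatio(m)
  vst <- vstCounts(m, sf)
  fpkm <- fpkmMatrix(m, annotation)

  lnc <- intersect(classifyLncRNA(annotation), rownames(m))
  pcg <- intersect(
    annotation$gene_id[annotation$biotype == "protein_coding"], rownames(m)
  )

  de <- nbLRT(m, full = cond, sizeFactors = sf)
  rownames(de) <- de$gene_id
  sig <- de$gene_id[!is.na(de$padj) & de$padj < cfg@padjMax]
  modLnc <- intersect(sig, lnc)
  lncSummary <- deDirectionSummary(de[lnc, ], cfg@padjMax)

  kin <- if (length(modLnc) >= cfg@kineticsK) {
    z <- zscoreProfiles(vst[modLnc, , drop = FALSE], as.character(cond))
    classifyKinetics(z,
      k = cfg@kineticsK, seed = cfg@seed,
      restarts = cfg@restarts, delta = cfg@kineticsDelta
    )
  } else {
    data.frame(
      gene_id = character(), cluster = integer(), klass = character(),
      direction = numeric(), stringsAsFactors = FALSE
    )
  }

  condMeanFpkm <- vapply(levels(cond), function(l) {
    rowMeans(fpkm[, cond == l, drop = FALSE])
  }, numeric(nrow(fpkm)))
  expressed <- rownames(fpkm)[apply(condMeanFpkm, 1, max) > cfg@fpkmMin]
  exprPcg <- intersect(expressed, pcg)
  upPcg <- intersect(
    de$gene_id[!is.na(de$padj) & de$padj < cfg@padjMax & de$log2fc > 0],
    exprPcg
  )

  enr <- if (length(upPcg)) {
    hypergeomEnrich(upPcg, exprPcg, terms)
  } else {
    NULL
  }
  selTerms <- if (!is.null(enr)) {
    selectResponseTerms(enr, cfg@keywords, cfg@fdrMax)
  } else {
    data.frame(term_id = character(), term_name = character())
  }
  ifnPcg <- if (nrow(selTerms)) {
    genesOfTerms(selTerms$term_id, terms, upPcg)
  } else {
    character()
  }

  corr <- correlateLncPcg(
    vst[modLnc, , drop = FALSE], vst[ifnPcg, , drop = FALSE], cfg@corrPMax
  )
  cis <- cisPairs(
    annotation[modLnc], annotation[ifnPcg], cfg@cisWindow
  )
  cand <- selectIFNViralLncRNAs(corr, cis)

  funnel <- c(
    genes = nrow(m), lncRNA = length(lnc),
    modulated_lncRNA = length(modLnc),
    up_expressed_PCG = length(upPcg),
    IFN_viral_PCG = length(ifnPcg),
    correlated_lnc = length(unique(corr$lnc_id)),
    candidates = nrow(cand)
  )
  message(
    "discovery funnel: ",
    paste(names(funnel), funnel, sep = "=", collapse = ", ")
  )

  res <- list(
    candidates = cand, de = de, summary = lncSummary, kinetics = kin,
    enrichment = enr, selectedTerms = selTerms, ifnPCG = ifnPcg,
    corr = corr, cis = cis, funnel = funnel, vst = vst,
    modulatedLnc = modLnc
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      de = file.path(outdir, "de_lrt.tsv"),
      kinetics = file.path(outdir, "kinetics.tsv"),
      candidates = file.path(outdir, "candidates.tsv")
    )
    writeTSV(de, paths$de)
    writeTSV(kin, paths$kinetics)
    writeTSV(cand, paths$candidates)
    if (!is.null(enr)) {
      paths$enrichment <- file.path(outdir, "enrichment.tsv")
      writeTSV(enr, paths$enrichment)
    }
    writeManifest(outdir, cfg, "discover", paths,
      extra = list(funnel = as.list(funnel))
    )
  }
  res
}

#' Replicate candidates in a case/control cohort
#'
#' Runs a Wald contrast of every case group against the healthy
#' controls, applies the replication filter (up-regulation with
#' \code{log2fc >= log2fcMin}, \code{p <= pMax} in at least
#' \code{minGroups} groups) to the candidate lncRNAs, computes the
#' per-sample IFN score, and correlates each candidate's expression with
#' it.
#'
#' @param se cohort \code{SummarizedExperiment} whose colData
#'   \code{group} column contains \code{"HC"} plus case groups.
#' @param candidates character vector of candidate lncRNA ids (or a
#'   discovery result list, whose \code{candidates$lnc_id} is used).
#' @param cfg a [PipelineConfig-class].
#' @param outdir optional output directory.
#' @return List with \code{report} (one row per candidate: replication
#'   flag, supporting group count, score correlation rho / p, and rank
#'   by |rho|), \code{deList}, \code{scores} and \code{replicated}.
#' @export
runCohort <- function(se, candidates, cfg = pipelineConfig(),
                      outdir = NULL) {
  if (is.list(candidates) && !is.null(candidates$candidates)) {
    candidates <- candidates$candidates$lnc_id
  }
  grp <- SummarizedExperiment::colData(se)$group
  if (is.null(grp) || !"HC" %in% grp) {
    stop("cohort colData must provide a 'group' column containing 'HC'")
  }
  caseGroups <- setdiff(unique(grp), "HC")
  if (length(caseGroups) < cfg@minGroups) {
    stop(
      "replication needs at least ", cfg@minGroups,
      " case groups; found ", length(caseGroups)
    )
  }
  m <- countsOf(se)
  sf <- sizeFactorsMedianRatio(m)
  vst <- vstCounts(m, sf)

  deList <- lapply(caseGroups, function(g) {
    nbWaldTest(m, grp, contrast = c("HC", g), sizeFactors = sf)
  })
  names(deList) <- caseGroups
  replicated <- cohortReplicationFilter(
    deList, cfg@log2fcMin, cfg@pMax, cfg@minGroups
  )

  hc <- colnames(m)[grp == "HC"]
  scores <- ifnScore(vst, cfg@ifnGenes, hc)

  present <- intersect(candidates, rownames(vst))
  if (length(present) < length(candidates)) {
    warning(
      length(candidates) - length(present),
      " candidate(s) absent from the cohort matrix"
    )
  }
  nUp <- vapply(present, function(g) {
    sum(vapply(deList, function(de) {
      i <- match(g, de$gene_id)
      !is.na(i) && !is.na(de$p[i]) && de$log2fc[i] >= cfg@log2fcMin &&
        de$p[i] <= cfg@pMax
    }, logical(1)))
  }, integer(1))
  sc <- lapply(present, function(g) {
    scoreCorrelation(setNames(vst[g, ], colnames(vst)), scores)
  })
  report <- data.frame(
    lnc_id = present,
    replicated = present %in% replicated,
    n_groups_up = nUp,
    rho = vapply(sc, `[[`, numeric(1), "rho"),
    p = vapply(sc, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  report$rank_by_abs_rho <- rank(-abs(report$rho),
    ties.method = "min",
    na.last = "keep"
  )
  report <- report[order(report$rank_by_abs_rho), , drop = FALSE]
  rownames(report) <- NULL

  res <- list(
    report = report, deList = deList, scores = scores,
    replicated = intersect(replicated, present), vst = vst
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      report = file.path(outdir, "cohort_report.tsv"),
      scores = file.path(outdir, "ifn_scores.tsv")
    )
    writeTSV(report, paths$report)
    writeTSV(scores, paths$scores)
    writeManifest(outdir, cfg, "cohort", paths)
  }
  res
}

#' Nominate targets from two co-expression networks
#'
#' Builds one signed network per dataset (powers from \code{cfg@betas}),
#' extracts the query gene's module in each, intersects the two modules
#' and reports the common protein-coding genes as putative targets,
#' annotated with their cohort DE status.
#'
#' @param tcExpr,cohortExpr expression matrices (genes x samples) for
#'   the time course and the cohort; both must contain the query gene.
#' @param query gene id (e.g. the NRIR-like lncRNA).
#' @param annotation annotation \code{GRanges} covering the genes.
#' @param cfg a [PipelineConfig-class].
#' @param deList optional cohort DE list for the target DE flags.
#' @param outdir optional output directory.
#' @return List with the two networks, the two query modules, the
#'   [ModuleIntersection-class] and the \code{targets} table; when the
#'   query is unassigned in a network, \code{assigned = FALSE} and a
#'   message names the dataset.
#' @export
runTargets <- function(tcExpr, cohortExpr, query, annotation,
                       cfg = pipelineConfig(), deList = list(),
                       outdir = NULL) {
  for (nm in c("timecourse", "cohort")) {
    mat <- if (nm == "timecourse") tcExpr else cohortExpr
    if (!query %in% rownames(mat)) {
      stop("query gene ", query, " absent from the ", nm, " dataset")
    }
  }
  netTc <- buildCoexpressionNetwork(
    tcExpr, cfg@betas[["timecourse"]],
    minModuleSize = cfg@minModuleSize[["timecourse"]],
    cutHeight = cfg@cutHeight
  )
  netCo <- buildCoexpressionNetwork(
    cohortExpr, cfg@betas[["cohort"]],
    minModuleSize = cfg@minModuleSize[["cohort"]],
    cutHeight = cfg@cutHeight
  )
  modTc <- moduleOf(moduleLabels(netTc), query)
  modCo <- moduleOf(moduleLabels(netCo), query)
  if (!modTc$assigned || !modCo$assigned) {
    nm <- c("timecourse", "cohort")[!c(modTc$assigned, modCo$assigned)]
    message(
      "query ", query, " is unassigned (label 0) in the ",
      paste(nm, collapse = " and "), " network; no module to intersect"
    )
    return(list(
      assigned = FALSE, networkTimecourse = netTc, networkCohort = netCo,
      moduleTimecourse = modTc, moduleCohort = modCo,
      intersection = NULL, targets = NULL
    ))
  }
  inter <- intersectModules(modTc$genes, modCo$genes, annotation)
  targets <- nominateTargets(inter, deList, cfg@log2fcMin, cfg@pMax)
  res <- list(
    assigned = TRUE, networkTimecourse = netTc, networkCohort = netCo,
    moduleTimecourse = modTc, moduleCohort = modCo,
    intersection = inter, targets = targets
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(targets = file.path(outdir, "targets.tsv"))
    writeTSV(targets, paths$targets)
    writeManifest(outdir, cfg, "targets", paths,
      extra = list(
        common_pcg = length(commonPCG(inter)),
        common_ncrna = length(commonNcRNA(inter))
      )
    )
  }
  res
}
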