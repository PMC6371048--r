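#' @import methods
#' @importFrom stats cor dist hclust cutree kmeans median p.adjust pchisq
#'   pnorm pt phyper quantile rnbinom rnorm rpois runif sd var logLik glm
#'   setNames as.dist offset
#' @importFrom utils head combn
NULL

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. The generator emulates the
#' two study designs the pipeline targets: an LPS-like stimulation time
#' course (t0 / 1.5 h / 4 h) of monocyte RNA-seq with planted lncRNA
#' kinetics and cis lncRNA-mRNA pairs, and a multi-group case/control
#' cohort in which a planted interferon (IFN) signature is tracked by an
#' NRIR-like lncRNA.
#'
#' @slot nPCG number of protein-coding genes.
#' @slot nLnc number of non-coding genes (a small share become pseudogene or
#'   short-transcript decoys that must fail the lncRNA filter).
#' @slot nChrom,chromLength number of chromosomes and their length (bp).
#' @slot fracLncModulated fraction of eligible lncRNAs with a planted effect.
#' @slot kineticClassProbs probabilities of the early / early_transient /
#'   late kinetic classes for planted genes; sums to 1.
#' @slot fracCisPaired fraction of up-modulated lncRNAs planted in cis
#'   (within \code{cisGapRange}) of a dedicated protein-coding partner.
#' @slot cisGapRange gene-body gap interval (bp) for planted cis pairs.
#' @slot nSignatureGenes size of the planted IFN signature (default 6).
#' @slot effectLog2FC planted |log2 fold-change| in the time course.
#' @slot nbDispersion negative-binomial dispersion alpha (Var = mu + alpha mu^2).
#' @slot libSizeRange library sizes are drawn log-uniformly over this range.
#' @slot repsPerTimepoint replicates per timepoint in the time course.
#' @slot responseSD standard deviation of the per-sample stimulation
#'   strength shared by all planted genes in the time course (relative to
#'   a mean strength of 1). Co-regulated genes co-fluctuate through this
#'   factor, which is what the correlation stage of the analysis assumes;
#'   0 disables it.
#' @slot fracPCGModulated fraction of protein-coding genes (outside the
#'   planted module) with a planted time-course effect.
#' @slot groups named integer vector of cohort group sizes; must contain
#'   a control group named \code{"HC"}.
#' @slot caseShift mean of the latent IFN activity in case groups (HC is 0).
#' @slot signatureB multiplicative log2 loading of signature/module genes on
#'   the latent activity.
#' @slot plantedModuleSize number of protein-coding genes co-regulated with
#'   the NRIR-like lncRNA (includes the signature genes).
#' @slot lowExprFrac fraction of protein-coding genes given near-zero
#'   expression so the FPKM filter has something to remove.
#' @slot seed integer seed from which all generator randomness flows.
#'
#' @seealso [simulationConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    nPCG = "integer", nLnc = "integer", nChrom = "integer",
    chromLength = "numeric", fracLncModulated = "numeric",
    kineticClassProbs = "numeric", fracCisPaired = "numeric",
    cisGapRange = "numeric", nSignatureGenes = "integer",
    effectLog2FC = "numeric", nbDispersion = "numeric",
    libSizeRange = "numeric", repsPerTimepoint = "integer",
    responseSD = "numeric",
    fracPCGModulated = "numeric", groups = "integer",
    caseShift = "numeric", signatureB = "numeric",
    plantedModuleSize = "integer", lowExprFrac = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  fr <- c(
    fracLncModulated = object@fracLncModulated,
    fracCisPaired = object@fracCisPaired,
    fracPCGModulated = object@fracPCGModulated,
    lowExprFrac = object@lowExprFrac
  )
  if (any(fr < 0 | fr > 1)) {
    msg <- c(msg, "all fractions must lie in [0, 1]")
  }
  if (length(object@kineticClassProbs) != 3L ||
    abs(sum(object@kineticClassProbs) - 1) > 1e-8 ||
    any(object@kineticClassProbs < 0)) {
    msg <- c(msg, "kineticClassProbs must be a non-negative 3-vector summing to 1")
  }
  if (object@nbDispersion <= 0) {
    msg <- c(msg, "nbDispersion must be > 0")
  }
  if (object@responseSD < 0) {
    msg <- c(msg, "responseSD must be non-negative")
  }
  if (length(object@cisGapRange) != 2L || any(object@cisGapRange < 0) ||
    diff(object@cisGapRange) < 0) {
    msg <- c(msg, "cisGapRange must be a non-decreasing non-negative interval")
  }
  if (length(object@libSizeRange) != 2L || any(object@libSizeRange <= 0) ||
    diff(object@libSizeRange) < 0) {
    msg <- c(msg, "libSizeRange must be a positive non-decreasing interval")
  }
  if (is.null(names(object@groups)) || any(object@groups < 1L)) {
    msg <- c(msg, "groups must be a named vector of positive sample counts")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults define the reference synthetic study: a 3-timepoint LPS-like
#' time course with 4 replicates per timepoint, a planted effect of
#' 2 log2 units, NB dispersion 0.1, and a 4-group cohort (HC plus three
#' case groups) whose latent IFN activity is shifted by 2 in cases.
#'
#' @param nPCG,nLnc,nChrom,chromLength gene counts and genome geometry.
#' @param fracLncModulated,kineticClassProbs,fracCisPaired,cisGapRange
#'   planted lncRNA structure.
#' @param nSignatureGenes,effectLog2FC,nbDispersion,libSizeRange,
#'   repsPerTimepoint,responseSD,fracPCGModulated,groups,caseShift,signatureB,
#'   plantedModuleSize,lowExprFrac,seed see the class documentation.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nPCG = 50, nLnc = 20, seed = 1)
#' @export
simulationConfig <- function(nPCG = 300L, nLnc = 150L, nChrom = 4L,
                             chromLength = 3e7,
                             fracLncModulated = 0.3,
                             kineticClassProbs = c(
                               early = 0.5,
                               early_transient = 0.25, late = 0.25
                             ),
                             fracCisPaired = 0.5,
                             cisGapRange = c(5e3, 1e5),
                             nSignatureGenes = 6L,
                             effectLog2FC = 2.0,
                             nbDispersion = 0.1,
                             libSizeRange = c(5e5, 1.5e6),
                             repsPerTimepoint = 4L,
                             responseSD = 0.25,
                             fracPCGModulated = 0.25,
                             groups = c(
                               HC = 20L, ncSSc = 20L,
                               lcSSc = 20L, dcSSc = 20L
                             ),
                             caseShift = 2.0,
                             signatureB = 1.0,
                             plantedModuleSize = 30L,
                             lowExprFrac = 0.15,
                             seed = 1L) {
  new("SimulationConfig",
    nPCG = as.integer(nPCG), nLnc = as.integer(nLnc),
    nChrom = as.integer(nChrom), chromLength = as.numeric(chromLength),
    fracLncModulated = fracLncModulated,
    kineticClassProbs = kineticClassProbs,
    fracCisPaired = fracCisPaired, cisGapRange = as.numeric(cisGapRange),
    nSignatureGenes = as.integer(nSignatureGenes),
    effectLog2FC = effectLog2FC, nbDispersion = nbDispersion,
    libSizeRange = as.numeric(libSizeRange),
    repsPerTimepoint = as.integer(repsPerTimepoint),
    responseSD = responseSD,
    fracPCGModulated = fracPCGModulated,
    groups = setNames(as.integer(groups), names(groups)),
    caseShift = caseShift, signatureB = signatureB,
    plantedModuleSize = as.integer(plantedModuleSize),
    lowExprFrac = lowExprFrac, seed = as.integer(seed)
  )
}

#' Ground truth of a simulation
#'
#' Records the planted structure of a synthetic dataset so recovery of the
#' analysis stages can be measured: which genes carry effects (with signed
#' log2FC and kinetic class), the planted cis lncRNA-mRNA pairs, the IFN
#' signature genes, the NRIR-like lncRNA tracking them, and the
#' protein-coding module co-regulated with it.
#'
#' @slot modulatedGenes data.frame with columns gene_id, biotype, log2fc,
#'   class.
#' @slot cisPairs data.frame with columns lnc_id, pcg_id, gap.
#' @slot signatureGenes,nrirLikeId,plantedModule character.
#' @export
setClass("GroundTruth",
  representation(
    modulatedGenes = "data.frame", cisPairs = "data.frame",
    signatureGenes = "character", nrirLikeId = "character",
    plantedModule = "character"
  )
)

setMethod("show", "GroundTruth", function(object) {
  cat(
    "GroundTruth:", nrow(object@modulatedGenes), "modulated genes,",
    nrow(object@cisPairs), "cis pairs,",
    length(object@plantedModule), "module genes; NRIR-like:",
    object@nrirLikeId, "\n"
  )
})

#' Gene-set collection (GMT-style term map)
#'
#' @slot ids unique term identifiers.
#' @slot termNames human-readable term names.
#' @slot genes list of character vectors of member gene ids (non-empty).
#' @export
setClass("TermMap",
  representation(ids = "character", termNames = "character", genes = "list")
)

setValidity("TermMap", function(object) {
  msg <- character()
  if (anyDuplicated(object@ids)) msg <- c(msg, "term ids must be unique")
  if (length(object@ids) != length(object@genes) ||
    length(object@ids) != length(object@termNames)) {
    msg <- c(msg, "ids, termNames and genes must be parallel")
  }
  if (any(lengths(object@genes) == 0L)) {
    msg <- c(msg, "term gene sets must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' @param ids,termNames,genes see the class slots.
#' @rdname TermMap-class
#' @export
termMap <- function(ids, termNames = ids, genes) {
  new("TermMap",
    ids = as.character(ids), termNames = as.character(termNames),
    genes = lapply(genes, as.character)
  )
}

#' @param x a \code{TermMap}.
#' @rdname TermMap-class
#' @export
setMethod("length", "TermMap", function(x) length(x@ids))

setMethod("show", "TermMap", function(object) {
  cat(
    "TermMap with", length(object@ids), "terms; median set size",
    stats::median(lengths(object@genes)), "\n"
  )
})

#' Pipeline configuration
#'
#' Holds the thresholds of the discovery and replication pipeline. The
#' defaults are the published conventions this pipeline reproduces:
#' |log2FC| >= 0.58 with p <= 0.05 for cohort contrasts, padj < 0.05 for
#' the time course, FPKM > 2 expression filter, +/-150 kb cis window,
#' Spearman p < 0.05, replication in >= 2 case groups, the six-gene IFN
#' score panel (IFI27, IFI44L, IFIT1, IFIT2, IFIT3, SERPING1), and
#' soft-threshold powers beta = 18 (time course) and beta = 13 (cohort).
#'
#' @slot cisWindow cis window in bp.
#' @slot log2fcMin,pMax,padjMax,fpkmMin,minGroups,corrPMax,fdrMax thresholds.
#' @slot ifnGenes signature gene ids used for the IFN score.
#' @slot keywords case-insensitive substrings selecting IFN/antiviral terms.
#' @slot betas named powers, \code{c(timecourse=, cohort=)}.
#' @slot kineticsK,kineticsDelta,restarts K-means and class-rule settings.
#' @slot minModuleSize named minimum module sizes per dataset.
#' @slot cutHeight static tree-cut height on 1 - TOM.
#' @slot seed seed for the pipeline's own randomness (K-means restarts).
#' @export
setClass("PipelineConfig",
  representation(
    cisWindow = "numeric", log2fcMin = "numeric", pMax = "numeric",
    padjMax = "numeric", fpkmMin = "numeric", minGroups = "integer",
    ifnGenes = "character", corrPMax = "numeric", fdrMax = "numeric",
    keywords = "character", betas = "numeric", kineticsK = "integer",
    kineticsDelta = "numeric", restarts = "integer",
    minModuleSize = "numeric", cutHeight = "numeric", seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  th <- c(
    object@cisWindow, object@log2fcMin, object@pMax, object@padjMax,
    object@fpkmMin, object@minGroups, object@corrPMax, object@fdrMax,
    object@betas, object@cutHeight
  )
  if (any(!is.finite(th)) || any(th <= 0)) {
    return("all thresholds must be positive and finite")
  }
  if (!all(c("timecourse", "cohort") %in% names(object@betas))) {
    return("betas must be named 'timecourse' and 'cohort'")
  }
  TRUE
})

#' Construct a pipeline configuration
#'
#' @param cisWindow,log2fcMin,pMax,padjMax,fpkmMin,minGroups,ifnGenes,
#'   corrPMax,fdrMax,keywords,betas,kineticsK,kineticsDelta,restarts,
#'   minModuleSize,cutHeight,seed see [PipelineConfig-class].
#' @return A validated [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' cfg@cisWindow
#' @export
pipelineConfig <- function(cisWindow = 150000, log2fcMin = 0.58,
                           pMax = 0.05, padjMax = 0.05, fpkmMin = 2,
                           minGroups = 2L,
                           ifnGenes = c(
                             "IFI27", "IFI44L", "IFIT1",
                             "IFIT2", "IFIT3", "SERPING1"
                           ),
                           corrPMax = 0.05, fdrMax = 0.05,
                           keywords = c(
                             "interferon", "type I IFN", "virus",
                             "viral", "defense response"
                           ),
                           betas = c(timecourse = 18, cohort = 13),
                           kineticsK = 6L, kineticsDelta = 0.5,
                           restarts = 10L,
                           minModuleSize = c(timecourse = 20, cohort = 10),
                           cutHeight = 0.995, seed = 1L) {
  new("PipelineConfig",
    cisWindow = cisWindow, log2fcMin = log2fcMin, pMax = pMax,
    padjMax = padjMax, fpkmMin = fpkmMin, minGroups = as.integer(minGroups),
    ifnGenes = ifnGenes, corrPMax = corrPMax, fdrMax = fdrMax,
    keywords = keywords, betas = betas, kineticsK = as.integer(kineticsK),
    kineticsDelta = kineticsDelta, restarts = as.integer(restarts),
    minModuleSize = minModuleSize, cutHeight = cutHeight,
    seed = as.integer(seed)
  )
}

#' Signed weighted co-expression network
#'
#' Container for one network: the signed adjacency at a soft-threshold
#' power beta, the topological overlap matrix (TOM), and module labels
#' from average-linkage clustering of 1 - TOM (label 0 = unassigned).
#'
#' @slot geneIds gene identifiers (row/column order of the matrices).
#' @slot beta soft-threshold power.
#' @slot adjacency symmetric matrix in [0,1], zero diagonal.
#' @slot tom symmetric matrix in [0,1], unit diagonal.
#' @slot moduleLabels named integer vector; 0 means unassigned.
#' @seealso [buildCoexpressionNetwork()]
#' @export
setClass("CoexpressionNetwork",
  representation(
    geneIds = "character", beta = "numeric", adjacency = "matrix",
    tom = "matrix", moduleLabels = "integer"
  )
)

setValidity("CoexpressionNetwork", function(object) {
  n <- length(object@geneIds)
  msg <- character()
  for (nm in c("adjacency", "tom")) {
    m <- slot(object, nm)
    if (!all(dim(m) == n)) msg <- c(msg, sprintf("%s must be %d x %d", nm, n, n))
    if (any(m < -1e-12 | m > 1 + 1e-12)) {
      msg <- c(msg, sprintf("%s entries must lie in [0, 1]", nm))
    }
    if (max(abs(m - t(m))) > 1e-8) msg <- c(msg, sprintf("%s must be symmetric", nm))
  }
  if (length(object@moduleLabels) != n) {
    msg <- c(msg, "moduleLabels must cover every gene")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CoexpressionNetwork", function(object) {
  nmod <- length(setdiff(unique(object@moduleLabels), 0L))
  cat(
    "CoexpressionNetwork:", length(object@geneIds), "genes, beta =",
    object@beta, ",", nmod, "modules (",
    sum(object@moduleLabels == 0L), "unassigned )\n"
  )
})

#' Intersection of two co-expression modules
#'
#' @slot moduleA,moduleB input gene sets.
#' @slot common their intersection, split by biotype into \code{commonPCG}
#'   (protein-coding) and \code{commonNcRNA} (everything else).
#' @slot commonPCG,commonNcRNA the biotype partition of \code{common}.
#' @export
setClass("ModuleIntersection",
  representation(
    moduleA = "character", moduleB = "character", common = "character",
    commonPCG = "character", commonNcRNA = "character"
  )
)

setValidity("ModuleIntersection", function(object) {
  msg <- character()
  if (!setequal(object@common, intersect(object@moduleA, object@moduleB))) {
    msg <- c(msg, "common must equal intersect(moduleA, moduleB)")
  }
  if (!setequal(union(object@commonPCG, object@commonNcRNA), object@common) ||
    length(intersect(object@commonPCG, object@commonNcRNA))) {
    msg <- c(msg, "commonPCG and commonNcRNA must partition common")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleIntersection", function(object) {
  cat(
    "ModuleIntersection:", length(object@common), "common transcripts (",
    length(object@commonPCG), "PCGs,", length(object@commonNcRNA),
    "ncRNAs )\n"
  )
})
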