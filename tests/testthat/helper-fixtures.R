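# Shared fixtures. Simulations are cached per session so several test
# files can reuse the same reference run without regenerating it.

.fixtures <- new.env(parent = emptyenv())

refConfig <- function(seed = 1L, ...) {
  simulationConfig(seed = seed, ...)
}

# default-condition simulation at a given seed: annotation, time course,
# cohort, term map
refSim <- function(seed = 1L) {
  key <- paste0("sim", seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- refConfig(seed)
    ann <- generateAnnotation(cfg)
    .fixtures[[key]] <- list(
      cfg = cfg, ann = ann,
      tc = simulateTimecourse(ann, cfg),
      cohort = simulateCohort(ann, cfg),
      terms = generateTermMap(ann, cfg)
    )
  }
  .fixtures[[key]]
}

# cached discovery run on the reference simulation
refDiscovery <- function(seed = 1L) {
  key <- paste0("disc", seed)
  if (is.null(.fixtures[[key]])) {
    s <- refSim(seed)
    .fixtures[[key]] <- suppressMessages(
      runDiscovery(s$tc$se, s$ann, s$terms, pipelineConfig())
    )
  }
  .fixtures[[key]]
}

# small annotation built by hand for unit tests of the annotation-driven
# operations
toyAnnotation <- function() {
  gr <- GenomicRanges::GRanges(
    seqnames = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    ranges = IRanges::IRanges(
      start = c(100000, 251000, 500000, 1000, 5000),
      end = c(101000, 260000, 502000, 3000, 9000)
    ),
    strand = c("+", "-", "+", "+", "-"),
    gene_id = c("lncA", "pcgB", "pcgC", "lncD", "pseudoE"),
    biotype = c(
      "lincRNA", "protein_coding", "protein_coding",
      "antisense", "pseudogene"
    ),
    transcript_length = c(500, 2000, 1500, 150, 2000)
  )
  names(gr) <- gr$gene_id
  gr
}

nbCountMatrix <- function(nGenes, groupSizes, mu, alpha, seed,
                          lfc = rep(0, nGenes)) {
  set.seed(seed)
  n <- sum(groupSizes)
  g <- rep(seq_along(groupSizes), groupSizes)
  m <- sapply(seq_len(n), function(s) {
    mus <- mu * 2^(lfc * (g[s] == 2))
    if (alpha > 0) rnbinom(nGenes, mu = mus, size = 1 / alpha) else rpois(nGenes, mus)
  })
  rownames(m) <- sprintf("g%04d", seq_len(nGenes))
  colnames(m) <- sprintf("s%02d", seq_len(n))
  list(counts = m, groups = paste0("grp", g))
}
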