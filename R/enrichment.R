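# Hypergeometric over-representation analysis and keyword selection of
# interferon / antiviral response terms.

#' Hypergeometric gene-set over-representation
#'
#' For each term, with universe size N, term size K (after intersecting
#' the term with the universe), query size n and overlap k, the one-sided
#' p-value is \code{P(X >= k)} for X hypergeometric. Terms with K = 0 are
#' skipped; FDR is Benjamini-Hochberg across the tested terms.
#'
#' @param query character vector of genes of interest (subset of the
#'   universe; genes outside it are dropped).
#' @param universe character vector of background genes.
#' @param terms a [TermMap-class].
#' @return data.frame with term_id, term_name, k, K, n, N, p, fdr,
#'   ordered by p.
#' @examples
#' tm <- termMap("t1", "toy", list(letters[1:5]))
#' hypergeomEnrich(letters[1:4], letters[1:10], tm)
#' @export
hypergeomEnrich <- function(query, universe, terms) {
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  if (!length(query)) stop("empty query")
  N <- length(universe)
  n <- length(query)
  tg <- lapply(terms@genes, intersect, universe)
  K <- lengths(tg)
  keep <- K > 0L
  k <- vapply(tg[keep], function(g) length(intersect(g, query)), integer(1))
  p <- phyper(k - 1L, K[keep], N - K[keep], n, lower.tail = FALSE)
  out <- data.frame(
    term_id = terms@ids[keep], term_name = terms@termNames[keep],
    k = k, K = K[keep], n = n, N = N, p = p, fdr = bhAdjust(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Select interferon / antiviral response terms
#'
#' Keeps significantly enriched terms (FDR at most \code{fdrMax}) whose
#' name matches any keyword case-insensitively. The default keywords
#' proxy the IFN-response and antiviral GO vocabulary.
#'
#' @param results data.frame from [hypergeomEnrich()].
#' @param keywords character vector of substrings.
#' @param fdrMax FDR threshold (inclusive).
#' @return The selected rows of \code{results}.
#' @export
selectResponseTerms <- function(results,
                                keywords = c(
                                  "interferon", "type I IFN", "virus",
                                  "viral", "defense response"
                                ),
                                fdrMax = 0.05) {
  hit <- Reduce(`|`, lapply(keywords, function(kw) {
    grepl(kw, results$term_name, ignore.case = TRUE, fixed = FALSE)
  }))
  results[results$fdr <= fdrMax & hit, , drop = FALSE]
}

#' Member genes of selected terms
#'
#' Union of the member genes of the given terms, intersected with a
#' restriction set (e.g. the up-regulated, expressed protein-coding
#' genes).
#'
#' @param termIds character vector of term ids.
#' @param terms a [TermMap-class] containing them.
#' @param restrict character vector to intersect with.
#' @return Character vector of gene ids.
#' @export
genesOfTerms <- function(termIds, terms, restrict) {
  missing <- setdiff(termIds, terms@ids)
  if (length(missing)) {
    stop("unknown term id(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(termIds, terms@ids)
  intersect(unique(unlist(terms@genes[idx], use.names = FALSE)), restrict)
}
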