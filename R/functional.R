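#' Gene-set enrichment by hypergeometric test with BH correction
#'
#' For each set, the overlap `k` between the query and the
#' universe-restricted set is tested against the upper hypergeometric tail;
#' p-values are Benjamini-Hochberg adjusted across sets and a set is kept
#' iff its FDR is at most `maxFdr`.
#'
#' @param query character vector of genes (subset of `universe`).
#' @param sets named list of gene sets (intersected with the universe).
#' @param universe character vector, the gene population.
#' @param maxFdr FDR threshold (default 0.05).
#' @return data.frame `set_name`, `k`, `K`, `n`, `N`, `p`, `fdr`, `kept`,
#'   ordered by p.
#' @export
genesetEnrichment <- function(query, sets, universe, maxFdr = 0.05) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(query, s))
    data.frame(set_name = nm, k = k, K = length(s), n = n, N = N,
               p = hyperEnrichment(k, length(s), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out$kept <- out$fdr <= maxFdr
  out[order(out$p, out$set_name), , drop = FALSE]
}

#' Cancer-hallmark change percentages
#'
#' Per hallmark gene set, the percentage of member genes with (i) a
#' promoter state transition, (ii) an assigned gained or lost enhancer,
#' (iii) differential expression. Denominator = hallmark set size.
#'
#' @param hallmarkSets named list of gene sets (non-empty).
#' @param promoterChanged genes with an off-diagonal state transition.
#' @param enhancerChanged genes with >= 1 assigned gained/lost enhancer.
#' @param degs differentially expressed genes.
#' @return data.frame `hallmark`, `n_genes`, `pct_promoter_changed`,
#'   `pct_enhancer_changed`, `pct_expression_changed`.
#' @export
hallmarkPercentages <- function(hallmarkSets, promoterChanged,
                                enhancerChanged, degs) {
  rows <- lapply(names(hallmarkSets), function(nm) {
    s <- unique(hallmarkSets[[nm]])
    if (!length(s)) stop("empty hallmark set: ", nm)
    pct <- function(changed) 100 * length(intersect(s, changed)) / length(s)
    data.frame(hallmark = nm, n_genes = length(s),
               pct_promoter_changed = pct(promoterChanged),
               pct_enhancer_changed = pct(enhancerChanged),
               pct_expression_changed = pct(degs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
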