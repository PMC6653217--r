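#' Call distal enhancers
#'
#' Keeps H3K27ac peaks whose distance from every TSS, measured from the
#' nearest peak edge, is at least `distalMinBp` (the ">= rule": a peak edge
#' exactly at the threshold is kept).
#'
#' @param peaks H3K27ac peak GRanges.
#' @param genes gene GRanges with 0-based `tss`.
#' @param distalMinBp minimum TSS distance (default 2000).
#' @return the distal subset of `peaks`, with a `distanceToTss` column.
#' @export
callDistalEnhancers <- function(peaks, genes, distalMinBp = 2000) {
  if (!length(peaks)) return(peaks)
  tss <- sort(S4Vectors::mcols(genes)$tss)
  s0 <- GenomicRanges::start(peaks) - 1
  e0 <- GenomicRanges::end(peaks)
  # distance from interval [s0, e0) to the nearest TSS position
  d <- vapply(seq_along(peaks), function(i) {
    dd <- ifelse(tss < s0[i], s0[i] - tss,
                 ifelse(tss >= e0[i], tss - e0[i] + 1, 0))
    min(dd)
  }, numeric(1))
  out <- peaks[d >= distalMinBp]
  S4Vectors::mcols(out)$distanceToTss <- d[d >= distalMinBp]
  out
}

#' Scaled-Poisson differential tag-count test
#'
#' Counts are scaled to a common library size (tags per 10 M), a +1
#' pseudocount is applied, and the ratio reported as
#' `(scaled_b + 1)/(scaled_a + 1)`. The p-value is the upper-tail Poisson
#' probability of observing the larger scaled count (or more) under a rate
#' equal to the smaller scaled count + 1. Symmetric in the two cells:
#' swapping them inverts the ratio and leaves p unchanged.
#'
#' @param tagA,tagB raw tag counts (vectorized, >= 0).
#' @param libA,libB library sizes (> 0).
#' @param scaleTo common library size to scale to (default 1e7).
#' @return data.frame `scaled_a`, `scaled_b`, `log2_ratio`, `p`.
#' @export
poissonDiffTest <- function(tagA, tagB, libA, libB, scaleTo = 1e7) {
  if (any(tagA < 0) || any(tagB < 0)) stop("negative tag counts")
  stopIfNot(all(libA > 0) && all(libB > 0), "library sizes must be > 0")
  sa <- round(tagA * scaleTo / libA)
  sb <- round(tagB * scaleTo / libB)
  hi <- pmax(sa, sb)
  lo <- pmin(sa, sb)
  # P(Pois(lo + 1) >= hi); 1 when the counts are equal
  p <- ifelse(hi == lo, 1, ppois(hi - 1, lo + 1, lower.tail = FALSE))
  data.frame(scaled_a = sa, scaled_b = sb,
             log2_ratio = log2((sb + 1) / (sa + 1)), p = p)
}

#' Merge per-cell enhancer calls into a common testing universe
#'
#' Single-linkage merge of overlapping (or touching) enhancer intervals
#' from the two cells, with per-cell tag counts summed over each cell's
#' peaks intersecting every merged region.
#'
#' @param enhA,enhB distal enhancer GRanges per cell with `tagCount`.
#' @return GRanges of union regions with `tag_a` and `tag_b`.
#' @export
enhancerUnion <- function(enhA, enhB) {
  all <- c(GenomicRanges::granges(enhA), GenomicRanges::granges(enhB))
  if (!length(all)) {
    u <- GenomicRanges::GRanges()
    S4Vectors::mcols(u) <- S4Vectors::DataFrame(tag_a = numeric(),
                                                tag_b = numeric())
    return(u)
  }
  u <- GenomicRanges::reduce(all, ignore.strand = TRUE)
  sumTags <- function(enh) {
    v <- rep(0, length(u))
    if (length(enh)) {
      h <- GenomicRanges::findOverlaps(u, enh)
      if (length(h))
        v <- as.numeric(tapply(
          S4Vectors::mcols(enh)$tagCount[S4Vectors::subjectHits(h)],
          factor(S4Vectors::queryHits(h), seq_along(u)), sum, default = 0))
    }
    v
  }
  S4Vectors::mcols(u)$tag_a <- sumTags(enhA)
  S4Vectors::mcols(u)$tag_b <- sumTags(enhB)
  u
}

#' Classify gained, lost and stable enhancers
#'
#' A union enhancer is gained iff its B:A scaled ratio is at least
#' `minFold` with `p < maxP`, lost iff the ratio is at most `1/minFold`
#' with `p < maxP`, and stable otherwise; the three statuses partition the
#' union.
#'
#' @param union GRanges from [enhancerUnion()] with `tag_a`, `tag_b`.
#' @param libA,libB per-cell library sizes.
#' @param minFold fold-change threshold (default 4).
#' @param maxP p-value threshold (default 1e-4).
#' @param genes optional gene GRanges; when given, each enhancer is
#'   annotated with its nearest gene (midpoint-to-TSS).
#' @return GRanges with `log2_ratio`, `p`, `status` and (optionally)
#'   `nearestGene`, `distanceToTss`.
#' @export
classifyEnhancerChanges <- function(union, libA = 1e7, libB = 1e7,
                                    minFold = 4, maxP = 1e-4,
                                    genes = NULL) {
  mc <- S4Vectors::mcols(union)
  t <- poissonDiffTest(mc$tag_a, mc$tag_b, libA, libB)
  ratio <- 2^t$log2_ratio
  status <- ifelse(ratio >= minFold & t$p < maxP, "gained",
                   ifelse(ratio <= 1 / minFold & t$p < maxP, "lost",
                          "stable"))
  S4Vectors::mcols(union)$log2_ratio <- t$log2_ratio
  S4Vectors::mcols(union)$p <- t$p
  S4Vectors::mcols(union)$status <- status
  if (!is.null(genes) && length(union)) {
    ng <- nearestGene(union, genes)
    S4Vectors::mcols(union)$nearestGene <- ng$gene_id
    S4Vectors::mcols(union)$distanceToTss <- ng$distance
  }
  union
}

#' Nearest gene by midpoint-to-TSS distance
#'
#' The gene minimizing the distance from the interval midpoint to its TSS;
#' ties go to the lexicographically smallest gene id.
#'
#' @param intervals GRanges.
#' @param genes gene GRanges with `gene_id` and 0-based `tss`.
#' @return data.frame `gene_id`, `distance` (one row per interval).
#' @export
nearestGene <- function(intervals, genes) {
  if (!length(genes)) stop("no genes available for nearest-gene assignment")
  gid <- S4Vectors::mcols(genes)$gene_id
  ord <- order(gid)
  tss <- S4Vectors::mcols(genes)$tss[ord]
  gid <- gid[ord]
  mids <- mid0(intervals)
  idx <- vapply(mids, function(m) {
    d <- abs(tss - m)
    which.min(d)  # first minimum = smallest gene_id after the sort
  }, integer(1))
  data.frame(gene_id = gid[idx], distance = abs(tss[idx] - mids),
             stringsAsFactors = FALSE)
}

#' Promoter x enhancer x expression synergy table
#'
#' Joins each differentially expressed gene to its promoter state
#' transition and the status of its assigned enhancers (gained beats lost
#' beats stable; "none" when no enhancer is assigned), and reports the
#' mean log2 fold change per combined class.
#'
#' @param transitions data.frame `gene_id`, `state_a`, `state_b`.
#' @param enhancers classified enhancer GRanges with `status` and
#'   `nearestGene`.
#' @param degs DEG data.frame (from [filterDegs()]) with `gene_id`, `fc`.
#' @return list with `records` (per-gene data.frame `gene_id`,
#'   `transition`, `enhancer_status`, `log2fc`, `class`) and `classMeans`
#'   (data.frame `class`, `n`, `mean_log2fc`).
#' @export
synergyTable <- function(transitions, enhancers, degs) {
  mc <- S4Vectors::mcols(enhancers)
  status <- vapply(degs$gene_id, function(g) {
    st <- mc$status[mc$nearestGene == g]
    if ("gained" %in% st) "gained"
    else if ("lost" %in% st) "lost"
    else if (length(st)) "stable"
    else "none"
  }, "")
  tr <- transitions[match(degs$gene_id, transitions$gene_id), ]
  transition <- paste0(tr$state_a, ">", tr$state_b)
  records <- data.frame(gene_id = degs$gene_id, transition = transition,
                        enhancer_status = status,
                        log2fc = log2(degs$fc),
                        class = paste0("P:", transition, " & E:", status),
                        stringsAsFactors = FALSE)
  cm <- aggregate(log2fc ~ class, records, mean)
  cm$n <- as.integer(table(records$class)[cm$class])
  list(records = records,
       classMeans = cm[c("class", "n", "log2fc")] |>
         setNames(c("class", "n", "mean_log2fc")))
}
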