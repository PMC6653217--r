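#' Define promoter windows
#'
#' TSS +/- `halfwidthBp`, i.e. the 0-based half-open interval
#' `[tss - halfwidth, tss + halfwidth)`, clipped at the chromosome edges.
#'
#' @param genes gene GRanges with 0-based `tss` metadata.
#' @param halfwidthBp promoter half-width (default 2000).
#' @param chromLength optional chromosome length for right-edge clipping.
#' @return GRanges of promoter windows, carrying `gene_id`.
#' @export
definePromoters <- function(genes, halfwidthBp = 2000, chromLength = NULL) {
  stopIfNot(halfwidthBp > 0, "halfwidthBp must be > 0")
  tss <- S4Vectors::mcols(genes)$tss
  s0 <- pmax(tss - halfwidthBp, 0)
  e0 <- tss + halfwidthBp
  if (!is.null(chromLength)) e0 <- pmin(e0, chromLength)
  w <- grFromBed0(as.character(GenomicRanges::seqnames(genes)), s0, e0)
  S4Vectors::mcols(w)$gene_id <- S4Vectors::mcols(genes)$gene_id
  names(w) <- S4Vectors::mcols(genes)$gene_id
  w
}

#' Mark enrichment of promoter windows
#'
#' A window is enriched for a mark iff the total overlap with that mark's
#' peaks is at least `minOverlapBp` and the normalized tag density over the
#' window is at least `minDensity`. Density is the overlap-weighted tag
#' count per kilobase of window per million library tags. Overlapping
#' windows share peaks independently; no peak is consumed.
#'
#' @param windows promoter GRanges from [definePromoters()].
#' @param peaks GRanges of a single mark and cell with `tagCount`.
#' @param librarySize library size for density normalization.
#' @param minOverlapBp minimum total overlap (default 1).
#' @param minDensity minimum normalized density (default 0, making peak
#'   presence the criterion).
#' @return data.frame `gene_id`, `overlap_bp`, `density`, `enriched`.
#' @export
markEnrichment <- function(windows, peaks, librarySize = 1e7,
                           minOverlapBp = 1, minDensity = 0) {
  hits <- GenomicRanges::findOverlaps(windows, peaks)
  ovw <- rep(0, length(windows))
  tagw <- rep(0, length(windows))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    inter <- IRanges::pintersect(GenomicRanges::ranges(windows)[qh],
                                 GenomicRanges::ranges(peaks)[sh])
    w <- IRanges::width(inter)
    frac <- w / GenomicRanges::width(peaks)[sh]
    tc <- S4Vectors::mcols(peaks)$tagCount[sh] * frac
    ovw <- as.numeric(tapply(w, factor(qh, seq_along(windows)), sum,
                             default = 0))
    tagw <- as.numeric(tapply(tc, factor(qh, seq_along(windows)), sum,
                              default = 0))
  }
  dens <- tagw / ((GenomicRanges::width(windows) / 1000) *
                    (librarySize / 1e6))
  data.frame(gene_id = S4Vectors::mcols(windows)$gene_id,
             overlap_bp = ovw, density = dens,
             enriched = ovw >= minOverlapBp & dens >= minDensity,
             stringsAsFactors = FALSE)
}

#' Classify a promoter chromatin state
#'
#' Total deterministic rule over the three marks: Active iff an active
#' mark (H3K4me3 or H3K27ac) is enriched and H3K27me3 is not; Poised iff
#' an active mark and H3K27me3 are both enriched; Repressive iff only
#' H3K27me3 is enriched; None otherwise.
#'
#' @param k4me3,k27ac,k27me3 logical enrichment flags (vectorized).
#' @return character vector of states.
#' @export
classifyPromoterState <- function(k4me3, k27ac, k27me3) {
  act <- k4me3 | k27ac
  ifelse(act & !k27me3, "Active",
         ifelse(act & k27me3, "Poised",
                ifelse(k27me3, "Repressive", "None")))
}

#' Promoter states for one cell
#'
#' Computes per-mark enrichment over promoter windows and applies
#' [classifyPromoterState()].
#'
#' @param windows promoter GRanges.
#' @param peaks peak GRanges (any marks/cells; filtered by `cell`).
#' @param cell condition label to use.
#' @param librarySize library size for density normalization.
#' @param minOverlapBp,minDensity enrichment thresholds.
#' @return data.frame `gene_id`, per-mark enrichment flags and densities,
#'   `state`.
#' @export
promoterStatesForCell <- function(windows, peaks, cell, librarySize = 1e7,
                                  minOverlapBp = 1, minDensity = 0) {
  mc <- S4Vectors::mcols(peaks)
  enr <- lapply(c(H3K4me3 = "H3K4me3", H3K27ac = "H3K27ac",
                  H3K27me3 = "H3K27me3"), function(mk)
    markEnrichment(windows, peaks[mc$cell == cell & mc$mark == mk],
                   librarySize, minOverlapBp, minDensity))
  data.frame(gene_id = enr$H3K4me3$gene_id,
             k4me3 = enr$H3K4me3$enriched,
             k27ac = enr$H3K27ac$enriched,
             k27me3 = enr$H3K27me3$enriched,
             density_k4me3 = enr$H3K4me3$density,
             density_k27ac = enr$H3K27ac$density,
             density_k27me3 = enr$H3K27me3$density,
             state = classifyPromoterState(enr$H3K4me3$enriched,
                                           enr$H3K27ac$enriched,
                                           enr$H3K27me3$enriched),
             stringsAsFactors = FALSE)
}

#' Tabulate promoter state transitions and mean expression fold change
#'
#' Builds the 4x4 transition matrix between the two cells and the mean
#' log2 expression fold change of the member genes of every cell.
#'
#' @param statesA,statesB named character vectors (gene -> state) over the
#'   same gene universe, or data.frames with `gene_id` and `state`.
#' @param expr expression data.frame with `gene_id` and `fc`.
#' @return a [TransitionSummary-class] object.
#' @export
transitionSummary <- function(statesA, statesB, expr) {
  if (is.data.frame(statesA)) statesA <- setNames(statesA$state, statesA$gene_id)
  if (is.data.frame(statesB)) statesB <- setNames(statesB$state, statesB$gene_id)
  if (!setequal(names(statesA), names(statesB)))
    stop("statesA and statesB cover different gene universes")
  genes <- names(statesA)
  statesB <- statesB[genes]
  lv <- promoterStateLevels()
  fa <- factor(statesA, lv)
  fb <- factor(statesB, lv)
  counts <- table(fa, fb)
  counts <- matrix(as.integer(counts), 4, 4, dimnames = list(lv, lv))
  lfc <- setNames(log2(expr$fc), expr$gene_id)[genes]
  meanM <- matrix(NA_real_, 4, 4, dimnames = list(lv, lv))
  geneM <- matrix(list(), 4, 4, dimnames = list(lv, lv))
  for (a in lv) for (b in lv) {
    members <- genes[statesA == a & statesB == b]
    geneM[[a, b]] <- members
    if (length(members)) meanM[a, b] <- mean(lfc[members], na.rm = TRUE)
  }
  new("TransitionSummary", counts = counts, meanLog2Fc = meanM,
      genes = geneM)
}
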