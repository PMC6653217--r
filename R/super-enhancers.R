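#' Stitch peaks into candidate super-enhancer regions
#'
#' Single-linkage merge of peaks whose gap is at most `stitchBp` on the
#' same chromosome. Peaks lying fully inside a TSS +/- `tssExclusionBp`
#' window are excluded before stitching (set `tssExclusionBp = 0` or
#' `genes = NULL` to disable). Region signal is the sum of constituent tag
#' counts.
#'
#' @param peaks H3K27ac peak GRanges with `tagCount`.
#' @param stitchBp maximum gap merged across (default 12500).
#' @param tssExclusionBp promoter-exclusion half-width (default 2000).
#' @param genes gene GRanges with `tss` (needed for the exclusion).
#' @return GRanges of stitched regions with `nConstituents` and `signal`,
#'   sorted by position.
#' @export
stitchPeaks <- function(peaks, stitchBp = 12500, tssExclusionBp = 2000,
                        genes = NULL) {
  if (!is.null(genes) && tssExclusionBp > 0 && length(peaks)) {
    tss <- S4Vectors::mcols(genes)$tss
    tssWin <- grFromBed0(as.character(GenomicRanges::seqnames(genes)),
                         pmax(tss - tssExclusionBp, 0),
                         tss + tssExclusionBp)
    inside <- GenomicRanges::countOverlaps(peaks, tssWin,
                                           type = "within") > 0
    peaks <- peaks[!inside]
  }
  if (!length(peaks)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(nConstituents = integer(),
                                                 signal = numeric())
    return(gr)
  }
  merged <- GenomicRanges::reduce(GenomicRanges::granges(peaks),
                                  min.gapwidth = stitchBp + 1,
                                  ignore.strand = TRUE)
  h <- GenomicRanges::findOverlaps(merged, peaks)
  f <- factor(S4Vectors::queryHits(h), seq_along(merged))
  S4Vectors::mcols(merged)$nConstituents <-
    as.integer(tapply(rep(1L, length(h)), f, sum, default = 0))
  S4Vectors::mcols(merged)$signal <- as.numeric(
    tapply(S4Vectors::mcols(peaks)$tagCount[S4Vectors::subjectHits(h)],
           f, sum, default = 0))
  sort(merged)
}

#' Inflection-point signal cutoff
#'
#' Regions are ranked by increasing signal; ranks and signals are rescaled
#' to [0, 1]; the cutoff is the (unscaled) signal at the first rank where
#' the secant slope over a single rank step exceeds 1. A degenerate curve
#' (all signals equal, or slope never exceeding 1 as for a straight line)
#' yields `Inf`, so nothing is called.
#'
#' @param signals numeric vector of per-region summed signals (>= 3).
#' @param smoothWindow width of a centered moving average applied to the
#'   secant-slope series before thresholding (0 = none, the default; a
#'   small window damps single-rank granularity noise at the bottom of
#'   the curve).
#' @return the unscaled signal threshold; regions strictly above it are
#'   super-enhancers.
#' @export
inflectionCutoff <- function(signals, smoothWindow = 0L) {
  n <- length(signals)
  if (n < 3) stop("need at least 3 regions to locate an inflection point")
  s <- sort(signals)
  rng <- s[n] - s[1]
  if (rng == 0) return(Inf)
  y <- (s - s[1]) / rng
  x <- (seq_len(n) - 1) / (n - 1)
  slope <- diff(y) / diff(x)
  if (smoothWindow > 1) {
    sm <- stats::filter(slope, rep(1 / smoothWindow, smoothWindow),
                        sides = 2)
    slope <- ifelse(is.na(sm), slope, as.numeric(sm))
  }
  i <- which(slope > 1)
  if (!length(i)) return(Inf)
  s[i[1]]
}

#' Call super-enhancers (stitch, rank, threshold at the inflection point)
#'
#' Composition of [stitchPeaks()] and [inflectionCutoff()]: a stitched
#' region is a super-enhancer iff its signal is strictly above the cutoff.
#' Each region is annotated with its nearest gene when `genes` is given.
#'
#' @param peaks H3K27ac peak GRanges with `tagCount`.
#' @param genes gene GRanges (TSS exclusion + nearest-gene annotation).
#' @param stitchBp,tssExclusionBp see [stitchPeaks()].
#' @param smoothWindow see [inflectionCutoff()].
#' @return a [SuperEnhancerSet-class]; with fewer than 3 stitched regions
#'   the cutoff is `Inf` and nothing is called.
#' @export
callSuperEnhancers <- function(peaks, genes = NULL, stitchBp = 12500,
                               tssExclusionBp = 2000, smoothWindow = 0L) {
  st <- stitchPeaks(peaks, stitchBp, tssExclusionBp, genes)
  n <- length(st)
  sig <- S4Vectors::mcols(st)$signal
  cutoff <- if (n >= 3) inflectionCutoff(sig, smoothWindow) else Inf
  ord <- rank(sig, ties.method = "first")
  S4Vectors::mcols(st)$rank <- ord
  S4Vectors::mcols(st)$scaledRank <- if (n > 1) (ord - 1) / (n - 1) else
    rep(0, n)
  rng <- if (n) max(sig) - min(sig) else 0
  S4Vectors::mcols(st)$scaledSignal <- if (n && rng > 0)
    (sig - min(sig)) / rng else rep(0, n)
  S4Vectors::mcols(st)$isSuper <- sig > cutoff
  if (!is.null(genes) && n) {
    ng <- nearestGene(st, genes)
    S4Vectors::mcols(st)$nearestGene <- ng$gene_id
    S4Vectors::mcols(st)$distanceToTss <- ng$distance
  }
  new("SuperEnhancerSet", regions = st, cutoff = cutoff)
}

#' Compare two super-enhancer sets
#'
#' A super-enhancer is shared iff it overlaps a super-enhancer of the
#' other set by at least `minOverlapBp`; gained = B-only, lost = A-only.
#'
#' @param seA,seB [SuperEnhancerSet-class] objects (cell A and cell B).
#' @param minOverlapBp minimum reciprocal overlap in bp (default 1).
#' @return list of GRanges: `gained`, `lost`, `sharedA`, `sharedB`.
#' @export
compareSuperEnhancers <- function(seA, seB, minOverlapBp = 1) {
  a <- regions(seA)[S4Vectors::mcols(regions(seA))$isSuper]
  b <- regions(seB)[S4Vectors::mcols(regions(seB))$isSuper]
  ovA <- GenomicRanges::countOverlaps(a, b, minoverlap = minOverlapBp) > 0
  ovB <- GenomicRanges::countOverlaps(b, a, minoverlap = minOverlapBp) > 0
  list(gained = b[!ovB], lost = a[!ovA],
       sharedA = a[ovA], sharedB = b[ovB])
}
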