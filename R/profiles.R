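#' Bin tag density around TSSs
#'
#' Splits the TSS +/- `windowBp` region of each gene into `nBins` bins and
#' computes the normalized tag density (tags per kilobase per million
#' mapped tags) per bin. Tags are single genomic positions (fragment
#' midpoints). A tag on a bin boundary belongs to the lower bin,
#' `floor((pos - windowStart)/binWidth)`. Profiles of "-"-strand genes are
#' reversed so bins always run 5' to 3'.
#'
#' @param tagPos integer vector of 0-based tag positions (one chromosome).
#' @param genes gene GRanges with `gene_id` and 0-based `tss` metadata
#'   (see [readGeneModels()]).
#' @param librarySize total mapped tags of the library (> 0).
#' @param windowBp half-width of the profiled window (default 3000, i.e.
#'   TSS +/- 3 kb).
#' @param nBins number of bins; `2*windowBp` must divide evenly (default
#'   200, giving 30-bp bins).
#' @return list with `density` (genes x bins matrix), `binMid` (bin
#'   midpoint offsets relative to the TSS), `binWidth`.
#' @examples
#' # 3 tags in one 30-bp bin of a 10 M library: density 3/(0.03 * 10) = 10
#' @export
binTagDensity <- function(tagPos, genes, librarySize,
                          windowBp = 3000, nBins = 200L) {
  stopIfNot(librarySize > 0, "librarySize must be > 0")
  total <- 2 * windowBp
  if (total %% nBins != 0)
    stop("window of ", total, " bp is not divisible into ", nBins, " bins")
  bw <- total / nBins
  tss <- S4Vectors::mcols(genes)$tss
  strand <- as.character(GenomicRanges::strand(genes))
  gid <- S4Vectors::mcols(genes)$gene_id
  dens <- matrix(0, length(genes), nBins,
                 dimnames = list(gid, NULL))
  tagPos <- sort(tagPos)
  for (i in seq_along(tss)) {
    lo <- tss[i] - windowBp
    sel <- tagPos[tagPos >= lo & tagPos < tss[i] + windowBp]
    if (length(sel)) {
      idx <- floor((sel - lo) / bw) + 1L
      cnt <- tabulate(idx, nBins)
      dens[i, ] <- cnt
    }
  }
  flip <- strand == "-"
  dens[flip, ] <- dens[flip, nBins:1, drop = FALSE]
  dens <- dens / ((bw / 1000) * (librarySize / 1e6))
  binMid <- seq(-windowBp + bw / 2, windowBp - bw / 2, by = bw)
  list(density = dens, binMid = binMid, binWidth = bw)
}

#' Expression decile groups
#'
#' Ranks genes by expression (descending) and splits them into 10 groups of
#' near-equal size (sizes differ by at most 1). Group 1 holds the top 10%
#' of the transcriptome. Ties are broken by gene id so the split is
#' deterministic.
#'
#' @param expr expression data.frame with `gene_id`.
#' @param valueColumn which abundance column to rank on (default `fpkm_a`).
#' @param nGroups number of groups (default 10).
#' @return named integer vector gene_id -> group (1 = highest).
#' @export
expressionDeciles <- function(expr, valueColumn = "fpkm_a", nGroups = 10L) {
  if (nrow(expr) < nGroups)
    stop("need at least ", nGroups, " genes to form ", nGroups, " groups")
  ord <- order(-expr[[valueColumn]], expr$gene_id)
  n <- nrow(expr)
  base <- n %/% nGroups
  extra <- n %% nGroups
  sizes <- rep(base, nGroups) + c(rep(1L, extra), rep(0L, nGroups - extra))
  grp <- rep(seq_len(nGroups), times = sizes)
  setNames(grp[order(ord)], expr$gene_id)[expr$gene_id]
}

#' Average profile per expression group
#'
#' Arithmetic mean of the density rows of each group's member genes.
#'
#' @param profile output of [binTagDensity()].
#' @param groups named gene -> group mapping covering the profiled genes.
#' @return matrix groups x bins of mean density.
#' @export
averageProfiles <- function(profile, groups) {
  dens <- profile$density
  g <- groups[rownames(dens)]
  if (anyNA(g)) stop("groups must cover every profiled gene")
  lev <- sort(unique(g))
  out <- t(vapply(lev, function(k) {
    rows <- dens[g == k, , drop = FALSE]
    if (nrow(rows) == 0) stop("empty expression group: ", k)
    colMeans(rows)
  }, numeric(ncol(dens))))
  rownames(out) <- as.character(lev)
  out
}
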