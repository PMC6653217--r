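#' Convert 0-based half-open coordinates to a GRanges
#'
#' BED files use 0-based half-open intervals; GRanges is 1-based closed.
#' All parsers funnel through this pair of helpers so the convention lives
#' in one place.
#'
#' @param chrom character vector of chromosome names.
#' @param start0 integer vector, 0-based inclusive starts.
#' @param end0 integer vector, exclusive ends.
#' @param strand strand characters ("+", "-" or ".").
#' @return A [GenomicRanges::GRanges] covering the same bases.
#' @keywords internal
grFromBed0 <- function(chrom, start0, end0, strand = ".") {
  if (any(start0 < 0)) stop("negative start coordinate")
  if (any(start0 >= end0)) stop("start must be < end (0-based half-open)")
  strand <- ifelse(strand %in% c("+", "-"), strand, "*")
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start0 + 1L, end = end0),
                         strand = strand)
}

#' @rdname grFromBed0
#' @param gr a GRanges.
#' @return `bed0FromGr`: a data.frame with `chrom`, `start0`, `end0`, `strand`.
#' @keywords internal
bed0FromGr <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start0 = GenomicRanges::start(gr) - 1L,
             end0 = GenomicRanges::end(gr),
             strand = ifelse(s == "*", ".", s),
             stringsAsFactors = FALSE)
}

# midpoint of a range, 0-based scale (midpoint of [s0, e0) is (s0+e0)/2)
mid0 <- function(gr) {
  (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
}

#' Promoter state vocabulary
#'
#' The four chromatin states a promoter can take, in display order.
#' @return character vector of length 4.
#' @export
promoterStateLevels <- function() c("Active", "Repressive", "Poised", "None")

stopIfNot <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
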