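# fixture builders shared across test files; everything is generated in code

writeTempLines <- function(lines, ext = ".bed") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# a handful of genes on one chromosome with known TSSs
tinyGenes <- function(tss = c(G1 = 1000, G2 = 20000, G3 = 50000),
                      strand = rep("+", length(tss)),
                      chrom = "chr1") {
  n <- length(tss)
  start0 <- ifelse(strand == "+", tss, tss + 1 - 2000)
  end0 <- ifelse(strand == "+", tss + 2000, tss + 1)
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(start0 + 1, end0), strand = strand)
  S4Vectors::mcols(gr)$gene_id <- names(tss)
  S4Vectors::mcols(gr)$tss <- unname(tss)
  names(gr) <- names(tss)
  gr
}

# peaks as GRanges from 0-based coordinates
tinyPeaks <- function(start0, end0, tagCount, mark = "H3K27ac",
                      cell = "B", chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("p%d", seq_along(gr)), tagCount = tagCount,
    score = NA_real_, mark = mark, cell = cell)
  gr
}

# enhancer-union GRanges with per-cell tag counts
tinyUnion <- function(tag_a, tag_b, width = 500, chrom = "chr1") {
  n <- length(tag_a)
  s <- seq(10000, by = 10 * width, length.out = n)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1, s + width))
  S4Vectors::mcols(gr)$tag_a <- tag_a
  S4Vectors::mcols(gr)$tag_b <- tag_b
  gr
}

onehotPwm <- function(word, tf = "TFX") {
  bases <- c("A", "C", "G", "T")
  b <- strsplit(word, "")[[1]]
  m <- matrix(0, 4, length(b), dimnames = list(bases, NULL))
  m[cbind(match(b, bases), seq_along(b))] <- 1
  list(tf_name = tf, matrix = m, width = length(b))
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# O(n^2) repeated pairwise merge: brute-force stitching oracle
bruteStitch <- function(start0, end0, stitch) {
  iv <- cbind(start0, end0)
  repeat {
    merged <- FALSE
    n <- nrow(iv)
    if (n < 2) break
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        gap <- max(iv[i, 1], iv[j, 1]) - min(iv[i, 2], iv[j, 2])
        if (gap <= stitch) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}

# exhaustive scan of the scaled-curve slope rule
bruteInflection <- function(signals) {
  s <- sort(signals)
  n <- length(s)
  if (max(s) == min(s)) return(Inf)
  y <- (s - min(s)) / (max(s) - min(s))
  x <- (0:(n - 1)) / (n - 1)
  for (i in 1:(n - 1)) {
    if ((y[i + 1] - y[i]) / (x[i + 1] - x[i]) > 1) return(s[i])
  }
  Inf
}

# Jaccard matrix by direct set computation
bruteJaccard <- function(edges) {
  tfs <- sort(unique(edges$tf))
  m <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (a in tfs) for (b in tfs) {
    ta <- unique(edges$gene[edges$tf == a])
    tb <- unique(edges$gene[edges$tf == b])
    m[a, b] <- length(intersect(ta, tb)) / length(union(ta, tb))
  }
  m
}
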