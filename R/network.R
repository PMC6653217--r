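#' Scan a PWM over one sequence
#'
#' Log-odds scoring against a background base distribution:
#' `score = sum_j log2(p_j(base_j)/bg(base_j))` at every offset, on both
#' strands (the minus strand scans the reverse-complemented matrix, so a
#' motif on the reverse strand is reported at its position in the given
#' sequence). An offset is a hit iff its score is at least
#' `scoreFraction` of the maximum achievable score. Windows containing
#' non-ACGT letters are skipped.
#'
#' @param pwm a PWM (list with `tf_name`, `matrix`, `width`).
#' @param sequence character or [Biostrings::DNAString].
#' @param bg background base frequencies over A,C,G,T (sums to 1).
#' @param scoreFraction hit threshold as a fraction of the maximum score
#'   (default 0.8).
#' @return data.frame `tf`, `offset` (1-based start in the sequence),
#'   `strand`, `score`; zero rows when the PWM is wider than the sequence.
#' @export
scanPwm <- function(pwm, sequence, bg = rep(0.25, 4), scoreFraction = 0.8) {
  stopIfNot(abs(sum(bg) - 1) < 1e-6, "background must sum to 1")
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  w <- pwm$width
  empty <- data.frame(tf = character(), offset = integer(),
                      strand = character(), score = numeric())
  if (w > L) return(empty)
  idx <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  lo <- log2(sweep(pwm$matrix, 1, bg, "/"))
  maxScore <- sum(apply(lo, 2, max))
  thr <- scoreFraction * maxScore
  nOff <- L - w + 1L
  scoreStrand <- function(m) {
    sc <- rep(0, nOff)
    for (j in seq_len(w)) {
      col <- m[, j][idx[j:(j + nOff - 1L)]]
      sc <- sc + col
    }
    sc  # NA where the window contained a non-ACGT letter
  }
  # reverse complement of the matrix: reverse positions, swap A<->T, C<->G
  loRc <- lo[c(4, 3, 2, 1), rev(seq_len(w)), drop = FALSE]
  rownames(loRc) <- c("A", "C", "G", "T")
  out <- list()
  for (str in c("+", "-")) {
    sc <- scoreStrand(if (str == "+") lo else loRc)
    hit <- which(!is.na(sc) & sc >= thr)
    if (length(hit))
      out[[str]] <- data.frame(tf = pwm$tf_name, offset = hit,
                               strand = str, score = sc[hit],
                               stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$offset, res$strand), , drop = FALSE]
}

#' Scan a PWM collection over a set of element sequences
#'
#' @param pwms named PWM list.
#' @param sequences named [Biostrings::DNAStringSet] (names = element ids).
#' @param bg,scoreFraction see [scanPwm()].
#' @return data.frame `tf`, `element_id`, `offset`, `strand`, `score`.
#' @export
scanPwmSet <- function(pwms, sequences, bg = rep(0.25, 4),
                       scoreFraction = 0.8) {
  chars <- as.character(sequences)
  out <- list()
  for (p in pwms) for (i in seq_along(chars)) {
    h <- scanPwm(p, chars[i], bg, scoreFraction)
    if (nrow(h)) {
      h$element_id <- names(chars)[i]
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(data.frame(tf = character(), element_id = character(),
                      offset = integer(), strand = character(),
                      score = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("tf", "element_id", "offset", "strand", "score")]
}

#' Hypergeometric motif enrichment
#'
#' With `k` target elements carrying at least one hit, `K` elements
#' carrying a hit overall, `n` targets and `N` elements in total, the
#' enrichment p-value is the upper hypergeometric tail `P(X >= k)`.
#'
#' @param k,K,n,N hit/total counts as above.
#' @return upper-tail p-value.
#' @export
hyperEnrichment <- function(k, K, n, N) {
  stopIfNot(all(k <= pmin(K, n)), "k cannot exceed min(K, n)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Motif enrichment of target vs background elements
#'
#' Scans the PWM over both element sets and applies [hyperEnrichment()]
#' on the per-element hit/no-hit counts.
#'
#' @param targetSeqs,backgroundSeqs disjoint named DNAStringSets.
#' @param pwm a PWM.
#' @param bg,scoreFraction scanner settings, see [scanPwm()].
#' @return list with `p`, `k`, `K`, `n`, `N`.
#' @export
motifEnrichment <- function(targetSeqs, backgroundSeqs, pwm,
                            bg = rep(0.25, 4), scoreFraction = 0.8) {
  if (!length(targetSeqs)) stop("empty target element set")
  hitIn <- function(seqs) vapply(as.character(seqs), function(s)
    nrow(scanPwm(pwm, s, bg, scoreFraction)) > 0, TRUE)
  ht <- hitIn(targetSeqs)
  hb <- hitIn(backgroundSeqs)
  k <- sum(ht); n <- length(ht)
  K <- k + sum(hb); N <- n + length(hb)
  list(p = hyperEnrichment(k, K, n, N), k = k, K = K, n = n, N = N)
}

#' Build the TF -> target regulatory network
#'
#' One proximal edge per motif hit in a promoter, one distal edge per hit
#' in an enhancer (through the enhancer's assigned gene); duplicate
#' (TF, gene) pairs are collapsed with mode "both". Hits should come from
#' significant motifs only. When `restrictTfToDeg` is on, only TFs in the
#' DEG list contribute edges.
#'
#' @param promoterHits,enhancerHits hit data.frames with `tf`,
#'   `element_id` (either may have zero rows).
#' @param elementGenes named vector element_id -> gene_id.
#' @param degList character vector of DEG gene ids (TF filter).
#' @param restrictTfToDeg restrict TFs to DEGs (default TRUE).
#' @param cell condition label stored on the edges.
#' @return a [RegulatoryNetwork-class].
#' @export
buildNetwork <- function(promoterHits, enhancerHits, elementGenes,
                         degList = character(), restrictTfToDeg = TRUE,
                         cell = "B") {
  collect <- function(hits, mode) {
    if (is.null(hits) || !nrow(hits))
      return(data.frame(tf = character(), gene = character(),
                        mode = character()))
    g <- elementGenes[hits$element_id]
    drop <- is.na(g)
    if (any(drop)) {
      warning(sum(drop), " hit(s) in elements without a gene assignment; ",
              "edges skipped")
      hits <- hits[!drop, , drop = FALSE]
      g <- g[!drop]
    }
    unique(data.frame(tf = hits$tf, gene = unname(g),
                      mode = rep(mode, nrow(hits)),
                      stringsAsFactors = FALSE))
  }
  edges <- rbind(collect(promoterHits, "proximal"),
                 collect(enhancerHits, "distal"))
  if (restrictTfToDeg) edges <- edges[edges$tf %in% degList, , drop = FALSE]
  if (nrow(edges)) {
    key <- paste(edges$tf, edges$gene, sep = "\r")
    modes <- tapply(edges$mode, key, function(m)
      if (length(unique(m)) > 1) "both" else m[1])
    first <- !duplicated(key)
    edges <- edges[first, , drop = FALSE]
    edges$mode <- as.character(modes[paste(edges$tf, edges$gene,
                                           sep = "\r")])
  }
  edges$cell <- rep(cell, nrow(edges))
  rownames(edges) <- NULL
  new("RegulatoryNetwork", edges = edges,
      tfs = sort(unique(edges$tf)))
}

#' Jaccard TF-TF cooperation matrix
#'
#' `JI(a, b) = |targets(a) intersect targets(b)| /
#' |targets(a) union targets(b)|` over the network's target-gene sets.
#' TFs without targets are excluded; the diagonal is 1.
#'
#' @param network a [RegulatoryNetwork-class].
#' @return symmetric numeric matrix of Jaccard indices.
#' @export
jaccardMatrix <- function(network) {
  edges <- networkEdges(network)
  tfs <- sort(unique(edges$tf))
  targets <- lapply(setNames(tfs, tfs),
                    function(tf) unique(edges$gene[edges$tf == tf]))
  targets <- targets[lengths(targets) > 0]
  tfs <- names(targets)
  m <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  for (i in seq_along(tfs)) for (j in seq_len(i)) {
    a <- targets[[i]]; b <- targets[[j]]
    ji <- length(intersect(a, b)) / length(union(a, b))
    m[i, j] <- ji; m[j, i] <- ji
  }
  m
}

#' Hub transcription factors
#'
#' TFs tightly cooperating (JI strictly above `jiMin`) with strictly more
#' than `minPartners` other factors.
#'
#' @param jiMatrix matrix from [jaccardMatrix()].
#' @param jiMin JI threshold (default 0.3, strict).
#' @param minPartners partner-count threshold (default 10, strict).
#' @return character vector of hub TF names.
#' @export
hubFactors <- function(jiMatrix, jiMin = 0.3, minPartners = 10) {
  if (!nrow(jiMatrix)) return(character())
  partners <- vapply(seq_len(nrow(jiMatrix)), function(i)
    sum(jiMatrix[i, -i] > jiMin), integer(1))
  rownames(jiMatrix)[partners > minPartners]
}

#' Cell-specific element sets
#'
#' Elements exclusive to one cell's active set: members of `a` that do not
#' overlap any member of `b` by at least `minOverlapBp`.
#'
#' @param a,b GRanges of active elements per cell.
#' @param minOverlapBp overlap that disqualifies specificity (default 1).
#' @return the `a`-specific subset.
#' @export
specificElements <- function(a, b, minOverlapBp = 1) {
  if (!length(a)) return(a)
  a[GenomicRanges::countOverlaps(a, b, minoverlap = minOverlapBp) == 0]
}
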