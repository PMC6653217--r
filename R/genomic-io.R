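#' Read a BED5+/broadPeak file of ChIP-seq peaks
#'
#' Peaks are the unit of input for the whole pipeline: each carries a
#' histone-mark label, the cell (condition) it was called in, and a tag
#' count read from a configurable column. Coordinates in the file are
#' 0-based half-open (BED); the returned GRanges is 1-based closed and
#' covers the identical bases.
#'
#' @param path BED file. Lines starting with `#`, `track` or `browser` are
#'   skipped; data lines must have at least `max(5, tagCountColumn)` fields.
#' @param mark histone-mark label attached to every peak (e.g. "H3K27ac").
#' @param cell condition label (e.g. "A" or "B").
#' @param tagCountColumn 1-based column holding the tag count; default 5
#'   (the BED score column). broadPeak signal lives in column 7.
#' @param scoreColumn optional column with a significance score, `NA_integer_`
#'   to skip.
#' @return GRanges with metadata columns `name`, `tagCount`, `score`,
#'   `mark`, `cell`.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t600\tpk1\t42", p)
#' readPeaks(p, mark = "H3K27ac", cell = "A")
#' @export
readPeaks <- function(path, mark, cell,
                      tagCountColumn = 5L, scoreColumn = NA_integer_) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineNo <- which(keep)
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = character(), tagCount = numeric(), score = numeric(),
      mark = character(), cell = character())
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  needed <- max(5L, tagCountColumn, if (is.na(scoreColumn)) 0L else scoreColumn)
  nf <- lengths(fields)
  if (any(nf < needed))
    stop(sprintf("malformed peak line %d in %s: %d field(s), need >= %d",
                 lineNo[which(nf < needed)[1]], path,
                 min(nf), needed))
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | !nzchar(chrom))
  if (length(bad))
    stop(sprintf("malformed peak line %d in %s: non-numeric coordinates",
                 lineNo[bad[1]], path))
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop(sprintf("invalid interval at line %d in %s: start %s, end %s",
                 lineNo[bad[1]], path, start0[bad[1]], end0[bad[1]]))
  tagCount <- suppressWarnings(
    as.numeric(vapply(fields, `[[`, "", tagCountColumn)))
  if (anyNA(tagCount) || any(tagCount < 0))
    stop(sprintf("line %d in %s: tag count missing or negative",
                 lineNo[which(is.na(tagCount) | tagCount < 0)[1]], path))
  gr <- grFromBed0(chrom, start0, end0)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = vapply(fields, `[[`, "", 4L),
    tagCount = tagCount,
    score = if (is.na(scoreColumn)) NA_real_ else
      suppressWarnings(as.numeric(vapply(fields, `[[`, "", scoreColumn))),
    mark = mark, cell = cell)
  gr
}

#' Write peaks back to BED5
#'
#' Inverse of [readPeaks()]: emits chrom, 0-based start, end, name and the
#' tag count in column 5.
#' @param peaks GRanges as returned by [readPeaks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  b <- bed0FromGr(peaks)
  mc <- S4Vectors::mcols(peaks)
  df <- data.frame(b$chrom, b$start0, b$end0,
                   name = if ("name" %in% colnames(mc)) mc$name else ".",
                   tag = mc$tagCount)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BED6 gene models
#'
#' Column 4 is the gene identifier and must be unique. The TSS is the
#' 0-based `start` for "+"-strand genes and `end - 1` for "-"-strand genes;
#' it is stored (0-based) in the `tss` metadata column.
#'
#' @param path BED6 file.
#' @return GRanges (gene bodies, stranded) with metadata columns `gene_id`
#'   and `tss` (0-based position).
#' @export
readGeneModels <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric", "numeric",
                                  "character", "character", "character"),
                   col.names = c("chrom", "start", "end", "gene", "score",
                                 "strand"))
  if (!all(df$strand %in% c("+", "-")))
    stop("gene model strand must be '+' or '-', got: ",
         paste(setdiff(df$strand, c("+", "-")), collapse = ", "))
  if (anyDuplicated(df$gene))
    stop("duplicate gene_id in ", path, ": ",
         df$gene[anyDuplicated(df$gene)])
  gr <- grFromBed0(df$chrom, df$start, df$end, df$strand)
  S4Vectors::mcols(gr)$gene_id <- df$gene
  S4Vectors::mcols(gr)$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  names(gr) <- df$gene
  gr
}

#' @rdname readGeneModels
#' @param genes GRanges from [readGeneModels()].
#' @param path output BED6 file.
#' @export
writeGeneModels <- function(genes, path) {
  b <- bed0FromGr(genes)
  df <- data.frame(b$chrom, b$start0, b$end0,
                   S4Vectors::mcols(genes)$gene_id, 0L, b$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' Tab-separated with a header; required columns `gene_id`, `fpkm_a`,
#' `fpkm_b`. When `fc` is absent it is computed as
#' `(fpkm_b + pseudocount) / (fpkm_a + pseudocount)`; `q` is optional
#' (NA when absent).
#'
#' @param path TSV file.
#' @param pseudocount FPKM pseudocount for fold change on zero-abundance
#'   genes (default 1).
#' @return data.frame with columns `gene_id`, `fpkm_a`, `fpkm_b`, `fc`,
#'   `q`, `is_deg`, `direction`.
#' @export
readExpression <- function(path, pseudocount = 1) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "fpkm_a", "fpkm_b")
  if (!all(need %in% colnames(df)))
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  if (any(df$fpkm_a < 0) || any(df$fpkm_b < 0))
    stop("negative abundance in ", path)
  if (!"fc" %in% colnames(df))
    df$fc <- (df$fpkm_b + pseudocount) / (df$fpkm_a + pseudocount)
  if (!"q" %in% colnames(df)) df$q <- NA_real_
  if (!"is_deg" %in% colnames(df)) df$is_deg <- FALSE
  if (!"direction" %in% colnames(df)) df$direction <- NA_character_
  df[c("gene_id", "fpkm_a", "fpkm_b", "fc", "q", "is_deg", "direction")]
}

#' @rdname readExpression
#' @param expr expression data.frame.
#' @export
writeExpression <- function(expr, path) {
  write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter differentially expressed genes
#'
#' Keeps genes with at least `minFc`-fold change in either direction
#' (up: `fc >= minFc`; down: `fc <= 1/minFc`, symmetric on the ratio
#' scale) and adjusted significance `q < maxQ`.
#'
#' @param expr expression data.frame from [readExpression()].
#' @param minFc fold-change threshold, default 1.5.
#' @param maxQ significance threshold, default 0.05; set `qFilter = FALSE`
#'   to filter on fold change alone (e.g. when only p-values exist).
#' @param qFilter logical, apply the q threshold.
#' @return the kept rows with `is_deg = TRUE` and `direction` in
#'   `c("up", "down")`.
#' @export
filterDegs <- function(expr, minFc = 1.5, maxQ = 0.05, qFilter = TRUE) {
  stopIfNot(minFc >= 1, "minFc must be >= 1")
  if (qFilter && anyNA(expr$q))
    stop("q missing for some genes; set qFilter = FALSE for fc-only mode")
  up <- expr$fc >= minFc
  down <- expr$fc <= 1 / minFc
  keep <- (up | down) & (!qFilter | expr$q < maxQ)
  out <- expr[keep, , drop = FALSE]
  out$is_deg <- TRUE
  out$direction <- ifelse(out$fc >= minFc, "up", "down")
  rownames(out) <- NULL
  out
}

#' Read JASPAR-style position weight matrices
#'
#' Accepts the JASPAR text dialect: a `>TF_NAME` header followed by four
#' rows `A [ counts... ]`, `C [...]`, `G [...]`, `T [...]` (brackets
#' optional). Count matrices are converted to per-column probabilities with
#' a pseudocount and renormalized.
#'
#' @param path PWM file.
#' @param pseudocount added to every count before normalization (default 0;
#'   use a small positive value to avoid zero probabilities).
#' @return named list of PWMs; each is a list with `tf_name`, `matrix`
#'   (4 x width probability matrix, rows A/C/G/T) and `width`.
#' @export
readPwms <- function(path, pseudocount = 0) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no PWM records (missing '>' headers) in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L)
      stop("PWM ", name, ": expected 4 base rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("PWM ", name, ": ragged rows")
    m <- do.call(rbind, rows) + pseudocount
    rownames(m) <- c("A", "C", "G", "T")
    cs <- colSums(m)
    if (any(cs <= 0))
      stop("PWM ", name, ": column of all zeros (position ",
           which(cs <= 0)[1], ")")
    m <- sweep(m, 2, cs, "/")
    out[[name]] <- list(tf_name = name, matrix = m, width = w)
  }
  out
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set name, description, then member genes.
#' @param path GMT file.
#' @return named list of character vectors (duplicate members removed).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line with fewer than 3 fields in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}
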