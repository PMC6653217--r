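#' @import methods
#' @importFrom stats rbinom rexp rgamma rnorm rpois runif setNames ppois phyper
#'   p.adjust pchisq chisq.test aggregate quantile sd
#' @importFrom utils read.table write.table modifyList
NULL

#' Promoter state transition summary
#'
#' Cross-tabulation of promoter chromatin states between two cell states,
#' with the mean expression log2 fold change and the member genes of every
#' cell of the 4x4 transition matrix.
#'
#' @slot counts 4x4 integer matrix, rows = state in cell A, cols = state in
#'   cell B, over the Active/Repressive/Poised/None vocabulary.
#' @slot meanLog2Fc 4x4 numeric matrix of per-cell mean log2 fold change;
#'   `NA` marks an empty cell.
#' @slot genes list-matrix (4x4) of member gene identifiers.
#' @export
setClass("TransitionSummary",
  representation(counts = "matrix", meanLog2Fc = "matrix", genes = "matrix"),
  validity = function(object) {
    lv <- promoterStateLevels()
    if (!identical(dim(object@counts), c(4L, 4L)))
      return("counts must be 4x4")
    if (!identical(rownames(object@counts), lv) ||
        !identical(colnames(object@counts), lv))
      return("counts dimnames must be the promoter state vocabulary")
    if (any(object@counts < 0)) return("negative transition count")
    TRUE
  })

#' Stitched regions and the super-enhancer call
#'
#' Result of stitching H3K27ac peaks into candidate regions, ranking them by
#' signal, and thresholding at the inflection point of the scaled
#' rank-signal curve.
#'
#' @slot regions GRanges of stitched regions with metadata columns
#'   `nConstituents`, `signal`, `rank`, `scaledRank`, `scaledSignal`,
#'   `isSuper`, and (when annotated) `nearestGene`, `distanceToTss`.
#' @slot cutoff numeric(1), the unscaled signal threshold; `Inf` when the
#'   curve is degenerate and nothing is called.
#' @export
setClass("SuperEnhancerSet",
  representation(regions = "GRanges", cutoff = "numeric"),
  validity = function(object) {
    mc <- S4Vectors::mcols(object@regions)
    need <- c("nConstituents", "signal", "rank", "isSuper")
    if (!all(need %in% colnames(mc)))
      return(paste("regions must carry metadata columns:",
                   paste(need, collapse = ", ")))
    if (length(object@regions) && any(mc$nConstituents < 1))
      return("every stitched region needs >= 1 constituent peak")
    TRUE
  })

#' TF-target regulatory network
#'
#' Directed TF -> target-gene edges inferred from motif hits in active
#' promoters (proximal evidence) and distal enhancers (distal evidence),
#' with the Jaccard cooperation matrix derived from shared target sets.
#'
#' @slot edges data.frame with columns `tf`, `gene`, `mode` (proximal /
#'   distal / both) and `cell`.
#' @slot tfs character, the TF universe the network was built over.
#' @export
setClass("RegulatoryNetwork",
  representation(edges = "data.frame", tfs = "character"),
  validity = function(object) {
    need <- c("tf", "gene", "mode", "cell")
    if (!all(need %in% colnames(object@edges)))
      return("edges needs columns tf, gene, mode, cell")
    if (!all(object@edges$mode %in% c("proximal", "distal", "both")))
      return("edge mode must be proximal, distal or both")
    if (anyDuplicated(object@edges[c("tf", "gene")]))
      return("duplicate (tf, gene) edge: modes must be collapsed")
    TRUE
  })

#' Non-negative matrix factorization result
#'
#' @slot basis genes x k non-negative matrix W.
#' @slot coef k x patients non-negative matrix H.
#' @slot cluster integer patient -> argmax component assignment.
#' @slot objective numeric, squared-error trace of the best restart
#'   (non-increasing by the multiplicative-update guarantee).
#' @slot seed integer seed the factorization was run under.
#' @export
setClass("NmfResult",
  representation(basis = "matrix", coef = "matrix", cluster = "integer",
                 objective = "numeric", seed = "integer"),
  validity = function(object) {
    if (any(object@basis < 0) || any(object@coef < 0))
      return("factors must be elementwise non-negative")
    if (ncol(object@basis) != nrow(object@coef))
      return("inner dimensions of basis and coef disagree")
    if (length(object@cluster) != ncol(object@coef))
      return("one cluster label per patient required")
    TRUE
  })

#' @describeIn TransitionSummary compact console display
#' @param object a `TransitionSummary`.
#' @export
setMethod("show", "TransitionSummary", function(object) {
  cat("TransitionSummary:", sum(object@counts), "genes\n")
  print(object@counts)
  off <- sum(object@counts) - sum(diag(object@counts))
  cat("off-diagonal (state-changing) genes:", off, "\n")
})

#' @describeIn SuperEnhancerSet compact console display
#' @param object a `SuperEnhancerSet`.
#' @export
setMethod("show", "SuperEnhancerSet", function(object) {
  n <- length(object@regions)
  ns <- sum(S4Vectors::mcols(object@regions)$isSuper)
  cat("SuperEnhancerSet:", n, "stitched regions,", ns,
      "super-enhancers (signal cutoff", format(object@cutoff, digits = 4),
      ")\n")
})

#' @describeIn RegulatoryNetwork compact console display
#' @param object a `RegulatoryNetwork`.
#' @export
setMethod("show", "RegulatoryNetwork", function(object) {
  cat("RegulatoryNetwork:", nrow(object@edges), "edges,",
      length(unique(object@edges$tf)), "TFs,",
      length(unique(object@edges$gene)), "target genes\n")
  print(table(object@edges$mode))
})

#' @describeIn NmfResult compact console display
#' @param object an `NmfResult`.
#' @export
setMethod("show", "NmfResult", function(object) {
  cat("NmfResult: k =", ncol(object@basis), ",",
      ncol(object@coef), "patients, final objective",
      format(utils::tail(object@objective, 1), digits = 6), "\n")
  print(table(cluster = object@cluster))
})

#' Accessors for result classes
#'
#' `regions()` returns the stitched-region GRanges; `seCutoff()` the signal
#' threshold; `networkEdges()` the edge table; `clusterAssignments()` the
#' NMF patient clusters; `transitionCounts()` / `transitionMeanLog2Fc()` /
#' `transitionGenes()` the slots of a [TransitionSummary].
#'
#' @param x a result object.
#' @return the corresponding slot, unmodified.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setMethod("regions", "SuperEnhancerSet", function(x) x@regions)

#' @rdname accessors
#' @export
setGeneric("seCutoff", function(x) standardGeneric("seCutoff"))
#' @rdname accessors
#' @export
setMethod("seCutoff", "SuperEnhancerSet", function(x) x@cutoff)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "RegulatoryNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setMethod("clusterAssignments", "NmfResult", function(x) x@cluster)

#' @rdname accessors
#' @export
setGeneric("transitionCounts", function(x) standardGeneric("transitionCounts"))
#' @rdname accessors
#' @export
setMethod("transitionCounts", "TransitionSummary", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("transitionMeanLog2Fc", function(x) standardGeneric("transitionMeanLog2Fc"))
#' @rdname accessors
#' @export
setMethod("transitionMeanLog2Fc", "TransitionSummary", function(x) x@meanLog2Fc)

#' @rdname accessors
#' @export
setGeneric("transitionGenes", function(x) standardGeneric("transitionGenes"))
#' @rdname accessors
#' @export
setMethod("transitionGenes", "TransitionSummary", function(x) x@genes)
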