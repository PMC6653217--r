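#' Pipeline run configuration
#'
#' All stage thresholds with their defaults: promoter half-width 2000 bp;
#' distal minimum 2000 bp; differential-enhancer fold 4 and p 1e-4;
#' stitching distance 12500 bp; motif p threshold 1e-10; JI threshold 0.3
#' with more than 10 partners for hubs; DEG fold 1.5 and q 0.05; gene-set
#' FDR 0.05; 200 bins over TSS +/- 3 kb; NMF k = 2.
#'
#' @param ... overrides for any default.
#' @return named list of class `RunConfig`.
#' @export
runConfig <- function(...) {
  cfg <- list(promoter_halfwidth = 2000, distal_min = 2000,
              min_fold = 4, max_p = 1e-4, stitch = 12500,
              tss_exclusion = 2000, motif_p = 1e-10,
              score_fraction = 0.8, ji_min = 0.3, min_partners = 10,
              deg_fc = 1.5, deg_q = 0.05, fdr = 0.05,
              n_bins = 200, window = 3000, k = 2, n_restarts = 30,
              library_size = 1e7, restrict_tf_to_deg = TRUE,
              seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown RunConfig field(s): ",
                        paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  class(cfg) <- "RunConfig"
  cfg
}

.readStudyPeaks <- function(dir, cell, mark) {
  path <- file.path(dir, sprintf("peaks_%s_%s.bed", cell, mark))
  if (!file.exists(path)) stop("missing input file: ", path)
  readPeaks(path, mark = mark, cell = cell)
}

.writeStage <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on a study directory
#'
#' Executes every stage in dependency order on the files written by
#' [simulateStudy()] (or any inputs in the same layout): DEG filtering,
#' TSS tag-density profiles, promoter-state classification and transition
#' summary, differential-enhancer calling and the promoter x enhancer
#' synergy table, super-enhancer calling and comparison, motif scanning /
#' enrichment / network construction with the Jaccard cooperation matrix,
#' cohort NMF clustering + chi-square + Kaplan-Meier/log-rank, gene-set
#' enrichment, and hallmark change percentages. Each stage writes a TSV to
#' `outDir`, and a JSON manifest records the configuration, seed, and the
#' MD5 checksum plus row count of every output, so a rerun under the same
#' seed is verifiably bit-identical.
#'
#' @param studyDir directory with the input files.
#' @param outDir output run directory (must not contain previous outputs;
#'   stages are write-once).
#' @param config a [runConfig()].
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(studyDir, outDir, config = runConfig()) {
  marks <- c("H3K4me3", "H3K27ac", "H3K4me1", "H3K27me3", "H3K9me3")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(outDir, name)
    if (file.exists(path)) stop("output exists (stages are write-once): ",
                                path)
    .writeStage(df, path)
    outputs[[name]] <<- path
  }
  need <- function(name) {
    p <- file.path(studyDir, name)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }

  # stage 1: io + DEG filter
  genes <- readGeneModels(need("genes.bed"))
  expr <- readExpression(need("expression.tsv"))
  degs <- filterDegs(expr, minFc = config$deg_fc, maxQ = config$deg_q)
  emit(degs, "degs.tsv")

  peaks <- list()
  for (cell in c("A", "B")) for (mark in marks)
    peaks[[paste(cell, mark)]] <- .readStudyPeaks(studyDir, cell, mark)
  allPeaks <- do.call(c, unname(peaks))

  # stage 2: TSS profiles per mark, decile-averaged
  deciles <- expressionDeciles(expr)
  profRows <- list()
  for (mark in marks) {
    tp <- file.path(studyDir, sprintf("tags_%s.bed", mark))
    if (!file.exists(tp)) next
    tags <- read.table(tp, sep = "\t")
    prof <- binTagDensity(tags[[2]], genes, config$library_size,
                          windowBp = config$window, nBins = config$n_bins)
    avg <- averageProfiles(prof, deciles)
    profRows[[mark]] <- data.frame(mark = mark,
                                   group = rep(rownames(avg),
                                               each = ncol(avg)),
                                   bin_mid = rep(prof$binMid,
                                                 nrow(avg)),
                                   density = as.vector(t(avg)))
  }
  emit(do.call(rbind, profRows), "profiles.tsv")

  # stage 3: promoter states + transitions
  windows <- definePromoters(genes, config$promoter_halfwidth)
  stA <- promoterStatesForCell(windows, allPeaks, "A", config$library_size)
  stB <- promoterStatesForCell(windows, allPeaks, "B", config$library_size)
  states <- data.frame(gene_id = stA$gene_id, state_a = stA$state,
                       state_b = stB$state)
  emit(cbind(states, density_k4me3_a = stA$density_k4me3,
             density_k27ac_a = stA$density_k27ac,
             density_k27me3_a = stA$density_k27me3,
             density_k4me3_b = stB$density_k4me3,
             density_k27ac_b = stB$density_k27ac,
             density_k27me3_b = stB$density_k27me3), "promoter_states.tsv")
  ts <- transitionSummary(setNames(states$state_a, states$gene_id),
                          setNames(states$state_b, states$gene_id), expr)
  lv <- promoterStateLevels()
  tsDf <- expand.grid(state_a = lv, state_b = lv, stringsAsFactors = FALSE)
  tsDf$count <- as.vector(transitionCounts(ts))
  tsDf$mean_log2fc <- as.vector(transitionMeanLog2Fc(ts))
  emit(tsDf, "transitions.tsv")

  # stage 4: differential enhancers + synergy
  k27 <- function(cell) allPeaks[S4Vectors::mcols(allPeaks)$cell == cell &
                                   S4Vectors::mcols(allPeaks)$mark ==
                                   "H3K27ac"]
  enhA <- callDistalEnhancers(k27("A"), genes, config$distal_min)
  enhB <- callDistalEnhancers(k27("B"), genes, config$distal_min)
  un <- enhancerUnion(enhA, enhB)
  calls <- classifyEnhancerChanges(un, config$library_size,
                                   config$library_size, config$min_fold,
                                   config$max_p, genes = genes)
  callDf <- cbind(bed0FromGr(calls),
                  as.data.frame(S4Vectors::mcols(calls)))
  emit(callDf, "enhancers.tsv")
  syn <- synergyTable(states, calls, degs)
  emit(syn$classMeans, "synergy.tsv")

  # stage 5: super-enhancers per cell + comparison
  seA <- callSuperEnhancers(k27("A"), genes, config$stitch,
                            config$tss_exclusion)
  seB <- callSuperEnhancers(k27("B"), genes, config$stitch,
                            config$tss_exclusion)
  seDf <- function(se) cbind(bed0FromGr(regions(se)),
                             as.data.frame(S4Vectors::mcols(regions(se))))
  emit(seDf(seA), "super_enhancers_A.tsv")
  emit(seDf(seB), "super_enhancers_B.tsv")
  cmp <- compareSuperEnhancers(seA, seB)
  emit(data.frame(gained = length(cmp$gained), lost = length(cmp$lost),
                  shared = length(cmp$sharedB)), "se_comparison.tsv")

  # stage 6: motif scan, enrichment, network, cooperation
  pwms <- readPwms(need("pwms.txt"))
  seqs <- Biostrings::readDNAStringSet(need("sequences.fa"))
  elements <- read.table(need("elements.tsv"), header = TRUE,
                         stringsAsFactors = FALSE)
  elementGenes <- setNames(elements$gene_id, elements$element_id)
  hits <- scanPwmSet(pwms, seqs, scoreFraction = config$score_fraction)
  promIds <- elements$element_id[elements$type == "promoter"]
  enhIds <- elements$element_id[elements$type == "enhancer"]
  # per-TF enrichment of enhancer elements against promoter background
  enrRows <- lapply(pwms, function(p) {
    hitEl <- unique(hits$element_id[hits$tf == p$tf_name])
    k <- sum(enhIds %in% hitEl); K <- length(intersect(
      c(promIds, enhIds), hitEl))
    data.frame(tf = p$tf_name, k = k, K = K, n = length(enhIds),
               N = length(promIds) + length(enhIds),
               p = hyperEnrichment(k, K, length(enhIds),
                                   length(promIds) + length(enhIds)))
  })
  emit(do.call(rbind, enrRows), "motif_enrichment.tsv")
  net <- buildNetwork(hits[hits$element_id %in% promIds, ],
                      hits[hits$element_id %in% enhIds, ],
                      elementGenes, degList = degs$gene_id,
                      restrictTfToDeg = config$restrict_tf_to_deg)
  emit(networkEdges(net), "network_edges.tsv")
  ji <- if (length(net@tfs) >= 2) jaccardMatrix(net) else
    matrix(0, 0, 0)
  jiDf <- if (nrow(ji)) data.frame(tf = rownames(ji),
                                   as.data.frame(ji, optional = TRUE))
          else data.frame(tf = character())
  emit(jiDf, "cooperation_ji.tsv")
  hubs <- if (nrow(ji)) hubFactors(ji, config$ji_min,
                                   config$min_partners) else character()
  emit(data.frame(hub_tf = hubs), "hubs.tsv")

  # stage 7: cohort validation
  cohort <- read.table(need("cohort.tsv"), header = TRUE,
                       stringsAsFactors = FALSE, check.names = FALSE)
  meta <- cohort[c("patient_id", "time", "event", "metastasis_label")]
  exprMat <- t(as.matrix(cohort[, setdiff(colnames(cohort),
                                          colnames(meta)), drop = FALSE]))
  colnames(exprMat) <- meta$patient_id
  panel <- intersect(degs$gene_id, rownames(exprMat))
  if (length(panel) < 2) panel <- rownames(exprMat)
  nmf <- nmfCluster(exprMat[panel, , drop = FALSE], k = config$k,
                    nRestarts = config$n_restarts, seed = config$seed)
  emit(data.frame(patient_id = meta$patient_id,
                  cluster = clusterAssignments(nmf)),
       "cohort_clusters.tsv")
  cs <- contingencyChisq(clusterAssignments(nmf), meta$metastasis_label)
  markerGene <- panel[1]
  grp <- splitByMean(exprMat[markerGene, ])
  lr <- logrankTest(meta$time[grp == "high"], meta$event[grp == "high"],
                    meta$time[grp == "low"], meta$event[grp == "low"])
  emit(data.frame(test = c("chisq_cluster_vs_metastasis",
                           paste0("logrank_", markerGene)),
                  statistic = c(cs$statistic, lr$statistic),
                  p = c(cs$p, lr$p)), "cohort_tests.tsv")
  km <- rbind(cbind(group = "high", kmCurve(meta$time[grp == "high"],
                                            meta$event[grp == "high"])),
              cbind(group = "low", kmCurve(meta$time[grp == "low"],
                                           meta$event[grp == "low"])))
  emit(km, "km_curves.tsv")

  # stage 8: gene-set enrichment; stage 9: hallmark percentages
  sets <- readGmt(need("hallmarks.gmt"))
  enr <- genesetEnrichment(degs$gene_id, sets, expr$gene_id, config$fdr)
  emit(enr, "geneset_enrichment.tsv")
  promChanged <- states$gene_id[states$state_a != states$state_b]
  mc <- S4Vectors::mcols(calls)
  enhChanged <- unique(mc$nearestGene[mc$status %in% c("gained", "lost")])
  emit(hallmarkPercentages(sets, promChanged, enhChanged, degs$gene_id),
       "hallmarks.tsv")

  manifest <- list(
    config = unclass(config), seed = config$seed,
    n_stage_outputs = length(outputs),
    outputs = lapply(setNames(names(outputs), names(outputs)), function(nm) {
      list(file = nm,
           md5 = unname(tools::md5sum(outputs[[nm]])),
           rows = length(readLines(outputs[[nm]])) - 1L)
    }))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
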