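smallCfg <- function(seed = 1, ...) {
  simConfig(seed = seed, n_genes = 60, chrom_length_bp = 2.2e6, ...)
}

test_that("genome simulation enforces spacing, determinism and feasibility", {
  cfg <- smallCfg()
  g <- simulateGenome(cfg)
  tss <- S4Vectors::mcols(g$genes)$tss
  expect_length(tss, 60)
  expect_true(all(diff(sort(tss)) >= cfg$min_tss_spacing_bp))
  g2 <- simulateGenome(cfg)
  expect_identical(S4Vectors::mcols(g2$genes)$tss, tss)
  expect_identical(as.character(GenomicRanges::strand(g2$genes)),
                   as.character(GenomicRanges::strand(g$genes)))
  expect_error(simulateGenome(simConfig(n_genes = 100,
                                        chrom_length_bp = 1e6)),
               "too small")
})

test_that("chromatin emission matches the drawn promoter states", {
  cfg <- smallCfg(seed = 3)
  g <- simulateGenome(cfg)
  ch <- simulateChromatin(cfg, g)
  tr <- ch$truth$states
  mc <- S4Vectors::mcols(ch$peaks)
  tssOf <- setNames(S4Vectors::mcols(g$genes)$tss,
                    S4Vectors::mcols(g$genes)$gene_id)
  promPeakMarks <- function(gene, cell) {
    w <- GenomicRanges::GRanges(cfg$chrom,
           IRanges::IRanges(tssOf[gene] - 1999, tssOf[gene] + 2000))
    sel <- ch$peaks[mc$cell == cell &
                      GenomicRanges::countOverlaps(ch$peaks, w) > 0]
    sort(unique(S4Vectors::mcols(sel)$mark))
  }
  ra <- tr$gene_id[tr$state_a == "Repressive" & tr$state_b == "Active"]
  if (length(ra)) {
    gene <- ra[1]
    expect_equal(promPeakMarks(gene, "A"), "H3K27me3")
    expect_true(all(c("H3K27ac", "H3K4me3") %in% promPeakMarks(gene, "B")))
    expect_false("H3K27me3" %in% promPeakMarks(gene, "B"))
  }
  none <- tr$gene_id[tr$state_a == "None"]
  if (length(none))
    expect_false(any(c("H3K4me3", "H3K27me3") %in%
                       promPeakMarks(none[1], "A")))
})

test_that("gained enhancers carry the configured expectation tag ratio", {
  cfg <- smallCfg(seed = 5, emit_residual_peaks = TRUE,
                  enhancer_intensity_shape = Inf)
  g <- simulateGenome(cfg)
  ch <- simulateChromatin(cfg, g)
  enh <- ch$truth$enhancers
  gained <- enh[enh$status == "gained", ]
  expect_gt(nrow(gained), 0)
  mc <- S4Vectors::mcols(ch$peaks)
  gr <- GenomicRanges::GRanges(gained$chrom,
          IRanges::IRanges(gained$start0 + 1, gained$end0))
  tagsIn <- function(cell) {
    sel <- mc$cell == cell & mc$mark == "H3K27ac"
    h <- GenomicRanges::findOverlaps(gr, ch$peaks[sel])
    sum(mc$tagCount[sel][S4Vectors::subjectHits(h)])
  }
  # fixed intensity: expectation ratio is exactly gain_fold; with Poisson
  # sampling over ~10 enhancers x 60 tags allow a loose band
  ratio <- tagsIn("B") / tagsIn("A")
  expect_gt(ratio, cfg$gain_fold / 2)
  expect_lt(ratio, cfg$gain_fold * 2)
  # by default the other cell contributes no peak at all
  cfg0 <- smallCfg(seed = 5)
  ch0 <- simulateChromatin(cfg0, simulateGenome(cfg0))
  enh0 <- ch0$truth$enhancers
  g0 <- enh0[enh0$status == "gained", ]
  gr0 <- GenomicRanges::GRanges(g0$chrom,
           IRanges::IRanges(g0$start0 + 1, g0$end0))
  mc0 <- S4Vectors::mcols(ch0$peaks)
  aPeaks <- ch0$peaks[mc0$cell == "A" & mc0$mark == "H3K27ac"]
  expect_equal(sum(GenomicRanges::countOverlaps(gr0, aPeaks)), 0)
})

test_that("with noise off every emitted peak maps to a truth record", {
  cfg <- smallCfg(seed = 7)
  g <- simulateGenome(cfg)
  ch <- simulateChromatin(cfg, g)
  tr <- ch$truth
  tssOf <- S4Vectors::mcols(g$genes)$tss
  prom <- GenomicRanges::GRanges(cfg$chrom,
            IRanges::IRanges(tssOf - 1999, tssOf + 2000))
  enhAll <- rbind(tr$enhancers[c("chrom", "start0", "end0")],
                  setNames(tr$superEnhancers[c("chrom", "start0", "end0")],
                           c("chrom", "start0", "end0")))
  known <- c(prom, GenomicRanges::GRanges(enhAll$chrom,
               IRanges::IRanges(enhAll$start0 + 1, enhAll$end0)))
  expect_true(all(GenomicRanges::countOverlaps(ch$peaks, known) > 0))
})

test_that("expression encodes the planted effects exactly when noise is off", {
  cfg <- smallCfg(seed = 2, noise_sd = 0)
  g <- simulateGenome(cfg)
  ch <- simulateChromatin(cfg, g)
  ex <- simulateExpression(cfg, ch$truth)
  tr <- ch$truth$states
  planted <- cfg$effect_log2fc_by_transition[cbind(tr$state_a, tr$state_b)] +
    cfg$enhancer_effect_log2fc * ch$truth$enhancerEffect[tr$gene_id]
  expect_equal(log2(ex$fc), unname(planted), tolerance = 1e-12)
  stable0 <- which(planted == 0)
  expect_true(all(abs(ex$fc[stable0] - 1) < 1e-12))
})

test_that("mean planted log2 fold change concentrates at the CLT rate", {
  cfg <- simConfig(seed = 11, n_genes = 220, chrom_length_bp = 8e6,
                   state_transition_probs = c("None>Active" = 1),
                   enhancer_gain_rate = 0, enhancer_loss_rate = 0,
                   enhancer_stable_rate = 0, se_fraction = 0)
  g <- simulateGenome(cfg)
  ch <- simulateChromatin(cfg, g)
  ex <- simulateExpression(cfg, ch$truth)
  m <- mean(log2(ex$fc))
  expect_lt(abs(m - 2), 3 * cfg$noise_sd / sqrt(220))
})

test_that("sequence planting respects co-occurrence and records true edges", {
  cfg <- smallCfg(seed = 4, n_tfs = 2)
  pwms <- makeSyntheticPwms(2, 8, seed = 5)
  el <- data.frame(element_id = paste0("e", 1:40),
                   gene_id = paste0("g", 1:40))
  sim <- simulateSequences(cfg, el, pwms, plantProb = 1, cooccurProb = 1)
  cons <- vapply(pwms, cistro:::pwmConsensus, "")
  hasWord <- function(s, w) grepl(w, s, fixed = TRUE)
  seqs <- as.character(sim$sequences)
  tf1els <- sim$edges$element_id[sim$edges$tf == names(pwms)[1]]
  expect_gt(length(tf1els), 0)
  for (e in tf1els) {
    expect_true(hasWord(seqs[e], cons[1]))
    expect_true(hasWord(seqs[e], cons[2]))  # cooccurrence prob 1
  }
  # determinism
  sim2 <- simulateSequences(cfg, el, pwms, plantProb = 1, cooccurProb = 1)
  expect_identical(as.character(sim2$sequences), seqs)
  # element shorter than the motif errors
  cfgShort <- smallCfg(element_seq_length = 6)
  expect_error(simulateSequences(cfgShort, el, pwms), "short")
})

test_that("null cohorts are null and the study is fully deterministic", {
  cfg <- smallCfg(seed = 9, hazard_ratio_per_marker = 1, marker_delta = 0)
  co <- simulateCohort(cfg, markerGenes = c("M1", "M2"))
  expect_true(all(co$expr >= 0))
  expect_true(all(co$clinical$time >= 0))
  expect_true(all(co$clinical$event %in% 0:1))
  co2 <- simulateCohort(cfg, markerGenes = c("M1", "M2"))
  expect_identical(co$expr, co2$expr)
  expect_identical(co$clinical, co2$clinical)
})

test_that("a written study is parseable and identical across reruns", {
  cfg <- smallCfg(seed = 12)
  d1 <- file.path(tempfile(), "s1"); d2 <- file.path(tempfile(), "s2")
  simulateStudy(cfg, d1)
  simulateStudy(cfg, d2)
  for (f in c("genes.bed", "expression.tsv", "peaks_B_H3K27ac.bed",
              "cohort.tsv", "truth/states.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  g <- readGeneModels(file.path(d1, "genes.bed"))
  expect_length(g, 60)
  e <- readExpression(file.path(d1, "expression.tsv"))
  expect_equal(nrow(e), 60)
  pw <- readPwms(file.path(d1, "pwms.txt"))
  expect_length(pw, cfg$n_tfs)
  expect_no_error(readPeaks(file.path(d1, "peaks_A_H3K4me3.bed"),
                            "H3K4me3", "A"))
})
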