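test_that("distal filter measures TSS-to-nearest-edge with a >= rule", {
  g <- tinyGenes(tss = c(G1 = 1000))
  keep <- callDistalEnhancers(tinyPeaks(5000, 5500, 10), g)
  expect_length(keep, 1)
  expect_equal(S4Vectors::mcols(keep)$distanceToTss, 4000)
  # peak overlapping the TSS: distance 0
  expect_length(callDistalEnhancers(tinyPeaks(900, 1200, 10), g), 0)
  # edge exactly at the threshold is kept
  atEdge <- callDistalEnhancers(tinyPeaks(3000, 3500, 10), g)
  expect_length(atEdge, 1)
  expect_equal(S4Vectors::mcols(atEdge)$distanceToTss, 2000)
  justIn <- callDistalEnhancers(tinyPeaks(2999, 3500, 10), g)
  expect_length(justIn, 0)
})

test_that("Poisson tail test matches direct pmf summation", {
  t1 <- poissonDiffTest(5, 40, 1e7, 1e7)
  expect_equal(2^t1$log2_ratio, 41 / 6)
  expect_equal(t1$p, sum(dpois(40:2000, 6)), tolerance = 1e-12)
  # library scaling: 5 tags in a 2e7 library scale to 2.5 -> round to 2
  t2 <- poissonDiffTest(5, 40, 2e7, 1e7)
  expect_equal(t2$scaled_a, 2)
  expect_equal(t2$p, sum(dpois(40:2000, 3)), tolerance = 1e-12)
  # equal counts: ratio 1, p 1
  t3 <- poissonDiffTest(7, 7, 1e7, 1e7)
  expect_equal(t3$log2_ratio, 0)
  expect_equal(t3$p, 1)
  t0 <- poissonDiffTest(0, 0, 1e7, 1e7)
  expect_equal(2^t0$log2_ratio, 1)
  expect_error(poissonDiffTest(-1, 3, 1e7, 1e7), "negative")
})

test_that("the differential test is antisymmetric under cell swap", {
  set.seed(10)
  a <- rpois(200, 30); b <- rpois(200, 90)
  f <- poissonDiffTest(a, b, 1e7, 1e7)
  r <- poissonDiffTest(b, a, 1e7, 1e7)
  expect_equal(f$p, r$p)
  expect_equal(f$log2_ratio, -r$log2_ratio)
})

test_that("gained/lost/stable classification honors fold and p thresholds", {
  un <- tinyUnion(tag_a = c(5, 50, 40, 400),
                  tag_b = c(195, 152, 3, 40))
  calls <- classifyEnhancerChanges(un)
  st <- S4Vectors::mcols(calls)$status
  expect_equal(st[1], "gained")   # ratio 196/6 = 32.7, p tiny
  expect_equal(st[2], "stable")   # ratio 3 < 4 despite tiny p
  expect_equal(st[3], "lost")     # ratio 4/41 <= 1/4
  expect_equal(st[4], "lost")
  # statuses partition the union
  expect_true(all(st %in% c("gained", "lost", "stable")))
  expect_length(st, length(un))
})

test_that("nearest gene uses midpoint distance with id tie-break", {
  g <- tinyGenes(tss = c(G2 = 20000, G1 = 1000))
  iv <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4751, 5250))
  ng <- nearestGene(iv, g)  # midpoint 5000
  expect_equal(ng$gene_id, "G1")
  expect_equal(ng$distance, 4000)
  # equidistant between 1000 and 20000 at midpoint 10500
  tie <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10251, 10750))
  gt <- tinyGenes(tss = c(G2 = 20000, G1 = 1000))
  expect_equal(nearestGene(tie, gt)$gene_id, "G1")
  atTss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(751, 1250))
  expect_equal(nearestGene(atTss, g)$distance, 0)
  expect_error(nearestGene(iv, g[0]), "no genes")
})

test_that("null enhancers are called differential at most at the calibrated rate", {
  set.seed(77)
  n <- 10000
  un <- tinyUnion(tag_a = rpois(n, 60), tag_b = rpois(n, 60))
  calls <- classifyEnhancerChanges(un)
  frac <- mean(S4Vectors::mcols(calls)$status != "stable")
  expect_lte(frac, 2 * 1e-4)
})

test_that("planted differential enhancers are recovered from the union", {
  cfg <- simConfig(seed = 41, n_genes = 200, chrom_length_bp = 6.5e6)
  g <- simulateGenome(cfg)
  ch <- simulateChromatin(cfg, g)
  mc <- S4Vectors::mcols(ch$peaks)
  k27 <- function(cl) ch$peaks[mc$cell == cl & mc$mark == "H3K27ac"]
  un <- enhancerUnion(callDistalEnhancers(k27("A"), g$genes),
                      callDistalEnhancers(k27("B"), g$genes))
  calls <- classifyEnhancerChanges(un, genes = g$genes)
  cm <- S4Vectors::mcols(calls)
  tr <- ch$truth$enhancers
  tg <- GenomicRanges::GRanges(tr$chrom,
          IRanges::IRanges(tr$start0 + 1, tr$end0))
  ov <- GenomicRanges::findOverlaps(tg, calls)
  got <- rep("none", length(tg))
  got[S4Vectors::queryHits(ov)] <- cm$status[S4Vectors::subjectHits(ov)]
  expect_gte(mean(got[tr$status == "gained"] == "gained"), 0.9)
  expect_gte(mean(got[tr$status == "lost"] == "lost"), 0.9)
  expect_gte(mean(got[tr$status == "stable"] == "stable"), 0.9)
})

test_that("synergy classes label the promoter x enhancer cross-product", {
  transitions <- data.frame(gene_id = c("G1", "G2", "G3"),
                            state_a = c("Repressive", "Active", "None"),
                            state_b = c("Active", "Active", "None"))
  enh <- tinyUnion(tag_a = c(5, 50), tag_b = c(195, 50))
  S4Vectors::mcols(enh)$status <- c("gained", "stable")
  S4Vectors::mcols(enh)$nearestGene <- c("G1", "G2")
  degs <- data.frame(gene_id = c("G1", "G2", "G3"), fc = c(16, 2, 0.5))
  syn <- synergyTable(transitions, enh, degs)
  r <- syn$records
  expect_equal(r$class[r$gene_id == "G1"], "P:Repressive>Active & E:gained")
  expect_equal(r$enhancer_status[r$gene_id == "G2"], "stable")
  expect_equal(r$enhancer_status[r$gene_id == "G3"], "none")
  expect_equal(r$log2fc[r$gene_id == "G1"], 4)
})

test_that("genes near gained enhancers out-change genes near lost ones", {
  cfg <- simConfig(seed = 42, n_genes = 250, chrom_length_bp = 8e6)
  g <- simulateGenome(cfg)
  ch <- simulateChromatin(cfg, g)
  ex <- simulateExpression(cfg, ch$truth)
  tr <- ch$truth$enhancers
  lfc <- setNames(log2(ex$fc), ex$gene_id)
  gained <- lfc[tr$gene_id[tr$status == "gained"]]
  lost <- lfc[tr$gene_id[tr$status == "lost"]]
  expect_gt(mean(gained), mean(lost))
})
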