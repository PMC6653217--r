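test_that("stitching merges across gaps up to the threshold, transitively", {
  one <- stitchPeaks(tinyPeaks(c(0, 5000), c(1000, 6000), c(10, 10)),
                     genes = NULL)
  expect_length(one, 1)
  b <- cistro:::bed0FromGr(one)
  expect_equal(c(b$start0, b$end0), c(0, 6000))
  expect_equal(S4Vectors::mcols(one)$signal, 20)
  expect_equal(S4Vectors::mcols(one)$nConstituents, 2L)

  two <- stitchPeaks(tinyPeaks(c(0, 14000), c(1000, 15000), c(10, 10)),
                     genes = NULL)
  expect_length(two, 2)

  # chain of three peaks 10 kb apart merges into one (single linkage)
  chain <- stitchPeaks(tinyPeaks(c(0, 11000, 22000),
                                 c(1000, 12000, 23000), c(5, 5, 5)),
                       genes = NULL)
  expect_length(chain, 1)
})

test_that("TSS-proximal peaks are excluded before stitching", {
  g <- tinyGenes(tss = c(G1 = 10000))
  pk <- tinyPeaks(c(9500, 30000), c(10500, 31000), c(100, 10))
  st <- stitchPeaks(pk, genes = g)
  expect_length(st, 1)
  expect_equal(S4Vectors::mcols(st)$signal, 10)
  # with the exclusion off the promoter peak stays
  stOff <- stitchPeaks(pk, tssExclusionBp = 0, genes = g)
  expect_length(stOff, 2)
})

test_that("stitching is idempotent", {
  set.seed(5)
  s0 <- sort(sample(0:500000, 80)) * 10
  pk <- tinyPeaks(s0, s0 + sample(200:2000, 80, replace = TRUE),
                  rpois(80, 50))
  st <- stitchPeaks(pk, genes = NULL)
  again <- stitchPeaks(tinyPeaks(GenomicRanges::start(st) - 1,
                                 GenomicRanges::end(st),
                                 S4Vectors::mcols(st)$signal),
                       genes = NULL)
  expect_equal(GenomicRanges::start(again), GenomicRanges::start(st))
  expect_equal(GenomicRanges::end(again), GenomicRanges::end(st))
  expect_equal(S4Vectors::mcols(again)$signal,
               S4Vectors::mcols(st)$signal)
})

test_that("the inflection cutoff matches the analytic tangent of y = x^2", {
  x <- (0:100) / 100
  cut <- inflectionCutoff(x^2)
  expect_equal(cut, 0.25, tolerance = 1e-3)
  # a straight line never exceeds slope 1: nothing is called
  expect_equal(inflectionCutoff((0:50) / 50), Inf)
  expect_equal(inflectionCutoff(rep(3, 10)), Inf)
  # a single dominant signal is the only super-enhancer
  cut2 <- inflectionCutoff(c(1, 1, 1, 100))
  expect_lt(cut2, 100)
  expect_equal(sum(c(1, 1, 1, 100) > cut2), 1)
  expect_error(inflectionCutoff(c(1, 2)), "at least 3")
})

test_that("the cutoff is invariant under positive rescaling of signals", {
  set.seed(8)
  s <- c(rgamma(150, 16, rate = 16 / 60), rgamma(10, 16, rate = 16 / 900))
  c1 <- inflectionCutoff(s)
  c2 <- inflectionCutoff(s * 37.5)
  expect_equal(c2, c1 * 37.5, tolerance = 1e-9)
  # the SE count is monotone non-increasing in the cutoff
  cuts <- sort(c(c1, quantile(s, c(0.1, 0.5, 0.9))))
  counts <- vapply(cuts, function(cc) sum(s > cc), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("stitching and cutoff agree with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:30) {
    n <- sample(10:100, 1)
    s0 <- sort(sample(0:300000, n))
    w <- sample(100:3000, n, replace = TRUE)
    tags <- rpois(n, 40) + 1
    pk <- tinyPeaks(s0, s0 + w, tags)
    st <- stitchPeaks(pk, genes = NULL)
    oracle <- bruteStitch(s0, s0 + w, 12500)
    expect_equal(GenomicRanges::start(st) - 1, unname(oracle[, 1]))
    expect_equal(GenomicRanges::end(st), unname(oracle[, 2]))
    sig <- S4Vectors::mcols(st)$signal
    if (length(sig) >= 3)
      expect_identical(inflectionCutoff(sig), bruteInflection(sig))
  }
})

test_that("planted clustered loci are recovered as super-enhancers", {
  cfg <- simConfig(seed = 1)
  g <- simulateGenome(cfg)
  ch <- simulateChromatin(cfg, g)
  mc <- S4Vectors::mcols(ch$peaks)
  se <- callSuperEnhancers(ch$peaks[mc$cell == "B" &
                                      mc$mark == "H3K27ac"], g$genes)
  sup <- regions(se)[S4Vectors::mcols(regions(se))$isSuper]
  tr <- ch$truth$superEnhancers
  tg <- GenomicRanges::GRanges(tr$chrom,
          IRanges::IRanges(tr$start0 + 1, tr$end0))
  inter <- sum(GenomicRanges::countOverlaps(sup, tg) > 0)
  jac <- inter / (length(sup) + length(tg) - inter)
  expect_gte(jac, 0.9)
  # every truth locus is found
  expect_equal(sum(GenomicRanges::countOverlaps(tg, sup) > 0), length(tg))
  # empty input gives an empty call set
  emptySe <- callSuperEnhancers(ch$peaks[0], g$genes)
  expect_length(regions(emptySe), 0)
})

test_that("a giant isolated region dominating the signal is called", {
  pk <- tinyPeaks(seq(0, 39 * 20000, by = 20000),
                  seq(0, 39 * 20000, by = 20000) + 1000,
                  c(rep(20, 39), 5000))
  se <- callSuperEnhancers(pk, genes = NULL)
  r <- regions(se)
  expect_true(S4Vectors::mcols(r)$isSuper[which.max(
    S4Vectors::mcols(r)$signal)])
})

test_that("set comparison splits shared, gained and lost by overlap", {
  mk <- function(s0) {
    pk <- tinyPeaks(s0, s0 + 1000, c(rep(10, length(s0) - 1), 1000))
    callSuperEnhancers(pk, genes = NULL)
  }
  base <- seq(0, 6 * 20000, by = 20000)
  seA <- mk(base)
  seB <- mk(base)  # identical: the dominant region is shared
  cmp <- compareSuperEnhancers(seA, seB)
  expect_length(cmp$gained, 0)
  expect_length(cmp$lost, 0)
  expect_length(cmp$sharedB, 1)
  seC <- mk(base + 500000)  # disjoint coordinates
  cmp2 <- compareSuperEnhancers(seA, seC)
  expect_length(cmp2$gained, 1)
  expect_length(cmp2$lost, 1)
  expect_length(cmp2$sharedA, 0)
  # a 1-bp overlap fails a 500-bp requirement
  shift <- mk(base + 999)
  cmp3 <- compareSuperEnhancers(seA, shift, minOverlapBp = 500)
  expect_length(cmp3$sharedB, 0)
})
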