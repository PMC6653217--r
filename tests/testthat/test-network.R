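test_that("scanner scores the consensus at the maximum on both strands", {
  pwm <- onehotPwm("ACGTAC")
  s <- paste0("TTTTT", "ACGTAC", "TTTTT")
  h <- scanPwm(pwm, s)
  expect_equal(nrow(h), 1)
  expect_equal(h$offset, 6)
  expect_equal(h$strand, "+")
  expect_equal(h$score, 6 * log2(4))  # 2 bits per consensus position
  # reverse complement on the minus strand, same score
  rc <- paste0("GGGGG", revcomp("ACGTAC"), "GGGGG")
  h2 <- scanPwm(pwm, rc)
  expect_equal(h2$strand, "-")
  expect_equal(h2$score, h$score)
  expect_equal(h2$offset, 6)
  # PWM wider than the sequence: empty result
  expect_equal(nrow(scanPwm(pwm, "ACG")), 0)
  # N-containing windows are skipped
  expect_equal(nrow(scanPwm(pwm, "ACGNAC")), 0)
})

test_that("scanning the reverse-complemented sequence mirrors hits", {
  set.seed(3)
  pwm <- readPwms(writeTempLines(c(">M",
    "A [ 8 1 0 2 ]", "C [ 1 6 1 2 ]", "G [ 1 2 8 2 ]", "T [ 0 1 1 4 ]"),
    ext = ".txt"), pseudocount = 0.5)$M
  s <- randomSeq(400)
  h <- scanPwm(pwm, s, scoreFraction = 0.7)
  hr <- scanPwm(pwm, revcomp(s), scoreFraction = 0.7)
  expect_equal(nrow(h), nrow(hr))
  expect_equal(sort(h$score), sort(hr$score))
  # offsets mirror: start o on one strand maps to L - w - o + 2
  expect_setequal(400 - pwm$width - h$offset + 2, hr$offset)
})

test_that("hit set equals exhaustive enumeration over all words", {
  pwm <- readPwms(writeTempLines(c(">W",
    "A [ 5 0 1 9 2 ]", "C [ 2 8 1 0 3 ]", "G [ 2 1 7 0 3 ]",
    "T [ 1 1 1 1 2 ]"), ext = ".txt"), pseudocount = 0.25)$W
  bases <- c("A", "C", "G", "T")
  words <- do.call(paste0, expand.grid(bases, bases, bases, bases, bases))
  lo <- log2(pwm$matrix / 0.25)
  scoreOf <- function(word, m) {
    b <- match(strsplit(word, "")[[1]], bases)
    sum(m[cbind(b, 1:5)])
  }
  rcM <- lo[4:1, 5:1]; rownames(rcM) <- bases
  maxScore <- sum(apply(lo, 2, max))
  oracleHit <- vapply(words, function(w)
    scoreOf(w, lo) >= 0.8 * maxScore ||
      scoreOf(w, rcM) >= 0.8 * maxScore, TRUE)
  # isolate every word with N separators so windows never span words
  seq <- paste(words, collapse = "N")
  h <- scanPwm(pwm, seq)
  hitOffsets <- unique(h$offset)
  wordStart <- (seq_along(words) - 1) * 6 + 1
  expect_setequal(hitOffsets, wordStart[oracleHit])
})

test_that("hypergeometric enrichment equals the combinatorial value", {
  expect_equal(hyperEnrichment(4, 4, 5, 10), 6 / 252, tolerance = 1e-12)
  expect_equal(hyperEnrichment(0, 4, 5, 10), 1)
  expect_equal(hyperEnrichment(5, 10, 5, 10), 1)  # all elements hit
  # exhaustive check on every small configuration
  for (N in 2:12) for (n in 1:(N - 1)) for (K in 0:N) {
    for (k in max(0, K + n - N):min(K, n)) {
      oracle <- sum(choose(K, k:min(K, n)) *
                      choose(N - K, n - (k:min(K, n)))) / choose(N, n)
      expect_equal(hyperEnrichment(k, K, n, N), oracle,
                   tolerance = 1e-10)
    }
  }
})

test_that("motif enrichment separates planted targets from background", {
  set.seed(11)
  pwm <- onehotPwm("ACGTACGT")
  tgt <- Biostrings::DNAStringSet(vapply(1:15, function(i)
    paste0(randomSeq(50), "ACGTACGT", randomSeq(50)), ""))
  names(tgt) <- paste0("t", 1:15)
  bgs <- Biostrings::DNAStringSet(vapply(1:30, function(i)
    randomSeq(108), ""))
  names(bgs) <- paste0("b", 1:30)
  e <- motifEnrichment(tgt, bgs, pwm)
  expect_equal(e$k, 15)
  expect_lt(e$p, 1e-8)
  expect_error(motifEnrichment(tgt[0], bgs, pwm), "empty target")
})

test_that("network edges collapse promoter + enhancer evidence to 'both'", {
  promHits <- data.frame(tf = c("TF1", "TF1"),
                         element_id = c("p1", "p2"))
  enhHits <- data.frame(tf = "TF1", element_id = "e1")
  map <- c(p1 = "G1", p2 = "G2", e1 = "G1")
  net <- buildNetwork(promHits, enhHits, map, restrictTfToDeg = FALSE)
  e <- networkEdges(net)
  expect_equal(nrow(e), 2)
  expect_equal(e$mode[e$gene == "G1"], "both")
  expect_equal(e$mode[e$gene == "G2"], "proximal")
  # unmapped elements are skipped with a warning
  expect_warning(
    netW <- buildNetwork(data.frame(tf = "TF1", element_id = "zz"),
                         enhHits[0, ], map, restrictTfToDeg = FALSE),
    "skipped")
  expect_equal(nrow(networkEdges(netW)), 0)
  # DEG restriction drops non-DEG TFs
  netD <- buildNetwork(promHits, enhHits, map, degList = character(),
                       restrictTfToDeg = TRUE)
  expect_equal(nrow(networkEdges(netD)), 0)
})

test_that("Jaccard matrix equals brute-force set computation", {
  expect_equal(unname(jaccardMatrix(buildNetwork(
    data.frame(tf = c("A", "A", "A", "B", "B", "B"),
               element_id = paste0("p", 1:6)),
    NULL, setNames(c("g1", "g2", "g3", "g2", "g3", "g4"),
                   paste0("p", 1:6)),
    restrictTfToDeg = FALSE))["A", "B"]), 0.5)
  set.seed(123)
  for (i in 1:100) {
    nTf <- sample(2:6, 1)
    edges <- unique(data.frame(
      tf = sample(LETTERS[1:nTf], 30, replace = TRUE),
      gene = sample(paste0("g", 1:12), 30, replace = TRUE)))
    edges$element_id <- paste0("el", seq_len(nrow(edges)))
    net <- buildNetwork(edges[c("tf", "element_id")], NULL,
                        setNames(edges$gene, edges$element_id),
                        restrictTfToDeg = FALSE)
    m <- jaccardMatrix(net)
    o <- bruteJaccard(networkEdges(net))
    expect_equal(m, o[rownames(m), colnames(m)])
    expect_true(all(diag(m) == 1))
    expect_equal(m, t(m))
  }
})

test_that("hub rule applies strict inequalities on JI and partner count", {
  mkMat <- function(nPartners, ji) {
    n <- nPartners + 1
    m <- matrix(0, n, n, dimnames = list(paste0("T", 1:n),
                                         paste0("T", 1:n)))
    diag(m) <- 1
    m[1, 2:n] <- ji; m[2:n, 1] <- ji
    m
  }
  expect_equal(hubFactors(mkMat(11, 0.4)), "T1")
  expect_length(hubFactors(mkMat(10, 0.4)), 0)   # needs > 10
  expect_length(hubFactors(mkMat(20, 0.3)), 0)   # needs JI > 0.3
  expect_length(hubFactors(matrix(0, 0, 0)), 0)
})

test_that("planted regulatory edges are recovered at high recall", {
  cfg <- simConfig(seed = 51)
  pwms <- makeSyntheticPwms(cfg$n_tfs, cfg$motif_width, seed = 52)
  el <- data.frame(element_id = paste0("el", 1:120),
                   gene_id = paste0("g", 1:120))
  sim <- simulateSequences(cfg, el, pwms)
  hits <- scanPwmSet(pwms, sim$sequences)
  net <- buildNetwork(hits, NULL, setNames(el$gene_id, el$element_id),
                      restrictTfToDeg = FALSE)
  e <- networkEdges(net)
  truth <- unique(paste(sim$edges$tf, sim$edges$gene_id))
  found <- unique(paste(e$tf, e$gene))
  expect_gte(mean(truth %in% found), 0.95)
})

test_that("the null generator yields no cooperation hubs", {
  cfg0 <- simConfig(seed = 61)
  pwms <- makeSyntheticPwms(6, 8, seed = 62)
  el <- data.frame(element_id = paste0("el", 1:100),
                   gene_id = paste0("g", 1:100))
  hubCounts <- vapply(1:5, function(sd) {
    cfg <- simConfig(seed = 100 + sd)
    sim <- simulateSequences(cfg, el, pwms, plantProb = 0, cooccurProb = 0)
    h <- scanPwmSet(pwms, sim$sequences)
    net <- buildNetwork(h, NULL, setNames(el$gene_id, el$element_id),
                        restrictTfToDeg = FALSE)
    if (length(net@tfs) < 2) return(0L)
    length(hubFactors(jaccardMatrix(net)))
  }, integer(1))
  expect_true(all(hubCounts == 0))
})
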