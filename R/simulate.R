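#' Simulation configuration
#'
#' Assembles and validates the parameter set for the synthetic-study
#' generator. Defaults describe a two-condition design (cell A = parental,
#' cell B = metastatic derivative) on a single toy chromosome, with planted
#' promoter-state transitions, gained/lost/stable distal enhancers,
#' clustered super-enhancer loci, motif-carrying element sequences, and a
#' two-group patient cohort with exponential survival.
#'
#' @param seed integer master seed; every generator derives its stream from
#'   it, so equal seeds give bit-identical studies.
#' @param n_genes number of genes (>= 10).
#' @param chrom chromosome name of the toy genome.
#' @param chrom_length_bp chromosome length.
#' @param min_tss_spacing_bp minimum spacing between adjacent TSSs; the
#'   default 25 kb keeps promoter windows disjoint and planted enhancer
#'   clusters of neighbouring genes more than one stitching distance apart.
#' @param marks histone-mark vocabulary.
#' @param state_transition_probs named probabilities over "fromState>toState"
#'   pairs (Active/Repressive/Poised/None); must sum to 1.
#' @param effect_log2fc_by_transition 4x4 matrix of mean expression log2
#'   fold-change per promoter-state transition (rows = state in A,
#'   cols = state in B).
#' @param enhancer_gain_rate,enhancer_loss_rate,enhancer_stable_rate
#'   per-gene probabilities of carrying a gained / lost / stable distal
#'   enhancer.
#' @param se_fraction fraction of genes carrying a clustered (3-5 enhancer)
#'   super-enhancer locus in cell B.
#' @param gain_fold planted tag-count expectation ratio for gained (and
#'   1/fold for lost) enhancers.
#' @param enhancer_effect_log2fc additive expression effect of a gained
#'   (+) or lost (-) enhancer, log2 units.
#' @param depth_per_cell sequencing library size per cell (tags).
#' @param promoter_tag_mean,enhancer_tag_mean,se_enhancer_tag_mean,
#'   enhancer_mark_tag_mean expected tag counts (at 10 M depth) for promoter
#'   peaks, single enhancers, super-enhancer constituents, and the
#'   accompanying H3K4me1 peaks.
#' @param enhancer_intensity_shape Gamma shape of the per-enhancer
#'   intensity distribution (mean fixed at the configured tag mean);
#'   enhancer strengths are heterogeneous in real chromatin, and a
#'   continuous intensity spectrum is what gives the rank-ordered signal
#'   curve its hockey-stick geometry. `Inf` gives every enhancer the same
#'   intensity. Tag counts remain Poisson given the intensity; the paired
#'   cell uses the same intensity, so planted fold changes are exact in
#'   expectation.
#' @param emit_residual_peaks when TRUE, a gained (lost) enhancer also
#'   emits a weak H3K27ac peak in the other cell with intensity divided by
#'   `gain_fold`, so the measured tag-count expectation ratio equals
#'   `gain_fold` exactly; by default the enhancer peak is present only in
#'   the cell that carries it and the other cell contributes zero tags.
#' @param noise_peak_rate expected background noise peaks per kilobase per
#'   cell (0 disables noise).
#' @param noise_sd log2 expression noise standard deviation.
#' @param base_log2_fpkm_mean,base_log2_fpkm_sd distribution of baseline
#'   log2 FPKM in cell A.
#' @param element_seq_length length (bp) of the simulated sequence
#'   representing each regulatory element.
#' @param n_tfs number of synthetic transcription factors.
#' @param motif_width width of each synthetic motif.
#' @param motif_plant_prob probability an element receives a primary motif.
#' @param motif_cooccurrence_prob probability the partner TF's motif is
#'   co-planted in an element that received a primary motif.
#' @param n_patients cohort size.
#' @param marker_delta expression shift (log2 units) of marker genes in the
#'   latent high-risk patient group.
#' @param hazard_ratio_per_marker hazard multiplier for the high-marker
#'   expression group.
#' @param baseline_hazard exponential baseline hazard (events/month).
#' @param censor_rate fraction of patients subjected to uniform censoring.
#' @param met_rate_group1,met_rate_group2 metastasis probability per latent
#'   group.
#' @param group2_frac fraction of patients in latent group 2.
#' @return a validated list of class `SimulationConfig`.
#' @export
simConfig <- function(seed = 1L,
                      n_genes = 500L,
                      chrom = "chrS",
                      chrom_length_bp = 1.4e7,
                      min_tss_spacing_bp = 25000,
                      marks = c("H3K4me3", "H3K27ac", "H3K4me1",
                                "H3K27me3", "H3K9me3"),
                      state_transition_probs = NULL,
                      effect_log2fc_by_transition = NULL,
                      enhancer_gain_rate = 0.15,
                      enhancer_loss_rate = 0.15,
                      enhancer_stable_rate = 0.30,
                      se_fraction = 0.08,
                      gain_fold = 8,
                      enhancer_effect_log2fc = 1,
                      depth_per_cell = 1e7,
                      promoter_tag_mean = 100,
                      enhancer_tag_mean = 60,
                      se_enhancer_tag_mean = 250,
                      enhancer_mark_tag_mean = 40,
                      enhancer_intensity_shape = 16,
                      emit_residual_peaks = FALSE,
                      noise_peak_rate = 0,
                      noise_sd = 0.5,
                      base_log2_fpkm_mean = 3,
                      base_log2_fpkm_sd = 1,
                      element_seq_length = 300L,
                      n_tfs = 6L,
                      motif_width = 8L,
                      motif_plant_prob = 0.6,
                      motif_cooccurrence_prob = 0.3,
                      n_patients = 200L,
                      marker_delta = 2,
                      hazard_ratio_per_marker = 3,
                      baseline_hazard = 0.02,
                      censor_rate = 0.2,
                      met_rate_group1 = 0.1,
                      met_rate_group2 = 0.5,
                      group2_frac = 0.5) {
  lv <- promoterStateLevels()
  if (is.null(state_transition_probs))
    state_transition_probs <- c(
      "Active>Active" = 0.30, "None>None" = 0.18,
      "Repressive>Repressive" = 0.08, "Poised>Poised" = 0.04,
      "Repressive>Active" = 0.10, "None>Active" = 0.10,
      "Active>Repressive" = 0.06, "Active>None" = 0.08,
      "None>Repressive" = 0.06)
  if (is.null(effect_log2fc_by_transition)) {
    m <- matrix(0, 4, 4, dimnames = list(lv, lv))
    m["Repressive", "Active"] <- 3.2
    m["None", "Active"] <- 2.0
    m["Poised", "Active"] <- 1.5
    m["Active", "Repressive"] <- -3.0
    m["None", "Repressive"] <- -3.2
    m["Poised", "Repressive"] <- -1.5
    m["Active", "None"] <- -2.0
    m["Repressive", "None"] <- 1.0
    m["Poised", "None"] <- -0.5
    m["Active", "Poised"] <- -1.5
    m["Repressive", "Poised"] <- 1.5
    m["None", "Poised"] <- 0.5
    effect_log2fc_by_transition <- m
  }
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              chrom = chrom, chrom_length_bp = chrom_length_bp,
              min_tss_spacing_bp = min_tss_spacing_bp, marks = marks,
              state_transition_probs = state_transition_probs,
              effect_log2fc_by_transition = effect_log2fc_by_transition,
              enhancer_gain_rate = enhancer_gain_rate,
              enhancer_loss_rate = enhancer_loss_rate,
              enhancer_stable_rate = enhancer_stable_rate,
              se_fraction = se_fraction, gain_fold = gain_fold,
              enhancer_effect_log2fc = enhancer_effect_log2fc,
              depth_per_cell = depth_per_cell,
              promoter_tag_mean = promoter_tag_mean,
              enhancer_tag_mean = enhancer_tag_mean,
              se_enhancer_tag_mean = se_enhancer_tag_mean,
              enhancer_mark_tag_mean = enhancer_mark_tag_mean,
              enhancer_intensity_shape = enhancer_intensity_shape,
              emit_residual_peaks = emit_residual_peaks,
              noise_peak_rate = noise_peak_rate, noise_sd = noise_sd,
              base_log2_fpkm_mean = base_log2_fpkm_mean,
              base_log2_fpkm_sd = base_log2_fpkm_sd,
              element_seq_length = as.integer(element_seq_length),
              n_tfs = as.integer(n_tfs),
              motif_width = as.integer(motif_width),
              motif_plant_prob = motif_plant_prob,
              motif_cooccurrence_prob = motif_cooccurrence_prob,
              n_patients = as.integer(n_patients),
              marker_delta = marker_delta,
              hazard_ratio_per_marker = hazard_ratio_per_marker,
              baseline_hazard = baseline_hazard,
              censor_rate = censor_rate,
              met_rate_group1 = met_rate_group1,
              met_rate_group2 = met_rate_group2,
              group2_frac = group2_frac)
  class(cfg) <- "SimulationConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  stopIfNot(cfg$n_genes >= 10L, "n_genes must be >= 10")
  stopIfNot(cfg$depth_per_cell > 0, "depth_per_cell must be > 0")
  probs <- c(cfg$enhancer_gain_rate, cfg$enhancer_loss_rate,
             cfg$enhancer_stable_rate, cfg$se_fraction,
             cfg$motif_plant_prob, cfg$motif_cooccurrence_prob,
             cfg$censor_rate, cfg$met_rate_group1, cfg$met_rate_group2,
             cfg$group2_frac, cfg$state_transition_probs)
  stopIfNot(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  stopIfNot(abs(sum(cfg$state_transition_probs) - 1) < 1e-8,
            "state_transition_probs must sum to 1")
  pairs <- strsplit(names(cfg$state_transition_probs), ">", fixed = TRUE)
  stopIfNot(all(unlist(pairs) %in% promoterStateLevels()),
            "state_transition_probs names must be 'from>to' state pairs")
  stopIfNot(cfg$enhancer_gain_rate + cfg$enhancer_loss_rate +
              cfg$enhancer_stable_rate + cfg$se_fraction <= 1,
            "enhancer role probabilities exceed 1")
  invisible(cfg)
}

# geometry of planted features, relative to the (0-based) TSS
.simGeom <- list(promoter_half = 1500, enh_offset_min = 5000,
                 enh_offset_max = 8000, enh_width = 800,
                 se_gap = 1500, gene_length = 2000, margin = 6000)

#' Simulate a toy genome
#'
#' Places `n_genes` TSSs on one chromosome with a guaranteed minimum
#' spacing, so promoter windows never overlap; strands are Bernoulli(0.5).
#'
#' @param cfg a [simConfig()].
#' @return list with `genes` (stranded GRanges of gene bodies, metadata
#'   `gene_id` and 0-based `tss`) and `chromLength`.
#' @export
simulateGenome <- function(cfg) {
  validateSimConfig(cfg)
  g <- .simGeom
  n <- cfg$n_genes
  usable <- cfg$chrom_length_bp - 2 * g$margin
  slack <- usable - (n - 1) * cfg$min_tss_spacing_bp
  if (slack <= 0)
    stop(sprintf(
      "chrom_length_bp %g too small for %d genes at %g bp minimum spacing",
      cfg$chrom_length_bp, n, cfg$min_tss_spacing_bp))
  set.seed(cfg$seed)
  extras <- sort(runif(n, 0, slack))
  tss <- round(g$margin + (seq_len(n) - 1) * cfg$min_tss_spacing_bp + extras)
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  start0 <- ifelse(strand == "+", tss, tss + 1 - g$gene_length)
  end0 <- ifelse(strand == "+", tss + g$gene_length, tss + 1)
  gene_id <- sprintf("G%04d", seq_len(n))
  genes <- grFromBed0(rep(cfg$chrom, n), start0, end0, strand)
  S4Vectors::mcols(genes)$gene_id <- gene_id
  S4Vectors::mcols(genes)$tss <- tss
  names(genes) <- gene_id
  list(genes = genes, chromLength = cfg$chrom_length_bp)
}

.drawTransitions <- function(cfg, n) {
  keys <- sample(names(cfg$state_transition_probs), n, replace = TRUE,
                 prob = cfg$state_transition_probs)
  parts <- strsplit(keys, ">", fixed = TRUE)
  data.frame(state_a = vapply(parts, `[[`, "", 1L),
             state_b = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

.peakRow <- function(chrom, s0, e0, mark, cell, mean, ds) {
  data.frame(chrom = chrom, start0 = s0, end0 = e0, mark = mark,
             cell = cell, tagCount = rpois(length(s0), mean * ds),
             stringsAsFactors = FALSE)
}

#' Simulate histone-mark peaks and the chromatin ground truth
#'
#' For every gene a promoter-state pair (cell A, cell B) is drawn and the
#' corresponding promoter peaks emitted: H3K4me3 + H3K27ac for Active and
#' Poised promoters, H3K27me3 for Repressive and Poised. Distal enhancers
#' (H3K27ac + H3K4me1, 5-8 kb downstream of the TSS) are planted with
#' status gained (tag expectation `gain_fold` times higher in B), lost
#' (mirror image) or stable; a configurable fraction of genes instead carry
#' a cluster of 3-5 high-signal enhancers within one stitching distance in
#' cell B (the true super-enhancer loci). Tag counts are Poisson with
#' depth-scaled means; optional uniform background noise peaks can be added.
#'
#' @param cfg a [simConfig()].
#' @param genome output of [simulateGenome()].
#' @return list with `peaks` (GRanges, metadata `name`, `tagCount`,
#'   `score`, `mark`, `cell`) and `truth` (list of data.frames: `states`,
#'   `enhancers`, `superEnhancers`, plus per-gene `enhancerEffect`).
#' @export
simulateChromatin <- function(cfg, genome) {
  validateSimConfig(cfg)
  g <- .simGeom
  genes <- genome$genes
  n <- length(genes)
  tss <- S4Vectors::mcols(genes)$tss
  gid <- S4Vectors::mcols(genes)$gene_id
  ds <- cfg$depth_per_cell / 1e7
  set.seed(cfg$seed + 101L)

  states <- .drawTransitions(cfg, n)
  states$gene_id <- gid
  states <- states[c("gene_id", "state_a", "state_b")]

  rows <- list()
  pw <- g$promoter_half
  for (cell in c("A", "B")) {
    st <- if (cell == "A") states$state_a else states$state_b
    act <- st %in% c("Active", "Poised")
    rep_ <- st %in% c("Repressive", "Poised")
    if (any(act)) {
      rows[[length(rows) + 1L]] <- .peakRow(cfg$chrom, tss[act] - pw,
        tss[act] + pw, "H3K4me3", cell, cfg$promoter_tag_mean, ds)
      rows[[length(rows) + 1L]] <- .peakRow(cfg$chrom, tss[act] - pw,
        tss[act] + pw, "H3K27ac", cell, cfg$promoter_tag_mean, ds)
    }
    if (any(rep_))
      rows[[length(rows) + 1L]] <- .peakRow(cfg$chrom, tss[rep_] - pw,
        tss[rep_] + pw, "H3K27me3", cell, cfg$promoter_tag_mean, ds)
  }

  # per-gene enhancer role
  role <- sample(c("gained", "lost", "stable", "se", "none"), n,
                 replace = TRUE,
                 prob = c(cfg$enhancer_gain_rate, cfg$enhancer_loss_rate,
                          cfg$enhancer_stable_rate, cfg$se_fraction,
                          1 - cfg$enhancer_gain_rate - cfg$enhancer_loss_rate -
                            cfg$enhancer_stable_rate - cfg$se_fraction))
  enh <- list(); se <- list()
  # per-enhancer intensity: Gamma around the configured mean (continuous
  # strength spectrum); the same draw drives both cells, so the planted
  # expectation ratio is exact
  drawIntensity <- function(n, mean) {
    if (is.infinite(cfg$enhancer_intensity_shape)) rep(mean, n)
    else rgamma(n, shape = cfg$enhancer_intensity_shape,
                rate = cfg$enhancer_intensity_shape / mean)
  }
  for (i in which(role %in% c("gained", "lost", "stable"))) {
    off <- round(runif(1, g$enh_offset_min, g$enh_offset_max))
    s0 <- tss[i] + off; e0 <- s0 + g$enh_width
    int <- drawIntensity(1, cfg$enhancer_tag_mean)
    emitA <- role[i] != "gained" || cfg$emit_residual_peaks
    emitB <- role[i] != "lost" || cfg$emit_residual_peaks
    mA <- switch(role[i], gained = int / cfg$gain_fold, lost = int,
                 stable = int)
    mB <- switch(role[i], gained = int, lost = int / cfg$gain_fold,
                 stable = int)
    if (emitA)
      rows[[length(rows) + 1L]] <- .peakRow(cfg$chrom, s0, e0, "H3K27ac", "A",
                                            mA, ds)
    if (emitB)
      rows[[length(rows) + 1L]] <- .peakRow(cfg$chrom, s0, e0, "H3K27ac", "B",
                                            mB, ds)
    k4cell <- switch(role[i], gained = "B", lost = "A", stable = c("A", "B"))
    for (cc in k4cell)
      rows[[length(rows) + 1L]] <- .peakRow(cfg$chrom, s0, e0, "H3K4me1", cc,
                                            cfg$enhancer_mark_tag_mean, ds)
    enh[[length(enh) + 1L]] <- data.frame(
      enh_id = sprintf("E_%s", gid[i]), chrom = cfg$chrom, start0 = s0,
      end0 = e0, gene_id = gid[i], status = role[i],
      stringsAsFactors = FALSE)
  }
  for (i in which(role == "se")) {
    k <- sample(3:5, 1)
    s0 <- tss[i] + g$enh_offset_min +
      (seq_len(k) - 1) * (g$enh_width + g$se_gap)
    e0 <- s0 + g$enh_width
    rows[[length(rows) + 1L]] <- .peakRow(cfg$chrom, s0, e0, "H3K27ac", "B",
      drawIntensity(k, cfg$se_enhancer_tag_mean), ds)
    rows[[length(rows) + 1L]] <- .peakRow(cfg$chrom, s0, e0, "H3K4me1", "B",
                                          cfg$enhancer_mark_tag_mean, ds)
    se[[length(se) + 1L]] <- data.frame(
      se_id = sprintf("SE_%s", gid[i]), chrom = cfg$chrom,
      start0 = min(s0), end0 = max(e0), gene_id = gid[i],
      n_constituents = k, stringsAsFactors = FALSE)
  }

  if (cfg$noise_peak_rate > 0) {
    for (cell in c("A", "B")) {
      nn <- rpois(1, cfg$noise_peak_rate * cfg$chrom_length_bp / 1000)
      if (nn > 0) {
        s0 <- round(runif(nn, 0, cfg$chrom_length_bp - 600))
        rows[[length(rows) + 1L]] <- .peakRow(cfg$chrom, s0, s0 + 500,
          sample(cfg$marks, nn, replace = TRUE), cell, 10, ds)
      }
    }
  }

  df <- do.call(rbind, rows)
  peaks <- grFromBed0(df$chrom, df$start0, df$end0)
  S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(
    name = sprintf("pk%05d", seq_len(nrow(df))), tagCount = df$tagCount,
    score = NA_real_, mark = df$mark, cell = df$cell)

  enhDf <- if (length(enh)) do.call(rbind, enh) else
    data.frame(enh_id = character(), chrom = character(),
               start0 = numeric(), end0 = numeric(), gene_id = character(),
               status = character())
  seDf <- if (length(se)) do.call(rbind, se) else
    data.frame(se_id = character(), chrom = character(), start0 = numeric(),
               end0 = numeric(), gene_id = character(),
               n_constituents = integer())
  effect <- setNames(rep(0L, n), gid)
  effect[enhDf$gene_id[enhDf$status == "gained"]] <- 1L
  effect[seDf$gene_id] <- 1L
  effect[enhDf$gene_id[enhDf$status == "lost"]] <- -1L
  list(peaks = peaks,
       truth = list(states = states, enhancers = enhDf,
                    superEnhancers = seDf, enhancerEffect = effect))
}

#' Simulate an expression table coupled to the chromatin ground truth
#'
#' log2(fpkm_b) - log2(fpkm_a) = transition effect + enhancer effect x
#' (gained - lost) + Normal(0, noise_sd). q-values are simulated small for
#' genes with a planted effect and Uniform(0,1) otherwise.
#'
#' @param cfg a [simConfig()].
#' @param truth the `truth` element of [simulateChromatin()].
#' @return expression data.frame as from [readExpression()].
#' @export
simulateExpression <- function(cfg, truth) {
  validateSimConfig(cfg)
  set.seed(cfg$seed + 202L)
  st <- truth$states
  n <- nrow(st)
  eff <- cfg$effect_log2fc_by_transition[cbind(st$state_a, st$state_b)] +
    cfg$enhancer_effect_log2fc * truth$enhancerEffect[st$gene_id]
  baseA <- rnorm(n, cfg$base_log2_fpkm_mean, cfg$base_log2_fpkm_sd)
  logB <- baseA + eff + rnorm(n, 0, cfg$noise_sd)
  fpkm_a <- 2^baseA
  fpkm_b <- 2^logB
  q <- ifelse(eff != 0, runif(n, 0, 5e-5), runif(n))
  data.frame(gene_id = st$gene_id, fpkm_a = fpkm_a, fpkm_b = fpkm_b,
             fc = fpkm_b / fpkm_a, q = q, is_deg = FALSE,
             direction = NA_character_, stringsAsFactors = FALSE)
}

#' Simulate TSS-proximal tag positions for profile plots
#'
#' Emits single-position tags around every TSS whose per-gene intensity is
#' coupled to the expression rank: activation-associated marks (H3K4me3,
#' H3K27ac, H3K4me1) load onto highly expressed genes, repression-associated
#' marks (H3K27me3, H3K9me3) onto lowly expressed ones. Positions are
#' Normal(TSS, 800 bp).
#'
#' @param cfg a [simConfig()].
#' @param genome output of [simulateGenome()].
#' @param expr expression table (uses `fpkm_a` ranking).
#' @param tagsPerGene peak tag intensity at the extreme rank.
#' @return data.frame with columns `mark`, `pos` (0-based tag positions),
#'   plus attribute `librarySize` = total tags per mark.
#' @export
simulateTssTags <- function(cfg, genome, expr, tagsPerGene = 40) {
  validateSimConfig(cfg)
  set.seed(cfg$seed + 303L)
  genes <- genome$genes
  tss <- S4Vectors::mcols(genes)$tss
  fr <- rank(expr$fpkm_a[match(S4Vectors::mcols(genes)$gene_id,
                               expr$gene_id)],
             ties.method = "first") / length(genes)
  out <- list()
  for (mark in c("H3K4me3", "H3K27ac", "H3K4me1", "H3K27me3", "H3K9me3")) {
    active <- mark %in% c("H3K4me3", "H3K27ac", "H3K4me1")
    lam <- 2 + tagsPerGene * (if (active) fr else 1 - fr)
    nt <- rpois(length(tss), lam)
    pos <- round(rep(tss, nt) + rnorm(sum(nt), 0, 800))
    pos <- pmin(pmax(pos, 0), cfg$chrom_length_bp - 1)
    out[[mark]] <- data.frame(mark = mark, pos = pos,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthetic one-hot position weight matrices
#'
#' Builds `nTf` PWMs with distinct random consensus words and probability-1
#' columns, so a scan at the default fraction-of-max threshold recovers
#' exactly the planted occurrences. Consensi are pairwise distinct and no
#' consensus equals another's reverse complement.
#'
#' @param nTf number of TFs.
#' @param width motif width.
#' @param seed RNG seed.
#' @param tfNames optional TF names (default TF1..TFn).
#' @return named PWM list in the format of [readPwms()].
#' @export
makeSyntheticPwms <- function(nTf, width = 8L, seed = 1L, tfNames = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  words <- character(0)
  banned <- character(0)
  while (length(words) < nTf) {
    w <- paste(sample(bases, width, replace = TRUE), collapse = "")
    rc <- .revcompStr(w)
    if (!(w %in% banned) && w != rc) {
      words <- c(words, w)
      banned <- c(banned, w, rc)
    }
  }
  if (is.null(tfNames)) tfNames <- paste0("TF", seq_len(nTf))
  out <- lapply(seq_len(nTf), function(i) {
    m <- matrix(0, 4, width, dimnames = list(bases, NULL))
    b <- strsplit(words[i], "")[[1]]
    m[cbind(match(b, bases), seq_len(width))] <- 1
    list(tf_name = tfNames[i], matrix = m, width = width)
  })
  names(out) <- tfNames
  out
}

.revcompStr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

pwmConsensus <- function(pwm) {
  paste(rownames(pwm$matrix)[apply(pwm$matrix, 2, which.max)], collapse = "")
}

#' Simulate element sequences with planted motif occurrences
#'
#' Background bases are i.i.d. uniform. Each element receives, with
#' probability `motif_plant_prob`, one exact-consensus occurrence of a
#' uniformly chosen primary TF; the partner TF (cyclic successor in the TF
#' list) is co-planted with probability `motif_cooccurrence_prob`. Primary
#' motifs land in the left half of the element and partners in the right
#' half, so co-planted occurrences never overwrite each other. All planted
#' (TF, element, gene) triples are returned as the true edge set.
#'
#' @param cfg a [simConfig()].
#' @param elements GRanges (or data.frame) with metadata/columns
#'   `element_id` and `gene_id`.
#' @param pwms PWM list (e.g. [makeSyntheticPwms()]).
#' @param plantProb,cooccurProb overrides for the config probabilities.
#' @return list with `sequences` ([Biostrings::DNAStringSet] named by
#'   element id) and `edges` (data.frame `tf`, `element_id`, `gene_id`).
#' @export
simulateSequences <- function(cfg, elements, pwms,
                              plantProb = cfg$motif_plant_prob,
                              cooccurProb = cfg$motif_cooccurrence_prob) {
  validateSimConfig(cfg)
  set.seed(cfg$seed + 404L)
  if (inherits(elements, "GRanges")) {
    eid <- S4Vectors::mcols(elements)$element_id
    gid <- S4Vectors::mcols(elements)$gene_id
  } else {
    eid <- elements$element_id; gid <- elements$gene_id
  }
  L <- cfg$element_seq_length
  wmax <- max(vapply(pwms, function(p) as.numeric(p$width), 0))
  if (L < wmax)
    stop("element sequence length ", L, " shorter than motif width ", wmax)
  if (L < 2 * wmax + 2)
    stop("element too short to host two non-overlapping motifs")
  tfs <- names(pwms)
  cons <- vapply(pwms, pwmConsensus, "")
  n <- length(eid)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
  edges <- list()
  half <- L %/% 2
  for (i in seq_len(n)) {
    if (runif(1) >= plantProb) next
    ti <- sample(length(tfs), 1)
    w <- pwms[[ti]]$width
    off <- sample.int(half - w + 1L, 1)  # left half
    substr(seqs[i], off, off + w - 1L) <- cons[ti]
    edges[[length(edges) + 1L]] <- data.frame(
      tf = tfs[ti], element_id = eid[i], gene_id = gid[i],
      stringsAsFactors = FALSE)
    if (length(tfs) > 1 && runif(1) < cooccurProb) {
      pj <- ti %% length(tfs) + 1L
      wp <- pwms[[pj]]$width
      off2 <- half + sample.int(L - half - wp + 1L, 1)
      substr(seqs[i], off2, off2 + wp - 1L) <- cons[pj]
      edges[[length(edges) + 1L]] <- data.frame(
        tf = tfs[pj], element_id = eid[i], gene_id = gid[i],
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(tf = character(), element_id = character(),
               gene_id = character())
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- eid
  list(sequences = ss, edges = edges)
}

#' Simulate a two-group patient cohort with survival
#'
#' Patients fall into two latent groups; marker genes are shifted by
#' `marker_delta` (log2 units) in group 2; the metastasis label is
#' Bernoulli with a higher rate in group 2. Survival time is exponential
#' with the hazard multiplied by `hazard_ratio_per_marker` for patients in
#' the high marker-expression half (mean split of the mean marker value),
#' with independent uniform censoring applied to a `censor_rate` fraction.
#'
#' @param cfg a [simConfig()].
#' @param markerGenes character vector of marker gene ids (>= 1).
#' @param nNoiseGenes unshifted filler genes included in the matrix.
#' @return list with `expr` (genes x patients matrix, non-negative),
#'   `clinical` (data.frame `patient_id`, `time`, `event`,
#'   `metastasis_label`, `group_true`).
#' @export
simulateCohort <- function(cfg, markerGenes, nNoiseGenes = 30L) {
  validateSimConfig(cfg)
  stopIfNot(length(markerGenes) >= 1, "need at least one marker gene")
  set.seed(cfg$seed + 505L)
  n <- cfg$n_patients
  grp <- 1L + rbinom(n, 1, cfg$group2_frac)
  genes <- c(markerGenes, sprintf("NOISE%03d", seq_len(nNoiseGenes)))
  expr <- matrix(rnorm(length(genes) * n, 5, 1), length(genes), n,
                 dimnames = list(genes, sprintf("P%03d", seq_len(n))))
  expr[markerGenes, grp == 2L] <-
    expr[markerGenes, grp == 2L, drop = FALSE] + cfg$marker_delta
  expr[expr < 0] <- 0
  met <- rbinom(n, 1, ifelse(grp == 2L, cfg$met_rate_group2,
                             cfg$met_rate_group1))
  score <- colMeans(expr[markerGenes, , drop = FALSE])
  high <- score > mean(score)
  rate <- cfg$baseline_hazard *
    ifelse(high, cfg$hazard_ratio_per_marker, 1)
  tev <- rexp(n, rate)
  cmax <- 2 / cfg$baseline_hazard
  cens <- ifelse(runif(n) < cfg$censor_rate, runif(n, 0, cmax), Inf)
  time <- pmin(tev, cens)
  event <- as.integer(tev <= cens)
  list(expr = expr,
       clinical = data.frame(patient_id = colnames(expr), time = time,
                             event = event, metastasis_label = met,
                             group_true = grp, stringsAsFactors = FALSE))
}

#' Generate and write a complete synthetic study
#'
#' Runs every generator and writes the study to `outDir` in the formats the
#' parsers read: `genes.bed`, `peaks_<cell>_<mark>.bed`, `tags_<mark>.bed`,
#' `expression.tsv`, `pwms.txt`, `elements.tsv` + `sequences.fa`,
#' `hallmarks.gmt`, `cohort.tsv`, and the ground truth under `truth/`.
#'
#' @param cfg a [simConfig()].
#' @param outDir output directory (created).
#' @return invisibly, a list with the in-memory objects (`genome`,
#'   `chromatin`, `expr`, `tags`, `pwms`, `seqs`, `cohort`, `markerGenes`).
#' @export
simulateStudy <- function(cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outDir, "truth"), showWarnings = FALSE)
  genome <- simulateGenome(cfg)
  chromatin <- simulateChromatin(cfg, genome)
  expr <- simulateExpression(cfg, chromatin$truth)
  tags <- simulateTssTags(cfg, genome, expr)
  writeGeneModels(genome$genes, file.path(outDir, "genes.bed"))
  pk <- chromatin$peaks
  mc <- S4Vectors::mcols(pk)
  for (cell in c("A", "B")) for (mark in cfg$marks) {
    sel <- pk[mc$cell == cell & mc$mark == mark]
    writePeaks(sel, file.path(outDir, sprintf("peaks_%s_%s.bed", cell, mark)))
  }
  for (mark in unique(tags$mark)) {
    p <- tags$pos[tags$mark == mark]
    write.table(data.frame(cfg$chrom, p, p + 1),
                file.path(outDir, sprintf("tags_%s.bed", mark)),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  writeExpression(expr, file.path(outDir, "expression.tsv"))

  # TF names are real gene ids so the DEG restriction is meaningful
  set.seed(cfg$seed + 606L)
  tfGenes <- sample(expr$gene_id, cfg$n_tfs)
  pwms <- makeSyntheticPwms(cfg$n_tfs, cfg$motif_width,
                            seed = cfg$seed + 707L, tfNames = tfGenes)
  writePwms(pwms, file.path(outDir, "pwms.txt"))

  tssdf <- S4Vectors::mcols(genome$genes)
  proms <- data.frame(element_id = paste0("prom_", tssdf$gene_id),
                      gene_id = tssdf$gene_id, type = "promoter",
                      stringsAsFactors = FALSE)
  enh <- chromatin$truth$enhancers
  enhEl <- if (nrow(enh)) data.frame(element_id = enh$enh_id,
                                     gene_id = enh$gene_id,
                                     type = "enhancer",
                                     stringsAsFactors = FALSE)
           else proms[0, ]
  elements <- rbind(proms, enhEl)
  seqs <- simulateSequences(cfg, elements, pwms)
  write.table(elements, file.path(outDir, "elements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(seqs$sequences,
                              file.path(outDir, "sequences.fa"))

  # hallmark-style gene sets: one enriched in state-changing genes, two null
  set.seed(cfg$seed + 808L)
  st <- chromatin$truth$states
  changed <- st$gene_id[st$state_a != st$state_b]
  hm <- list(
    HM_INVASION = unique(c(sample(changed, min(30, length(changed))),
                           sample(st$gene_id, 10))),
    HM_NEUTRAL1 = sample(st$gene_id, 40),
    HM_NEUTRAL2 = sample(st$gene_id, 40))
  writeGmt(hm, file.path(outDir, "hallmarks.gmt"))

  up <- st$gene_id[st$state_a == "Repressive" & st$state_b == "Active"]
  markerGenes <- if (length(up) >= 5) up[seq_len(min(20, length(up)))] else
    st$gene_id[seq_len(10)]
  cohort <- simulateCohort(cfg, markerGenes)
  cdf <- cbind(cohort$clinical[c("patient_id", "time", "event",
                                 "metastasis_label")],
               as.data.frame(t(cohort$expr)))
  write.table(cdf, file.path(outDir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  tr <- chromatin$truth
  write.table(tr$states, file.path(outDir, "truth", "states.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tr$enhancers, file.path(outDir, "truth", "enhancers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tr$superEnhancers,
              file.path(outDir, "truth", "super_enhancers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(seqs$edges, file.path(outDir, "truth", "edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$clinical, file.path(outDir, "truth", "patients.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste("seed", cfg$seed), paste("n_genes", cfg$n_genes)),
             file.path(outDir, "truth", "config.txt"))
  invisible(list(genome = genome, chromatin = chromatin, expr = expr,
                 tags = tags, pwms = pwms, seqs = seqs, cohort = cohort,
                 markerGenes = markerGenes, elements = elements))
}

#' Write PWMs in JASPAR text format
#' @param pwms PWM list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$tf_name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste(b, "[", paste(format(p$matrix[b, ], trim = TRUE),
                                     collapse = " "), "]"), con)
  }
  invisible(path)
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
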