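## Synthetic-data generator: a fully seeded fixture bundle (annotation,
## genome FASTA, counts, peaks, tracks, open chromatin) with planted ground
## truth for every structure the downstream analysis assumes: five temporal
## expression templates with KO effects, 4-TF combinatorial promoter
## classes (CENL enrichment in cluster B), CEBPE-to-E2F1 promoter distances
## with motif strength anti-correlated to distance, and CEBP-motif-bearing
## enhancers near late-cluster genes inside open chromatin.
##
## One global seed feeds independent named substreams (annotation / truth /
## expression / binding), so each simulator can be re-run alone and still
## reproduce its slice of the bundle.

#' Default CEBP-family motif model (consensus ATTGCGCAAT)
#' @param p_consensus Probability mass on the consensus base per column.
#' @export
default_cebp_motif <- function(p_consensus = 0.97) {
  consensus <- strsplit("ATTGCGCAAT", "")[[1]]
  off <- (1 - p_consensus) / 3
  ppm <- matrix(off, 4, length(consensus),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) ppm[consensus[j], j] <- p_consensus
  motif_model(ppm, name = "CEBP")
}

#' Simulation configuration
#'
#' Defaults define the study conditions of the synthetic cohort: 3000
#' genes on 3 chromosomes at 20 kb spacing; 10 WT stages (8 granulocytic
#' plus 2 monocytic) and 4 KO stages with 3 replicates each; negative
#' binomial counts at dispersion 0.1; a knockout effect of |log2FC| = 1.5;
#' CENL promoter frequency 20% within cluster B versus 2% elsewhere.
#'
#' @param seed Global integer seed.
#' @param n_genes,n_chromosomes,gene_spacing Gene layout.
#' @param wt_stages,ko_stages Ordered stage labels.
#' @param replicates Replicates per (stage, genotype).
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param cluster_fractions Named fractions over A-E and background
#'   (sum <= 1; remainder goes to background).
#' @param de_fraction Per-cluster fraction of non-CENL genes that are DE in
#'   the knockout.
#' @param ko_effect_log2fc Planted |log2FC| of DE genes.
#' @param cenl_fraction_in_B,cenl_fraction_elsewhere Planted CENL rates.
#' @param bit_prob_ab,bit_prob_other Per-TF promoter binding probabilities
#'   for clusters A/B and for all other genes.
#' @param peak_width Planted peak width (bp).
#' @param motif CEBP [motif_model()] planted at motif-assisted CEBPE sites
#'   and enhancers.
#' @param signal_jitter_sd Per-bin track noise SD (0 = noise-free).
#' @param false_peak_rate False peaks per gene per TF.
#' @param bin_size Track bin size (bp).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 3000L,
                       n_chromosomes = 3L,
                       gene_spacing = 20000L,
                       wt_stages = c("LSK", "GMP", "GP", "PM", "MY",
                                     "MM", "BC", "GR", "PMO", "MO"),
                       ko_stages = c("GP", "PM", "MY", "MM"),
                       replicates = 3L,
                       nb_dispersion = 0.1,
                       cluster_fractions = c(A = 0.20, B = 0.15, C = 0.15,
                                             D = 0.05, E = 0.10,
                                             background = 0.35),
                       de_fraction = c(A = 0.40, B = 0.15, C = 0.41,
                                       D = 0.30, E = 0.10,
                                       background = 0.05),
                       ko_effect_log2fc = 1.5,
                       cenl_fraction_in_B = 0.20,
                       cenl_fraction_elsewhere = 0.02,
                       bit_prob_ab = c("PU.1" = 0.40, "CEBPA" = 0.30,
                                       "CEBPE" = 0.30, "MYC" = 0.25,
                                       "E2F1" = 0.30, "NFYB" = 0.20,
                                       "LIN54" = 0.20),
                       bit_prob_other = 0.10,
                       peak_width = 400L,
                       motif = default_cebp_motif(),
                       signal_jitter_sd = 0.1,
                       false_peak_rate = 0.02,
                       bin_size = 100L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chromosomes = as.integer(n_chromosomes),
              gene_spacing = as.integer(gene_spacing),
              wt_stages = wt_stages, ko_stages = ko_stages,
              replicates = as.integer(replicates),
              nb_dispersion = nb_dispersion,
              cluster_fractions = cluster_fractions,
              de_fraction = de_fraction,
              ko_effect_log2fc = ko_effect_log2fc,
              cenl_fraction_in_B = cenl_fraction_in_B,
              cenl_fraction_elsewhere = cenl_fraction_elsewhere,
              bit_prob_ab = bit_prob_ab, bit_prob_other = bit_prob_other,
              peak_width = as.integer(peak_width), motif = motif,
              signal_jitter_sd = signal_jitter_sd,
              false_peak_rate = false_peak_rate,
              bin_size = as.integer(bin_size))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1 || cfg$n_chromosomes < 1) {
    stop("config error: n_genes and n_chromosomes must be positive")
  }
  if (cfg$gene_spacing <= 0) stop("config error: gene_spacing must be > 0")
  if (cfg$peak_width <= 0) stop("config error: peak_width must be > 0")
  if (cfg$replicates < 1) stop("config error: replicates must be >= 1")
  fr <- cfg$cluster_fractions
  if (any(fr < 0 | fr > 1) || sum(fr) > 1 + 1e-9) {
    stop("config error: cluster_fractions must lie in [0,1] and sum <= 1")
  }
  need <- c("A", "B", "C", "D", "E")
  if (!all(need %in% names(fr))) {
    stop("config error: cluster_fractions must name clusters A-E")
  }
  if (!all(cfg$ko_stages %in% cfg$wt_stages)) {
    stop("config error: ko_stages must be a subset of wt_stages")
  }
  for (p in c(cfg$cenl_fraction_in_B, cfg$cenl_fraction_elsewhere,
              cfg$de_fraction, cfg$bit_prob_ab, cfg$bit_prob_other,
              cfg$false_peak_rate)) {
    if (any(p < 0 | p > 1)) stop("config error: probabilities must be in [0,1]")
  }
  if (cfg$signal_jitter_sd < 0) stop("config error: negative jitter sd")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed=", x$seed, " genes=", x$n_genes, " chroms=",
      x$n_chromosomes, " stages=", length(x$wt_stages), "WT+",
      length(x$ko_stages), "KO x", x$replicates, " reps\n", sep = "")
  invisible(x)
}

#' Stage-profile templates of the five planted clusters
#'
#' Multiplicative expression templates over the WT stages: A decays after
#' the early progenitor stages, B peaks transiently at MY, C rises through
#' late granulocytic stages, D rises late in both the granulocytic and
#' monocytic arms, E is expressed only in the monocytic arm, background is
#' flat.
#'
#' @param config A [sim_config()].
#' @param include_background Include the flat background row.
#' @return Matrix (clusters x stages).
#' @export
cluster_templates <- function(config, include_background = FALSE) {
  s <- length(config$wt_stages)
  if (s != 10) {
    # generic shapes for non-default stage counts
    idx <- seq_len(s)
    early <- rev(idx) / s
    mid <- exp(-((idx - ceiling(s / 2))^2) / 2)
    late <- idx / s
    tm <- rbind(A = 0.25 + 4 * early, B = 0.5 + 8 * mid,
                C = 0.25 + 8 * late^2, D = 0.25 + 6 * late,
                E = c(rep(0.25, s - 2), 4, 8))
  } else {
    tm <- rbind(
      A = c(4, 4, 3, 2, 1, 0.5, 0.25, 0.25, 1, 0.5),
      B = c(0.5, 0.5, 1, 2, 8, 2, 0.5, 0.5, 0.5, 0.5),
      C = c(0.25, 0.25, 0.25, 0.5, 1, 3, 5, 8, 0.25, 0.25),
      D = c(0.25, 0.25, 0.25, 0.5, 1, 2, 4, 6, 4, 6),
      E = c(0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25, 4, 8))
  }
  if (include_background) tm <- rbind(tm, background = rep(1, s))
  colnames(tm) <- config$wt_stages
  tm
}

#' Simulate the gene annotation and genome sequence
#'
#' Genes are evenly spaced (plus/minus 10% positional jitter) on
#' `n_chromosomes` chromosomes with alternating strand; the genome is
#' i.i.d. uniform ACGT. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return `list(annotation, genome)`.
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  with_seed(substream(config$seed, "annotation"), {
    sp <- config$gene_spacing
    per <- rep(config$n_genes %/% config$n_chromosomes,
               config$n_chromosomes)
    extra <- config$n_genes - sum(per)
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    per <- per[per > 0]
    chroms <- stats::setNames((per + 1) * sp,
                              paste0("chr", seq_along(per)))
    genes <- NULL
    gi <- 0L
    for (ci in seq_along(per)) {
      n <- per[ci]
      tss <- round(seq_len(n) * sp - sp / 2 +
                     stats::runif(n, -0.1 * sp, 0.1 * sp))
      tss <- pmax(0, pmin(chroms[ci] - 1, tss))
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("g%04d", gi + seq_len(n)),
        chrom = names(chroms)[ci],
        strand = rep(c("+", "-"), length.out = n),
        tss = tss, stringsAsFactors = FALSE))
      gi <- gi + n
    }
    annotation <- genome_annotation(chroms, genes)
    genome <- vapply(chroms, function(len) {
      intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, len, replace = TRUE)])
    }, character(1))
    list(annotation = annotation, genome = genome)
  })
}

#' Plant the per-gene ground truth
#'
#' Assigns each gene a major cluster (A-E or background), a CENL flag
#' (probability `cenl_fraction_in_B` inside cluster B, otherwise
#' `cenl_fraction_elsewhere`), a knockout DE status with its true log2FC
#' (CENL genes are always Up; cluster C DE genes are Down; other DE genes
#' split evenly), the 7-TF promoter binding bits (CENL genes always carry
#' CEBPE, E2F1, NFYB and LIN54), and -- for cluster A/B genes with CEBPE
#' binding -- a planted distance to the nearest E2F1 site together with a
#' CEBP motif strength (0 = none, 1 = two-base degraded, 2 = full
#' consensus) that is anti-correlated with the distance.
#'
#' @param annotation From [simulate_annotation()].
#' @param config A [sim_config()].
#' @return `data.frame` of class `synthetic_truth`.
#' @export
simulate_truth <- function(annotation, config) {
  g <- annotation$genes
  n <- nrow(g)
  tfs <- names(config$bit_prob_ab)
  with_seed(substream(config$seed, "truth"), {
    fr <- config$cluster_fractions
    labs <- c("A", "B", "C", "D", "E")
    counts <- round(fr[labs] * n)
    pool <- c(rep(labs, counts),
              rep("background", max(0, n - sum(counts))))[seq_len(n)]
    cluster <- sample(pool)
    cenl_p <- ifelse(cluster == "B", config$cenl_fraction_in_B,
                     config$cenl_fraction_elsewhere)
    cenl <- stats::rbinom(n, 1, cenl_p) == 1
    de_p <- config$de_fraction[cluster]
    de <- cenl | (stats::rbinom(n, 1, de_p) == 1)
    dir_up <- ifelse(cluster == "C", FALSE, stats::runif(n) < 0.5)
    status <- ifelse(!de, "Neutral", ifelse(cenl | dir_up, "Up", "Down"))
    tlfc <- ifelse(status == "Up", config$ko_effect_log2fc,
                   ifelse(status == "Down", -config$ko_effect_log2fc, 0))
    bits <- vapply(tfs, function(tf) {
      p <- ifelse(cluster %in% c("A", "B"), config$bit_prob_ab[[tf]],
                  config$bit_prob_other)
      stats::rbinom(n, 1, p)
    }, integer(n))
    colnames(bits) <- tfs
    bits[cenl, c("CEBPE", "E2F1", "NFYB", "LIN54")] <- 1L
    # CEBPE-to-E2F1 distance + motif strength (clusters A/B, CEBPE-bound)
    distance <- rep(NA_real_, n)
    strength <- rep(0L, n)
    prox <- cluster %in% c("A", "B") & bits[, "CEBPE"] == 1
    both <- prox & bits[, "E2F1"] == 1
    ov <- both & stats::runif(n) < 0.5
    distance[ov] <- 0
    near <- both & !ov
    distance[near] <- round(stats::runif(sum(near), 100, 600))
    far <- prox & bits[, "E2F1"] == 0
    distance[far] <- round(stats::runif(sum(far), 1600, 5800))
    strength[near] <- 1L
    strength[far] <- 2L
    # motif-assisted CEBPE binding outside the proximal clusters
    other_c <- !prox & bits[, "CEBPE"] == 1
    strength[other_c] <- ifelse(stats::runif(n)[other_c] < 0.6, 2L, 0L)
    baseline <- stats::rlnorm(n, meanlog = log(150), sdlog = 1)
    truth <- data.frame(gene_id = g$gene_id, cluster = cluster,
                        cenl = cenl, de_status = status,
                        true_log2fc = tlfc, baseline = baseline,
                        planted_distance = distance,
                        motif_strength = strength,
                        stringsAsFactors = FALSE)
    truth <- cbind(truth, stats::setNames(as.data.frame(bits),
                                          paste0("bit_", tfs)))
    structure(truth, class = c("synthetic_truth", "data.frame"))
  })
}

#' Simulate the count matrix and sample sheet
#'
#' Counts are negative binomial with mean
#' `baseline x stage template x KO effect` and dispersion
#' `nb_dispersion`; KO samples exist for `ko_stages` only, and planted DE
#' genes have their KO mean scaled by `2^true_log2fc`. Neutral genes have
#' identical WT and KO means by construction.
#'
#' @param annotation,truth,config Generator inputs.
#' @return `list(counts, samples)`.
#' @export
simulate_expression <- function(annotation, truth, config) {
  if (!all(truth$cluster %in% c("A", "B", "C", "D", "E", "background"))) {
    stop("unknown cluster label in truth")
  }
  tm <- cluster_templates(config, include_background = TRUE)
  with_seed(substream(config$seed, "expression"), {
    samples <- rbind(
      expand.grid(replicate = seq_len(config$replicates),
                  genotype = "WT", stage = config$wt_stages,
                  stringsAsFactors = FALSE)[, 3:1],
      expand.grid(replicate = seq_len(config$replicates),
                  genotype = "KO", stage = config$ko_stages,
                  stringsAsFactors = FALSE)[, 3:1])
    samples$sample_id <- paste(samples$stage, samples$genotype,
                               samples$replicate, sep = "_")
    samples <- samples[, c("sample_id", "stage", "genotype", "replicate")]
    size <- 1 / config$nb_dispersion
    n <- nrow(truth)
    counts <- matrix(0L, n, nrow(samples),
                     dimnames = list(truth$gene_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- truth$baseline * tm[truth$cluster, samples$stage[j]]
      if (samples$genotype[j] == "KO") mu <- mu * 2^truth$true_log2fc
      counts[, j] <- stats::rnbinom(n, mu = mu, size = size)
    }
    list(counts = counts, samples = samples)
  })
}

# clamp a peak center so [c - w/2, c + w/2) fits in [0, len)
clamp_center <- function(center, width, len) {
  pmin(pmax(center, ceiling(width / 2)), len - ceiling(width / 2))
}

#' Simulate TF peak sets, signal tracks and open chromatin
#'
#' Plants, per gene and TF bit, a `peak_width` peak inside the promoter.
#' CEBPE peaks of cluster A/B genes are placed at the planted distance from
#' an E2F1 peak (overlapping when the distance is 0); the CEBP consensus is
#' written into the genome sequence at CEBPE peaks with planted motif
#' strength > 0 (full consensus for strength 2, a two-base degraded copy
#' for strength 1) and never at distance-0 (overlap-class) promoters.
#' Cluster C genes receive 1-2 CEBP-motif-bearing enhancer peaks (CEBPA
#' and/or CEBPE) 5-50 kb from their TSS inside open-chromatin regions,
#' resampled until the closest-TSS rule links them back to their gene.
#' Tracks render peaks as plateaus of the planted signal plus truncated
#' Gaussian jitter; false peaks are added at `false_peak_rate` per gene.
#' Peaks that would cross a chromosome edge are repositioned (and counted
#' in a message).
#'
#' @param annotation,genome From [simulate_annotation()].
#' @param truth From [simulate_truth()].
#' @param config A [sim_config()].
#' @return `list(peaksets, tracks, open_chromatin, genome, enhancers)`;
#'   `genome` carries the written motifs, `enhancers` the planted
#'   enhancer-to-gene truth.
#' @export
simulate_binding <- function(annotation, genome, truth, config) {
  g <- annotation$genes
  chrlen <- annotation$chromosomes
  w <- config$peak_width
  hw <- floor(w / 2)
  tfs <- names(config$bit_prob_ab)
  consensus <- paste(rownames(config$motif$ppm)[
    apply(config$motif$ppm, 2, which.max)], collapse = "")
  degraded <- degrade_motif(consensus)
  with_seed(substream(config$seed, "binding"), {
    n <- nrow(g)
    repositioned <- 0L
    cap <- 10L * n + 64L
    pk_tf <- character(cap); pk_chrom <- character(cap)
    pk_start <- numeric(cap); pk_score <- numeric(cap)
    pk_n <- 0L
    add_peak <- function(tf, chrom, center, strength) {
      c2 <- clamp_center(center, w, chrlen[[chrom]])
      if (c2 != center) repositioned <<- repositioned + 1L
      pk_n <<- pk_n + 1L
      pk_tf[pk_n] <<- tf; pk_chrom[pk_n] <<- chrom
      pk_start[pk_n] <<- c2 - hw; pk_score[pk_n] <<- strength
      c2
    }
    # motif writes are collected and applied per chromosome in one pass
    mw_chrom <- character(cap); mw_center <- numeric(cap)
    mw_seq <- character(cap); mw_n <- 0L
    add_motif <- function(chrom, center, s) {
      mw_n <<- mw_n + 1L
      mw_chrom[mw_n] <<- chrom; mw_center[mw_n] <<- center
      mw_seq[mw_n] <<- s
    }
    rstrength <- function(k = 1) stats::rlnorm(k, meanlog = log(5),
                                               sdlog = 0.4)
    cp_gene <- character(n); cp_chrom <- character(n)
    cp_start <- numeric(n); cp_n <- 0L
    # midpoints of distal planted structures; new enhancers must keep
    # >1200 bp away so overlap-merging cannot fuse planted regions
    dm_chrom <- character(cap); dm_mid <- numeric(cap); dm_n <- 0L
    bits <- as.matrix(truth[, paste0("bit_", tfs)])
    colnames(bits) <- tfs
    for (i in seq_len(n)) {
      chrom <- g$chrom[i]
      tss <- g$tss[i]
      placed_e2f1 <- FALSE
      if (bits[i, "CEBPE"] == 1) {
        ccenter <- tss + round(stats::runif(1, -600, 600))
        ccenter <- add_peak("CEBPE", chrom, ccenter, rstrength())
        cp_n <- cp_n + 1L
        cp_gene[cp_n] <- g$gene_id[i]; cp_chrom[cp_n] <- chrom
        cp_start[cp_n] <- ccenter - hw
        d <- truth$planted_distance[i]
        if (!is.na(d)) {
          if (d == 0) {
            ecenter <- ccenter + round(stats::runif(1, -hw / 2, hw / 2))
          } else if (bits[i, "E2F1"] == 1) {
            side <- -sign(ccenter - tss); if (side == 0) side <- 1
            ecenter <- ccenter + side * (w + d)
          } else {
            side <- sample(c(-1, 1), 1)
            ecenter <- ccenter + side * (w + d)
            if (ecenter - hw < 0 || ecenter + hw > chrlen[[chrom]]) {
              ecenter <- ccenter - side * (w + d)
            }
          }
          add_peak("E2F1", chrom, ecenter, rstrength())
          placed_e2f1 <- TRUE
          if (d > 0 && bits[i, "E2F1"] == 0) {
            dm_n <- dm_n + 1L
            dm_chrom[dm_n] <- chrom; dm_mid[dm_n] <- ecenter
          }
        }
        st <- truth$motif_strength[i]
        if (st > 0) {
          add_motif(chrom, ccenter, if (st == 2) consensus else degraded)
        }
      }
      for (tf in tfs) {
        if (tf == "CEBPE") next
        if (tf == "E2F1" && placed_e2f1) next
        if (bits[i, tf] == 1) {
          add_peak(tf, chrom, tss + round(stats::runif(1, -600, 600)),
                   rstrength())
        }
      }
    }
    # enhancers near cluster-C genes, inside open chromatin
    c_idx <- which(truth$cluster == "C")
    ecap <- 2L * length(c_idx) + round(0.2 * n) + 8L
    en_gene <- character(ecap); en_chrom <- character(ecap)
    en_start <- numeric(ecap); en_tfs <- character(ecap); en_n <- 0L
    oc_chrom <- character(ecap); oc_start <- numeric(ecap); oc_n <- 0L
    n_enh_per <- 1L + stats::rbinom(length(c_idx), 1L, 0.5)
    for (t in seq_along(c_idx)) {
      i <- c_idx[t]
      chrom <- g$chrom[i]
      tss <- g$tss[i]
      for (e in seq_len(n_enh_per[t])) {
        mid <- NA
        for (try in 1:100) {
          cand <- tss + sample(c(-1, 1), 1) *
            round(stats::runif(1, 5000, 50000))
          if (cand - 500 < 0 || cand + 500 > chrlen[[chrom]]) next
          near_mid <- dm_n > 0 &&
            any(dm_chrom[seq_len(dm_n)] == chrom &
                  abs(dm_mid[seq_len(dm_n)] - cand) <= 1200)
          if (near_mid) next
          link <- link_to_closest_gene(
            data.frame(chrom = chrom, start = cand - 250, end = cand + 250),
            annotation)
          if (link$gene_id == g$gene_id[i] && link$distance > 1500) {
            mid <- cand
            break
          }
        }
        if (is.na(mid)) next
        tf_pick <- sample(c("CEBPA", "CEBPE", "both"), 1,
                          prob = c(0.3, 0.3, 0.4))
        for (tf in if (tf_pick == "both") c("CEBPA", "CEBPE") else tf_pick) {
          add_peak(tf, chrom, mid, rstrength())
        }
        add_motif(chrom, mid, consensus)
        dm_n <- dm_n + 1L
        dm_chrom[dm_n] <- chrom; dm_mid[dm_n] <- mid
        en_n <- en_n + 1L
        en_gene[en_n] <- g$gene_id[i]; en_chrom[en_n] <- chrom
        en_start[en_n] <- mid - hw; en_tfs[en_n] <- tf_pick
        oc_n <- oc_n + 1L
        oc_chrom[oc_n] <- chrom; oc_start[oc_n] <- mid - 500
      }
    }
    # random distal open chromatin
    for (r in seq_len(round(0.2 * n))) {
      for (try in 1:50) {
        chrom <- sample(names(chrlen), 1)
        mid <- round(stats::runif(1, 1000, chrlen[[chrom]] - 1000))
        if (min_tss_distance(mid, chrom, annotation) > 1500) {
          oc_n <- oc_n + 1L
          oc_chrom[oc_n] <- chrom; oc_start[oc_n] <- mid - 500
          break
        }
      }
    }
    # false peaks
    n_false <- round(config$false_peak_rate * n)
    for (tf in tfs) {
      for (r in seq_len(n_false)) {
        chrom <- sample(names(chrlen), 1)
        center <- round(stats::runif(1, hw, chrlen[[chrom]] - hw))
        add_peak(tf, chrom, center, rstrength())
      }
    }
    # apply collected motif writes, one string conversion per chromosome
    for (chrom in unique(mw_chrom[seq_len(mw_n)])) {
      raw <- charToRaw(genome[[chrom]])
      for (j in which(mw_chrom[seq_len(mw_n)] == chrom)) {
        ms <- charToRaw(mw_seq[j])
        at <- mw_center[j] - floor(length(ms) / 2) + 1
        at <- max(1, min(length(raw) - length(ms) + 1, at))
        raw[at:(at + length(ms) - 1)] <- ms
      }
      genome[[chrom]] <- rawToChar(raw)
    }
    cebpe_promoter <- data.frame(gene_id = cp_gene[seq_len(cp_n)],
                                 chrom = cp_chrom[seq_len(cp_n)],
                                 start = cp_start[seq_len(cp_n)],
                                 end = cp_start[seq_len(cp_n)] + w,
                                 stringsAsFactors = FALSE)
    enh <- data.frame(gene_id = en_gene[seq_len(en_n)],
                      chrom = en_chrom[seq_len(en_n)],
                      start = en_start[seq_len(en_n)],
                      end = en_start[seq_len(en_n)] + w,
                      tfs = en_tfs[seq_len(en_n)],
                      stringsAsFactors = FALSE)
    oc <- data.frame(chrom = oc_chrom[seq_len(oc_n)],
                     start = oc_start[seq_len(oc_n)],
                     end = oc_start[seq_len(oc_n)] + 1000,
                     stringsAsFactors = FALSE)
    if (repositioned > 0) {
      message("simulate_binding: repositioned ", repositioned,
              " peak(s) at chromosome edges")
    }
    peaksets <- lapply(stats::setNames(tfs, tfs), function(tf) {
      sel <- which(pk_tf[seq_len(pk_n)] == tf)
      peak_set(data.frame(chrom = pk_chrom[sel], start = pk_start[sel],
                          end = pk_start[sel] + w, score = pk_score[sel],
                          stringsAsFactors = FALSE),
               tf = tf, population = "synthetic")
    })
    tracks <- lapply(stats::setNames(c("PU.1", "CEBPA", "CEBPE"),
                                     c("PU.1", "CEBPA", "CEBPE")),
                     function(tf) {
      render_track(peaksets[[tf]], annotation, config$bin_size,
                   config$signal_jitter_sd, name = tf)
    })
    open_chromatin <- peak_set(oc, tf = "open_chromatin",
                               population = "synthetic")
    list(peaksets = peaksets, tracks = tracks,
         open_chromatin = open_chromatin, genome = genome,
         enhancers = enh, cebpe_promoter_peaks = cebpe_promoter)
  })
}

# two-base degraded copy of a consensus (transversion at two inner sites)
degrade_motif <- function(consensus) {
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  s <- strsplit(consensus, "")[[1]]
  pos <- c(3L, length(s) - 2L)
  s[pos] <- flip[s[pos]]
  paste(s, collapse = "")
}

# peaks -> plateau track (max of overlapping plateaus) + truncated jitter
render_track <- function(peakset, annotation, bin_size, jitter_sd, name) {
  values <- lapply(annotation$chromosomes, function(len) {
    numeric(ceiling(len / bin_size))
  })
  df <- as.data.frame(peakset)
  for (i in seq_len(nrow(df))) {
    b0 <- df$start[i] %/% bin_size + 1L
    b1 <- min((df$end[i] - 1L) %/% bin_size + 1L,
              length(values[[df$chrom[i]]]))
    sc <- if (is.na(df$score[i])) 1 else df$score[i]
    values[[df$chrom[i]]][b0:b1] <- pmax(values[[df$chrom[i]]][b0:b1], sc)
  }
  if (jitter_sd > 0) {
    for (chrom in names(values)) {
      nz <- which(values[[chrom]] > 0)
      if (length(nz)) {
        values[[chrom]][nz] <- pmax(
          0, values[[chrom]][nz] + stats::rnorm(length(nz), 0, jitter_sd))
      }
    }
  }
  signal_track(values, bin_size, name = name, population = "synthetic")
}

#' Generate the full in-memory fixture bundle
#'
#' Runs [simulate_annotation()], [simulate_truth()],
#' [simulate_expression()] and [simulate_binding()] in order and returns
#' every piece (including the motif-bearing genome and the planted truth).
#'
#' @param config A [sim_config()].
#' @export
simulate_fixture <- function(config = sim_config()) {
  ann <- simulate_annotation(config)
  truth <- simulate_truth(ann$annotation, config)
  expr <- simulate_expression(ann$annotation, truth, config)
  bnd <- simulate_binding(ann$annotation, ann$genome, truth, config)
  list(config = config, annotation = ann$annotation, genome = bnd$genome,
       counts = expr$counts, samples = expr$samples,
       peaksets = bnd$peaksets, tracks = bnd$tracks,
       open_chromatin = bnd$open_chromatin, truth = truth,
       enhancers = bnd$enhancers,
       cebpe_promoter_peaks = bnd$cebpe_promoter_peaks)
}

#' Write the fixture bundle to disk
#'
#' Emits the gene table, genome FASTA, counts and sample sheet, per-TF
#' peak BEDs, per-TF signal tracks, open chromatin BED, the CEBP motif
#' PFM, the truth tables, a config echo and a `manifest.json` with MD5
#' checksums. Identical configs produce byte-identical bundles.
#'
#' @param dir Output directory.
#' @param config A [sim_config()].
#' @param force Overwrite a non-empty directory.
#' @return The manifest (invisibly).
#' @export
write_fixture <- function(dir, config = sim_config(), force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force) {
    stop("output directory not empty (use force = TRUE): ", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- simulate_fixture(config)
  paths <- character(0)
  emit <- function(fname, writer) {
    p <- file.path(dir, fname)
    writer(p)
    paths <<- c(paths, p)
  }
  emit("genes.tsv", function(p) write_gene_table(fx$annotation, p))
  emit("genome.fa", function(p) write_fasta(fx$genome, p))
  emit("counts.tsv", function(p) {
    write_counts(fx$counts, fx$samples, p, file.path(dir, "samples.tsv"))
  })
  paths <- c(paths, file.path(dir, "samples.tsv"))
  for (tf in names(fx$peaksets)) {
    fn <- paste0("peaks_", gsub("[^A-Za-z0-9]", "", tf), ".bed")
    local({
      tf_ <- tf; fn_ <- fn
      emit(fn_, function(p) write_bed(fx$peaksets[[tf_]], p))
    })
  }
  for (tf in names(fx$tracks)) {
    fn <- paste0("track_", gsub("[^A-Za-z0-9]", "", tf), ".bedgraph")
    local({
      tf_ <- tf; fn_ <- fn
      emit(fn_, function(p) write_signal(fx$tracks[[tf_]], p))
    })
  }
  emit("open_chromatin.bed", function(p) write_bed(fx$open_chromatin, p))
  emit("cebp_motif.pfm", function(p) write_pfm(config$motif, p))
  emit("truth_genes.tsv", function(p) {
    utils::write.table(fx$truth, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  emit("truth_enhancers.tsv", function(p) {
    utils::write.table(fx$enhancers, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  emit("config.json", function(p) {
    cfg <- unclass(config)
    cfg$motif <- list(name = config$motif$name,
                      ppm = unname(apply(config$motif$ppm, 2, c,
                                         simplify = FALSE)),
                      background = unname(config$motif$background))
    jsonlite::write_json(cfg, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  manifest <- list(
    files = lapply(stats::setNames(basename(paths), basename(paths)),
                   function(f) {
                     unname(tools::md5sum(file.path(dir, f)))
                   }),
    seed = config$seed, n_genes = config$n_genes)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
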