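# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small fixture: 240 genes, 2 chromosomes, default noise
small_cfg <- function(seed = 7L, n_genes = 240L, n_chromosomes = 2L,
                      ...) {
  sim_config(seed = seed, n_genes = n_genes,
             n_chromosomes = n_chromosomes, ...)
}

small_fixture <- function() {
  cache_get("small", function() suppressMessages(
    simulate_fixture(small_cfg())))
}

# same layout with noise switched off (exact plateau / exact binarization)
noisefree_fixture <- function() {
  cache_get("noisefree", function() suppressMessages(
    simulate_fixture(small_cfg(signal_jitter_sd = 0,
                               false_peak_rate = 0))))
}

# tiny deterministic annotation for interval unit tests
toy_annotation <- function(tss = c(5000, 12000, 30000), len = 50000) {
  genome_annotation(
    c(chr1 = len),
    data.frame(gene_id = sprintf("g%02d", seq_along(tss)), chrom = "chr1",
               strand = rep(c("+", "-"), length.out = length(tss)),
               tss = tss, stringsAsFactors = FALSE))
}

make_peaks <- function(starts, ends, chrom = "chr1", score = NA_real_,
                       tf = "TF") {
  if (!length(starts)) {
    return(peak_set(data.frame(chrom = character(), start = numeric(),
                               end = numeric()), tf = tf))
  }
  peak_set(data.frame(chrom = chrom, start = starts, end = ends,
                      score = score), tf = tf)
}

# constant-value signal track helper
flat_track <- function(len = 50000, bin = 100, value = 0, name = "TF") {
  signal_track(list(chr1 = rep(value, ceiling(len / bin))), bin,
               name = name)
}

# brute-force oracles ----------------------------------------------------

# O(n*m) closest-TSS scan with lexicographic tie-break
oracle_closest_gene <- function(mid, annotation) {
  g <- annotation$genes
  best_id <- NA_character_
  best_d <- Inf
  for (i in seq_len(nrow(g))) {
    d <- abs(mid - g$tss[i])
    if (d < best_d || (d == best_d && g$gene_id[i] < best_id)) {
      best_d <- d
      best_id <- g$gene_id[i]
    }
  }
  list(gene_id = best_id, distance = best_d)
}

# all-pairs half-open overlap / gap distance
oracle_overlap <- function(q, r) {
  any(q[1] < r[, 2] & r[, 1] < q[2])
}

oracle_distance <- function(q, r) {
  if (oracle_overlap(q, r)) return(0)
  min(pmax(r[, 1] - q[2], q[1] - r[, 2]))
}

# exhaustive two-strand window-scan motif scorer
oracle_motif_score <- function(seq, ppm, background = rep(0.25, 4)) {
  names(background) <- c("A", "C", "G", "T")
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score_one <- function(win) {
    b <- strsplit(win, "")[[1]]
    if (any(!b %in% c("A", "C", "G", "T"))) return(-Inf)
    ri <- match(b, c("A", "C", "G", "T"))
    sum(log2(ppm[cbind(ri, seq_along(b))] / background[b]))
  }
  L <- ncol(ppm)
  best <- -Inf
  for (s in c(seq, rc(seq))) {
    for (i in seq_len(nchar(s) - L + 1)) {
      best <- max(best, score_one(substr(s, i, i + L - 1)))
    }
  }
  max(best, 0)
}

# exact rank-sum p by enumerating all C(n+m, n) group assignments
oracle_wilcoxon_greater <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  obs <- sum(rank(pooled)[seq_len(n)])
  r <- rank(pooled)
  stats <- apply(idx, 2, function(j) sum(r[j]))
  mean(stats >= obs)
}

# hypergeometric tail sum for one-sided 2x2 enrichment
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  sum(stats::dhyper(a:min(m, k), m, n, k))
}

# O(n^2) pair-counting adjusted Rand index
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / tot
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(0)
  (s11 - expected) / (maxi - expected)
}
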