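## Binding module: signal summarization over CREs, median-threshold
## binarization, interval overlap/distance queries, PWM log-odds motif
## scoring, CEBPE-to-E2F1 distance-class profiling, and per-cluster binding
## comparisons.

#' Length-weighted mean track signal over an interval
#'
#' Bins partially covered by the interval contribute proportionally to the
#' overlapped length.
#'
#' @param track A [signal_track()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval within the track bounds.
#' @export
region_signal <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("no track values for chromosome ", chrom)
  if (end <= start) stop("zero- or negative-length interval")
  bs <- track$bin_size
  if (start < 0 || end > length(v) * bs) {
    stop("interval [", start, ",", end, ") off chromosome ", chrom)
  }
  b0 <- start %/% bs          # first bin index (0-based)
  b1 <- (end - 1) %/% bs      # last bin index
  bins <- b0:b1
  w <- pmin(end, (bins + 1) * bs) - pmax(start, bins * bs)
  sum(w * v[bins + 1]) / (end - start)
}

#' Median-threshold binding binarization
#'
#' A promoter is called bound when its signal is strictly above the median
#' signal over the promoters of the differentially expressed reference gene
#' set; ties therefore fall to unbound.
#'
#' @param signal_by_gene Named numeric vector of promoter signal.
#' @param de_gene_set Character vector (subset of the names) of DE genes
#'   that define the threshold.
#' @return `list(bound = <named logical>, threshold, evidence = "median",
#'   n_reference)`.
#' @export
binarize_binding <- function(signal_by_gene, de_gene_set) {
  if (!length(de_gene_set)) stop("empty DE reference gene set")
  missing_genes <- setdiff(de_gene_set, names(signal_by_gene))
  if (length(missing_genes)) {
    stop("DE gene(s) without promoter signal: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  threshold <- stats::median(signal_by_gene[de_gene_set])
  list(bound = signal_by_gene > threshold, threshold = threshold,
       evidence = "median", n_reference = length(de_gene_set))
}

#' Overlap indicator against a reference peak set
#'
#' 1 iff the region shares at least one base (half-open arithmetic) with any
#' reference peak.
#'
#' @param regions `data.frame` with `chrom`, `start`, `end` (and optionally
#'   ids as rownames or a `gene_id` column).
#' @param reference_peaks A [peak_set()] (or interval `data.frame`).
#' @return Integer vector of 0/1 per region.
#' @export
overlap_binary <- function(regions, reference_peaks) {
  regions <- as.data.frame(regions)
  if (!nrow(reference_peaks)) {
    warning("empty reference peak set; all regions unbound")
    return(integer(nrow(regions)))
  }
  as.integer(GenomicRanges::countOverlaps(
    as_granges(regions), as_granges(as.data.frame(reference_peaks))) > 0)
}

#' Fraction of peaks in A overlapping any peak in B
#' @param peaks_a,peaks_b Peak sets / interval `data.frame`s; A nonempty.
#' @export
overlap_fraction <- function(peaks_a, peaks_b) {
  if (!nrow(peaks_a)) stop("empty peak set A")
  mean(overlap_binary(peaks_a, peaks_b) == 1)
}

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_seq <- function(s) {
  codes <- utf8ToInt(s)
  out <- integer(length(codes))
  out[codes == 65L] <- 1L  # A
  out[codes == 67L] <- 2L  # C
  out[codes == 71L] <- 3L  # G
  out[codes == 84L] <- 4L  # T
  out  # anything else (N) stays 0
}

#' Maximum PWM log-odds motif score over an interval (both strands)
#'
#' Every window of motif length on both strands is scored as
#' `sum log2(p[base, j] / background[base])`; windows containing `N` score
#' `-Inf`; the final score is the best window floored at 0, so a region
#' with no better-than-background match scores exactly 0.
#'
#' @param genome Named character vector of chromosome sequences (see
#'   [read_fasta()]).
#' @param chrom,start,end Interval (0-based half-open), at least as long as
#'   the motif.
#' @param motif A [motif_model()].
#' @export
motif_score <- function(genome, chrom, start, end, motif) {
  seqlen <- nchar(genome[[chrom]])
  if (is.null(genome[[chrom]])) stop("no sequence for ", chrom)
  if (start < 0 || end > seqlen) stop("interval off chromosome ", chrom)
  s <- substr(genome[[chrom]], start + 1, end)
  L <- ncol(motif$ppm)
  if (nchar(s) < L) {
    stop("interval shorter than motif (", nchar(s), " < ", L, ")")
  }
  lo <- log2(motif$ppm / motif$background)           # 4 x L
  lo_rc <- lo[4:1, L:1, drop = FALSE]                # reverse complement
  codes <- encode_seq(s)
  n_win <- length(codes) - L + 1L
  best <- -Inf
  for (mat in list(lo, lo_rc)) {
    sc <- numeric(n_win)
    for (j in seq_len(L)) {
      cj <- codes[j:(j + n_win - 1L)]
      col <- mat[, j]
      v <- ifelse(cj == 0L, -Inf, col[pmax(cj, 1L)])
      sc <- sc + v
    }
    best <- max(best, sc)
  }
  max(best, 0)
}

#' Distance to the closest reference region
#'
#' 0 when a query overlaps any reference (half-open arithmetic; abutting
#' regions also have gap 0); otherwise the minimum gap. Queries on
#' chromosomes without any reference get `NA` (cross-chromosome pairs are
#' never compared).
#'
#' @param query_regions,reference_regions Interval `data.frame`s /
#'   [peak_set()]s; reference nonempty.
#' @return Numeric distance per query row.
#' @export
distance_to_closest <- function(query_regions, reference_regions) {
  if (!nrow(reference_regions)) stop("empty reference region set")
  q <- as_granges(as.data.frame(query_regions))
  r <- as_granges(as.data.frame(reference_regions))
  # cross-chromosome queries are expected (they yield NA); silence the
  # seqlevel-mismatch chatter
  hits <- suppressWarnings(GenomicRanges::distanceToNearest(q, r))
  out <- rep(NA_real_, length(q))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  out
}

#' Default CEBPE-to-E2F1 distance-class edges (bp)
#'
#' A dedicated overlap class at 0, then geometric x4 bins spanning the
#' 0-1540 kb profiling range.
#' @export
default_distance_edges <- function() {
  c(0, 1500, 6000, 24000, 96000, 384000, 1540000)
}

distance_class_labels <- function(edges) {
  inner <- paste0("(", fmt_int(edges[-length(edges)]), ",",
                  fmt_int(edges[-1]), "]")
  c("0", inner)
}

#' CEBPE-to-E2F1 distance-class profile of bound promoters
#'
#' For each CEBPE-bound promoter, the distance from its CEBPE peak to the
#' closest E2F1 site is assigned to a distance class (a dedicated class for
#' overlap/0); the per-class summary reports the count and the median motif
#' score with its bootstrap standard error. Distances beyond the last edge
#' fall in an `overflow` class.
#'
#' @param cebpe_promoter_peaks `data.frame` with `gene_id`, `chrom`,
#'   `start`, `end` (one CEBPE peak per bound promoter).
#' @param e2f1_peaks [peak_set()] of E2F1 sites.
#' @param motif_scores Named numeric vector (per `gene_id`) of CEBPE motif
#'   scores at the CEBPE peaks.
#' @param edges Increasing distance-class edges starting at 0.
#' @param seed Seed for the bootstrap SE of the median.
#' @return `list(table = per-promoter data.frame, summary = per-class
#'   data.frame(class, n, median_motif_score, se_motif_score))`.
#' @export
distance_class_profile <- function(cebpe_promoter_peaks, e2f1_peaks,
                                   motif_scores,
                                   edges = default_distance_edges(),
                                   seed = 1L) {
  if (length(edges) < 2 || is.unsorted(edges, strictly = TRUE) ||
      edges[1] != 0) {
    stop("edges must be increasing and start at 0")
  }
  labels <- c(distance_class_labels(edges), "overflow")
  if (!nrow(cebpe_promoter_peaks)) {
    return(list(
      table = data.frame(gene_id = character(), distance = numeric(),
                         class = character(), motif_score = numeric(),
                         stringsAsFactors = FALSE),
      summary = data.frame(class = character(), n = integer(),
                           median_motif_score = numeric(),
                           se_motif_score = numeric(),
                           stringsAsFactors = FALSE)))
  }
  d <- distance_to_closest(cebpe_promoter_peaks, e2f1_peaks)
  cls <- ifelse(d == 0, "0",
                labels[pmin(findInterval(d, edges, left.open = TRUE),
                            length(labels) - 1L) + 1L])
  cls[is.na(d)] <- "overflow"
  d[is.na(d)] <- Inf
  if (any(cls == "overflow")) {
    message(sum(cls == "overflow"),
            " promoter(s) beyond the last distance edge -> overflow class")
  }
  sc <- motif_scores[cebpe_promoter_peaks$gene_id]
  tab <- data.frame(gene_id = cebpe_promoter_peaks$gene_id, distance = d,
                    class = factor(cls, levels = labels),
                    motif_score = unname(sc), stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(labels, function(l) {
    s <- tab$motif_score[tab$class == l]
    if (!length(s)) return(NULL)
    se <- if (length(s) >= 3) median_se(s, seed = seed)$se else NA_real_
    data.frame(class = l, n = length(s),
               median_motif_score = stats::median(s),
               se_motif_score = se, stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = summ)
}

#' Per-cluster one-sided binding comparisons
#'
#' For each cluster's DE genes, tests whether their binding signal at the
#' given element type is stochastically greater than the signal over all DE
#' genes (one-sided Wilcoxon rank-sum), BH-adjusted across all supplied
#' comparisons (clusters x element types). Groups with fewer than
#' `min_n` values are excluded with a message.
#'
#' @param groups Named list of lists: `groups[[element_type]][[cluster]]`
#'   is the numeric signal vector of that cluster's DE genes.
#' @param background Named list: `background[[element_type]]` is the signal
#'   vector over all DE genes.
#' @param min_n Minimum group size (default 3).
#' @return `data.frame(element_type, cluster, n, p, padj)`.
#' @export
compare_binding <- function(groups, background, min_n = 3L) {
  rows <- list()
  for (et in names(groups)) {
    bg <- background[[et]]
    bg <- bg[is.finite(bg)]
    for (cl in names(groups[[et]])) {
      g <- groups[[et]][[cl]]
      g <- g[is.finite(g)]
      if (length(g) < min_n) {
        message("compare_binding: excluding ", et, "/", cl,
                " (n = ", length(g), " < ", min_n, ")")
        next
      }
      wt <- wilcoxon_one_sided(g, bg, alternative = "greater")
      rows[[paste(et, cl, sep = ":")]] <-
        data.frame(element_type = et, cluster = cl, n = length(g),
                   p = wt$p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(element_type = character(), cluster = character(),
                      n = integer(), p = numeric(), padj = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$padj <- bh_adjust(out$p)
  out
}

#' Promoter signal and binary binding layers for a panel of TFs
#'
#' Builds the regions x TFs binding matrix: a continuous layer (length
#' weighted mean track signal over each promoter, for TFs with tracks) and
#' a binary layer. Binarization evidence per TF is either `"median"`
#' (strictly above the median promoter signal over the DE reference genes)
#' or `"overlap"` (>= 1 bp promoter overlap with the TF's peak set, for TFs
#' whose evidence is a pre-annotated region set, e.g. MYC/E2F1/NFYB from
#' ESC data).
#'
#' @param promoters A [define_promoters()] map.
#' @param tracks Named list of [signal_track()]s (median-evidence TFs).
#' @param peaksets Named list of [peak_set()]s (overlap-evidence TFs).
#' @param de_genes DE reference gene ids for the median thresholds.
#' @param evidence Named character vector TF -> `"median"`/`"overlap"`;
#'   defaults to `"median"` for TFs with tracks, `"overlap"` otherwise.
#' @return `list(signal = matrix, binary = matrix, thresholds = named
#'   numeric (NA for overlap evidence), evidence)` of class
#'   `binding_matrix`.
#' @export
binding_matrix <- function(promoters, tracks = list(), peaksets = list(),
                           de_genes, evidence = NULL) {
  tfs <- union(names(tracks), names(peaksets))
  if (!length(tfs)) stop("no TFs supplied")
  if (is.null(evidence)) {
    evidence <- stats::setNames(
      ifelse(tfs %in% names(tracks), "median", "overlap"), tfs)
  }
  genes <- promoters$gene_id
  signal <- matrix(NA_real_, length(genes), length(tfs),
                   dimnames = list(genes, tfs))
  binary <- matrix(0L, length(genes), length(tfs),
                   dimnames = list(genes, tfs))
  thresholds <- stats::setNames(rep(NA_real_, length(tfs)), tfs)
  for (tf in tfs) {
    if (evidence[[tf]] == "median") {
      tr <- tracks[[tf]]
      if (is.null(tr)) stop("median evidence for ", tf, " needs a track")
      sig <- vapply(seq_len(nrow(promoters)), function(i) {
        region_signal(tr, promoters$chrom[i], promoters$start[i],
                      promoters$end[i])
      }, numeric(1))
      names(sig) <- genes
      signal[, tf] <- sig
      bb <- binarize_binding(sig, intersect(de_genes, genes))
      binary[, tf] <- as.integer(bb$bound)
      thresholds[[tf]] <- bb$threshold
    } else {
      ps <- peaksets[[tf]]
      if (is.null(ps)) stop("overlap evidence for ", tf, " needs peaks")
      binary[, tf] <- overlap_binary(promoters, ps)
    }
  }
  structure(list(signal = signal, binary = binary, thresholds = thresholds,
                 evidence = evidence),
            class = "binding_matrix")
}

#' @export
print.binding_matrix <- function(x, ...) {
  cat("<binding_matrix> ", nrow(x$binary), " regions x ", ncol(x$binary),
      " TFs\n", sep = "")
  cat("  evidence:", paste(names(x$evidence), x$evidence, sep = "=",
                           collapse = " "), "\n")
  invisible(x)
}
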