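## CRE catalog: promoter windows around TSSs and distal fixed-width
## enhancers linked to their closest gene.
##
## Definitions: a promoter is the window within `half_width` (default
## 1000 bp) of a TSS; an enhancer is a TF-bound, open-chromatin (or
## previously cataloged) region whose midpoint lies > 1000 bp from every
## TSS, recentered to exactly 500 bp. "Distal" is always evaluated on the
## region midpoint, both before and after recentering, so the constraint is
## self-consistent with the recentering anchor.

interval_midpoint <- function(start, end) floor((start + end) / 2)

#' Define promoter windows
#'
#' `[tss - half_width, tss + half_width)`, clipped to chromosome bounds;
#' strand-agnostic (the promoter definition is a distance, not an
#' orientation).
#'
#' @param annotation A [genome_annotation()].
#' @param half_width Half-width in bp (default 1000).
#' @return `data.frame(gene_id, chrom, start, end)` of class `promoter_map`.
#' @export
define_promoters <- function(annotation, half_width = 1000L) {
  if (half_width <= 0) stop("half_width must be positive")
  g <- annotation$genes
  len <- annotation$chromosomes[g$chrom]
  out <- data.frame(
    gene_id = g$gene_id, chrom = g$chrom,
    start = pmax(0, g$tss - half_width),
    end = pmin(len, g$tss + half_width),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, half_width = half_width,
            class = c("promoter_map", "data.frame"))
}

# minimum |midpoint - tss| over all genes, per region
min_tss_distance <- function(mid, chrom, annotation) {
  out <- rep(Inf, length(mid))
  g <- annotation$genes
  for (cn in unique(chrom)) {
    tss <- sort(g$tss[g$chrom == cn])
    i <- which(chrom == cn)
    if (!length(tss)) next
    pos <- findInterval(mid[i], tss)
    lo <- ifelse(pos >= 1, tss[pmax(pos, 1)], NA)
    hi <- ifelse(pos < length(tss), tss[pmin(pos + 1, length(tss))], NA)
    d <- pmin(abs(mid[i] - lo), abs(mid[i] - hi), na.rm = TRUE)
    out[i] <- d
  }
  out
}

#' Build the enhancer catalog
#'
#' (i) TF peaks from all supplied sets are unioned and overlap-merged; merged
#' regions are kept when their midpoint lies more than `distal_bp` from every
#' TSS and they overlap (>= 1 bp) open chromatin or the prior enhancer set.
#' (ii) Prior enhancer regions passing the same distal filter are added.
#' Duplicates are removed, every surviving region is recentered to exactly
#' `width` bp around its midpoint, the distal filter is re-applied to the
#' recentered midpoint, and each enhancer is linked to its closest gene
#' (closest TSS; ties to the lexicographically smallest gene id).
#'
#' @param tf_peaksets Named list of [peak_set()]s; the five canonical TFs are
#'   PU.1, CEBPA, CEBPE, MYC, E2F1 (missing ones warn).
#' @param open_chromatin [peak_set()] of open-chromatin regions.
#' @param prior_enhancers Optional [peak_set()] of previously cataloged
#'   enhancers.
#' @param annotation A [genome_annotation()].
#' @param width Fixed enhancer width (default 500).
#' @param distal_bp Distal cutoff from TSS (default 1000).
#' @return `data.frame` of class `enhancer_catalog` with columns `chrom`,
#'   `start`, `end`, `gene_id`, `distance`, `provenance`.
#' @export
call_enhancers <- function(tf_peaksets, open_chromatin,
                           prior_enhancers = NULL, annotation,
                           width = 500L, distal_bp = 1000L) {
  canonical <- c("PU.1", "CEBPA", "CEBPE", "MYC", "E2F1")
  missing_tfs <- setdiff(canonical, names(tf_peaksets))
  if (length(missing_tfs)) {
    warning("enhancer calling without peak set(s) for: ",
            paste(missing_tfs, collapse = ", "))
  }
  empty <- function() {
    structure(data.frame(chrom = character(), start = integer(),
                         end = integer(), gene_id = character(),
                         distance = numeric(), provenance = character(),
                         stringsAsFactors = FALSE),
              width = width, class = c("enhancer_catalog", "data.frame"))
  }

  all_peaks <- do.call(rbind, lapply(unname(tf_peaksets), function(ps) {
    as.data.frame(ps)[, c("chrom", "start", "end")]
  }))
  cand <- NULL
  if (!is.null(all_peaks) && nrow(all_peaks)) {
    merged <- GenomicRanges::reduce(as_granges(all_peaks))
    mdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                      start = GenomicRanges::start(merged) - 1L,
                      end = GenomicRanges::end(merged),
                      stringsAsFactors = FALSE)
    mid <- interval_midpoint(mdf$start, mdf$end)
    distal <- min_tss_distance(mid, mdf$chrom, annotation) > distal_bp
    support <- as_granges(rbind(
      as.data.frame(open_chromatin)[, c("chrom", "start", "end")],
      if (!is.null(prior_enhancers))
        as.data.frame(prior_enhancers)[, c("chrom", "start", "end")]))
    hit <- GenomicRanges::countOverlaps(as_granges(mdf), support) > 0
    keep <- distal & hit
    if (any(keep)) {
      cand <- cbind(mdf[keep, , drop = FALSE],
                    provenance = "tf_open_chromatin")
    }
  }
  if (!is.null(prior_enhancers) && nrow(prior_enhancers)) {
    pdf <- as.data.frame(prior_enhancers)[, c("chrom", "start", "end")]
    mid <- interval_midpoint(pdf$start, pdf$end)
    distal <- min_tss_distance(mid, pdf$chrom, annotation) > distal_bp
    if (any(distal)) {
      cand <- rbind(cand, cbind(pdf[distal, , drop = FALSE],
                                provenance = "prior_set"))
    }
  }
  if (is.null(cand) || !nrow(cand)) {
    warning("no enhancers survive the distal/open-chromatin filters")
    return(empty())
  }
  # recenter to fixed width around the midpoint, then re-check distality
  mid <- interval_midpoint(cand$start, cand$end)
  cand$start <- mid - floor(width / 2)
  cand$end <- cand$start + width
  cand <- cand[cand$start >= 0 &
                 cand$end <= annotation$chromosomes[cand$chrom], ,
               drop = FALSE]
  mid <- interval_midpoint(cand$start, cand$end)
  cand <- cand[min_tss_distance(mid, cand$chrom, annotation) > distal_bp, ,
               drop = FALSE]
  # deduplicate on exact coordinates (provenance of the first kept);
  # tf_open_chromatin sorts before prior_set so provenance is deterministic
  cand <- cand[order(cand$chrom, cand$start, cand$end, cand$provenance), ,
               drop = FALSE]
  cand <- cand[!duplicated(cand[, c("chrom", "start", "end")]), ,
               drop = FALSE]
  if (!nrow(cand)) {
    warning("no enhancers survive recentering")
    return(empty())
  }
  linked <- link_to_closest_gene(cand, annotation)
  structure(linked[, c("chrom", "start", "end", "gene_id", "distance",
                       "provenance")],
            width = width, class = c("enhancer_catalog", "data.frame"))
}

#' Link regions to their closest gene
#'
#' Distance is `|region midpoint - TSS|`, minimized over all genes on the
#' same chromosome; ties break to the lexicographically smallest gene id.
#'
#' @param regions `data.frame` with `chrom`, `start`, `end`.
#' @param annotation A [genome_annotation()].
#' @return `regions` with `gene_id` and `distance` columns added.
#' @export
link_to_closest_gene <- function(regions, annotation) {
  if (!nrow(annotation$genes)) stop("empty annotation")
  regions <- as.data.frame(regions)
  mid <- interval_midpoint(regions$start, regions$end)
  gene_id <- rep(NA_character_, nrow(regions))
  distance <- rep(NA_real_, nrow(regions))
  g <- annotation$genes
  for (cn in unique(regions$chrom)) {
    gi <- which(g$chrom == cn)
    ri <- which(regions$chrom == cn)
    if (!length(gi)) next
    ord <- gi[order(g$tss[gi])]
    tss <- g$tss[ord]
    ids <- g$gene_id[ord]
    pos <- findInterval(mid[ri], tss)
    for (t in seq_along(ri)) {
      m <- mid[ri[t]]
      j <- pos[t]
      cand <- unique(pmax(1, pmin(length(tss), c(j, j + 1))))
      d <- min(abs(m - tss[cand]))
      # all genes at the minimizing distance (either side), smallest id wins
      hits <- which(tss == m - d | tss == m + d)
      gene_id[ri[t]] <- sort(ids[hits])[1]
      distance[ri[t]] <- d
    }
  }
  regions$gene_id <- gene_id
  regions$distance <- distance
  regions
}

#' Mean binding signal over a gene's linked enhancers
#'
#' Sum of per-enhancer region signal divided by the number of linked
#' enhancers (the "normalized to the total number of enhancers" rule).
#' Genes with zero linked enhancers yield `NaN` and are excluded downstream.
#'
#' @param track A [signal_track()].
#' @param enhancers An [call_enhancers()] catalog.
#' @param gene_id Gene to summarize.
#' @export
gene_enhancer_signal <- function(track, enhancers, gene_id) {
  e <- enhancers[enhancers$gene_id == gene_id, , drop = FALSE]
  if (!nrow(e)) return(NaN)
  mean(vapply(seq_len(nrow(e)), function(i) {
    region_signal(track, e$chrom[i], e$start[i], e$end[i])
  }, numeric(1)))
}

#' Per-gene mean enhancer signal for many genes at once
#' @inheritParams gene_enhancer_signal
#' @param gene_ids Genes to summarize (default: all linked genes).
#' @return Named numeric vector (NaN for genes without enhancers).
#' @export
enhancer_signal_by_gene <- function(track, enhancers, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- unique(enhancers$gene_id)
  if (!length(gene_ids)) return(stats::setNames(numeric(0), character(0)))
  per <- vapply(seq_len(nrow(enhancers)), function(i) {
    region_signal(track, enhancers$chrom[i], enhancers$start[i],
                  enhancers$end[i])
  }, numeric(1))
  sums <- tapply(per, enhancers$gene_id, sum)
  cnts <- tapply(per, enhancers$gene_id, length)
  out <- stats::setNames(rep(NaN, length(gene_ids)), gene_ids)
  hit <- intersect(gene_ids, names(sums))
  out[hit] <- sums[hit] / cnts[hit]
  out
}
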