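## Expression module: gene filtering, log-CPM normalization, k-means
## clustering of stage profiles with elbow k-selection, minor-to-major
## cluster merging, and KO-vs-WT differential-expression labeling.

#' Filter genes for analysis
#'
#' Keeps genes with at least 1 read in at least two samples and a
#' positive standard deviation across samples.
#'
#' @param counts Integer count matrix (genes x samples).
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) == 0 || ncol(counts) == 0) {
    stop("empty count matrix")
  }
  expressed <- rowSums(counts >= 1) >= 2
  variable <- apply(counts, 1, stats::sd) > 0
  rownames(counts)[expressed & variable]
}

#' log2(CPM + 1) normalization
#'
#' `value = log2(count / library_size * 1e6 + 1)` per cell; library size is
#' the column sum. Invariant to rescaling all counts of a sample.
#'
#' @param counts Integer count matrix.
#' @return Numeric matrix of the same shape.
#' @export
normalize_log_cpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  log2(sweep(counts, 2, lib, "/") * 1e6 + 1)
}

#' Per-gene stage-mean expression profiles
#'
#' Averages log-CPM over the replicates of each stage (WT samples by
#' default, mirroring clustering of the wild-type differentiation course)
#' and optionally standardizes each gene to zero mean / unit variance so
#' clustering sees profile shape, not expression level.
#'
#' @param expr log-CPM matrix from [normalize_log_cpm()].
#' @param samples Sample sheet.
#' @param genotype Genotype whose samples define the profiles.
#' @param standardize Standardize each row (default TRUE).
#' @return Matrix genes x stages (stage order = order of first appearance in
#'   the sheet).
#' @export
stage_profiles <- function(expr, samples, genotype = "WT",
                           standardize = TRUE) {
  sel <- samples[samples$genotype == genotype, , drop = FALSE]
  if (!nrow(sel)) stop("no samples with genotype ", genotype)
  stages <- unique(sel$stage)
  prof <- vapply(stages, function(s) {
    ids <- sel$sample_id[sel$stage == s]
    rowMeans(expr[, ids, drop = FALSE])
  }, numeric(nrow(expr)))
  colnames(prof) <- stages
  if (standardize) {
    mu <- rowMeans(prof)
    sdv <- apply(prof, 1, stats::sd)
    sdv[sdv == 0] <- 1  # flat profiles map to the zero vector
    prof <- (prof - mu) / sdv
  }
  prof
}

# k-means++ seeding: D^2-weighted center sampling
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1, prob = probs), ]
    dj <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}

# One Lloyd run from given centers; falls back to a plain assignment
# evaluation if stats::kmeans aborts on an empty cluster.
lloyd_from <- function(x, centers, iter_max = 100L) {
  fit <- tryCatch(
    stats::kmeans(x, centers = centers, iter.max = iter_max,
                  algorithm = "Lloyd"),
    error = function(e) NULL,
    warning = function(w) suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd")))
  if (!is.null(fit)) {
    return(list(cluster = fit$cluster, centers = fit$centers,
                wss = fit$tot.withinss))
  }
  # empty-cluster abort: score the seeding assignment itself (valid
  # clustering; keeps the WSS curve well-defined)
  d <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
  assign <- max.col(-d, ties.method = "first")
  wss <- sum((x - centers[assign, , drop = FALSE])^2)
  list(cluster = assign, centers = centers, wss = wss)
}

best_kmeans <- function(x, k, n_restarts, extra_centers = NULL,
                        iter_max = 100L) {
  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    fit <- lloyd_from(x, kmeanspp_centers(x, k), iter_max)
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  if (!is.null(extra_centers)) {
    fit <- lloyd_from(x, extra_centers, iter_max)
    if (fit$wss < best$wss) best <- fit
  }
  best
}

#' Choose k by the elbow of the within-cluster sum-of-squares curve
#'
#' For each k in `k_grid` the best of `n_restarts` k-means++ Lloyd restarts
#' is kept; the candidate set at k+1 additionally contains the best
#' k-solution with its widest cluster split (its centroid plus the farthest
#' member point), which makes the WSS curve non-increasing by construction.
#' The chosen k maximizes the perpendicular distance from the (axis
#' normalized) WSS curve to the chord joining its endpoints.
#'
#' @param x Numeric matrix (observations x features), e.g. standardized
#'   stage profiles.
#' @param k_grid Increasing integer grid with at least 3 points.
#' @param n_restarts Restarts per k.
#' @param seed Integer seed.
#' @return `list(k, wss = data.frame(k, wss))`.
#' @export
select_k <- function(x, k_grid, n_restarts = 10L, seed = 1L) {
  k_grid <- as.integer(k_grid)
  if (length(k_grid) < 3) stop("k_grid needs at least 3 points (elbow undefined)")
  if (is.unsorted(k_grid, strictly = TRUE)) stop("k_grid must be increasing")
  if (max(k_grid) > nrow(x)) stop("k exceeds number of observations")
  with_seed(seed, {
    wss <- numeric(length(k_grid))
    prev <- NULL
    for (i in seq_along(k_grid)) {
      k <- k_grid[i]
      extra <- NULL
      if (!is.null(prev) && k == prev$k + 1L) {
        extra <- split_widest(x, prev$fit)
      }
      fit <- best_kmeans(x, k, n_restarts, extra_centers = extra)
      wss[i] <- fit$wss
      prev <- list(k = k, fit = fit)
    }
    list(k = k_grid[elbow_index(k_grid, wss)],
         wss = data.frame(k = k_grid, wss = wss))
  })
}

# previous best solution's centers plus the farthest point of the cluster
# with the largest within-SS ("widest" cluster)
split_widest <- function(x, fit) {
  k <- nrow(fit$centers)
  per <- vapply(seq_len(k), function(j) {
    idx <- which(fit$cluster == j)
    if (!length(idx)) return(0)
    sum((x[idx, , drop = FALSE] -
           matrix(fit$centers[j, ], length(idx), ncol(x), byrow = TRUE))^2)
  }, numeric(1))
  j <- which.max(per)
  idx <- which(fit$cluster == j)
  d <- rowSums((x[idx, , drop = FALSE] -
                  matrix(fit$centers[j, ], length(idx), ncol(x),
                         byrow = TRUE))^2)
  rbind(fit$centers, x[idx[which.max(d)], ])
}

# max perpendicular distance to the chord, after scaling both axes to [0,1]
elbow_index <- function(k, wss) {
  kx <- (k - k[1]) / max(k[length(k)] - k[1], 1)
  wy <- if (wss[1] == wss[length(wss)]) rep(0, length(wss)) else
    (wss - wss[length(wss)]) / (wss[1] - wss[length(wss)])
  # chord runs (0,1) -> (1,0); distance = |kx + wy - 1| / sqrt(2)
  which.max(abs(kx + wy - 1))
}

#' Cluster genes into k minor clusters
#'
#' Lloyd's k-means (Euclidean) on per-gene standardized stage-mean profiles,
#' best of `n_restarts` k-means++ restarts by WSS; deterministic given
#' `seed`.
#'
#' @param x Profiles matrix (genes x stages), typically [stage_profiles()].
#' @param k Number of minor clusters (>= 2).
#' @param n_restarts Restarts.
#' @param seed Integer seed.
#' @return Object of class `cluster_assignment`: `minor` (named integer),
#'   `centroids` (k x stages), `wss`, `k`, and a `major` slot filled by
#'   [merge_clusters()].
#' @export
kmeans_cluster <- function(x, k, n_restarts = 10L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds number of genes")
  fit <- with_seed(seed, best_kmeans(x, k, n_restarts))
  structure(list(minor = stats::setNames(fit$cluster, rownames(x)),
                 centroids = fit$centers, wss = fit$wss, k = k,
                 major = NULL, map = NULL),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment> k=", x$k, " genes=", length(x$minor),
      " wss=", fmt_num(x$wss), "\n", sep = "")
  if (!is.null(x$major)) print(table(x$major))
  invisible(x)
}

#' Merge minor clusters into major stage-profile classes
#'
#' Each minor centroid is assigned to the template (A-E) with the highest
#' Pearson correlation; minor clusters whose best correlation is below
#' `min_cor` stay `"unassigned"`. An explicit `minor -> major` map (as a
#' named character vector, names = minor ids) overrides the correlation
#' rule, mirroring a fixed manual merge table. Ties break in template order.
#'
#' @param assignment A [kmeans_cluster()] result.
#' @param templates Named list/matrix of per-stage template profiles
#'   (names give the major labels, conventionally A-E).
#' @param explicit_map Optional named character vector, e.g. `c("6" = "B")`.
#' @param min_cor Correlation threshold (default 0.5).
#' @return The assignment with `major` (named character per gene) and `map`
#'   (per minor cluster) filled in.
#' @export
merge_clusters <- function(assignment, templates, explicit_map = NULL,
                           min_cor = 0.5) {
  tmpl <- if (is.matrix(templates)) {
    lapply(stats::setNames(seq_len(nrow(templates)), rownames(templates)),
           function(i) templates[i, ])
  } else templates
  n_stage <- ncol(assignment$centroids)
  if (any(lengths(tmpl) != n_stage)) {
    stop("template length must equal number of stages (", n_stage, ")")
  }
  map <- character(assignment$k)
  for (j in seq_len(assignment$k)) {
    r <- vapply(tmpl, function(t) {
      suppressWarnings(stats::cor(assignment$centroids[j, ], t))
    }, numeric(1))
    r[is.na(r)] <- -Inf
    map[j] <- if (max(r) < min_cor) "unassigned" else
      names(tmpl)[which.max(r)]  # which.max: first = template order
  }
  if (!is.null(explicit_map)) {
    idx <- as.integer(names(explicit_map))
    if (any(is.na(idx)) || any(idx < 1 | idx > assignment$k)) {
      stop("explicit_map names must be minor cluster ids 1..k")
    }
    map[idx] <- unname(explicit_map)
  }
  assignment$map <- stats::setNames(map, seq_len(assignment$k))
  assignment$major <- stats::setNames(map[assignment$minor],
                                      names(assignment$minor))
  assignment
}

#' KO-vs-WT differential expression at one stage
#'
#' Compares KO and WT replicates of `stage` on the log2(CPM+1) scale.
#' log2FC is the mean difference (KO - WT) on that scale; p-values are
#' BH-adjusted across all tested genes. Labels: `Up` if log2FC > 0 and
#' adjusted p < 0.05, `Down` if log2FC < 0 and adjusted p < 0.05, else
#' `Neutral`.
#'
#' Two test statistics are available. The default, `"moderated"`, is the
#' empirical-Bayes moderated t with a mean-variance trend (limma-trend),
#' which borrows variance information across genes -- at 2-3 replicates
#' per genotype a per-gene Welch test has so few degrees of freedom that
#' even strong planted effects rarely survive FDR control, whereas the
#' moderated test stays calibrated under the null and recovers them.
#' `"welch"` gives the plain per-gene Welch t-test.
#'
#' @param counts Integer count matrix.
#' @param samples Sample sheet.
#' @param stage Stage label with >= 2 replicates per genotype.
#' @param genes Genes to test (default: [filter_genes()] of `counts`).
#' @param alpha Adjusted-p cutoff for labeling.
#' @param method `"moderated"` (default) or `"welch"`.
#' @return `data.frame(gene_id, log2fc, p, padj, label)` of class
#'   `de_result`.
#' @export
differential_expression <- function(counts, samples, stage,
                                    genes = NULL, alpha = 0.05,
                                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  ko <- samples$sample_id[samples$stage == stage & samples$genotype == "KO"]
  wt <- samples$sample_id[samples$stage == stage & samples$genotype == "WT"]
  if (length(ko) < 2 || length(wt) < 2) {
    stop("need >= 2 replicates per genotype at stage ", stage,
         " (WT: ", length(wt), ", KO: ", length(ko), ")")
  }
  if (is.null(genes)) genes <- filter_genes(counts)
  expr <- normalize_log_cpm(counts[genes, c(wt, ko), drop = FALSE])
  xko <- expr[, ko, drop = FALSE]
  xwt <- expr[, wt, drop = FALSE]
  lfc <- rowMeans(xko) - rowMeans(xwt)
  if (method == "moderated") {
    design <- cbind(intercept = 1,
                    ko = as.integer(c(wt, ko) %in% ko))
    fit <- limma::eBayes(limma::lmFit(expr, design), trend = TRUE)
    p <- fit$p.value[, "ko"]
  } else {
    p <- vapply(seq_along(genes), function(i) {
      a <- xko[i, ]; b <- xwt[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        return(if (mean(a) == mean(b)) 1 else 0)
      }
      stats::t.test(a, b)$p.value
    }, numeric(1))
  }
  p <- unname(p)
  padj <- bh_adjust(p)
  label <- rep("Neutral", length(genes))
  label[lfc > 0 & padj < alpha] <- "Up"
  label[lfc < 0 & padj < alpha] <- "Down"
  structure(data.frame(gene_id = genes, log2fc = lfc, p = p, padj = padj,
                       label = label, stringsAsFactors = FALSE,
                       row.names = NULL),
            stage = stage, class = c("de_result", "data.frame"))
}
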