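## Statistical primitives shared by the binding and class modules.

#' One-sided Wilcoxon rank-sum test
#'
#' Tests whether `x` is stochastically greater (`alternative = "greater"`)
#' or less (`"less"`) than `y`. Uses the exact rank-sum null when the
#' combined sample size is at most 16 and there are no ties; otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction. The branch taken is recorded in the `method` tag.
#'
#' @param x,y Numeric samples (each nonempty).
#' @param alternative `"greater"` or `"less"` (of `x` relative to `y`).
#' @param exact_max Combined-size cutoff for the exact branch.
#' @return `list(statistic, p, method, alternative)` with
#'   `method %in% c("exact", "normal-approx")`.
#' @export
wilcoxon_one_sided <- function(x, y, alternative = c("greater", "less"),
                               exact_max = 16L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  list(statistic = unname(wt$statistic),
       p = min(1, wt$p.value),
       method = if (exact) "exact" else "normal-approx",
       alternative = alternative)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; adjusted values are >= raw and
#' capped at 1. `NA`s propagate.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' One-sided Fisher's exact test for enrichment of cell (1,1)
#'
#' Hypergeometric upper-tail probability of observing at least the given
#' count in the top-left cell of a 2x2 table with fixed margins.
#'
#' @param table_2x2 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @return `list(statistic, p, method)`; `statistic` is the (1,1) count.
#' @export
fisher_exact_one_sided <- function(table_2x2) {
  m <- as.matrix(table_2x2)
  if (!all(dim(m) == c(2, 2))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != floor(m))) {
    stop("table cells must be nonnegative integers")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero margin in 2x2 table")
  }
  ft <- stats::fisher.test(m, alternative = "greater")
  list(statistic = m[1, 1], p = ft$p.value, method = "exact")
}

#' Median and its bootstrap standard error
#'
#' The standard error is the standard deviation of the median over seeded
#' bootstrap resamples; used for the "median +/- SE" summaries of binding
#' signal and expression response.
#'
#' @param values Numeric vector of length >= 3.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed (required: results must be reproducible).
#' @return `list(median, se)`.
#' @export
median_se <- function(values, n_boot = 1000L, seed) {
  values <- as.numeric(values)
  if (length(values) < 3) stop("median_se needs at least 3 values")
  if (missing(seed)) stop("median_se requires a seed")
  meds <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stats::median(sample(values, replace = TRUE))
    }, numeric(1))
  })
  list(median = stats::median(values), se = stats::sd(meds))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions, 0
#' in expectation for independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("partitions must have equal length")
  }
  mclust::adjustedRandIndex(labels_a, labels_b)
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. All internal randomness goes through this so
## substreams stay independent of call order.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

## Named substream seeds derived from one global seed; kept < 2^31.
substream <- function(seed, name) {
  offs <- c(annotation = 11L, truth = 23L, expression = 37L, binding = 53L,
            cluster = 71L, de = 89L, boot = 97L, pipeline = 113L)
  if (!name %in% names(offs)) stop("unknown substream: ", name)
  as.integer((as.numeric(seed) * 1009 + offs[[name]]) %% 2147483647)
}
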