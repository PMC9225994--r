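## Regulatory classes: GLM-ranked TF importance for DE-vs-neutral
## classification, and the combinatorial CENL/CE/Rest promoter classes with
## enrichment and expression-response summaries.
##
## Bit order is fixed C (CEBPE), E (E2F1), N (NFYB), L (LIN54) in all
## outputs. Classification applies the rules in order CENL -> CE -> Rest,
## so CE means "C and E with at most one of N, L".

TF_PANEL <- c("PU.1", "CEBPA", "CEBPE", "MYC", "E2F1")

#' Build the TF-feature / DE-label table for one cluster
#'
#' One row per gene of the cluster with the five TF binding bits and the
#' DE-vs-neutral response label. Genes absent from the DE table are dropped
#' with a message; `Up` and `Down` both count as `DE`.
#'
#' @param binary Binary layer of a [binding_matrix()] (genes x TFs, must
#'   contain the five panel TFs).
#' @param de A [differential_expression()] result.
#' @param cluster_genes Gene ids of the cluster under study.
#' @return `data.frame(gene_id, PU.1, CEBPA, CEBPE, MYC, E2F1, label)`.
#' @export
build_feature_table <- function(binary, de, cluster_genes) {
  missing_tfs <- setdiff(TF_PANEL, colnames(binary))
  if (length(missing_tfs)) {
    stop("binary layer lacks TF(s): ", paste(missing_tfs, collapse = ", "))
  }
  genes <- intersect(cluster_genes, rownames(binary))
  in_de <- genes %in% de$gene_id
  if (any(!in_de)) {
    message("build_feature_table: dropping ", sum(!in_de),
            " gene(s) without DE results")
  }
  genes <- genes[in_de]
  lab <- de$label[match(genes, de$gene_id)]
  out <- data.frame(gene_id = genes,
                    binary[genes, TF_PANEL, drop = FALSE],
                    label = ifelse(lab == "Neutral", "neutral", "DE"),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  out
}

#' Ranked TF importance from a logistic GLM
#'
#' Logistic regression of the DE/neutral label on the five TF bits
#' (intercept included). Importance is the absolute Wald z-statistic of
#' each coefficient when the unpenalized fit converges without separation;
#' otherwise the fit is repeated with a small ridge penalty on standardized
#' features and importance is the absolute standardized coefficient
#' (flagged in the metadata). Constant features get importance 0 and the
#' last ranks; ties break alphabetically by TF name.
#'
#' @param feature_table A [build_feature_table()] result (>= 20 genes, both
#'   labels present).
#' @param ridge_lambda Ridge penalty for the fallback fit.
#' @return `data.frame(tf, coefficient, z, importance, rank)` of class
#'   `importance_ranking`, with attributes `converged` and `ridge`.
#' @export
rank_tf_importance <- function(feature_table, ridge_lambda = 1e-2) {
  tfs <- intersect(TF_PANEL, names(feature_table))
  y <- feature_table$label
  if (length(unique(y)) < 2) stop("both DE and neutral labels required")
  if (nrow(feature_table) < 20) stop("need >= 20 genes")
  x <- as.matrix(feature_table[, tfs, drop = FALSE])
  storage.mode(x) <- "double"
  yb <- as.integer(y == "DE")
  sds <- apply(x, 2, stats::sd)
  live <- sds > 0
  coefficient <- z <- importance <- stats::setNames(rep(0, length(tfs)), tfs)
  ridge <- FALSE
  converged <- TRUE
  if (sum(live) > 0) {
    xl <- x[, live, drop = FALSE]
    fit <- suppressWarnings(
      stats::glm(yb ~ xl, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    # separation shows up as non-convergence or exploding coefficients/SEs
    separated <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 10,
                                       na.rm = TRUE) ||
      anyNA(stats::coef(fit))
    if (!separated) {
      cf <- sm[-1, , drop = FALSE]
      coefficient[live] <- cf[, "Estimate"]
      z[live] <- cf[, "z value"]
      importance[live] <- abs(cf[, "z value"])
    } else {
      converged <- FALSE
      ridge <- TRUE
      xs <- scale(xl)
      rf <- glmnet::glmnet(xs, yb, family = "binomial", alpha = 0,
                           lambda = ridge_lambda, standardize = FALSE)
      cf <- as.numeric(stats::coef(rf))[-1]
      coefficient[live] <- cf
      z[live] <- NA_real_
      importance[live] <- abs(cf)
    }
  }
  ord <- order(-importance, names(importance))  # ties: alphabetical
  rank <- integer(length(tfs))
  rank[ord] <- seq_along(tfs)
  out <- data.frame(tf = tfs, coefficient = unname(coefficient),
                    z = unname(z), importance = unname(importance),
                    rank = rank, stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, converged = converged, ridge = ridge,
            ridge_lambda = if (ridge) ridge_lambda else NA_real_,
            class = c("importance_ranking", "data.frame"))
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat("<importance_ranking>",
      if (attr(x, "ridge")) "(ridge fallback)" else "(GLM |z|)", "\n")
  print(as.data.frame(x))
  invisible(x)
}

#' Assemble the C/E/N/L promoter bits
#'
#' C, E and N come from promoter overlap (or median-threshold binding) with
#' the CEBPE, E2F1 and NFYB evidence; LIN54 evidence is either a peak
#' overlap (default) or a motif hit (`motif_score > 0`), per
#' `lin54_evidence`.
#'
#' @param genes Gene ids (row order of the output).
#' @param cebpe,e2f1,nfyb Named 0/1 vectors (or logical) per gene.
#' @param lin54 Named 0/1 vector (overlap evidence) or named numeric motif
#'   scores (motif evidence).
#' @param lin54_evidence `"overlap"` or `"motif"`.
#' @return Integer matrix genes x `c("C","E","N","L")`.
#' @export
assign_promoter_bits <- function(genes, cebpe, e2f1, nfyb, lin54,
                                 lin54_evidence = c("overlap", "motif")) {
  lin54_evidence <- match.arg(lin54_evidence)
  pull <- function(v, what) {
    if (is.null(v)) stop("missing evidence source: ", what)
    miss <- setdiff(genes, names(v))
    if (length(miss)) {
      stop("missing ", what, " evidence for gene(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    v[genes]
  }
  l_raw <- pull(lin54, "LIN54")
  l_bit <- if (lin54_evidence == "motif") as.integer(l_raw > 0) else
    as.integer(l_raw != 0)
  bits <- cbind(C = as.integer(pull(cebpe, "CEBPE") != 0),
                E = as.integer(pull(e2f1, "E2F1") != 0),
                N = as.integer(pull(nfyb, "NFYB") != 0),
                L = l_bit)
  rownames(bits) <- genes
  bits
}

#' Classify a promoter from its C/E/N/L bits
#'
#' `CENL` when all four TFs bind; else `CE` when CEBPE and E2F1 bind (with
#' at most one of NFYB, LIN54); else `Rest`. Rules apply in that order, so
#' the 16 bit combinations partition as CENL:1, CE:3, Rest:12.
#'
#' @param bits Length-4 0/1 vector `(C, E, N, L)` or a matrix with columns
#'   `C`, `E`, `N`, `L`.
#' @return Character class(es).
#' @export
classify_promoter <- function(bits) {
  if (is.matrix(bits)) {
    b <- bits[, c("C", "E", "N", "L"), drop = FALSE]
  } else {
    b <- matrix(bits, 1, 4, dimnames = list(NULL, c("C", "E", "N", "L")))
  }
  if (!all(b %in% c(0L, 1L))) stop("bits must be 0/1")
  unname(ifelse(b[, "C"] & b[, "E"] & b[, "N"] & b[, "L"], "CENL",
                ifelse(b[, "C"] & b[, "E"], "CE", "Rest")))
}

#' Promoter class table for a set of genes
#' @param bits Matrix from [assign_promoter_bits()].
#' @return `data.frame(gene_id, C, E, N, L, bits, class)`.
#' @export
promoter_class_table <- function(bits) {
  data.frame(gene_id = rownames(bits), as.data.frame(bits),
             bits = apply(bits, 1, paste, collapse = ""),
             class = classify_promoter(bits),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' CENL class frequency by cluster, with enrichment test
#'
#' Per cluster: gene count, CENL count and CENL percentage. Enrichment of
#' CENL in the focal cluster versus all other clusters is tested with a
#' one-sided Fisher's exact test on the 2x2 table. Raw 4-bit subclasses
#' with `n <= min_subclass_n` are suppressed from the subclass report (the
#' three classes themselves are always reported).
#'
#' @param class_table A [promoter_class_table()].
#' @param cluster_by_gene Named character vector gene -> major cluster.
#' @param focal Focal cluster for the enrichment test (default `"B"`).
#' @param min_subclass_n Suppression threshold for raw subclasses.
#' @return `list(frequencies, enrichment = list(focal, table, p),
#'   subclasses)`.
#' @export
class_frequency_by_cluster <- function(class_table, cluster_by_gene,
                                       focal = "B", min_subclass_n = 30L) {
  cl <- cluster_by_gene[class_table$gene_id]
  cl[is.na(cl)] <- "unassigned"
  clusters <- sort(unique(cl))
  freq <- do.call(rbind, lapply(clusters, function(k) {
    idx <- cl == k
    n <- sum(idx)
    n_cenl <- sum(class_table$class[idx] == "CENL")
    data.frame(cluster = k, n = n, n_cenl = n_cenl,
               pct_cenl = if (n > 0) 100 * n_cenl / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  enrichment <- NULL
  if (focal %in% clusters && length(clusters) >= 2) {
    a <- sum(cl == focal & class_table$class == "CENL")
    b <- sum(cl == focal & class_table$class != "CENL")
    cc <- sum(cl != focal & class_table$class == "CENL")
    d <- sum(cl != focal & class_table$class != "CENL")
    tab <- matrix(c(a, cc, b, d), 2, 2,
                  dimnames = list(c("focal", "other"), c("CENL", "not")))
    enrichment <- list(focal = focal, table = tab,
                       p = fisher_exact_one_sided(tab)$p)
  }
  sub <- as.data.frame(table(bits = class_table$bits),
                       stringsAsFactors = FALSE)
  names(sub)[2] <- "n"
  sub <- sub[sub$n > min_subclass_n, , drop = FALSE]
  rownames(sub) <- NULL
  list(frequencies = freq, enrichment = enrichment, subclasses = sub)
}

#' Expression response (KO vs WT) by promoter class
#'
#' Per class: gene count, median log2 fold change with its bootstrap
#' standard error, and one-sided Wilcoxon tests (CENL > Rest, CE > Rest)
#' BH-adjusted. Classes with fewer than `min_n` genes are excluded from the
#' tests.
#'
#' @param class_table A [promoter_class_table()].
#' @param de A [differential_expression()] result.
#' @param min_n Minimum class size for testing.
#' @param seed Seed for the bootstrap SE.
#' @return `list(summary, tests)`.
#' @export
class_expression_response <- function(class_table, de, min_n = 3L,
                                      seed = 1L) {
  lfc <- de$log2fc[match(class_table$gene_id, de$gene_id)]
  classes <- c("CENL", "CE", "Rest")
  vals <- lapply(stats::setNames(classes, classes), function(k) {
    v <- lfc[class_table$class == k]
    v[!is.na(v)]
  })
  summary_df <- do.call(rbind, lapply(classes, function(k) {
    v <- vals[[k]]
    if (length(v) >= 3) {
      ms <- median_se(v, seed = seed)
      data.frame(class = k, n = length(v), median_log2fc = ms$median,
                 se_log2fc = ms$se, stringsAsFactors = FALSE)
    } else {
      data.frame(class = k, n = length(v),
                 median_log2fc = if (length(v)) stats::median(v) else NA_real_,
                 se_log2fc = NA_real_, stringsAsFactors = FALSE)
    }
  }))
  tests <- NULL
  for (k in c("CENL", "CE")) {
    if (length(vals[[k]]) < min_n || length(vals$Rest) < min_n) {
      message("class_expression_response: skipping ", k,
              " > Rest test (class too small)")
      next
    }
    wt <- wilcoxon_one_sided(vals[[k]], vals$Rest, "greater")
    tests <- rbind(tests, data.frame(
      comparison = paste0(k, ">Rest"), n = length(vals[[k]]), p = wt$p,
      stringsAsFactors = FALSE))
  }
  if (!is.null(tests)) tests$padj <- bh_adjust(tests$p)
  list(summary = summary_df, tests = tests)
}
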