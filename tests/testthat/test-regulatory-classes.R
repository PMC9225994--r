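# Combinatorial promoter classes and GLM-ranked TF importance.

all_bits <- function() {
  b <- as.matrix(expand.grid(C = 0:1, E = 0:1, N = 0:1, L = 0:1))
  rownames(b) <- apply(b, 1, paste, collapse = "")
  b
}

test_that("classify_promoter partitions the 16 combinations as 1/3/12", {
  cls <- classify_promoter(all_bits())
  expect_equal(sum(cls == "CENL"), 1)
  expect_equal(sum(cls == "CE"), 3)
  expect_equal(sum(cls == "Rest"), 12)
  expect_equal(classify_promoter(c(1, 1, 1, 1)), "CENL")
  expect_equal(classify_promoter(c(1, 1, 1, 0)), "CE")
  expect_equal(classify_promoter(c(1, 1, 0, 1)), "CE")
  expect_equal(classify_promoter(c(1, 0, 1, 1)), "Rest")
  expect_error(classify_promoter(c(1, 2, 0, 0)), "0/1")
})

test_that("promoter bits assemble in fixed C,E,N,L order with evidence checks", {
  genes <- c("g1", "g2")
  ev <- function(v) stats::setNames(v, genes)
  bits <- assign_promoter_bits(genes, ev(c(1, 0)), ev(c(1, 0)),
                               ev(c(1, 0)), ev(c(1, 0)))
  expect_identical(colnames(bits), c("C", "E", "N", "L"))
  expect_equal(unname(bits["g1", ]), c(1L, 1L, 1L, 1L))
  # LIN54 via motif score > 0
  bits2 <- assign_promoter_bits(genes, ev(c(0, 0)), ev(c(0, 0)),
                                ev(c(0, 0)), ev(c(3.2, 0)),
                                lin54_evidence = "motif")
  expect_equal(unname(bits2["g1", ]), c(0L, 0L, 0L, 1L))
  expect_error(
    assign_promoter_bits(genes, ev(c(1, 0)), ev(c(1, 0)), ev(c(1, 0)),
                         stats::setNames(1, "g1")),
    "missing LIN54")
})

test_that("feature table pairs TF bits with DE labels and conserves rows", {
  binary <- matrix(0L, 4, 5,
                   dimnames = list(paste0("g", 1:4),
                                   c("PU.1", "CEBPA", "CEBPE", "MYC",
                                     "E2F1")))
  binary["g1", "CEBPE"] <- 1L
  de <- structure(data.frame(gene_id = paste0("g", 1:3),
                             log2fc = c(1, 0, -1), p = c(0.001, 0.9, 0.2),
                             padj = c(0.01, 0.95, 0.4),
                             label = c("Up", "Neutral", "Neutral"),
                             stringsAsFactors = FALSE),
                  class = c("de_result", "data.frame"))
  expect_message(ft <- build_feature_table(binary, de, paste0("g", 1:4)),
                 "dropping 1")
  expect_equal(nrow(ft), 3)
  expect_equal(ft$label[ft$gene_id == "g1"], "DE")
  panel <- c("PU.1", "CEBPA", "CEBPE", "MYC", "E2F1")
  expect_equal(unname(unlist(ft[ft$gene_id == "g1", panel])),
               c(0, 0, 1, 0, 0))
  expect_error(build_feature_table(binary[, 1:4], de, "g1"), "E2F1")
})

sim_feature_table <- function(n, or_cebpe = 6, seed = 1) {
  with_seed_local <- function(expr) expr
  set.seed(seed)
  tfs <- c("PU.1", "CEBPA", "CEBPE", "MYC", "E2F1")
  x <- matrix(stats::rbinom(n * 5, 1, 0.3), n, 5,
              dimnames = list(paste0("g", seq_len(n)), tfs))
  eta <- -1 + log(or_cebpe) * x[, "CEBPE"]
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  data.frame(gene_id = rownames(x), x,
             label = ifelse(y == 1, "DE", "neutral"),
             check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("importance ranking recovers a planted driver and handles edge cases", {
  hits <- vapply(1:20, function(s) {
    r <- rank_tf_importance(sim_feature_table(600, or_cebpe = 6, seed = s))
    r$tf[r$rank == 1] == "CEBPE"
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  ft <- sim_feature_table(200, seed = 3)
  ft$MYC <- 0  # constant feature
  r <- rank_tf_importance(ft)
  expect_equal(r$importance[r$tf == "MYC"], 0)
  expect_equal(r$rank[r$tf == "MYC"], 5)

  expect_error(rank_tf_importance(ft[ft$label == "DE", ]), "both")
  expect_error(rank_tf_importance(ft[1:10, ]), ">= 20")
})

test_that("importance is invariant to column order and gene relabeling", {
  ft <- sim_feature_table(300, seed = 5)
  r1 <- rank_tf_importance(ft)
  ft2 <- ft[, c("gene_id", "E2F1", "MYC", "CEBPE", "CEBPA", "PU.1",
                "label")]
  r2 <- rank_tf_importance(ft2)
  expect_equal(r1[order(r1$tf), ], r2[order(r2$tf), ],
               ignore_attr = TRUE)
  ft3 <- ft
  ft3$gene_id <- rev(ft3$gene_id)
  r3 <- rank_tf_importance(ft3)
  expect_equal(r1$importance, r3$importance)
})

test_that("separated fits fall back to a flagged ridge refit", {
  set.seed(6)
  n <- 60
  tfs <- c("PU.1", "CEBPA", "CEBPE", "MYC", "E2F1")
  x <- matrix(stats::rbinom(n * 5, 1, 0.4), n, 5,
              dimnames = list(paste0("g", 1:n), tfs))
  ft <- data.frame(gene_id = rownames(x), x,
                   label = ifelse(x[, "CEBPE"] == 1, "DE", "neutral"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  r <- rank_tf_importance(ft)  # perfect separation on CEBPE
  expect_true(attr(r, "ridge"))
  expect_false(attr(r, "converged"))
  expect_equal(r$tf[r$rank == 1], "CEBPE")
})

test_that("CENL frequency table and enrichment recover planted contrasts", {
  set.seed(7)
  n <- 1000
  cl <- stats::setNames(sample(c("A", "B"), n, TRUE, prob = c(0.6, 0.4)),
                        paste0("g", 1:n))
  cenl_p <- ifelse(cl == "B", 0.2, 0.02)
  is_cenl <- stats::rbinom(n, 1, cenl_p) == 1
  bits <- cbind(C = as.integer(is_cenl), E = as.integer(is_cenl),
                N = as.integer(is_cenl), L = as.integer(is_cenl))
  rownames(bits) <- names(cl)
  tab <- promoter_class_table(bits)
  fr <- class_frequency_by_cluster(tab, cl, focal = "B")
  b_row <- fr$frequencies[fr$frequencies$cluster == "B", ]
  expect_lt(abs(b_row$pct_cenl - 20), 5)
  expect_lt(fr$enrichment$p, 1e-6)
  # subclass suppression: only combinations with n > 30 reported
  expect_true(all(fr$subclasses$n > 30))

  # identical frequencies (exactly 10% CENL in both clusters) -> no enrichment
  cl0 <- stats::setNames(rep(c("A", "B"), each = 500), paste0("g", 1:n))
  cenl0 <- rep(c(rep(TRUE, 50), rep(FALSE, 450)), 2)
  bits0 <- cbind(C = as.integer(cenl0), E = as.integer(cenl0),
                 N = as.integer(cenl0), L = as.integer(cenl0))
  rownames(bits0) <- names(cl0)
  fr0 <- class_frequency_by_cluster(promoter_class_table(bits0), cl0,
                                    focal = "B")
  expect_gte(fr0$enrichment$p, 0.4)
})

test_that("class expression response finds planted CENL upregulation only", {
  set.seed(8)
  mk <- function(n_cenl, n_ce, n_rest, cenl_shift) {
    gene_id <- paste0("g", seq_len(n_cenl + n_ce + n_rest))
    cls <- c(rep("CENL", n_cenl), rep("CE", n_ce), rep("Rest", n_rest))
    lfc <- stats::rnorm(length(gene_id), 0, 0.3)
    lfc[cls == "CENL"] <- lfc[cls == "CENL"] + cenl_shift
    list(ct = data.frame(gene_id = gene_id, class = cls,
                         stringsAsFactors = FALSE),
         de = structure(data.frame(gene_id = gene_id, log2fc = lfc,
                                   p = 0.5, padj = 0.5, label = "Neutral",
                                   stringsAsFactors = FALSE),
                        class = c("de_result", "data.frame")))
  }
  d <- mk(40, 60, 300, cenl_shift = 1)
  resp <- class_expression_response(d$ct, d$de, seed = 1)
  expect_gt(resp$summary$median_log2fc[resp$summary$class == "CENL"], 0)
  expect_lt(resp$tests$padj[resp$tests$comparison == "CENL>Rest"], 0.01)
  expect_gt(resp$tests$padj[resp$tests$comparison == "CE>Rest"], 0.05)

  # null: no planted shift -> mostly non-significant over seeds
  nulls <- vapply(1:50, function(s) {
    set.seed(100 + s)
    d0 <- mk(40, 60, 300, cenl_shift = 0)
    r0 <- class_expression_response(d0$ct, d0$de, seed = s)
    all(r0$tests$padj >= 0.05)
  }, logical(1))
  expect_gte(mean(nulls), 0.8)

  # empty class: summary row kept, test skipped
  d2 <- mk(40, 0, 300, cenl_shift = 1)
  expect_message(r2 <- class_expression_response(d2$ct, d2$de, seed = 1),
                 "skipping CE")
  expect_equal(r2$summary$n[r2$summary$class == "CE"], 0)
})
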