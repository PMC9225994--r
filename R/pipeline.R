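## Pipeline orchestration: simulate/load -> cluster -> DE -> CRE catalog ->
## binding -> classes -> importance, with a machine-readable run report.

#' Pipeline configuration
#'
#' Either a `simulate` block (a [sim_config()]) or a set of input paths
#' (`genes`, `genome`, `counts`, `samples`, named `peaks`, named `tracks`,
#' `open_chromatin`, optional `prior_enhancers`, optional `pfm`), plus the
#' stage parameters. All stochastic stages derive their seeds from `seed`.
#'
#' @param simulate Optional [sim_config()] block.
#' @param inputs Optional named list of input paths (see above).
#' @param k Number of minor clusters; set `k_grid` instead to choose k by
#'   the elbow rule.
#' @param k_grid Optional increasing grid for [select_k()].
#' @param n_restarts K-means restarts.
#' @param de_stage Stage for the KO-vs-WT contrast.
#' @param alpha Adjusted-p cutoff for DE labels.
#' @param promoter_half_width,enhancer_width,distal_bp CRE parameters (bp).
#' @param distance_edges Distance-class edges.
#' @param lin54_evidence `"overlap"` or `"motif"` LIN54 evidence.
#' @param focal_cluster Focal cluster for CENL enrichment.
#' @param min_subclass_n Subclass suppression threshold.
#' @param templates Optional cluster templates matrix for
#'   [merge_clusters()]; defaults to [cluster_templates()] when simulating.
#' @param explicit_map Optional minor-to-major override map.
#' @param seed Integer pipeline seed.
#' @export
pipeline_config <- function(simulate = sim_config(), inputs = NULL,
                            k = 8L, k_grid = NULL, n_restarts = 10L,
                            de_stage = "MY", alpha = 0.05,
                            promoter_half_width = 1000L,
                            enhancer_width = 500L, distal_bp = 1000L,
                            distance_edges = default_distance_edges(),
                            lin54_evidence = c("overlap", "motif"),
                            focal_cluster = "B", min_subclass_n = 30L,
                            templates = NULL, explicit_map = NULL,
                            seed = 1L) {
  lin54_evidence <- match.arg(lin54_evidence)
  if (is.null(simulate) && is.null(inputs)) {
    stop("config error at /inputs: either a simulate block or input paths ",
         "are required")
  }
  if (!is.null(inputs)) {
    req <- c("genes", "genome", "counts", "samples", "peaks", "tracks",
             "open_chromatin")
    miss <- setdiff(req, names(inputs))
    if (length(miss)) {
      stop("config error at /inputs/", miss[1], ": missing input")
    }
  }
  structure(list(simulate = simulate, inputs = inputs, k = k,
                 k_grid = k_grid, n_restarts = n_restarts,
                 de_stage = de_stage, alpha = alpha,
                 promoter_half_width = promoter_half_width,
                 enhancer_width = enhancer_width, distal_bp = distal_bp,
                 distance_edges = distance_edges,
                 lin54_evidence = lin54_evidence,
                 focal_cluster = focal_cluster,
                 min_subclass_n = min_subclass_n, templates = templates,
                 explicit_map = explicit_map, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a
#' `simulate` block maps onto [sim_config()] arguments.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    sim_args <- raw$simulate
    known <- names(formals(sim_config))
    bad <- setdiff(names(sim_args), known)
    if (length(bad)) stop("config error at /simulate/", bad[1],
                          ": unknown field")
    sim <- do.call(sim_config, sim_args)
  }
  known <- setdiff(names(formals(pipeline_config)), c("simulate"))
  args <- raw[intersect(names(raw), known)]
  bad <- setdiff(names(raw), c(known, "simulate"))
  if (length(bad)) stop("config error at /", bad[1], ": unknown field")
  do.call(pipeline_config, c(list(simulate = sim), args))
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    return(simulate_fixture(config$simulate))
  }
  ip <- config$inputs
  for (f in c("genes", "genome", "counts", "samples", "open_chromatin")) {
    if (!file.exists(ip[[f]])) stop("input error: missing file ", ip[[f]])
  }
  annotation <- read_gene_table(ip$genes)
  genome <- read_fasta(ip$genome, annotation)
  cs <- read_counts(ip$counts, ip$samples)
  peaksets <- lapply(stats::setNames(names(ip$peaks), names(ip$peaks)),
                     function(tf) read_bed(ip$peaks[[tf]], tf = tf))
  tracks <- lapply(stats::setNames(names(ip$tracks), names(ip$tracks)),
                   function(tf) {
                     read_signal(ip$tracks[[tf]], ip$bin_size %||% 100L,
                                 annotation, name = tf)
                   })
  list(annotation = annotation, genome = genome, counts = cs$counts,
       samples = cs$samples, peaksets = peaksets, tracks = tracks,
       open_chromatin = read_bed(ip$open_chromatin, tf = "open_chromatin"),
       prior_enhancers = if (!is.null(ip$prior_enhancers))
         read_bed(ip$prior_enhancers, tf = "prior"),
       motif = if (!is.null(ip$pfm)) read_pfm(ip$pfm),
       truth = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one overlapping TF peak per promoter (highest score, then leftmost)
promoter_tf_peaks <- function(promoters, peakset) {
  hits <- GenomicRanges::findOverlaps(as_granges(promoters),
                                      as_granges(as.data.frame(peakset)))
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (!length(qh)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  }
  sc <- peakset$score[sh]
  sc[is.na(sc)] <- 0
  ord <- order(qh, -sc, peakset$start[sh])
  keep <- ord[!duplicated(qh[ord])]
  data.frame(gene_id = promoters$gene_id[qh[keep]],
             chrom = peakset$chrom[sh[keep]],
             start = peakset$start[sh[keep]],
             end = peakset$end[sh[keep]], stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (simulate/load, expression
#' clustering, differential expression, CRE catalog, binding, promoter
#' classes, TF importance) and returns all stage outputs plus a run
#' report. With `out_dir`, stage tables (TSV), BEDs and `report.json` are
#' written; re-running an identical config reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return Object of class `pipeline_result`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(parameters = list(
    k = config$k, de_stage = config$de_stage, alpha = config$alpha,
    promoter_half_width = config$promoter_half_width,
    enhancer_width = config$enhancer_width,
    lin54_evidence = config$lin54_evidence, seed = config$seed))

  ## stage 1: inputs
  fx <- load_pipeline_inputs(config)
  report$inputs <- list(n_genes = nrow(fx$annotation$genes),
                        n_samples = nrow(fx$samples),
                        simulated = !is.null(config$simulate))

  ## stage 2: expression clustering
  genes_kept <- filter_genes(fx$counts)
  expr <- normalize_log_cpm(fx$counts[genes_kept, , drop = FALSE])
  prof <- stage_profiles(expr, fx$samples)
  seed_cl <- substream(config$seed, "cluster")
  wss_curve <- NULL
  k <- config$k
  if (!is.null(config$k_grid)) {
    sel <- select_k(prof, config$k_grid, config$n_restarts, seed_cl)
    k <- sel$k
    wss_curve <- sel$wss
  }
  assignment <- kmeans_cluster(prof, k, config$n_restarts, seed_cl)
  templates <- config$templates
  if (is.null(templates) && !is.null(config$simulate)) {
    templates <- cluster_templates(config$simulate)
  }
  if (is.null(templates)) stop("templates required to merge clusters")
  assignment <- merge_clusters(assignment, templates,
                               explicit_map = config$explicit_map)
  report$clustering <- list(k = k, n_genes = length(assignment$minor),
                            major_sizes = as.list(table(assignment$major)))

  ## stage 3: differential expression
  de <- differential_expression(fx$counts, fx$samples, config$de_stage,
                                genes = genes_kept, alpha = config$alpha)
  report$de <- list(stage = config$de_stage,
                    labels = as.list(table(de$label)))

  ## stage 4: CRE catalog
  promoters <- define_promoters(fx$annotation, config$promoter_half_width)
  canonical <- intersect(c("PU.1", "CEBPA", "CEBPE", "MYC", "E2F1"),
                         names(fx$peaksets))
  enhancers <- call_enhancers(fx$peaksets[canonical], fx$open_chromatin,
                              fx$prior_enhancers, fx$annotation,
                              width = config$enhancer_width,
                              distal_bp = config$distal_bp)
  report$catalog <- list(n_promoters = nrow(promoters),
                         n_enhancers = nrow(enhancers))

  ## stage 5: binding
  de_genes <- de$gene_id[de$label != "Neutral"]
  bm <- binding_matrix(promoters, tracks = fx$tracks,
                       peaksets = fx$peaksets, de_genes = de_genes)
  cebpe_prom <- promoter_tf_peaks(promoters, fx$peaksets$CEBPE)
  motif <- fx$motif %||% (if (!is.null(config$simulate))
    config$simulate$motif else default_cebp_motif())
  mscores <- stats::setNames(vapply(seq_len(nrow(cebpe_prom)), function(i) {
    motif_score(fx$genome, cebpe_prom$chrom[i], cebpe_prom$start[i],
                cebpe_prom$end[i], motif)
  }, numeric(1)), cebpe_prom$gene_id)
  dprof <- distance_class_profile(cebpe_prom, fx$peaksets$E2F1, mscores,
                                  edges = config$distance_edges,
                                  seed = substream(config$seed, "boot"))
  enh_sig <- enhancer_signal_by_gene(fx$tracks$CEBPE, enhancers,
                                     gene_ids = de_genes)
  prom_sig <- bm$signal[, "CEBPE"]
  majors <- assignment$major
  grp <- function(sig) {
    ids <- intersect(names(sig)[is.finite(sig)], de_genes)
    split(sig[ids], majors[ids])
  }
  comparisons <- compare_binding(
    groups = list(promoter = grp(prom_sig), enhancer = grp(enh_sig)),
    background = list(promoter = prom_sig[intersect(names(prom_sig),
                                                    de_genes)],
                      enhancer = enh_sig[is.finite(enh_sig)]))
  report$binding <- list(
    n_cebpe_bound_promoters = nrow(cebpe_prom),
    distance_classes = stats::setNames(as.list(dprof$summary$n),
                                       dprof$summary$class),
    n_comparisons = nrow(comparisons))

  ## stage 6: promoter classes
  lin54 <- if (config$lin54_evidence == "overlap") {
    stats::setNames(bm$binary[, "LIN54"], rownames(bm$binary))
  } else {
    stats::setNames(vapply(seq_len(nrow(promoters)), function(i) {
      motif_score(fx$genome, promoters$chrom[i], promoters$start[i],
                  promoters$end[i], motif)
    }, numeric(1)), promoters$gene_id)
  }
  bits <- assign_promoter_bits(
    genes = rownames(bm$binary),
    cebpe = stats::setNames(bm$binary[, "CEBPE"], rownames(bm$binary)),
    e2f1 = stats::setNames(bm$binary[, "E2F1"], rownames(bm$binary)),
    nfyb = stats::setNames(bm$binary[, "NFYB"], rownames(bm$binary)),
    lin54 = lin54, lin54_evidence = config$lin54_evidence)
  class_table <- promoter_class_table(bits)
  freq <- class_frequency_by_cluster(class_table, majors,
                                     focal = config$focal_cluster,
                                     min_subclass_n = config$min_subclass_n)
  b_genes <- names(majors)[majors == config$focal_cluster]
  response <- class_expression_response(
    class_table[class_table$gene_id %in% b_genes, , drop = FALSE], de,
    seed = substream(config$seed, "boot"))
  report$classes <- list(
    frequencies = freq$frequencies,
    enrichment_p = if (!is.null(freq$enrichment)) freq$enrichment$p)

  ## stage 7: TF importance (clusters A and B)
  importance <- list()
  for (cl in c("A", "B")) {
    cl_genes <- names(majors)[majors == cl]
    ft <- build_feature_table(bm$binary, de, cl_genes)
    importance[[cl]] <- tryCatch(rank_tf_importance(ft),
                                 error = function(e) {
                                   message("importance for cluster ", cl,
                                           " skipped: ",
                                           conditionMessage(e))
                                   NULL
                                 })
  }
  report$importance <- lapply(importance, function(r) {
    if (is.null(r)) NULL else stats::setNames(as.list(r$rank), r$tf)
  })

  result <- structure(list(
    config = config, fixture = fx, filtered_genes = genes_kept,
    assignment = assignment, wss_curve = wss_curve, de = de,
    promoters = promoters, enhancers = enhancers, binding = bm,
    cebpe_promoter_peaks = cebpe_prom, motif_scores = mscores,
    distance_profile = dprof, comparisons = comparisons,
    class_table = class_table, class_frequencies = freq,
    class_response = response, importance = importance,
    report = report), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  genes kept:", length(x$filtered_genes), "\n")
  cat("  clusters (major):",
      paste(names(table(x$assignment$major)),
            table(x$assignment$major), sep = "=", collapse = " "), "\n")
  cat("  DE labels:", paste(names(table(x$de$label)), table(x$de$label),
                            sep = "=", collapse = " "), "\n")
  cat("  enhancers:", nrow(x$enhancers), "\n")
  en <- x$class_frequencies$enrichment
  if (!is.null(en)) {
    cat("  CENL enrichment in", en$focal, ": p =",
        format(en$p, digits = 3), "\n")
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  cl <- data.frame(gene_id = names(result$assignment$minor),
                   minor = unname(result$assignment$minor),
                   major = unname(result$assignment$major),
                   stringsAsFactors = FALSE)
  write_tsv(cl, p("clusters.tsv"))
  if (!is.null(result$wss_curve)) write_tsv(result$wss_curve,
                                            p("wss_curve.tsv"))
  write_tsv(as.data.frame(result$de),
            p(paste0("de_", attr(result$de, "stage"), ".tsv")))
  prom <- result$promoters
  write_bed(peak_set(data.frame(chrom = prom$chrom, start = prom$start,
                                end = prom$end)), p("promoters.bed"))
  enh <- result$enhancers
  enh_lines <- paste(enh$chrom, fmt_int(enh$start), fmt_int(enh$end),
                     enh$gene_id, fmt_num(enh$distance), ".", sep = "\t")
  writeLines(enh_lines, p("enhancers.bed"))
  jsonlite::write_json(result$report$catalog, p("catalog_stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sig <- as.data.frame(result$binding$signal)
  sig <- data.frame(gene_id = rownames(sig), sig, check.names = FALSE)
  write_tsv(sig, p("binding_matrix.tsv"))
  bin <- as.data.frame(result$binding$binary)
  bin <- data.frame(gene_id = rownames(bin), bin, check.names = FALSE)
  write_tsv(bin, p("binary_matrix.tsv"))
  write_tsv(result$distance_profile$summary, p("distance_profile.tsv"))
  write_tsv(result$comparisons, p("binding_comparisons.tsv"))
  write_tsv(result$class_table, p("promoter_classes.tsv"))
  write_tsv(result$class_frequencies$frequencies,
            p("class_frequencies.tsv"))
  write_tsv(result$class_response$summary, p("class_response.tsv"))
  for (cl_name in names(result$importance)) {
    r <- result$importance[[cl_name]]
    if (!is.null(r)) {
      write_tsv(as.data.frame(r),
                p(paste0("importance_", cl_name, ".tsv")))
    }
  }
  report <- result$report
  report$row_counts <- list(
    clusters = nrow(cl), de = nrow(result$de),
    enhancers = nrow(result$enhancers),
    promoter_classes = nrow(result$class_table))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(out_dir)
}
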