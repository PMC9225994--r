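# Signal summarization, binarization, overlaps, motif scoring, distances.

test_that("region signal is the length-weighted mean of overlapped bins", {
  tr <- flat_track(len = 1000, bin = 100, value = 2)
  expect_equal(region_signal(tr, "chr1", 150, 450), 2)
  tr2 <- signal_track(list(chr1 = c(1, 3, rep(0, 8))), 100)
  expect_equal(region_signal(tr2, "chr1", 50, 150), 2)  # equal halves of 1, 3
  expect_equal(region_signal(tr2, "chr1", 0, 100), 1)
  expect_error(region_signal(tr2, "chr1", 100, 100), "length")
  expect_error(region_signal(tr2, "chr1", 900, 1100), "off chromosome")
})

test_that("median binarization uses a strict cut over the DE reference", {
  sig <- stats::setNames(c(1, 2, 3, 4, 9), paste0("g", 1:5))
  b <- binarize_binding(sig, paste0("g", 1:4))
  expect_equal(b$threshold, 2.5)
  expect_equal(names(which(b$bound)), c("g3", "g4", "g5"))

  ties <- stats::setNames(rep(3, 4), paste0("g", 1:4))
  b2 <- binarize_binding(ties, names(ties))
  expect_false(any(b2$bound))  # "above" is strict
  expect_error(binarize_binding(sig, character(0)), "empty")

  set.seed(41)
  for (i in 1:20) {
    s <- stats::setNames(stats::rnorm(101)^2, paste0("g", 1:101))
    de <- sample(names(s), 51)
    expect_lte(mean(binarize_binding(s, de)$bound[de]), 0.5)
  }
})

test_that("overlap predicates use half-open interval arithmetic", {
  prom <- data.frame(chrom = "chr1", start = 4000, end = 6000)
  expect_equal(overlap_binary(prom, make_peaks(5900, 6100)), 1L)
  expect_equal(overlap_binary(prom, make_peaks(6000, 6200)), 0L)  # abutting
  expect_warning(z <- overlap_binary(prom, make_peaks(numeric(0),
                                                      numeric(0))),
                 "empty")
  expect_equal(z, 0L)

  set.seed(42)
  ref <- cbind(start = sample(0:9500, 60), width = sample(50:400, 60,
                                                          replace = TRUE))
  refp <- make_peaks(ref[, 1], ref[, 1] + ref[, 2])
  qs <- sample(0:9800, 500, replace = TRUE)
  q <- data.frame(chrom = "chr1", start = qs, end = qs + 150)
  got <- overlap_binary(q, refp)
  want <- vapply(seq_len(500), function(i) {
    as.integer(oracle_overlap(c(qs[i], qs[i] + 150),
                              cbind(refp$start, refp$end)))
  }, integer(1))
  expect_identical(got, want)
})

test_that("overlap fraction counts source peaks with any hit", {
  a <- make_peaks(c(0, 1000, 2000, 3000, 4000),
                  c(100, 1100, 2100, 3100, 4100))
  b <- make_peaks(c(50, 1050, 2050, 3050), c(80, 1080, 2080, 3080))
  expect_equal(overlap_fraction(a, b), 0.8)
  expect_equal(overlap_fraction(a, a), 1)
  expect_equal(overlap_fraction(a, make_peaks(9000, 9100)), 0)
  expect_error(overlap_fraction(make_peaks(numeric(0), numeric(0)), a),
               "empty")
})

test_that("motif score is the floored two-strand max log-odds", {
  ppm <- matrix(0.01, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  ppm["A", 1] <- 0.97; ppm["C", 2] <- 0.97
  ppm["G", 3] <- 0.97; ppm["T", 4] <- 0.97
  m <- motif_model(ppm, "test")
  genome <- c(chr1 = "TTTTTACGTTTTTT")
  expect_equal(motif_score(genome, "chr1", 0, 14, m),
               4 * log2(0.97 / 0.25), tolerance = 1e-10)
  # reverse complement of ACGT is ACGT; check an asymmetric motif instead
  ppm2 <- ppm; ppm2["A", 4] <- 0.97; ppm2["T", 4] <- 0.01
  m2 <- motif_model(sweep(ppm2, 2, colSums(ppm2), "/"), "asym")
  fwd <- c(chr1 = "GGGGACGAGGGG")
  rev <- c(chr1 = "CCCCTCGTCCCC")  # reverse complement
  expect_equal(motif_score(fwd, "chr1", 0, 12, m2),
               motif_score(rev, "chr1", 0, 12, m2))
  # no window better than background scores exactly 0
  bad <- c(chr1 = "TTTTTTTTTTTT")
  expect_equal(motif_score(bad, "chr1", 0, 12, m2), 0)
  # N-containing windows are excluded, not scored
  withn <- c(chr1 = "NNACGNNNNN")
  expect_equal(motif_score(withn, "chr1", 0, 10, m), 0)
  expect_error(motif_score(genome, "chr1", 0, 3, m), "shorter")
})

test_that("motif score matches the exhaustive window-scan oracle", {
  set.seed(43)
  m <- default_cebp_motif()
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    if (i %% 5 == 0) {
      s <- sub("^(.{20})(.{10})", "\\1ATTGCGCAAT", s)  # plant consensus
    }
    genome <- c(chr1 = s)
    expect_equal(motif_score(genome, "chr1", 0, 60, m),
                 oracle_motif_score(s, m$ppm), tolerance = 1e-10)
  }
})

test_that("distance to closest reference follows half-open gap rules", {
  q <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(distance_to_closest(q, make_peaks(150, 250)), 0)
  expect_equal(distance_to_closest(q, make_peaks(300, 400)), 100)
  expect_equal(distance_to_closest(q, make_peaks(200, 250)), 0)  # abutting
  expect_error(distance_to_closest(q, make_peaks(numeric(0), numeric(0))),
               "empty")
  # cross-chromosome pairs are excluded
  q2 <- data.frame(chrom = "chr9", start = 1, end = 5)
  expect_true(is.na(distance_to_closest(q2, make_peaks(1, 5))))

  set.seed(44)
  rs <- sample(0:50000, 80)
  ref <- make_peaks(rs, rs + sample(50:300, 80, replace = TRUE))
  qsta <- sample(0:50000, 300, replace = TRUE)
  qd <- data.frame(chrom = "chr1", start = qsta, end = qsta + 120)
  got <- distance_to_closest(qd, ref)
  for (i in seq_len(300)) {
    expect_equal(got[i], oracle_distance(c(qsta[i], qsta[i] + 120),
                                         cbind(ref$start, ref$end)))
  }
})

test_that("distance-class profile plants its classes and summaries", {
  peaks <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                      start = c(100, 300, 500, 700) * 10,
                      end = c(100, 300, 500, 700) * 10 + 400)
  e2f1 <- make_peaks(peaks$start + 100, peaks$start + 300, tf = "E2F1")
  sc <- stats::setNames(c(0, 1, 2, 3), peaks$gene_id)
  pr <- distance_class_profile(peaks, e2f1, sc, seed = 1)
  expect_true(all(pr$table$class == "0"))
  expect_equal(pr$summary$n, 4)

  empty <- distance_class_profile(peaks[0, ], e2f1, sc, seed = 1)
  expect_equal(nrow(empty$table), 0)

  fx <- small_fixture()
  cp <- fx$cebpe_promoter_peaks
  m <- fx$config$motif
  sc2 <- stats::setNames(vapply(seq_len(nrow(cp)), function(i) {
    motif_score(fx$genome, cp$chrom[i], cp$start[i], cp$end[i], m)
  }, numeric(1)), cp$gene_id)
  pr2 <- suppressMessages(
    distance_class_profile(cp, fx$peaksets$E2F1, sc2, seed = 1))
  med <- pr2$summary$median_motif_score[pr2$summary$class %in%
                                          c("0", "(0,1500]", "(1500,6000]")]
  expect_true(all(diff(med) >= 0))  # planted anti-correlation recovered
})

test_that("binding comparisons are one-sided with BH across groups", {
  set.seed(45)
  bg <- stats::rlnorm(400)
  up <- stats::rlnorm(200) * 2
  null_g <- sample(bg, 200)
  res <- compare_binding(
    groups = list(promoter = list(hot = up, cold = null_g)),
    background = list(promoter = bg))
  expect_lt(res$padj[res$cluster == "hot"], 0.01)
  expect_gt(res$padj[res$cluster == "cold"], 0.05)

  single <- compare_binding(groups = list(promoter = list(hot = up)),
                            background = list(promoter = bg))
  expect_equal(single$p, single$padj)

  expect_message(
    tiny <- compare_binding(groups = list(promoter = list(few = c(1, 2))),
                            background = list(promoter = bg)),
    "excluding")
  expect_equal(nrow(tiny), 0)

  # identical distribution -> p roughly uniform over resamples
  meds <- vapply(1:200, function(i) {
    g <- sample(bg, 150)
    compare_binding(list(promoter = list(x = g)),
                    list(promoter = bg))$p
  }, numeric(1))
  expect_gt(stats::median(meds), 0.3)
  expect_lt(stats::median(meds), 0.7)
})

test_that("binding matrix layers honor per-TF evidence", {
  fx <- noisefree_fixture()
  prom <- define_promoters(fx$annotation)
  de_genes <- fx$truth$gene_id[fx$truth$de_status != "Neutral"]
  bm <- binding_matrix(prom, tracks = fx$tracks, peaksets = fx$peaksets,
                       de_genes = de_genes)
  expect_setequal(colnames(bm$binary),
                  union(names(fx$tracks), names(fx$peaksets)))
  expect_equal(unname(bm$evidence["CEBPE"]), "median")
  expect_equal(unname(bm$evidence["E2F1"]), "overlap")
  # noise-free: median binarization marks exactly the planted bound set
  for (tf in c("PU.1", "CEBPA", "CEBPE")) {
    planted <- fx$truth[[paste0("bit_", tf)]] == 1
    names(planted) <- fx$truth$gene_id
    # enhancer peaks are distal; restrict the claim to promoter bits
    expect_equal(unname(bm$binary[fx$truth$gene_id, tf]),
                 unname(as.integer(planted[fx$truth$gene_id])))
  }
})
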