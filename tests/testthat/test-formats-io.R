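# I/O layer: parsing, validation, canonical round trips.

test_that("read_bed parses BED3/BED6 with half-open coordinates", {
  f <- withr::local_tempfile(lines = c("chr1\t100\t200",
                                       "chr1\t50\t80"))
  ps <- read_bed(f)
  expect_s3_class(ps, "peak_set")
  expect_equal(ps$start, c(50, 100))  # sorted
  expect_equal(ps$end, c(80, 200))
  expect_equal(ps$strand, c(".", "."))

  f6 <- withr::local_tempfile(
    lines = "chr2\t10\t40\tname\t3.5\t-")
  ps6 <- read_bed(f6)
  expect_equal(ps6$score, 3.5)
  expect_equal(ps6$strand, "-")
})

test_that("read_bed rejects malformed and invalid lines by number", {
  bad_end <- withr::local_tempfile(lines = "chr1\t200\t100")
  expect_error(read_bed(bad_end), "end <= start")
  short <- withr::local_tempfile(lines = c("chr1\t1\t2", "chr1\t5"))
  expect_error(read_bed(short), "line 2")
  nonnum <- withr::local_tempfile(lines = "chr1\tx\t100")
  expect_error(read_bed(nonnum), "line 1")
})

test_that("BED write/read is a fixed point and canonicalizes input", {
  f <- withr::local_tempfile(lines = c("chr2\t5\t10\t.\t1.25\t+",
                                       "chr1\t100\t200\t.\t2\t-",
                                       "chr1\t1\t4\t.\t0.5\t."))
  ps <- read_bed(f)
  out <- withr::local_tempfile()
  write_bed(ps, out)
  ps2 <- read_bed(out)
  expect_identical(as.data.frame(ps), as.data.frame(ps2))
  out2 <- withr::local_tempfile()
  write_bed(ps2, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("gene table round trip enforces annotation invariants", {
  ann <- toy_annotation()
  f <- withr::local_tempfile()
  write_gene_table(ann, f)
  back <- read_gene_table(f)
  expect_identical(back$genes, ann$genes)
  expect_equal(back$chromosomes, ann$chromosomes)

  dup <- c("# chrom_sizes: chr1:10000",
           "gene_id\tchrom\tstrand\ttss",
           "g1\tchr1\t+\t1000", "g1\tchr1\t-\t5000")
  fd <- withr::local_tempfile(lines = dup)
  expect_error(read_gene_table(fd), "g1")

  oob <- c("# chrom_sizes: chr1:10000",
           "gene_id\tchrom\tstrand\ttss",
           "g1\tchr1\t+\t10001")
  fo <- withr::local_tempfile(lines = oob)
  expect_error(read_gene_table(fo), "bounds")
})

test_that("count matrix reader validates cells and the sample sheet", {
  cts <- c("gene_id\ts1\ts2\ts3\ts4",
           "g1\t0\t1\t2\t0", "g2\t5\t5\t5\t5", "g3\t1\t0\t0\t0")
  sheet <- c("sample_id\tstage\tgenotype\treplicate",
             "s1\tMY\tWT\t1", "s2\tMY\tWT\t2",
             "s3\tMY\tKO\t1", "s4\tMY\tKO\t2")
  fc <- withr::local_tempfile(lines = cts)
  fs <- withr::local_tempfile(lines = sheet)
  pair <- read_counts(fc, fs)
  expect_identical(dim(pair$counts), c(3L, 4L))
  expect_identical(colnames(pair$counts), pair$samples$sample_id)

  fs2 <- withr::local_tempfile(lines = sheet[1:4])
  expect_error(read_counts(fc, fs2), "mismatch.*s4")

  neg <- sub("g1\t0", "g1\t-1", cts)
  fneg <- withr::local_tempfile(lines = neg)
  expect_error(read_counts(fneg, fs), "negative")

  frac <- sub("g1\t0", "g1\t0.5", cts)
  ffrac <- withr::local_tempfile(lines = frac)
  expect_error(read_counts(ffrac, fs), "non-integer")
})

test_that("FASTA reading upper-cases and polices the alphabet", {
  f <- withr::local_tempfile(lines = c(">chr1", "acgt", ">chr2", "ACGTN"))
  seqs <- read_fasta(f)
  expect_equal(unname(seqs["chr1"]), "ACGT")
  expect_equal(unname(seqs["chr2"]), "ACGTN")

  bad <- withr::local_tempfile(lines = c(">chr1", "ACXT"))
  expect_error(read_fasta(bad), "position 3")

  ann <- toy_annotation()
  extra <- withr::local_tempfile(lines = c(">chrZ", "ACGT"))
  expect_warning(read_fasta(extra, ann), "chrZ")
})

test_that("FASTA write/read round trips", {
  seqs <- c(chr1 = paste(rep("ACGTA", 30), collapse = ""), chr2 = "TTTT")
  f <- withr::local_tempfile()
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
})

test_that("signal reader densifies the grid and validates alignment", {
  ann <- toy_annotation(tss = c(100, 500, 900), len = 1000)
  f <- withr::local_tempfile(lines = c("chr1\t0\t100\t2.0",
                                       "chr1\t300\t500\t1.5"))
  tr <- read_signal(f, 100, ann)
  expect_equal(tr$values$chr1[1], 2.0)
  expect_equal(tr$values$chr1[2:3], c(0, 0))  # uncovered -> 0
  expect_equal(tr$values$chr1[4:5], c(1.5, 1.5))
  expect_length(tr$values$chr1, 10)

  off <- withr::local_tempfile(lines = "chr1\t0\t150\t1.0")
  expect_error(read_signal(off, 100, ann), "grid")
  neg <- withr::local_tempfile(lines = "chr1\t0\t100\t-1")
  expect_error(read_signal(neg, 100, ann), "negative")
})

test_that("signal write/read round trips (zero runs omitted)", {
  ann <- toy_annotation(tss = c(100, 500, 900), len = 1000)
  v <- c(0, 0, 2, 2, 0, 1.25, 0, 0, 0, 3)
  tr <- signal_track(list(chr1 = v), 100, name = "X")
  f <- withr::local_tempfile()
  write_signal(tr, f)
  back <- read_signal(f, 100, ann)
  expect_equal(back$values$chr1, v)
})

test_that("PFM reader builds a normalized motif and round trips", {
  lines <- c(">CEBP", "A [ 10 0 80 ]", "C [ 70 10 10 ]",
             "G [ 10 80 0 ]", "T [ 10 10 10 ]")
  f <- withr::local_tempfile(lines = lines)
  m <- read_pfm(f)
  expect_s3_class(m, "motif_model")
  expect_equal(colSums(m$ppm), rep(1, 3), tolerance = 1e-9)
  expect_equal(ncol(m$ppm), 3)
  f2 <- withr::local_tempfile()
  write_pfm(m, f2)
  m2 <- read_pfm(f2, pseudocount = 0)
  expect_equal(m2$ppm, m$ppm, tolerance = 1e-3)
})

test_that("parsers reject random corruptions without silent acceptance", {
  set.seed(2024)
  ann <- toy_annotation(tss = c(1000, 5000, 9000), len = 10000)
  n_each <- 250
  # BED corruptions
  for (i in seq_len(n_each)) {
    kind <- sample(4, 1)
    line <- switch(kind,
      paste("chr1", 500, sample(0:500, 1), sep = "\t"),        # end <= start
      paste("chr1", "abc", 100, sep = "\t"),                   # non-numeric
      paste("chr1", 10, 20, ".", 1, "x", sep = "\t"),          # bad strand
      paste("chr1", 10, sep = "\t"))                           # short line
    f <- withr::local_tempfile(lines = line)
    expect_error(read_bed(f))
  }
  # gene table corruptions
  for (i in seq_len(n_each)) {
    kind <- sample(3, 1)
    body <- switch(kind,
      c("g1\tchr1\t+\t100", "g1\tchr1\t-\t200"),   # duplicate id
      "g1\tchr1\t+\t99999",                        # out of bounds
      "g1\tchr1\t*\t100")                          # bad strand
    f <- withr::local_tempfile(lines = c("# chrom_sizes: chr1:10000",
                                         "gene_id\tchrom\tstrand\ttss",
                                         body))
    expect_error(read_gene_table(f))
  }
  # count corruptions
  sheet <- withr::local_tempfile(
    lines = c("sample_id\tstage\tgenotype\treplicate",
              "s1\tMY\tWT\t1", "s2\tMY\tKO\t1"))
  for (i in seq_len(n_each)) {
    bad_val <- sample(c("-3", "1.7", "NA", ""), 1)
    f <- withr::local_tempfile(
      lines = c("gene_id\ts1\ts2", paste0("g1\t", bad_val, "\t2")))
    expect_error(read_counts(f, sheet))
  }
  # signal corruptions
  for (i in seq_len(n_each)) {
    kind <- sample(3, 1)
    line <- switch(kind,
      "chr1\t0\t150\t1",          # off grid
      "chr1\t0\t100\t-0.5",       # negative
      "chrZ\t0\t100\t1")          # unknown chromosome
    f <- withr::local_tempfile(lines = line)
    expect_error(read_signal(f, 100, ann))
  }
})
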