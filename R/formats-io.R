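## Containers and on-disk formats.
##
## All coordinates are BED-convention: 0-based, half-open [start, end).
## A gene's TSS is a single 0-based position (for "-" genes, the rightmost
## transcript base as supplied in the gene table). One convention everywhere
## avoids off-by-one drift between the interval and sequence layers.

#' Construct a genome annotation
#'
#' The coordinate backbone of the pipeline: chromosome lengths plus a gene
#' table with strand-resolved transcription start sites (TSS, 0-based).
#'
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param genes `data.frame` with columns `gene_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`), `tss` (0-based position).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, genes) {
  stopifnot(is.numeric(chromosomes), !is.null(names(chromosomes)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  req <- c("gene_id", "chrom", "strand", "tss")
  if (!all(req %in% names(genes))) {
    stop("gene table must have columns: ", paste(req, collapse = ", "))
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup)) {
    stop("duplicate gene_id(s): ", paste(dup, collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  missing_chrom <- setdiff(genes$chrom, names(chromosomes))
  if (length(missing_chrom)) {
    stop("gene chrom(s) absent from chromosome table: ",
         paste(missing_chrom, collapse = ", "))
  }
  bad <- genes$tss < 0 | genes$tss >= chromosomes[genes$chrom]
  if (any(bad)) {
    stop("tss outside chromosome bounds for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "))
  }
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", length(x$chromosomes), " chromosome(s), ",
      nrow(x$genes), " gene(s)\n", sep = "")
  invisible(x)
}

#' Construct a peak set
#'
#' Sorted genomic intervals for one TF in one cell population, with an
#' optional nonnegative per-interval signal value.
#'
#' @param intervals `data.frame` with columns `chrom`, `start`, `end` and
#'   optionally `strand` and `score`.
#' @param tf TF (or mark) name.
#' @param population Cell-population label.
#' @return Object of class `peak_set` (a sorted `data.frame`).
#' @export
peak_set <- function(intervals, tf = NA_character_, population = NA_character_) {
  df <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(df))) {
    stop("intervals need columns chrom, start, end")
  }
  if (is.null(df$strand)) df$strand <- rep(".", nrow(df))
  if (is.null(df$score)) df$score <- rep(NA_real_, nrow(df))
  df <- df[, c("chrom", "start", "end", "strand", "score")]
  df$chrom <- as.character(df$chrom)
  validate_intervals(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, tf = tf, population = population,
            class = c("peak_set", "data.frame"))
}

validate_intervals <- function(df, where = "interval") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop(where, ": missing coordinates")
  }
  if (any(df$start < 0)) stop(where, ": start must be >= 0")
  if (any(df$end <= df$start)) {
    i <- which(df$end <= df$start)[1]
    stop(where, " ", i, ": end (", df$end[i], ") must be > start (",
         df$start[i], ")")
  }
  if (any(!nzchar(df$chrom))) stop(where, ": empty chrom name")
  invisible(df)
}

#' @export
print.peak_set <- function(x, ...) {
  cat("<peak_set> tf=", attr(x, "tf"), " population=", attr(x, "population"),
      " n=", nrow(x), "\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

## 1-based closed GRanges view of half-open intervals (shared namespace only;
## no seqlengths enforced so peak sets can be compared before an annotation
## exists).
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Construct a binned signal track
#'
#' @param values Named list (one element per chromosome) of nonnegative,
#'   finite per-bin values.
#' @param bin_size Bin width in bp.
#' @param name TF or mark name.
#' @param population Cell-population label.
#' @export
signal_track <- function(values, bin_size, name = NA_character_,
                         population = NA_character_) {
  stopifnot(is.list(values), !is.null(names(values)), bin_size >= 1)
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("signal track ", name, ": values on ", chrom,
           " must be finite and >= 0")
    }
  }
  structure(list(values = values, bin_size = as.integer(bin_size),
                 name = name, population = population),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> ", x$name, " bin_size=", x$bin_size, " chroms=",
      length(x$values), "\n", sep = "")
  invisible(x)
}

# ---- BED ---------------------------------------------------------------

#' Read a BED3/BED6 file into a peak set
#'
#' Tab-separated BED with 3 or 6 columns; coordinates parsed as 0-based
#' half-open; strand taken from column 6 when present, else `"."`; signal
#' from column 5 when present.
#'
#' @param path File path.
#' @inheritParams peak_set
#' @return A sorted [peak_set()].
#' @export
read_bed <- function(path, tf = NA_character_, population = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(peak_set(data.frame(chrom = character(), start = integer(),
                               end = integer()), tf, population))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 3L & nf < 6L)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1], ": expected 3 or >= 6 fields, got ",
         nf[bad[1]])
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    stop("BED parse error at line ", i, ": non-numeric coordinate")
  }
  score <- rep(NA_real_, length(lines))
  strand <- rep(".", length(lines))
  six <- nf >= 6L
  if (any(six)) {
    score[six] <- suppressWarnings(
      as.numeric(vapply(fields[six], `[[`, "", 5L)))
    strand[six] <- vapply(fields[six], `[[`, "", 6L)
    if (!all(strand %in% c("+", "-", "."))) {
      i <- which(!strand %in% c("+", "-", "."))[1]
      stop("BED parse error at line ", i, ": bad strand '", strand[i], "'")
    }
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   strand = strand, score = score, stringsAsFactors = FALSE)
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop("BED validation error at line ", bad[1], ": end <= start")
  }
  if (any(df$start < 0)) {
    stop("BED validation error at line ", which(df$start < 0)[1],
         ": negative start")
  }
  peak_set(df, tf, population)
}

#' Write a peak set as canonical BED
#'
#' Sorted, tab-separated. BED3 when no interval carries a score or strand;
#' otherwise BED6 with `.` names and `0` for missing scores. Floats use 6
#' significant digits. `read_bed()` of the output reproduces the peak set.
#'
#' @param x A [peak_set()].
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "peak_set"))
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  bed6 <- any(!is.na(x$score)) || any(x$strand != ".")
  if (bed6) {
    score <- ifelse(is.na(x$score), "0", fmt_num(x$score))
    lines <- paste(x$chrom, fmt_int(x$start), fmt_int(x$end), ".",
                   score, x$strand, sep = "\t")
  } else {
    lines <- paste(x$chrom, fmt_int(x$start), fmt_int(x$end), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

# 6 significant digits, no scientific notation
fmt_num <- function(x) {
  out <- formatC(signif(x, 6), format = "fg", flag = "#", digits = 6)
  sub("\\.$", "", trimws(out))
}

# ---- gene table --------------------------------------------------------

#' Read a gene annotation table
#'
#' Tab-separated file with a `# chrom_sizes: name:length,...` header line (or
#' a companion `chrom_path` two-column file) followed by a header
#' `gene_id  chrom  strand  tss` and one row per gene.
#'
#' @param path Gene table path.
#' @param chrom_path Optional two-column (name, length) chromosome-sizes file;
#'   overrides the in-file header.
#' @return A [genome_annotation()].
#' @export
read_gene_table <- function(path, chrom_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  chromosomes <- NULL
  if (!is.null(chrom_path)) {
    cs <- utils::read.table(chrom_path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "length"),
                            stringsAsFactors = FALSE)
    chromosomes <- stats::setNames(as.numeric(cs$length), cs$chrom)
  } else if (length(lines) && startsWith(lines[1], "# chrom_sizes:")) {
    spec <- sub("^# chrom_sizes:\\s*", "", lines[1])
    parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    chromosomes <- stats::setNames(
      as.numeric(vapply(parts, `[[`, "", 2L)),
      vapply(parts, `[[`, "", 1L))
  } else {
    stop("gene table needs a '# chrom_sizes:' header or a chrom_path file")
  }
  body <- lines[!startsWith(lines, "#")]
  con <- textConnection(body)
  on.exit(close(con))
  genes <- utils::read.table(con, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c("character", "character",
                                            "character", "numeric"))
  genome_annotation(chromosomes, genes)
}

#' Write a gene annotation table (round-trips with [read_gene_table()])
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @export
write_gene_table <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  header <- paste0("# chrom_sizes: ",
                   paste(names(annotation$chromosomes),
                         fmt_int(annotation$chromosomes),
                         sep = ":", collapse = ","))
  g <- annotation$genes
  lines <- c(header,
             "gene_id\tchrom\tstrand\ttss",
             paste(g$gene_id, g$chrom, g$strand, fmt_int(g$tss), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# ---- counts + sample sheet ---------------------------------------------

#' Read a count matrix and its sample sheet
#'
#' Counts: tab-separated with a header of sample ids and a leading `gene_id`
#' column. Sample sheet: tab-separated with columns `sample_id`, `stage`,
#' `genotype` (`WT`/`KO`), `replicate`. Sample ids must match the count
#' columns exactly; counts must be nonnegative integers.
#'
#' @param path_counts,path_samples File paths.
#' @return `list(counts = <integer matrix>, samples = <data.frame>)`.
#' @export
read_counts <- function(path_counts, path_samples) {
  cts <- utils::read.table(path_counts, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(cts)[1] != "gene_id") stop("counts: first column must be gene_id")
  gene_ids <- as.character(cts$gene_id)
  if (anyDuplicated(gene_ids)) stop("counts: duplicate gene ids")
  m <- as.matrix(cts[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("counts: duplicate sample ids")
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("counts: missing cells")
  if (any(m < 0)) stop("counts: negative count")
  if (any(m != floor(m))) stop("counts: non-integer count")
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  samples <- utils::read.table(path_samples, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  validate_count_pair(m, samples)
  list(counts = m, samples = samples)
}

validate_count_pair <- function(counts, samples) {
  req <- c("sample_id", "stage", "genotype", "replicate")
  if (!all(req %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(samples$genotype %in% c("WT", "KO"))) {
    stop("sample sheet genotype must be WT or KO")
  }
  miss <- setdiff(colnames(counts), samples$sample_id)
  extra <- setdiff(samples$sample_id, colnames(counts))
  if (length(miss) || length(extra)) {
    stop("sample sheet / count matrix mismatch; missing from sheet: [",
         paste(miss, collapse = ", "), "]; missing from matrix: [",
         paste(extra, collapse = ", "), "]")
  }
  invisible(TRUE)
}

#' Write a count matrix and sample sheet (round-trips with [read_counts()])
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param samples Sample sheet `data.frame`.
#' @param path_counts,path_samples Output paths.
#' @export
write_counts <- function(counts, samples, path_counts, path_samples) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path_counts, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(samples, path_samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path_counts)
}

# ---- FASTA -------------------------------------------------------------

#' Read a genome FASTA
#'
#' Sequences are upper-cased and must use the alphabet `{A,C,G,T,N}` only.
#' Records absent from `annotation` raise a warning (they are kept).
#'
#' @param path FASTA path.
#' @param annotation Optional [genome_annotation()] to check record names
#'   against.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("FASTA parse error: ",
                                           conditionMessage(e)))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  for (nm in names(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[nm]])
    if (bad > 0) {
      stop("FASTA record ", nm, ": non-{A,C,G,T,N} character '",
           substr(seqs[[nm]], bad, bad), "' at position ", bad)
    }
  }
  if (!is.null(annotation)) {
    extra <- setdiff(names(seqs), names(annotation$chromosomes))
    if (length(extra)) {
      warning("FASTA record(s) absent from annotation: ",
              paste(extra, collapse = ", "))
    }
  }
  seqs
}

#' Write sequences as FASTA (60-column wrapped)
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path, width = 60L)
  invisible(path)
}

# ---- signal (bedGraph-style) -------------------------------------------

#' Read a binned signal track from bedGraph-style text
#'
#' Four tab-separated columns (chrom, start, end, value); every interval must
#' be aligned to the `bin_size` grid; uncovered bins are 0; values must be
#' nonnegative. The track is densified to one value per bin over each
#' chromosome of `annotation`.
#'
#' @param path File path.
#' @param bin_size Bin width (bp).
#' @param annotation A [genome_annotation()] supplying chromosome lengths.
#' @param name,population Track labels.
#' @return A [signal_track()].
#' @export
read_signal <- function(path, bin_size, annotation, name = NA_character_,
                        population = NA_character_) {
  stopifnot(inherits(annotation, "genome_annotation"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  values <- lapply(annotation$chromosomes, function(len) {
    numeric(ceiling(len / bin_size))
  })
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) != 4L)) {
      stop("signal parse error at line ", which(lengths(fields) != 4L)[1],
           ": expected 4 fields")
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.numeric(vapply(fields, `[[`, "", 2L))
    end <- as.numeric(vapply(fields, `[[`, "", 3L))
    val <- as.numeric(vapply(fields, `[[`, "", 4L))
    if (anyNA(start) || anyNA(end) || anyNA(val)) {
      stop("signal parse error: non-numeric field")
    }
    if (any(start %% bin_size != 0) ||
        any(end %% bin_size != 0 & end != annotation$chromosomes[chrom])) {
      i <- which(start %% bin_size != 0 |
                   (end %% bin_size != 0 & end != annotation$chromosomes[chrom]))[1]
      stop("signal grid error at line ", i, ": interval [", start[i], ",",
           end[i], ") not aligned to bin_size ", bin_size)
    }
    if (any(val < 0)) {
      stop("signal validation error at line ", which(val < 0)[1],
           ": negative value")
    }
    unknown <- setdiff(chrom, names(values))
    if (length(unknown)) {
      stop("signal chrom(s) absent from annotation: ",
           paste(unique(unknown), collapse = ", "))
    }
    for (i in seq_along(chrom)) {
      b0 <- start[i] %/% bin_size + 1L
      b1 <- ceiling(end[i] / bin_size)
      values[[chrom[i]]][b0:b1] <- val[i]
    }
  }
  signal_track(values, bin_size, name, population)
}

#' Write a signal track as bedGraph-style text (zero runs omitted)
#' @param track A [signal_track()].
#' @param path Output path.
#' @export
write_signal <- function(track, path) {
  out <- character(0)
  bs <- track$bin_size
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      out <- c(out, paste(chrom, fmt_int(starts[keep] * bs),
                          fmt_int(ends[keep] * bs), fmt_num(r$values[keep]),
                          sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# ---- motif models ------------------------------------------------------

#' Construct a motif model (position probability matrix)
#'
#' @param ppm 4 x L numeric matrix with rownames `A,C,G,T`; columns must sum
#'   to 1 (within 1e-6) and entries lie in (0, 1].
#' @param name Motif name.
#' @param background Length-4 background probabilities (default uniform).
#' @export
motif_model <- function(ppm, name = "motif", background = rep(0.25, 4)) {
  ppm <- as.matrix(ppm)
  if (nrow(ppm) != 4 || is.null(rownames(ppm)) ||
      !identical(rownames(ppm), c("A", "C", "G", "T"))) {
    stop("ppm must be 4 x L with rownames A,C,G,T")
  }
  if (any(ppm <= 0) || any(ppm > 1)) stop("ppm entries must be in (0, 1]")
  if (any(abs(colSums(ppm) - 1) > 1e-6)) stop("ppm columns must sum to 1")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 probabilities summing to 1")
  }
  background <- stats::setNames(as.numeric(background), c("A", "C", "G", "T"))
  structure(list(name = name, ppm = ppm, background = background),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> ", x$name, " length=", ncol(x$ppm), " consensus=",
      paste(rownames(x$ppm)[apply(x$ppm, 2, which.max)], collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Read a JASPAR-style position frequency matrix
#'
#' Expects a `>name` header followed by four lines
#' `A [ n1 n2 ... ]` (rows A, C, G, T). Counts are converted to
#' probabilities with a pseudocount.
#'
#' @param path PFM text path.
#' @param pseudocount Added to every cell before normalization.
#' @param background Background probabilities for [motif_model()].
#' @export
read_pfm <- function(path, pseudocount = 0.5, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1], ">")) {
    stop("PFM parse error: expected '>name' header")
  }
  name <- sub("^>\\s*", "", lines[1])
  if (length(lines) < 5) stop("PFM parse error: expected 4 base rows")
  rows <- lapply(lines[2:5], function(l) {
    base <- substr(l, 1, 1)
    nums <- gsub("[][]", " ", substr(l, 2, nchar(l)))
    vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    if (anyNA(vals)) stop("PFM parse error in row ", base)
    list(base = base, vals = vals)
  })
  bases <- vapply(rows, `[[`, "", "base")
  if (!setequal(bases, c("A", "C", "G", "T"))) {
    stop("PFM parse error: rows must be A, C, G, T")
  }
  counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
  rownames(counts) <- bases
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  counts <- counts + pseudocount
  motif_model(sweep(counts, 2, colSums(counts), "/"), name = name,
              background = background)
}

#' Write a motif model as a JASPAR-style PFM (probabilities scaled to 100)
#' @param motif A [motif_model()].
#' @param path Output path.
#' @export
write_pfm <- function(motif, path) {
  counts <- round(motif$ppm * 100, 2)
  lines <- c(paste0(">", motif$name),
             vapply(c("A", "C", "G", "T"), function(b) {
               paste0(b, " [ ", paste(fmt_num(counts[b, ]), collapse = " "),
                      " ]")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
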