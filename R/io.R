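## Readers and writers for every external format the pipeline touches.
##
## Coordinate conventions: all genomic intervals are held 0-based half-open
## internally. BED is native; GTF is converted on load (plus strand
## TSS = start - 1, minus strand TSS = end - 1). STRING-style integer
## combined scores (0-1000) are divided by 1000 on load.

# ---------------------------------------------------------------------------
# TimecourseMatrix

#' Construct a time-course expression matrix
#'
#' The central expression container: a genes-by-samples FPKM matrix with a
#' time design. Every sample is identified by a `(time, condition, replicate)`
#' triple; the first time label in `time_levels` is the reference time point
#' against which fold changes are computed.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns; non-negative FPKM.
#' @param time character vector of time labels per column (e.g. `"8h"`, `"2d"`).
#' @param condition character vector of condition labels per column
#'   (e.g. `"ctrl"`, `"kd"`).
#' @param replicate integer vector of replicate indices per column.
#' @param time_levels ordered unique time labels; defaults to order of first
#'   appearance. The first level is the reference time point.
#' @return an object of class `timecourse_matrix` with elements `values`
#'   (the matrix, columns renamed to `t<time>_<condition>_r<rep>`), `samples`
#'   (a data.frame of sample descriptors) and `time_levels`.
#' @export
timecourse_matrix <- function(values, time, condition = "ctrl", replicate = 1L,
                              time_levels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    format_error("values must be a numeric matrix")
  n <- ncol(values)
  time <- as.character(rep_len(time, n))
  condition <- as.character(rep_len(condition, n))
  replicate <- as.integer(rep_len(replicate, n))
  if (is.null(rownames(values)))
    format_error("values must carry gene ids as rownames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    format_error("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    format_error("expression values must be finite and non-negative")
  if (is.null(time_levels)) time_levels <- unique(time)
  if (!all(time %in% time_levels))
    format_error("time label(s) outside time_levels: %s",
                 paste(setdiff(time, time_levels), collapse = ", "))
  samples <- data.frame(time = time, condition = condition, replicate = replicate,
                        stringsAsFactors = FALSE)
  key <- with(samples, paste(time, condition, replicate))
  if (anyDuplicated(key))
    format_error("duplicate sample descriptor(s): %s",
                 paste(unique(key[duplicated(key)]), collapse = "; "))
  samples$sample <- sprintf("t%s_%s_r%d", time, condition, replicate)
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples,
                 time_levels = time_levels),
            class = "timecourse_matrix")
}

#' @export
print.timecourse_matrix <- function(x, ...) {
  cat(sprintf("timecourse_matrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  time points:", paste(x$time_levels, collapse = ", "), "\n")
  cat("  conditions: ", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.timecourse_matrix <- function(x) dim(x$values)

#' Gene identifiers of a time-course matrix
#' @param x a `timecourse_matrix`.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Reference time point of a time-course matrix
#' @param x a `timecourse_matrix`.
#' @return the reference (first) time label.
#' @export
reference_time <- function(x) x$time_levels[[1L]]

SAMPLE_PATTERN <- "^t([0-9]+(?:\\.[0-9]+)?[hd])_([A-Za-z0-9.]+)_r([0-9]+)$"

parse_sample_names <- function(nm, path = "<memory>") {
  m <- regmatches(nm, regexec(SAMPLE_PATTERN, nm))
  bad <- nm[lengths(m) == 0L]
  if (length(bad))
    format_error("%s: column name(s) do not match 't<time><h|d>_<condition>_r<rep>': %s",
                 path, paste(bad, collapse = ", "))
  data.frame(time = vapply(m, `[`, "", 2L),
             condition = vapply(m, `[`, "", 3L),
             replicate = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

## time labels like "18h"/"7d" sorted by unit then numeric value
order_time_levels <- function(labels) {
  num <- as.numeric(sub("[hd]$", "", labels))
  unit <- substring(labels, nchar(labels))
  labels[order(match(unit, c("h", "d")), num)]
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds gene ids and whose
#' remaining column names encode sample descriptors as
#' `t<time><h|d>_<condition>_r<replicate>` (e.g. `t8h_ctrl_r1`). Lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return a [timecourse_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) format_error("no such file: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) format_error("%s: expected gene id column plus >=1 sample", path)
  ids <- as.character(df[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) format_error("%s: duplicate gene id(s): %s", path,
                                paste(dup, collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) format_error("%s: non-numeric expression values", path)
  if (any(!is.finite(vals)) || any(vals < 0))
    format_error("%s: expression values must be finite and non-negative", path)
  rownames(vals) <- ids
  desc <- parse_sample_names(colnames(vals), path)
  timecourse_matrix(vals, desc$time, desc$condition, desc$replicate,
                    time_levels = order_time_levels(unique(desc$time)))
}

#' Write an expression matrix to TSV
#'
#' @param x a [timecourse_matrix()].
#' @param path output path.
#' @return `path`, invisibly. Round-trips with [read_expression()].
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "timecourse_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header_comment(list(format = "expression")), con)
  writeLines(paste(c("gene_id", colnames(x$values)), collapse = "\t"), con)
  body <- cbind(rownames(x$values),
                apply(x$values, 2L, function(v) format(v, digits = 15, trim = TRUE,
                                                       scientific = FALSE)))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PeakSet (BED)

#' Construct a peak set
#'
#' Intervals in 0-based half-open coordinates, sorted within chromosome.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param name,score optional per-peak name and score.
#' @return a `peak_set` data.frame.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = NULL) {
  n <- length(chrom)
  if (is.null(name)) name <- sprintf("peak%d", seq_len(n))
  if (is.null(score)) score <- rep(0, n)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), name = as.character(name),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_set", "data.frame")
  df
}

#' Read a BED peak file
#'
#' BED intervals are 0-based half-open and kept that way internally. At least
#' three columns are required; columns 4 (name) and 5 (score) are used when
#' present. Intervals are sorted within chromosome after load.
#'
#' @param path BED file path.
#' @return a `peak_set` data.frame with columns chrom, start, end, name, score.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) format_error("no such file: %s", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") & nzchar(lines)
  lnum <- which(keep)
  if (!length(lnum)) return(peak_set(character(), numeric(), numeric()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    format_error("%s line %d: BED needs >=3 columns", path, lnum[which(nf < 3L)[1L]])
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad))
    format_error("%s line %d: non-numeric BED coordinates", path, lnum[bad[1L]])
  rev <- which(start >= end)
  if (length(rev))
    format_error("%s line %d: start >= end", path, lnum[rev[1L]])
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  score <- suppressWarnings(ifelse(nf >= 5L,
                                   as.numeric(vapply(fields, function(f) f[min(5L, length(f))], "")),
                                   0))
  score[!is.finite(score)] <- 0
  peak_set(chrom, start, end,
           name = ifelse(is.na(name), sprintf("peak%d", seq_along(chrom)), name),
           score = score)
}

#' Write a peak set as BED6
#' @param peaks a `peak_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t.", peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), peaks$name, peaks$score)
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GeneModelSet (TSS table / GTF)

#' Construct a gene model set
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome names.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss 0-based transcription start sites.
#' @return a `gene_model_set` data.frame.
#' @export
gene_model_set <- function(gene_id, chrom, strand, tss) {
  df <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   strand = as.character(strand), tss = as.numeric(tss),
                   stringsAsFactors = FALSE)
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) format_error("duplicate gene id(s) in gene models: %s",
                                paste(dup, collapse = ", "))
  if (any(!df$strand %in% c("+", "-")))
    format_error("unknown strand value(s): %s",
                 paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  if (any(df$tss < 0)) format_error("TSS positions must be >= 0")
  class(df) <- c("gene_model_set", "data.frame")
  df
}

#' Read gene models (TSS table or GTF)
#'
#' A TSS table is a tab-delimited file with columns `gene_id`, `chrom`,
#' `strand`, `tss` (0-based). A GTF (detected by a `.gtf`/`.gff` extension or
#' `format = "gtf"`) is converted on load: 1-based inclusive coordinates give
#' the 0-based TSS as `start - 1` on the plus strand and `end - 1` on the
#' minus strand; rows of type `gene` are used (falling back to `transcript`;
#' with several transcripts per gene the 5'-most TSS is kept).
#'
#' @param path file path.
#' @param format `"auto"`, `"tsv"` or `"gtf"`.
#' @return a `gene_model_set` data.frame.
#' @export
read_tss <- function(path, format = c("auto", "tsv", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) format_error("no such file: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE)) "gtf" else "tsv"
  if (format == "gtf") return(read_tss_gtf(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss")
  miss <- setdiff(need, names(df))
  if (length(miss)) format_error("%s: missing column(s): %s", path,
                                 paste(miss, collapse = ", "))
  gene_model_set(df$gene_id, df$chrom, df$strand, df$tss)
}

read_tss_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    format_error("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  type <- as.character(gr$type)
  sel <- if (any(type == "gene")) gr[type == "gene"] else gr[type == "transcript"]
  if (!length(sel)) format_error("%s: no 'gene' or 'transcript' rows", path)
  if (is.null(sel$gene_id)) format_error("%s: rows lack gene_id attribute", path)
  strand <- as.character(GenomicRanges::strand(sel))
  if (any(strand == "*")) format_error("%s: unknown strand on gene/transcript row", path)
  tss1 <- ifelse(strand == "+", GenomicRanges::start(sel), GenomicRanges::end(sel))
  df <- data.frame(gene_id = as.character(sel$gene_id),
                   chrom = as.character(GenomicRanges::seqnames(sel)),
                   strand = strand, tss = tss1 - 1, stringsAsFactors = FALSE)
  ## one TSS per gene: keep the 5'-most transcript start
  df <- df[order(df$gene_id, ifelse(df$strand == "+", df$tss, -df$tss)), ]
  df <- df[!duplicated(df$gene_id), ]
  gene_model_set(df$gene_id, df$chrom, df$strand, df$tss)
}

#' Write a TSS table
#' @param models a `gene_model_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header_comment(list(format = "tss", coords = "0-based")), con)
  writeLines("gene_id\tchrom\tstrand\ttss", con)
  writeLines(sprintf("%s\t%s\t%s\t%d", models$gene_id, models$chrom, models$strand,
                     as.integer(models$tss)), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GeneSetCollection (GMT)

#' Read gene sets from a GMT file
#'
#' @param path GMT path: one set per line, `name <TAB> description <TAB>
#'   member1 <TAB> member2 ...`.
#' @return named list of character vectors; descriptions kept in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) format_error("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    format_error("%s line %d: GMT needs name, description and >=1 member",
                 path, short[1L])
  nm <- vapply(fields, `[`, "", 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) format_error("%s: duplicate gene set name(s): %s", path,
                                paste(dup, collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(fields, `[`, "", 2L), nm)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, members) paste(c(nm, d, members), collapse = "\t"),
                  names(sets), description, sets)
  writeLines(unlist(lines, use.names = FALSE), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# EdgeTable (STRING-export style)

#' Read an interaction edge table
#'
#' Tab-delimited with header columns `node_a`, `node_b` and `confidence`
#' (or STRING's `combined_score`). Integer scores above 1 are interpreted as
#' STRING 0-1000 combined scores and divided by 1000. Self-loops are dropped;
#' duplicate undirected edges are collapsed keeping the maximum confidence.
#'
#' @param path file path.
#' @return data.frame with columns node_a, node_b, confidence in \[0, 1\].
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) format_error("no such file: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("node_a", "node_b") %in% names(df)))
    format_error("%s: need columns node_a, node_b", path)
  sc <- if ("confidence" %in% names(df)) df$confidence
        else if ("combined_score" %in% names(df)) df$combined_score
        else format_error("%s: need a confidence or combined_score column", path)
  sc <- as.numeric(sc)
  if (any(!is.finite(sc))) format_error("%s: non-numeric confidence", path)
  if (any(sc > 1)) {
    if (any(sc > 1000) || any(sc < 0))
      format_error("%s: scores must lie in [0,1] or STRING [0,1000]", path)
    sc <- sc / 1000
  }
  if (any(sc < 0 | sc > 1)) format_error("%s: confidence outside [0,1]", path)
  edge_table(df$node_a, df$node_b, sc)
}

edge_table <- function(node_a, node_b, confidence) {
  a <- as.character(node_a); b <- as.character(node_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; confidence <- as.numeric(confidence)[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  df <- data.frame(node_a = lo, node_b = hi, confidence = confidence,
                   stringsAsFactors = FALSE)
  df <- df[order(df$node_a, df$node_b, -df$confidence), , drop = FALSE]
  df <- df[!duplicated(df[c("node_a", "node_b")]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an interaction edge table
#' @param edges data.frame with node_a, node_b, confidence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(tsv_header_comment(list(format = "edges")), con)
  writeLines("node_a\tnode_b\tconfidence", con)
  writeLines(sprintf("%s\t%s\t%s", edges$node_a, edges$node_b,
                     format(edges$confidence, digits = 15, trim = TRUE)), con)
  invisible(path)
}
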