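#' Read a peak file (BED3, BED6 or narrowPeak) into a GRanges
#'
#' Coordinates are converted from BED 0-based half-open to the 1-based
#' closed convention of [GenomicRanges::GRanges] at the boundary. For
#' narrowPeak input, column 9 (\eqn{-\log_{10} q}) is converted to a raw
#' q-value stored in `qvalue`, and column 10 is kept as `summit`, the
#' 0-based offset of the summit from the interval start (`-1` when absent
#' becomes `NA`).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"narrowPeak"`, `"bed"`.
#' @param genome optional `Seqinfo` from [genome_model()]; when given,
#'   intervals are bound-checked against it.
#' @param label condition label stored in `metadata()` (e.g. `"PRbs"`).
#' @return A sorted `GRanges` with metadata columns `name`, `score`,
#'   `qvalue`, `summit` (narrowPeak) or whatever BED columns were present.
#' @export
read_peaks <- function(path, format = c("auto", "narrowPeak", "bed"),
                       genome = NULL, label = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.narrowPeak$", path, ignore.case = TRUE))
      "narrowPeak" else "bed"
  .check_bed_coords(path)
  gr <- rtracklayer::import(path, format = format)
  strand(gr) <- "*"
  if (format == "narrowPeak") {
    mc <- mcols(gr)
    q <- ifelse(mc$qValue < 0, NA_real_, 10^(-mc$qValue))
    summit <- ifelse(mc$peak < 0, NA_integer_, mc$peak)
    mcols(gr) <- DataFrame(name = mc$name, score = mc$score,
                           signal = mc$signalValue, pvalue_nl10 = mc$pValue,
                           qvalue = q, summit = summit)
    bad <- !is.na(summit) & summit >= width(gr)
    .assert(!any(bad), "summit offset outside interval for peak(s): ",
            paste(head(mc$name[bad]), collapse = ", "))
  }
  if (!is.null(genome)) gr <- set_genome(gr, genome, label)
  else {
    if (!is.null(label)) metadata(gr)$label <- label
    gr <- sort(gr)
  }
  gr
}

# Fail with a line number on non-numeric or end <= start records, which
# rtracklayer silently tolerates as zero-width ranges.
.check_bed_coords <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    .assert(length(f) >= 3, "line ", i, ": fewer than 3 columns")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    .assert(!is.na(s) && !is.na(e), "line ", i, ": non-numeric coordinates")
    .assert(e > s, "line ", i, ": end <= start (", f[2], ", ", f[3], ")")
    .assert(s >= 0, "line ", i, ": negative start")
  }
  invisible(TRUE)
}

#' Write a peak GRanges to BED3/BED6/narrowPeak
#'
#' Inverse of [read_peaks()]: 1-based closed coordinates become BED 0-based
#' half-open; `qvalue` becomes \eqn{-\log_{10} q}; `summit` is written as
#' the 0-based offset (or `-1`). Floats are formatted with `%.6g` so that
#' write -> read -> write is byte-stable.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @param format `"bed3"`, `"bed6"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(gr, path, format = c("narrowPeak", "bed6", "bed3")) {
  format <- match.arg(format)
  chrom <- as.character(seqnames(gr))
  s0 <- format(start(gr) - 1L, scientific = FALSE, trim = TRUE)
  e0 <- format(end(gr), scientific = FALSE, trim = TRUE)
  mc <- mcols(gr)
  nm <- if (!is.null(mc$name)) as.character(mc$name) else paste0("peak_", seq_along(gr))
  sc <- if (!is.null(mc$score)) mc$score else 0
  num <- function(x) sprintf("%.6g", x)
  df <- switch(format,
    bed3 = data.frame(chrom, s0, e0),
    bed6 = data.frame(chrom, s0, e0, nm, num(sc), "."),
    narrowPeak = {
      q <- mc$qvalue %||% rep(NA_real_, length(gr))
      qcol <- ifelse(is.na(q), -1, -log10(q))
      summ <- mc$summit %||% rep(NA_integer_, length(gr))
      data.frame(chrom, s0, e0, nm, num(sc), ".",
                 num(mc$signal %||% rep(0, length(gr))),
                 num(mc$pvalue_nl10 %||% rep(-1, length(gr))),
                 num(qcol),
                 ifelse(is.na(summ), -1L, as.integer(summ)))
    })
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read TAD coordinates from a BED3 file
#'
#' TADs must be non-overlapping within each chromosome; a `tad_id` metadata
#' column (`tad_1`, `tad_2`, ... in sorted order) is attached.
#'
#' @inheritParams read_peaks
#' @return A sorted `GRanges` with a `tad_id` column.
#' @export
read_tads <- function(path, genome = NULL) {
  gr <- read_peaks(path, format = "bed", genome = genome, label = "TADs")
  make_tad_set(granges(gr))
}

#' Construct a validated TAD set from a GRanges
#' @param gr TAD intervals.
#' @return sorted `GRanges` with `tad_id`.
#' @export
make_tad_set <- function(gr) {
  gr <- sort(gr)
  ov <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  .assert(length(ov) == 0, "TADs overlap within a chromosome")
  mcols(gr)$tad_id <- paste0("tad_", seq_along(gr))
  metadata(gr)$label <- "TADs"
  gr
}

#' Read a gene model table
#'
#' Expected TSV columns: `gene_id`, `chrom`, `strand` (+/-), `tss`, `tes`
#' (1-based positions), `biotype`. The TSS is the transcription start (for
#' `-` strand genes `tss > tes`).
#'
#' @param path file path.
#' @return A `data.frame` with the columns above.
#' @export
read_gene_model <- function(path) {
  g <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  validate_gene_model(g)
}

#' @rdname read_gene_model
#' @param genes a data.frame to validate.
#' @export
validate_gene_model <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  miss <- setdiff(need, names(genes))
  .assert(length(miss) == 0, "gene model missing column(s): ",
          paste(miss, collapse = ", "))
  .assert(!anyDuplicated(genes$gene_id), "duplicate gene_id in gene model")
  .assert(all(genes$strand %in% c("+", "-")), "strand must be + or -")
  ok <- ifelse(genes$strand == "+", genes$tss <= genes$tes,
               genes$tss >= genes$tes)
  .assert(all(ok), "tss/tes inconsistent with strand")
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  genes
}

#' Read an expression / differential table (gene_id, log2FC, q)
#' @param path TSV with header columns `gene_id`, `log2FC`, `q`.
#' @return data.frame.
#' @export
read_expression <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "log2FC", "q"), names(x))
  .assert(length(miss) == 0, "expression table missing column(s): ",
          paste(miss, collapse = ", "))
  x
}

#' Read a gene list (one id per line)
#' @param path text file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}
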