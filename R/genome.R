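#' Genome model: an ordered map of chromosome names to lengths
#'
#' A minimal stand-in for a reference assembly: chromosome names and sizes,
#' represented as a [GenomeInfoDb::Seqinfo] object. All peak sets, TADs and
#' shuffles are validated against it.
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length (bp).
#' @return A `Seqinfo` object.
#' @examples
#' genome_model(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_model <- function(chrom_sizes) {
  .assert(length(chrom_sizes) > 0, "chrom_sizes must be non-empty")
  .assert(!is.null(names(chrom_sizes)) && all(nzchar(names(chrom_sizes))),
          "chrom_sizes must be named")
  .assert(!anyDuplicated(names(chrom_sizes)), "duplicate chromosome names")
  .assert(all(chrom_sizes > 0), "all chromosome lengths must be > 0")
  Seqinfo(seqnames = names(chrom_sizes), seqlengths = as.integer(chrom_sizes))
}

#' Read/write a genome model as a two-column TSV (chrom, length)
#'
#' The `.fai`-style dialect (5 columns, length in column 2) is also accepted
#' on read.
#'
#' @param path file path.
#' @return `read_genome()` returns a `Seqinfo`; `write_genome()` returns the
#'   path invisibly.
#' @export
read_genome <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", rep(NA, 20))[seq_len(
                      max(utils::count.fields(path, sep = "\t")))],
                    stringsAsFactors = FALSE)
  genome_model(setNames(as.numeric(tab[[2]]), tab[[1]]))
}

#' @rdname read_genome
#' @param genome a `Seqinfo`.
#' @export
write_genome <- function(genome, path) {
  write.table(data.frame(seqnames(genome), seqlengths(genome)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @importFrom GenomeInfoDb seqnames
genome_lengths <- function(genome) {
  setNames(as.numeric(seqlengths(genome)), seqnames(genome))
}

# Attach a genome (Seqinfo) to a GRanges, checking bounds.
set_genome <- function(gr, genome, label = NULL) {
  bad <- !(as.character(seqnames(gr)) %in% seqnames(genome))
  if (any(bad))
    stop("intervals on chromosomes absent from genome: ",
         paste(unique(as.character(seqnames(gr))[bad]), collapse = ", "))
  gl <- genome_lengths(genome)
  over <- end(gr) > gl[as.character(seqnames(gr))]
  .assert(!any(over), "intervals extend beyond chromosome bounds")
  seqlevels(gr) <- seqnames(genome)
  seqinfo(gr) <- genome
  if (!is.null(label)) metadata(gr)$label <- label
  sort(gr)
}

peak_label <- function(gr) metadata(gr)$label %||% "peaks"

same_genome <- function(a, b) {
  identical(seqlevels(a), seqlevels(b)) &&
    identical(seqlengths(a), seqlengths(b))
}

check_same_genome <- function(a, b) {
  .assert(same_genome(a, b), "peak sets are on different genomes")
}
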