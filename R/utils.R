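#' @keywords internal
"_PACKAGE"

#' @import methods
#' @importFrom stats fisher.test t.test p.adjust rnorm runif rpois rbinom
#'   pnorm cor quantile sd dhyper setNames
#' @importFrom utils read.table write.table head tail
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   strand<- findOverlaps countOverlaps reduce mcols mcols<- start<- end<-
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits metadata metadata<- DataFrame
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo
#'   seqinfo<- seqlevels<- seqlengths<- keepSeqlevels
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement letterFrequency
NULL

# Deterministic per-entity RNG sub-seeds: one master seed fans out into a
# fixed table of streams so that, e.g., adding peaks never perturbs the
# contact matrix draw.
.stream_names <- c("genome", "tads", "regions", "pr", "pax", "er",
                   "matrix", "genes", "expr", "shuffle", "bootstrap",
                   "misc")

derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  i <- match(stream, .stream_names)
  if (is.na(i)) stop("unknown RNG stream: ", stream)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, length(.stream_names))[i]
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
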