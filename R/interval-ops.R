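#' Filter peaks by q-value
#'
#' Keeps exactly the peaks with raw q-value strictly below `q_max` (the
#' peak-calling significance filter; the default reproduces the q < 1e-5
#' cut applied to MACS2 output before any downstream analysis).
#'
#' @param gr a peak `GRanges` with a `qvalue` metadata column.
#' @param q_max keep peaks with `qvalue < q_max`.
#' @return the filtered `GRanges`, original order preserved.
#' @export
filter_q <- function(gr, q_max = 1e-5) {
  q <- mcols(gr)$qvalue
  .assert(!is.null(q), "peaks carry no qvalue column")
  if (anyNA(q)) {
    nm <- mcols(gr)$name %||% as.character(seq_along(gr))
    stop("missing qvalue for peak(s): ",
         paste(head(nm[is.na(q)]), collapse = ", "))
  }
  gr[q < q_max]
}

#' Overlap two peak sets (>= min_bp shared bases counts as positive)
#'
#' @param a,b peak `GRanges` on the same genome.
#' @param min_bp minimum overlap in bp (default 1).
#' @return list with `flags_a`, `flags_b` (logical, per interval: overlaps
#'   the other set) and `pairs`, a data.frame of overlapping index pairs.
#' @export
peak_intersect <- function(a, b, min_bp = 1L) {
  check_same_genome(a, b)
  ov <- findOverlaps(a, b, minoverlap = min_bp)
  list(flags_a = overlapsAny(a, b, minoverlap = min_bp),
       flags_b = overlapsAny(b, a, minoverlap = min_bp),
       pairs = data.frame(a = queryHits(ov), b = subjectHits(ov)))
}

#' Partition the union of several peak sets into membership groups
#'
#' Sites are clustered as connected components of the >=1 bp overlap graph
#' across all sets (for intervals, components are exactly the merged
#' overlapping regions); each component gets the signature of the sets it
#' touches. Groups are mutually exclusive and exhaustive.
#'
#' @param sets named list of >= 2 peak `GRanges` on one genome.
#' @param min_bp minimum overlap to connect two intervals.
#' @return list with `components` (a `GRanges` of merged sites with a
#'   `signature` column, set names joined by `+`) and `counts` (table of
#'   component counts per signature).
#' @export
venn_partition <- function(sets, min_bp = 1L) {
  .assert(is.list(sets) && length(sets) >= 2, "need >= 2 peak sets")
  .assert(!is.null(names(sets)) && all(nzchar(names(sets))),
          "sets must be named")
  for (s in sets[-1]) check_same_genome(sets[[1]], s)
  all_gr <- do.call(c, unname(lapply(sets, granges)))
  comp <- reduce(all_gr, min.gapwidth = 0L)
  member <- vapply(sets, function(s)
    overlapsAny(comp, s, minoverlap = min_bp), logical(length(comp)))
  member <- matrix(member, nrow = length(comp),
                   dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "+"))
  mcols(comp)$signature <- sig
  list(components = comp, counts = table(sig))
}

#' Pairwise overlap fractions between peak sets
#'
#' Entry (A, B) is the fraction of A intervals that overlap at least one B
#' interval; the matrix is not symmetric in general. Empty sets yield `NA`
#' rows.
#'
#' @inheritParams venn_partition
#' @return numeric matrix, rows = "of set", columns = "overlapping set".
#' @export
pairwise_overlap_fractions <- function(sets, min_bp = 1L) {
  .assert(is.list(sets) && length(sets) >= 2 && !is.null(names(sets)),
          "need >= 2 named peak sets")
  n <- length(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (length(sets[[i]]) == 0) next
    m[i, j] <- mean(overlapsAny(sets[[i]], sets[[j]], minoverlap = min_bp))
  }
  m
}

#' Distance from each interval in `a` to its nearest interval in `b`
#'
#' Distance is 0 for overlapping (or book-ended) intervals and the
#' edge-to-edge gap in bp otherwise; `Inf` when `b` has no interval on the
#' chromosome. Ties are broken toward the lower-coordinate `b` interval.
#'
#' @param a,b peak `GRanges` on the same genome.
#' @return data.frame with `distance` and `nearest` (index into `b`, NA at
#'   the Inf sentinel).
#' @export
nearest_distance <- function(a, b) {
  check_same_genome(a, b)
  d <- rep(Inf, length(a))
  idx <- rep(NA_integer_, length(a))
  hits <- GenomicRanges::distanceToNearest(a, b, select = "all")
  if (length(hits)) {
    df <- data.frame(q = queryHits(hits), s = subjectHits(hits),
                     d = mcols(hits)$distance)
    df <- df[order(df$q, df$d, start(b)[df$s]), ]
    keep <- !duplicated(df$q)
    d[df$q[keep]] <- df$d[keep]
    idx[df$q[keep]] <- df$s[keep]
  }
  data.frame(distance = d, nearest = idx)
}

#' Randomly relocate intervals on their genome
#'
#' Re-places every interval uniformly at random, preserving its length,
#' keeping it on its original chromosome when `same_chrom` and avoiding
#' mutual overlaps when `no_overlap` (the `-chrom -noOverlapping`
#' randomisation used for interval association testing). Placement is by
#' rejection sampling, widest intervals first.
#'
#' @param gr intervals to shuffle (`GRanges` with seqlengths set).
#' @param genome optional `Seqinfo`; defaults to `seqinfo(gr)`.
#' @param same_chrom keep each interval on its chromosome.
#' @param no_overlap forbid overlaps among shuffled intervals.
#' @param seed integer seed (required: shuffles are always reproducible).
#' @param max_retries rejection-sampling budget per interval.
#' @return shuffled `GRanges` (metadata columns preserved, sorted).
#' @export
shuffle_intervals <- function(gr, genome = NULL, same_chrom = TRUE,
                              no_overlap = TRUE, seed, max_retries = 1000L) {
  genome <- genome %||% seqinfo(gr)
  gl <- genome_lengths(genome)
  .assert(all(!is.na(gl)), "genome lengths required for shuffling")
  with_seed(seed, {
    ord <- order(-width(gr))
    new_chrom <- character(length(gr)); new_start <- integer(length(gr))
    placed <- list()  # per chromosome: matrix of (start,end)
    for (i in ord) {
      w <- width(gr)[i]
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        chrom <- if (same_chrom) as.character(seqnames(gr)[i])
                 else sample(names(gl), 1)
        L <- gl[[chrom]]
        if (L < w) next
        s <- sample.int(L - w + 1L, 1L)
        if (no_overlap && !is.null(placed[[chrom]])) {
          p <- placed[[chrom]]
          if (any(s <= p[, 2] & (s + w - 1L) >= p[, 1])) next
        }
        new_chrom[i] <- chrom; new_start[i] <- s
        placed[[chrom]] <- rbind(placed[[chrom]], c(s, s + w - 1L))
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place interval of width ", w, " after ",
             max_retries, " retries; consider no_overlap = FALSE")
    }
    out <- GRanges(new_chrom, IRanges(new_start, width = width(gr)),
                   seqinfo = genome)
    mcols(out) <- mcols(gr)
    sort(out)
  })
}

#' Fisher's exact test of association between two interval sets
#'
#' Builds the 2x2 contingency table used by interval-association testing:
#' `n11` = A intervals overlapping B, `n12` = A not overlapping B, `n21` =
#' B not overlapping A, and `n22` = the remaining number of placement
#' slots, `round(G / (mean width A + mean width B)) - n11 - n12 - n21`
#' (floored at 0), where G is the genome length. Two A intervals hitting
#' the same B interval count separately. The two-tailed p-value comes from
#' the exact hypergeometric test on this table.
#'
#' @param a,b peak `GRanges` on one genome.
#' @param genome optional `Seqinfo`; defaults to `seqinfo(a)`.
#' @param min_bp minimum overlap in bp.
#' @return list with `table` (2x2 matrix), `p` (two-tailed), `odds_ratio`.
#' @export
fisher_association <- function(a, b, genome = NULL, min_bp = 1L) {
  check_same_genome(a, b)
  genome <- genome %||% seqinfo(a)
  G <- sum(genome_lengths(genome))
  n11 <- sum(overlapsAny(a, b, minoverlap = min_bp))
  n12 <- length(a) - n11
  n21 <- length(b) - sum(overlapsAny(b, a, minoverlap = min_bp))
  mean_w <- mean(width(a)) + mean(width(b))
  n22 <- max(0, round(G / mean_w) - n11 - n12 - n21)
  tab <- matrix(c(n11, n12, n21, n22), 2, 2, byrow = TRUE,
                dimnames = list(c("in A", "not in A"),
                                c("in B", "not in B")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate contingency table (zero margin); p = 1")
    return(list(table = tab, p = 1, odds_ratio = NA_real_))
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  list(table = tab, p = ft$p.value, odds_ratio = unname(ft$estimate))
}

# ---- feature annotation -----------------------------------------------

.feature_levels <- c("promoter", "utr5", "utr3", "exon", "first_intron",
                     "other_intron", "gene_body", "downstream",
                     "proximal_intergenic", "distal_intergenic")

#' Classify peaks relative to genomic features
#'
#' Each peak is assigned exactly one category by the position of its summit
#' (midpoint when no summit is recorded), with fixed priority: promoter
#' (TSS -1 kb ... +100 bp, strand-aware) > 5'UTR > 3'UTR > exon > first
#' intron > other intron > immediate downstream (<= 1 kb past the TES) >
#' proximal intergenic (<= 50 kb from a gene) > distal intergenic
#' (> 50 kb). UTR/exon/intron levels require an exon table (and UTRs
#' additionally `cds_start`/`cds_end` in the gene model); without exons,
#' intragenic positions fall in a single `gene_body` category.
#'
#' @param peaks peak `GRanges`.
#' @param genes gene model data.frame (see [read_gene_model()]), optionally
#'   with `cds_start`, `cds_end` columns.
#' @param exons optional data.frame `gene_id`, `start`, `end`.
#' @param proximal_cut distal/proximal boundary in bp (default 50,000).
#' @return list with `category` (factor per peak) and `percentages` (named
#'   numeric summing to 100).
#' @export
annotate_features <- function(peaks, genes, exons = NULL,
                              proximal_cut = 50000) {
  genes <- validate_gene_model(genes)
  pos <- summit_position(peaks)
  pos_gr <- GRanges(seqnames(peaks), IRanges(pos, pos))
  span_lo <- pmin(genes$tss, genes$tes)
  span_hi <- pmax(genes$tss, genes$tes)
  # candidate genes within proximal_cut of the summit
  cand_gr <- GRanges(genes$chrom,
                     IRanges(pmax(1, span_lo - proximal_cut),
                             span_hi + proximal_cut))
  GenomeInfoDb::seqlevels(pos_gr) <-
    union(GenomeInfoDb::seqlevels(pos_gr), GenomeInfoDb::seqlevels(cand_gr))
  GenomeInfoDb::seqlevels(cand_gr) <- GenomeInfoDb::seqlevels(pos_gr)
  ov <- findOverlaps(pos_gr, cand_gr)
  cat_idx <- rep(match("distal_intergenic", .feature_levels), length(peaks))
  orphan <- !(as.character(seqnames(peaks)) %in% genes$chrom)
  if (any(orphan))
    warning(sum(orphan), " peak(s) on chromosomes absent from the gene model; ",
            "classified distal_intergenic")
  if (length(ov)) {
    for (k in seq_along(ov)) {
      p <- queryHits(ov)[k]; g <- subjectHits(ov)[k]
      ci <- .classify_position(pos[p], genes[g, ], exons)
      if (ci < cat_idx[p]) cat_idx[p] <- ci
    }
  }
  category <- factor(.feature_levels[cat_idx], levels = .feature_levels)
  pct <- 100 * table(category) / max(1L, length(peaks))
  list(category = category, percentages = pct)
}

# priority index (lower = higher priority) of position p relative to one gene
.classify_position <- function(p, gene, exons) {
  lv <- function(x) match(x, .feature_levels)
  plus <- gene$strand == "+"
  prom <- if (plus) c(gene$tss - 1000, gene$tss + 100)
          else c(gene$tss - 100, gene$tss + 1000)
  if (p >= prom[1] && p <= prom[2]) return(lv("promoter"))
  lo <- min(gene$tss, gene$tes); hi <- max(gene$tss, gene$tes)
  if (p >= lo && p <= hi) {
    ex <- if (!is.null(exons)) exons[exons$gene_id == gene$gene_id, ] else NULL
    if (is.null(ex) || nrow(ex) == 0) return(lv("gene_body"))
    ex <- ex[order(ex$start), ]
    in_exon <- any(p >= ex$start & p <= ex$end)
    if (in_exon) {
      cs <- gene$cds_start; ce <- gene$cds_end
      if (!is.null(cs) && !is.na(cs) && !is.null(ce) && !is.na(ce)) {
        if (p < cs) return(lv(if (plus) "utr5" else "utr3"))
        if (p > ce) return(lv(if (plus) "utr3" else "utr5"))
      }
      return(lv("exon"))
    }
    if (nrow(ex) >= 2) {
      # intron index in transcription order
      starts <- ex$start; ends <- ex$end
      ii <- which(p > ends[-nrow(ex)] & p < starts[-1])
      if (length(ii)) {
        intron_no <- if (plus) ii[1] else (nrow(ex) - 1) - ii[1] + 1
        return(lv(if (intron_no == 1) "first_intron" else "other_intron"))
      }
    }
    return(lv("other_intron"))
  }
  down <- if (plus) c(gene$tes + 1, gene$tes + 1000)
          else c(gene$tes - 1000, gene$tes - 1)
  if (p >= down[1] && p <= down[2]) return(lv("downstream"))
  lv("proximal_intergenic")  # caller pre-filtered to within proximal_cut
}

#' Absolute summit position of each peak (midpoint fallback)
#' @param peaks a peak `GRanges`, optionally with a `summit` offset column.
#' @return integer vector of 1-based positions.
#' @export
summit_position <- function(peaks) {
  mid <- as.integer(floor((start(peaks) + end(peaks)) / 2))
  s <- mcols(peaks)$summit
  if (is.null(s)) return(mid)
  ifelse(is.na(s), mid, start(peaks) + as.integer(s))
}
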