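#' Position frequency matrix with pseudocount and background
#'
#' Builds a motif model from a 4 x w matrix of per-position base
#' frequencies (rows A, C, G, T). Columns are renormalised to sum to 1
#' after adding the pseudocount. Scores are log2 odds against the
#' background, discretised on a fixed grid (`step`, in bits) so that the
#' score distribution under the background can be computed exactly by
#' dynamic programming.
#'
#' @param mat 4 x w numeric matrix (rows A, C, G, T), frequencies or counts.
#' @param name motif name.
#' @param pseudocount added to every cell before normalisation (default
#'   0.01).
#' @param background base frequencies (A, C, G, T), positive, summing to 1.
#' @param step score discretisation, bits (default 0.01).
#' @return a `motif_pfm` object (list with `prob`, `log_odds`,
#'   `log_odds_int`, `name`, `background`, `step`, `width`).
#' @export
motif_pfm <- function(mat, name = "motif", pseudocount = 0.01,
                      background = rep(0.25, 4), step = 0.01) {
  mat <- as.matrix(mat)
  .assert(nrow(mat) == 4, "PFM must have 4 rows (A, C, G, T)")
  .assert(ncol(mat) >= 4, "motif length must be >= 4")
  .assert(all(background > 0) && abs(sum(background) - 1) < 1e-6,
          "background must be positive and sum to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  p <- apply(mat + pseudocount, 2, function(col) col / sum(col))
  lo <- log2(p / background)
  lo_int <- round(lo / step)
  structure(list(prob = p, log_odds = lo, log_odds_int = lo_int,
                 name = name, background = background, step = step,
                 width = ncol(mat)),
            class = "motif_pfm")
}

#' Exact score distribution of a PFM under its background
#'
#' Dynamic programming over positions: the distribution of the sum of
#' discretised per-position log-odds when bases are drawn i.i.d. from the
#' background. Total probability mass is 1 up to float rounding.
#'
#' @param pfm a [motif_pfm()] object.
#' @return data.frame `score` (bits, on the discretisation grid) and
#'   `prob`.
#' @export
pwm_score_distribution <- function(pfm) {
  li <- pfm$log_odds_int
  w <- pfm$width
  mins <- apply(li, 2, min); maxs <- apply(li, 2, max)
  lo_total <- sum(mins); hi_total <- sum(maxs)
  n <- hi_total - lo_total + 1
  # fixed frame over the total score range; partial sums are stored as if
  # every remaining column contributed its minimum, later shifts add the
  # per-column excess (li[b, k] - mins[k] >= 0)
  P <- numeric(n)  # index = score_int - lo_total + 1
  for (b in 1:4) {
    idx <- li[b, 1] - mins[1] + 1
    P[idx] <- P[idx] + pfm$background[b]
  }
  if (w >= 2) for (k in 2:w) {
    Pn <- numeric(n)
    for (b in 1:4) {
      sh <- li[b, k] - mins[k]
      if (sh == 0) Pn <- Pn + pfm$background[b] * P
      else {
        Pn[(1 + sh):n] <- Pn[(1 + sh):n] +
          pfm$background[b] * P[1:(n - sh)]
      }
    }
    P <- Pn
  }
  keep <- P > 0
  data.frame(score = (lo_total:hi_total)[keep] * pfm$step,
             prob = P[keep])
}

#' Log-odds threshold for a target scan p-value
#'
#' Returns the minimal score `s` on the discretisation grid such that
#' `P(score >= s) <= pvalue` under the background model ([exact
#' distribution][pwm_score_distribution]). `Inf` when even the maximal
#' score is too likely (e.g. a uniform PFM), meaning no window can match.
#'
#' @param pfm a [motif_pfm()] object.
#' @param pvalue target p-value in (0, 1).
#' @return list with `threshold` (bits), `attained_p`
#'   (`P(score >= threshold)`).
#' @export
pwm_threshold <- function(pfm, pvalue = 1e-4) {
  .assert(pvalue > 0 && pvalue < 1 || pvalue == 1,
          "pvalue must be in (0, 1]")
  dist <- pwm_score_distribution(pfm)
  surv <- rev(cumsum(rev(dist$prob)))  # P(score >= score_i)
  ok <- which(surv <= pvalue + 1e-12)
  if (length(ok) == 0) return(list(threshold = Inf, attained_p = 0))
  i <- ok[1]
  list(threshold = dist$score[i], attained_p = surv[i])
}

.base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.encode_seq <- function(s) {
  v <- strsplit(toupper(as.character(s)), "")[[1]]
  unname(.base_codes[v])  # non-ACGT -> NA
}

# reverse-complement PWM: score of RC window on forward strand
.rc_log_odds_int <- function(li) {
  li[c(4, 3, 2, 1), rev(seq_len(ncol(li))), drop = FALSE]
}

#' Scan sequences with a PFM at a score threshold (both strands)
#'
#' Every window of motif width whose discretised log-odds score reaches
#' `threshold` is reported, on the forward strand and (via the
#' reverse-complement matrix) on the reverse strand at the same forward
#' coordinates. Windows containing non-ACGT letters are skipped.
#'
#' @param seqs `DNAStringSet`, character vector, or a single string.
#' @param pfm a [motif_pfm()] object.
#' @param threshold score threshold in bits (from [pwm_threshold()]).
#' @return data.frame `seq` (name), `pos` (1-based window start), `strand`,
#'   `score` (bits).
#' @export
scan_sequences <- function(seqs, pfm, threshold) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  if (!is.finite(threshold))
    return(data.frame(seq = character(0), pos = integer(0),
                      strand = character(0), score = numeric(0)))
  w <- pfm$width
  li_f <- pfm$log_odds_int
  li_r <- .rc_log_odds_int(li_f)
  out <- list()
  for (nm in names(seqs)) {
    codes <- .encode_seq(seqs[[nm]])
    L <- length(codes)
    if (L < w) next
    starts <- seq_len(L - w + 1L)
    score_with <- function(li) {
      sc <- numeric(length(starts))
      for (p in seq_len(w)) sc <- sc + li[cbind(codes[starts + p - 1L], p)]
      sc * pfm$step
    }
    for (str in c("+", "-")) {
      sc <- score_with(if (str == "+") li_f else li_r)
      hit <- which(!is.na(sc) & sc >= threshold - 1e-12)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(seq = nm, pos = hit,
                                              strand = str,
                                              score = sc[hit])
    }
  }
  if (length(out) == 0)
    return(data.frame(seq = character(0), pos = integer(0),
                      strand = character(0), score = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$seq, res$pos, res$strand), , drop = FALSE]
}

#' Motif fold-enrichment between two region sets
#'
#' For each motif: scan both sets at the exact-p-value threshold, count
#' regions with at least one match (overlapping matches in a region count
#' once), and report `log2FE = log2(f_A / f_B)` where `f` is the fraction
#' of regions with a match (with +0.5 count smoothing by default), a
#' Fisher exact p on the 2x2 with/without table, and BH-adjusted p across
#' the motif library.
#'
#' @param seqs_a,seqs_b character vectors / `DNAStringSet` of region
#'   sequences (e.g. 200 bp summit-centred windows).
#' @param pfms list of [motif_pfm()] objects.
#' @param pvalue scan threshold p-value (default 1e-4).
#' @param smoothing apply +0.5 smoothing to the fractions (default TRUE).
#' @return data.frame `motif`, `hits_a`, `hits_b`, `f_a`, `f_b`, `log2FE`,
#'   `p`, `padj`, sorted by `padj`.
#' @export
motif_enrichment <- function(seqs_a, seqs_b, pfms, pvalue = 1e-4,
                             smoothing = TRUE) {
  if (is(seqs_a, "DNAStringSet")) seqs_a <- as.character(seqs_a)
  if (is(seqs_b, "DNAStringSet")) seqs_b <- as.character(seqs_b)
  n_a <- length(seqs_a); n_b <- length(seqs_b)
  if (is.null(names(seqs_a))) names(seqs_a) <- paste0("a_", seq_len(n_a))
  if (is.null(names(seqs_b))) names(seqs_b) <- paste0("b_", seq_len(n_b))
  rows <- lapply(pfms, function(pfm) {
    thr <- pwm_threshold(pfm, pvalue)$threshold
    h_a <- length(unique(scan_sequences(seqs_a, pfm, thr)$seq))
    h_b <- length(unique(scan_sequences(seqs_b, pfm, thr)$seq))
    if (smoothing) {
      f_a <- (h_a + 0.5) / (n_a + 0.5); f_b <- (h_b + 0.5) / (n_b + 0.5)
    } else {
      f_a <- h_a / n_a; f_b <- h_b / n_b
    }
    p <- fisher.test(matrix(c(h_a, n_a - h_a, h_b, n_b - h_b), 2,
                            byrow = TRUE))$p.value
    data.frame(motif = pfm$name, hits_a = h_a, hits_b = h_b,
               f_a = f_a, f_b = f_b, log2FE = log2(f_a / f_b), p = p)
  })
  res <- do.call(rbind, rows)
  res$padj <- p.adjust(res$p, method = "BH")
  res[order(res$padj, res$p, -abs(res$log2FE)), , drop = FALSE]
}

#' Proportion of regions with a motif match, per bin around summits
#'
#' Bins of `bin` bp tile the window `[-window, +window)` around each
#' summit; the profile value of a bin is the fraction of regions with at
#' least one match whose position falls in that bin offset.
#'
#' @param peaks peak `GRanges` (summit from the `summit` column, midpoint
#'   fallback).
#' @param matches match positions: `GRanges` (midpoints used) or a
#'   data.frame with `chrom` and `pos`.
#' @param window half-window, bp (default 2,000).
#' @param bin bin size, bp (default 200).
#' @return data.frame `offset` (bin start relative to summit),
#'   `proportion`.
#' @export
occurrence_profile <- function(peaks, matches, window = 2000, bin = 200) {
  .assert(window %% bin == 0, "window must be divisible by bin")
  nb <- 2L * window / bin
  if (is(matches, "GRanges")) {
    mpos <- as.integer(floor((start(matches) + end(matches)) / 2))
    mchrom <- as.character(seqnames(matches))
  } else {
    mpos <- matches$pos; mchrom <- as.character(matches$chrom)
  }
  summ <- summit_position(peaks)
  pchrom <- as.character(seqnames(peaks))
  hit <- matrix(FALSE, length(peaks), nb)
  for (i in seq_along(peaks)) {
    off <- mpos[mchrom == pchrom[i]] - summ[i]
    off <- off[off >= -window & off < window]
    if (length(off))
      hit[i, unique(floor((off + window) / bin) + 1L)] <- TRUE
  }
  data.frame(offset = seq(-window, window - bin, by = bin),
             proportion = colMeans(hit))
}

#' Read-coverage heatmap matrix around peak summits
#'
#' Counts coverage intervals (reads) overlapping each `bin`-bp bin in the
#' `[-window, +window)` window around each summit; rows are sorted by
#' descending peak height. Bins falling off a chromosome end are zero and
#' the region is flagged.
#'
#' @param peaks peak `GRanges`; height taken from `signal`, else `score`.
#' @param reads coverage interval `GRanges`.
#' @param window half-window, bp (default 5,000).
#' @param bin bin size, bp (default 200).
#' @param sort_by `"height"` (default) or `"none"`.
#' @return numeric matrix (regions x bins) with a logical `clipped`
#'   attribute per row; rownames are peak names/indices.
#' @export
signal_heatmap <- function(peaks, reads, window = 5000, bin = 200,
                           sort_by = c("height", "none")) {
  sort_by <- match.arg(sort_by)
  .assert(window %% bin == 0, "window must be divisible by bin")
  nb <- 2L * window / bin
  summ <- summit_position(peaks)
  height <- mcols(peaks)$signal %||% mcols(peaks)$score %||%
    rep(0, length(peaks))
  ord <- if (sort_by == "height") order(-height) else seq_along(peaks)
  gl <- genome_lengths(seqinfo(peaks))
  mat <- matrix(0, length(peaks), nb)
  clipped <- logical(length(peaks))
  offs <- seq(-window, window - bin, by = bin)
  for (r in seq_along(peaks)) {
    i <- ord[r]
    b_start <- summ[i] + offs
    b_end <- b_start + bin - 1L
    L <- gl[[as.character(seqnames(peaks)[i])]]
    L <- if (is.na(L)) Inf else L
    valid <- b_end >= 1 & b_start <= L
    clipped[r] <- any(!valid)
    if (any(valid)) {
      bins_gr <- GRanges(seqnames(peaks)[i],
                         IRanges(pmax(1, b_start[valid]),
                                 pmin(L, b_end[valid])))
      GenomeInfoDb::seqlevels(bins_gr) <-
        GenomeInfoDb::seqlevels(reads)
      mat[r, which(valid)] <- countOverlaps(bins_gr, reads)
    }
  }
  nm <- mcols(peaks)$name %||% as.character(seq_along(peaks))
  rownames(mat) <- nm[ord]
  attr(mat, "clipped") <- clipped
  attr(mat, "order") <- ord
  mat
}
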