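#' ContactMatrix: symmetric binned Hi-C counts for one chromosome
#'
#' Dense symmetric matrix of (raw or normalised) contact counts at a fixed
#' bin size. Bin `i` covers bases `[(i-1)*bin_size + 1, i*bin_size]`.
#'
#' @slot chrom chromosome name.
#' @slot bin_size bin width in bp.
#' @slot counts square symmetric numeric matrix, non-negative.
#' @slot normalized whether counts have been scaled.
#' @export
setClass("ContactMatrix",
         representation(chrom = "character", bin_size = "integer",
                        counts = "matrix", normalized = "logical"))

setValidity("ContactMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (any(m < 0)) return("counts must be non-negative")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    return("counts must be symmetric")
  if (object@bin_size <= 0L) return("bin_size must be > 0")
  TRUE
})

#' Construct a ContactMatrix
#' @param counts square symmetric non-negative matrix.
#' @param chrom chromosome name.
#' @param bin_size bin width (bp).
#' @param normalized logical flag.
#' @return a `ContactMatrix`.
#' @export
contact_matrix <- function(counts, chrom, bin_size, normalized = FALSE) {
  new("ContactMatrix", chrom = as.character(chrom),
      bin_size = as.integer(bin_size),
      counts = unname(as.matrix(counts)), normalized = normalized)
}

#' @describeIn contact_matrix number of bins.
#' @param m a `ContactMatrix`.
#' @export
n_bins <- function(m) nrow(m@counts)

#' Load a contact matrix from bins + pixels TSVs
#'
#' `bins_path`: TSV with header `chrom`, `start`, `end`, `bin_id`
#' (0-based half-open bins, consecutive ids per chromosome).
#' `pixels_path`: TSV with header `bin1`, `bin2`, `count` (upper triangle
#' or mixed; conflicting duplicate entries for a pair are an error).
#'
#' @param bins_path,pixels_path file paths.
#' @return named list of `ContactMatrix`, one per chromosome.
#' @export
read_contacts <- function(bins_path, pixels_path) {
  bins <- read.table(bins_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  px <- read.table(pixels_path, sep = "\t", header = TRUE)
  .assert(all(c("chrom", "start", "end", "bin_id") %in% names(bins)),
          "bins file needs chrom, start, end, bin_id")
  .assert(all(c("bin1", "bin2", "count") %in% names(px)),
          "pixels file needs bin1, bin2, count")
  .assert(all(px$bin1 %in% bins$bin_id) && all(px$bin2 %in% bins$bin_id),
          "pixel bin ids outside bin table range")
  out <- list()
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    b <- b[order(b$start), ]
    bin_size <- as.integer(b$end[1] - b$start[1])
    nb <- nrow(b)
    local <- setNames(seq_len(nb), as.character(b$bin_id))
    sel <- px$bin1 %in% b$bin_id & px$bin2 %in% b$bin_id
    p <- px[sel, , drop = FALSE]
    m <- matrix(0, nb, nb)
    if (nrow(p)) {
      i <- local[as.character(p$bin1)]; j <- local[as.character(p$bin2)]
      key_lo <- pmin(i, j); key_hi <- pmax(i, j)
      key <- paste(key_lo, key_hi)
      agg <- tapply(p$count, key, unique)
      if (any(lengths(agg) > 1))
        stop("conflicting entries for pixel(s): ",
             paste(head(names(agg)[lengths(agg) > 1]), collapse = "; "))
      m[cbind(key_lo, key_hi)] <- p$count
      m[cbind(key_hi, key_lo)] <- p$count
    }
    out[[ch]] <- contact_matrix(m, ch, bin_size)
  }
  out
}

#' Write a ContactMatrix as bins + pixels TSVs (upper triangle)
#' @param m a `ContactMatrix`.
#' @param bins_path,pixels_path output paths.
#' @param bin_id_offset starting bin id (for multi-chromosome files).
#' @return invisible list of the two paths.
#' @export
write_contacts <- function(m, bins_path, pixels_path, bin_id_offset = 0L) {
  nb <- n_bins(m)
  bins <- data.frame(chrom = m@chrom,
                     start = (seq_len(nb) - 1L) * m@bin_size,
                     end = seq_len(nb) * m@bin_size,
                     bin_id = bin_id_offset + seq_len(nb) - 1L)
  ut <- which(upper.tri(m@counts, diag = TRUE) & m@counts != 0,
              arr.ind = TRUE)
  px <- data.frame(bin1 = bin_id_offset + ut[, 1] - 1L,
                   bin2 = bin_id_offset + ut[, 2] - 1L,
                   count = m@counts[ut])
  px <- px[order(px$bin1, px$bin2), ]
  write.table(bins, bins_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(px, pixels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(bins = bins_path, pixels = pixels_path))
}

#' Scale a contact matrix to a fixed total (sequencing-depth normalisation)
#' @param m a `ContactMatrix`.
#' @param total target matrix sum (default 1e6).
#' @return normalised `ContactMatrix`.
#' @export
depth_normalize <- function(m, total = 1e6) {
  s <- sum(m@counts)
  .assert(s > 0, "cannot normalize an all-zero matrix")
  contact_matrix(m@counts * (total / s), m@chrom, m@bin_size,
                 normalized = TRUE)
}

#' Focal (box) average smoothing of a contact matrix
#'
#' Replaces each entry by the mean of its `k x k` neighbourhood; at matrix
#' edges the kernel shrinks to the cells that exist. Symmetry is
#' preserved.
#'
#' @param m a `ContactMatrix`.
#' @param k odd kernel size (default 3).
#' @return smoothed `ContactMatrix`.
#' @export
smooth_focal <- function(m, k = 3L) {
  .assert(k >= 1 && k %% 2 == 1, "k must be odd and >= 1")
  M <- m@counts
  n <- nrow(M)
  h <- (k - 1L) / 2L
  # 2D box sums via cumulative sums, kernel clipped at edges
  cs <- apply(apply(M, 2, cumsum), 1, cumsum)  # cs[j, i] = sum M[1:i, 1:j]
  cs <- t(cs)
  S <- matrix(0, n + 1L, n + 1L)
  S[-1, -1] <- cs
  lo_r <- pmax(1L, seq_len(n) - h); hi_r <- pmin(n, seq_len(n) + h)
  lo_c <- lo_r; hi_c <- hi_r
  block <- S[hi_r + 1L, hi_c + 1L, drop = FALSE] -
    S[lo_r, hi_c + 1L, drop = FALSE] -
    S[hi_r + 1L, lo_c, drop = FALSE] + S[lo_r, lo_c, drop = FALSE]
  cnt <- outer(hi_r - lo_r + 1L, hi_c - lo_c + 1L)
  out <- block / cnt
  out <- (out + t(out)) / 2  # guard float asymmetry
  contact_matrix(out, m@chrom, m@bin_size, normalized = m@normalized)
}

#' Virtual 4C: one-versus-all contact profile of a bait bin
#'
#' Extracts the bait row over `region` and scales it to per-mille (sums to
#' 1,000). By default the bait's self-contact bin is excluded from the
#' normalisation sum (self-ligation dominance) and reported as 0; set
#' `include_self = TRUE` to keep it.
#'
#' @param m a `ContactMatrix`.
#' @param bait_bin bait bin index (1-based).
#' @param region integer vector `c(from, to)` of bin indices; default whole
#'   chromosome.
#' @param include_self include the bait self-bin in the profile.
#' @return data.frame `bin`, `value` (per-mille profile over the region).
#' @export
virtual_4c <- function(m, bait_bin, region = NULL,
                       include_self = FALSE) {
  nb <- n_bins(m)
  region <- region %||% c(1L, nb)
  .assert(region[1] >= 1 && region[2] <= nb && region[1] <= region[2],
          "region outside matrix")
  .assert(bait_bin >= region[1] && bait_bin <= region[2],
          "bait must lie within region")
  bins <- seq.int(region[1], region[2])
  v <- m@counts[bait_bin, bins]
  if (!include_self) v[bins == bait_bin] <- 0
  s <- sum(v)
  .assert(s > 0, "bait row is all zero over the region")
  data.frame(bin = bins, value = 1000 * v / s)
}

#' Per-bin compartment score (first eigenvector of the O/E correlation)
#'
#' Divides the matrix by its mean-per-distance decay, computes the Pearson
#' correlation matrix of the result, and returns its first eigenvector.
#' When `orientation_track` is given (e.g. gene density per bin), the sign
#' is fixed so that high-track bins score positive (A-like).
#'
#' @param m a `ContactMatrix`.
#' @param orientation_track optional numeric vector, one value per bin.
#' @return numeric score per bin.
#' @export
compartment_eigenvector <- function(m, orientation_track = NULL) {
  M <- m@counts
  n <- nrow(M)
  d <- abs(row(M) - col(M))
  expected <- vapply(0:(n - 1), function(k) mean(M[d == k]), 0)
  .assert(any(expected > 0), "no compartment structure: empty matrix")
  oe <- M / expected[d + 1]
  oe[!is.finite(oe)] <- 0
  C <- suppressWarnings(cor(oe))
  C[!is.finite(C)] <- 0
  if (all(abs(C[upper.tri(C)]) < 1e-12))
    stop("no compartment structure: degenerate (constant) matrix")
  ev <- eigen(C, symmetric = TRUE)
  score <- ev$vectors[, 1]
  if (!is.null(orientation_track)) {
    .assert(length(orientation_track) == n,
            "orientation track length must equal bin count")
    cc <- suppressWarnings(cor(score, orientation_track))
    if (is.finite(cc) && cc < 0) score <- -score
  }
  score
}

#' Assign A/B compartment labels to TADs from per-bin scores
#'
#' A TAD is labelled `A` when the mean compartment score of its bins is
#' positive, `B` otherwise.
#'
#' @param scores per-bin scores from [compartment_eigenvector()].
#' @param tads TAD `GRanges` (one chromosome, matching the matrix).
#' @param chrom chromosome of the score vector.
#' @param bin_size bin width in bp.
#' @return the TADs with a `compartment` metadata column.
#' @export
assign_tad_compartments <- function(scores, tads, chrom, bin_size) {
  tads_c <- tads[as.character(seqnames(tads)) == chrom]
  lab <- vapply(seq_along(tads_c), function(i) {
    b1 <- max(1L, ceiling(start(tads_c)[i] / bin_size))
    b2 <- min(length(scores), ceiling(end(tads_c)[i] / bin_size))
    if (b2 < b1) return(NA_character_)
    if (mean(scores[b1:b2]) > 0) "A" else "B"
  }, "")
  mcols(tads_c)$compartment <- lab
  tads_c
}

#' Compare two compartment labelings of the same TAD partition
#'
#' @param tads_a,tads_b TAD `GRanges` with `compartment` columns (same
#'   partition; TADs unlabelled in either are excluded and counted).
#' @param genes optional gene model data.frame; genes with TSS in switched
#'   TADs are counted.
#' @return list with `frac_A_to_B`, `frac_B_to_A`, `n_genes_A_to_B`,
#'   `n_genes_B_to_A`, `n_excluded`.
#' @export
compare_compartments <- function(tads_a, tads_b, genes = NULL) {
  .assert(length(tads_a) == length(tads_b) &&
            all(start(tads_a) == start(tads_b)) &&
            all(end(tads_a) == end(tads_b)),
          "TAD partitions differ")
  la <- mcols(tads_a)$compartment
  lb <- mcols(tads_b)$compartment
  ok <- !is.na(la) & !is.na(lb)
  n_excluded <- sum(!ok)
  a2b <- ok & la == "A" & lb == "B"
  b2a <- ok & la == "B" & lb == "A"
  count_genes <- function(sel) {
    if (is.null(genes) || !any(sel)) return(0L)
    tss <- GRanges(genes$chrom, IRanges(genes$tss, genes$tss))
    sw <- granges(tads_a[sel])
    GenomeInfoDb::seqlevels(tss) <-
      union(GenomeInfoDb::seqlevels(tss), GenomeInfoDb::seqlevels(sw))
    GenomeInfoDb::seqlevels(sw) <- GenomeInfoDb::seqlevels(tss)
    sum(overlapsAny(tss, sw))
  }
  list(frac_A_to_B = if (sum(ok & la == "A")) sum(a2b) / sum(ok & la == "A") else NA_real_,
       frac_B_to_A = if (sum(ok & la == "B")) sum(b2a) / sum(ok & la == "B") else NA_real_,
       n_genes_A_to_B = count_genes(a2b),
       n_genes_B_to_A = count_genes(b2a),
       n_excluded = n_excluded)
}

#' Label matrix bins as PgCR / TSS / other and map them to TADs
#'
#' A bin overlapping a PgCR is `PgCR`; otherwise a bin containing a TSS is
#' `TSS`; all remaining bins are `other` (PgCR takes precedence). Each bin
#' is assigned the TAD containing its midpoint (`NA` outside TADs).
#'
#' @param chrom chromosome name.
#' @param nb number of bins.
#' @param bin_size bin width, bp.
#' @param tads TAD `GRanges`.
#' @param pgcrs PgCR `GRanges` (may be empty).
#' @param tss_positions integer vector of TSS coordinates on `chrom`.
#' @return data.frame `bin`, `class` (factor PgCR/TSS/other), `tad_id`.
#' @export
bin_class_map <- function(chrom, nb, bin_size, tads, pgcrs, tss_positions) {
  bin_gr <- GRanges(chrom, IRanges((seq_len(nb) - 1L) * bin_size + 1L,
                                   seq_len(nb) * bin_size))
  cls <- rep("other", nb)
  if (length(tss_positions)) {
    tss_bin <- unique(ceiling(tss_positions / bin_size))
    tss_bin <- tss_bin[tss_bin >= 1 & tss_bin <= nb]
    cls[tss_bin] <- "TSS"
  }
  if (length(pgcrs)) {
    pg <- pgcrs[as.character(seqnames(pgcrs)) == chrom]
    if (length(pg)) {
      pg2 <- granges(pg)
      GenomeInfoDb::seqlevels(pg2) <-
        union(GenomeInfoDb::seqlevels(pg2), GenomeInfoDb::seqlevels(bin_gr))
      GenomeInfoDb::seqlevels(bin_gr) <- GenomeInfoDb::seqlevels(pg2)
      cls[overlapsAny(bin_gr, pg2)] <- "PgCR"
    }
  }
  mid <- (seq_len(nb) - 1L) * bin_size + bin_size %/% 2L
  tads_c <- tads[as.character(seqnames(tads)) == chrom]
  tad_id <- rep(NA_character_, nb)
  if (length(tads_c)) {
    for (i in seq_along(tads_c))
      tad_id[mid >= start(tads_c)[i] & mid <= end(tads_c)[i]] <-
        mcols(tads_c)$tad_id[i]
  }
  data.frame(bin = seq_len(nb),
             class = factor(cls, levels = c("PgCR", "TSS", "other")),
             tad_id = tad_id, stringsAsFactors = FALSE)
}

#' Intra-TAD observed/expected contact enrichment between bin classes
#'
#' Fits the expected contact frequency per genomic distance as the mean
#' observed intra-TAD contact at that distance (the intra-TAD background),
#' then, for each class pair (TSS-TSS, PgCR-PgCR, PgCR-TSS, ...), reports
#' `log2(sum(observed) / sum(expected))` over intra-TAD bin pairs of that
#' combination, plus the per-pair log2 ratios as a distribution.
#'
#' @param m a `ContactMatrix`.
#' @param classes output of [bin_class_map()] for the same chromosome.
#' @return list with `log2_enrichment` (named numeric per class pair),
#'   `per_pair` (data.frame `pair`, `log2_ratio`), `decay` (expected per
#'   distance).
#' @export
intra_tad_enrichment <- function(m, classes) {
  M <- m@counts
  nb <- n_bins(m)
  .assert(nrow(classes) == nb, "classes must cover all matrix bins")
  tid <- classes$tad_id
  cls <- as.character(classes$class)
  in_tad <- which(!is.na(tid))
  pairs <- NULL
  for (t in unique(tid[in_tad])) {
    b <- which(!is.na(tid) & tid == t)
    if (length(b) < 2) next
    cmb <- t(utils::combn(b, 2))
    pairs <- rbind(pairs, cmb)
  }
  .assert(!is.null(pairs), "no intra-TAD bin pairs")
  i <- pairs[, 1]; j <- pairs[, 2]
  d <- j - i
  obs <- M[cbind(i, j)]
  decay <- tapply(obs, d, mean)
  exp_ <- as.numeric(decay[as.character(d)])
  # canonical order for mixed pairs (PgCR before TSS before other)
  pair_class <- vapply(seq_along(i), function(k) {
    a <- cls[i[k]]; b <- cls[j[k]]
    paste(sort(factor(c(a, b), levels = c("PgCR", "TSS", "other"))),
          collapse = "-")
  }, "")
  stats <- vapply(split(seq_along(obs), pair_class), function(idx) {
    so <- sum(obs[idx]); se <- sum(exp_[idx])
    if (se <= 0) return(NA_real_)
    log2(so / se)
  }, 0)
  if (anyNA(stats))
    warning("class pair(s) with zero expected mass omitted: ",
            paste(names(stats)[is.na(stats)], collapse = ", "))
  per_pair <- data.frame(pair = pair_class,
                         log2_ratio = log2(ifelse(exp_ > 0 & obs > 0,
                                                  obs / exp_, NA)),
                         distance = d)
  list(log2_enrichment = stats[!is.na(stats)], per_pair = per_pair,
       decay = setNames(as.numeric(decay), names(decay)))
}
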