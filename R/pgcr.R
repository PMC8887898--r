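#' Parameters of the Progestin Control Region calling rule
#'
#' A PgCR is a cluster of at least `min_pr_peaks` PR binding sites in which
#' every consecutive edge-to-edge gap is at most `max_gap`, supported by at
#' least one PAX2 binding site, and fully contained within one TAD. The
#' defaults (25 kb gap, 2 peaks, PAX2 required) are the published rule;
#' `flank` (1.5 kb) is only used when exporting flanked intervals for
#' coverage plotting.
#'
#' @param max_gap maximum gap between consecutive member PR peaks, bp.
#' @param min_pr_peaks minimum number of member PR peaks (>= 2).
#' @param require_pax require a PAX2 peak overlapping the cluster span.
#' @param pax_mode test PAX2 against the bare cluster `"span"` (default) or
#'   the span extended by `flank` on both sides (`"flanked"`).
#' @param gap_mode measure gaps `"edge"`-to-edge (default) or
#'   `"summit"`-to-summit.
#' @param flank flank size in bp for plotting/export.
#' @return a `pgcr_params` list.
#' @export
pgcr_params <- function(max_gap = 25000, min_pr_peaks = 2,
                        require_pax = TRUE,
                        pax_mode = c("span", "flanked"),
                        gap_mode = c("edge", "summit"),
                        flank = 1500) {
  .assert(max_gap > 0, "max_gap must be > 0")
  .assert(min_pr_peaks >= 2, "min_pr_peaks must be >= 2")
  structure(list(max_gap = max_gap, min_pr_peaks = min_pr_peaks,
                 require_pax = require_pax,
                 pax_mode = match.arg(pax_mode),
                 gap_mode = match.arg(gap_mode),
                 flank = flank),
            class = "pgcr_params")
}

#' Cluster PR binding sites by the maximum-gap rule
#'
#' Scans each chromosome left to right and emits the maximal runs of
#' consecutive PR peaks in which each gap (next start minus previous end,
#' in bp of separation) is at most `params$max_gap`; runs with fewer than
#' `params$min_pr_peaks` members are discarded.
#'
#' @param pr PR peak `GRanges` (auto-sorted with a notice if unsorted).
#' @param params a [pgcr_params()] object.
#' @return `GRanges` of candidate cluster spans (first member start to last
#'   member end) with metadata `n_pr` and `pr_members` (IntegerList of
#'   indices into the sorted input).
#' @export
cluster_pr_sites <- function(pr, params = pgcr_params()) {
  if (is.unsorted(order(as.factor(seqnames(pr)), start(pr)))) {
    message("PR peaks unsorted; sorting")
  }
  ord <- order(as.factor(seqnames(pr)), start(pr), end(pr))
  pr <- pr[ord]
  n <- length(pr)
  if (n == 0)
    return(GRanges(seqinfo = seqinfo(pr)))
  chrom <- as.character(seqnames(pr))
  if (params$gap_mode == "summit") {
    pos <- summit_position(pr)
    gap <- pos[-1] - pos[-n]
  } else {
    gap <- start(pr)[-1] - end(pr)[-n] - 1L  # bp strictly between peaks
  }
  new_run <- c(TRUE, gap > params$max_gap | chrom[-1] != chrom[-n])
  run_id <- cumsum(new_run)
  keep_runs <- which(tabulate(run_id) >= params$min_pr_peaks)
  spans <- lapply(keep_runs, function(r) {
    idx <- which(run_id == r)
    list(chrom = chrom[idx[1]],
         start = min(start(pr)[idx]), end = max(end(pr)[idx]),
         idx = idx)
  })
  if (length(spans) == 0)
    return(GRanges(seqinfo = seqinfo(pr)))
  out <- GRanges(vapply(spans, `[[`, "", "chrom"),
                 IRanges(vapply(spans, `[[`, 0, "start"),
                         vapply(spans, `[[`, 0, "end")),
                 seqinfo = seqinfo(pr))
  mcols(out)$n_pr <- vapply(spans, function(s) length(s$idx), 0L)
  mcols(out)$pr_members <- IRanges::IntegerList(lapply(spans, `[[`, "idx"))
  out
}

#' Call Progestin Control Regions from candidate clusters
#'
#' Keeps clusters whose span overlaps at least one PAX2 peak (>= 1 bp; or
#' the flanked span under `pax_mode = "flanked"`) and lies entirely within
#' a single TAD. Clusters on chromosomes without TADs are dropped with a
#' warning.
#'
#' @param clusters output of [cluster_pr_sites()].
#' @param pax PAX2 peak `GRanges`.
#' @param tads TAD `GRanges` with `tad_id` (see [make_tad_set()]).
#' @param params a [pgcr_params()] object.
#' @return `GRanges` of PgCRs named `pgcr_1..k` with metadata `n_pr`,
#'   `pr_members`, `pax_support` (IntegerList of PAX2 peak indices),
#'   `pax_count` and `tad_id`.
#' @export
call_pgcrs <- function(clusters, pax, tads, params = pgcr_params()) {
  if (length(clusters) == 0) return(clusters)
  no_tad_chrom <- !(as.character(seqnames(clusters)) %in%
                      as.character(seqnames(tads)))
  if (any(no_tad_chrom))
    warning(sum(no_tad_chrom), " cluster(s) on chromosomes without TADs dropped")
  test_span <- clusters
  if (params$pax_mode == "flanked") {
    test_span <- GRanges(seqnames(clusters),
                         IRanges(pmax(1L, start(clusters) - params$flank),
                                 end(clusters) + params$flank))
  }
  pax_hits <- findOverlaps(test_span, pax)
  has_pax <- overlapsAny(test_span, pax)
  within_tad <- findOverlaps(clusters, tads, type = "within")
  in_one_tad <- countOverlaps(clusters, tads, type = "within") >= 1L
  keep <- (!params$require_pax | has_pax) & in_one_tad & !no_tad_chrom
  out <- clusters[keep]
  if (length(out) == 0) return(out)
  kept_idx <- which(keep)
  mcols(out)$pax_support <- IRanges::IntegerList(lapply(kept_idx, function(i)
    subjectHits(pax_hits)[queryHits(pax_hits) == i]))
  mcols(out)$pax_count <- lengths(mcols(out)$pax_support)
  tad_of <- setNames(rep(NA_character_, length(clusters)), NULL)
  tad_of[queryHits(within_tad)] <- mcols(tads)$tad_id[subjectHits(within_tad)]
  mcols(out)$tad_id <- tad_of[kept_idx]
  mcols(out)$name <- paste0("pgcr_", seq_along(out))
  out
}

#' Summary statistics of a PgCR set
#'
#' @param pgcrs output of [call_pgcrs()].
#' @param tads the TAD set used for calling.
#' @return list with `count`, `mean_size`, `sizes`, `relative_position`
#'   (PgCR midpoint position within its TAD, in `[0, 1]`), and `flanked`
#'   (`GRanges` of spans extended by `flank`, clipped at chromosome ends).
#' @param flank flank in bp for the `flanked` intervals (default 1,500).
#' @export
pgcr_stats <- function(pgcrs, tads, flank = 1500) {
  if (length(pgcrs) == 0)
    return(list(count = 0L, mean_size = NA_real_, sizes = numeric(0),
                relative_position = numeric(0), flanked = pgcrs))
  .assert(!is.null(mcols(pgcrs)$tad_id) && !anyNA(mcols(pgcrs)$tad_id),
          "every PgCR must carry a tad_id")
  tad_idx <- match(mcols(pgcrs)$tad_id, mcols(tads)$tad_id)
  mid <- (start(pgcrs) + end(pgcrs)) / 2
  relpos <- (mid - start(tads)[tad_idx]) / width(tads)[tad_idx]
  gl <- genome_lengths(seqinfo(pgcrs))
  hi <- gl[as.character(seqnames(pgcrs))]
  hi[is.na(hi)] <- Inf
  flanked <- GRanges(seqnames(pgcrs),
                     IRanges(pmax(1, start(pgcrs) - flank),
                             pmin(hi, end(pgcrs) + flank)),
                     seqinfo = seqinfo(pgcrs))
  list(count = length(pgcrs),
       mean_size = mean(width(pgcrs)),
       sizes = width(pgcrs),
       relative_position = relpos,
       flanked = flanked)
}

#' Write called PgCRs as BED6+ (name, score = number of PR members, then
#' pax_count and tad_id as extra columns)
#' @param pgcrs output of [call_pgcrs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgcrs <- function(pgcrs, path) {
  df <- data.frame(chrom = as.character(seqnames(pgcrs)),
                   start = format(start(pgcrs) - 1L, scientific = FALSE, trim = TRUE),
                   end = format(end(pgcrs), scientific = FALSE, trim = TRUE),
                   name = mcols(pgcrs)$name,
                   score = mcols(pgcrs)$n_pr,
                   strand = ".",
                   pax_count = mcols(pgcrs)$pax_count,
                   tad_id = mcols(pgcrs)$tad_id)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
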