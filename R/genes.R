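#' GREAT-style basal-plus-extension association parameters
#'
#' Defaults: basal regulatory domain 5 kb upstream / 1 kb downstream of
#' each TSS (strand-aware), extended up to 100 kb on both sides but never
#' into a neighbouring gene's basal domain.
#'
#' @param basal_up,basal_down,max_ext distances in bp.
#' @return a `great_params` list.
#' @export
great_params <- function(basal_up = 5000, basal_down = 1000,
                         max_ext = 100000) {
  .assert(basal_up > 0 && basal_down > 0 && max_ext > 0,
          "all distances must be > 0")
  structure(list(basal_up = basal_up, basal_down = basal_down,
                 max_ext = max_ext), class = "great_params")
}

#' Build one regulatory domain per gene (basal plus extension)
#'
#' The basal domain is `[tss - basal_up, tss + basal_down]` for `+` strand
#' genes and mirrored for `-` strand. Each side is then extended up to
#' `max_ext` bp, stopping early at the nearest neighbouring basal domain
#' edge, so domains overlap only where basal domains themselves overlap.
#'
#' @param genes gene model data.frame ([read_gene_model()]).
#' @param params a [great_params()] object.
#' @return data.frame `gene_id`, `chrom`, `domain_start`, `domain_end`,
#'   `basal_start`, `basal_end` (1-based closed).
#' @export
build_regulatory_domains <- function(genes, params = great_params()) {
  genes <- validate_gene_model(genes)
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - params$basal_up,
                        genes$tss - params$basal_down)
  basal_end <- ifelse(plus, genes$tss + params$basal_down,
                      genes$tss + params$basal_up)
  basal_start <- pmax(1, basal_start)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    basal_start = basal_start, basal_end = basal_end,
                    domain_start = NA_real_, domain_end = NA_real_,
                    stringsAsFactors = FALSE)
  for (ch in unique(out$chrom)) {
    i <- which(out$chrom == ch)
    i <- i[order(out$basal_start[i], out$basal_end[i])]
    bs <- out$basal_start[i]; be <- out$basal_end[i]
    for (k in seq_along(i)) {
      left_lim <- be[be < bs[k]]
      left_lim <- if (length(left_lim)) max(left_lim) + 1 else 1
      right_lim <- bs[bs > be[k]]
      right_lim <- if (length(right_lim)) min(right_lim) - 1 else Inf
      out$domain_start[i[k]] <- max(bs[k] - params$max_ext, left_lim, 1)
      out$domain_end[i[k]] <- min(be[k] + params$max_ext, right_lim)
    }
  }
  out[, c("gene_id", "chrom", "domain_start", "domain_end",
          "basal_start", "basal_end")]
}

#' Associate peaks to genes through regulatory domains
#'
#' A peak is associated to every gene whose regulatory domain contains the
#' peak midpoint (the cited association tool's convention); under
#' `mode = "overlap"` any >= 1 bp overlap with the domain counts instead.
#'
#' @param peaks peak `GRanges`.
#' @param domains output of [build_regulatory_domains()].
#' @param mode `"midpoint"` (default) or `"overlap"`.
#' @return list with `genes` (character vector of associated gene ids) and
#'   `assignments` (data.frame `gene_id`, `peak` index).
#' @export
associate_peaks_to_genes <- function(peaks, domains,
                                     mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  dom_gr <- GRanges(domains$chrom,
                    IRanges(domains$domain_start, domains$domain_end))
  q <- if (mode == "midpoint") {
    mid <- as.integer(floor((start(peaks) + end(peaks)) / 2))
    GRanges(seqnames(peaks), IRanges(mid, mid))
  } else granges(peaks)
  GenomeInfoDb::seqlevels(q) <-
    union(GenomeInfoDb::seqlevels(q), GenomeInfoDb::seqlevels(dom_gr))
  GenomeInfoDb::seqlevels(dom_gr) <- GenomeInfoDb::seqlevels(q)
  ov <- findOverlaps(q, dom_gr)
  assignments <- data.frame(gene_id = domains$gene_id[subjectHits(ov)],
                            peak = queryHits(ov),
                            stringsAsFactors = FALSE)
  list(genes = unique(assignments$gene_id), assignments = assignments)
}

#' Thresholds defining regulated genes
#' @param lfc_cut absolute log2 fold-change threshold (inclusive).
#' @param q_cut significance threshold (exclusive: `q < q_cut`).
#' @return a `regulation_thresholds` list.
#' @export
regulation_thresholds <- function(lfc_cut = 0.8, q_cut = 0.05) {
  .assert(lfc_cut >= 0, "lfc_cut must be >= 0")
  .assert(q_cut > 0 && q_cut <= 1, "q_cut must be in (0, 1]")
  structure(list(lfc_cut = lfc_cut, q_cut = q_cut),
            class = "regulation_thresholds")
}

#' Classify genes as induced / repressed / non-regulated
#'
#' Pure threshold rule: induced iff `log2FC >= lfc_cut` and `q < q_cut`;
#' repressed iff `log2FC <= -lfc_cut` and `q < q_cut`; otherwise
#' non-regulated. The fold-change threshold is inclusive (a gene exactly at
#' the cut is regulated), the q threshold exclusive.
#'
#' @param expr data.frame with `gene_id`, `log2FC`, `q`.
#' @param thr a [regulation_thresholds()] object.
#' @return the input with a `regulation` factor column added.
#' @export
classify_regulated <- function(expr, thr = regulation_thresholds()) {
  miss <- setdiff(c("gene_id", "log2FC", "q"), names(expr))
  .assert(length(miss) == 0, "expression table missing column(s): ",
          paste(miss, collapse = ", "))
  sig <- expr$q < thr$q_cut
  reg <- ifelse(sig & expr$log2FC >= thr$lfc_cut, "induced",
         ifelse(sig & expr$log2FC <= -thr$lfc_cut, "repressed",
                "non-regulated"))
  expr$regulation <- factor(reg, levels = c("induced", "repressed",
                                            "non-regulated"))
  expr
}

#' Intersect peak-associated genes with regulated genes
#'
#' @param assoc_genes character vector of gene ids associated to peaks.
#' @param regulated_genes character vector of regulated gene ids.
#' @return list with `n_regulated`, `n_intersection`, and `percentage`
#'   (`100 * n_intersection / n_regulated`, rounded to the nearest
#'   integer; `NA` when the regulated set is empty).
#' @export
intersect_associated_with_regulated <- function(assoc_genes,
                                                regulated_genes) {
  n_reg <- length(unique(regulated_genes))
  n_int <- length(intersect(unique(assoc_genes), unique(regulated_genes)))
  pct <- if (n_reg == 0) NA_real_ else round(100 * n_int / n_reg)
  list(n_regulated = n_reg, n_intersection = n_int, percentage = pct)
}

#' Genes whose TSS lies in a TAD containing at least one PgCR
#'
#' @param genes gene model data.frame.
#' @param tads TAD `GRanges` with `tad_id`.
#' @param pgcrs PgCR `GRanges` with `tad_id` metadata.
#' @param biotype_filter keep only this biotype (`NULL` for all).
#' @return character vector of gene ids ("PgCR-genes").
#' @export
genes_in_pgcr_tads <- function(genes, tads, pgcrs,
                               biotype_filter = "protein_coding") {
  genes <- validate_gene_model(genes)
  if (length(pgcrs) == 0) return(character(0))
  pgcr_tads <- unique(mcols(pgcrs)$tad_id)
  tad_sub <- tads[mcols(tads)$tad_id %in% pgcr_tads]
  if (!is.null(biotype_filter))
    genes <- genes[genes$biotype %in% biotype_filter, , drop = FALSE]
  if (nrow(genes) == 0) return(character(0))
  tss_gr <- GRanges(genes$chrom, IRanges(genes$tss, genes$tss))
  GenomeInfoDb::seqlevels(tss_gr) <-
    union(GenomeInfoDb::seqlevels(tss_gr), GenomeInfoDb::seqlevels(tad_sub))
  tad_sub2 <- tad_sub
  GenomeInfoDb::seqlevels(tad_sub2) <- GenomeInfoDb::seqlevels(tss_gr)
  inside <- overlapsAny(tss_gr, tad_sub2)
  genes$gene_id[inside]
}

#' Signed gene-to-PgCR distances and the close/far fold-change comparison
#'
#' For every regulated gene, computes the signed distance from its TSS to
#' the nearest PgCR midpoint (negative when the TSS coordinate is below
#' the midpoint, i.e. the gene is upstream of the PgCR on the genomic
#' axis), splits genes at `close_cut` (1 Mb), and compares absolute
#' log2 fold-changes between the two groups with Welch's unequal-variance
#' t-test.
#'
#' @param genes gene model data.frame.
#' @param pgcrs PgCR `GRanges`.
#' @param expr expression data.frame (`gene_id`, `log2FC`, `q`).
#' @param thr regulation thresholds; only regulated genes enter the test.
#' @param close_cut close/far boundary in bp (default 1 Mb).
#' @return list with `distances` (data.frame `gene_id`, `log2FC`,
#'   `distance`, `group`) and `welch` (`statistic`, `df`, `p`; `NA`s when a
#'   group has < 2 members).
#' @export
distance_fc_analysis <- function(genes, pgcrs, expr,
                                 thr = regulation_thresholds(),
                                 close_cut = 1e6) {
  genes <- validate_gene_model(genes)
  expr <- classify_regulated(expr, thr)
  reg <- expr[expr$regulation != "non-regulated", , drop = FALSE]
  reg <- reg[reg$gene_id %in% genes$gene_id, , drop = FALSE]
  g <- genes[match(reg$gene_id, genes$gene_id), , drop = FALSE]
  if (length(pgcrs) == 0 || nrow(reg) == 0) {
    d <- rep(Inf, nrow(reg))
  } else {
    mid <- as.integer(floor((start(pgcrs) + end(pgcrs)) / 2))
    d <- vapply(seq_len(nrow(reg)), function(i) {
      on_chrom <- as.character(seqnames(pgcrs)) == g$chrom[i]
      if (!any(on_chrom)) return(Inf)
      inside <- on_chrom & start(pgcrs) <= g$tss[i] & end(pgcrs) >= g$tss[i]
      if (any(inside)) return(0)
      dd <- g$tss[i] - mid[on_chrom]
      dd[which.min(abs(dd))]  # which.min takes the first = lower coordinate
    }, 0)
  }
  group <- ifelse(abs(d) <= close_cut, "close", "far")
  distances <- data.frame(gene_id = reg$gene_id, log2FC = reg$log2FC,
                          distance = d, group = group,
                          stringsAsFactors = FALSE)
  x <- abs(reg$log2FC[group == "close"])
  y <- abs(reg$log2FC[group == "far"])
  welch <- if (length(x) >= 2 && length(y) >= 2) {
    tt <- t.test(x, y, var.equal = FALSE)
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  } else list(statistic = NA_real_, df = NA_real_, p = NA_real_)
  list(distances = distances, welch = welch)
}

#' Resampling test of a gene-set intersection against a random-draw null
#'
#' Draws `n_draw` genes from `universe` without replacement `iters` times,
#' intersects each draw with `target`, and summarises the null
#' distribution of intersection sizes: mean, nearest-rank 2.5/97.5
#' percentiles, and a +1-smoothed two-sided empirical p-value for the
#' observed intersection. The null mean estimates the hypergeometric
#' expectation `n_draw * |target| / |universe|`.
#'
#' @param universe character vector of all eligible gene ids.
#' @param n_draw genes per draw.
#' @param target gene ids to intersect with (must be a subset of
#'   `universe`).
#' @param observed observed intersection size (optional).
#' @param iters number of draws (default 10,000).
#' @param seed integer seed.
#' @return list with `draws`, `null_mean`, `percentile_ci` (integer
#'   endpoints), `observed`, `empirical_p`, `seed`, `universe_size`,
#'   `target_size`, `n_draw`, and `null_draws` (the raw statistics).
#' @export
bootstrap_intersection <- function(universe, n_draw, target,
                                   observed = NULL, iters = 10000, seed) {
  universe <- unique(universe)
  target <- unique(target)
  bad <- setdiff(target, universe)
  if (length(bad))
    stop("target genes not in universe: ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5))
  N <- length(universe)
  .assert(n_draw <= N, "n_draw exceeds universe size")
  is_target <- universe %in% target
  stat <- with_seed(seed, {
    vapply(seq_len(iters), function(i)
      sum(is_target[sample.int(N, n_draw)]), 0L)
  })
  srt <- sort(stat)
  nearest_rank <- function(p) srt[max(1L, ceiling(p * iters))]
  ci <- c(nearest_rank(0.025), nearest_rank(0.975))
  emp_p <- if (is.null(observed)) NA_real_ else {
    lo <- (1 + sum(stat <= observed)) / (iters + 1)
    hi <- (1 + sum(stat >= observed)) / (iters + 1)
    min(1, 2 * min(lo, hi))
  }
  list(draws = iters, null_mean = mean(stat),
       percentile_ci = as.integer(ci),
       observed = observed, empirical_p = emp_p, seed = seed,
       universe_size = N, target_size = length(target), n_draw = n_draw,
       null_draws = stat)
}
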