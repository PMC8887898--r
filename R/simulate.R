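#' Configuration for the synthetic-data generator
#'
#' The defaults emulate the study conditions the pipeline was built for:
#' a ~121 Mb multi-chromosome genome tiled by 121 TADs (~1 Mb average),
#' 121 planted PgCR-like regions with a ~25 kb average span, Hi-C bins of
#' 20 kb with power-law distance decay and Poisson counts, and expression
#' effects concentrated within 1 Mb of planted regions. All generators
#' draw from per-entity RNG streams derived from `seed`, so identical
#' configs give bitwise-identical outputs and adding one entity type never
#' perturbs another.
#'
#' @param seed integer master seed (required).
#' @param chrom_sizes named vector of chromosome lengths (bp).
#' @param n_pr_peaks,n_pax_peaks,n_er_peaks background peak counts.
#' @param peak_width peak width, bp.
#' @param colocal_fraction fraction of PR peaks given a PAX2 peak whose
#'   midpoint lies within `colocal_dist` (exact after rounding).
#' @param colocal_dist co-localisation distance, bp.
#' @param n_tads number of TADs tiling the genome.
#' @param n_regions number of planted PgCR-like regions.
#' @param region_span_range min/max span of planted regions, bp (uniform;
#'   the default averages 25 kb).
#' @param bin_size Hi-C bin size, bp.
#' @param decay_exponent power-law slope of contact decay.
#' @param contact_scale expected count at distance 0.
#' @param loop_boost multiplicative boost for planted region-promoter bin
#'   pairs within a TAD.
#' @param n_genes number of genes.
#' @param effect_size mean |log2FC| of genes within 1 Mb of a planted
#'   region.
#' @param sigma log2FC noise SD (> 0).
#' @param gc GC content of generated sequence.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed,
                       chrom_sizes = setNames(rep(30.25e6, 4),
                                              paste0("chr", 1:4)),
                       n_pr_peaks = 500, n_pax_peaks = 400,
                       n_er_peaks = 300, peak_width = 400,
                       colocal_fraction = 0.5, colocal_dist = 1000,
                       n_tads = 121, n_regions = 121,
                       region_span_range = c(10000, 40000),
                       bin_size = 20000, decay_exponent = 1,
                       contact_scale = 100, loop_boost = 2,
                       n_genes = 1000, effect_size = 1, sigma = 0.3,
                       gc = 0.5) {
  .assert(!missing(seed), "seed is required")
  .assert(all(chrom_sizes > 0), "zero-length chromosome in config")
  .assert(colocal_fraction >= 0 && colocal_fraction <= 1,
          "colocal_fraction must be in [0, 1]")
  .assert(bin_size > 0 && peak_width > 0 && colocal_dist > 0,
          "all lengths must be > 0")
  .assert(sigma > 0, "sigma must be > 0")
  .assert(bin_size <= max(chrom_sizes), "bin_size exceeds chromosome length")
  structure(list(seed = as.integer(seed), chrom_sizes = chrom_sizes,
                 n_pr_peaks = n_pr_peaks, n_pax_peaks = n_pax_peaks,
                 n_er_peaks = n_er_peaks, peak_width = peak_width,
                 colocal_fraction = colocal_fraction,
                 colocal_dist = colocal_dist,
                 n_tads = n_tads, n_regions = n_regions,
                 region_span_range = region_span_range,
                 bin_size = bin_size, decay_exponent = decay_exponent,
                 contact_scale = contact_scale, loop_boost = loop_boost,
                 n_genes = n_genes, effect_size = effect_size,
                 sigma = sigma, gc = gc),
            class = "sim_config")
}

#' Generate the genome model and (optionally) background sequence
#'
#' @param cfg a [sim_config()] object.
#' @param sequence also generate i.i.d. background sequence at GC content
#'   `cfg$gc` (intended for small genomes; the coordinate-only model is
#'   enough for all interval analyses).
#' @return list with `genome` (`Seqinfo`) and `seqs` (`DNAStringSet` or
#'   `NULL`).
#' @export
sim_genome <- function(cfg, sequence = FALSE) {
  genome <- genome_model(cfg$chrom_sizes)
  seqs <- NULL
  if (sequence) {
    seqs <- with_seed(derive_seed(cfg$seed, "genome"), {
      p <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
      DNAStringSet(vapply(cfg$chrom_sizes, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = p),
              collapse = ""), ""))
    })
    names(seqs) <- names(cfg$chrom_sizes)
  }
  list(genome = genome, seqs = seqs)
}

# Place n intervals of width w uniformly, non-overlapping, with at least
# min_gap bp to each other and to `avoid`; bounded rejection sampling.
.place_intervals <- function(genome, n, w, min_gap = 0L, avoid = NULL,
                             max_retries = 1000L) {
  gl <- genome_lengths(genome)
  chroms <- names(gl)
  placed <- lapply(chroms, function(ch) {
    if (is.null(avoid)) NULL else {
      a <- avoid[as.character(seqnames(avoid)) == ch]
      if (length(a) == 0) NULL else cbind(start(a), end(a))
    }
  })
  names(placed) <- chroms
  keep_n <- lapply(chroms, function(ch) nrow(placed[[ch]]) %||% 0L)
  out_chrom <- character(n); out_start <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      ch <- sample(chroms, 1, prob = gl)
      if (gl[[ch]] < w) next
      s <- sample.int(gl[[ch]] - w + 1L, 1L)
      p <- placed[[ch]]
      if (!is.null(p) &&
          any(s - min_gap <= p[, 2] & (s + w - 1L + min_gap) >= p[, 1]))
        next
      out_chrom[i] <- ch; out_start[i] <- s
      placed[[ch]] <- rbind(p, c(s, s + w - 1L))
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place interval ", i, " after ",
                  max_retries, " retries (placement error)")
  }
  GRanges(out_chrom, IRanges(out_start, width = w), seqinfo = genome)
}

.decorate_peaks <- function(gr, prefix, label) {
  if (length(gr)) {
    mcols(gr)$name <- paste0(prefix, "_", seq_along(gr))
    mcols(gr)$score <- 0
    mcols(gr)$signal <- round(abs(rnorm(length(gr), 10, 3)) + 1, 3)
    mcols(gr)$pvalue_nl10 <- round(runif(length(gr), 8, 20), 3)
    mcols(gr)$qvalue <- 10^(-runif(length(gr), 6, 12))
    mcols(gr)$summit <- as.integer(width(gr) %/% 2)
  }
  metadata(gr)$label <- label
  sort(gr)
}

#' Plant PR, PAX2 and ER peak sets with tunable co-localisation
#'
#' Places `n_pr_peaks` PR peaks uniformly (non-overlapping), then gives
#' exactly `round(colocal_fraction * n_pr_peaks)` of them a PAX2 peak
#' whose midpoint lies within `colocal_dist` bp of the PR midpoint; the
#' remaining PAX2 peaks (and all ER peaks) are placed uniformly, away
#' from any PR midpoint by more than `colocal_dist` so the co-localised
#' count is exact. Every peak carries a summit (midpoint) and a height.
#'
#' @param cfg a [sim_config()] object.
#' @param genome `Seqinfo` from [sim_genome()].
#' @return list of `GRanges`: `PR`, `PAX`, `ER`.
#' @export
sim_peaks <- function(cfg, genome) {
  w <- cfg$peak_width
  pr <- with_seed(derive_seed(cfg$seed, "pr"), {
    .decorate_peaks(.place_intervals(genome, cfg$n_pr_peaks, w),
                    "pr", "PRbs")
  })
  pax <- with_seed(derive_seed(cfg$seed, "pax"), {
    n_col <- round(cfg$colocal_fraction * cfg$n_pr_peaks)
    .assert(n_col <= cfg$n_pax_peaks,
            "colocal_fraction requires more PAX peaks than n_pax_peaks")
    gl <- genome_lengths(genome)
    target <- if (n_col > 0) sample(seq_along(pr), n_col) else integer(0)
    col_gr <- NULL
    if (n_col > 0) {
      mid_pr <- floor((start(pr)[target] + end(pr)[target]) / 2)
      off <- sample(seq(-cfg$colocal_dist, cfg$colocal_dist), n_col,
                    replace = TRUE)
      mid_pax <- mid_pr + off
      s <- pmax(1, mid_pax - w %/% 2)
      L <- gl[as.character(seqnames(pr)[target])]
      s <- pmin(s, L - w + 1)
      col_gr <- GRanges(seqnames(pr)[target], IRanges(s, width = w),
                        seqinfo = genome)
    }
    # background PAX kept > colocal_dist from every PR midpoint
    pr_len <- gl[as.character(seqnames(pr))]
    exclusion <- GRanges(seqnames(pr),
                         IRanges(pmax(1, floor((start(pr) + end(pr)) / 2) -
                                        cfg$colocal_dist - w),
                                 pmin(pr_len,
                                      floor((start(pr) + end(pr)) / 2) +
                                        cfg$colocal_dist + w)),
                         seqinfo = genome)
    avoid <- if (is.null(col_gr)) exclusion else c(exclusion, granges(col_gr))
    bg <- .place_intervals(genome, cfg$n_pax_peaks - n_col, w,
                           avoid = avoid)
    all_pax <- if (is.null(col_gr)) bg else c(granges(col_gr), bg)
    .decorate_peaks(all_pax, "pax", "PAXbs")
  })
  er <- with_seed(derive_seed(cfg$seed, "er"), {
    .decorate_peaks(.place_intervals(genome, cfg$n_er_peaks, w),
                    "er", "ERbs")
  })
  list(PR = pr, PAX = pax, ER = er)
}

#' Write a consensus motif instance under the summit of each peak
#'
#' @param seqs `DNAStringSet`.
#' @param peaks peak `GRanges` on the same chromosomes.
#' @param consensus motif string (e.g. `"GAACATTATGTTC"`).
#' @return modified `DNAStringSet`.
#' @export
plant_motif_instances <- function(seqs, peaks, consensus) {
  chars <- lapply(as.character(seqs), function(s) strsplit(s, "")[[1]])
  cons <- strsplit(toupper(consensus), "")[[1]]
  pos <- summit_position(peaks)
  for (i in seq_along(peaks)) {
    ch <- as.character(seqnames(peaks)[i])
    s <- pos[i] - length(cons) %/% 2
    s <- max(1, min(s, length(chars[[ch]]) - length(cons) + 1))
    chars[[ch]][s:(s + length(cons) - 1)] <- cons
  }
  out <- DNAStringSet(vapply(chars, paste, "", collapse = ""))
  names(out) <- names(seqs)
  out
}

#' Tile the genome with TADs
#'
#' Partitions each chromosome into contiguous TADs whose boundaries fall
#' on Hi-C bin edges; TAD sizes are drawn from a jittered equal split (at
#' least 5 bins each).
#'
#' @param cfg a [sim_config()] object.
#' @param genome `Seqinfo`.
#' @return TAD `GRanges` with `tad_id` ([make_tad_set()]).
#' @export
sim_tads <- function(cfg, genome) {
  gl <- genome_lengths(genome)
  # largest-remainder allocation: exactly n_tads in total, >= 1 per chrom
  cum <- round(cumsum(cfg$n_tads * gl / sum(gl)))
  n_per <- diff(c(0, cum))
  n_per[n_per < 1] <- 1
  names(n_per) <- names(gl)
  with_seed(derive_seed(cfg$seed, "tads"), {
    pieces <- lapply(names(gl), function(ch) {
      nb <- floor(gl[[ch]] / cfg$bin_size)
      k <- min(n_per[[ch]], max(1L, nb %/% 5L))
      if (k == 1) {
        cuts <- integer(0)
      } else {
        # jittered equal split on bin edges, >= 5 bins per TAD
        target <- round(seq(0, nb, length.out = k + 1L))[2:k]
        jit <- target + sample(-2:2, k - 1L, replace = TRUE)
        cuts <- sort(unique(pmin(nb - 5L, pmax(5L, jit))))
      }
      edges <- c(0L, cuts, nb) * cfg$bin_size
      GRanges(ch, IRanges(head(edges, -1) + 1L, tail(edges, -1)),
              seqinfo = genome)
    })
    make_tad_set(do.call(c, pieces))
  })
}

#' Simulate a full PgCR-calling scenario with known truth
#'
#' Plants `n_regions` compliant PgCR-like regions inside TAD interiors:
#' each region holds 2-5 PR peaks whose first/last peaks delimit the span
#' exactly, with every consecutive gap below `max_gap`, plus one PAX2
#' peak inside the span. Background PR peaks are placed pairwise more
#' than `max_gap` apart (and away from planted regions), so no background
#' run can satisfy the two-peak rule: on this generator's output the
#' caller's sensitivity is 1 and its false-discovery rate 0 by
#' construction.
#'
#' @param cfg a [sim_config()] object.
#' @param params the [pgcr_params()] the caller will use.
#' @return list with `genome`, `tads`, `truth` (planted region `GRanges`),
#'   `PR`, `PAX` peak sets.
#' @export
sim_pgcr_scenario <- function(cfg, params = pgcr_params()) {
  genome <- genome_model(cfg$chrom_sizes)
  tads <- sim_tads(cfg, genome)
  w <- cfg$peak_width
  with_seed(derive_seed(cfg$seed, "regions"), {
    margin <- 2000L
    big <- tads[width(tads) >= diff(cfg$region_span_range) +
                  cfg$region_span_range[2] + 2 * margin]
    .assert(length(big) >= cfg$n_regions,
            "not enough TADs large enough to host planted regions")
    host <- sort(sample(seq_along(big), cfg$n_regions))
    span <- round(runif(cfg$n_regions, cfg$region_span_range[1],
                        cfg$region_span_range[2]))
    s <- vapply(seq_len(cfg$n_regions), function(i) {
      t <- big[host[i]]
      lo <- start(t) + margin
      hi <- end(t) - margin - span[i]
      round(runif(1, lo, hi))
    }, 0)
    truth <- GRanges(seqnames(big)[host], IRanges(s, width = span),
                     seqinfo = genome)
    pr_list <- list(); pax_list <- list()
    gap_target <- 0.9 * params$max_gap
    for (i in seq_len(cfg$n_regions)) {
      k <- max(2L, ceiling((span[i] - w) / gap_target) + 1L,
               sample(2:5, 1))
      # first peak starts at the region start, last ends at the region end
      starts <- round(seq(start(truth)[i], end(truth)[i] - w + 1,
                          length.out = k))
      pr_list[[i]] <- GRanges(seqnames(truth)[i],
                              IRanges(starts, width = w), seqinfo = genome)
      mid <- round((start(truth)[i] + end(truth)[i]) / 2)
      pax_list[[i]] <- GRanges(seqnames(truth)[i],
                               IRanges(mid - w %/% 2, width = w),
                               seqinfo = genome)
    }
    planted_pr <- do.call(c, pr_list)
    planted_pax <- do.call(c, pax_list)
    avoid <- GRanges(seqnames(truth),
                     IRanges(pmax(1, start(truth) - params$max_gap - w),
                             end(truth) + params$max_gap + w),
                     seqinfo = genome)
    bg_pr <- .place_intervals(genome, cfg$n_pr_peaks, w,
                              min_gap = params$max_gap + 1L, avoid = avoid)
    bg_pax <- .place_intervals(genome, cfg$n_pax_peaks, w,
                               avoid = c(granges(avoid), granges(bg_pr)))
    list(genome = genome, tads = tads, truth = sort(truth),
         PR = .decorate_peaks(c(planted_pr, bg_pr), "pr", "prePRbs"),
         PAX = .decorate_peaks(c(planted_pax, bg_pax), "pax", "PAXbs"))
  })
}

#' Simulate a binned contact matrix with distance decay and planted loops
#'
#' Expected counts follow `scale * (1 + |i - j|) ^ -decay_exponent`;
#' bin pairs formed by one planted-region bin and one TSS bin inside the
#' same TAD are multiplied by `loop_boost`; observed counts are Poisson
#' draws, symmetrised.
#'
#' @param cfg a [sim_config()] object.
#' @param chrom chromosome to simulate.
#' @param chrom_length its length, bp.
#' @param tads TAD `GRanges`.
#' @param regions planted PgCR-like `GRanges` (may be empty).
#' @param tss_positions TSS coordinates on `chrom`.
#' @param noise draw Poisson counts (default) or return expected values.
#' @return list with `matrix` (`ContactMatrix`), `expected` (matrix),
#'   `classes` (the [bin_class_map()]).
#' @export
sim_contacts <- function(cfg, chrom, chrom_length, tads, regions,
                         tss_positions, noise = TRUE) {
  nb <- floor(chrom_length / cfg$bin_size)
  .assert(nb >= 1, "bin_size larger than chromosome")
  classes <- bin_class_map(chrom, nb, cfg$bin_size, tads, regions,
                           tss_positions)
  d <- abs(row(diag(nb)) - col(diag(nb)))
  E <- cfg$contact_scale * (1 + d)^(-cfg$decay_exponent)
  cls <- as.character(classes$class)
  tid <- classes$tad_id
  pg <- which(cls == "PgCR"); ts <- which(cls == "TSS")
  for (i in pg) for (j in ts) {
    if (!is.na(tid[i]) && !is.na(tid[j]) && tid[i] == tid[j]) {
      E[i, j] <- E[i, j] * cfg$loop_boost
      E[j, i] <- E[j, i] * cfg$loop_boost
    }
  }
  M <- if (noise) {
    with_seed(derive_seed(cfg$seed, "matrix") +
                match(chrom, names(cfg$chrom_sizes), nomatch = 1L), {
      ut <- upper.tri(E, diag = TRUE)
      O <- matrix(0, nb, nb)
      O[ut] <- rpois(sum(ut), E[ut])
      O + t(O) - diag(diag(O))
    })
  } else E
  list(matrix = contact_matrix(M, chrom, cfg$bin_size),
       expected = E, classes = classes)
}

#' Simulate a gene model on the genome
#'
#' @param cfg a [sim_config()] object.
#' @param genome `Seqinfo`.
#' @param prop_coding fraction of protein-coding genes (default 0.85).
#' @return gene model data.frame ([read_gene_model()] schema).
#' @export
sim_genes <- function(cfg, genome, prop_coding = 0.85) {
  gl <- genome_lengths(genome)
  with_seed(derive_seed(cfg$seed, "genes"), {
    chrom <- sample(names(gl), cfg$n_genes, replace = TRUE, prob = gl)
    len <- round(runif(cfg$n_genes, 5000, 100000))
    tss <- vapply(seq_len(cfg$n_genes), function(i)
      round(runif(1, len[i] + 1, gl[[chrom[i]]] - len[i])), 0)
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    tes <- ifelse(strand == "+", tss + len, tss - len)
    biotype <- sample(c("protein_coding", "lncRNA"), cfg$n_genes,
                      replace = TRUE,
                      prob = c(prop_coding, 1 - prop_coding))
    validate_gene_model(data.frame(
      gene_id = paste0("gene_", seq_len(cfg$n_genes)),
      chrom = chrom, strand = strand, tss = tss, tes = tes,
      biotype = biotype, stringsAsFactors = FALSE))
  })
}

#' Simulate an expression table whose effects depend on PgCR distance
#'
#' Genes whose TSS lies within 1 Mb of a planted region draw their log2
#' fold-change from `N(+/- effect_size, sigma)` (random sign); all other
#' genes from `N(0, sigma)`. q-values are BH-adjusted normal-tail
#' p-values of the z-score `log2FC / sigma`, so large effects get small q.
#'
#' @param cfg a [sim_config()] object.
#' @param genes gene model data.frame.
#' @param regions planted region `GRanges` (may be empty: all genes far).
#' @param close_cut close/far boundary, bp (default 1 Mb).
#' @return data.frame `gene_id`, `log2FC`, `q`, `close` (logical truth).
#' @export
sim_expression <- function(cfg, genes, regions, close_cut = 1e6) {
  .assert(cfg$sigma > 0, "sigma must be > 0")
  close <- rep(FALSE, nrow(genes))
  if (length(regions) > 0) {
    mid <- floor((start(regions) + end(regions)) / 2)
    rchrom <- as.character(seqnames(regions))
    close <- vapply(seq_len(nrow(genes)), function(i) {
      on <- rchrom == genes$chrom[i]
      any(on) && min(abs(genes$tss[i] - mid[on])) <= close_cut
    }, TRUE)
  }
  with_seed(derive_seed(cfg$seed, "expr"), {
    sign <- sample(c(-1, 1), nrow(genes), replace = TRUE)
    mu <- ifelse(close, sign * cfg$effect_size, 0)
    lfc <- rnorm(nrow(genes), mu, cfg$sigma)
    p <- 2 * pnorm(-abs(lfc) / cfg$sigma)
    data.frame(gene_id = genes$gene_id, log2FC = lfc,
               q = p.adjust(p, method = "BH"), close = close,
               stringsAsFactors = FALSE)
  })
}

#' Write a simulation bundle to disk
#'
#' Writes whatever components are present: `genome.tsv` (+ `genome.fa`),
#' `pr.narrowPeak` / `pax.narrowPeak` / `er.narrowPeak`, `tads.bed`,
#' `regions.bed` (planted truth), `genes.tsv`, `expression.tsv`, and
#' `bins.tsv` / `pixels.tsv` for a contact matrix.
#'
#' @param sim named list of simulation outputs (from the `sim_*`
#'   functions).
#' @param outdir output directory (created).
#' @return character vector of paths written, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- function(f) file.path(outdir, f)
  if (!is.null(sim$genome)) {
    write_genome(sim$genome, p("genome.tsv")); paths <- c(paths, p("genome.tsv"))
  }
  if (!is.null(sim$seqs)) {
    writeXStringSet(sim$seqs, p("genome.fa")); paths <- c(paths, p("genome.fa"))
  }
  for (nm in intersect(c("PR", "PAX", "ER"), names(sim))) {
    f <- p(paste0(tolower(nm), ".narrowPeak"))
    write_peaks(sim[[nm]], f, format = "narrowPeak")
    paths <- c(paths, f)
  }
  if (!is.null(sim$tads)) {
    write_peaks(sim$tads, p("tads.bed"), format = "bed3")
    paths <- c(paths, p("tads.bed"))
  }
  if (!is.null(sim$truth)) {
    write_peaks(sim$truth, p("regions.bed"), format = "bed3")
    paths <- c(paths, p("regions.bed"))
  }
  if (!is.null(sim$genes)) {
    write.table(sim$genes, p("genes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p("genes.tsv"))
  }
  if (!is.null(sim$expression)) {
    write.table(sim$expression[, c("gene_id", "log2FC", "q")],
                p("expression.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p("expression.tsv"))
  }
  if (!is.null(sim$matrix)) {
    write_contacts(sim$matrix, p("bins.tsv"), p("pixels.tsv"))
    paths <- c(paths, p("bins.tsv"), p("pixels.tsv"))
  }
  invisible(paths)
}
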