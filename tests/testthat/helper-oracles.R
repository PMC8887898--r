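# Brute-force oracles and small fixture builders shared across tests.
# Oracles deliberately use plain loops / arithmetic, independent of the
# package's GenomicRanges-based code paths.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

toy_genome <- function(sizes = c(chr1 = 1e6, chr2 = 8e5)) genome_model(sizes)

random_peaks <- function(n, genome, max_width = 500, seed = NULL,
                         label = "peaks") {
  if (!is.null(seed)) set.seed(seed)
  gl <- setNames(as.numeric(GenomeInfoDb::seqlengths(genome)),
                 GenomeInfoDb::seqnames(genome))
  chrom <- sample(names(gl), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i)
    sample.int(gl[[chrom[i]]] - w[i], 1), 0L)
  gr <- GRanges(chrom, IRanges(s, width = w))
  gr <- set_genome(gr, genome, label)
  mcols(gr)$name <- paste0("p", seq_along(gr))
  mcols(gr)$score <- 0
  mcols(gr)$signal <- round(runif(n, 1, 20), 3)
  mcols(gr)$pvalue_nl10 <- round(runif(n, 6, 30), 3)
  mcols(gr)$qvalue <- 10^(-runif(n, 2, 12))
  mcols(gr)$summit <- as.integer(width(gr) %/% 2)
  gr
}

# overlap length of 1-based closed intervals
.ov_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)

oracle_overlap_flags <- function(a, b, min_bp = 1) {
  ca <- as.character(seqnames(a)); cb <- as.character(seqnames(b))
  vapply(seq_along(a), function(i) {
    any(cb == ca[i] &
          .ov_len(start(a)[i], end(a)[i], start(b), end(b)) >= min_bp)
  }, TRUE)
}

# connected components of the overlap graph over the union of sets
oracle_component_count <- function(sets, min_bp = 1) {
  all <- do.call(rbind, lapply(sets, function(g)
    data.frame(chrom = as.character(seqnames(g)), s = start(g), e = end(g))))
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (all$chrom[i] == all$chrom[j] &&
        .ov_len(all$s[i], all$e[i], all$s[j], all$e[j]) >= min_bp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

oracle_nearest <- function(a, b) {
  ca <- as.character(seqnames(a)); cb <- as.character(seqnames(b))
  vapply(seq_along(a), function(i) {
    on <- which(cb == ca[i])
    if (!length(on)) return(Inf)
    d <- pmax(0, pmax(start(b)[on] - end(a)[i], start(a)[i] - end(b)[on]) - 1)
    ov <- .ov_len(start(a)[i], end(a)[i], start(b)[on], end(b)[on]) >= 1
    d[ov] <- 0
    min(d)
  }, 0)
}

# maximal runs of sorted intervals with inter-peak gap <= max_gap
oracle_clusters <- function(chrom, s, e, max_gap, min_peaks) {
  ord <- order(chrom, s, e)
  chrom <- chrom[ord]; s <- s[ord]; e <- e[ord]
  runs <- list(); cur <- 1
  if (length(s) == 0) return(list())
  for (i in seq_along(s)[-1]) {
    gap <- s[i] - e[i - 1] - 1
    if (chrom[i] != chrom[i - 1] || gap > max_gap) {
      runs[[length(runs) + 1]] <- cur; cur <- i
    } else cur <- c(cur, i)
  }
  runs[[length(runs) + 1]] <- cur
  keep <- Filter(function(r) length(r) >= min_peaks, runs)
  lapply(keep, function(r)
    list(chrom = chrom[r[1]], start = min(s[r]), end = max(e[r]),
         n = length(r)))
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df))
}

# exact score distribution by enumerating all 4^w words
oracle_pwm_enumeration <- function(pfm) {
  w <- pfm$width
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  sc <- numeric(nrow(words)); pr <- numeric(nrow(words))
  for (r in seq_len(nrow(words))) {
    sc[r] <- sum(pfm$log_odds_int[cbind(words[r, ], seq_len(w))]) * pfm$step
    pr[r] <- prod(pfm$background[words[r, ]])
  }
  list(score = sc, prob = pr)
}

toy_gene_model <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(100000, 400000, 50000),
    tes = c(120000, 380000, 90000),
    biotype = c("protein_coding", "protein_coding", "lncRNA"),
    cds_start = c(101000, 381000, NA),
    cds_end = c(119000, 399000, NA),
    stringsAsFactors = FALSE)
}

toy_exons <- function() {
  data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB"),
    start = c(100000, 105000, 115000, 380000, 395000),
    end = c(101500, 106000, 120000, 385000, 400000),
    stringsAsFactors = FALSE)
}
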