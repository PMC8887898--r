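small_cfg <- function(seed, ...) {
  sim_config(seed = seed, chrom_sizes = c(chr1 = 2e6, chr2 = 1.5e6),
             n_pr_peaks = 60, n_pax_peaks = 60, n_er_peaks = 30,
             n_tads = 6, n_regions = 4, n_genes = 120, ...)
}

test_that("generators are bitwise deterministic under a fixed seed", {
  cfg <- small_cfg(7)
  g1 <- sim_genome(cfg, sequence = TRUE)
  g2 <- sim_genome(cfg, sequence = TRUE)
  expect_identical(as.character(g1$seqs), as.character(g2$seqs))
  p1 <- sim_peaks(cfg, g1$genome); p2 <- sim_peaks(cfg, g1$genome)
  expect_identical(start(p1$PR), start(p2$PR))
  expect_identical(start(p1$PAX), start(p2$PAX))
  t1 <- sim_tads(cfg, g1$genome); t2 <- sim_tads(cfg, g1$genome)
  expect_identical(start(t1), start(t2))
  e1 <- sim_expression(cfg, sim_genes(cfg, g1$genome), GRanges())
  e2 <- sim_expression(cfg, sim_genes(cfg, g1$genome), GRanges())
  expect_identical(e1$log2FC, e2$log2FC)
  # written files are byte-identical across runs
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(list(genome = g1$genome, PR = p1$PR, tads = t1), d1)
  write_simulation(list(genome = g1$genome, PR = p2$PR, tads = t2), d2)
  expect_identical(readLines(file.path(d1, "pr.narrowPeak")),
                   readLines(file.path(d2, "pr.narrowPeak")))
})

test_that("sequence generation hits the requested length and GC", {
  cfg <- sim_config(seed = 3, chrom_sizes = c(chr1 = 1e6, chr2 = 2e5))
  g <- sim_genome(cfg, sequence = TRUE)
  expect_equal(names(g$seqs), c("chr1", "chr2"))
  expect_equal(unname(Biostrings::width(g$seqs)), c(1e6, 2e5))
  gc <- Biostrings::letterFrequency(g$seqs[1], "GC", as.prob = TRUE)
  expect_gt(gc, 0.49); expect_lt(gc, 0.51)  # binomial 99% bound at n = 1e6
  expect_error(sim_config(seed = 1, chrom_sizes = c(chr1 = 0)),
               "zero-length")
})

test_that("co-localisation contract: all PR peaks get a nearby PAX at fraction 1", {
  cfg <- small_cfg(11, colocal_fraction = 1, colocal_dist = 500)
  g <- genome_model(cfg$chrom_sizes)
  pk <- sim_peaks(cfg, g)
  mid <- function(gr) floor((start(gr) + end(gr)) / 2)
  d <- nearest_distance(pk$PR, pk$PAX)$distance
  # midpoint distance <= 500 implies edge distance < 500 for 400 bp peaks
  mids_pr <- mid(pk$PR); mids_pax <- mid(pk$PAX)
  dmid <- vapply(seq_along(pk$PR), function(i) {
    on <- as.character(seqnames(pk$PAX)) == as.character(seqnames(pk$PR)[i])
    min(abs(mids_pax[on] - mids_pr[i]))
  }, 0)
  expect_true(all(dmid <= 500))
  # at fraction 0 PAX midpoints all stay beyond colocal_dist of PR midpoints
  cfg0 <- small_cfg(12, colocal_fraction = 0, colocal_dist = 1000)
  pk0 <- sim_peaks(cfg0, g)
  dmid0 <- vapply(seq_along(pk0$PR), function(i) {
    on <- as.character(seqnames(pk0$PAX)) ==
      as.character(seqnames(pk0$PR)[i])
    if (!any(on)) return(Inf)
    min(abs(mid(pk0$PAX)[on] - mid(pk0$PR)[i]))
  }, 0)
  expect_true(all(dmid0 > 1000))
  # nearest distances at fraction 0 look like the uniform background
  # (uniform placement conditioned on staying > colocal_dist from every
  # PR midpoint, exactly what the generator promises): build such a
  # background sample independently and KS-compare
  set.seed(99)
  gl <- genome_lengths(g)
  n_per <- table(factor(as.character(seqnames(pk0$PAX)), names(gl)))
  bg_mid <- lapply(names(gl), function(ch) {
    prm <- mid(pk0$PR)[as.character(seqnames(pk0$PR)) == ch]
    got <- numeric(0)
    while (length(got) < n_per[[ch]]) {
      cand <- sample.int(gl[[ch]], 50)
      ok <- vapply(cand, function(x) all(abs(x - prm) > 1000), TRUE)
      got <- c(got, cand[ok])
    }
    sort(got[seq_len(n_per[[ch]])])
  })
  d_bg <- vapply(seq_along(pk0$PR), function(i) {
    ch <- as.character(seqnames(pk0$PR)[i])
    min(abs(bg_mid[[match(ch, names(gl))]] - mid(pk0$PR)[i]))
  }, 0)
  ks <- suppressWarnings(ks.test(dmid0, d_bg))
  expect_gt(ks$p.value, 0.01)
})

test_that("peak placement fails cleanly when the genome is saturated", {
  cfg <- sim_config(seed = 5, chrom_sizes = c(chr1 = 5000), bin_size = 1000,
                    n_pr_peaks = 50, peak_width = 400)
  expect_error(sim_peaks(cfg, genome_model(cfg$chrom_sizes)),
               "placement error")
})

test_that("TADs tile the genome on bin boundaries", {
  cfg <- small_cfg(21)
  g <- genome_model(cfg$chrom_sizes)
  tads <- sim_tads(cfg, g)
  for (ch in names(cfg$chrom_sizes)) {
    tt <- tads[as.character(seqnames(tads)) == ch]
    expect_equal(start(tt)[1], 1)
    expect_true(all(diff(start(tt)) == width(tt)[-length(tt)]))
    expect_true(all((end(tt) %% cfg$bin_size) == 0 |
                      end(tt) == genome_lengths(g)[[ch]]))
  }
})

test_that("planted loop pixels average loop_boost times the decay prediction", {
  cfg_base <- sim_config(seed = 1, chrom_sizes = c(chr1 = 2e6), n_tads = 2,
                         loop_boost = 2, contact_scale = 80)
  g <- genome_model(cfg_base$chrom_sizes)
  tads <- sim_tads(cfg_base, g)
  regions <- GRanges("chr1", IRanges(start(tads)[1] + 300000, width = 20000))
  tss <- start(tads)[1] + 700001
  sc0 <- sim_contacts(cfg_base, "chr1", 2e6, tads, regions, tss,
                      noise = FALSE)
  pg_bin <- which(sc0$classes$class == "PgCR")[1]
  ts_bin <- which(sc0$classes$class == "TSS")[1]
  d <- abs(ts_bin - pg_bin)
  decay_pred <- cfg_base$contact_scale * (1 + d)^(-cfg_base$decay_exponent)
  expect_equal(sc0$expected[pg_bin, ts_bin], 2 * decay_pred)
  # Monte-Carlo mean of the observed pixel over 200 replicate draws
  draws <- vapply(1:200, function(r) {
    cfg_r <- sim_config(seed = r, chrom_sizes = c(chr1 = 2e6), n_tads = 2,
                        loop_boost = 2, contact_scale = 80)
    sim_contacts(cfg_r, "chr1", 2e6, tads, regions, tss)$matrix@counts[
      pg_bin, ts_bin]
  }, 0)
  se <- sd(draws) / sqrt(200)
  expect_lt(abs(mean(draws) - 2 * decay_pred), 3 * se)
  # loop_boost = 1: expected equals pure decay everywhere
  cfg1 <- sim_config(seed = 1, chrom_sizes = c(chr1 = 2e6), n_tads = 2,
                     loop_boost = 1, contact_scale = 80)
  sc1 <- sim_contacts(cfg1, "chr1", 2e6, tads, regions, tss, noise = FALSE)
  dmat <- abs(row(sc1$expected) - col(sc1$expected))
  expect_equal(sc1$expected,
               cfg1$contact_scale * (1 + dmat)^(-1))
  # same seed -> identical pixel table
  a <- sim_contacts(cfg_base, "chr1", 2e6, tads, regions, tss)
  b <- sim_contacts(cfg_base, "chr1", 2e6, tads, regions, tss)
  expect_identical(a$matrix@counts, b$matrix@counts)
  expect_error(sim_config(seed = 1, chrom_sizes = c(chr1 = 5000),
                          bin_size = 20000), "bin_size")
})

test_that("expression effects concentrate near planted regions", {
  cfg <- small_cfg(31, effect_size = 1, sigma = 0.3)
  g <- genome_model(cfg$chrom_sizes)
  genes <- sim_genes(cfg, g)
  regions <- set_genome(GRanges("chr1", IRanges(1000000, 1025000)), g)
  expr <- sim_expression(cfg, genes, regions)
  expect_gt(mean(abs(expr$log2FC[expr$close])),
            mean(abs(expr$log2FC[!expr$close])))
  # q-values are consistent: large effects get small q
  expect_lt(max(expr$q[abs(expr$log2FC) > 1.2]),
            min(expr$q[abs(expr$log2FC) < 0.05]) + 1e-12)
  # no regions -> everything far
  expr0 <- sim_expression(cfg, genes, GRanges())
  expect_true(all(!expr0$close))
  expect_error(sim_config(seed = 1, sigma = 0), "sigma")
})

test_that("welch power and type-I calibration across seeds", {
  g <- genome_model(c(chr1 = 2e7))
  regions <- set_genome(GRanges("chr1", IRanges(5e6, 5025000)), g)
  run_p <- function(seed, effect) {
    cfg <- sim_config(seed = seed, chrom_sizes = c(chr1 = 2e7),
                      n_genes = 300, effect_size = effect, sigma = 0.3)
    genes <- sim_genes(cfg, g)
    expr <- sim_expression(cfg, genes, regions)
    x <- abs(expr$log2FC[expr$close]); y <- abs(expr$log2FC[!expr$close])
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    t.test(x, y, var.equal = FALSE)$p.value
  }
  # power: effect 1, sigma 0.3 -> p < 0.01 in >= 95% of seeds
  p_eff <- vapply(1:60, run_p, 0, effect = 1)
  expect_gte(mean(p_eff < 0.01, na.rm = TRUE), 0.95)
  # type I: effect 0 -> non-significant at 5% in >= 90% of seeds
  p_null <- vapply(101:200, run_p, 0, effect = 0)
  expect_gte(mean(p_null >= 0.05, na.rm = TRUE), 0.90)
})

test_that("planted compliant clusters are recovered perfectly", {
  for (seed in c(2, 9)) {
    cfg <- sim_config(seed = seed, chrom_sizes = c(chr1 = 2e7, chr2 = 2e7),
                      n_tads = 40, n_regions = 20, n_pr_peaks = 100,
                      n_pax_peaks = 80)
    scen <- sim_pgcr_scenario(cfg)
    called <- call_pgcrs(cluster_pr_sites(scen$PR), scen$PAX, scen$tads)
    expect_equal(length(called), length(scen$truth))
    expect_equal(start(called), start(scen$truth))
    expect_equal(end(called), end(scen$truth))
  }
})

test_that("simulation files round-trip through the package readers", {
  cfg <- small_cfg(41)
  g <- sim_genome(cfg, sequence = FALSE)
  pk <- sim_peaks(cfg, g$genome)
  tads <- sim_tads(cfg, g$genome)
  genes <- sim_genes(cfg, g$genome)
  expr <- sim_expression(cfg, genes, GRanges())
  d <- tempfile()
  write_simulation(list(genome = g$genome, PR = pk$PR, PAX = pk$PAX,
                        tads = tads, genes = genes, expression = expr), d)
  pr_back <- read_peaks(file.path(d, "pr.narrowPeak"), genome = g$genome)
  expect_equal(granges(pr_back), granges(pk$PR), ignore_attr = TRUE)
  expect_equal(mcols(pr_back)$summit, mcols(pk$PR)$summit)
  tads_back <- read_tads(file.path(d, "tads.bed"), genome = g$genome)
  expect_equal(granges(tads_back), granges(tads), ignore_attr = TRUE)
  genes_back <- read_gene_model(file.path(d, "genes.tsv"))
  expect_equal(genes_back$tss, genes$tss)
  expr_back <- read_expression(file.path(d, "expression.tsv"))
  expect_equal(expr_back$log2FC, expr$log2FC)
})
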