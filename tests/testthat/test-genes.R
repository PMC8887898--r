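test_that("regulatory domains follow the basal-plus-extension arithmetic", {
  # isolated + strand gene: 5 kb + 100 kb upstream, 1 kb + 100 kb downstream
  g <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                  tss = 500000, tes = 520000, biotype = "protein_coding")
  d <- build_regulatory_domains(g)
  expect_equal(d$basal_start, 495000)
  expect_equal(d$basal_end, 501000)
  expect_equal(d$domain_start, 395000)
  expect_equal(d$domain_end, 601000)
  # - strand gene: basal mirrored
  gm <- g; gm$strand <- "-"; gm$tes <- 480000
  dm <- build_regulatory_domains(gm)
  expect_equal(dm$basal_start, 499000)
  expect_equal(dm$basal_end, 505000)
  # two + strand genes 30 kb apart: extension truncated at neighbor basal
  g2 <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                   strand = "+", tss = c(500000, 530000),
                   tes = c(505000, 535000), biotype = "protein_coding")
  d2 <- build_regulatory_domains(g2)
  # upstream extension of b stops just after a's basal end (501,000)
  expect_equal(d2$domain_start[2], 501001)
  # downstream extension of a stops just before b's basal start (525,000)
  expect_equal(d2$domain_end[1], 524999)
  expect_error(build_regulatory_domains(rbind(g, g)), "duplicate")
})

test_that("domains never invade a neighbour's basal region (property)", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    g <- data.frame(gene_id = paste0("g", 1:n), chrom = "chr1",
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    tss = sort(sample.int(5e6, n)) + 2e5,
                    biotype = "protein_coding")
    g$tes <- ifelse(g$strand == "+", g$tss + 5000, g$tss - 5000)
    d <- build_regulatory_domains(g)
    violations <- 0L
    for (i in seq_len(n)) {
      js <- setdiff(seq_len(n), i)
      # overlap of domain i with each foreign basal j
      lo <- pmax(d$domain_start[i], d$basal_start[js])
      hi <- pmin(d$domain_end[i], d$basal_end[js])
      hit <- lo <= hi
      # allowed only where basal i itself reaches (basal-basal overlap)
      bad <- hit & !(lo >= d$basal_start[i] & lo <= d$basal_end[i] |
                       hi >= d$basal_start[i] & hi <= d$basal_end[i] |
                       d$basal_start[js] <= d$basal_start[i] &
                       d$basal_end[js] >= d$basal_end[i])
      violations <- violations + sum(bad)
    }
    expect_equal(violations, 0L)
    expect_true(all(d$domain_start <= d$basal_start))
    expect_true(all(d$domain_end >= d$basal_end))
  }
})

test_that("peak-gene association matches a brute-force midpoint scan", {
  genome <- toy_genome(c(chr1 = 5e6))
  set.seed(9)
  g <- data.frame(gene_id = paste0("g", 1:30), chrom = "chr1",
                  strand = sample(c("+", "-"), 30, replace = TRUE),
                  tss = sort(sample.int(4.5e6, 30)) + 2e5,
                  biotype = "protein_coding")
  g$tes <- ifelse(g$strand == "+", g$tss + 10000, g$tss - 10000)
  d <- build_regulatory_domains(g)
  peaks <- random_peaks(200, genome, seed = 10)
  assoc <- associate_peaks_to_genes(peaks, d)
  mid <- floor((start(peaks) + end(peaks)) / 2)
  brute <- unique(unlist(lapply(seq_along(peaks), function(i)
    d$gene_id[mid[i] >= d$domain_start & mid[i] <= d$domain_end])))
  expect_setequal(assoc$genes, brute)
  # a peak in the overlap of two basal domains associates to both genes
  g2 <- data.frame(gene_id = c("x", "y"), chrom = "chr1", strand = "+",
                   tss = c(1000000, 1003000), tes = c(1010000, 1013000),
                   biotype = "protein_coding")
  d2 <- build_regulatory_domains(g2)
  pk <- GRanges("chr1", IRanges(1000500, 1000600))
  expect_setequal(associate_peaks_to_genes(pk, d2)$genes, c("x", "y"))
})

test_that("regulated-gene classification applies inclusive/exclusive cuts", {
  expr <- data.frame(
    gene_id = paste0("g", 1:6),
    log2FC = c(0.9, -0.5, 0.8, -0.8, 2.0, 0.9),
    q = c(0.01, 0.001, 0.049, 0.0, 0.05, 0.9))
  out <- classify_regulated(expr, regulation_thresholds(0.8, 0.05))
  expect_equal(as.character(out$regulation),
               c("induced",        # 0.9 / 0.01
                 "non-regulated",  # below the fold cut
                 "induced",        # exactly at the cut: inclusive
                 "repressed",      # -0.8 inclusive
                 "non-regulated",  # q == q_cut: exclusive
                 "non-regulated")) # large fold, non-significant
  # pure threshold function: permutation-invariant and idempotent
  perm <- sample(nrow(expr))
  out_perm <- classify_regulated(expr[perm, ], regulation_thresholds(0.8, 0.05))
  expect_equal(as.character(out_perm$regulation),
               as.character(out$regulation)[perm])
  expect_equal(classify_regulated(out), out)
  expect_error(classify_regulated(expr[, 1:2]), "missing column")
})

test_that("association percentages use exact integer arithmetic", {
  mk_ids <- function(n) paste0("g", seq_len(n))
  # 224 of 1886 regulated genes carry a binding site -> 12%
  reg <- mk_ids(1886)
  assoc <- c(reg[1:224], paste0("x", 1:500))
  r <- intersect_associated_with_regulated(assoc, reg)
  expect_equal(r$n_intersection, 224)
  expect_equal(r$percentage, 12)
  # 199 of 950 -> 21%
  reg2 <- mk_ids(950)
  r2 <- intersect_associated_with_regulated(reg2[1:199], reg2)
  expect_equal(r2$percentage, 21)
  # disjoint -> 0 / 0%
  r3 <- intersect_associated_with_regulated(paste0("a", 1:10), reg2)
  expect_equal(r3$n_intersection, 0)
  expect_equal(r3$percentage, 0)
  # empty regulated set -> missing percentage
  expect_true(is.na(intersect_associated_with_regulated("a", character(0))$percentage))
})

test_that("PgCR-gene assignment via TADs honours biotype and containment", {
  g <- toy_genome(c(chr1 = 3e6))
  tads <- make_tad_set(set_genome(
    GRanges("chr1", IRanges(c(1, 1000001, 2000001),
                            c(1000000, 2000000, 3000000))), g))
  pgcrs <- set_genome(GRanges("chr1", IRanges(500000, 525000)), g)
  mcols(pgcrs)$tad_id <- "tad_1"
  genes <- data.frame(
    gene_id = c("pc1", "pc2", "pc3", "lnc1", "out1"),
    chrom = "chr1", strand = "+",
    tss = c(100000, 400000, 900000, 600000, 1500000),
    tes = c(110000, 410000, 910000, 610000, 1510000),
    biotype = c(rep("protein_coding", 3), "lncRNA", "protein_coding"))
  got <- genes_in_pgcr_tads(genes, tads, pgcrs)
  expect_setequal(got, c("pc1", "pc2", "pc3"))
  expect_equal(genes_in_pgcr_tads(genes, tads, pgcrs[0]), character(0))
  # brute-force containment oracle on a random fixture
  set.seed(21)
  genes_r <- data.frame(gene_id = paste0("g", 1:100), chrom = "chr1",
                        strand = "+", tss = sample.int(3e6 - 1e4, 100),
                        biotype = "protein_coding")
  genes_r$tes <- genes_r$tss + 1000
  got_r <- genes_in_pgcr_tads(genes_r, tads, pgcrs)
  brute <- genes_r$gene_id[genes_r$tss >= 1 & genes_r$tss <= 1000000]
  expect_setequal(got_r, brute)
})

test_that("distance sign, close/far split and Welch test are correct", {
  g <- toy_genome(c(chr1 = 5e6))
  pgcrs <- set_genome(GRanges("chr1", IRanges(2000000, 2025000)), g)
  genes <- data.frame(
    gene_id = c("in", "up", "down", "far"),
    chrom = "chr1", strand = "+",
    tss = c(2010000, 1500000, 2500000, 4900000),
    tes = c(2020000, 1510000, 2510000, 4910000),
    biotype = "protein_coding")
  expr <- data.frame(gene_id = genes$gene_id,
                     log2FC = c(1.2, 0.9, -1.5, 1.0),
                     q = rep(0.001, 4))
  res <- distance_fc_analysis(genes, pgcrs, expr)
  d <- res$distances
  expect_equal(d$distance[d$gene_id == "in"], 0)
  expect_lt(d$distance[d$gene_id == "up"], 0)     # TSS below midpoint
  expect_gt(d$distance[d$gene_id == "down"], 0)
  expect_equal(d$group, c("close", "close", "close", "far"))
  # Welch statistic equals the closed-form computation
  x <- c(1.2, 0.9, 1.5); y <- c(0.3, 0.4)
  tt <- t.test(x, y, var.equal = FALSE)
  orc <- oracle_welch(x, y)
  expect_equal(unname(tt$statistic), orc$statistic, tolerance = 1e-12)
  expect_equal(unname(tt$parameter), orc$df, tolerance = 1e-12)
  expect_equal(tt$p.value, orc$p, tolerance = 1e-12)
  # no PgCRs -> everything far
  res0 <- distance_fc_analysis(genes, pgcrs[0], expr)
  expect_true(all(res0$distances$group == "far"))
})

test_that("bootstrap null matches the hypergeometric expectation", {
  # tiny closed-form case: N = 10, K = 4, n = 5 -> mean 2.0
  uni <- paste0("g", 1:10)
  bt <- bootstrap_intersection(uni, 5, uni[1:4], iters = 10000, seed = 1)
  se <- sqrt(5 * 0.4 * 0.6 * (10 - 5) / (10 - 1) / 10000)
  expect_lt(abs(bt$null_mean - 2.0), 3 * se)
  # 20 random configurations
  set.seed(77)
  for (rep in 1:20) {
    N <- sample(50:400, 1)
    K <- sample.int(N - 1, 1)
    n <- sample.int(N, 1)
    uni <- paste0("u", seq_len(N))
    bt <- bootstrap_intersection(uni, n, uni[seq_len(K)],
                                 iters = 2000, seed = rep)
    mu <- n * K / N
    v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
    tol <- 3 * sqrt(v / 2000) + 1e-9
    expect_lt(abs(bt$null_mean - mu), tol)
    expect_true(all(bt$percentile_ci == round(bt$percentile_ci)))
    expect_lte(bt$percentile_ci[1], bt$percentile_ci[2])
  }
})

test_that("bootstrap contract: degenerate target, determinism, errors", {
  uni <- paste0("g", 1:50)
  bt <- bootstrap_intersection(uni, 7, uni, iters = 500, seed = 3)
  expect_equal(bt$null_mean, 7)
  expect_equal(bt$percentile_ci, c(7L, 7L))
  bt1 <- bootstrap_intersection(uni, 10, uni[1:20], observed = 9,
                                iters = 1000, seed = 5)
  bt2 <- bootstrap_intersection(uni, 10, uni[1:20], observed = 9,
                                iters = 1000, seed = 5)
  expect_identical(bt1$null_draws, bt2$null_draws)
  expect_true(bt1$empirical_p >= 0 && bt1$empirical_p <= 1)
  expect_error(bootstrap_intersection(uni, 5, c(uni[1], "zz"), iters = 10,
                                      seed = 1),
               "not in universe.*zz")
  expect_error(bootstrap_intersection(uni, 51, uni[1], iters = 10, seed = 1),
               "exceeds")
})

test_that("welch test calibrated under the null (type I <= 7%)", {
  set.seed(123)
  rej <- vapply(1:200, function(i) {
    x <- rnorm(40); y <- rnorm(35)
    t.test(x, y, var.equal = FALSE)$p.value < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.07)
})
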