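#' Run the end-to-end PgCR analysis pipeline
#'
#' Stages: load (or simulate) inputs -> q-filter peaks -> cluster PR sites
#' and call PgCRs -> GREAT-style gene association and intersection with
#' regulated genes -> PgCR-gene assignment via TADs and distance /
#' fold-change comparison -> bootstrap intersection test -> optional
#' intra-TAD Hi-C enrichment -> report bundle. Inputs are validated
#' before any computation; all outputs (TSV/JSON) plus a manifest with
#' parameter values, seeds and input checksums are written to
#' `config$outdir`, and re-running an identical config reproduces
#' identical files.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{inputs}{either `simulate: {seed: <int>, ...sim_config
#'       overrides}` or file paths `pr`, `pax`, `tads`, `genes`,
#'       `expression` (and optionally `bins`, `pixels`).}
#'     \item{pgcr}{[pgcr_params()] overrides.}
#'     \item{great}{[great_params()] overrides.}
#'     \item{regulation}{[regulation_thresholds()] overrides.}
#'     \item{qfilter}{peak q-value cut (default 1e-5).}
#'     \item{bootstrap}{`iters` (default 10,000) and `seed`.}
#'     \item{outdir}{output directory.}
#'   }
#' @return the report list, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .assert(!is.null(config$outdir), "config$outdir is required")
  inputs <- config$inputs %||% stop("config$inputs is required")

  # fail fast: every referenced file must exist before any compute
  file_keys <- intersect(names(inputs),
                         c("pr", "pax", "tads", "genes", "expression",
                           "genome", "bins", "pixels"))
  for (k in file_keys)
    .assert(file.exists(inputs[[k]]),
            "input file missing at validation: ", k, " = ", inputs[[k]])

  pg_par <- do.call(pgcr_params, config$pgcr %||% list())
  gr_par <- do.call(great_params, config$great %||% list())
  thr <- do.call(regulation_thresholds, config$regulation %||% list())
  q_cut <- config$qfilter %||% 1e-5
  boot <- config$bootstrap %||% list()
  boot_iters <- boot$iters %||% 10000
  boot_seed <- boot$seed %||% 1L

  log_stage <- function(...) message("[pipeline] ", ...)

  if (!is.null(inputs$simulate)) {
    sim_args <- inputs$simulate
    cfg <- do.call(sim_config, sim_args)
    log_stage("simulating inputs (seed ", cfg$seed, ")")
    scen <- sim_pgcr_scenario(cfg, pg_par)
    genome <- scen$genome
    pr <- scen$PR; pax <- scen$PAX
    tads <- scen$tads
    genes <- sim_genes(cfg, genome)
    expr <- sim_expression(cfg, genes, scen$truth)
    truth <- scen$truth
  } else {
    genome <- if (!is.null(inputs$genome)) read_genome(inputs$genome) else NULL
    pr <- read_peaks(inputs$pr, genome = genome, label = "PRbs")
    pax <- read_peaks(inputs$pax, genome = genome, label = "PAXbs")
    tads <- read_tads(inputs$tads, genome = genome)
    genes <- read_gene_model(inputs$genes)
    expr <- read_expression(inputs$expression)
    truth <- NULL
  }

  log_stage("q-filtering peaks at q < ", q_cut)
  n_pr_in <- length(pr); n_pax_in <- length(pax)
  if (!is.null(mcols(pr)$qvalue)) pr <- filter_q(pr, q_cut)
  if (!is.null(mcols(pax)$qvalue)) pax <- filter_q(pax, q_cut)
  log_stage("PR peaks ", n_pr_in, " -> ", length(pr),
            "; PAX peaks ", n_pax_in, " -> ", length(pax))

  log_stage("clustering PR sites and calling PgCRs")
  clusters <- cluster_pr_sites(pr, pg_par)
  pgcrs <- call_pgcrs(clusters, pax, tads, pg_par)
  stats <- pgcr_stats(pgcrs, tads, flank = pg_par$flank)
  log_stage(length(clusters), " candidate clusters -> ",
            length(pgcrs), " PgCRs")

  log_stage("gene association (basal plus extension)")
  domains <- build_regulatory_domains(genes, gr_par)
  assoc <- associate_peaks_to_genes(pr, domains)
  expr_cls <- classify_regulated(expr, thr)
  regulated <- expr_cls$gene_id[expr_cls$regulation != "non-regulated"]
  assoc_vs_reg <- intersect_associated_with_regulated(assoc$genes, regulated)

  log_stage("PgCR-gene assignment and distance/fold-change analysis")
  pgcr_genes <- genes_in_pgcr_tads(genes, tads, pgcrs)
  dfc <- distance_fc_analysis(genes, pgcrs, expr, thr)

  log_stage("bootstrap intersection test (", boot_iters, " draws)")
  coding <- genes$gene_id[genes$biotype == "protein_coding"]
  target <- intersect(pgcr_genes, coding)
  draw_set <- intersect(regulated, coding)
  bt <- if (length(draw_set) >= 1 && length(coding) >= length(draw_set)) {
    bootstrap_intersection(coding, length(draw_set), target,
                           observed = length(intersect(draw_set, target)),
                           iters = boot_iters, seed = boot_seed)
  } else NULL

  hic <- NULL
  if (!is.null(inputs$bins) && !is.null(inputs$pixels)) {
    log_stage("intra-TAD contact enrichment")
    mats <- read_contacts(inputs$bins, inputs$pixels)
    hic <- lapply(names(mats), function(ch) {
      m <- mats[[ch]]
      cls <- bin_class_map(ch, n_bins(m), m@bin_size, tads, pgcrs,
                           genes$tss[genes$chrom == ch])
      intra_tad_enrichment(m, cls)$log2_enrichment
    })
    names(hic) <- names(mats)
  }

  report <- make_report(list(
    params = list(pgcr = unclass(pg_par), great = unclass(gr_par),
                  regulation = unclass(thr), qfilter = q_cut,
                  bootstrap = list(iters = boot_iters, seed = boot_seed)),
    peaks = list(pr_in = n_pr_in, pr_kept = length(pr),
                 pax_in = n_pax_in, pax_kept = length(pax)),
    clusters = clusters, pgcrs = pgcrs, pgcr_stats = stats,
    association = assoc_vs_reg,
    n_associated_genes = length(assoc$genes),
    regulation = table(expr_cls$regulation),
    pgcr_genes = pgcr_genes, distance_fc = dfc, bootstrap = bt,
    hic = hic, truth = truth))

  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  atomic_write <- function(writer, path) {
    tmp <- paste0(path, ".tmp")
    writer(tmp)
    file.rename(tmp, path)
  }
  if (length(pgcrs))
    atomic_write(function(f) write_pgcrs(pgcrs, f),
                 file.path(outdir, "pgcrs.bed"))
  atomic_write(function(f) write.table(dfc$distances, f, sep = "\t",
                                       quote = FALSE, row.names = FALSE),
               file.path(outdir, "gene_distances.tsv"))
  atomic_write(function(f) jsonlite::write_json(
    report, f, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"),
    file.path(outdir, "report.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pgcrtools")),
    parameters = report$parameters,
    seeds = list(simulate = (inputs$simulate %||% list())$seed,
                 bootstrap = boot_seed),
    input_checksums = if (length(file_keys))
      as.list(tools::md5sum(unlist(inputs[file_keys]))) else list())
  atomic_write(function(f) jsonlite::write_json(
    manifest, f, auto_unbox = TRUE, pretty = TRUE, na = "null"),
    file.path(outdir, "manifest.json"))
  invisible(report)
}

#' Assemble the pipeline summary report
#'
#' Collapses stage outputs into the headline numbers: PgCR count and mean
#' size, association percentages, regulated-gene counts, the close/far
#' Welch comparison, the bootstrap null mean / CI / observed value, and
#' intra-TAD enrichment log-ratios. Percentages in the report are always
#' recomputed from the counts shown next to them.
#'
#' @param stages named list of stage outputs (see [run_pipeline()]).
#' @return a nested report list.
#' @export
make_report <- function(stages) {
  st <- stages$pgcr_stats
  assoc <- stages$association
  bt <- stages$bootstrap
  dfc <- stages$distance_fc
  recovery <- NULL
  if (!is.null(stages$truth)) {
    pg <- stages$pgcrs
    tr <- stages$truth
    matched <- sum(overlapsAny(tr, pg))
    extra <- sum(!overlapsAny(pg, tr))
    recovery <- list(planted = length(tr), recovered = matched,
                     sensitivity = matched / max(1L, length(tr)),
                     false_discoveries = extra,
                     fdr = if (length(pg)) extra / length(pg) else 0)
  }
  list(
    parameters = stages$params,
    peak_filtering = stages$peaks,
    pgcrs = list(n_candidate_clusters = length(stages$clusters),
                 count = st$count,
                 mean_size_bp = st$mean_size,
                 mean_relative_position = if (length(st$relative_position))
                   mean(st$relative_position) else NA),
    association = list(n_associated_genes = stages$n_associated_genes,
                       n_regulated = assoc$n_regulated,
                       n_intersection = assoc$n_intersection,
                       percentage = assoc$percentage),
    regulation = as.list(stages$regulation),
    pgcr_genes = list(count = length(stages$pgcr_genes)),
    distance_fc = list(n_close = sum(dfc$distances$group == "close"),
                       n_far = sum(dfc$distances$group == "far"),
                       welch = dfc$welch),
    bootstrap = if (is.null(bt)) NULL else
      bt[c("draws", "null_mean", "percentile_ci", "observed",
           "empirical_p", "universe_size", "target_size", "n_draw")],
    hic = stages$hic,
    recovery = recovery)
}
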