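#' Run the full differential-methylation pipeline
#'
#' Orchestrates every stage end-to-end: island detection and probe
#' annotation, probe filtering, beta computation (when intensities rather
#' than betas are supplied), paired testing with optional maxT adjustment,
#' direction calls, fold-change candidate selection, cross-tabulations and
#' percentage summaries, heat-map matrix export, and (when pathway and
#' target-map inputs are given) per-miR over-representation analysis.
#' Every intermediate table is written under `out_dir` and a
#' machine-readable JSON report records input hashes, thresholds, the
#' seed, per-stage row counts and output paths. Identical configurations
#' (including the seed) produce identical outputs.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \describe{
#'   \item{simulate}{optional list of [sim_config()] arguments; when
#'     present, all inputs are generated synthetically and the report
#'     gains a ground-truth block (recall/precision of planted sites).}
#'   \item{paths}{for file-based runs: `genome` (FASTA), `manifest`
#'     (TSV), either `tumor_betas`/`normal_betas` or
#'     `meth`/`unmeth`/`pairing` (TSV), `gene_models` (TSV), optional
#'     `pathways` (GMT) and `target_map` (TSV).}
#'   \item{thresholds}{`alpha` (0.05), `min_abs_fc` (2), `offset` (100),
#'     `pseudo` (0.01).}
#'   \item{maxt}{`use_maxt` (FALSE), `gate_maxt` (FALSE), `n_perm`
#'     (10000), `seed` (mandatory when any stochastic stage is enabled).}
#'   \item{out_dir}{output directory (created).}
#' }
#'
#' @param config Path to a YAML config file, or a list as described.
#' @return The run report (list), invisibly; also written as
#'   `report.json` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config field missing: out_dir")
  thr <- utils::modifyList(list(alpha = 0.05, min_abs_fc = 2,
                                offset = 100, pseudo = 0.01),
                           config$thresholds %||% list())
  mx <- utils::modifyList(list(use_maxt = FALSE, gate_maxt = FALSE,
                               n_perm = 10000L, seed = NULL),
                          config$maxt %||% list())
  simulate <- !is.null(config$simulate)
  if ((simulate || isTRUE(mx$use_maxt)) &&
      is.null(mx$seed) && is.null(config$simulate$seed))
    stop("config field missing: seed (required for stochastic stages)")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(thresholds = thr, maxt = mx[c("use_maxt", "gate_maxt",
                                               "n_perm")],
                 seed = mx$seed, stages = list(), outputs = list())

  if (simulate) {
    cfg <- do.call(sim_config, config$simulate)
    study <- simulate_study(cfg)
    genome <- stats::setNames(study$genome$sequence, study$genome$chrom)
    gene_models <- study$genome$gene_models
    manifest <- study$manifest
    tumor <- study$betas$tumor; normal <- study$betas$normal
    truth <- study$betas$truth
    if (is.null(mx$seed)) mx$seed <- cfg$seed
    report$seed <- mx$seed
    write_genome_fasta(study$genome$sequence, study$genome$chrom,
                       out("genome.fa"))
    write_table_tsv(gene_models, out("gene_models.tsv"))
    write_table_tsv(manifest, out("manifest.tsv"))
    write_matrix_tsv(tumor, out("tumor_betas.tsv"))
    write_matrix_tsv(normal, out("normal_betas.tsv"))
    write_table_tsv(truth, out("truth.tsv"))
  } else {
    p <- config$paths
    for (f in c("genome", "manifest", "gene_models"))
      if (is.null(p[[f]])) stop("config field missing: paths$", f)
    have_betas <- !is.null(p$tumor_betas) && !is.null(p$normal_betas)
    if (!have_betas &&
        (is.null(p$meth) || is.null(p$unmeth) || is.null(p$pairing)))
      stop("config field missing: paths$tumor_betas/normal_betas ",
           "or paths$meth/unmeth/pairing")
    files <- unlist(p)
    missing_files <- files[!file.exists(files)]
    if (length(missing_files))
      stop("input file(s) not found: ", paste(missing_files, collapse = ", "))
    report$input_hashes <- as.list(tools::md5sum(files))
    genome <- read_genome_fasta(p$genome)
    gene_models <- read_table_tsv(p$gene_models)
    manifest <- read_table_tsv(p$manifest)
    if (have_betas) {
      tumor <- read_matrix_tsv(p$tumor_betas)
      normal <- read_matrix_tsv(p$normal_betas)
    } else {
      meth <- read_matrix_tsv(p$meth); unmeth <- read_matrix_tsv(p$unmeth)
      betas <- compute_beta(meth, unmeth, offset = thr$offset)
      pairing <- read_table_tsv(p$pairing)
      tumor <- betas[, pairing$tumor_id, drop = FALSE]
      normal <- betas[, pairing$normal_id, drop = FALSE]
    }
    truth <- NULL
  }

  # --- annotate ------------------------------------------------------------
  islands <- do.call(rbind, lapply(names(genome), function(ch)
    detect_cpg_islands(genome[[ch]], chrom = ch)))
  write_islands_bed(islands, out("islands.bed"))
  ann <- annotate_probes(manifest, islands, gene_models,
                         known_chroms = names(genome))
  write_table_tsv(ann, out("annotations.tsv"))
  report$stages$annotate <- list(n_islands = nrow(islands),
                                 n_probes = nrow(ann),
                                 n_rejected = length(attr(ann, "rejects")))

  # --- filter --------------------------------------------------------------
  flt <- filter_probes(manifest)
  keep <- rownames(tumor) %in% flt$kept
  tumor <- tumor[keep, , drop = FALSE]
  normal <- normal[keep, , drop = FALSE]
  report$stages$filter <- as.list(flt$report)

  # --- test ----------------------------------------------------------------
  results <- call_sites(tumor, normal, alpha = thr$alpha,
                        use_maxt = isTRUE(mx$use_maxt),
                        gate_maxt = isTRUE(mx$gate_maxt),
                        n_perm = mx$n_perm, seed = mx$seed,
                        pseudo = thr$pseudo)
  write_table_tsv(results, out("site_results.tsv"))
  n_sig <- sum(results$direction != "none")
  report$stages$test <- list(n_probes = nrow(results), n_significant = n_sig,
                             n_hyper = sum(results$direction == "hyper"),
                             n_hypo = sum(results$direction == "hypo"))

  # --- select --------------------------------------------------------------
  selected <- select_fold_candidates(results, min_abs_fc = thr$min_abs_fc)
  write_table_tsv(selected, out("fold_candidates.tsv"))
  report$stages$select <- list(n_selected = nrow(selected))

  # --- tabulate ------------------------------------------------------------
  ct_all <- crosstab_region(results, ann, subset = "all")
  ct_mir <- crosstab_region(results, ann, subset = "mir_only")
  ft <- crosstab_features(results, ann)
  write_table_tsv(cbind(chrom = rownames(ct_all$counts), ct_all$counts),
                  out("crosstab_region_all.tsv"))
  write_table_tsv(cbind(chrom = rownames(ct_mir$counts), ct_mir$counts),
                  out("crosstab_region_mir.tsv"))
  write_table_tsv(cbind(feature = rownames(ft), ft),
                  out("crosstab_features.tsv"))
  pct <- if (ct_all$grand > 0) summarize_percentages(ct_all) else NULL
  report$stages$tabulate <- list(
    grand_total = ct_all$grand, mir_total = ct_mir$grand,
    region_pct = as.list(pct$region_pct),
    direction_pct = as.list(pct$direction_pct))
  mir_sel <- selected[vapply(seq_len(nrow(selected)), function(j) {
    i <- match(selected$probe_id[j], ann$probe_id)
    isTRUE(ann$is_mir[i])
  }, logical(1)), , drop = FALSE]
  export_heatmap_matrix(mir_sel, ann, out("heatmap_matrix.tsv"))

  # --- enrich --------------------------------------------------------------
  if (!simulate && !is.null(config$paths$pathways) &&
      !is.null(config$paths$target_map)) {
    pathways <- read_gmt(config$paths$pathways)
    tmap <- read_target_map(config$paths$target_map)
    per_mir <- lapply(tmap, hypergeom_ora, pathways = pathways)
    counts <- pathway_mir_counts(per_mir, alpha = thr$alpha)
    write_table_tsv(counts$per_mir, out("pathways_per_mir.tsv"))
    write_table_tsv(counts$per_pathway, out("mirs_per_pathway.tsv"))
    report$stages$enrich <- list(n_mirs = length(per_mir),
                                 n_pathways = length(pathways))
  }

  # --- ground truth --------------------------------------------------------
  if (simulate) {
    tr <- truth[match(results$probe_id, truth$probe_id), ]
    called <- results$direction != "none"
    planted <- tr$true_direction != "null"
    hit <- called & planted & results$direction == tr$true_direction
    report$ground_truth <- list(
      n_planted = sum(planted),
      recall = if (sum(planted)) sum(hit) / sum(planted) else NA,
      precision = if (sum(called)) sum(hit & called) / sum(called) else NA)
  }

  report$outputs <- as.list(list.files(config$out_dir, full.names = TRUE))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
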