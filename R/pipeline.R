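#' Default pipeline parameters
#'
#' All thresholds of the workflow with their standard values: membership
#' threshold 0.60, overview bin 0.5 cM, physical half-window 0.5 Mbp, MTA
#' significance `-log10 p >= 5`, DEG thresholds `|log2FC| >= 1` and
#' `FDR < 0.05`, nine fuzzy clusters with fuzzifier 2, required promoter
#' element ABRE.
#'
#' @return Named list of parameters.
#' @export
default_params <- function() {
  list(seed = 1,
       ci_policy = "prefer_reported",
       extrapolation_limit_cm = 5,
       membership_threshold = 0.60,
       overview_bin_cm = 0.5,
       kmax_cap = 12,
       n_starts = 20,
       em_tol = 1e-8,
       half_window_bp = 500000,
       mta_threshold = 5.0,
       lfc_min = 1.0,
       fdr_max = 0.05,
       n_clusters = 9,
       fuzzifier = 2.0,
       membership_min = 0.5,
       containment = "any",
       required_motif = "ABRE",
       genotypes = c("mutant", "wildtype"))
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) mq_format_error(
      sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  params <- default_params()
  for (nm in names(config$params %||% list()))
    params[[nm]] <- config$params[[nm]]
  config$params <- params
  config
}

#' Run the full meta-QTL to candidate-gene pipeline
#'
#' Executes the stages in order — compendium standardization, consensus
#' map and projection, chromosome-wise meta-analysis, GWAS validation, and
#' the candidate-gene funnel — writing each stage's outputs before the
#' next starts, and returns a summary report.
#'
#' @param config Either a YAML file path or a list with elements:
#'   `inputs` (named paths `qtl_table maps anchors mtas genome genes
#'   deg_stats expression`) or `simulation` (arguments to [sim_config()];
#'   the bundle is generated under `<out_dir>/inputs` and then read back
#'   through the standard readers); `params` (overrides of
#'   [default_params()]); `out_dir` (output directory).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return List of class `mqtl_pipeline`: `report` (named summary
#'   fields), `mqtls`, `validation`, `decgs`, `stages` (intermediate
#'   objects), `truth` (when simulated).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- resolve_config(config)
  p <- config$params
  out_dir <- out_dir %||% config$out_dir %||% tempfile("mqtl_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(config$simulation)) {
    cfg <- do.call(sim_config, config$simulation)
    bundle <- write_input_bundle(cfg, file.path(out_dir, "inputs"))
    truth <- bundle$truth_data
    inputs <- bundle[setdiff(names(bundle), "truth_data")]
  } else {
    inputs <- config$inputs
    if (is.null(inputs)) mq_format_error(
      "config must provide either 'inputs' or 'simulation'")
  }

  # stage 1: compendium
  qtls <- read_qtl_table(inputs$qtl_table)
  qtls <- standardize_qtls(qtls, policy = p$ci_policy)
  write_qtl_table(qtls, file.path(out_dir, "qtls_standardized.tsv"))

  # stage 2: consensus map + projection
  maps <- read_genetic_maps(inputs$maps)
  consensus <- merge_maps(maps)
  write_consensus_map(consensus, file.path(out_dir, "consensus_map.tsv"))
  projected <- project_qtls(qtls, maps, consensus,
                            extrapolation_limit = p$extrapolation_limit_cm)

  # stage 3: meta-analysis
  meta <- run_meta_analysis(projected, kmax_cap = p$kmax_cap,
                            threshold = p$membership_threshold,
                            n_starts = p$n_starts, tol = p$em_tol,
                            seed = p$seed,
                            bin_width_cm = p$overview_bin_cm)
  write_tsv(meta$mqtls, file.path(out_dir, "mqtls.tsv"))
  write_tsv(meta$model_selection, file.path(out_dir, "model_selection.tsv"))
  write_tsv(meta$overview, file.path(out_dir, "overview_index.tsv"))

  # stage 4: GWAS validation
  anchors <- read_marker_anchors(inputs$anchors)
  genome <- Biostrings::readDNAStringSet(inputs$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrom_lengths <- setNames(Biostrings::width(genome), names(genome))
  windows <- anchor_mqtls(meta$mqtls, meta$membership, qtls, anchors,
                          consensus = consensus,
                          half_window = p$half_window_bp,
                          chrom_lengths_bp = chrom_lengths)
  write_tsv(windows, file.path(out_dir, "mqtl_windows.tsv"))
  mtas <- read_mta_table(inputs$mtas)
  coloc <- colocalize(windows, mtas, threshold = p$mta_threshold)
  write_tsv(coloc$summary, file.path(out_dir, "validation_summary.tsv"))
  jsonlite::write_json(
    list(validated_fraction = coloc$validated_fraction,
         n_validated = sum(coloc$summary$validated)),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)

  # stage 5: candidate-gene funnel
  genes <- read_gene_models(inputs$genes)
  deg_stats <- read_deg_stats(inputs$deg_stats)
  expr <- read_expression_table(inputs$expression)
  gw <- genes_in_windows(genes, windows, containment = p$containment)
  deg_ids <- filter_degs(deg_stats, lfc_min = p$lfc_min,
                         fdr_max = p$fdr_max)
  inter <- intersect(unique(gw$gene_id), deg_ids)
  sig <- list(cluster = NA_integer_, genes = character(0))
  clu <- NULL
  if (length(inter) >= 2) {
    prof <- expression_profiles(expr[expr$gene_id %in% inter, ],
                                genotypes = p$genotypes)
    std <- standardize_profiles(prof)
    cc <- min(p$n_clusters, nrow(std))
    if (nrow(std) >= 2 && cc >= 1) {
      clu <- fuzzy_cmeans(std, c = cc, m = p$fuzzifier, seed = p$seed)
      sig <- select_signature_cluster(clu, std, genotypes = p$genotypes,
                                      membership_min = p$membership_min)
    }
  }
  motifs <- load_cre_motifs()
  decgs <- if (length(sig$genes) > 0) {
    proms <- extract_promoters(genes[genes$gene_id %in% sig$genes, ],
                               genome)
    screen_decgs(sig$genes, proms, motifs,
                 required_motif = p$required_motif, gene_windows = gw,
                 deg_stats = deg_stats, cluster_id = sig$cluster)
  } else {
    screen_decgs(character(0), Biostrings::DNAStringSet(), motifs,
                 required_motif = p$required_motif)
  }
  write_tsv(decgs, file.path(out_dir, "decgs.tsv"))

  # report
  in_ci <- projected$ci_high_cm - projected$ci_low_cm
  mq_ci <- meta$mqtls$ci_high_cm - meta$mqtls$ci_low_cm
  fold_by_chr <- vapply(split(seq_len(nrow(projected)), projected$chr),
    function(idx) {
      ch <- projected$chr[idx[1]]
      mqc <- mq_ci[meta$mqtls$chr == ch]
      if (length(mqc) == 0) return(NA_real_)
      mean(in_ci[idx]) / mean(mqc)
    }, numeric(1))
  fold_by_chr <- fold_by_chr[is.finite(fold_by_chr)]
  report <- list(
    n_qtls_in = nrow(qtls),
    n_qtls_projected = nrow(projected),
    n_mqtls = nrow(meta$mqtls),
    mean_input_ci_cm = mean(in_ci),
    mean_mqtl_ci_cm = if (nrow(meta$mqtls) > 0) mean(mq_ci) else NA_real_,
    ci_reduction_pct = if (nrow(meta$mqtls) > 0)
      100 * (1 - mean(mq_ci) / mean(in_ci)) else NA_real_,
    reduction_fold_range = if (length(fold_by_chr) > 0)
      range(fold_by_chr) else c(NA_real_, NA_real_),
    n_mqtls_validated = sum(coloc$summary$validated),
    validated_fraction = coloc$validated_fraction,
    n_genes_in_windows = length(unique(gw$gene_id)),
    n_degs = length(deg_ids),
    n_intersection = length(inter),
    signature_cluster = sig$cluster,
    signature_cluster_size = length(sig$genes),
    n_decgs = nrow(decgs))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c("meta-QTL pipeline report",
               sprintf("  %-24s %s", names(report),
                       vapply(report, function(v)
                         paste(format(v, digits = 6), collapse = " - "),
                         character(1)))),
             file.path(out_dir, "report.txt"))
  structure(list(report = report, mqtls = meta$mqtls, validation = coloc,
                 decgs = decgs, truth = truth, out_dir = out_dir,
                 stages = list(qtls = qtls, consensus = consensus,
                               projected = projected, meta = meta,
                               windows = windows, gene_windows = gw,
                               deg_ids = deg_ids, intersection = inter,
                               clustering = clu, signature = sig)),
            class = "mqtl_pipeline")
}

#' @export
print.mqtl_pipeline <- function(x, ...) {
  r <- x$report
  cat("meta-QTL pipeline run\n")
  cat(sprintf("  QTLs in/projected: %d / %d\n", r$n_qtls_in,
              r$n_qtls_projected))
  cat(sprintf("  MQTLs: %d (mean CI %.2f cM vs input %.2f cM, %.1f%% reduction)\n",
              r$n_mqtls, r$mean_mqtl_ci_cm, r$mean_input_ci_cm,
              r$ci_reduction_pct))
  cat(sprintf("  validated by MTAs: %d (%.1f%%)\n", r$n_mqtls_validated,
              100 * r$validated_fraction))
  cat(sprintf("  genes in windows: %d; DEGs: %d; intersection: %d\n",
              r$n_genes_in_windows, r$n_degs, r$n_intersection))
  cat(sprintf("  signature cluster: %s (%d genes); DECGs: %d\n",
              ifelse(is.na(r$signature_cluster), "none",
                     r$signature_cluster),
              r$signature_cluster_size, r$n_decgs))
  invisible(x)
}
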