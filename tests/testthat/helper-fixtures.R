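# fixture builders; everything is generated in code at test time

write_map_tsv <- function(maps_df, path = tempfile(fileext = ".tsv")) {
  write.table(data.frame(map_id = maps_df$map_id, chr = maps_df$chr,
                         marker = maps_df$marker,
                         position_cM = maps_df$position_cm),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_map <- function(map_id, markers, positions, chr = 1L) {
  data.frame(map_id = map_id, chr = chr, marker = markers,
             position_cm = positions, stringsAsFactors = FALSE)
}

# one canonical QTL row with overridable fields
make_qtl <- function(...) {
  base <- data.frame(qtl_id = "Q1", study_id = "S1", trait = "root length",
                     chr = 1L, peak_cm = 40, ci_low_cm = NA_real_,
                     ci_high_cm = NA_real_, lod = 3.2, pve = 0.1,
                     pop_type = "F2", pop_size = 200L, marker_left = "M1",
                     marker_right = "M2", map_id = "mapA",
                     condition = "drought", stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# projected panel straight from the generator, for meta-analysis tests
make_projected_panel <- function(seed, loci_cm = c(20, 60, 100),
                                 per_locus = c(20, 20), chrom_len_cm = 120,
                                 s_range = c(0.5, 2)) {
  cfg <- sim_config(seed = seed, n_chromosomes = 1,
                    chrom_len_cm = chrom_len_cm,
                    true_mqtls = data.frame(chr = 1, cm = loci_cm),
                    qtls_per_locus = per_locus, s_range = s_range)
  pan <- simulate_qtl_panel(cfg)
  tf <- tempfile(fileext = ".tsv")
  write_qtl_table(pan$qtls, tf)
  qtls <- standardize_qtls(read_qtl_table(tf))
  maps <- read_genetic_maps(write_map_tsv(pan$maps))
  consensus <- merge_maps(maps)
  projected <- project_qtls(qtls, maps, consensus)
  list(cfg = cfg, panel = pan, qtls = qtls, maps = maps,
       consensus = consensus, projected = projected)
}

# small funnel-scale simulation configuration (one 40 cM chromosome,
# ~10 Mb genome, loci on anchor markers)
funnel_sim_args <- function(seed, noise_sd = 0.3) {
  list(seed = seed, n_chromosomes = 1, chrom_len_cm = 40,
       true_mqtls = data.frame(chr = 1, cm = c(10, 25)),
       qtls_per_locus = c(8, 12), mta_planted_fraction = 1,
       n_candidates = 6, decoys_per_class = 3, n_background_genes = 6,
       expression_noise_sd = noise_sd)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# run only the candidate funnel from a generated bundle (truth windows),
# skipping the QTL/meta/GWAS stages; returns found vs planted DECGs
run_funnel_only <- function(sim_args, n_clusters = 4) {
  cfg <- do.call(sim_config, sim_args)
  tw <- true_windows(cfg)
  gex <- simulate_genome_and_expression(cfg, tw)
  windows <- data.frame(mqtl_id = tw$locus_id, chr = tw$chr,
                        start_bp = tw$start_bp, end_bp = tw$end_bp)
  genes <- gex$genes
  gw <- genes_in_windows(genes, windows)
  deg_ids <- filter_degs(gex$deg_stats)
  inter <- intersect(unique(gw$gene_id), deg_ids)
  prof <- expression_profiles(
    gex$expression[gex$expression$gene_id %in% inter, ])
  std <- standardize_profiles(prof)
  clu <- fuzzy_cmeans(std, c = min(n_clusters, nrow(std)), seed = cfg$seed)
  sig <- select_signature_cluster(clu, std)
  proms <- extract_promoters(genes[genes$gene_id %in% sig$genes, ],
                             gex$genome)
  decgs <- screen_decgs(sig$genes, proms, load_cre_motifs(),
                        gene_windows = gw, deg_stats = gex$deg_stats,
                        cluster_id = sig$cluster)
  list(found = decgs$gene_id, planted = gex$truth$decgs,
       classes = gex$truth$classes, stages = list(
        gw = gw, deg_ids = deg_ids, inter = inter, sig = sig))
}
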