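#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' desk-scale multi-study QTL panel: several studies re-detect a small set
#' of planted loci with positional noise whose magnitude is exactly
#' formula-consistent (each QTL's positional sd `s` is drawn from
#' `s_range`, its CI width is `3.92 s`, and `R^2` is back-solved from the
#' population-specific CI formula given the drawn population size, so the
#' compendium, the CI standardization and the planted noise agree).
#'
#' @param seed Integer master seed; every generator output is a
#'   deterministic function of it.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_len_cm Chromosome length (cM).
#' @param bp_per_cm Physical-to-genetic scaling (bp per cM).
#' @param true_mqtls `data.frame` `chr cm` of planted loci; default three
#'   evenly spread loci per chromosome (20, 60 and 100 cM on the default
#'   120 cM chromosome).
#' @param min_locus_sep_cm Minimum separation enforced between planted
#'   loci on a chromosome.
#' @param n_studies Number of simulated mapping studies.
#' @param qtls_per_locus `c(min, max)` QTLs each locus contributes.
#' @param population_mix Named sampling weights over population types.
#' @param n_range `c(min, max)` population sizes.
#' @param s_range `c(min, max)` positional standard deviations (cM).
#' @param marker_spacing_cm Anchor-marker spacing on the true map.
#' @param marker_jitter_sd Per-study marker-position jitter sd (cM).
#' @param marker_drop_prob Probability a study map omits an interior
#'   marker.
#' @param n_control_qtls Extra well-watered-control rows written to the
#'   compendium (the reader must drop them).
#' @param n_mta_panels Number of GWAS panels.
#' @param snps_per_panel Background SNPs per panel.
#' @param mta_planted_fraction Fraction of true windows that receive a
#'   significant planted SNP.
#' @param mtas_per_window `c(min, max)` significant SNPs per planted
#'   window.
#' @param n_candidates Planted candidate genes (pass every funnel stage).
#' @param decoys_per_class Decoy genes per class; each decoy class
#'   violates exactly one funnel condition (in-window non-DEG,
#'   out-of-window DEG, signature without the required element, element
#'   without signature).
#' @param n_background_genes Additional genes outside windows.
#' @param gene_len_bp Gene body length.
#' @param expression_noise_sd Gaussian noise sd added to expression
#'   profiles (FPKM units).
#' @param half_window_bp Physical half-window used for the truth windows.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 2,
                       chrom_len_cm = 120,
                       bp_per_cm = 250000,
                       true_mqtls = NULL,
                       min_locus_sep_cm = 10,
                       n_studies = 10,
                       qtls_per_locus = c(5, 10),
                       population_mix = c(F2 = 0.3, BC = 0.2, RIL = 0.3,
                                          DH = 0.2),
                       n_range = c(100, 300),
                       s_range = c(0.5, 2),
                       marker_spacing_cm = 5,
                       marker_jitter_sd = 0.25,
                       marker_drop_prob = 0.1,
                       n_control_qtls = 2,
                       n_mta_panels = 7,
                       snps_per_panel = 200,
                       mta_planted_fraction = 0.5,
                       mtas_per_window = c(1, 2),
                       n_candidates = 8,
                       decoys_per_class = 3,
                       n_background_genes = 10,
                       gene_len_bp = 3000,
                       expression_noise_sd = 0.3,
                       half_window_bp = 500000) {
  if (is.null(true_mqtls))
    true_mqtls <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ch)
      data.frame(chr = ch, cm = chrom_len_cm * c(1, 3, 5) / 6)))
  true_mqtls <- true_mqtls[order(true_mqtls$chr, true_mqtls$cm), ,
                           drop = FALSE]
  for (ch in unique(true_mqtls$chr)) {
    pos <- true_mqtls$cm[true_mqtls$chr == ch]
    if (length(pos) > 1 && min(diff(sort(pos))) < min_locus_sep_cm)
      mq_value_error(sprintf(
        "planted loci on chr %d closer than %g cM", ch, min_locus_sep_cm))
    if (any(pos <= 0 | pos >= chrom_len_cm))
      mq_value_error("planted loci must lie strictly inside the chromosome")
  }
  true_mqtls$locus_id <- sprintf(
    "L%d.%d", as.integer(true_mqtls$chr),
    as.integer(stats::ave(true_mqtls$cm, true_mqtls$chr, FUN = seq_along)))
  true_mqtls$anchor_bp <- pmax(1, round(true_mqtls$cm * bp_per_cm))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Truth physical windows of the planted loci
#'
#' @param cfg A `sim_config`.
#' @return `data.frame` `locus_id chr cm anchor_bp start_bp end_bp`.
#' @export
true_windows <- function(cfg) {
  tw <- cfg$true_mqtls
  tw$start_bp <- pmax(1, tw$anchor_bp - cfg$half_window_bp)
  tw$end_bp <- pmin(cfg$chrom_len_cm * cfg$bp_per_cm,
                    tw$anchor_bp + cfg$half_window_bp)
  tw
}

sim_trait_pool <- c(
  "root length", "root number", "root dry weight", "panicle number",
  "spikelet fertility", "grain yield", "plant height", "leaf rolling",
  "relative water content", "shoot biomass", "tiller number",
  "germination rate", "flowering time", "osmotic adjustment",
  "harvest index")

# draw a (population type, N, R^2) triple whose formula CI width equals
# 3.92 * s for a drawn s in s_range
draw_population <- function(cfg, mapping = ci_formula_map()) {
  for (try in 1:500) {
    pt <- sample(names(cfg$population_mix), 1, prob = cfg$population_mix)
    n <- sample_range(cfg$n_range[1], cfg$n_range[2])
    s <- runif(1, cfg$s_range[1], cfg$s_range[2])
    width <- 3.92 * s
    r2 <- switch(unname(mapping[pt]),
                 f2 = 530 / (n * width),
                 ril = 163 / (n * width),
                 dh = (97.462 / width)^(1 / 0.835) / n)
    if (r2 > 0.005 && r2 <= 1)
      return(list(pop_type = pt, pop_size = n, s = s, width = width,
                  r2 = r2))
  }
  mq_value_error("could not draw a feasible (population, N, R^2) triple")
}

#' Simulate a multi-study QTL panel
#'
#' Generates per-study genetic maps sharing jittered anchor markers, and a
#' QTL compendium in which each QTL's peak is drawn
#' `Normal(true locus, s^2)` with `s` implied by its formula-derived CI.
#' A few well-watered-control rows are appended to exercise the reader's
#' condition filter.
#'
#' @param cfg A `sim_config`.
#' @return List: `qtls` (compendium `data.frame`, canonical columns),
#'   `maps` (per-study map table), `anchors` (marker physical anchors),
#'   `studies` (study metadata), `truth` (`data.frame` `qtl_id locus_id
#'   chr true_cm`).
#' @export
simulate_qtl_panel <- function(cfg) {
  set.seed(cfg$seed)
  base_markers <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes),
    function(ch) {
      pos <- seq(0, cfg$chrom_len_cm, by = cfg$marker_spacing_cm)
      data.frame(chr = ch, marker = sprintf("M%d_%03d", ch, seq_along(pos)),
                 cm = pos, stringsAsFactors = FALSE)
    }))
  study_ids <- sprintf("S%02d", seq_len(cfg$n_studies))
  maps <- list()
  for (sid in study_ids) {
    mm <- base_markers
    n_int <- nrow(mm)
    interior <- !(mm$cm %in% c(0, cfg$chrom_len_cm))
    drop <- interior & runif(n_int) < cfg$marker_drop_prob
    mm <- mm[!drop, , drop = FALSE]
    mm$position_cM <- mm$cm + rnorm(nrow(mm), 0, cfg$marker_jitter_sd)
    mm <- mm[order(mm$chr, mm$position_cM), ]
    maps[[sid]] <- data.frame(map_id = paste0("map_", sid), chr = mm$chr,
                              marker = mm$marker,
                              position_cm = mm$position_cM,
                              stringsAsFactors = FALSE)
  }
  maps_df <- do.call(rbind, c(maps, list(make.row.names = FALSE)))

  loci <- cfg$true_mqtls
  qtl_rows <- list(); truth <- list()
  qn <- 0L
  for (li in seq_len(nrow(loci))) {
    n_q <- sample_range(cfg$qtls_per_locus[1], cfg$qtls_per_locus[2])
    for (j in seq_len(n_q)) {
      qn <- qn + 1L
      sid <- sample(study_ids, 1)
      smap <- maps[[sid]]
      smap <- smap[smap$chr == loci$chr[li], , drop = FALSE]
      pop <- draw_population(cfg)
      peak <- rnorm(1, loci$cm[li], pop$s)
      peak <- min(max(peak, 0.5), cfg$chrom_len_cm - 0.5)
      below <- smap$marker[smap$position_cm <= peak]
      above <- smap$marker[smap$position_cm >= peak]
      ml <- if (length(below) > 0) tail(below, 1) else head(smap$marker, 1)
      mr <- if (length(above) > 0) head(above, 1) else tail(smap$marker, 1)
      report_ci <- runif(1) < 0.7
      qtl_rows[[qn]] <- data.frame(
        qtl_id = sprintf("Q%04d", qn), study_id = sid,
        trait = sample(sim_trait_pool, 1), chr = loci$chr[li],
        peak_cm = peak,
        ci_low_cm = if (report_ci) peak - pop$width / 2 else NA_real_,
        ci_high_cm = if (report_ci) peak + pop$width / 2 else NA_real_,
        lod = round(runif(1, 1.6, 12), 2), pve = pop$r2,
        pop_type = pop$pop_type, pop_size = pop$pop_size,
        marker_left = ml, marker_right = mr,
        map_id = paste0("map_", sid), condition = "drought",
        stringsAsFactors = FALSE)
      truth[[qn]] <- data.frame(qtl_id = sprintf("Q%04d", qn),
                                locus_id = loci$locus_id[li],
                                chr = loci$chr[li], true_cm = loci$cm[li],
                                stringsAsFactors = FALSE)
    }
  }
  qtls <- do.call(rbind, qtl_rows)
  # well-watered-control rows the reader must drop
  if (cfg$n_control_qtls > 0) {
    ctrl <- qtls[sample(nrow(qtls), min(cfg$n_control_qtls, nrow(qtls))), ]
    ctrl$qtl_id <- sprintf("QC%03d", seq_len(nrow(ctrl)))
    ctrl$condition <- "control"
    qtls <- rbind(qtls, ctrl)
  }
  qtls <- qtls[order(qtls$chr, qtls$peak_cm), ]
  rownames(qtls) <- NULL
  anchors <- data.frame(marker = base_markers$marker,
                        chr = base_markers$chr,
                        position_bp = pmax(1, round(base_markers$cm *
                                                      cfg$bp_per_cm)),
                        stringsAsFactors = FALSE)
  studies <- data.frame(study_id = study_ids,
                        map_id = paste0("map_", study_ids),
                        stringsAsFactors = FALSE)
  list(qtls = qtls, maps = maps_df, anchors = anchors, studies = studies,
       truth = do.call(rbind, truth))
}

#' Simulate GWAS marker-trait associations
#'
#' Plants significant SNPs (`-log10 p >= 5`) inside a configured fraction
#' of the supplied truth windows and scatters sub-threshold background
#' SNPs over the panels.
#'
#' @param cfg A `sim_config`.
#' @param windows Truth windows ([true_windows()]).
#' @return List: `mtas` (MTA `data.frame`), `truth` (planted window ids).
#' @export
simulate_mtas <- function(cfg, windows) {
  set.seed(cfg$seed + 1L)
  n_planted <- round(cfg$mta_planted_fraction * nrow(windows))
  planted <- if (n_planted > 0)
    sort(sample(nrow(windows), n_planted)) else integer(0)
  rows <- list()
  sn <- 0L
  panels <- sprintf("panel%d", seq_len(cfg$n_mta_panels))
  for (wi in planted) {
    k <- sample_range(cfg$mtas_per_window[1], cfg$mtas_per_window[2])
    for (j in seq_len(k)) {
      sn <- sn + 1L
      pos <- round(runif(1, windows$anchor_bp[wi] - 0.6 * cfg$half_window_bp,
                         windows$anchor_bp[wi] + 0.6 * cfg$half_window_bp))
      rows[[sn]] <- data.frame(
        snp_id = sprintf("snp_p%04d", sn), chr = windows$chr[wi],
        position_bp = max(1, pos), neg_log10_p = runif(1, 5, 9),
        trait = sample(sim_trait_pool, 1),
        panel_id = sample(panels, 1), stringsAsFactors = FALSE)
    }
  }
  chrom_len_bp <- cfg$chrom_len_cm * cfg$bp_per_cm
  bg <- 0L
  for (p in panels) {
    for (j in seq_len(cfg$snps_per_panel)) {
      bg <- bg + 1L
      rows[[sn + bg]] <- data.frame(
        snp_id = sprintf("snp_b%05d", bg),
        chr = sample(cfg$n_chromosomes, 1),
        position_bp = sample(chrom_len_bp, 1),
        neg_log10_p = runif(1, 0.1, 4.9),
        trait = sample(sim_trait_pool, 1), panel_id = p,
        stringsAsFactors = FALSE)
    }
  }
  mtas <- do.call(rbind, rows)
  rownames(mtas) <- NULL
  list(mtas = mtas, truth = windows$locus_id[planted])
}

# promoter genomic region for a simulated gene (same rule the extractor
# applies)
sim_promoter_region <- function(strand, tss, atg, utr5) {
  up <- if (utr5 > 100) 1500 else 2000
  if (strand == "+") c(atg - up, tss) else c(tss, atg + up)
}

# mutate every occurrence of the patterns out of chrom[lo..hi]
sanitize_region <- function(chrom, lo, hi, patterns = c("ACGTG", "CACGT")) {
  for (pass in 1:25) {
    seg <- substr(chrom, lo, hi)
    found <- FALSE
    for (pat in patterns) {
      hits <- gregexpr(pat, seg, fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      found <- TRUE
      for (h in hits) {
        pos <- lo + h - 1L + 2L  # centre base of the 5-mer
        cur <- substr(chrom, pos, pos)
        repl <- if (cur == "T") "A" else "T"
        substr(chrom, pos, pos) <- repl
      }
    }
    if (!found) return(chrom)
  }
  chrom
}

#' Simulate a genome, gene models and expression data
#'
#' Places planted candidate genes inside the truth windows and decoy genes
#' that each violate exactly one funnel condition; writes a consistent
#' genome (with ABRE elements planted in, or scrubbed from, promoters),
#' DE statistics and a two-genotype, three-timepoint expression table with
#' the mutant-up / wild-type-down signature for the planted candidates.
#'
#' @param cfg A `sim_config`.
#' @param windows Truth windows ([true_windows()]).
#' @return List: `genome` (`DNAStringSet`), `genes` (gene-model table with
#'   `class` column), `deg_stats`, `expression`, `truth` (list with
#'   `decgs`, `classes`).
#' @export
simulate_genome_and_expression <- function(cfg, windows) {
  set.seed(cfg$seed + 2L)
  chrom_len_bp <- round(cfg$chrom_len_cm * cfg$bp_per_cm)
  chroms <- lapply(seq_len(cfg$n_chromosomes), function(ch)
    paste(sample(c("A", "C", "G", "T"), chrom_len_bp, replace = TRUE),
          collapse = ""))
  names(chroms) <- as.character(seq_len(cfg$n_chromosomes))

  classes <- c(rep("candidate", cfg$n_candidates),
               rep("inwindow_nondeg", cfg$decoys_per_class),
               rep("outwindow_deg", cfg$decoys_per_class),
               rep("no_abre", cfg$decoys_per_class),
               rep("no_signature", cfg$decoys_per_class),
               rep("background", cfg$n_background_genes))
  in_window <- classes %in% c("candidate", "inwindow_nondeg", "no_abre",
                              "no_signature")
  genes <- list()
  margin <- cfg$gene_len_bp + 2200
  win_of <- rep(NA_integer_, length(classes))
  wi_cycle <- rep(seq_len(nrow(windows)), length.out = sum(in_window))
  cyc <- 0L
  for (i in seq_along(classes)) {
    if (in_window[i]) {
      cyc <- cyc + 1L
      wi <- wi_cycle[cyc]
      win_of[i] <- wi
      ch <- windows$chr[wi]
      pos <- round(windows$anchor_bp[wi] + runif(1, -200000, 200000))
    } else {
      # keep clear of every window by > 1.5x the half-window
      repeat {
        ch <- sample(cfg$n_chromosomes, 1)
        pos <- round(runif(1, margin, chrom_len_bp - margin))
        anch <- windows$anchor_bp[windows$chr == ch]
        if (length(anch) == 0 ||
            min(abs(anch - pos)) > 1.5 * cfg$half_window_bp + margin) break
      }
    }
    pos <- min(max(pos, margin), chrom_len_bp - margin)
    strand <- sample(c("+", "-"), 1)
    utr5 <- sample(c(50, 150), 1)
    start <- pos; end <- pos + cfg$gene_len_bp - 1L
    tss <- if (strand == "+") start else end
    atg <- if (strand == "+") start + utr5 else end - utr5
    genes[[i]] <- data.frame(
      gene_id = sprintf("gene%03d", i), chr = ch, start_bp = start,
      end_bp = end, strand = strand, tss_bp = tss, atg_bp = atg,
      utr5_len = utr5, class = classes[i], stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)

  # plant or scrub the ABRE core (ACGTG) in each promoter
  needs_abre <- genes$class %in% c("candidate", "inwindow_nondeg",
                                   "outwindow_deg", "no_signature")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    reg <- sim_promoter_region(g$strand, g$tss_bp, g$atg_bp, g$utr5_len)
    key <- as.character(g$chr)
    if (needs_abre[i]) {
      mid <- round(mean(reg)) - 2L
      substr(chroms[[key]], mid, mid + 4L) <- "ACGTG"
    } else {
      chroms[[key]] <- sanitize_region(chroms[[key]], reg[1], reg[2])
    }
  }

  # DE statistics: every gene appears in the genotype contrast; the
  # planted candidates also in the time-course contrast (union semantics)
  is_deg <- genes$class %in% c("candidate", "outwindow_deg", "no_abre",
                               "no_signature")
  deg_rows <- list()
  for (i in seq_len(nrow(genes))) {
    if (is_deg[i]) {
      lfc <- runif(1, 1.2, 3) *
        (if (genes$class[i] == "no_signature") -1 else 1)
      fdr <- runif(1, 1e-4, 0.04)
    } else {
      lfc <- runif(1, -0.6, 0.6)
      fdr <- runif(1, 0.1, 0.9)
    }
    deg_rows[[i]] <- data.frame(gene_id = genes$gene_id[i], log2fc = lfc,
                                fdr = fdr, contrast = "mutant_vs_wildtype",
                                stringsAsFactors = FALSE)
  }
  cand <- which(genes$class == "candidate")
  extra <- lapply(cand, function(i)
    data.frame(gene_id = genes$gene_id[i], log2fc = runif(1, 1.2, 3),
               fdr = runif(1, 1e-4, 0.04), contrast = "mutant_timecourse",
               stringsAsFactors = FALSE))
  deg_stats <- do.call(rbind, c(deg_rows, extra))

  # expression profiles: class-specific genotype x time shapes + noise
  shapes <- list(
    signature = list(mutant = c(0, 1, 2), wildtype = c(0, -1, -2)),
    inverse   = list(mutant = c(0, -1, -2), wildtype = c(0, 1, 2)),
    bothup    = list(mutant = c(0, 1, 2), wildtype = c(0, 1, 2)),
    bothdown  = list(mutant = c(0, -1, -2), wildtype = c(0, -1, -2)),
    flat      = list(mutant = c(0, 0, 0), wildtype = c(0, 0, 0)))
  shape_of <- function(cls, i) switch(
    cls,
    candidate = "signature", no_abre = "signature",
    inwindow_nondeg = "signature", outwindow_deg = "signature",
    no_signature = c("inverse", "bothup", "bothdown")[(i %% 3) + 1],
    background = c("bothup", "bothdown", "flat")[(i %% 3) + 1])
  tps <- c(0, 3, 6)
  expr_rows <- list(); en <- 0L
  for (i in seq_len(nrow(genes))) {
    sh <- shapes[[shape_of(genes$class[i], i)]]
    base <- runif(1, 10, 40)
    amp <- runif(1, 1.5, 2.5)
    for (gt in c("mutant", "wildtype")) {
      for (ti in seq_along(tps)) {
        for (rep_i in 1:3) {
          en <- en + 1L
          val <- base + amp * sh[[gt]][ti] +
            rnorm(1, 0, cfg$expression_noise_sd)
          expr_rows[[en]] <- data.frame(
            gene_id = genes$gene_id[i], genotype = gt, timepoint = tps[ti],
            replicate = rep_i, fpkm = max(0, val), stringsAsFactors = FALSE)
        }
      }
    }
  }
  expression <- do.call(rbind, expr_rows)
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  list(genome = genome, genes = genes, deg_stats = deg_stats,
       expression = expression,
       truth = list(decgs = genes$gene_id[genes$class == "candidate"],
                    classes = setNames(genes$class, genes$gene_id)))
}

#' Write a gene-model table as GFF3
#'
#' Writes `gene` features (attribute `ID`) and a `five_prime_UTR` feature
#' per gene (attribute `Parent`) so [read_gene_models()] round-trips the
#' models.
#'
#' @param genes Gene-model table (as from
#'   [simulate_genome_and_expression()]).
#' @param path Output GFF3 path.
#' @return The path, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  g1 <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chr),
    ranges = IRanges::IRanges(genes$start_bp, genes$end_bp),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  utr_start <- ifelse(genes$strand == "+", genes$tss_bp,
                      genes$atg_bp + 1)
  utr_end <- ifelse(genes$strand == "+", genes$atg_bp - 1, genes$tss_bp)
  g2 <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chr),
    ranges = IRanges::IRanges(utr_start, utr_end),
    strand = genes$strand, type = "five_prime_UTR",
    Parent = genes$gene_id)
  gr <- c(g1, g2)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a complete simulated input bundle
#'
#' Generates every pipeline input under one directory:
#' `qtl_table.tsv`, `maps.tsv`, `anchors.tsv`, `mtas.tsv`, `genome.fa`,
#' `genes.gff3`, `deg_stats.tsv`, `expression.tsv` and `truth.json`.
#'
#' @param cfg A `sim_config`.
#' @param dir Output directory (created if absent).
#' @return Named list of file paths plus the in-memory `truth` list,
#'   invisibly.
#' @export
write_input_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_qtl_panel(cfg)
  tw <- true_windows(cfg)
  mta <- simulate_mtas(cfg, tw)
  gex <- simulate_genome_and_expression(cfg, tw)
  paths <- list(
    qtl_table = file.path(dir, "qtl_table.tsv"),
    maps = file.path(dir, "maps.tsv"),
    anchors = file.path(dir, "anchors.tsv"),
    mtas = file.path(dir, "mtas.tsv"),
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    deg_stats = file.path(dir, "deg_stats.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"))
  write_qtl_table(panel$qtls, paths$qtl_table)
  write_tsv(data.frame(map_id = panel$maps$map_id, chr = panel$maps$chr,
                       marker = panel$maps$marker,
                       position_cM = panel$maps$position_cm),
            paths$maps)
  write_tsv(panel$anchors, paths$anchors)
  write_tsv(mta$mtas, paths$mtas)
  Biostrings::writeXStringSet(gex$genome, paths$genome)
  write_gene_models(gex$genes, paths$genes)
  write_tsv(gex$deg_stats, paths$deg_stats)
  write_tsv(gex$expression, paths$expression)
  truth <- list(loci = cfg$true_mqtls, qtls = panel$truth,
                mta_planted = mta$truth, decgs = gex$truth$decgs,
                gene_classes = as.list(gex$truth$classes))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, list(truth_data = truth)))
}
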