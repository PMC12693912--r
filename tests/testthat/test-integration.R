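test_that("FPKM formula, linearity and scaling laws hold", {
  expect_equal(compute_fpkm(0, 1e6, 1000), 0)
  expect_equal(compute_fpkm(100, 1e6, 1000), 100)
  cs <- c(1, 10, 250, 10000)
  expect_equal(compute_fpkm(2 * cs, 1e6, 500), 2 * compute_fpkm(cs, 1e6, 500))
  ls <- c(200, 1000, 5000)
  expect_equal(compute_fpkm(100, 1e6, 2 * ls),
               compute_fpkm(100, 1e6, ls) / 2)
  expect_error(compute_fpkm(10, 0, 100), "must be > 0")
  expect_error(compute_fpkm(-1, 1e6, 100), ">= 0")
})

test_that("DEG filter is inclusive on fold change, strict on FDR", {
  st <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   log2fc = c(1.0, 0.99, -2.0, 1.5),
                   fdr = c(0.049, 0.001, 0.05, 0.01),
                   contrast = "c1")
  expect_setequal(filter_degs(st), c("g1", "g4"))
  # union across contrasts
  st2 <- rbind(st, data.frame(gene_id = "g2", log2fc = -3, fdr = 0.001,
                              contrast = "c2"))
  expect_setequal(filter_degs(st2), c("g1", "g2", "g4"))
})

test_that("gene-window overlap follows the any-overlap rule and the oracle", {
  w <- data.frame(mqtl_id = "W1", chr = 1L, start_bp = 1000, end_bp = 2000)
  g <- data.frame(gene_id = c("inside", "edge", "outside", "spanning"),
                  chr = 1L, start_bp = c(1200, 2000, 2001, 500),
                  end_bp = c(1800, 2500, 3000, 2500))
  gw <- genes_in_windows(g, w)
  expect_setequal(gw$gene_id, c("inside", "edge", "spanning"))
  gw_full <- genes_in_windows(g, w, containment = "full")
  expect_equal(gw_full$gene_id, "inside")
  set.seed(21)
  n_g <- 500; n_w <- 40
  rg <- data.frame(gene_id = sprintf("g%03d", 1:n_g),
                   chr = sample(1:3, n_g, replace = TRUE),
                   start_bp = sample(1:2e6, n_g, replace = TRUE))
  rg$end_bp <- rg$start_bp + sample(500:5000, n_g, replace = TRUE)
  rw <- data.frame(mqtl_id = sprintf("w%02d", 1:n_w),
                   chr = sample(1:3, n_w, replace = TRUE),
                   start_bp = sample(1:2e6, n_w, replace = TRUE))
  rw$end_bp <- rw$start_bp + sample(1e4:2e5, n_w, replace = TRUE)
  got <- genes_in_windows(rg, rw)
  want <- oracle_genes_in_windows(rg, rw)
  key <- function(d) sort(paste(d$gene_id, d$mqtl_id))
  expect_equal(key(got), key(want))
})

test_that("fuzzy c-means memberships are proper and the objective never rises", {
  set.seed(3)
  x <- rbind(matrix(rnorm(60, 0, 0.2), 20, 3) +
               matrix(rep(c(-1, 0, 1), each = 20), 20, 3),
             matrix(rnorm(60, 0, 0.2), 20, 3) +
               matrix(rep(c(1, 0, -1), each = 20), 20, 3))
  rownames(x) <- sprintf("g%02d", 1:40)
  cl <- fuzzy_cmeans(x, c = 2, seed = 5)
  expect_equal(unname(rowSums(cl$memberships)), rep(1, 40),
               tolerance = 1e-9)
  expect_true(all(diff(cl$objective) <= 1e-8))
  truth <- rep(1:2, each = 20)
  labels <- max.col(cl$memberships)
  expect_gte(adjusted_rand_index(truth, labels), 0.9)
})

test_that("fuzzy c-means degenerate cases follow the conventions", {
  x <- matrix(c(0, 1, 2, 4, 5, 6), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  cl1 <- fuzzy_cmeans(x, c = 1, seed = 1)
  expect_equal(as.numeric(cl1$centers), colMeans(x))
  expect_equal(as.numeric(cl1$memberships), c(1, 1))
  # a point coincident with a center gets membership 1 there
  y <- rbind(x, a2 = x[1, ], b2 = x[2, ])
  cl2 <- fuzzy_cmeans(y, c = 2, seed = 2)
  expect_lt(cl2$n_iter, 500)
  coincident <- which.min(rowSums((cl2$centers -
    matrix(y["a2", ], 2, 3, byrow = TRUE))^2))
  expect_equal(unname(cl2$memberships["a2", coincident]), 1)
  expect_error(fuzzy_cmeans(x, c = 5), "more clusters")
})

test_that("fuzzy c-means agrees with the e1071 reference on separated groups", {
  skip_if_not_installed("e1071")
  set.seed(9)
  x <- rbind(matrix(rnorm(90, 0, 0.3), 30, 3) +
               matrix(rep(c(-2, 0, 2), each = 30), 30, 3),
             matrix(rnorm(90, 0, 0.3), 30, 3) +
               matrix(rep(c(2, 0, -2), each = 30), 30, 3))
  rownames(x) <- sprintf("g%02d", 1:60)
  ours <- fuzzy_cmeans(x, c = 2, m = 2, seed = 4)
  ref <- e1071::cmeans(x, centers = 2, m = 2)
  ref_lab <- as.integer(ref$cluster)
  our_lab <- max.col(ours$memberships)
  expect_gte(adjusted_rand_index(ref_lab, our_lab), 0.99)
  # centers agree up to label permutation
  perm <- if (sum((ours$centers[1, ] - ref$centers[1, ])^2) <
              sum((ours$centers[1, ] - ref$centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(ours$centers), unname(ref$centers[perm, ]),
               tolerance = 0.05)
})

test_that("signature-cluster selection honors the slope sign constraints", {
  layout <- data.frame(genotype = rep(c("mutant", "wildtype"), each = 3),
                       timepoint = rep(c(0, 3, 6), 2))
  mk_profiles <- function(mat) {
    attr(mat, "layout") <- layout
    mat
  }
  # two clusters: one signature-shaped, one inverse
  sig <- c(-1, 0, 1, 1, 0, -1)
  inv <- -sig
  x <- rbind(matrix(rep(sig, 10), 10, 6, byrow = TRUE),
             matrix(rep(inv, 10), 10, 6, byrow = TRUE))
  rownames(x) <- sprintf("g%02d", 1:20)
  x <- x + matrix(rnorm(120, 0, 0.05), 20, 6)
  cl <- fuzzy_cmeans(mk_profiles(x), c = 2, seed = 6)
  pick <- select_signature_cluster(cl, mk_profiles(x))
  expect_setequal(pick$genes, sprintf("g%02d", 1:10))
  expect_gt(pick$slopes$mutant_slope[pick$cluster], 0)
  expect_lt(pick$slopes$wildtype_slope[pick$cluster], 0)
  # all-flat profiles: sign constraints fail, empty result with warning
  flat <- matrix(rnorm(60, 0, 1e-3), 10, 6,
                 dimnames = list(sprintf("f%d", 1:10), NULL))
  clf <- fuzzy_cmeans(mk_profiles(flat), c = 1, seed = 7)
  expect_warning(res <- select_signature_cluster(clf, mk_profiles(flat)),
                 "no cluster")
  expect_equal(res$genes, character(0))
})

test_that("promoter extraction follows the 2000/1500 bp UTR rule", {
  genome <- Biostrings::DNAStringSet(setNames(random_dna(20000, seed = 2),
                                              "1"))
  g <- data.frame(gene_id = "gA", chr = 1L, start_bp = 9950,
                  end_bp = 12949, strand = "+", tss_bp = 9950,
                  atg_bp = 10000, utr5_len = 50)
  p <- extract_promoter(g, genome)
  expect_equal(unname(attr(p, "region")), c(8000, 9950))
  expect_equal(as.character(p),
               as.character(Biostrings::subseq(genome[["1"]], 8000, 9950)))
  # 5'UTR over 100 bp: 1500-bp branch
  g$utr5_len <- 101; g$tss_bp <- 9899; g$atg_bp <- 10000
  p2 <- extract_promoter(g, genome)
  expect_equal(unname(attr(p2, "region")), c(8500, 9899))
  # minus strand: mirrored coordinates, reverse complement
  gm <- data.frame(gene_id = "gB", chr = 1L, start_bp = 3000,
                   end_bp = 5999, strand = "-", tss_bp = 5999,
                   atg_bp = 5949, utr5_len = 50)
  pm <- extract_promoter(gm, genome)
  expect_equal(unname(attr(pm, "region")), c(5999, 7949))
  expect_equal(as.character(pm), as.character(
    Biostrings::reverseComplement(
      Biostrings::subseq(genome[["1"]], 5999, 7949))))
  # clipping at the sequence start warns
  gc <- data.frame(gene_id = "gC", chr = 1L, start_bp = 280,
                   end_bp = 3279, strand = "+", tss_bp = 280,
                   atg_bp = 300, utr5_len = 20)
  expect_warning(pc <- extract_promoter(gc, genome), "clipped")
  expect_equal(unname(attr(pc, "region")), c(1, 280))
  expect_error(extract_promoter(transform(g, chr = 9), genome),
               "absent")
})

test_that("gene models round-trip through GFF3", {
  cfg <- sim_config(seed = 23, n_chromosomes = 1, chrom_len_cm = 40,
                    true_mqtls = data.frame(chr = 1, cm = c(10, 25)),
                    n_candidates = 3, decoys_per_class = 1,
                    n_background_genes = 2)
  gex <- simulate_genome_and_expression(cfg, true_windows(cfg))
  tf <- tempfile(fileext = ".gff3")
  write_gene_models(gex$genes, tf)
  back <- read_gene_models(tf)
  ord <- match(gex$genes$gene_id, back$gene_id)
  expect_equal(back$start_bp[ord], gex$genes$start_bp)
  expect_equal(back$strand[ord], gex$genes$strand)
  expect_equal(back$utr5_len[ord], gex$genes$utr5_len)
  expect_equal(back$tss_bp[ord], gex$genes$tss_bp)
  expect_equal(back$atg_bp[ord], gex$genes$atg_bp)
})

test_that("CRE scanning matches known motifs and the sliding-window oracle", {
  motifs <- load_cre_motifs()
  # G-box core
  hits <- scan_cres("CACGTG", motifs)
  expect_true(any(hits$motif == "Gbox" & hits$start == 1 &
                    hits$strand == "+"))
  # palindrome: also reported on the minus strand
  expect_true(any(hits$motif == "Gbox" & hits$strand == "-"))
  expect_equal(nrow(scan_cres("", motifs)), 0L)
  # N never matches, even degenerate positions
  expect_equal(nrow(scan_cres("CANNTG", motifs[motifs$name == "MYC", ])),
               0L)
  expect_gt(nrow(scan_cres("CAGATG", motifs[motifs$name == "MYC", ])), 0)
  # oracle equivalence on random sequences
  set.seed(14)
  for (i in 1:5) {
    s <- random_dna(2000)
    got <- scan_cres(s, motifs)
    want <- oracle_scan(s, motifs)
    expect_equal(got, want)
  }
  # strand symmetry: scanning the reverse complement swaps strands
  s <- random_dna(1500, seed = 15)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  fwd <- scan_cres(s, motifs)
  rev <- scan_cres(rc, motifs)
  expect_equal(nrow(fwd[fwd$strand == "+", ]),
               nrow(rev[rev$strand == "-", ]))
  expect_equal(nrow(fwd[fwd$strand == "-", ]),
               nrow(rev[rev$strand == "+", ]))
  tf <- tempfile(); writeLines(c("name\tiupac", "bad\tACXT"), tf)
  expect_error(load_cre_motifs(tf), "invalid IUPAC")
})

test_that("DECG screening requires the signature cluster AND the element", {
  motifs <- load_cre_motifs()
  proms <- Biostrings::DNAStringSet(c(
    with_abre = paste0(random_dna(200, seed = 31), "ACGTG",
                       random_dna(200)),
    no_abre = gsub("ACGTG|CACGT", "AAAAA",
                   random_dna(500, seed = 32))))
  out <- screen_decgs(c("with_abre", "no_abre"), proms, motifs)
  expect_equal(out$gene_id, "with_abre")
  expect_gte(out$n_required_hits, 1L)
  # not in the signature cluster -> never screened in
  out2 <- screen_decgs("no_abre", proms, motifs)
  expect_equal(nrow(out2), 0L)
  expect_error(screen_decgs("g", proms, motifs, required_motif = "XXX"),
               "not in catalog")
})

test_that("motif enrichment flags a heavily planted element", {
  motifs <- load_cre_motifs()[c(1, 6), ]  # ABRE, Wbox
  set.seed(41)
  proms <- Biostrings::DNAStringSet(setNames(
    vapply(1:20, function(i)
      paste0(substr(random_dna(300), 1, 140), "ACGTG", random_dna(140),
             collapse = ""), character(1)),
    sprintf("p%d", 1:20)))
  enr <- cre_enrichment(proms, motifs, n_shuffle = 30, seed = 2)
  expect_equal(enr$n_with_hit[enr$motif == "ABRE"], 20L)
  expect_lt(enr$p_value[enr$motif == "ABRE"], 0.05)
})
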