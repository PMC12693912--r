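# independent oracles used by the tests; deliberately naive implementations

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# sliding-window IUPAC matcher: position-by-position set membership;
# subject N matches nothing
oracle_scan_one <- function(seq_chars, iupac) {
  pat <- strsplit(iupac, "")[[1]]
  w <- length(pat)
  L <- length(seq_chars)
  if (w > L) return(integer(0))
  ok <- rep(TRUE, L - w + 1L)
  for (j in seq_len(w)) {
    ok <- ok & seq_chars[j:(L - w + j)] %in% iupac_sets[[pat[j]]]
  }
  which(ok)
}

oracle_scan <- function(sequence, motifs, both_strands = TRUE) {
  chars <- strsplit(as.character(sequence), "")[[1]]
  out <- list()
  for (i in seq_len(nrow(motifs))) {
    fwd <- oracle_scan_one(chars, motifs$iupac[i])
    if (length(fwd) > 0)
      out[[length(out) + 1L]] <- data.frame(motif = motifs$name[i],
                                            start = fwd, strand = "+")
    if (both_strands) {
      rev <- oracle_scan_one(chars, revcomp_chr(motifs$iupac[i]))
      if (length(rev) > 0)
        out[[length(out) + 1L]] <- data.frame(motif = motifs$name[i],
                                              start = rev, strand = "-")
    }
  }
  if (length(out) == 0)
    return(data.frame(motif = character(0), start = integer(0),
                      strand = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif, res$strand), ]
  rownames(res) <- NULL
  res
}

# brute-force window x SNP co-localization counts
oracle_colocalize_counts <- function(windows, mtas, threshold) {
  counts <- integer(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    k <- 0L
    for (j in seq_len(nrow(mtas))) {
      if (mtas$chr[j] == windows$chr[i] &&
          mtas$position_bp[j] >= windows$start_bp[i] &&
          mtas$position_bp[j] <= windows$end_bp[i] &&
          mtas$neg_log10_p[j] >= threshold)
        k <- k + 1L
    }
    counts[i] <- k
  }
  counts
}

# brute-force gene/window overlap map (any-overlap rule)
oracle_genes_in_windows <- function(genes, windows) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(windows))) {
      if (genes$chr[i] == windows$chr[j] &&
          genes$start_bp[i] <= windows$end_bp[j] &&
          genes$end_bp[i] >= windows$start_bp[j])
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = genes$gene_id[i], mqtl_id = windows$mqtl_id[j])
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene_id = character(0), mqtl_id = character(0)))
  do.call(rbind, rows)
}

# mixture log-likelihood with known per-observation sds
oracle_loglik <- function(x, s, mu, pi_k) {
  sum(vapply(seq_along(x), function(i)
    log(sum(pi_k * dnorm(x[i], mu, s[i]))), numeric(1)))
}

# dense grid search over (mu1, mu2, pi) for the K = 2 mixture
oracle_grid_k2 <- function(x, s, n_mu = 81, n_pi = 19) {
  mus <- seq(min(x), max(x), length.out = n_mu)
  pis <- seq(0.05, 0.95, length.out = n_pi)
  best <- -Inf
  for (p in pis) {
    for (m1 in mus) {
      for (m2 in mus) {
        ll <- oracle_loglik(x, s, c(m1, m2), c(p, 1 - p))
        if (ll > best) best <- ll
      }
    }
  }
  best
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(v) sum(v * (v - 1) / 2)
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  n <- length(a)
  expected <- si * sj / (n * (n - 1) / 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
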